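# mRNA/protein separation.
#
# Curated networks often carry one node per gene product while the data
# observe transcripts.  Separating each qualifying product into an mRNA
# node (target of the transcriptional regulations) and a protein node
# (target of the post-translational regulations, source of all outgoing
# actions) removes the spurious inconsistencies that arise when a
# transcript-level observation is pinned to a node that behaves as a
# protein.

#' Split gene-product nodes into mRNA and protein nodes
#'
#' A node of kind `GENE_PRODUCT` or `PROTEIN` qualifies when it is the
#' target of at least one transcriptional regulation **or** its gene has
#' transcript-level data (`observed_transcripts`).  For each qualifying
#' node `X` (unless `mRNA_<gene>` already exists, which makes the transform
#' idempotent):
#'
#' * a node `mRNA_<gene>` of kind `MRNA` is created;
#' * every transcriptional in-edge of `X` is re-targeted to the mRNA node;
#' * an activating edge `mRNA_<gene> -> X` is added (more transcript tends
#'   to mean more protein);
#' * post-translational in-edges and all out-edges stay on `X`, whose kind
#'   becomes `PROTEIN` (the protein is the biochemical actor).
#'
#' Non-qualifying nodes are left untouched.  Two normalizations are applied
#' to the whole graph afterwards: every `COMPLEX` node receives an
#' activating post-translational in-edge from each constituent protein
#' (parsed from its colon-joined name; missing constituents are created),
#' and every edge between two protein-level nodes whose level is
#' unspecified is marked post-translational.  With a `splicing_map`,
#' several protein nodes of the same gene share one mRNA node.
#'
#' @param graph a [signed_graph()].
#' @param observed_transcripts character vector of gene names with
#'   transcript-level data (significant or not).
#' @param splicing_map optional named list `gene -> protein node names`;
#'   listed proteins are (re)assigned to that gene before splitting.
#' @return list with components `graph` (the modified [signed_graph()]) and
#'   `report` (list `split_genes`, `untouched`, `added_edges`).
#' @export
split_gene_products <- function(graph, observed_transcripts = character(),
                                splicing_map = NULL) {
  stopifnot(inherits(graph, "signed_graph"))
  nodes <- graph$nodes
  edges <- graph$edges

  if (!is.null(splicing_map)) {
    for (g in names(splicing_map)) {
      nodes$gene[nodes$name %in% splicing_map[[g]]] <- g
    }
  }

  bad <- edges$level == "transcriptional" &
    nodes$kind[match(edges$target, nodes$name)] %in% c("COMPLEX", "PHENOTYPE")
  if (any(bad)) {
    stop("transcriptional edge(s) target complex/phenotype node(s): ",
         paste(unique(edges$target[bad]), collapse = ", "), call. = FALSE)
  }

  splittable <- nodes$kind %in% c("GENE_PRODUCT", "PROTEIN")
  has_tr_in <- nodes$name %in%
    edges$target[edges$level == "transcriptional"]
  observed <- !is.na(nodes$gene) & nodes$gene %in% observed_transcripts
  mrna_name <- ifelse(is.na(nodes$gene), NA_character_,
                      paste0("mRNA_", nodes$gene))
  already <- !is.na(mrna_name) & mrna_name %in% nodes$name
  qualify <- splittable & (has_tr_in | observed) & !already

  new_nodes <- list()
  new_edges <- list()
  for (i in which(qualify)) {
    x <- nodes$name[i]
    mn <- mrna_name[i]
    # re-target transcriptional in-edges to the mRNA node
    retarget <- edges$target == x & edges$level == "transcriptional"
    edges$target[retarget] <- mn
    if (!(mn %in% vapply(new_nodes, function(z) z$name, character(1)))) {
      new_nodes[[length(new_nodes) + 1L]] <-
        data.frame(name = mn, kind = "MRNA", gene = nodes$gene[i],
                   stringsAsFactors = FALSE)
    }
    new_edges[[length(new_edges) + 1L]] <-
      data.frame(source = mn, target = x, sign = "+", level = "",
                 stringsAsFactors = FALSE)
    nodes$kind[i] <- "PROTEIN"
  }
  split_protein <- nodes$name[qualify]
  split_genes <- sort(unique(nodes$gene[qualify]), method = "radix")
  n_added <- length(new_edges)

  if (length(new_nodes)) {
    nn <- do.call(rbind, new_nodes)
    nn <- nn[!duplicated(nn$name), , drop = FALSE]
    nodes <- rbind(nodes, nn)
  }
  if (length(new_edges)) edges <- rbind(edges, do.call(rbind, new_edges))

  # complexes gain activating in-edges from their constituent proteins
  protein_kinds <- c("PROTEIN", "GENE_PRODUCT", "PHOSPHO_PROTEIN",
                     "FAMILY", "COMPLEX")
  for (cx in nodes$name[nodes$kind == "COMPLEX"]) {
    for (part in parse_complex_constituents(cx)) {
      if (!(part %in% nodes$name)) {
        nodes <- rbind(nodes, data.frame(
          name = part, kind = infer_node_kind(part),
          gene = infer_gene(part), stringsAsFactors = FALSE))
      }
      present <- any(edges$source == part & edges$target == cx)
      if (!present) {
        edges <- rbind(edges, data.frame(
          source = part, target = cx, sign = "+",
          level = "post_translational", stringsAsFactors = FALSE))
      }
    }
  }

  # protein-protein interactions default to post-translational
  src_k <- nodes$kind[match(edges$source, nodes$name)]
  tgt_k <- nodes$kind[match(edges$target, nodes$name)]
  pp <- edges$level == "" & src_k %in% protein_kinds & tgt_k %in% protein_kinds
  edges$level[pp] <- "post_translational"

  out <- signed_graph(edges, nodes[, c("name", "kind", "gene")])
  report <- list(
    split_genes = split_genes,
    untouched = sort(setdiff(graph$nodes$name, split_protein),
                     method = "radix"),
    added_edges = n_added
  )
  list(graph = out, report = report)
}

# "(A:B)" -> c("A", "B"), respecting nested parentheses as in
# "((CCNA.)_p:CDC2)".
parse_complex_constituents <- function(name) {
  inner <- sub("^\\((.*)\\)$", "\\1", name)
  chars <- strsplit(inner, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == ":" && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  trimws(mapply(function(s, e) paste(chars[s:e], collapse = ""),
                starts, ends))
}

#' Expand a family node into member nodes
#'
#' Replaces a `FAMILY` node by one node per member; each member inherits a
#' copy of every in- and out-edge of the family (same sign and level).
#' Family expansion is opt-in per node: the case-study network keeps its
#' family nodes, which aggregate interactions known for at least one
#' member.
#'
#' @param graph a [signed_graph()].
#' @param family_node name of a node of kind `FAMILY`.
#' @param members non-empty character vector of member node names.
#' @return the modified [signed_graph()].
#' @export
expand_family <- function(graph, family_node, members) {
  stopifnot(inherits(graph, "signed_graph"))
  i <- match(family_node, graph$nodes$name)
  if (is.na(i)) stop("unknown node '", family_node, "'", call. = FALSE)
  if (graph$nodes$kind[i] != "FAMILY") {
    stop("'", family_node, "' is not a FAMILY node", call. = FALSE)
  }
  if (!length(members)) stop("empty member list", call. = FALSE)
  edges <- graph$edges
  keep <- edges$source != family_node & edges$target != family_node
  inherited <- list()
  fam_e <- edges[!keep, , drop = FALSE]
  for (m in members) {
    e <- fam_e
    e$source[e$source == family_node] <- m
    e$target[e$target == family_node] <- m
    inherited[[m]] <- e
  }
  edges <- rbind(edges[keep, , drop = FALSE], do.call(rbind, inherited))
  nodes <- graph$nodes[-i, c("name", "kind", "gene"), drop = FALSE]
  nodes <- rbind(nodes, data.frame(name = members,
                                   kind = infer_node_kind(members),
                                   gene = infer_gene(members),
                                   stringsAsFactors = FALSE))
  signed_graph(edges, nodes[!duplicated(nodes$name), , drop = FALSE])
}
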