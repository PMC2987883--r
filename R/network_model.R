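#' Multiply two variation signs
#'
#' The sign algebra used throughout the package: an influence travelling
#' along an activating edge keeps the sign of its source, an influence
#' travelling along an inhibiting edge flips it.  Only the two definite
#' signs `"+"` and `"-"` participate; the dual edge label `"?"` is handled
#' at the constraint level (it contributes both signs) and is rejected here.
#'
#' @param a,b character vectors of `"+"`/`"-"` (recycled to common length).
#' @return character vector of `"+"`/`"-"`.
#' @examples
#' sign_product("+", "-")   # "-"
#' sign_product("-", "-")   # "+"
#' @export
sign_product <- function(a, b) {
  ok <- function(x) all(x %in% c("+", "-"))
  if (!ok(a) || !ok(b)) {
    stop("sign_product() is defined on {'+','-'} only", call. = FALSE)
  }
  ifelse(a == b, "+", "-")
}

#' Phenotype node lexicon
#'
#' Node names that denote phenotypic read-outs rather than molecular
#' species.  Used by [infer_node_kind()].
#'
#' @return character vector of node names.
#' @export
default_phenotypes <- function() {
  c("Apoptosis", "Cell_Migration", "Cell_Cycle_Anaphase",
    "Cell_Cycle_G2", "Cell_Cycle_M", "Cell_Cycle_S")
}

#' Infer the molecular kind of a node from its name
#'
#' Naming conventions: `mRNA_<gene>` is a transcript; names containing a
#' colon are protein complexes (e.g. `"(CCNB1:CDC2)"`); a `_p` or
#' `_phosphorylated` suffix marks a phosphorylated protein; parenthesised
#' names with a dot (`"(RAC.)"`, `"(.RAS)"`) are protein families; names in
#' the phenotype lexicon are phenotypes; everything else is an
#' undifferentiated gene product.
#'
#' @param name character vector of node names.
#' @param phenotypes phenotype lexicon, see [default_phenotypes()].
#' @return character vector of kinds, one of `"MRNA"`, `"COMPLEX"`,
#'   `"PHOSPHO_PROTEIN"`, `"FAMILY"`, `"PHENOTYPE"`, `"GENE_PRODUCT"`.
#' @export
infer_node_kind <- function(name, phenotypes = default_phenotypes()) {
  vapply(name, function(nm) {
    if (startsWith(nm, "mRNA_")) {
      "MRNA"
    } else if (grepl(":", nm, fixed = TRUE)) {
      "COMPLEX"
    } else if (grepl("(_p|_phosphorylated)$", nm)) {
      "PHOSPHO_PROTEIN"
    } else if (grepl("^\\(.*\\.\\)$", nm) || grepl("^\\(\\..*\\)$", nm)) {
      "FAMILY"
    } else if (nm %in% phenotypes) {
      "PHENOTYPE"
    } else {
      "GENE_PRODUCT"
    }
  }, character(1), USE.NAMES = FALSE)
}

# Gene identifier backing a node: transcripts and phosphoproteins map to the
# unmodified gene, families to the family stem, complexes/phenotypes to NA.
infer_gene <- function(name, kind = infer_node_kind(name)) {
  mapply(function(nm, kd) {
    switch(kd,
      MRNA = sub("_$", "", sub("^mRNA_", "", nm)),
      PHOSPHO_PROTEIN = sub("(_p|_phosphorylated)$", "", nm),
      FAMILY = gsub("[().]", "", nm),
      COMPLEX = NA_character_,
      PHENOTYPE = NA_character_,
      nm)
  }, name, kind, USE.NAMES = FALSE)
}

normalize_sign <- function(x) {
  x <- trimws(x)
  x[x == "−"] <- "-"   # unicode minus as printed in some sources
  x
}

normalize_level <- function(x) {
  x <- trimws(x)
  x[is.na(x)] <- ""
  bad <- !(x %in% c("transcriptional", "post_translational", ""))
  if (any(bad)) {
    stop("unknown regulation level token(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Construct a signed interaction graph
#'
#' A signed graph is a directed graph whose edges carry an influence sign
#' (`"+"` activation, `"-"` inhibition, `"?"` dual/unknown) and a
#' regulation level (`"transcriptional"`, `"post_translational"`, or `""`
#' when unspecified).  Nodes are typed by molecular kind (see
#' [infer_node_kind()]); kinds may be overridden through the `nodes`
#' argument.
#'
#' Parallel edges with the same endpoints are merged: identical duplicates
#' are dropped; edges with conflicting signs collapse into a single dual
#' (`"?"`) edge with a warning, since the constraint semantics only consult
#' the achievable influence signs.  Conflicting levels collapse to
#' unspecified with a warning.
#'
#' @param edges `data.frame` with columns `source`, `target`, `sign`, and
#'   optionally `level`.  `NULL` or zero rows give an edgeless graph.
#' @param nodes optional extra nodes: a character vector of names, or a
#'   `data.frame` with columns `name` and optionally `kind`, `gene`
#'   (non-`NA` entries override inference).
#' @param phenotypes phenotype lexicon used for kind inference.
#' @return an object of class `signed_graph`: a list with `data.frame`
#'   components `nodes` (`name`, `kind`, `gene`) and `edges` (`source`,
#'   `target`, `sign`, `level`), both in deterministic lexicographic order.
#' @export
signed_graph <- function(edges = NULL, nodes = NULL,
                         phenotypes = default_phenotypes()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), level = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("source", "target", "sign")
    if (!all(need %in% names(edges))) {
      stop("edges need columns source, target, sign", call. = FALSE)
    }
    if (is.null(edges$level)) edges$level <- ""
    edges <- edges[, c("source", "target", "sign", "level")]
    edges$source <- trimws(as.character(edges$source))
    edges$target <- trimws(as.character(edges$target))
    edges$sign <- normalize_sign(as.character(edges$sign))
    edges$level <- normalize_level(as.character(edges$level))
    bad <- !(edges$sign %in% c("+", "-", "?"))
    if (any(bad)) {
      stop("unknown sign token(s): ",
           paste(unique(edges$sign[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(edges$source == "" | edges$target == "")) {
      stop("edge endpoints must be non-empty names", call. = FALSE)
    }
    edges <- merge_parallel_edges(edges)
  }

  node_names <- unique(c(edges$source, edges$target))
  kind_over <- character(0)
  gene_over <- character(0)
  if (!is.null(nodes)) {
    if (is.character(nodes)) {
      node_names <- unique(c(node_names, trimws(nodes)))
    } else {
      nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
      if (is.null(nodes$name)) stop("nodes need a 'name' column", call. = FALSE)
      nodes$name <- trimws(as.character(nodes$name))
      node_names <- unique(c(node_names, nodes$name))
      if (!is.null(nodes$kind)) {
        k <- as.character(nodes$kind)
        keep <- !is.na(k) & k != ""
        kind_over <- stats::setNames(k[keep], nodes$name[keep])
        valid <- c("MRNA", "PROTEIN", "PHOSPHO_PROTEIN", "COMPLEX",
                   "FAMILY", "PHENOTYPE", "GENE_PRODUCT")
        if (!all(kind_over %in% valid)) {
          stop("invalid node kind(s): ",
               paste(setdiff(kind_over, valid), collapse = ", "),
               call. = FALSE)
        }
      }
      if (!is.null(nodes$gene)) {
        g <- as.character(nodes$gene)
        keep <- !is.na(g) & g != ""
        gene_over <- stats::setNames(g[keep], nodes$name[keep])
      }
    }
  }
  node_names <- sort(node_names, method = "radix")
  kind <- infer_node_kind(node_names, phenotypes)
  kind[node_names %in% names(kind_over)] <-
    kind_over[node_names[node_names %in% names(kind_over)]]
  gene <- infer_gene(node_names, kind)
  gene[node_names %in% names(gene_over)] <-
    gene_over[node_names[node_names %in% names(gene_over)]]

  edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  g <- list(
    nodes = data.frame(name = node_names, kind = kind, gene = gene,
                       stringsAsFactors = FALSE),
    edges = edges
  )
  class(g) <- "signed_graph"
  g
}

merge_parallel_edges <- function(edges) {
  key <- paste(edges$source, edges$target, sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  pieces <- lapply(split(seq_len(nrow(edges)), key), function(i) {
    e <- edges[i, , drop = FALSE]
    sg <- unique(e$sign)
    lv <- unique(e$level)
    if (length(sg) > 1L) {
      warning("parallel edges ", e$source[1], " -> ", e$target[1],
              " with conflicting signs merged into a dual edge",
              call. = FALSE)
      sg <- "?"
    }
    lv_def <- setdiff(lv, "")
    if (length(lv_def) > 1L) {
      warning("parallel edges ", e$source[1], " -> ", e$target[1],
              " with conflicting levels merged as unspecified",
              call. = FALSE)
      lv <- ""
    } else {
      lv <- if (length(lv_def)) lv_def else ""
    }
    data.frame(source = e$source[1], target = e$target[1], sign = sg,
               level = lv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("signed interaction graph:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  kt <- table(x$nodes$kind)
  cat("  kinds:", paste(names(kt), kt, sep = "=", collapse = ", "), "\n")
  lt <- table(ifelse(x$edges$level == "", "unspecified", x$edges$level))
  if (nrow(x$edges)) {
    cat("  levels:", paste(names(lt), lt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

split_fields <- function(line, sep) {
  strsplit(line, sep, fixed = TRUE)[[1]]
}

detect_sep <- function(header, dialect) {
  switch(dialect,
    csv = ",",
    tsv = "\t",
    auto = if (grepl("\t", header, fixed = TRUE)) "\t" else ",")
}

read_table_lines <- function(file, text) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'", call. = FALSE)
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines <- sub("\r$", "", lines)
  lines[nzchar(trimws(lines))]
}

#' Read a signed interaction network from CSV
#'
#' The dialect is a plain delimited table with header
#' `source,target,sign,level` (`level` and a fifth `kind` column optional;
#' tab separation accepted).  Sign tokens are `+`, `-`, `?`.  A row with an
#' empty `target` declares an isolated node (its `kind` column, when
#' present, overrides kind inference for that node; on edge rows a `kind`
#' entry applies to the source node).  This on-disk syntax emulates the
#' tabular exchange format of qualitative network tools; it is this
#' package's own dialect, chosen to be lossless and human-diffable.
#'
#' @param file path to a file (ignored when `text` given).
#' @param text literal table text.
#' @param dialect `"auto"` (default; sniffs tab vs comma), `"csv"` or `"tsv"`.
#' @param phenotypes phenotype lexicon for kind inference.
#' @return a [signed_graph()].
#' @export
read_network <- function(file = NULL, text = NULL,
                         dialect = c("auto", "csv", "tsv"),
                         phenotypes = default_phenotypes()) {
  dialect <- match.arg(dialect)
  lines <- read_table_lines(file, text)
  if (!length(lines)) return(signed_graph())
  sep <- detect_sep(lines[1], dialect)
  header <- tolower(trimws(split_fields(lines[1], sep)))
  col <- function(nm) match(nm, header)
  if (is.na(col("source")) || is.na(col("target"))) {
    stop("line 1: header must contain 'source' and 'target'", call. = FALSE)
  }
  if (length(lines) == 1L) return(signed_graph())

  edges <- vector("list", length(lines) - 1L)
  decl <- list()
  for (i in seq_along(lines)[-1]) {
    f <- trimws(split_fields(lines[i], sep))
    length(f) <- length(header)
    f[is.na(f)] <- ""
    src <- f[col("source")]
    tgt <- f[col("target")]
    sgn <- if (!is.na(col("sign"))) normalize_sign(f[col("sign")]) else ""
    lvl <- if (!is.na(col("level"))) f[col("level")] else ""
    knd <- if (!is.na(col("kind"))) f[col("kind")] else ""
    if (src == "") stop("line ", i, ": missing source node", call. = FALSE)
    if (tgt == "") {
      decl[[length(decl) + 1L]] <-
        data.frame(name = src, kind = if (knd == "") NA_character_ else knd,
                   stringsAsFactors = FALSE)
      next
    }
    if (!(sgn %in% c("+", "-", "?"))) {
      stop("line ", i, ": unknown sign token '", sgn, "'", call. = FALSE)
    }
    if (knd != "") {
      decl[[length(decl) + 1L]] <-
        data.frame(name = src, kind = knd, stringsAsFactors = FALSE)
    }
    edges[[i - 1L]] <- data.frame(source = src, target = tgt, sign = sgn,
                                  level = lvl, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  nodes <- if (length(decl)) do.call(rbind, decl) else NULL
  signed_graph(edges, nodes, phenotypes)
}

#' Write a signed interaction network as CSV text
#'
#' Rows are emitted in lexicographic (source, target) order so the output
#' is byte-stable; [read_network()] of the result reconstructs the graph
#' exactly (isolated nodes are written as declaration rows with an empty
#' target, and node kinds that differ from name-based inference are written
#' in a fifth `kind` column).
#'
#' @param graph a [signed_graph()].
#' @param file optional path; when given the text is also written there.
#' @return the CSV text, invisibly when `file` is given.
#' @export
write_network <- function(graph, file = NULL) {
  stopifnot(inherits(graph, "signed_graph"))
  inferred <- infer_node_kind(graph$nodes$name)
  explicit <- graph$nodes$kind != inferred
  need_kind <- any(explicit)
  isolated <- setdiff(graph$nodes$name,
                      c(graph$edges$source, graph$edges$target))
  declared <- sort(unique(c(isolated, graph$nodes$name[explicit])),
                   method = "radix")
  kind_of <- stats::setNames(graph$nodes$kind, graph$nodes$name)

  header <- c("source", "target", "sign", "level", if (need_kind) "kind")
  rows <- character(0)
  if (length(declared)) {
    if (need_kind) {
      dk <- ifelse(explicit[match(declared, graph$nodes$name)],
                   kind_of[declared], "")
      rows <- paste(declared, "", "", "", dk, sep = ",")
    } else {
      rows <- paste(declared, "", "", "", sep = ",")
    }
  }
  if (nrow(graph$edges)) {
    e <- graph$edges
    erows <- paste(e$source, e$target, e$sign, e$level, sep = ",")
    if (need_kind) erows <- paste0(erows, ",")
    rows <- c(rows, erows)
  }
  txt <- paste(c(paste(header, collapse = ","), rows), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Export a network in SIF format
#'
#' Three-column `source <tab> sign <tab> target` lines for use in standard
#' graph viewers.  Level annotation and isolated nodes are not representable
#' in SIF and are dropped.
#'
#' @inheritParams write_network
#' @return the SIF text, invisibly when `file` is given.
#' @export
write_sif <- function(graph, file = NULL) {
  stopifnot(inherits(graph, "signed_graph"))
  e <- graph$edges
  txt <- paste0(paste(e$source, e$sign, e$target, sep = "\t"),
                collapse = "\n")
  if (nrow(e)) txt <- paste0(txt, "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Read an observation set from CSV
#'
#' An observation set is a partial map from node names to variation signs
#' in `{+, -}`, represented in R as a named character vector.  The table
#' has header `node,sign`.  Duplicate rows with identical signs are
#' de-duplicated; conflicting duplicates are an error.
#'
#' @inheritParams read_network
#' @return named character vector of `"+"`/`"-"`, names sorted.
#' @export
read_observations <- function(file = NULL, text = NULL,
                              dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- read_table_lines(file, text)
  if (!length(lines)) return(empty_observations())
  sep <- detect_sep(lines[1], dialect)
  header <- tolower(trimws(split_fields(lines[1], sep)))
  ni <- match("node", header)
  si <- match("sign", header)
  if (is.na(ni) || is.na(si)) {
    stop("line 1: header must contain 'node' and 'sign'", call. = FALSE)
  }
  if (length(lines) == 1L) return(empty_observations())
  nodes <- character(0); signs <- character(0)
  for (i in seq_along(lines)[-1]) {
    f <- trimws(split_fields(lines[i], sep))
    length(f) <- length(header)
    f[is.na(f)] <- ""
    nm <- f[ni]; sg <- normalize_sign(f[si])
    if (nm == "") stop("line ", i, ": missing node name", call. = FALSE)
    if (!(sg %in% c("+", "-"))) {
      stop("line ", i, ": observation sign must be '+' or '-', got '",
           sg, "'", call. = FALSE)
    }
    nodes <- c(nodes, nm); signs <- c(signs, sg)
  }
  as_observations(stats::setNames(signs, nodes))
}

empty_observations <- function() {
  stats::setNames(character(0), character(0))
}

#' Validate and normalize an observation set
#'
#' @param obs named character vector (or 2-column `data.frame`
#'   `node`,`sign`) of `"+"`/`"-"` variations.
#' @param graph optional [signed_graph()]; when given, every observed name
#'   must be a node of the graph.
#' @return named character vector sorted by name.
#' @export
as_observations <- function(obs, graph = NULL) {
  if (is.data.frame(obs)) {
    obs <- stats::setNames(as.character(obs$sign), as.character(obs$node))
  }
  if (!length(obs)) return(empty_observations())
  if (is.null(names(obs)) || any(!nzchar(names(obs)))) {
    stop("observations must be a named vector", call. = FALSE)
  }
  obs <- stats::setNames(normalize_sign(obs), names(obs))
  if (!all(obs %in% c("+", "-"))) {
    stop("observation signs must be '+' or '-' (dual '?' is not a valid ",
         "node observation)", call. = FALSE)
  }
  if (anyDuplicated(names(obs))) {
    for (nm in unique(names(obs)[duplicated(names(obs))])) {
      if (length(unique(obs[names(obs) == nm])) > 1L) {
        stop("conflicting observations for node '", nm, "'", call. = FALSE)
      }
    }
    obs <- obs[!duplicated(names(obs))]
  }
  if (!is.null(graph)) {
    missing <- setdiff(names(obs), graph$nodes$name)
    if (length(missing)) {
      stop("observed node(s) absent from the graph: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  obs[order(names(obs), method = "radix")]
}

#' Write an observation set as CSV text
#'
#' @param obs named character vector of `"+"`/`"-"`.
#' @param file optional output path.
#' @return the CSV text, invisibly when `file` is given.
#' @export
write_observations <- function(obs, file = NULL) {
  obs <- as_observations(obs)
  txt <- paste(c("node,sign", paste(names(obs), obs, sep = ",")),
               collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Transcript-to-product name aliases
#'
#' Family transcripts are printed with an underscore spelling
#' (`mRNA_RAC_`) while the corresponding network node is the parenthesised
#' family (`"(RAC.)"`).  This table records the alias pairs used by the
#' case study; the generic rules (`mRNA_X_` to `(X.)`, `mRNA_X` to `X`)
#' cover everything else.
#'
#' @return named character vector: transcript name -> product node name.
#' @export
default_aliases <- function() {
  c(mRNA_RAS = "(.RAS)",
    mRNA_CCNE_ = "(CCNE.)",
    mRNA_NFKB_ = "(NFKB.)",
    mRNA_PIK3C_ = "(PIK3C.)",
    mRNA_PIK3R_ = "(PIK3R.)",
    mRNA_RAC_ = "(RAC.)",
    mRNA_RHO_ = "(RHO.)",
    mRNA_TGFB_ = "(TGFB.)",
    mRNA_TNF_ = "(TNF.)")
}

#' Map an observation set onto the nodes of a graph
#'
#' Observation files name transcripts (`mRNA_AKT1`) and phenotypes.  In an
#' mRNA/protein-separated graph these names match nodes directly
#' (`mode = "exact"`; entries without a matching node are dropped).  In an
#' unseparated gene-product graph, transcript observations stand for the
#' product node, so `mode = "product"` additionally attaches each
#' `mRNA_<gene>` entry to the product node (`<gene>`, or the family node
#' via the alias table / the `mRNA_X_` to `(X.)` rule) when that node
#' exists; a transcript node bearing the same name also keeps the entry.
#'
#' @param obs named character vector of observations.
#' @param graph a [signed_graph()].
#' @param mode `"exact"` or `"product"`.
#' @param aliases transcript-to-product alias table, see [default_aliases()].
#' @return named character vector of observations on graph nodes.
#' @export
map_observations <- function(obs, graph, mode = c("exact", "product"),
                             aliases = default_aliases()) {
  mode <- match.arg(mode)
  obs <- as_observations(obs)
  nodes <- graph$nodes$name
  out <- character(0)
  add <- function(out, nm, sg) {
    if (nm %in% names(out) && out[[nm]] != sg) {
      stop("conflicting mapped observations for node '", nm, "'",
           call. = FALSE)
    }
    out[nm] <- sg
    out
  }
  for (nm in names(obs)) {
    if (nm %in% nodes) out <- add(out, nm, obs[[nm]])
    if (mode == "product" && startsWith(nm, "mRNA_")) {
      cand <- character(0)
      if (nm %in% names(aliases)) cand <- aliases[[nm]]
      g <- sub("^mRNA_", "", nm)
      cand <- c(cand, if (endsWith(g, "_")) {
        paste0("(", sub("_$", "", g), ".)")
      } else {
        g
      })
      for (p in unique(cand)) {
        if (p %in% nodes) out <- add(out, p, obs[[nm]])
      }
    }
  }
  as_observations(out)
}
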