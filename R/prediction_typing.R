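# Classification of protein-level predictions against transcript data.
#
# Under the naive transcription dogma a protein follows its mRNA.  A
# predicted protein sign that opposes the observed transcript sign
# (Type I) therefore flags a post-translational regulation strong enough
# to reverse transcriptional production; an absent/non-significant
# transcript (Type II) is weaker evidence in the same direction; agreement
# (Type III) suggests the transcriptional route dominates.

#' Name of the transcript node corresponding to a protein-level node
#'
#' Proteins map by prefixing (`IGF1` to `mRNA_IGF1`), phosphorylated
#' proteins map to the unmodified gene's transcript (`RB1_p` to
#' `mRNA_RB1`), and families map to the aggregate family transcript
#' (`"(RAC.)"` to `mRNA_RAC_`, `"(.RAS)"` to `mRNA_RAS`), with the alias
#' table taking precedence over the generic rules.  Transcripts, complexes
#' and phenotypes have no corresponding transcript (`NA`).
#'
#' @param node character vector of node names.
#' @param kind optional kinds (inferred from names when omitted).
#' @param aliases transcript-to-product aliases, see [default_aliases()];
#'   used here in the product-to-transcript direction.
#' @return character vector of transcript node names (`NA` where not
#'   applicable).
#' @export
corresponding_mrna <- function(node, kind = NULL,
                               aliases = default_aliases()) {
  if (is.null(kind)) kind <- infer_node_kind(node)
  rev_alias <- stats::setNames(names(aliases), unname(aliases))
  mapply(function(nm, kd) {
    if (kd %in% c("MRNA", "COMPLEX", "PHENOTYPE")) return(NA_character_)
    if (nm %in% names(rev_alias)) return(rev_alias[[nm]])
    if (kd == "FAMILY") {
      if (grepl("^\\(\\.", nm)) {
        return(paste0("mRNA_", gsub("[().]", "", nm)))
      }
      return(paste0("mRNA_", gsub("[().]", "", nm), "_"))
    }
    if (kd == "PHOSPHO_PROTEIN") {
      nm <- sub("(_p|_phosphorylated)$", "", nm)
    }
    paste0("mRNA_", nm)
  }, node, kind, USE.NAMES = FALSE)
}

#' Classify predictions against transcript observations
#'
#' Each protein-level prediction (kinds `PROTEIN`, `GENE_PRODUCT`,
#' `PHOSPHO_PROTEIN`, `FAMILY`) is compared with the observed sign of its
#' corresponding transcript:
#'
#' * **Type I** — transcript observed with the opposite sign; flags a
#'   potentially active post-translational regulation overriding
#'   transcription.
#' * **Type II** — transcript absent from the observation set (not
#'   significant, or not measured).
#' * **Type III** — transcript observed with the same sign; transcription
#'   dominates.
#'
#' Predictions on mRNA, complex and phenotype nodes are not compared
#' (`ptype = NA`); they are reported separately.
#'
#' @param predictions `data.frame` with columns `node`, `sign` (and
#'   optionally `deduction`), as from [compute_predictions()].
#' @param observations named character vector of observations (the full
#'   observation set, including transcripts that are not graph nodes).
#' @param graph optional [signed_graph()] supplying node kinds; kinds are
#'   inferred from names when absent.
#' @param aliases alias table, see [default_aliases()].
#' @return the `predictions` frame with columns `kind`, `mrna_node`,
#'   `mrna_status` (`OBSERVED_OPPOSITE`, `NOT_SIGNIFICANT_OR_ABSENT`,
#'   `OBSERVED_SAME`, `NOT_APPLICABLE`) and `ptype` (`"I"`, `"II"`,
#'   `"III"`, `NA`) added.
#' @export
type_predictions <- function(predictions, observations, graph = NULL,
                             aliases = default_aliases()) {
  obs <- as_observations(observations)
  if (!is.null(graph)) {
    kind <- graph$nodes$kind[match(predictions$node, graph$nodes$name)]
    kind[is.na(kind)] <- infer_node_kind(predictions$node[is.na(kind)])
  } else {
    kind <- infer_node_kind(predictions$node)
  }
  mrna <- corresponding_mrna(predictions$node, kind, aliases)
  status <- character(nrow(predictions))
  ptype <- rep(NA_character_, nrow(predictions))
  for (k in seq_len(nrow(predictions))) {
    if (is.na(mrna[k])) {
      status[k] <- "NOT_APPLICABLE"
    } else if (!(mrna[k] %in% names(obs))) {
      status[k] <- "NOT_SIGNIFICANT_OR_ABSENT"
      ptype[k] <- "II"
    } else if (obs[[mrna[k]]] == predictions$sign[k]) {
      status[k] <- "OBSERVED_SAME"
      ptype[k] <- "III"
    } else {
      status[k] <- "OBSERVED_OPPOSITE"
      ptype[k] <- "I"
    }
  }
  predictions$kind <- kind
  predictions$mrna_node <- mrna
  predictions$mrna_status <- status
  predictions$ptype <- ptype
  predictions
}

#' Summarize typed predictions
#'
#' @param typed output of [type_predictions()].
#' @return list with `type_counts` (named integer vector over `I`, `II`,
#'   `III`, `NA`) and `kind_counts` (named integer vector over the node
#'   groups `mRNA`, `protein` — which pools plain proteins, gene products
#'   and phosphoproteins —, `complex`, `family`, `phenotype`).
#' @export
summarize_types <- function(typed) {
  tc <- c(I = sum(typed$ptype == "I", na.rm = TRUE),
          II = sum(typed$ptype == "II", na.rm = TRUE),
          III = sum(typed$ptype == "III", na.rm = TRUE),
          "NA" = sum(is.na(typed$ptype)))
  grp <- c(MRNA = "mRNA", PROTEIN = "protein", GENE_PRODUCT = "protein",
           PHOSPHO_PROTEIN = "protein", COMPLEX = "complex",
           FAMILY = "family", PHENOTYPE = "phenotype")
  kinds <- grp[typed$kind]
  kc <- vapply(c("mRNA", "protein", "complex", "family", "phenotype"),
               function(g) sum(kinds == g, na.rm = TRUE), integer(1))
  list(type_counts = tc, kind_counts = kc)
}
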