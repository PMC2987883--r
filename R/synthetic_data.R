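# Generators for synthetic networks, observation sets and expression
# series.  All generators are pure functions of their parameters and seed.
# The defaults emulate the structure of the case-study inputs: a curated
# signed network of ~130 genes with ~300 interactions, and probe-level
# microarray time series with linear per-gene trends, Gaussian noise and
# sporadic outliers.

#' Generate a random signed interaction network
#'
#' @param n_nodes number of nodes.
#' @param edge_density expected in-degree; the edge count is
#'   `round(edge_density * n_nodes)` (capped by the number of available
#'   node pairs).  Default 2.3, the case-study scale (130 genes, ~300
#'   interactions).
#' @param p_minus,p_dual probability that an edge is inhibiting / dual
#'   (`p_minus + p_dual <= 1`; the remainder is activating).
#' @param p_transcriptional probability that an edge is transcriptional
#'   (otherwise post-translational).
#' @param acyclic generate a DAG (edges respect a fixed node order).
#'   Default `TRUE`.
#' @param seed integer seed; the same seed reproduces the same graph.
#' @return a [signed_graph()]; isolated nodes are retained.
#' @export
generate_network <- function(n_nodes, edge_density = 2.3, p_minus = 0.3,
                             p_dual = 0.05, p_transcriptional = 0.5,
                             acyclic = TRUE, seed = 1L) {
  stopifnot(n_nodes >= 1L, p_minus >= 0, p_dual >= 0,
            p_minus + p_dual <= 1,
            p_transcriptional >= 0, p_transcriptional <= 1)
  set.seed(seed)
  nodes <- sprintf("G%03d", seq_len(n_nodes))
  if (acyclic) {
    pairs <- which(upper.tri(matrix(0L, n_nodes, n_nodes)), arr.ind = TRUE)
  } else {
    pairs <- which(!diag(n_nodes), arr.ind = TRUE)
  }
  m <- min(round(edge_density * n_nodes), nrow(pairs))
  if (m < 1L || n_nodes == 1L) return(signed_graph(nodes = nodes))
  sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
  signs <- sample(c("+", "-", "?"), m, replace = TRUE,
                  prob = c(1 - p_minus - p_dual, p_minus, p_dual))
  levels <- sample(c("transcriptional", "post_translational"), m,
                   replace = TRUE,
                   prob = c(p_transcriptional, 1 - p_transcriptional))
  edges <- data.frame(source = nodes[sel[, 1L]], target = nodes[sel[, 2L]],
                      sign = signs, level = levels,
                      stringsAsFactors = FALSE)
  signed_graph(edges, nodes)
}

topological_order <- function(cc) {
  indeg <- lengths(cc$preds)
  order <- integer(0)
  avail <- which(indeg == 0L)
  indeg_left <- indeg
  while (length(avail)) {
    v <- avail[1L]                       # lexicographic tie-break
    avail <- avail[-1L]
    order <- c(order, v)
    for (w in cc$succ[[v]]) {
      hits <- sum(cc$preds[[w]] == v)
      indeg_left[w] <- indeg_left[w] - hits
      if (indeg_left[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(order) < cc$n) return(NULL)  # cyclic
  order
}

#' Sample a consistent observation set by construction
#'
#' Draws a total sign assignment that satisfies the consistency rule —
#' forward-sampling along a topological order when the graph is acyclic,
#' otherwise by randomized backtracking search over the constraint system —
#' and reveals a random subset of it as observations.  The hidden
#' assignment is a witness, so the revealed observations are consistent by
#' construction.  An error is raised only when the graph admits no
#' consistent total assignment at all (e.g. a purely negative odd cycle
#' with no other inputs).
#'
#' @param graph a [signed_graph()].
#' @param reveal_fraction fraction of nodes revealed as observations.
#' @param seed integer seed.
#' @return list with `observations` (named character vector) and
#'   `assignment` (the hidden total assignment).
#' @export
sample_consistent_observations <- function(graph, reveal_fraction = 0.3,
                                           seed = 1L) {
  stopifnot(reveal_fraction >= 0, reveal_fraction <= 1)
  set.seed(seed)
  cc <- .sc_compile(graph)
  ord <- topological_order(cc)
  vals <- stats::setNames(rep(NA_character_, cc$n), cc$nodes)
  if (!is.null(ord)) {
    for (v in ord) {
      ach <- achievable_signs(graph, vals[!is.na(vals)], cc$nodes[v])
      vals[v] <- if (length(ach) == 1L) ach else sample(ach, 1L)
    }
  } else {
    dom <- .sc_sample_solution(cc, .sc_dom_init(cc, empty_observations()))
    if (is.null(dom)) {
      stop("the graph admits no consistent total assignment", call. = FALSE)
    }
    vals[] <- ifelse(dom[, 1L], "+", "-")
  }
  k <- round(reveal_fraction * cc$n)
  revealed <- if (k >= 1L) sort(sample(cc$nodes, k), method = "radix")
              else character(0)
  list(observations = vals[revealed], assignment = vals)
}

#' Corrupt an observation set to create inconsistencies
#'
#' Flips the signs of `k` observed nodes, preferring nodes whose
#' constraint is currently tight (the achievable set under the other
#' observations is exactly the observed sign), so that a flip provably
#' breaks the local constraint whenever such nodes exist.
#'
#' @param graph a [signed_graph()].
#' @param obs a consistent observation set.
#' @param k number of flips (`0 <= k <= length(obs)`).
#' @param seed integer seed.
#' @return the corrupted observation set.
#' @export
inject_inconsistency <- function(graph, obs, k, seed = 1L) {
  obs <- as_observations(obs, graph)
  if (k > length(obs)) {
    stop("k exceeds the number of observations", call. = FALSE)
  }
  if (k == 0L) return(obs)
  set.seed(seed)
  tight <- Filter(function(v) {
    identical(achievable_signs(graph, obs[names(obs) != v], v),
              unname(obs[v]))
  }, names(obs))
  rest <- setdiff(names(obs), tight)
  ordering <- c(if (length(tight) > 1L) sample(tight) else tight,
                if (length(rest) > 1L) sample(rest) else rest)
  flip <- ordering[seq_len(k)]
  obs[flip] <- ifelse(obs[flip] == "+", "-", "+")
  obs
}

#' Simulate a probe-level expression time series
#'
#' Per gene `g`, `intensity(probe, t) = a_g + b_g * t + e` with
#' `e ~ N(0, noise_sd^2)`; a fraction `outlier_rate` of points is displaced
#' by `outlier_magnitude * noise_sd` (random direction).  Defaults emulate
#' RMA-normalized log2 intensities sampled at 7 occasions with 5 pooled
#' probe-set lines per gene.
#'
#' @param n_genes number of genes.
#' @param probes_per_gene probe sets per gene (default 5).
#' @param times numeric time values (default `0:6`).
#' @param slopes per-gene slope `b_g`: scalar or vector of length
#'   `n_genes` (intensity units per time unit).
#' @param intercept_mean,intercept_sd distribution of baselines `a_g`
#'   (defaults 8 and 0.5, a typical log2 scale).
#' @param noise_sd measurement noise SD (default 0.3).
#' @param outlier_rate,outlier_magnitude outlier fraction and displacement
#'   in noise-SD units.
#' @param seed integer seed.
#' @return an [expression_series()] with attributes `slopes` (named per
#'   gene) and `outliers` (logical matrix marking displaced points).
#' @export
simulate_timeseries <- function(n_genes = 50L, probes_per_gene = 5L,
                                times = 0:6, slopes = 0,
                                intercept_mean = 8, intercept_sd = 0.5,
                                noise_sd = 0.3, outlier_rate = 0,
                                outlier_magnitude = 5, seed = 1L) {
  stopifnot(length(times) >= 2L, outlier_rate >= 0, outlier_rate <= 1,
            noise_sd > 0)
  set.seed(seed)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  slopes <- stats::setNames(rep_len(slopes, n_genes), genes)
  probes <- as.vector(vapply(genes, function(g) {
    paste0(g, "_s", seq_len(probes_per_gene))
  }, character(probes_per_gene)))
  probe_to_gene <- stats::setNames(rep(genes, each = probes_per_gene),
                                   probes)
  a <- stats::setNames(stats::rnorm(n_genes, intercept_mean, intercept_sd),
                       genes)
  nr <- length(probes); nc <- length(times)
  mu <- outer(a[probe_to_gene[probes]], rep(1, nc)) +
    outer(slopes[probe_to_gene[probes]], times)
  noise <- matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  out_mask <- matrix(stats::runif(nr * nc) < outlier_rate, nr, nc)
  shift <- matrix(sample(c(-1, 1), nr * nc, replace = TRUE), nr, nc) *
    outlier_magnitude * noise_sd
  m <- mu + noise + out_mask * shift
  dimnames(m) <- list(probes, times)
  dimnames(out_mask) <- dimnames(m)
  series <- expression_series(m, times, probe_to_gene)
  attr(series, "slopes") <- slopes
  attr(series, "outliers") <- out_mask
  series
}
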