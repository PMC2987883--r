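# Average-trend extraction from expression time series.
#
# The observation sets consumed by the consistency engine are signed calls
# of the average trend of a gene's response between two steady states.
# Probe-set series belonging to one gene are pooled (every probe line is
# kept, so transcript-variant spread enters the significance assessment),
# outlying points are removed, and a gene is called significant when both
# (a) the slope of the pooled least-squares regression differs from zero
# and (b) a two-sample location test between the initial and final time
# points rejects, each at its own significance level.  No multiplicity
# correction is applied: the gene list has already been reduced to the
# network's genes.

#' Trend-caller configuration
#'
#' @param alpha_regression significance level for the regression slope
#'   (two-sided t-test; for simple linear regression this coincides with
#'   the model F-test).  Default 0.05.
#' @param alpha_ttest significance level for the two-sample location test
#'   between the first and last time point.  Default 0.05.
#' @param outlier_sd_multiplier residual threshold in units of the residual
#'   standard deviation.  Default 2.
#' @param refit_after_outlier_removal refit the regression on the pruned
#'   points (default `TRUE`); with `FALSE` outliers are reported but all
#'   points enter the fit.
#' @param welch use the unequal-variance (Welch) variant of the location
#'   test instead of the classic pooled-variance Student test.  Default
#'   `FALSE`.
#' @return list of class `trend_config`.
#' @export
trend_config <- function(alpha_regression = 0.05, alpha_ttest = 0.05,
                         outlier_sd_multiplier = 2,
                         refit_after_outlier_removal = TRUE,
                         welch = FALSE) {
  stopifnot(alpha_regression > 0, alpha_regression < 1,
            alpha_ttest > 0, alpha_ttest < 1,
            outlier_sd_multiplier > 0)
  structure(list(alpha_regression = alpha_regression,
                 alpha_ttest = alpha_ttest,
                 outlier_sd_multiplier = outlier_sd_multiplier,
                 refit_after_outlier_removal = refit_after_outlier_removal,
                 welch = welch),
            class = "trend_config")
}

#' Construct an expression time series
#'
#' @param matrix numeric matrix, probe sets in rows (rownames are probe-set
#'   ids), time points in columns.
#' @param times numeric vector of time values, one per column.
#' @param probe_to_gene named character vector mapping probe-set id to gene
#'   name; every probe row must map to exactly one gene.
#' @return list of class `expression_series`.
#' @export
expression_series <- function(matrix, times, probe_to_gene) {
  matrix <- as.matrix(matrix)
  if (length(times) != ncol(matrix)) {
    stop("length(times) must equal ncol(matrix)", call. = FALSE)
  }
  if (length(times) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (is.null(rownames(matrix))) {
    stop("matrix must have probe-set rownames", call. = FALSE)
  }
  unmapped <- setdiff(rownames(matrix), names(probe_to_gene))
  if (length(unmapped)) {
    stop("probe set(s) without gene mapping: ",
         paste(utils::head(unmapped, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(matrix = matrix, times = as.numeric(times),
                 probe_to_gene = probe_to_gene),
            class = "expression_series")
}

#' Read an expression series from TSV files
#'
#' The matrix file is a TSV with probe-set ids in the first column and a
#' header row of time values; the map file is a two-column TSV
#' `probe<tab>gene`.
#'
#' @param matrix_file,map_file file paths.
#' @return an [expression_series()].
#' @export
read_expression_series <- function(matrix_file, map_file) {
  m <- utils::read.delim(matrix_file, row.names = 1L, check.names = FALSE)
  times <- as.numeric(colnames(m))
  if (anyNA(times)) {
    stop("matrix header must be numeric time values", call. = FALSE)
  }
  map <- utils::read.delim(map_file, header = TRUE,
                           stringsAsFactors = FALSE)
  expression_series(as.matrix(m), times,
                    stats::setNames(as.character(map[[2L]]),
                                    as.character(map[[1L]])))
}

#' Pool probe-level points by gene
#'
#' Every probe measurement is kept (no per-gene averaging): a gene with
#' `p` probe sets over `t` time points contributes `p * t` points.
#'
#' @param series an [expression_series()].
#' @return named list (sorted by gene) of `data.frame`s with columns
#'   `time`, `intensity`, `probe`.
#' @export
group_probes <- function(series) {
  stopifnot(inherits(series, "expression_series"))
  genes <- series$probe_to_gene[rownames(series$matrix)]
  out <- lapply(split(rownames(series$matrix), genes), function(probes) {
    sub <- series$matrix[probes, , drop = FALSE]
    data.frame(
      time = rep(series$times, each = length(probes)),
      intensity = as.vector(sub),
      probe = rep(probes, times = ncol(sub)),
      stringsAsFactors = FALSE)
  })
  out[order(names(out), method = "radix")]
}

#' Remove outlying points relative to the regression line
#'
#' Residuals are distances from the ordinary least-squares line fitted to
#' all points; a point is an outlier when its absolute residual exceeds
#' `outlier_sd_multiplier` standard deviations of the residuals.  Removal
#' is a single pass (no re-estimation of the threshold on the pruned set).
#'
#' @param points `data.frame` with columns `time`, `intensity`.
#' @param config a [trend_config()].
#' @return list with components `kept` and `removed` (both `data.frame`s).
#' @export
remove_outliers <- function(points, config = trend_config()) {
  if (nrow(points) < 3L) {
    warning("fewer than 3 points; no outlier removal", call. = FALSE)
    return(list(kept = points, removed = points[0, , drop = FALSE]))
  }
  fit <- stats::lm(intensity ~ time, data = points)
  res <- stats::resid(fit)
  s <- stats::sd(res)
  if (!is.finite(s) || s == 0) {
    return(list(kept = points, removed = points[0, , drop = FALSE]))
  }
  out <- abs(res) > config$outlier_sd_multiplier * s
  list(kept = points[!out, , drop = FALSE],
       removed = points[out, , drop = FALSE])
}

#' Fit the average trend of one gene
#'
#' Ordinary least-squares regression of pooled intensity on time gives the
#' slope and its two-sided p-value (`p_regression`); a two-sample location
#' test between the pooled intensities at the earliest and the latest time
#' point gives `p_ttest`.  A sign is called iff both p-values fall below
#' their configured levels; the call is the sign of the slope.
#'
#' @param gene gene name.
#' @param points `data.frame` with columns `time`, `intensity` (at least 3
#'   points spanning at least 2 distinct times).
#' @param config a [trend_config()].
#' @param n_outliers_removed bookkeeping count carried into the result.
#' @return one-row `data.frame`: `gene`, `n_points`, `slope`,
#'   `p_regression`, `p_ttest`, `n_outliers_removed`, `sign_call`
#'   (`"+"`, `"-"` or `NA`).
#' @export
fit_trend <- function(gene, points, config = trend_config(),
                      n_outliers_removed = 0L) {
  if (nrow(points) < 3L) {
    stop("gene '", gene, "': need at least 3 points", call. = FALSE)
  }
  if (length(unique(points$time)) < 2L) {
    stop("gene '", gene, "': all points at a single time", call. = FALSE)
  }
  fit <- stats::lm(intensity ~ time, data = points)
  cf <- stats::coef(summary(fit))
  slope <- cf["time", "Estimate"]
  p_reg <- cf["time", "Pr(>|t|)"]
  first <- points$intensity[points$time == min(points$time)]
  last <- points$intensity[points$time == max(points$time)]
  p_t <- if (length(first) < 2L || length(last) < 2L) {
    NA_real_
  } else {
    tryCatch(
      stats::t.test(first, last, var.equal = !config$welch)$p.value,
      error = function(e) {
        # essentially-constant data: decide on the mean difference
        if (isTRUE(all.equal(mean(first), mean(last)))) 1 else 0
      })
  }
  call <- NA_character_
  if (!is.na(p_reg) && !is.na(p_t) &&
      p_reg < config$alpha_regression && p_t < config$alpha_ttest &&
      slope != 0) {
    call <- if (slope > 0) "+" else "-"
  }
  data.frame(gene = gene, n_points = nrow(points), slope = slope,
             p_regression = p_reg, p_ttest = p_t,
             n_outliers_removed = n_outliers_removed,
             sign_call = call, stringsAsFactors = FALSE)
}

#' Fit trends for every gene of a series
#'
#' @param series an [expression_series()].
#' @param config a [trend_config()].
#' @param gene_whitelist optional character vector restricting the genes
#'   analyzed (e.g. the genes of the network under study).
#' @return `data.frame` with one row per gene, see [fit_trend()].
#' @export
fit_all_trends <- function(series, config = trend_config(),
                           gene_whitelist = NULL) {
  groups <- group_probes(series)
  if (!is.null(gene_whitelist)) {
    groups <- groups[names(groups) %in% gene_whitelist]
  }
  rows <- lapply(names(groups), function(g) {
    pts <- groups[[g]]
    if (nrow(pts) < 3L) return(NULL)
    rm <- suppressWarnings(remove_outliers(pts, config))
    kept <- if (config$refit_after_outlier_removal) rm$kept else pts
    if (nrow(kept) < 3L || length(unique(kept$time)) < 2L) return(NULL)
    fit_trend(g, kept, config, n_outliers_removed = nrow(rm$removed))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), n_points = integer(),
                      slope = numeric(), p_regression = numeric(),
                      p_ttest = numeric(), n_outliers_removed = integer(),
                      sign_call = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Extract a signed observation set from an expression series
#'
#' Runs the full trend caller and returns `mRNA_<gene> -> sign` entries for
#' every gene with a significant call.
#'
#' @inheritParams fit_all_trends
#' @return named character vector of observations (possibly empty).
#' @export
extract_observations <- function(series, config = trend_config(),
                                 gene_whitelist = NULL) {
  fits <- fit_all_trends(series, config, gene_whitelist)
  fits <- fits[!is.na(fits$sign_call), , drop = FALSE]
  if (!nrow(fits)) return(empty_observations())
  as_observations(stats::setNames(fits$sign_call,
                                  paste0("mRNA_", fits$gene)))
}
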