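# Sign-consistency engine.
#
# The qualitative rule: the variation sign of a node cannot be opposite to
# the signs of all the influences it gathers from its predecessors; a node
# without predecessors is a free input.  The rule is valid when the two
# expression snapshots being compared are steady states of the system.
#
# Internally the graph is compiled to integer adjacency lists and node sign
# domains are represented as an n x 2 logical matrix (column 1 = "+"
# possible, column 2 = "-" possible).  Arc-consistency propagation prunes
# each node's domain to the influences achievable from its predecessors'
# domains; search branches on undetermined nodes.  Propagation plus
# branching is a sound and complete decision procedure for the rule, and
# invariant predictions are obtained by refutation (a node is predicted "+"
# exactly when fixing it to "-" is unsatisfiable).

.sc_compile <- function(graph) {
  nodes <- graph$nodes$name              # already sorted lexicographically
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  preds <- rep(list(integer(0)), n)
  psign <- rep(list(integer(0)), n)
  succ <- rep(list(integer(0)), n)
  e <- graph$edges
  if (nrow(e)) {
    s <- unname(idx[e$source])
    t <- unname(idx[e$target])
    sg <- ifelse(e$sign == "?", 0L, ifelse(e$sign == "+", 1L, -1L))
    for (k in seq_along(s)) {
      preds[[t[k]]] <- c(preds[[t[k]]], s[k])
      psign[[t[k]]] <- c(psign[[t[k]]], sg[k])
      succ[[s[k]]] <- c(succ[[s[k]]], t[k])
    }
    succ <- lapply(succ, unique)
  }
  list(nodes = nodes, idx = idx, n = n, preds = preds, psign = psign,
       succ = succ, has_pred = lengths(preds) > 0L)
}

.sc_dom_init <- function(cc, fixed) {
  dom <- matrix(TRUE, nrow = cc$n, ncol = 2L)
  if (length(fixed)) {
    i <- unname(cc$idx[names(fixed)])
    dom[i, 1L] <- fixed == "+"
    dom[i, 2L] <- fixed == "-"
  }
  dom
}

# Signs achievable at node v from its predecessors' current domains.
.sc_achievable <- function(cc, dom, v) {
  p <- cc$preds[[v]]
  if (!length(p)) return(c(TRUE, TRUE))
  sg <- cc$psign[[v]]
  plus <- FALSE; minus <- FALSE
  for (k in seq_along(p)) {
    u <- p[k]
    if (sg[k] == 0L) {
      plus <- TRUE; minus <- TRUE
    } else if (sg[k] == 1L) {
      plus <- plus || dom[u, 1L]; minus <- minus || dom[u, 2L]
    } else {
      plus <- plus || dom[u, 2L]; minus <- minus || dom[u, 1L]
    }
    if (plus && minus) break
  }
  c(plus, minus)
}

# Arc-consistency fixpoint.  With collect_conflicts = TRUE a locally
# unsatisfiable node is reported and frozen at its forced sign (so that
# propagation downstream continues from the observed value) instead of
# aborting.
.sc_propagate <- function(cc, dom, collect_conflicts = FALSE) {
  queue <- which(cc$has_pred)
  inq <- logical(cc$n); inq[queue] <- TRUE
  frozen <- logical(cc$n)
  conflicts <- list()
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; inq[v] <- FALSE
    if (frozen[v]) next
    ach <- .sc_achievable(cc, dom, v)
    nd <- dom[v, ] & ach
    if (!any(nd)) {
      if (!collect_conflicts) {
        return(list(ok = FALSE, dom = dom, conflict = v))
      }
      conflicts[[length(conflicts) + 1L]] <- list(v = v, ach = ach)
      frozen[v] <- TRUE
      next
    }
    if (!identical(nd, dom[v, ])) {
      dom[v, ] <- nd
      for (w in cc$succ[[v]]) {
        if (!inq[w] && !frozen[w]) { queue <- c(queue, w); inq[w] <- TRUE }
      }
    }
  }
  list(ok = TRUE, dom = dom, conflicts = conflicts)
}

# Satisfiability of the constraint system under fixed signs.  Branches only
# on undetermined nodes that have successors: once those are decided and
# propagation has converged, remaining undetermined nodes are sinks whose
# domains already lie inside their achievable sets.
.sc_sat <- function(cc, dom) {
  pr <- .sc_propagate(cc, dom)
  if (!pr$ok) return(FALSE)
  dom <- pr$dom
  und <- which(dom[, 1L] & dom[, 2L])
  und <- und[lengths(cc$succ[und]) > 0L]
  if (!length(und)) return(TRUE)
  v <- und[1L]
  d <- dom; d[v, 2L] <- FALSE
  if (.sc_sat(cc, d)) return(TRUE)
  d <- dom; d[v, 1L] <- FALSE
  .sc_sat(cc, d)
}

# Randomized complete search for a single consistent total assignment
# (uses the session RNG; callers seed it).  NULL when none exists.
.sc_sample_solution <- function(cc, dom) {
  pr <- .sc_propagate(cc, dom)
  if (!pr$ok) return(NULL)
  dom <- pr$dom
  und <- which(dom[, 1L] & dom[, 2L])
  if (!length(und)) return(dom)
  v <- if (length(und) == 1L) und else sample(und, 1L)
  first_plus <- stats::runif(1) < 0.5
  for (plus in if (first_plus) c(TRUE, FALSE) else c(FALSE, TRUE)) {
    d <- dom
    d[v, if (plus) 2L else 1L] <- FALSE
    res <- .sc_sample_solution(cc, d)
    if (!is.null(res)) return(res)
  }
  NULL
}

.sc_enum <- function(cc, dom, acc) {
  pr <- .sc_propagate(cc, dom)
  if (!pr$ok) return(acc)
  dom <- pr$dom
  und <- which(dom[, 1L] & dom[, 2L])
  if (!length(und)) {
    acc[[length(acc) + 1L]] <-
      stats::setNames(ifelse(dom[, 1L], "+", "-"), cc$nodes)
    return(acc)
  }
  v <- und[1L]
  d <- dom; d[v, 2L] <- FALSE
  acc <- .sc_enum(cc, d, acc)
  d <- dom; d[v, 1L] <- FALSE
  .sc_enum(cc, d, acc)
}

#' Signs achievable at a node from its predecessors
#'
#' Returns the set of variation signs that some incoming influence can
#' supply at `node`: each predecessor `u` with edge sign `s` contributes
#' `sign(u) * s`; a dual (`"?"`) edge contributes both signs, as does a
#' signed edge from a predecessor whose sign is unknown (absent from
#' `values`).  A node without predecessors is a free input and both signs
#' are returned.
#'
#' @param graph a [signed_graph()].
#' @param values partial map of node signs (named character vector of
#'   `"+"`/`"-"`).
#' @param node node name.
#' @return character vector, subset of `c("+", "-")` (never empty).
#' @export
achievable_signs <- function(graph, values, node) {
  if (!(node %in% graph$nodes$name)) {
    stop("unknown node '", node, "'", call. = FALSE)
  }
  e <- graph$edges[graph$edges$target == node, , drop = FALSE]
  if (!nrow(e)) return(c("+", "-"))
  out <- character(0)
  for (k in seq_len(nrow(e))) {
    su <- if (e$source[k] %in% names(values)) values[[e$source[k]]] else NA
    if (e$sign[k] == "?" || is.na(su)) {
      out <- c(out, "+", "-")
    } else {
      out <- c(out, sign_product(su, e$sign[k]))
    }
    if (all(c("+", "-") %in% out)) break
  }
  intersect(c("+", "-"), out)
}

#' Is a total sign assignment consistent with the graph?
#'
#' True iff every node that has at least one predecessor carries a sign in
#' its achievable set (see [achievable_signs()]).  Observed nodes with
#' predecessors are constrained like any other node; free inputs are not.
#'
#' @param graph a [signed_graph()].
#' @param assignment named character vector covering every node.
#' @return logical scalar.
#' @export
is_consistent_total <- function(graph, assignment) {
  missing <- setdiff(graph$nodes$name, names(assignment))
  if (length(missing)) {
    stop("assignment is partial; missing: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  for (v in unique(graph$edges$target)) {
    if (!(assignment[[v]] %in% achievable_signs(graph, assignment, v))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Enumerate all consistent total assignments
#'
#' Explicit enumeration (with arc-consistency pruning) of every total sign
#' assignment that extends `observations` and satisfies the consistency
#' rule.  Used as the reference semantics for [compute_predictions()]; the
#' number of unobserved nodes is guarded because the solution count can be
#' exponential.
#'
#' @param graph a [signed_graph()].
#' @param observations named character vector of `"+"`/`"-"`.
#' @param guard maximum number of unobserved nodes (default 25).
#' @return list of named character vectors (possibly empty), in
#'   deterministic order.
#' @export
enumerate_consistent <- function(graph, observations = NULL, guard = 25L) {
  obs <- as_observations(if (is.null(observations)) empty_observations()
                         else observations, graph)
  n_un <- nrow(graph$nodes) - length(obs)
  if (n_un > guard) {
    stop("enumeration over ", n_un, " unobserved nodes exceeds the guard (",
         guard, "); use compute_predictions() instead", call. = FALSE)
  }
  cc <- .sc_compile(graph)
  .sc_enum(cc, .sc_dom_init(cc, obs), list())
}

new_consistency_result <- function(consistent, n_solutions = NA_integer_,
                                   inconsistencies = empty_inconsistencies()) {
  structure(list(consistent = consistent,
                 n_solutions = n_solutions,
                 inconsistencies = inconsistencies),
            class = "consistency_result")
}

empty_inconsistencies <- function() {
  data.frame(node = character(), sign = character(),
             achievable = character(), type = character(),
             group = integer(), witness = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("consistency:", if (x$consistent) "CONSISTENT" else "INCONSISTENT",
      "\n")
  if (!is.na(x$n_solutions)) {
    cat("  consistent completions:", x$n_solutions, "\n")
  }
  if (nrow(x$inconsistencies)) {
    cat("  inconsistent nodes:",
        paste(unique(x$inconsistencies$node), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Check consistency of observations against a network
#'
#' @param graph a [signed_graph()].
#' @param observations named character vector of `"+"`/`"-"` on graph nodes.
#' @param count_solutions if `TRUE` and the number of unobserved nodes is
#'   within `guard`, the exact number of consistent completions is counted
#'   by enumeration; otherwise `n_solutions` is `NA`.
#' @param guard enumeration guard, see [enumerate_consistent()].
#' @return a `consistency_result`: list with `consistent` (logical),
#'   `n_solutions` (integer or `NA`), `inconsistencies` (a `data.frame`,
#'   see [localize_inconsistencies()]).
#' @export
check_consistency <- function(graph, observations,
                              count_solutions = FALSE, guard = 25L) {
  obs <- as_observations(observations, graph)
  cc <- .sc_compile(graph)
  sat <- .sc_sat(cc, .sc_dom_init(cc, obs))
  if (!sat) {
    return(new_consistency_result(FALSE, 0L,
                                  localize_inconsistencies(graph, obs)))
  }
  n <- NA_integer_
  if (count_solutions && nrow(graph$nodes) - length(obs) <= guard) {
    n <- length(enumerate_consistent(graph, obs, guard))
  }
  new_consistency_result(TRUE, n)
}

#' Localize inconsistent parts of the network
#'
#' Propagates forced signs (observations plus everything they determine)
#' to a fixpoint.  A node whose forced sign is not among the influences
#' achievable from its predecessors' forced signs is locally unsatisfiable
#' and yields one report, with the predecessor signs used as witness
#' context.  When the system is globally unsatisfiable without any locally
#' unsatisfiable node (a cyclic conflict), a minimal conflicting
#' observation set is found by deletion-based shrinking and reported as a
#' single group with `type = "core"`.
#'
#' @inheritParams check_consistency
#' @return `data.frame` with columns `node`, `sign` (the observed or forced
#'   sign), `achievable` (collapsed with `/`), `type` (`"local"` or
#'   `"core"`), `group` (conflict group id), `witness` (predecessor signs,
#'   collapsed).  Zero rows when consistent.
#' @export
localize_inconsistencies <- function(graph, observations) {
  obs <- as_observations(observations, graph)
  cc <- .sc_compile(graph)
  pr <- .sc_propagate(cc, .sc_dom_init(cc, obs), collect_conflicts = TRUE)
  reports <- list()
  for (cf in pr$conflicts) {
    v <- cf$v
    p <- cc$preds[[v]]
    det <- p[xor(pr$dom[p, 1L], pr$dom[p, 2L])]
    witness <- paste(cc$nodes[det],
                     ifelse(pr$dom[det, 1L], "+", "-"),
                     sep = "=", collapse = ";")
    dv <- c("+", "-")[c(pr$dom[v, 1L], pr$dom[v, 2L])]
    reports[[length(reports) + 1L]] <- data.frame(
      node = cc$nodes[v],
      sign = if (length(dv) == 1L) dv else NA_character_,
      achievable = paste(c("+", "-")[cf$ach], collapse = "/"),
      type = "local",
      group = length(reports) + 1L,
      witness = witness,
      stringsAsFactors = FALSE)
  }
  if (!length(reports)) {
    if (.sc_sat(cc, .sc_dom_init(cc, obs))) return(empty_inconsistencies())
    # global conflict without a locally unsatisfiable node: shrink the
    # observation set to a minimal conflicting core
    core <- obs
    for (nm in names(obs)) {
      trial <- core[setdiff(names(core), nm)]
      if (!.sc_sat(cc, .sc_dom_init(cc, trial))) core <- trial
    }
    if (!length(core)) {
      # the topology alone is unsatisfiable (e.g. a purely negative odd
      # cycle); there is no observation to blame
      reports[[1L]] <- data.frame(
        node = NA_character_, sign = NA_character_,
        achievable = NA_character_, type = "core", group = 1L,
        witness = "", stringsAsFactors = FALSE)
    } else {
      reports[[1L]] <- data.frame(
        node = names(core),
        sign = unname(core),
        achievable = NA_character_,
        type = "core",
        group = 1L,
        witness = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, reports)
  out <- out[order(out$group, out$node, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute invariant sign predictions
#'
#' A prediction is an unobserved node whose variation sign is identical in
#' every consistent completion of the observations.  Invariance is
#' established by refutation: after propagating the observations, a node
#' still allowing both signs is tested by fixing each sign in turn and
#' deciding satisfiability; exactly one satisfiable sign makes the node a
#' prediction.  On an inconsistent instance the prediction set is empty and
#' the result carries the localized reports.  Results agree exactly with
#' the invariants of [enumerate_consistent()] wherever enumeration is
#' feasible.
#'
#' @inheritParams check_consistency
#' @return list with components `result` (a `consistency_result`) and
#'   `predictions` (`data.frame` with columns `node`, `sign`, `deduction`
#'   in `{"FORWARD","BACKWARD"}`, sorted by node).
#' @export
compute_predictions <- function(graph, observations) {
  obs <- as_observations(observations, graph)
  cc <- .sc_compile(graph)
  dom0 <- .sc_dom_init(cc, obs)
  if (!.sc_sat(cc, dom0)) {
    return(list(result = new_consistency_result(
                  FALSE, 0L, localize_inconsistencies(graph, obs)),
                predictions = empty_predictions()))
  }
  pr <- .sc_propagate(cc, dom0)
  dom <- pr$dom
  unobs <- which(!(cc$nodes %in% names(obs)))
  pred_nodes <- character(0)
  pred_signs <- character(0)
  for (v in unobs) {
    if (xor(dom[v, 1L], dom[v, 2L])) {
      pred_nodes <- c(pred_nodes, cc$nodes[v])
      pred_signs <- c(pred_signs, if (dom[v, 1L]) "+" else "-")
      next
    }
    d <- dom; d[v, 2L] <- FALSE
    sat_plus <- .sc_sat(cc, d)
    d <- dom; d[v, 1L] <- FALSE
    sat_minus <- .sc_sat(cc, d)
    if (xor(sat_plus, sat_minus)) {
      pred_nodes <- c(pred_nodes, cc$nodes[v])
      pred_signs <- c(pred_signs, if (sat_plus) "+" else "-")
    }
  }
  preds <- data.frame(node = pred_nodes, sign = pred_signs,
                      stringsAsFactors = FALSE)
  preds <- preds[order(preds$node, method = "radix"), , drop = FALSE]
  rownames(preds) <- NULL
  preds <- classify_deductions(graph, obs, preds)
  list(result = new_consistency_result(TRUE), predictions = preds)
}

empty_predictions <- function() {
  data.frame(node = character(), sign = character(),
             deduction = character(), stringsAsFactors = FALSE)
}

#' Label predictions as forward or backward deductions
#'
#' A prediction on node `v` is a *forward* deduction when it follows from
#' the concerted action of `v`'s precursors alone: taking the final signs
#' of all predecessors (observed or predicted; still-undetermined
#' predecessors contribute both signs), the achievable set at `v` is the
#' singleton containing exactly the predicted sign.  Every other prediction
#' is *backward*: it is forced globally through `v`'s successors, as the
#' only possible explanation of downstream observations.  A predicted node
#' without predecessors is always backward.
#'
#' @param graph a [signed_graph()].
#' @param observations named character vector of observations.
#' @param predictions `data.frame` with columns `node`, `sign`.
#' @return the `predictions` frame with a `deduction` column added.
#' @export
classify_deductions <- function(graph, observations, predictions) {
  obs <- as_observations(observations)
  values <- c(obs, stats::setNames(predictions$sign, predictions$node))
  deduction <- character(nrow(predictions))
  for (k in seq_len(nrow(predictions))) {
    ach <- achievable_signs(graph, values, predictions$node[k])
    deduction[k] <- if (identical(ach, predictions$sign[k])) {
      "FORWARD"
    } else {
      "BACKWARD"
    }
  }
  predictions$deduction <- deduction
  predictions
}
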