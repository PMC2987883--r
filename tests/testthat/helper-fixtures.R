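# Shared helpers: brute-force oracle and small graph builders.

# Invariants of the full solution set, computed by explicit enumeration.
# Independent reference for compute_predictions().
oracle_invariants <- function(graph, obs) {
  sols <- enumerate_consistent(graph, obs)
  un <- sort(setdiff(graph$nodes$name, names(obs)), method = "radix")
  inv <- stats::setNames(character(0), character(0))
  if (length(sols)) {
    for (v in un) {
      ss <- unique(vapply(sols, function(a) a[[v]], character(1)))
      if (length(ss) == 1L) inv[v] <- ss
    }
  }
  list(solutions = sols, invariants = inv)
}

prediction_map <- function(predictions) {
  stats::setNames(predictions$sign, predictions$node)
}

# Node B regulated transcriptionally by A and post-translationally by C.
fig2a_motif <- function() {
  signed_graph(data.frame(
    source = c("A", "C"), target = c("B", "B"), sign = c("+", "-"),
    level = c("transcriptional", "post_translational")))
}

random_observations <- function(graph, k, seed) {
  set.seed(seed)
  nm <- sample(graph$nodes$name, k)
  stats::setNames(sample(c("+", "-"), k, replace = TRUE), nm)[order(nm)]
}
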