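test_that("achievable signs follow predecessor signs through edge labels", {
  g <- load_fixture("fig3_original_motifs")
  # single activating predecessor with known sign forces that sign
  expect_identical(achievable_signs(g, c(PDGFRB = "+"), "(PIK3R.)"), "+")
  # no predecessors: free input
  expect_setequal(achievable_signs(g, character(0), "PDGFRB"), c("+", "-"))
  # dual edge contributes both signs even from a signed predecessor
  gd <- signed_graph(data.frame(source = "U", target = "V", sign = "?"))
  expect_setequal(achievable_signs(gd, c(U = "+"), "V"), c("+", "-"))
  # signed edge from an unknown predecessor contributes both signs
  gs <- signed_graph(data.frame(source = "U", target = "V", sign = "-"))
  expect_setequal(achievable_signs(gs, character(0), "V"), c("+", "-"))
  expect_error(achievable_signs(g, character(0), "NOPE"), "unknown node")
})

test_that("total-assignment consistency matches the local rule", {
  g <- signed_graph(data.frame(
    source = c("(RAC.)", "(RHO.)"), target = "Cell_Migration", sign = "+",
    level = "post_translational"))
  bad <- c("(RAC.)" = "+", "(RHO.)" = "+", Cell_Migration = "-")
  expect_false(is_consistent_total(g, bad))
  good <- c("(RAC.)" = "-", "(RHO.)" = "+", Cell_Migration = "-")
  expect_true(is_consistent_total(g, good))
  # isolated node: any sign is fine
  g1 <- signed_graph(nodes = "X")
  expect_true(is_consistent_total(g1, c(X = "+")))
  expect_error(is_consistent_total(g, c("(RAC.)" = "+")), "partial")
})

test_that("enumeration finds the exact solution set", {
  g <- load_fixture("fig1_igf_motif")
  sols <- enumerate_consistent(g, load_fixture("fig1_observations"))
  expect_length(sols, 1L)
  s <- sols[[1]]
  expect_identical(unname(s[c("IGF1", "IGFBP3", "(.RAS)", "(PIK3C.)")]),
                   c("+", "-", "+", "+"))
  # two unconnected unobserved nodes: all four assignments
  g2 <- signed_graph(nodes = c("A", "B"))
  expect_length(enumerate_consistent(g2), 4L)
  # locally contradicted motif: no solutions
  g3 <- signed_graph(data.frame(source = "PDGFRB", target = "(PIK3R.)",
                                sign = "+"))
  expect_length(enumerate_consistent(g3, c(PDGFRB = "+", "(PIK3R.)" = "-")),
                0L)
  # every enumerated assignment satisfies the rule
  for (s in enumerate_consistent(load_fixture("fig3_original_motifs"))) {
    expect_true(is_consistent_total(load_fixture("fig3_original_motifs"), s))
  }
})

test_that("the enumeration guard trips on large unobserved sets", {
  g <- generate_network(40, seed = 7)
  expect_error(enumerate_consistent(g), "guard")
  expect_silent(compute_predictions(g, character(0)))
})

test_that("predictions equal the enumeration-oracle invariants", {
  for (i in 1:50) {
    acyc <- i <= 30
    g <- generate_network(12, acyclic = acyc, seed = 100 + i)
    obs <- if (acyc) {
      sample_consistent_observations(g, 0.3, seed = 200 + i)$observations
    } else {
      random_observations(g, 4L, seed = 300 + i)
    }
    orc <- oracle_invariants(g, obs)
    cp <- compute_predictions(g, obs)
    expect_identical(cp$result$consistent, length(orc$solutions) > 0)
    expect_identical(prediction_map(cp$predictions), orc$invariants)
  }
})

test_that("a chain with no observations yields no predictions", {
  g <- signed_graph(data.frame(source = "A", target = "B", sign = "+"))
  cp <- compute_predictions(g, character(0))
  expect_identical(nrow(cp$predictions), 0L)
  expect_true(cp$result$consistent)
})

test_that("adding observations never increases the solution count", {
  for (i in 1:10) {
    g <- generate_network(10, acyclic = TRUE, seed = 400 + i)
    sc <- sample_consistent_observations(g, 0.5, seed = 500 + i)
    obs <- sc$observations
    n_full <- length(enumerate_consistent(g, obs))
    expect_gt(n_full, 0L)
    if (length(obs) >= 1L) {
      # removing one observation never breaks consistency
      sub <- obs[-1]
      n_sub <- length(enumerate_consistent(g, sub))
      expect_gte(n_sub, n_full)
      # adding one observation drawn from the witness keeps consistency
      hidden <- sc$assignment
      extra_nodes <- setdiff(names(hidden), names(obs))
      if (length(extra_nodes)) {
        aug <- c(obs, hidden[extra_nodes[1]])
        n_aug <- length(enumerate_consistent(g, aug))
        expect_lte(n_aug, n_full)
        expect_gt(n_aug, 0L)
      }
    }
  }
})

test_that("predictions persist under consistent observation supersets", {
  for (i in 1:10) {
    g <- generate_network(12, acyclic = TRUE, seed = 600 + i)
    sc <- sample_consistent_observations(g, 0.25, seed = 700 + i)
    obs <- sc$observations
    preds <- prediction_map(compute_predictions(g, obs)$predictions)
    extra <- setdiff(names(sc$assignment), names(obs))[1:3]
    extra <- extra[!is.na(extra)]
    aug <- c(obs, sc$assignment[extra])
    preds2 <- prediction_map(compute_predictions(g, aug)$predictions)
    for (v in names(preds)) {
      if (v %in% names(aug)) next     # became observed
      expect_identical(preds2[[v]], preds[[v]])
    }
  }
})

test_that("inconsistency localization pinpoints the conflicting nodes", {
  g <- load_fixture("fig3_original_motifs")
  rep <- localize_inconsistencies(g, load_fixture("fig3_observations"))
  expect_setequal(rep$node, c("(PIK3R.)", "Cell_Migration"))
  expect_identical(rep$sign[rep$node == "(PIK3R.)"], "-")
  expect_identical(rep$achievable[rep$node == "(PIK3R.)"], "+")
  expect_match(rep$witness[rep$node == "Cell_Migration"], "\\(RAC\\.\\)=\\+")
  # consistent instance: empty report
  g1 <- load_fixture("fig1_igf_motif")
  expect_identical(
    nrow(localize_inconsistencies(g1, load_fixture("fig1_observations"))),
    0L)
})

test_that("global conflicts without a local culprit yield a minimal core", {
  # one hidden regulator driving two observed targets with incompatible
  # signs: no node is locally unsatisfiable (the regulator can explain
  # either observation alone), yet no completion satisfies both
  g <- signed_graph(data.frame(source = "U", target = c("A", "B"),
                               sign = "+"))
  obs <- c(A = "+", B = "-")
  expect_length(enumerate_consistent(g, obs), 0L)
  rep <- localize_inconsistencies(g, obs)
  core <- rep[rep$type == "core", ]
  expect_setequal(core$node, c("A", "B"))
  # the reported observation subset is itself unsatisfiable
  expect_length(enumerate_consistent(
    g, stats::setNames(core$sign, core$node)), 0L)
})

test_that("deduction labels are forward iff forced by precursors alone", {
  g <- load_fixture("fig1_igf_motif")
  cp <- compute_predictions(g, load_fixture("fig1_observations"))
  lab <- stats::setNames(cp$predictions$deduction, cp$predictions$node)
  expect_identical(unname(lab["(PIK3C.)"]), "FORWARD")
  expect_identical(unname(lab[c("IGF1", "IGFBP3", "(.RAS)")]),
                   rep("BACKWARD", 3))
  # single observed activating predecessor, same predicted sign: forward
  g2 <- signed_graph(data.frame(source = "A", target = "B", sign = "+"))
  cp2 <- compute_predictions(g2, c(A = "+"))
  expect_identical(cp2$predictions$deduction, "FORWARD")
  # a predicted node with no predecessors is always backward
  g3 <- signed_graph(data.frame(source = "A", target = "B", sign = "+"))
  cp3 <- compute_predictions(g3, c(B = "+"))
  expect_identical(cp3$predictions$node, "A")
  expect_identical(cp3$predictions$deduction, "BACKWARD")
})

test_that("results are independent of input edge order", {
  g <- load_fixture("fig1_igf_motif")
  for (seed in 1:5) {
    set.seed(seed)
    shuffled <- signed_graph(g$edges[sample(nrow(g$edges)), ])
    cp1 <- compute_predictions(g, load_fixture("fig1_observations"))
    cp2 <- compute_predictions(shuffled, load_fixture("fig1_observations"))
    expect_identical(cp2$predictions, cp1$predictions)
  }
})

test_that("solution counting is exact when requested", {
  g <- signed_graph(nodes = c("A", "B"))
  res <- check_consistency(g, character(0), count_solutions = TRUE)
  expect_identical(res$n_solutions, 4L)
  res2 <- check_consistency(g, c(A = "+"), count_solutions = FALSE)
  expect_true(is.na(res2$n_solutions))
})
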