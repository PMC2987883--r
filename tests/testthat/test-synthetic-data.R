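test_that("network generation is a pure function of its parameters", {
  g1 <- generate_network(20, seed = 42)
  g2 <- generate_network(20, seed = 42)
  expect_identical(write_network(g1), write_network(g2))
  g3 <- generate_network(20, seed = 43)
  expect_false(identical(write_network(g1), write_network(g3)))
})

test_that("generated networks match the requested scale", {
  g <- generate_network(130, edge_density = 2.3, seed = 1)
  expect_identical(nrow(g$nodes), 130L)
  expect_equal(nrow(g$edges), 299L, tolerance = 0.05)
  # one node: no edges, node retained
  g1 <- generate_network(1, seed = 1)
  expect_identical(nrow(g1$nodes), 1L)
  expect_identical(nrow(g1$edges), 0L)
  # acyclic graphs have a topological order (no back edges)
  ga <- generate_network(30, acyclic = TRUE, seed = 2)
  idx <- stats::setNames(seq_len(30), ga$nodes$name)
  expect_true(all(idx[ga$edges$source] < idx[ga$edges$target]))
})

test_that("sampled observations are consistent by construction", {
  for (i in 1:25) {
    g <- generate_network(12, acyclic = TRUE, seed = 800 + i)
    sc <- sample_consistent_observations(g, 0.4, seed = 900 + i)
    expect_true(is_consistent_total(g, sc$assignment))
    expect_true(check_consistency(g, sc$observations)$consistent)
    expect_identical(sc$observations,
                     sc$assignment[sort(names(sc$observations),
                                        method = "radix")])
  }
  # full reveal returns the whole witness; zero reveal returns nothing
  g <- generate_network(8, acyclic = TRUE, seed = 3)
  full <- sample_consistent_observations(g, 1, seed = 4)
  expect_length(full$observations, 8L)
  none <- sample_consistent_observations(g, 0, seed = 4)
  expect_length(none$observations, 0L)
})

test_that("a purely negative odd cycle admits no consistent assignment", {
  g <- signed_graph(data.frame(source = c("A", "B", "C"),
                               target = c("B", "C", "A"), sign = "-"))
  expect_length(enumerate_consistent(g), 0L)
  expect_error(sample_consistent_observations(g, 0.5, seed = 1),
               "no consistent")
})

test_that("injected sign flips create localizable inconsistencies", {
  g <- signed_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                               sign = "+"))
  obs <- c(A = "+", B = "+", C = "+")
  expect_identical(inject_inconsistency(g, obs, 0), obs)
  bad <- inject_inconsistency(g, obs, 1, seed = 5)
  expect_identical(sum(bad != obs), 1L)
  rep <- localize_inconsistencies(g, bad)
  expect_true(names(bad)[bad != obs] %in% rep$node)
  expect_error(inject_inconsistency(g, obs, 4), "exceeds")
})

test_that("simulated series have the requested structure", {
  s <- simulate_timeseries(n_genes = 4, probes_per_gene = 3, times = 0:5,
                           slopes = c(1, -1, 0, 2), seed = 6)
  expect_identical(dim(s$matrix), c(12L, 6L))
  expect_length(unique(unname(s$probe_to_gene)), 4L)
  expect_identical(unname(attr(s, "slopes")), c(1, -1, 0, 2))
  s2 <- simulate_timeseries(n_genes = 4, probes_per_gene = 3, times = 0:5,
                            slopes = c(1, -1, 0, 2), seed = 6)
  expect_identical(s$matrix, s2$matrix)
})

test_that("fixture transcriptions are frozen by checksum", {
  sums <- c(
    fig1_igf_motif.csv = "850d5fc75330aed6584b9e91b751b1de",
    fig3_original_motifs.csv = "9fbb5c507469bae11e24e7b055f6fbb8",
    fig4_subnetworks.csv = "5a6e8f1eafdf94d6fb4d0d74df672d7c",
    synthetic_core_network.csv = "734eda965d0f0f96ac0aa864af567423",
    synthetic_core_observations.csv = "006af606e09297b3e141a936779cd05f",
    table1_observations.csv = "8b561b4d95b06618d2b67926a5b9cb2a",
    table2_expected_predictions.csv = "9965256501b655ce25b546fe67e1995a")
  for (f in names(sums)) {
    path <- system.file("extdata", f, package = "qualnet")
    expect_identical(unname(tools::md5sum(path)), unname(sums[f]),
                     label = f)
  }
})

test_that("fixture registry contents have the documented shapes", {
  expect_identical(nrow(load_fixture("table2_expected_predictions")), 31L)
  g1 <- load_fixture("fig1_igf_motif")
  expect_identical(nrow(g1$nodes), 7L)
  expect_identical(nrow(g1$edges), 7L)
  f4 <- load_fixture("fig4_subnetworks")
  expect_setequal(names(f4), c("A", "B", "C", "D", "E"))
  expect_error(load_fixture("nope"), "unknown fixture")
})

test_that("published subnetworks reproduce their prediction chains", {
  f4 <- load_fixture("fig4_subnetworks")
  t1 <- load_fixture("table1_observations")
  t2 <- load_fixture("table2_expected_predictions")
  expected <- stats::setNames(t2$sign, t2$node)
  labels <- stats::setNames(t2$deduction, t2$node)

  # IGF/TGFBR2/TP73 subnetwork: ten published rows, exact signs and labels
  oA <- map_observations(t1, f4$A, mode = "exact")
  cpA <- compute_predictions(f4$A, oA)
  wantA <- c("(.RAS)", "(PIK3C.)", "IGF1", "IGF2", "IGFBP3", "TGFBR2",
             "TP73", "mRNA_BCL2", "mRNA_IGF2", "mRNA_TGFBR2")
  expect_setequal(cpA$predictions$node, wantA)
  got <- prediction_map(cpA$predictions)
  expect_identical(got[wantA], expected[wantA])
  gotlab <- stats::setNames(cpA$predictions$deduction, cpA$predictions$node)
  expect_identical(gotlab[wantA], labels[wantA])

  # JUN/FASLG subnetwork
  cpB <- compute_predictions(f4$B, map_observations(t1, f4$B, "exact"))
  gB <- prediction_map(cpB$predictions)
  expect_identical(gB[c("FASLG", "JUN", "mRNA_TP53")],
                   expected[c("FASLG", "JUN", "mRNA_TP53")])

  # RAC/RHO/cell-migration subnetwork: the family is predicted down
  cpC <- compute_predictions(f4$C, map_observations(t1, f4$C, "exact"))
  gC <- prediction_map(cpC$predictions)
  expect_identical(unname(gC["(RAC.)"]), "-")
  expect_identical(
    cpC$predictions$deduction[cpC$predictions$node == "(RAC.)"], "BACKWARD")

  # PRKCB1/RB1 subnetwork
  cpD <- compute_predictions(f4$D, map_observations(t1, f4$D, "exact"))
  gD <- prediction_map(cpD$predictions)
  expect_identical(gD[c("PRKCB1", "RB1_p")],
                   expected[c("PRKCB1", "RB1_p")])

  # cyclin/CDC2 subnetwork, driven by the complex observations
  oE <- c("((CCNA.)_p:CDC2)" = "-", "(CCNB1_p:CDC2)" = "-")
  cpE <- compute_predictions(f4$E, oE)
  expect_identical(prediction_map(cpE$predictions)[["CDC2"]],
                   expected[["CDC2"]])
  expect_identical(cpE$predictions$deduction, "FORWARD")
})
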