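test_that("the ideal helix has 3.8 A consecutive CA-CA distances", {
  s <- generate_toy_structure(12, c(-57, -47))
  ca <- as.matrix(s$atoms[s$atoms$atom == "CA", c("x", "y", "z")])
  d <- unname(sqrt(rowSums(diff(ca)^2)))
  expect_equal(d, rep(3.8, 11), tolerance = 0.05)
})

test_that("structure generation is deterministic and normalizes torsions", {
  s1 <- generate_toy_structure(8, c(-57, -47), seed = 2L)
  s2 <- generate_toy_structure(8, c(-57, -47), seed = 2L)
  expect_identical(s1$atoms, s2$atoms)
  expect_warning(s3 <- generate_toy_structure(5, c(303, -47)), "normalized")
  # 303 degrees == -57 degrees
  s4 <- generate_toy_structure(5, c(-57, -47))
  expect_equal(s3$atoms$x, s4$atoms$x, tolerance = 1e-9)
})

test_that("the study-calibrated preset reproduces the 63/1254 class split", {
  fm <- generate_feature_table(paper_calibrated_spec(seed = 3L))
  expect_equal(nrow(fm), 1317L)
  expect_equal(sum(fm$label == 1L), 63L)
  expect_equal(sum(fm$label == 0L), 1254L)
  expect_equal(100 * mean(fm$label == 1L), 4.78, tolerance = 0.005)
  expect_equal(100 * mean(fm$label == 0L), 95.22, tolerance = 0.005)
  expect_identical(names(fm), c("residue", feature_registry(), "label"))
  expect_false(anyNA(fm))
})

test_that("without planted effects the group medians stay close", {
  spec <- synthetic_spec(1317, 63, seed = 19L)
  fm <- generate_feature_table(spec)
  for (f in feature_registry()) {
    gap <- abs(stats::median(fm[[f]][fm$label == 1L]) -
               stats::median(fm[[f]][fm$label == 0L]))
    expect_lt(gap, 0.5)
  }
})

test_that("a planted +2 SD effect is detected by the bootstrap test", {
  spec <- synthetic_spec(1317, 63, effect_sizes = c(closeness = 2), seed = 23L)
  fm <- generate_feature_table(spec)
  t <- bootstrap_median_test(fm$closeness[fm$label == 0L],
                             fm$closeness[fm$label == 1L], seed = 24L)
  expect_lt(t$p_value, 0.01)
})

test_that("feature tables are bit-reproducible and validate their spec", {
  spec <- synthetic_spec(100, 10, effect_sizes = c(degree = 1), seed = 5L)
  expect_identical(generate_feature_table(spec), generate_feature_table(spec))
  expect_error(generate_feature_table(
    synthetic_spec(100, 0, effect_sizes = c(degree = 1), seed = 1L)),
    "no deficient group")
  expect_error(synthetic_spec(100, 10, effect_sizes = c(nope = 1)))
})

test_that("the shared latent factor induces the requested correlation", {
  fm <- generate_feature_table(synthetic_spec(4000, 0, correlation = 0.3, seed = 31L))
  x <- as.matrix(fm[, feature_registry()])
  off <- stats::cor(x)[upper.tri(diag(14))]
  expect_equal(mean(off), 0.3, tolerance = 0.03)
})

test_that("random graphs honour their edge-probability extremes", {
  g0 <- generate_random_graph(10, "erdos_renyi", p = 0, seed = 1L)
  g1 <- generate_random_graph(10, "erdos_renyi", p = 1, seed = 1L)
  expect_equal(igraph::ecount(g0), 0L)
  expect_equal(igraph::ecount(g1), 45L)
  expect_error(generate_random_graph(10, "erdos_renyi", p = 1.5), "p must lie")
})

test_that("Erdos-Renyi edge counts stay inside the binomial 99% band", {
  n_pairs <- choose(100, 2)
  lo <- stats::qbinom(0.005, n_pairs, 0.1)
  hi <- stats::qbinom(0.995, n_pairs, 0.1)
  counts <- vapply(1:10, function(seed)
    igraph::ecount(generate_random_graph(100, "erdos_renyi", p = 0.1, seed = seed)),
    0)
  expect_true(all(counts >= lo & counts <= hi))
  # determinism
  expect_true(igraph::identical_graphs(
    generate_random_graph(50, "barabasi_albert", m = 2, seed = 9L),
    generate_random_graph(50, "barabasi_albert", m = 2, seed = 9L)))
})

test_that("fixture writing emits the three pipeline inputs", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_fixtures(dir, n_res = 10L, n_deficient = 2L, seed = 3L)
  expect_true(all(file.exists(paths)))
  s <- parse_structure(paths[["structure"]])
  expect_equal(nrow(residue_table(s)), 10L)
  labs <- utils::read.csv(paths[["labels"]])
  expect_equal(sum(labs$label), 2L)
})
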