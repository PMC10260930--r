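toy_table <- function(degree, betweenness, closeness = NULL) {
  data.frame(residue = as.character(seq_along(degree)),
             degree = degree, betweenness = betweenness,
             closeness = closeness %||% rep(0.5, length(degree)),
             stringsAsFactors = FALSE)
}

test_that("degree range [2, 13] reproduces the published bin edges", {
  tab <- toy_table(degree = c(2, 5, 9, 13), betweenness = 10^c(0.5, 1, 2, 3))
  grid <- bin_criticality(tab)$grid
  expect_equal(grid$degree_edges[2:5], c(4.75, 7.5, 10.25, 13.0))
  expect_equal(grid$degree_edges[1], 1.989, tolerance = 5e-4)  # nudged lower edge
  expect_equal(diff(grid$degree_edges[2:5]), rep(2.75, 3))
})

test_that("the (max degree, max log-betweenness) node is HDHB", {
  tab <- toy_table(degree = c(2, 5, 9, 13), betweenness = 10^c(0.5, 1, 2, 3))
  lab <- bin_criticality(tab)$labels
  expect_equal(lab$label[4], "HDHB")
  expect_equal(lab$label[1], "LDLB")
})

test_that("labels match a direct interval-membership oracle on 500 random points", {
  tab <- with_seed(42, toy_table(degree = sample(2:60, 500, replace = TRUE),
                                 betweenness = 10^runif(500, -1, 5)))
  res <- bin_criticality(tab)
  ora_deg <- oracle_bin(tab$degree, res$grid$degree_edges)
  ora_lb <- oracle_bin(log10(tab$betweenness), res$grid$logbet_edges)
  expect_equal(res$labels$degree_bin, ora_deg)
  expect_equal(res$labels$logbet_bin, ora_lb)
  expected <- ifelse(ora_deg == 4 & ora_lb == 4, "HDHB",
              ifelse(ora_deg == 1 & ora_lb == 4, "LDHB",
              ifelse(ora_deg == 1 & ora_lb == 1, "LDLB", "UNCLASSIFIED")))
  expect_equal(res$labels$label, expected)
})

test_that("HDHB degrees always exceed LDLB degrees", {
  tab <- with_seed(7, toy_table(degree = sample(2:40, 300, replace = TRUE),
                                betweenness = 10^runif(300, 0, 5)))
  lab <- bin_criticality(tab)$labels
  if (any(lab$label == "HDHB") && any(lab$label == "LDLB")) {
    expect_gt(min(lab$degree[lab$label == "HDHB"]),
              max(lab$degree[lab$label == "LDLB"]))
  }
})

test_that("zero-betweenness nodes are excluded from binning and left unclassified", {
  tab <- toy_table(degree = c(2, 5, 9, 13, 4), betweenness = c(10, 100, 1000, 10000, 0))
  lab <- bin_criticality(tab)$labels
  expect_equal(lab$label[5], "UNCLASSIFIED")
  expect_true(is.na(lab$degree_bin[5]))
})

test_that("degenerate axes are rejected", {
  expect_error(bin_criticality(toy_table(degree = c(3, 3, 3), betweenness = c(1, 2, 3))),
               "distinct")
  expect_error(bin_criticality(toy_table(degree = c(1, 2, 3), betweenness = c(0, 0, 5))),
               "positive betweenness")
})

test_that("a single node is its own Pareto front", {
  expect_equal(pareto_supercritical(toy_table(3, 3, 3)), "1")
})

test_that("the documented 3-point example yields a single-front point", {
  tab <- data.frame(residue = c("a", "b", "c"),
                    degree = c(3, 1, 2), betweenness = c(3, 2, 1),
                    closeness = c(3, 3, 1), stringsAsFactors = FALSE)
  expect_equal(pareto_supercritical(tab), "a")
})

test_that("duplicated non-dominated points are all kept", {
  tab <- data.frame(residue = c("a", "b", "c"),
                    degree = c(3, 3, 1), betweenness = c(2, 2, 1),
                    closeness = c(1, 1, 0), stringsAsFactors = FALSE)
  expect_equal(sort(pareto_supercritical(tab)), c("a", "b"))
})

test_that("the front matches the O(n^2) dominance oracle on random points", {
  for (seed in c(1, 5, 9)) {
    tab <- with_seed(seed, data.frame(
      residue = as.character(1:400),
      degree = sample(1:30, 400, replace = TRUE),
      betweenness = rexp(400, 1 / 100),
      closeness = runif(400), stringsAsFactors = FALSE))
    m <- as.matrix(tab[, c("degree", "betweenness", "closeness")])
    expect_equal(pareto_supercritical(tab), tab$residue[oracle_pareto(m)])
  }
})

test_that("the front is invariant under strictly monotone axis transforms", {
  tab <- with_seed(3, data.frame(
    residue = as.character(1:200),
    degree = sample(1:20, 200, replace = TRUE),
    betweenness = rexp(200, 1 / 1000) + 0.1,
    closeness = runif(200), stringsAsFactors = FALSE))
  f1 <- pareto_supercritical(tab)
  tab$betweenness <- log10(tab$betweenness)
  tab$degree <- tab$degree^3
  expect_equal(pareto_supercritical(tab), f1)
})
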