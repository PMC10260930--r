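test_that("Kyte-Doolittle lookups return the published scale values", {
  expect_equal(kd_hydrophobicity("ILE"), 4.5)
  expect_equal(kd_hydrophobicity("ARG"), -4.5)
  expect_equal(kd_hydrophobicity("GLY"), -0.4)
  expect_equal(kd_hydrophobicity(c("ala", "VAL")), c(1.8, 4.2))
  expect_error(kd_hydrophobicity("XYZ"), "XYZ")
})

test_that("terminal residues have undefined phi/psi and interior torsions round-trip", {
  s <- generate_toy_structure(12, c(-57, -47))
  d <- backbone_dihedrals(s)
  expect_true(is.na(d$phi[1]))
  expect_true(is.na(d$psi[12]))
  expect_equal(d$phi[2:12], rep(-57, 11), tolerance = 0.5)
  expect_equal(d$psi[1:11], rep(-47, 11), tolerance = 0.5)
})

test_that("torsion round-trip holds across a seeded sweep of (phi, psi)", {
  torsion_grid <- with_seed(21, cbind(runif(6, -179, 179), runif(6, -179, 179)))
  for (r in seq_len(nrow(torsion_grid))) {
    tor <- torsion_grid[r, ]
    s <- generate_toy_structure(6, tor)
    d <- backbone_dihedrals(s)
    expect_equal(d$phi[2:6], rep(tor[1], 5), tolerance = 0.5)
    expect_equal(d$psi[1:5], rep(tor[2], 5), tolerance = 0.5)
  }
})

test_that("chain breaks and collinear geometry yield missing dihedrals", {
  s <- generate_toy_structure(6, c(-57, -47))
  # pull residues 4..6 far away: break between 3 and 4
  shift <- s$atoms$seqnum >= 4L
  s$atoms$x[shift] <- s$atoms$x[shift] + 100
  d <- backbone_dihedrals(s)
  expect_true(is.na(d$psi[3]))
  expect_true(is.na(d$phi[4]))

  atoms <- data.frame(
    chain = "A", seqnum = c(1L, 1L, 1L, 2L), icode = "", resname = "ALA",
    atom = c("N", "CA", "C", "N"), element = c("N", "C", "C", "N"),
    x = c(0, 1, 2, 2.8), y = 0, z = 0,  # collinear backbone
    occupancy = 1, altloc = "", is_backbone = TRUE, stringsAsFactors = FALSE)
  s_lin <- structure(list(atoms = atoms), class = "fv_structure")
  expect_true(is.na(backbone_dihedrals(s_lin)$psi[1]))
})

single_atom_structure <- function(xyz, element = "C", n = 1L) {
  atoms <- data.frame(
    chain = "A", seqnum = seq_len(nrow(xyz)), icode = "", resname = "GLY",
    atom = "CA", element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "", is_backbone = TRUE, stringsAsFactors = FALSE)
  structure(list(atoms = atoms), class = "fv_structure")
}

test_that("an isolated carbon's surface equals the expanded-sphere area", {
  s <- single_atom_structure(matrix(c(0, 0, 0), 1))
  expect_equal(sasa(s)$sasa, 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("atoms far apart do not occlude each other", {
  s <- single_atom_structure(matrix(c(0, 0, 0, 100, 0, 0), 2, byrow = TRUE))
  a <- sasa(s)$sasa
  expect_equal(a, rep(4 * pi * 3.1^2, 2), tolerance = 1e-6)
})

test_that("an atom enclosed by a dense cage has near-zero accessible area", {
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- rbind(c(0, 0, 0), dirs * 2.0)
  s <- single_atom_structure(cage)
  buried <- sasa(s)$sasa[1]
  expect_lt(buried, 0.01 * 4 * pi * 3.1^2)
})

test_that("surface areas are converged in the point count", {
  s <- generate_toy_structure(8, c(-57, -47))
  a1 <- sasa(s, n_points = 960L)$sasa
  a2 <- sasa(s, n_points = 1920L)$sasa
  expect_lt(max(abs(a1 - a2) / pmax(a2, 1)), 0.02)
})

test_that("relative accessibility divides by the bundled reference areas", {
  ref <- gxg_reference()
  expect_equal(relative_accessibility(ref[["GLY"]], "GLY"), 1.0)
  expect_equal(relative_accessibility(0, "TRP"), 0.0)
  expect_equal(relative_accessibility(40.0, "GLY"), 40.0 / ref[["GLY"]])
  expect_error(relative_accessibility(10, "UNK"), "UNK")
})

synthetic_blocks <- function(n = 20L, seed = 5L) {
  with_seed(seed, {
    key <- residue_key("A", seq_len(n))
    cent <- data.frame(residue = key, degree = sample(2:10, n, TRUE),
                       betweenness = rexp(n) + 0.1, closeness = runif(n),
                       kcore = sample(1:3, n, TRUE), burts_constraint = runif(n),
                       authority = runif(n), pagerank = runif(n))
    struct <- data.frame(residue = key, kd_hydrophobicity = rnorm(n),
                         sasa = runif(n, 0, 200), sesa = runif(n, 0, 150),
                         relative_sesa = runif(n), phi = runif(n, -180, 180),
                         psi = runif(n, -180, 180))
    cons <- data.frame(residue = key, conservation = rnorm(n))
    labs <- data.frame(residue = key, label = as.integer(seq_len(n) <= 3))
    list(cent = cent, struct = struct, cons = cons, labs = labs)
  })
}

test_that("a complete table is fully retained with the 14 registry features in order", {
  b <- synthetic_blocks()
  fm <- assemble_feature_matrix(b$cent, b$struct, b$cons, b$labs)
  expect_equal(nrow(fm), 20L)
  expect_identical(names(fm), c("residue", feature_registry(), "label"))
  expect_equal(sum(fm$label), 3L)
  expect_equal(nrow(attr(fm, "drop_log")), 0L)
})

test_that("rows with zero betweenness or missing features are dropped and logged", {
  b <- synthetic_blocks()
  b$cent$betweenness[2] <- 0
  b$struct$phi[5] <- NA
  fm <- assemble_feature_matrix(b$cent, b$struct, b$cons, b$labs)
  log <- attr(fm, "drop_log")
  expect_equal(nrow(fm), 18L)
  expect_setequal(log$residue, c("A:2:", "A:5:"))
  expect_true("zero betweenness" %in% log$reason)
  expect_true("missing phi" %in% log$reason)
  # conservation of records
  expect_equal(nrow(fm) + nrow(log), 20L)
})

test_that("labels for residues absent from the structure warn and are ignored", {
  b <- synthetic_blocks()
  b$labs <- rbind(b$labs, data.frame(residue = "B:999:", label = 1L))
  expect_warning(fm <- assemble_feature_matrix(b$cent, b$struct, b$cons, b$labs),
                 "B:999:")
  expect_equal(sum(fm$label), 3L)
})

test_that("the structural block records provenance and the SESA fallback is flagged", {
  s <- generate_toy_structure(6, c(-57, -47))
  sf <- compute_structural_features(s, n_points = 240L)
  prov <- attr(sf, "provenance")
  expect_equal(unname(prov[["sesa"]]), "computed_approximate")
  expect_equal(unname(prov[["sasa"]]), "computed")
  imported <- data.frame(residue = sf$residue, sesa = seq_len(nrow(sf)) * 10)
  sf2 <- compute_structural_features(s, sesa = imported, n_points = 240L)
  expect_equal(attr(sf2, "provenance")[["sesa"]], "imported")
  expect_equal(sf2$sesa, imported$sesa)
})
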