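test_that("cationic atoms are identified by formal charge, any element", {
  p <- cation_pose(matrix(c(0, 0, 4), ncol = 3))
  expect_identical(cationic_atoms(p), 1L)
  # guanidinium dialect: charge on a carbon still counts
  g <- ligand_pose("g", "g", data.frame(
    element = c("C", "N", "N"), x = c(0, 1.3, -1.3), y = c(0, 0.5, 0.5),
    z = 0, formal_charge = c(1L, 0L, 0L), stringsAsFactors = FALSE))
  expect_identical(cationic_atoms(g), 1L)
  # neutral pose, heuristic off -> empty
  n <- ligand_pose("n", "n", data.frame(
    element = c("C", "O"), x = c(0, 1.2), y = 0, z = 0,
    formal_charge = c(0L, 0L), stringsAsFactors = FALSE))
  expect_length(cationic_atoms(n), 0L)
})

test_that("amine heuristic flags protonatable nitrogens but not amides", {
  # C-N(-C) secondary amine vs O=C-N amide
  amine <- ligand_pose("a", "a", data.frame(
    element = c("C", "N", "C"), x = c(-1.5, 0, 1.5), y = 0, z = 0,
    formal_charge = 0L, stringsAsFactors = FALSE),
    bonds = data.frame(from = c(1L, 2L), to = c(2L, 3L), order = c(1L, 1L)))
  got <- cationic_atoms(amine, heuristic = TRUE)
  expect_identical(as.integer(got), 2L)
  expect_true(attr(got, "inferred"))
  amide <- ligand_pose("b", "b", data.frame(
    element = c("O", "C", "N", "C"), x = c(-1.2, 0, 1.4, 2.8), y = 0, z = 0,
    formal_charge = 0L, stringsAsFactors = FALSE),
    bonds = data.frame(from = c(1L, 2L, 3L), to = c(2L, 3L, 4L),
                       order = c(2L, 1L, 1L)))
  expect_length(cationic_atoms(amide, heuristic = TRUE), 0L)
})

test_that("the 6-Angstrom ionic boundary is inclusive", {
  anchor <- asp_residue_atoms(cg = c(0, 0, 0))
  at <- function(d) cation_pose(matrix(c(0, 0, d), ncol = 3))
  expect_true(ionic_contact(at(6.00), anchor)$ionic_to_anchor)
  expect_false(ionic_contact(at(6.01), anchor)$ionic_to_anchor)
  expect_true(ionic_contact(at(5.95), anchor)$ionic_to_anchor)
  r <- ionic_contact(at(6.00), anchor)
  expect_equal(r$min_distance, 6.0, tolerance = 1e-12)
})

test_that("minimum is taken over all cationic atoms", {
  anchor <- asp_residue_atoms(cg = c(1, 2, 3))
  pose <- cation_pose(rbind(c(1, 2, 3 + 8), c(1, 2 + 5, 3)))
  r <- ionic_contact(pose, anchor)
  expect_true(r$ionic_to_anchor)
  expect_equal(r$min_distance, 5, tolerance = 1e-12)
  expect_identical(r$contributing_atom, 2L)
  bf <- brute_force_ionic(pose, anchor)
  expect_identical(r$ionic_to_anchor, bf$hit)
  expect_equal(r$min_distance, bf$min_d, tolerance = 1e-12)
})

test_that("poses without cations never form the contact", {
  anchor <- asp_residue_atoms()
  neutral <- ligand_pose("n", "n", data.frame(
    element = "C", x = 0, y = 0, z = 1, formal_charge = 0L,
    stringsAsFactors = FALSE))
  r <- ionic_contact(neutral, anchor)
  expect_false(r$ionic_to_anchor)
  expect_identical(r$min_distance, Inf)
})

test_that("ionic contact equals the brute-force all-pairs scan on random poses", {
  set.seed(99)
  anchor <- asp_residue_atoms(cg = c(2, -1, 4))
  for (i in 1:300) {
    n_cat <- sample(0:3, 1)
    pose <- if (n_cat == 0) {
      ligand_pose("p", "l", data.frame(element = "C", x = rnorm(1, 2, 6),
                                       y = rnorm(1, -1, 6), z = rnorm(1, 4, 6),
                                       formal_charge = 0L,
                                       stringsAsFactors = FALSE))
    } else {
      cation_pose(matrix(rnorm(3 * n_cat, mean = c(2, -1, 4), sd = 5),
                         ncol = 3, byrow = TRUE))
    }
    r <- ionic_contact(pose, anchor)
    bf <- brute_force_ionic(pose, anchor)
    expect_identical(r$ionic_to_anchor, bf$hit)
    expect_equal(r$min_distance, bf$min_d, tolerance = 1e-12)
  }
})

test_that("enlarging the cutoff never loses a contact (monotonicity)", {
  set.seed(5)
  anchor <- asp_residue_atoms()
  for (i in 1:50) {
    pose <- cation_pose(matrix(rnorm(3, sd = 5), ncol = 3))
    hits <- vapply(c(2, 4, 6, 8, 12), function(d)
      ionic_contact(pose, anchor, ionic_criterion(d))$ionic_to_anchor, TRUE)
    expect_true(all(diff(hits) >= 0))
  }
})

test_that("contact records are invariant under joint rigid motion", {
  set.seed(31)
  anchor <- asp_residue_atoms(cg = c(1, 1, 1))
  pose <- cation_pose(rbind(c(1, 1, 6.5), c(4, 1, 1)))
  r0 <- ionic_contact(pose, anchor)
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    move <- function(df) {
      xyz <- sweep(as.matrix(df[, c("x", "y", "z")]) %*% t(R), 2, t, `+`)
      df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
      df
    }
    a2 <- move(anchor)
    p2 <- pose; p2$atoms <- move(pose$atoms)
    r <- ionic_contact(p2, a2)
    expect_identical(r$ionic_to_anchor, r0$ionic_to_anchor)
    expect_equal(r$min_distance, r0$min_distance, tolerance = 1e-9)
  }
})

test_that("anchor validation rejects non-acidic residues and missing carbons", {
  pose <- cation_pose(matrix(c(0, 0, 4), ncol = 3))
  bad <- asp_residue_atoms(); bad$resname <- "ALA"
  expect_error(ionic_contact(pose, bad), "ASP or GLU")
  noCG <- asp_residue_atoms()
  noCG <- noCG[noCG$name != "CG", ]
  expect_error(ionic_contact(pose, noCG), "carboxyl carbon")
})

test_that("extended fingerprint detects hbond, pi-cation and hydrophobic contacts", {
  tpl <- fixture_template()
  model <- tpl$model; bw <- tpl$bwmap; site <- tpl$site
  # place a polar ligand atom 3.2 A from the 6.51 tyrosine OH
  oh <- resolve_bw(model, bw, "6.51")
  oh <- oh[oh$name == "OH", ]
  lig1 <- ligand_pose("p", "l", data.frame(
    element = "O", x = oh$x + 3.2, y = oh$y, z = oh$z, formal_charge = 0L,
    stringsAsFactors = FALSE))
  fp1 <- extended_fingerprint(lig1, model, site, bw)
  expect_true(any(fp1$type == "hbond" & fp1$bw_label == "6.51"))
  # cation 5 A above the 7.39 phenylalanine ring centroid
  ring <- resolve_bw(model, bw, "7.39")
  ring <- ring[ring$name %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), ]
  cen <- colMeans(ring[, c("x", "y", "z")])
  lig2 <- cation_pose(matrix(cen + c(0, 0, 5), ncol = 3))
  fp2 <- extended_fingerprint(lig2, model, site, bw)
  expect_true(any(fp2$type == "pi_cation" & fp2$bw_label == "7.39"))
  # everything far away -> empty report
  far <- ligand_pose("f", "f", data.frame(
    element = "C", x = 500, y = 500, z = 500, formal_charge = 0L,
    stringsAsFactors = FALSE))
  expect_identical(nrow(extended_fingerprint(far, model, site, bw)), 0L)
})
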