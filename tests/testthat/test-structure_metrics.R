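test_that("kabsch_superpose finds the optimal rigid fit", {
  set.seed(7)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-10)

  for (k in 1:10) {
    rot <- ureatraj:::random_rotation()
    mob <- sweep(x %*% t(rot), 2, rnorm(3, sd = 10), "+")
    fit <- kabsch_superpose(x, mob)
    expect_equal(fit$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
  # collinear two-point case: centering leaves +-0.5 vs +-1.5 along x
  fit2 <- kabsch_superpose(rbind(c(0, 0, 0), c(1, 0, 0)),
                           rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(fit2$rmsd, 1.0, tolerance = 1e-10)

  expect_error(kabsch_superpose(x, x[1:5, ]), "mismatch")

  # agreement with an independent implementation on noisy pairs
  mob <- x + matrix(rnorm(30, sd = 0.3), 10, 3)
  fit <- kabsch_superpose(x, mob)
  ref_rmsd <- bio3d::rmsd(as.vector(t(x)), as.vector(t(mob)), fit = TRUE)
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 2e-3)  # bio3d rounds to 3 dp
})

test_that("rmsd_series is zero for static and rigidly tumbling motion", {
  hx <- build_toy_protein("helix", 8)
  sel <- protein_heavy_atoms(hx$system)
  traj <- static_traj(hx$frame, 6)
  expect_equal(rmsd_series(traj, hx$frame, sel)$values, rep(0, 6),
               tolerance = 1e-8)

  set.seed(3)
  frames <- lapply(1:6, function(f) {
    sweep(hx$frame %*% t(ureatraj:::random_rotation()), 2, rnorm(3, sd = 5),
          "+")
  })
  tumb <- traj_from_frames(frames)
  expect_equal(rmsd_series(tumb, hx$frame, sel)$values, rep(0, 6),
               tolerance = 1e-8)
  expect_error(rmsd_series(traj, hx$frame, integer(0)), "empty")
})

test_that("rmsd grows monotonically along a native-to-extended interpolation", {
  native <- build_toy_protein("helix", 12)
  extended <- ureatraj:::residues_to_system(
    ureatraj:::build_backbone(rep(-139, 12), rep(135, 12)))
  frames <- lapply(seq(0, 1, length.out = 20), function(w) {
    (1 - w) * native$frame + w * extended$frame
  })
  traj <- traj_from_frames(frames)
  rs <- rmsd_series(traj, native$frame, protein_heavy_atoms(native$system))
  expect_equal(rs$values[1], 0, tolerance = 1e-8)
  expect_true(all(diff(rs$values) > -1e-8))
  expect_gt(utils::tail(rs$values, 1), 3)
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), 1:2), 1.0)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(cube, 1:8), sqrt(3), tolerance = 1e-12)
  expect_equal(radius_of_gyration(rbind(c(5, 5, 5)), 1), 0)
  expect_error(radius_of_gyration(cube, integer(0)), "empty")
  # rigid invariance
  set.seed(1)
  rot <- ureatraj:::random_rotation()
  moved <- sweep(cube %*% t(rot), 2, c(3, 1, -2), "+")
  expect_equal(radius_of_gyration(moved, 1:8), sqrt(3), tolerance = 1e-10)
})

test_that("Shrake-Rupley SASA matches the lone-sphere closed form", {
  sys <- build_toy_protein("beads", 6)
  radii <- c(C = 1.9)
  a <- sasa(sys$frame, sys$system, selection = 1, probe = 1.4,
            radii = radii)
  expect_equal(unname(a), 4 * pi * 3.3^2, tolerance = 0.02 * 4 * pi * 3.3^2)
  # 960 points on a lone sphere is exact (no neighbor cuts any point)
  expect_equal(unname(a), 4 * pi * 3.3^2, tolerance = 1e-9)

  # two distant atoms are additive
  fr <- rbind(c(0, 0, 0), c(100, 0, 0))
  at <- data.frame(serial = 1:2, name = "CA", element = "C",
                   is_heavy = TRUE, residue_index = 1:2,
                   residue_name = "ALA", chain = "A", role = NA,
                   x = fr[, 1], y = fr[, 2], z = fr[, 3])
  b <- build_system_from_atoms(at)
  a2 <- sasa(b$frame, b$system, selection = 1:2)
  expect_equal(unname(a2), rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)

  # an atom caged by a tight octahedron of neighbors is buried
  cage <- rbind(c(0, 0, 0), 2.2 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  atc <- data.frame(serial = 1:7, name = "CA", element = "C",
                    is_heavy = TRUE, residue_index = 1:7,
                    residue_name = "ALA", chain = "A", role = NA,
                    x = cage[, 1], y = cage[, 2], z = cage[, 3])
  bc <- build_system_from_atoms(atc)
  ac <- sasa(bc$frame, bc$system, selection = 1:7)
  expect_equal(unname(ac[1]), 0)

  expect_error(sasa(sys$frame, sys$system, selection = 1,
                    radii = c(N = 1.55)), "missing radius")
})

test_that("SASA converges in point count and is rigid-invariant", {
  hx <- build_toy_protein("helix", 8)
  a960 <- sasa(hx$frame, hx$system, n_points = 960)
  a4000 <- sasa(hx$frame, hx$system, n_points = 4000)
  expect_lt(abs(sum(a960) - sum(a4000)) / sum(a4000), 0.02)

  set.seed(9)
  rot <- ureatraj:::random_rotation()
  moved <- sweep(hx$frame %*% t(rot), 2, c(10, -4, 2), "+")
  am <- sasa(moved, hx$system, n_points = 960)
  expect_equal(sum(am), sum(a960), tolerance = 0.02 * sum(a960))
})

test_that("polar/apolar SASA partition is exact and sums to total", {
  # mixed-polarity chain: alternate LEU (hydrophobic) / SER (polar)
  hx <- build_toy_protein("helix", 8)
  sys <- hx$system
  sys$atoms$residue_name <- ifelse(sys$atoms$residue_index %% 2 == 0,
                                   "SER", "LEU")
  sys$residues$name <- ifelse(sys$residues$index %% 2 == 0, "SER", "LEU")
  sys <- classify_system(sys)
  p <- sasa_partition(sasa(hx$frame, sys), sys)
  expect_equal(p$polar + p$apolar, p$total, tolerance = 1e-9)
  expect_gt(p$polar, 0)
  expect_gt(p$apolar, 0)

  # all-hydrophobic system: polar share is zero
  p2 <- sasa_partition(sasa(hx$frame, hx$system), hx$system)
  expect_equal(p2$polar, 0)
  expect_equal(p2$apolar, p2$total)
})

test_that("sasa_normalize divides by the water-reference mean", {
  s <- metric_series("SASA", c(6000, 5500), c(0, 1), "Angstrom^2")
  ref <- metric_series("SASA", c(5000, 5000), c(0, 1), "Angstrom^2")
  out <- sasa_normalize(s, ref)
  expect_equal(out$values, c(1.2, 1.1))
  expect_equal(mean(sasa_normalize(ref, ref)$values), 1.0)
  d <- sasa_normalize(s, ref, mode = "delta")
  expect_equal(d$values, c(1000, 500))
  zero <- metric_series("SASA", c(0, 0), c(0, 1), "Angstrom^2")
  expect_error(sasa_normalize(s, zero), "zero reference")
})

test_that("TM-score: self-identity, rigid invariance, the d0 half-score case", {
  hx <- build_toy_protein("helix", 20)
  ca <- hx$frame[ca_atoms(hx$system), ]
  expect_equal(tm_score(ca, ca), 1.0, tolerance = 1e-10)
  expect_equal(tm_score(ca, sweep(ca, 2, c(10, 3, -7), "+")), 1.0,
               tolerance = 1e-9)
  d0 <- 1.24 * (20 - 15)^(1 / 3) - 1.8
  shifted <- ca
  shifted[, 1] <- shifted[, 1] + d0
  expect_equal(tm_score(ca, shifted, refine = FALSE, superpose = FALSE),
               0.5, tolerance = 1e-12)
  expect_error(tm_score(ca[1:10, ], ca[1:10, ]), "16")
  expect_error(tm_score(ca, ca[1:10, ]), "mismatch")
})

test_that("TM-score refinement never scores below the plain fit", {
  set.seed(5)
  hx <- build_toy_protein("helix", 24)
  ca <- hx$frame[ca_atoms(hx$system), ]
  for (k in 1:8) {
    mod <- ca + matrix(rnorm(nrow(ca) * 3, sd = runif(1, 0.5, 4)),
                       nrow(ca), 3)
    mod[1:5, ] <- mod[1:5, ] + 8  # a displaced segment rewards re-fitting
    t_plain <- tm_score(ca, mod, refine = FALSE)
    t_ref <- tm_score(ca, mod, refine = TRUE)
    expect_gte(t_ref, t_plain - 1e-12)
    expect_lte(t_ref, 1)
  }
})

test_that("s2_index counts retained native structure assignments", {
  nat <- c(`1` = "H", `2` = "H", `3` = "H", `4` = "H", `5` = "C", `6` = "C")
  cur <- c(`1` = "H", `2` = "H", `3` = "C", `4` = "C", `5` = "C", `6` = "C")
  expect_equal(s2_index(cur, nat), 0.5)
  expect_equal(s2_index(nat, nat), 1.0)
  allc <- stats::setNames(rep("C", 6), names(nat))
  expect_equal(s2_index(allc, nat), 0.0)
  expect_warning(out <- s2_index(allc, allc), "no native")
  expect_equal(out, 1)
  expect_error(s2_index(cur[1:5], nat), "mismatch")
})

test_that("structure_index combines S2 and S3 as labelled", {
  expect_equal(structure_index(1, 1), 1)
  expect_equal(structure_index(0.8, 0.6, "mean"), 0.7)
  expect_equal(structure_index(0.8, 0.6, "s3_only"), 0.6)
  expect_error(structure_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("secondary structure assignment recognizes ideal geometries", {
  hx <- build_toy_protein("helix", 12)
  ss <- assign_ss(hx$frame, hx$system)
  expect_true(all(ss[3:10] == "H"))

  ext <- ureatraj:::residues_to_system(
    ureatraj:::build_backbone(rep(180, 10), rep(180, 10)))
  expect_true(all(assign_ss(ext$frame, ext$system) == "C"))

  hp <- build_toy_protein("hairpin", 18)
  ss_hp <- assign_ss(hp$frame, hp$system)
  # interior strand residues (strands are 1-7 and 12-18)
  expect_true(all(ss_hp[c(3, 4, 5, 14, 15, 16)] == "E"))
  expect_true(all(ss_hp[8:11] == "C"))
})
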