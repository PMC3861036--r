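# a bead protein at the origin plus one water and one urea at controlled
# nearest-approach distances
shell_fixture <- function(d_water, d_urea) {
  rows <- list(
    data.frame(serial = 1, name = "CA", element = "C", is_heavy = TRUE,
               residue_index = 1, residue_name = "ALA", chain = "A",
               role = NA, x = 0, y = 0, z = 0),
    data.frame(serial = 2, name = "O", element = "O", is_heavy = TRUE,
               residue_index = 2, residue_name = "HOH", chain = "S",
               role = NA, x = d_water, y = 0, z = 0),
    data.frame(serial = 3:6, name = c("C", "O", "N1", "N2"),
               element = c("C", "O", "N", "N"), is_heavy = TRUE,
               residue_index = 3, residue_name = "URE", chain = "S",
               role = NA, x = d_urea + c(0, 0.1, 0.2, 0.3), y = 0, z = 0))
  build_system_from_atoms(do.call(rbind, rows))
}

test_that("shell_assign uses the 5/6 Angstrom molecule-level cutoffs", {
  b <- shell_fixture(d_water = 7.0, d_urea = 4.0)
  sa <- shell_assign(b$frame, b$system)
  expect_equal(sa$shell[sa$species == "urea"], "FSS")
  expect_equal(sa$shell[sa$species == "water"], "bulk")

  b2 <- shell_fixture(d_water = 5.5, d_urea = 5.5)
  sa2 <- shell_assign(b2$frame, b2$system)
  expect_equal(sa2$shell[sa2$species == "water"], "intermediate")
  expect_error(shell_assign(b$frame, b$system, fss_cutoff = 7,
                            bulk_cutoff = 6), "fss_cutoff")
  # labels partition the solvent molecules
  expect_equal(nrow(sa), 2)
  expect_true(all(sa$shell %in% c("FSS", "intermediate", "bulk")))
})

test_that("shell ratios report counts, handle zero-urea frames", {
  b <- shell_fixture(d_water = 4.0, d_urea = 20.0)
  traj <- static_traj(b$frame, 3)
  sr <- shell_ratio_series(traj, b$system)
  # FSS has 1 water, 0 urea -> undefined, excluded with a count
  expect_true(all(is.na(sr$per_frame$fss_ratio)))
  expect_equal(sr$summary$n_excluded[sr$summary$shell == "FSS"], 3)
  expect_equal(sr$per_frame$fss_water[1], 1)
})

test_that("uniform 6:1 box shows no FSS/bulk preference; enrichment 2 halves the FSS ratio", {
  sp0 <- synthetic_spec(seed = 5, dt_ns = 0.1, n_frames = 80,
                        protein = list(kind = "cluster", n_residues = 27,
                                       schedule = list(type = "static")),
                        n_water = 600, n_urea = 100, box = c(50, 50, 50),
                        solvent_mode = "equilibrium", fss_enrichment = 1)
  b0 <- synthesize_trajectory(sp0)
  pf0 <- shell_ratio_series(b0$traj, b0$system)$per_frame
  fss0 <- sum(pf0$fss_water) / sum(pf0$fss_urea)
  bulk0 <- sum(pf0$bulk_water) / sum(pf0$bulk_urea)
  expect_lt(abs(fss0 - bulk0) / bulk0, 0.15)  # null calibration

  sp2 <- synthetic_spec(seed = 6, dt_ns = 0.1, n_frames = 80,
                        protein = list(kind = "cluster", n_residues = 27,
                                       schedule = list(type = "static")),
                        n_water = 600, n_urea = 100, box = c(50, 50, 50),
                        solvent_mode = "equilibrium", fss_enrichment = 2)
  b2 <- synthesize_trajectory(sp2)
  pf2 <- shell_ratio_series(b2$traj, b2$system)$per_frame
  fss2 <- sum(pf2$fss_water) / sum(pf2$fss_urea)
  bulk2 <- sum(pf2$bulk_water) / sum(pf2$bulk_urea)
  expect_lt(abs(fss2 - 3) / 3, 0.15)
  expect_lt(abs(bulk2 - 6) / 6, 0.15)
})

test_that("cc_uw is the urea:water contact ratio per group", {
  # residue 1 with 1 urea heavy atom at 3 A (4 atoms but 1 in range) and two
  # waters in range -> counts 1 vs 2
  rows <- list(
    data.frame(serial = 1, name = "CA", element = "C", is_heavy = TRUE,
               residue_index = 1, residue_name = "ALA", chain = "A",
               role = NA, x = 0, y = 0, z = 0),
    data.frame(serial = 2:5, name = c("C", "O", "N1", "N2"),
               element = c("C", "O", "N", "N"), is_heavy = TRUE,
               residue_index = 2, residue_name = "URE", chain = "S",
               role = NA, x = c(3, 6, 7, 8), y = 0, z = 0),
    data.frame(serial = 6:7, name = "O", element = "O", is_heavy = TRUE,
               residue_index = 3:4, residue_name = "HOH", chain = "S",
               role = NA, x = c(0, 3), y = c(3, 0), z = 0))
  b <- build_system_from_atoms(do.call(rbind, rows))
  traj <- static_traj(b$frame, 2)
  cc <- cc_uw(traj, b$system, group_by = "residue")
  expect_equal(cc$cc_uw, 0.5)
  expect_equal(cc$urea_contacts, 1)
  expect_equal(cc$water_contacts, 2)

  # zero urea contacts -> coefficient 0
  rows[[2]]$x <- rows[[2]]$x + 20
  b2 <- build_system_from_atoms(do.call(rbind, rows))
  cc2 <- cc_uw(static_traj(b2$frame, 2), b2$system, group_by = "residue")
  expect_equal(cc2$cc_uw, 0)
})

test_that("sticky urea targeted at core residues raises CC_UW(core)", {
  sp <- synthetic_spec(seed = 31, dt_ns = 0.02, n_frames = 600,
                       protein = list(kind = "cluster", n_residues = 27,
                                      schedule = list(type = "static")),
                       n_water = 60, n_urea = 15, box = c(30, 30, 30),
                       d_urea = 20, d_water = 20,
                       sticky = list(enabled = TRUE, capture_prob = 1,
                                     k_off = 1, targets = 1:9))
  b <- synthesize_trajectory(sp)
  sys <- b$system
  sys$residues$is_core[sys$residues$species == "protein"] <-
    sys$residues$index[sys$residues$species == "protein"] %in% 1:9
  cc <- cc_uw(b$traj, sys, group_by = "core")
  core_val <- cc$cc_uw[cc$group == "core"]
  noncore_val <- cc$cc_uw[cc$group == "non_core"]
  expect_gt(core_val, noncore_val)
})

test_that("residence events follow the run/merge rules", {
  # molecule in contact frames 10-49 of 100, dt 0.1 -> one 4.0 ns event
  b <- shell_fixture(d_water = 20, d_urea = 20)
  frames <- lapply(1:100, function(f) {
    fr <- b$frame
    if (f >= 10 && f <= 49) fr[3:6, 1] <- fr[3:6, 1] - 17  # urea at 3 A
    fr
  })
  traj <- traj_from_frames(frames, dt = 0.1)
  ev <- residence_events(traj, b$system, species = "urea")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ns, 4.0)
  expect_equal(ev$n_frames, 40)

  # contact frames {1-5, 7-9}: two events at tolerance 0, one at tolerance 1
  frames2 <- lapply(1:10, function(f) {
    fr <- b$frame
    if (f <= 5 || (f >= 7 && f <= 9)) fr[3:6, 1] <- fr[3:6, 1] - 17
    fr
  })
  traj2 <- traj_from_frames(frames2, dt = 0.1)
  ev0 <- residence_events(traj2, b$system, species = "urea")
  expect_equal(sort(ev0$duration_ns), c(0.3, 0.5))
  ev1 <- residence_events(traj2, b$system, species = "urea",
                          gap_tolerance_frames = 1)
  expect_equal(ev1$duration_ns, 0.9)
})

test_that("sticky-urea kinetics are recovered and the long binder ranks first", {
  sp <- synthetic_spec(seed = 13, dt_ns = 0.02, n_frames = 2200,
                       protein = list(kind = "cluster", n_residues = 27,
                                      schedule = list(type = "static")),
                       n_water = 40, n_urea = 25, box = c(30, 30, 30),
                       d_urea = 20, d_water = 20,
                       sticky = list(enabled = TRUE, capture_prob = 1,
                                     k_off = 1, targets = NULL),
                       long_binder = list(molecule = 1, start_frame = 1,
                                          n_frames = 1000))
  b <- synthesize_trajectory(sp)
  ev <- residence_events(b$traj, b$system, species = "urea")
  lb_res <- 27 + 40 + 1
  evk <- ev[ev$molecule != lb_res, ]
  expect_gt(nrow(evk), 300)
  expect_lt(abs(mean(evk$duration_ns) - 1.0), 0.15)
  rep <- long_residence_report(ev, min_duration_ns = 10)
  expect_equal(rep$ranked$molecule[1], lb_res)
  expect_equal(rep$ranked$longest_ns[1], 20.0)
  # per-molecule dot map covers every frame of the scripted window
  mp <- rep$maps[[as.character(lb_res)]]
  expect_equal(setdiff(1:1000, mp$frame), integer(0))
  # water (no stickiness) has much shorter residences
  evw <- residence_events(b$traj, b$system, species = "water")
  expect_lt(mean(evw$duration_ns), 0.5 * mean(evk$duration_ns))
  # no event set exceeds the trajectory duration per molecule
  tot <- tapply(ev$duration_ns, ev$molecule, sum)
  expect_true(all(tot <= 44 + 1e-9))
})

test_that("long_residence_report handles thresholds and empty input", {
  ev <- data.frame(molecule = c(10L, 11L), species = "urea",
                   start_ns = c(0, 0), end_ns = c(1, 0.2),
                   duration_ns = c(1, 0.2), n_frames = c(10, 2))
  attr(ev, "contact_map") <- data.frame(molecule = c(10L, 11L),
                                        residue = c(1L, 2L),
                                        frame = c(1L, 1L))
  out <- long_residence_report(ev, 0.5)
  expect_equal(out$ranked$molecule, 10)
  expect_equal(names(out$maps), "10")
  none <- long_residence_report(ev, 5)
  expect_equal(nrow(none$ranked), 0)
})

test_that("nonbonded energies match Coulomb and Lennard-Jones closed forms", {
  par <- data.frame(charge = c(1, -1), sigma = c(1, 1), epsilon = c(0, 0))
  fr <- rbind(c(0, 0, 0), c(3.3206, 0, 0))
  e <- nonbonded_energy(fr, par, 1, 2)
  expect_equal(e$elec, -332.0636 / 3.3206, tolerance = 1e-9)

  par2 <- data.frame(charge = c(0, 0), sigma = c(3.2, 3.2),
                     epsilon = c(0.15, 0.15))
  expect_equal(nonbonded_energy(rbind(c(0, 0, 0), c(3.2, 0, 0)),
                                par2, 1, 2)$vdw, 0, tolerance = 1e-12)
  expect_equal(nonbonded_energy(rbind(c(0, 0, 0), c(2^(1 / 6) * 3.2, 0, 0)),
                                par2, 1, 2)$vdw, -0.15, tolerance = 1e-9)

  # symmetry in group order and linear scaling with charge
  set.seed(8)
  fr3 <- matrix(runif(18, 0, 6), 6, 3)
  par3 <- data.frame(charge = rnorm(6), sigma = runif(6, 2, 4),
                     epsilon = runif(6, 0.05, 0.3))
  e1 <- nonbonded_energy(fr3, par3, 1:3, 4:6)
  e2 <- nonbonded_energy(fr3, par3, 4:6, 1:3)
  expect_equal(e1$elec, e2$elec)
  expect_equal(e1$vdw, e2$vdw)
  par4 <- par3
  par4$charge <- 2 * par3$charge
  expect_equal(nonbonded_energy(fr3, par4, 1:3, 4:6)$elec, 4 * e1$elec,
               tolerance = 1e-9)

  expect_error(nonbonded_energy(fr3, par3, 1:3, 3:6), "disjoint")
  frclash <- rbind(c(0, 0, 0), c(0.05, 0, 0))
  expect_error(nonbonded_energy(frclash, par, 1, 2), "clash")
})

test_that("assign_core marks buried residues by relative accessibility", {
  sp <- ureatraj:::bead_cluster(27)
  sys <- assign_core(sp$system, sp$frame)
  core <- sys$residues$is_core
  expect_true(any(core))          # the cluster center is buried
  expect_true(any(!core))         # corners are exposed
  # residue 14 is the 3x3x3 center in grid order
  expect_true(core[14])
})
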