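# helix plus one water whose O sits at `dist` from a backbone carbonyl O,
# with H1 aimed so the D-H-A angle is `angle` degrees
water_probe_system <- function(dist = 3.0, angle = 180) {
  hx <- build_toy_protein("helix", 6)
  idx_o <- which(hx$system$atoms$residue_index == 3 &
                   hx$system$atoms$name == "O")
  idx_c <- which(hx$system$atoms$residue_index == 3 &
                   hx$system$atoms$name == "C")
  o3 <- hx$frame[idx_o, ]
  # approach radially away from the protein so the probe clashes with nothing
  u <- ureatraj:::unit(o3 - colMeans(hx$frame))
  wO <- o3 + dist * u
  clear <- min(sqrt(rowSums(sweep(hx$frame, 2, wO)^2)))
  stopifnot(clear >= dist - 1e-9)
  # place H 0.96 A from wO so the D-H-A angle equals `angle`: in the
  # triangle (wO, H, o3) the angle at the acceptor is
  # asin(0.96 sin(angle) / dist), so the angle at the donor follows
  perp <- ureatraj:::unit(ureatraj:::cross3(u, c(0, 0, 1)))
  th <- angle * pi / 180
  alp <- pi - th - asin(0.96 * sin(th) / dist)
  h1 <- wO + 0.96 * (cos(alp) * (-u) + sin(alp) * perp)
  h2 <- wO + 0.96 * perp
  at <- hx$system$atoms
  at$x <- hx$frame[, 1]; at$y <- hx$frame[, 2]; at$z <- hx$frame[, 3]
  wat <- data.frame(serial = max(at$serial) + 1:3,
                    name = c("O", "H1", "H2"), element = c("O", "H", "H"),
                    is_heavy = c(TRUE, FALSE, FALSE), residue_index = 7,
                    residue_name = "HOH", chain = "S", role = NA,
                    x = c(wO[1], h1[1], h2[1]), y = c(wO[2], h1[2], h2[2]),
                    z = c(wO[3], h1[3], h2[3]))
  build_system_from_atoms(rbind(at, wat))
}

solvent_bonds <- function(hb) {
  hb[hb$donor_species %in% c("water", "urea") |
       hb$acceptor_species %in% c("water", "urea"), , drop = FALSE]
}

test_that("hydrogen bonds require both the distance and the angle cutoff", {
  good <- water_probe_system(3.0, 180)
  hb <- solvent_bonds(detect_hbonds(good$frame, good$system))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_species, "water")
  expect_equal(hb$acceptor_part, "backbone")
  expect_equal(hb$distance, 3.0, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)

  far <- water_probe_system(3.6, 180)
  expect_equal(nrow(solvent_bonds(detect_hbonds(far$frame, far$system))), 0)

  bent <- water_probe_system(3.0, 110)
  expect_equal(nrow(solvent_bonds(detect_hbonds(bent$frame, bent$system))),
               0)
  # just inside the angle cutoff: accepted (>= convention)
  at120 <- water_probe_system(3.0, 120.01)
  expect_equal(nrow(solvent_bonds(detect_hbonds(at120$frame,
                                                at120$system))), 1)
})

test_that("detection is invariant under rigid motion and matches brute force", {
  set.seed(14)
  for (k in 1:6) {
    b <- random_water_system(n_water = 10, seed = k, spread = 8)
    got <- detect_hbonds(b$frame, b$system)
    got_expl <- got[!is.na(got$hydrogen), c("donor", "hydrogen", "acceptor")]
    want <- brute_hbonds(b$frame, b$system)
    expect_equal(nrow(got_expl), nrow(want))
    if (nrow(want) > 0) {
      o1 <- got_expl[order(got_expl$donor, got_expl$acceptor), ]
      o2 <- want[order(want[, 1], want[, 3]), , drop = FALSE]
      expect_equal(unname(as.matrix(o1)), unname(o2))
    }
    rot <- ureatraj:::random_rotation()
    moved <- sweep(b$frame %*% t(rot), 2, c(7, -3, 11), "+")
    got2 <- detect_hbonds(moved, b$system)
    expect_equal(nrow(got2), nrow(got))
  }
})

test_that("urea donates through its N-H hydrogens and accepts at its O", {
  # urea with explicit H placed so H11 points at a carbonyl O
  hx <- build_toy_protein("helix", 6)
  idx_o <- which(hx$system$atoms$residue_index == 3 &
                   hx$system$atoms$name == "O")
  idx_c <- which(hx$system$atoms$residue_index == 3 &
                   hx$system$atoms$name == "C")
  o3 <- hx$frame[idx_o, ]
  u <- ureatraj:::unit(o3 - hx$frame[idx_c, ])
  n1 <- o3 + 2.9 * u
  at <- hx$system$atoms
  at$x <- hx$frame[, 1]; at$y <- hx$frame[, 2]; at$z <- hx$frame[, 3]
  ure <- data.frame(serial = max(at$serial) + 1:5,
                    name = c("C", "O", "N1", "N2", "H11"),
                    element = c("C", "O", "N", "N", "H"),
                    is_heavy = c(rep(TRUE, 4), FALSE), residue_index = 7,
                    residue_name = "URE", chain = "S", role = NA,
                    x = c(n1[1] + 1.3 * u[1], n1[1] + 2.5 * u[1],
                          n1[1], n1[1] + 1.3 * u[1] + 1.2,
                          n1[1] - 1.0 * u[1]),
                    y = c(n1[2] + 1.3 * u[2], n1[2] + 2.5 * u[2],
                          n1[2], n1[2] + 1.3 * u[2],
                          n1[2] - 1.0 * u[2]),
                    z = c(n1[3] + 1.3 * u[3], n1[3] + 2.5 * u[3],
                          n1[3], n1[3] + 1.3 * u[3],
                          n1[3] - 1.0 * u[3]))
  b <- build_system_from_atoms(rbind(at, ure))
  hb <- solvent_bonds(detect_hbonds(b$frame, b$system))
  expect_true(any(hb$donor_species == "urea" &
                    hb$acceptor_part == "backbone"))
})

test_that("occupancy totals, lifetimes and the 0.5 ns retention rule", {
  b <- water_probe_system(3.0, 180)
  n_at <- nrow(b$system$atoms)
  wat_idx <- which(b$system$atoms$residue_index == 7)
  # bond present in frames 1-4 and 7-8 of 10 (6 frames, dt 0.1 -> 0.6 ns)
  frames <- lapply(1:10, function(f) {
    fr <- b$frame
    if (!(f %in% c(1:4, 7:8))) fr[wat_idx, ] <- fr[wat_idx, ] + 30
    fr
  })
  occ <- hbond_occupancy(traj_from_frames(frames, dt = 0.1), b$system)
  solv <- occ[occ$donor_species == "water", ]
  expect_equal(solv$total_ns, 0.6, tolerance = 1e-9)
  expect_equal(solv$longest_ns, 0.4, tolerance = 1e-9)
  expect_true(solv$retained)

  # 4 of 10 frames -> 0.4 ns, not retained
  frames2 <- lapply(1:10, function(f) {
    fr <- b$frame
    if (f > 4) fr[wat_idx, ] <- fr[wat_idx, ] + 30
    fr
  })
  occ2 <- hbond_occupancy(traj_from_frames(frames2, dt = 0.1), b$system)
  solv2 <- occ2[occ2$donor_species == "water", ]
  expect_equal(solv2$total_ns, 0.4, tolerance = 1e-9)
  expect_false(solv2$retained)

  # always present: total = lifetime = trajectory length
  occ3 <- hbond_occupancy(static_traj(b$frame, 10, dt = 0.1), b$system)
  solv3 <- occ3[occ3$donor_species == "water", ]
  expect_equal(solv3$total_ns, 1.0, tolerance = 1e-9)
  expect_equal(solv3$longest_ns, 1.0, tolerance = 1e-9)
})

test_that("partitions sum to 100% and follow the donor/acceptor split", {
  mk <- function(n, donor_sp, acc_sp, donor_part, acc_part) {
    data.frame(donor = seq_len(n), acceptor = seq_len(n) + 100,
               donor_species = donor_sp, acceptor_species = acc_sp,
               donor_part = donor_part, acceptor_part = acc_part)
  }
  bonds <- rbind(mk(4, "urea", "protein", "n/a", "backbone"),
                 mk(6, "water", "protein", "n/a", "sidechain"))
  p <- hbond_partition(bonds)
  expect_equal(p$urea$pct_of_solvent_bonds, 40)
  expect_equal(p$water$pct_of_solvent_bonds, 60)
  expect_equal(p$urea$pct_of_solvent_bonds + p$water$pct_of_solvent_bonds,
               100)

  # 2 urea-donor + 1 urea-acceptor backbone bonds -> donor fraction 66.7%
  bonds2 <- rbind(mk(2, "urea", "protein", "n/a", "backbone"),
                  mk(1, "protein", "urea", "backbone", "n/a"))
  p2 <- hbond_partition(bonds2)
  expect_equal(p2$urea$donor_pct, 200 / 3, tolerance = 1e-9)
  expect_equal(p2$urea$donor_pct + p2$urea$acceptor_pct, 100)
  expect_equal(p2$urea$backbone_pct, 100)

  expect_error(hbond_partition(mk(2, "protein", "protein", "backbone",
                                  "backbone")), "no solvent")
})
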