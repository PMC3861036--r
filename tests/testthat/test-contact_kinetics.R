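test_that("contact_timeline applies the heavy-atom cutoff per frame", {
  # two residue pairs: one fixed at 3.4 A, one at 3.6 A
  at <- data.frame(serial = 1:4, name = "CA", element = "C", is_heavy = TRUE,
                   residue_index = 1:4, residue_name = "ALA", chain = "A",
                   role = NA,
                   x = c(0, 50, 3.4, 53.6), y = 0, z = 0)
  # residues (1,3) at 3.4 and (2,4) at 3.6; |i-j| >= 2 -- use min_seq_sep 2
  b <- build_system_from_atoms(at)
  traj <- static_traj(b$frame, 4)
  tl <- contact_timeline(traj, b$system, cutoff = 3.5, min_seq_sep = 2)
  expect_equal(nrow(tl$contacts), 1)
  expect_equal(unlist(tl$contacts[1, ]), c(res_i = 1, res_j = 3))
  expect_true(all(tl$presence))
  expect_error(contact_timeline(traj, b$system, cutoff = -2), "cutoff")
})

test_that("contact_timeline matches the brute-force residue-pair oracle", {
  set.seed(21)
  for (k in 1:5) {
    n <- 10
    at <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(serial = 3 * (i - 1) + 1:3,
                 name = c("N", "CA", "C"), element = c("N", "C", "C"),
                 is_heavy = TRUE, residue_index = i, residue_name = "ALA",
                 chain = "A", role = NA,
                 x = runif(3, 0, 15), y = runif(3, 0, 15),
                 z = runif(3, 0, 15))
    }))
    b <- build_system_from_atoms(at)
    traj <- static_traj(b$frame, 2)
    tl <- contact_timeline(traj, b$system, cutoff = 4.5)
    want <- brute_residue_contacts(b$frame, b$system, 4.5)
    got <- as.matrix(tl$contacts)
    dimnames(got) <- NULL
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("native_contact_set keeps occupancy strictly above threshold", {
  pres <- rbind(rep(c(TRUE, FALSE), c(95, 5)),
                rep(c(TRUE, FALSE), c(81, 19)),
                rep(c(TRUE, FALSE), c(79, 21)))
  tl <- timeline_from_presence(pres, data.frame(res_i = c(1, 2, 3),
                                                res_j = c(5, 6, 7)))
  nat <- native_contact_set(tl, 0.80)
  expect_equal(nat$res_i, c(1, 2))
  expect_equal(nat$occupancy, c(0.95, 0.81))

  allon <- timeline_from_presence(matrix(TRUE, 3, 10),
                                  data.frame(res_i = 1:3, res_j = 5:7))
  expect_equal(nrow(native_contact_set(allon, 0.80)), 3)
  expect_equal(nrow(native_contact_set(tl, 0)), 3)
})

test_that("s3_series is the per-frame fraction of native contacts", {
  pres <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                c(TRUE, FALSE, TRUE, FALSE))
  tl <- timeline_from_presence(pres, data.frame(res_i = c(1, 2),
                                                res_j = c(5, 6)))
  nat <- data.frame(res_i = c(1, 2), res_j = c(5, 6), occupancy = 1)
  s3 <- s3_series(tl, nat)
  expect_equal(s3$values, c(1, 0.5, 0.5, 0))
  expect_error(s3_series(tl, nat[0, ]), "empty")
  # native contacts missing from the timeline count as absent
  nat2 <- rbind(nat, data.frame(res_i = 3, res_j = 9, occupancy = 1))
  expect_equal(s3_series(tl, nat2)$values[1], 2 / 3)
})

test_that("opening_stats measures maximal absent runs", {
  pres <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                 nrow = 1)
  tl <- timeline_from_presence(pres, data.frame(res_i = 1, res_j = 5),
                               dt = 0.1)
  nat <- data.frame(res_i = 1, res_j = 5, occupancy = 1)
  st <- opening_stats(tl, nat)
  expect_equal(st$n_open, 1)
  expect_equal(st$mean_open_ns, 0.3)
  expect_equal(st$total_open_ns, 0.3)

  never <- timeline_from_presence(matrix(TRUE, 1, 9),
                                  data.frame(res_i = 1, res_j = 5), dt = 0.1)
  st2 <- opening_stats(never, nat)
  expect_equal(st2$n_open, 0)
  expect_equal(st2$mean_open_ns, 0)

  # open + closed time partitions the trajectory duration exactly
  set.seed(2)
  pres3 <- matrix(runif(200) > 0.3, nrow = 4)
  tl3 <- timeline_from_presence(pres3, data.frame(res_i = 1:4, res_j = 5:8),
                                dt = 0.1)
  nat3 <- data.frame(res_i = 1:4, res_j = 5:8, occupancy = 1)
  st3 <- opening_stats(tl3, nat3)
  expect_equal(st3$total_open_ns + rowSums(pres3) * 0.1,
               rep(ncol(pres3) * 0.1, 4))
})

test_that("telegraph schedules are recovered within 15% at 1e3 events", {
  # the frame grid must resolve the kinetics (dt * k << 1), otherwise
  # sub-frame openings are missed and sub-frame gaps merge adjacent ones;
  # 25 contacts x 250 ns puts the S3 standard error near 0.006, so the
  # 0.02 recovery band is a >3-sigma bound
  sp <- synthetic_spec(seed = 77, dt_ns = 0.02, n_frames = 12500,
                       protein = list(schedule = list(
                         type = "telegraph", n_pairs = 25,
                         k_open = 1, k_close = 1)))
  b <- synthesize_trajectory(sp)
  tl <- contact_timeline(b$traj, b$system)
  nat <- data.frame(res_i = b$truth$schedule$pairs$res_i,
                    res_j = b$truth$schedule$pairs$res_j, occupancy = 1)
  st <- opening_stats(tl, nat)
  expect_gt(sum(st$n_open), 1000)
  pooled_mean <- sum(st$mean_open_ns * st$n_open) / sum(st$n_open)
  expect_lt(abs(pooled_mean - 1.0), 0.15)
  # S3 long-run mean at the stationary closed fraction 1/2
  s3 <- s3_series(tl, nat)
  expect_lt(abs(mean(s3$values) - 0.5), 0.02)
})

test_that("opening-time shifts are classified with a strict margin", {
  mk <- function(means) data.frame(res_i = seq_along(means),
                                   res_j = seq_along(means) + 4,
                                   n_open = 1, mean_open_ns = means,
                                   total_open_ns = means)
  out <- opening_shift_classify(mk(0.25), mk(0.10))
  expect_equal(out$pct_longer_in_a, 100)
  expect_equal(out$pct_longer_in_b, 0)
  expect_equal(out$pct_total_shifted, 100)

  same <- opening_shift_classify(mk(c(0.2, 0.4)), mk(c(0.2, 0.4)))
  expect_equal(unlist(same), c(pct_longer_in_a = 0, pct_longer_in_b = 0,
                               pct_total_shifted = 0))
  # difference exactly at the threshold counts for neither side
  border <- opening_shift_classify(mk(0.3), mk(0.2))
  expect_equal(border$pct_total_shifted, 0)
  expect_error(opening_shift_classify(mk(0.3), mk(c(0.1, 0.2))), "mismatch")
  # percentages bounded
  mixed <- opening_shift_classify(mk(c(1, 0.1, 0.5)), mk(c(0.1, 1, 0.5)))
  expect_lte(mixed$pct_total_shifted, 100)
})

test_that("per-residue lost time averages over the residue's contacts", {
  pres <- rbind(rep(c(FALSE, TRUE), c(30, 70)),  # contact (1,5): 30% lost
                rep(TRUE, 100))                  # contact (1,9): 0% lost
  tl <- timeline_from_presence(pres, data.frame(res_i = c(1, 1),
                                                res_j = c(5, 9)))
  nat <- data.frame(res_i = c(1, 1), res_j = c(5, 9),
                    occupancy = c(0.9, 1.0))
  lt <- lost_time_per_residue(tl, nat)
  expect_equal(lt$lost_pct[lt$residue == 1], 15)  # mean of 30 and 0
  expect_equal(lt$lost_pct[lt$residue == 5], 30)
  expect_equal(lt$lost_pct[lt$residue == 9], 0)

  # reference_excess: occ_ref 0.9, occ_now 0.45 -> 50%
  pres2 <- matrix(rep(c(TRUE, FALSE), c(45, 55)), nrow = 1)
  tl2 <- timeline_from_presence(pres2, data.frame(res_i = 1, res_j = 5))
  nat2 <- data.frame(res_i = 1, res_j = 5, occupancy = 0.9)
  lt2 <- lost_time_per_residue(tl2, nat2, mode = "reference_excess")
  expect_equal(lt2$lost_pct[lt2$residue == 1], 50)

  allon <- timeline_from_presence(matrix(TRUE, 2, 10),
                                  data.frame(res_i = c(1, 1),
                                             res_j = c(5, 9)))
  expect_true(all(lost_time_per_residue(allon, nat)$lost_pct == 0))
})

test_that("lost-time correlation returns Pearson r with a t-test p-value", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(lost_time_correlation(x, x)$r, 1)
  expect_equal(lost_time_correlation(x, -x)$r, -1)
  expect_error(lost_time_correlation(x, rep(1, 5)), "zero variance")
  expect_error(lost_time_correlation(x, x[1:3]), "length mismatch")

  set.seed(123)
  ok <- 0
  for (s in 1:40) {
    z <- matrix(rnorm(2000), ncol = 2)
    y <- 0.7 * z[, 1] + sqrt(1 - 0.49) * z[, 2]
    r <- lost_time_correlation(z[, 1], y)$r
    if (r > 0.66 && r < 0.74) ok <- ok + 1
  }
  expect_gte(ok / 40, 0.9)
})
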