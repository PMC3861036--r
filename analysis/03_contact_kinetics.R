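#!/usr/bin/env Rscript
# Stage 3: native-contact kinetics on telegraph ground truth. The S3 series
# must sit at the scheduled closed fraction, the mean opening time at
# 1/k_close, and the opening-time shift classification must flag exactly the
# contacts whose closing rate differs between two conditions.

suppressMessages(library(ureatraj))
BASE_SEED <- 20251001L
dir.create("results", showWarnings = FALSE)

mk <- function(seed, k_close, n_pairs = 10) synthesize_trajectory(
  synthetic_spec(
    seed = seed, dt_ns = 0.02, n_frames = 12500,
    protein = list(schedule = list(type = "telegraph", n_pairs = n_pairs,
                                   k_open = 1, k_close = k_close))))

b <- mk(BASE_SEED + 1L, 1, n_pairs = 25)
tl <- contact_timeline(b$traj, b$system)
native <- data.frame(res_i = b$truth$schedule$pairs$res_i,
                     res_j = b$truth$schedule$pairs$res_j, occupancy = 1)
s3 <- s3_series(tl, native)
st <- opening_stats(tl, native)
cat(sprintf("symmetric telegraph (k = 1/ns): S3 long-run mean %.4f (expect 0.5)\n",
            mean(s3$values)))
cat(sprintf("  pooled mean opening time %.3f ns over %d events (expect 1 ns)\n",
            sum(st$mean_open_ns * st$n_open) / sum(st$n_open),
            sum(st$n_open)))
write.csv(cbind(native[1:2], st[, c("n_open", "mean_open_ns",
                                    "total_open_ns")]),
          "results/opening_stats.csv", row.names = FALSE)

# two-condition comparison: contacts 1-3 close 4x slower in condition A
ba <- mk(BASE_SEED + 11L, c(1, 1, 1, rep(4, 7)))
bb <- mk(BASE_SEED + 12L, rep(4, 10))
native10 <- data.frame(res_i = ba$truth$schedule$pairs$res_i,
                       res_j = ba$truth$schedule$pairs$res_j, occupancy = 1)
sta <- opening_stats(contact_timeline(ba$traj, ba$system), native10)
stb <- opening_stats(contact_timeline(bb$traj, bb$system), native10)
shift <- opening_shift_classify(sta, stb, threshold_ns = 0.1)
cat(sprintf("shift classification (|0.1| ns margin): %.0f%% longer in A, %.0f%% in B, %.0f%% total (scripted: 30/0/30)\n",
            shift$pct_longer_in_a, shift$pct_longer_in_b,
            shift$pct_total_shifted))

# per-contact lost time and its cross-condition correlation. The conditions
# share the same heterogeneous per-contact opening rates (intrinsically
# flexible contacts are flexible in both), realized independently -- that
# shared heterogeneity is what makes lost times correlate across conditions.
k_close_het <- exp(seq(log(0.5), log(8), length.out = 20))
mk_het <- function(seed) synthesize_trajectory(synthetic_spec(
  seed = seed, dt_ns = 0.02, n_frames = 12500,
  protein = list(schedule = list(type = "telegraph", n_pairs = 20,
                                 k_open = 1, k_close = k_close_het))))
bha <- mk_het(BASE_SEED + 21L)
bhb <- mk_het(BASE_SEED + 22L)
native20 <- data.frame(res_i = bha$truth$schedule$pairs$res_i,
                       res_j = bha$truth$schedule$pairs$res_j, occupancy = 1)
lca <- attr(lost_time_per_residue(contact_timeline(bha$traj, bha$system),
                                  native20), "per_contact")
lcb <- attr(lost_time_per_residue(contact_timeline(bhb$traj, bhb$system),
                                  native20), "per_contact")
ct <- lost_time_correlation(lca$lost_pct, lcb$lost_pct)
cat(sprintf("lost-time correlation across conditions (shared rate heterogeneity): r = %.3f (p = %.2g, n = %d)\n",
            ct$r, ct$p_value, ct$n))
write.csv(data.frame(res_i = native20$res_i, res_j = native20$res_j,
                     k_close = k_close_het, lost_pct_a = lca$lost_pct,
                     lost_pct_b = lcb$lost_pct),
          "results/lost_time_per_contact.csv", row.names = FALSE)
cat("tables written to results/opening_stats.csv, results/lost_time_per_contact.csv\n")
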