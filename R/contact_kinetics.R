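#' Residue-residue contact timeline over a trajectory
#'
#' A contact between residues i and j exists in a frame when at least one
#' pair of heavy atoms across the two residues is closer than `cutoff`
#' (3.5 Angstrom by default). Residue pairs closer than `min_seq_sep` in
#' sequence are excluded (nearest neighbours are trivially always in contact
#' and would dilute the native-contact index). Pairs never present in any
#' frame are omitted.
#'
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @param min_seq_sep minimum |i - j| between residue indices (pairs with
#'   smaller separation are excluded; the default 3 keeps |i-j| >= 3).
#' @param pairs optional two-column matrix restricting the candidate residue
#'   pairs.
#' @return object of class `contact_timeline`: list with `contacts` (data
#'   frame res_i, res_j), `presence` (logical contacts x frames matrix),
#'   `dt` (ns), `times`.
#' @export
contact_timeline <- function(traj, system, cutoff = 3.5, min_seq_sep = 3,
                             pairs = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  prot_res <- system$residues$index[system$residues$species %in% "protein"]
  if (length(prot_res) < 2L) stop("need at least 2 protein residues")
  heavy <- protein_heavy_atoms(system)
  resi_of <- system$atoms$residue_index
  nf <- n_frames(traj)

  keymat <- NULL
  keys <- character(0)
  pres_list <- list()
  for (f in seq_len(nf)) {
    pd <- pair_distances(traj$coords[, , f], heavy, heavy, cutoff,
                         box = if (is.null(traj$box)) NULL else traj$box[f, ])
    ri <- resi_of[pd$i]; rj <- resi_of[pd$j]
    lo <- pmin(ri, rj); hi <- pmax(ri, rj)
    ok <- (hi - lo) >= min_seq_sep
    pk <- unique(paste(lo[ok], hi[ok]))
    pres_list[[f]] <- pk
    keys <- union(keys, pk)
  }
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    want <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    keys <- intersect(keys, want)
  }
  keys <- keys[order(as.integer(sub(" .*", "", keys)),
                     as.integer(sub(".* ", "", keys)))]
  presence <- matrix(FALSE, nrow = length(keys), ncol = nf)
  for (f in seq_len(nf)) presence[, f] <- keys %in% pres_list[[f]]
  ij <- do.call(rbind, strsplit(keys, " "))
  contacts <- data.frame(res_i = as.integer(ij[, 1]),
                         res_j = as.integer(ij[, 2]))
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else NA_real_
  structure(list(contacts = contacts, presence = presence, dt = dt,
                 times = traj$times),
            class = "contact_timeline")
}

#' @export
print.contact_timeline <- function(x, ...) {
  cat("<contact_timeline>", nrow(x$contacts), "contacts x",
      ncol(x$presence), "frames, dt =", x$dt, "ns\n")
  invisible(x)
}

contact_key <- function(tl) paste(tl$contacts$res_i, tl$contacts$res_j)

#' Native-contact set from a reference (native/water) timeline
#'
#' Keeps the contacts present in strictly more than `occupancy_threshold` of
#' the reference frames (native contacts are those occurring for more than
#' 80% of the time in the native-state reference run).
#'
#' @param reference_timeline `contact_timeline` from the reference run.
#' @param occupancy_threshold occupancy fraction (strict inequality).
#' @return data frame res_i, res_j, occupancy.
#' @export
native_contact_set <- function(reference_timeline, occupancy_threshold = 0.80) {
  tl <- reference_timeline
  if (nrow(tl$contacts) == 0L) stop("empty reference timeline")
  occ <- rowMeans(tl$presence)
  keep <- occ > occupancy_threshold
  out <- tl$contacts[keep, , drop = FALSE]
  out$occupancy <- occ[keep]
  rownames(out) <- NULL
  out
}

# rows of timeline matching a native set (NA when a native contact never
# appears in the timeline -- it is then absent in every frame)
match_native <- function(timeline, native) {
  match(paste(native$res_i, native$res_j), contact_key(timeline))
}

native_presence <- function(timeline, native) {
  rows <- match_native(timeline, native)
  pres <- matrix(FALSE, nrow = nrow(native), ncol = ncol(timeline$presence))
  has <- !is.na(rows)
  pres[has, ] <- timeline$presence[rows[has], , drop = FALSE]
  pres
}

#' Native-contact index S3 per frame
#'
#' Fraction of the native contacts present in each frame.
#'
#' @param timeline a `contact_timeline` for the analyzed condition.
#' @param native native-contact set from [native_contact_set()].
#' @return a `metric_series` in `[0, 1]`.
#' @export
s3_series <- function(timeline, native) {
  if (nrow(native) == 0L) stop("empty native-contact set")
  pres <- native_presence(timeline, native)
  metric_series("S3", colMeans(pres), timeline$times, "dimensionless")
}

#' Opening-interval statistics per native contact
#'
#' An opening is a maximal run of frames in which a native contact is absent;
#' its duration is run length times dt. Contacts that never open have zero
#' intervals and mean 0.
#'
#' @param timeline a `contact_timeline`.
#' @param native native-contact set.
#' @return data frame res_i, res_j, n_open, mean_open_ns, total_open_ns.
#' @export
opening_stats <- function(timeline, native) {
  if (is.na(timeline$dt)) stop("dt unknown (single-frame timeline)")
  pres <- native_presence(timeline, native)
  dt <- timeline$dt
  stats <- t(apply(pres, 1, function(p) {
    r <- rle(!p)
    lens <- r$lengths[r$values]
    if (length(lens) == 0L) c(0, 0, 0)
    else c(length(lens), mean(lens) * dt, sum(lens) * dt)
  }))
  data.frame(res_i = native$res_i, res_j = native$res_j,
             n_open = stats[, 1], mean_open_ns = stats[, 2],
             total_open_ns = stats[, 3])
}

#' Classify opening-time shifts between two conditions
#'
#' A contact counts for condition a when its mean opening time in a exceeds
#' that in b by strictly more than `threshold_ns` (0.1 ns, the margin used to
#' call a contact's flexibility changed), and symmetrically for b.
#' Percentages are over the native-contact count.
#'
#' @param stats_a,stats_b outputs of [opening_stats()] over the same
#'   contacts.
#' @param threshold_ns shift threshold in ns (strict inequality).
#' @return list pct_longer_in_a, pct_longer_in_b, pct_total_shifted.
#' @export
opening_shift_classify <- function(stats_a, stats_b, threshold_ns = 0.1) {
  if (nrow(stats_a) != nrow(stats_b) ||
      any(stats_a$res_i != stats_b$res_i) ||
      any(stats_a$res_j != stats_b$res_j))
    stop("contact-set mismatch between stats_a and stats_b")
  d <- stats_a$mean_open_ns - stats_b$mean_open_ns
  n <- nrow(stats_a)
  pa <- 100 * sum(d > threshold_ns) / n
  pb <- 100 * sum(-d > threshold_ns) / n
  list(pct_longer_in_a = pa, pct_longer_in_b = pb,
       pct_total_shifted = pa + pb)
}

#' Per-residue percentage of lost native-contact time
#'
#' Per contact, lost% is either the percentage of frames in which the contact
#' is absent ("absolute") or the occupancy deficit relative to the reference
#' run, 100 max(0, occ_ref - occ_now) / occ_ref ("reference_excess"). The
#' per-residue value is the mean over the native contacts the residue is
#' involved in; residues with no native contacts are NA.
#'
#' @param timeline a `contact_timeline` for the analyzed condition.
#' @param native native-contact set (with reference occupancies for the
#'   reference_excess mode).
#' @param mode "absolute" or "reference_excess".
#' @return data frame residue, lost_pct (NA for residues without native
#'   contacts), plus attribute "per_contact".
#' @export
lost_time_per_residue <- function(timeline, native,
                                  mode = c("absolute", "reference_excess")) {
  mode <- match.arg(mode)
  if (nrow(native) == 0L) stop("empty native-contact set")
  pres <- native_presence(timeline, native)
  occ_now <- rowMeans(pres)
  lost <- if (mode == "absolute") 100 * (1 - occ_now)
  else 100 * pmax(0, native$occupancy - occ_now) / native$occupancy
  residues <- sort(unique(c(native$res_i, native$res_j)))
  per_res <- vapply(residues, function(r) {
    mean(lost[native$res_i == r | native$res_j == r])
  }, numeric(1))
  out <- data.frame(residue = residues, lost_pct = per_res)
  attr(out, "per_contact") <- data.frame(res_i = native$res_i,
                                         res_j = native$res_j,
                                         lost_pct = lost)
  out
}

#' Pearson correlation between paired lost-time vectors
#'
#' Used to compare the time each native contact (or residue) remains lost
#' across two conditions. Two-sided p-value from the t distribution.
#'
#' @param lost_a,lost_b equal-length numeric vectors, n >= 3.
#' @return list r, p_value, n.
#' @export
lost_time_correlation <- function(lost_a, lost_b) {
  if (length(lost_a) != length(lost_b)) stop("length mismatch")
  ok <- is.finite(lost_a) & is.finite(lost_b)
  a <- lost_a[ok]; b <- lost_b[ok]
  if (length(a) < 3L) stop("need at least 3 paired values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in lost-time vector")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
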