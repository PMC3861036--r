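#' Root-mean-square fluctuation per atom or residue
#'
#' After optional superposition of every frame onto the mean structure
#' (computed iteratively: fit to the first frame, average, re-fit to the
#' average), RMSF_i = sqrt(<|r_i(t) - <r_i>|^2>). Per-residue values are the
#' unweighted mean over each residue's heavy atoms in the selection.
#'
#' @param traj an `mdtraj` with >= 2 frames.
#' @param system the `mdsystem` (needed for per-residue grouping).
#' @param selection atom indices (default: protein heavy atoms). The same
#'   selection is used for fitting.
#' @param superpose remove global rigid motion first.
#' @param per_residue average atom RMSF within residues.
#' @param fit_selection optional different atom set to superpose on (e.g.
#'   backbone only).
#' @return per-residue data frame (residue, rmsf) or named per-atom vector,
#'   Angstrom.
#' @export
rmsf <- function(traj, system, selection = NULL, superpose = TRUE,
                 per_residue = TRUE, fit_selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- protein_heavy_atoms(system)
  fit_sel <- fit_selection %||% selection
  n <- length(selection)
  stack <- array(NA_real_, dim = c(n, 3, nf))
  if (superpose) {
    ref <- traj$coords[fit_sel, , 1]
    for (f in seq_len(nf)) {
      fit <- kabsch_superpose(ref, traj$coords[fit_sel, , f])
      stack[, , f] <- apply_superposition(traj$coords[selection, , f], fit)
    }
    mean1 <- apply(stack, c(1, 2), mean)
    fitref <- mean1[match(fit_sel, selection), , drop = FALSE]
    if (!anyNA(fitref)) {
      for (f in seq_len(nf)) {
        fit <- kabsch_superpose(fitref, traj$coords[fit_sel, , f])
        stack[, , f] <- apply_superposition(traj$coords[selection, , f], fit)
      }
    }
  } else {
    stack <- traj$coords[selection, , , drop = FALSE]
  }
  mu <- apply(stack, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(f) rowSums((stack[, , f] - mu)^2),
                 numeric(n))
  atom_rmsf <- sqrt(rowMeans(matrix(dev2, nrow = n)))
  names(atom_rmsf) <- selection
  if (!per_residue) return(atom_rmsf)
  resi <- system$atoms$residue_index[selection]
  per <- tapply(atom_rmsf, resi, mean)
  data.frame(residue = as.integer(names(per)), rmsf = as.numeric(per))
}

#' Convert RMSF to a pseudo B-factor (and back)
#'
#' B = (8 pi^2 / 3) RMSF^2, the isotropic Debye-Waller relation, so that
#' crystallographic B-factors can be put on the same scale as computed
#' fluctuations.
#'
#' @param rmsf per-residue RMSF, Angstrom (non-negative).
#' @return pseudo-B in Angstrom^2.
#' @export
bfactor_scale <- function(rmsf) {
  if (any(rmsf < 0)) stop("RMSF must be non-negative")
  (8 * pi^2 / 3) * rmsf^2
}

#' @rdname bfactor_scale
#' @param b B-factor in Angstrom^2 (non-negative).
#' @export
bfactor_to_rmsf <- function(b) {
  if (any(b < 0)) stop("B-factor must be non-negative")
  sqrt(b * 3 / (8 * pi^2))
}

#' Compare side-chain stiffness between two conditions
#'
#' Per residue, side-chain heavy-atom RMSF in trajectory a vs b, both
#' superposed on the protein backbone; a residue is "stiffer in a" when its
#' side-chain RMSF is strictly smaller in a. The fraction is over residues
#' with at least one side-chain heavy atom.
#'
#' @param traj_a,traj_b two `mdtraj` of the same system.
#' @param system the shared classified `mdsystem`.
#' @return list `fraction_stiffer_in_a` and `per_residue` data frame
#'   (residue, rmsf_a, rmsf_b, stiffer_in_a).
#' @export
sidechain_stiffness_compare <- function(traj_a, traj_b, system) {
  sc <- select_atoms(system, species = "protein", heavy_only = TRUE,
                     role = "sidechain")
  if (length(sc) == 0L) stop("no side-chain heavy atoms in selection")
  bb <- select_atoms(system, species = "protein", heavy_only = TRUE,
                     role = "backbone")
  ra <- rmsf(traj_a, system, selection = sc, fit_selection = bb)
  rb <- rmsf(traj_b, system, selection = sc, fit_selection = bb)
  tab <- merge(ra, rb, by = "residue", suffixes = c("_a", "_b"))
  tab$stiffer_in_a <- tab$rmsf_a < tab$rmsf_b
  list(fraction_stiffer_in_a = mean(tab$stiffer_in_a),
       per_residue = tab)
}

#' Mean RMSD between frames separated by fixed time lags
#'
#' For each lag tau, the average over window starts t of
#' RMSD(frame t, frame t + tau), the reference always being the first frame
#' of the window; probes short-timescale mobility.
#'
#' @param traj an `mdtraj`.
#' @param lags_ns time lags, each smaller than the trajectory duration.
#' @param selection atom indices (default: all atoms).
#' @param superpose remove rigid-body motion per pair.
#' @return data frame lag_ns, mean_rmsd, n_windows.
#' @export
timelag_rmsd <- function(traj, lags_ns, selection = NULL, superpose = TRUE) {
  nf <- n_frames(traj)
  dt <- traj$times[2] - traj$times[1]
  dur <- traj$times[nf] - traj$times[1]
  if (any(lags_ns >= dur + dt / 2)) stop("lag must be below trajectory duration")
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[1])
  rows <- lapply(lags_ns, function(lag) {
    k <- round(lag / dt)
    if (k < 1L) stop("lag smaller than frame spacing")
    starts <- seq_len(nf - k)
    vals <- vapply(starts, function(t0) {
      a <- traj$coords[selection, , t0]
      b <- traj$coords[selection, , t0 + k]
      if (superpose) kabsch_superpose(a, b)$rmsd
      else sqrt(mean(rowSums((a - b)^2)))
    }, numeric(1))
    data.frame(lag_ns = k * dt, mean_rmsd = mean(vals),
               n_windows = length(starts))
  })
  do.call(rbind, rows)
}

# Unwrap periodic coordinates by accumulating minimum-image displacements.
# Requires that no particle moves more than half a box length per frame.
unwrap_coords <- function(coords, box) {
  nf <- dim(coords)[3]
  out <- coords
  for (f in 2:nf) {
    d <- matrix(coords[, , f] - coords[, , f - 1], ncol = 3)
    bx <- box[f, ]
    shift <- -round(sweep(d, 2, bx, "/")) %*% diag(bx)
    if (any(abs(d + shift) > rep(bx / 2 + 1e-6, each = nrow(d))))
      stop("unwrapping failed: displacement exceeds half a box length")
    out[, , f] <- out[, , f - 1] + d + shift
  }
  out
}

#' Mean-square displacement of solvent molecules
#'
#' MSD(tau) = <|r(t+tau) - r(t)|^2> over molecules (heavy-atom center of
#' mass by default) and all overlapping time origins. Coordinates must be
#' unwrapped; with a periodic box they are unwrapped by minimum-image
#' displacement accumulation (error if a molecule moves more than half a box
#' per frame).
#'
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param species "water" or "urea".
#' @param lags_ns time lags.
#' @param use_com use per-molecule center of mass (else every heavy atom
#'   independently).
#' @param origins "all" (every valid origin) or "independent"
#'   (non-overlapping windows, for error estimation).
#' @return data frame lag_ns, msd (Angstrom^2), n_samples.
#' @export
msd_curve <- function(traj, system, species = "water", lags_ns,
                      use_com = TRUE, origins = c("all", "independent")) {
  origins <- match.arg(origins)
  a <- system$atoms
  mol_res <- system$residues$index[system$residues$species %in% species]
  if (length(mol_res) == 0L) stop("no molecules of species ", species)
  sel <- which(a$residue_index %in% mol_res & a$is_heavy)
  coords <- traj$coords[sel, , , drop = FALSE]
  if (!is.null(traj$box)) coords <- unwrap_coords(coords, traj$box)
  if (use_com) {
    resi <- a$residue_index[sel]
    groups <- split(seq_along(sel), resi)
    nf <- dim(coords)[3]
    com <- array(NA_real_, dim = c(length(groups), 3, nf))
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      com[g, , ] <- apply(coords[idx, , , drop = FALSE], c(2, 3), mean)
    }
    coords <- com
  }
  nf <- dim(coords)[3]
  dt <- traj$times[2] - traj$times[1]
  rows <- lapply(lags_ns, function(lag) {
    k <- round(lag / dt)
    if (k >= nf) stop("lag beyond trajectory length")
    if (k == 0L) return(data.frame(lag_ns = 0, msd = 0,
                                   n_samples = dim(coords)[1] * nf))
    starts <- if (origins == "all") seq_len(nf - k)
    else seq(1L, nf - k, by = k)
    s <- 0
    for (t0 in starts) {
      d <- coords[, , t0 + k] - coords[, , t0]
      s <- s + sum(d * d)
    }
    n <- dim(coords)[1] * length(starts)
    data.frame(lag_ns = k * dt, msd = s / n, n_samples = n)
  })
  do.call(rbind, rows)
}

#' Einstein diffusion coefficient from an MSD curve
#'
#' D = slope/6 of the least-squares line through MSD(tau) over the stated
#' fraction of the available lag range (default 10-50%, avoiding the
#' ballistic start and the poorly sampled tail). Fit diagnostics (slope,
#' intercept, R-squared, range) are always reported so fit-range dependence
#' is visible.
#'
#' @param msd data frame from [msd_curve()].
#' @param fit_range fraction interval of the maximum lag to fit over.
#' @return list D (Angstrom^2/ns), slope, intercept, r_squared, n_points,
#'   fit_lags_ns, negative_slope flag.
#' @export
diffusion_coefficient <- function(msd, fit_range = c(0.1, 0.5)) {
  maxlag <- max(msd$lag_ns)
  keep <- msd$lag_ns >= fit_range[1] * maxlag &
    msd$lag_ns <= fit_range[2] * maxlag
  if (sum(keep) < 3L) stop("fewer than 3 lag points in fit range")
  fit <- stats::lm(msd ~ lag_ns, data = msd[keep, ])
  slope <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((msd$msd[keep] - mean(msd$msd[keep]))^2)
  list(D = slope / 6,
       slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_points = sum(keep),
       fit_lags_ns = range(msd$lag_ns[keep]),
       negative_slope = slope < 0)
}
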