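#' Per-frame metric series container
#' @param name metric name.
#' @param values numeric per-frame values.
#' @param times frame times in ns.
#' @param units unit string (non-empty).
#' @return object of class `metric_series`.
#' @export
metric_series <- function(name, values, times, units) {
  stopifnot(length(values) == length(times), nzchar(units))
  structure(list(name = name, values = values, times = times, units = units),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s [%s], %d frames, mean %.4g\n",
              x$name, x$units, length(x$values), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.metric_series <- function(x, ...) {
  data.frame(time_ns = x$times, value = x$values)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Returns the proper rotation and translation that minimize the (optionally
#' weighted) RMSD of `mobile` onto `reference`, together with that minimal
#' RMSD. The rotation is found from the SVD of the weighted covariance
#' matrix; a reflection in the SVD solution is corrected so that
#' `det(rotation) = +1` always.
#'
#' @param reference,mobile n x 3 coordinate matrices, n >= 3.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom). The superposed mobile is
#'   `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile))
    stop("point-count mismatch between reference and mobile")
  n <- nrow(reference)
  # n = 2 (collinear) is degenerate but well-defined up to an axial spin and
  # has a unique minimal RMSD, so it is accepted
  if (n < 2L) stop("need at least 2 points for superposition")
  w <- weights %||% rep(1, n)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  cref <- colSums(reference * w)
  cmob <- colSums(mobile * w)
  a <- sweep(reference, 2, cref)
  b <- sweep(mobile, 2, cmob)
  h <- t(b * w) %*% a
  sv <- svd(h)
  # reflection correction; rank-deficient (collinear/planar) cases take the
  # proper-rotation branch
  d <- if (det(sv$v %*% t(sv$u)) < 0) -1 else 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- b %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - a)^2)))
  list(rotation = rot, translation = as.numeric(cref - cmob %*% t(rot)),
       rmsd = rmsd)
}

apply_superposition <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' RMSD of every frame against a reference frame
#'
#' @param traj an `mdtraj`.
#' @param reference n_atoms x 3 reference coordinates (full system).
#' @param selection atom indices used both for fitting and for the RMSD.
#' @return a `metric_series` ("RMSD", Angstrom).
#' @export
rmsd_series <- function(traj, reference, selection) {
  if (length(selection) == 0L) stop("empty selection")
  ref <- as.matrix(reference)[selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(ref, traj$coords[selection, , f])$rmsd
  }, numeric(1))
  metric_series("RMSD", vals, traj$times, "Angstrom")
}

#' Radius of gyration of a selection in one frame
#'
#' sqrt(sum w_i |r_i - rbar|^2 / sum w_i); with `mass_weighted = TRUE`
#' weights are atomic masses from the element, otherwise unit weights.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param selection atom indices.
#' @param mass_weighted logical.
#' @param elements element symbols (needed for mass weighting).
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection, mass_weighted = FALSE,
                               elements = NULL) {
  if (length(selection) == 0L) stop("empty selection")
  x <- as.matrix(frame)[selection, , drop = FALSE]
  w <- if (mass_weighted) {
    if (is.null(elements)) stop("elements required for mass weighting")
    element_mass(elements[selection])
  } else rep(1, nrow(x))
  w <- w / sum(w)
  ctr <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2, ctr)^2)))
}

element_mass <- function(el) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974, Na = 22.990, Cl = 35.45, K = 39.098, Mg = 24.305,
         Zn = 65.38, Fe = 55.845, Ca = 40.078, D = 2.014)
  out <- m[el]
  out[is.na(out)] <- 12.0
  unname(out)
}

#' Radius-of-gyration series over a trajectory
#' @inheritParams rmsd_series
#' @param mass_weighted logical.
#' @param elements element symbols per atom.
#' @export
rgyr_series <- function(traj, selection, mass_weighted = FALSE,
                        elements = NULL) {
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(traj$coords[, , f], selection, mass_weighted, elements)
  }, numeric(1))
  metric_series("RadGyr", vals, traj$times, "Angstrom")
}

#' TM-score between two CA traces of equal length
#'
#' TM = (1/L) sum 1 / (1 + (d_i/d0)^2), d0 = 1.24 (L-15)^(1/3) - 1.8. The
#' traces are first superposed with the Kabsch algorithm on all CA atoms;
#' with `refine = TRUE` the superposition is iteratively recomputed on the
#' subset of residues with d_i < max(d0, 0.5) until the score stops
#' improving, and the best score found is returned. No alignment search is
#' performed (the sequences are identical by construction), so the refined
#' value is a lower bound of the full TM-align optimum.
#'
#' @param reference_ca,model_ca L x 3 CA coordinates, L >= 16.
#' @param refine iterate superposition on close pairs.
#' @param superpose apply the Kabsch superposition first (set FALSE to score
#'   the coordinates exactly as given, i.e. under the identity
#'   superposition; implies no refinement).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(reference_ca, model_ca, refine = TRUE,
                     superpose = TRUE) {
  ref <- as.matrix(reference_ca); mod <- as.matrix(model_ca)
  if (nrow(ref) != nrow(mod)) stop("length mismatch between CA traces")
  L <- nrow(ref)
  if (L < 16L) stop("TM-score requires at least 16 residues (d0 > 0)")
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  score_from <- function(fit) {
    d <- sqrt(rowSums((apply_superposition(mod, fit) - ref)^2))
    list(tm = mean(1 / (1 + (d / d0)^2)), d = d)
  }
  if (!superpose) {
    d <- sqrt(rowSums((mod - ref)^2))
    return(mean(1 / (1 + (d / d0)^2)))
  }
  fit <- kabsch_superpose(ref, mod)
  cur <- score_from(fit)
  best <- cur$tm
  if (refine) {
    thr <- max(d0, 0.5)
    for (iter in 1:20) {
      sub <- which(cur$d < thr)
      if (length(sub) < 3L) break
      fit2 <- kabsch_superpose(ref[sub, , drop = FALSE],
                               mod[sub, , drop = FALSE])
      cur <- score_from(fit2)
      if (cur$tm <= best + 1e-9) break
      best <- cur$tm
    }
  }
  best
}

#' TM-score series over a trajectory
#' @param traj an `mdtraj`.
#' @param reference full-system reference coordinates.
#' @param ca_selection CA atom indices.
#' @param refine see [tm_score()].
#' @export
tm_score_series <- function(traj, reference, ca_selection, refine = TRUE) {
  ref <- as.matrix(reference)[ca_selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    tm_score(ref, traj$coords[ca_selection, , f], refine = refine)
  }, numeric(1))
  metric_series("TMscore", vals, traj$times, "dimensionless")
}

#' Combine native-structure indexes into the global structure index
#'
#' Follows unfolding from 1 (fully native) towards 0. Two candidate
#' definitions are provided because the combination rule is a modelling
#' choice: the mean of the secondary-structure index S2 and the
#' native-contact index S3 (default) or S3 alone. Outputs must be labelled
#' with the mode used.
#'
#' @param s2,s3 numbers (or equal-length vectors) in `[0, 1]`.
#' @param mode "mean" or "s3_only".
#' @return structure index in `[0, 1]`.
#' @export
structure_index <- function(s2, s3, mode = c("mean", "s3_only")) {
  mode <- match.arg(mode)
  if (any(s2 < 0 | s2 > 1, na.rm = TRUE) || any(s3 < 0 | s3 > 1, na.rm = TRUE))
    stop("s2 and s3 must lie in [0, 1]")
  if (mode == "mean") (s2 + s3) / 2 else s3
}
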