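#' Default van der Waals radii (Bondi), Angstrom
#'
#' Used by the Shrake-Rupley SASA; hydrogens are normally absorbed into the
#' heavy-atom surface (SASA is computed on heavy atoms only), but a radius is
#' provided should they be included explicitly.
#' @return named numeric vector of radii by element.
#' @export
vdw_radii_default <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20,
    P = 1.80, Na = 2.27, Cl = 1.75, K = 2.75, Mg = 1.73, Zn = 1.39,
    Fe = 1.63, Ca = 2.31)
}

# Deterministic quasi-uniform sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each selected atom, `n_points` quasi-uniform points are placed on the
#' sphere of radius r_i + probe; the accessible area is the fraction of
#' points not inside any neighbor sphere r_j + probe, times
#' 4 pi (r_i + probe)^2. Computed on heavy atoms only by default, matching
#' trajectories with implicit hydrogens.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param system the `mdsystem` (for elements and selections).
#' @param selection atom indices to compute areas for (default: protein heavy
#'   atoms). Neighbors are taken from the same selection.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points sphere points per atom.
#' @param radii named radii table by element; every selected element must
#'   have an entry.
#' @return numeric vector of per-atom areas (Angstrom^2), named by atom
#'   index.
#' @export
sasa <- function(frame, system, selection = NULL, probe = 1.4,
                 n_points = 960, radii = vdw_radii_default()) {
  if (is.null(selection)) selection <- protein_heavy_atoms(system)
  if (length(selection) == 0L) stop("empty selection")
  el <- system$atoms$element[selection]
  if (any(!el %in% names(radii)))
    stop("missing radius for element(s): ",
         paste(unique(el[!el %in% names(radii)]), collapse = ", "))
  r <- unname(radii[el]) + probe
  x <- as.matrix(frame)[selection, , drop = FALSE]
  pts <- sphere_points(n_points)
  n <- length(selection)
  areas <- numeric(n)
  maxr <- max(r)
  # neighbor lists once per frame
  nb <- pair_distances(as.matrix(frame), selection, selection,
                       cutoff = 2 * maxr + 1e-9)
  nb_of <- vector("list", n)
  if (nrow(nb) > 0) {
    ia <- match(nb$i, selection); ja <- match(nb$j, selection)
    for (k in seq_len(nrow(nb))) {
      nb_of[[ia[k]]] <- c(nb_of[[ia[k]]], ja[k])
      nb_of[[ja[k]]] <- c(nb_of[[ja[k]]], ia[k])
    }
  }
  for (k in seq_len(n)) {
    surf <- pts * r[k]
    surf <- sweep(surf, 2, x[k, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb_of[[k]]) {
      if (sqrt(sum((x[j, ] - x[k, ])^2)) >= r[k] + r[j]) next
      d2 <- (surf[, 1] - x[j, 1])^2 + (surf[, 2] - x[j, 2])^2 +
        (surf[, 3] - x[j, 3])^2
      acc <- acc & d2 > r[j]^2
      if (!any(acc)) break
    }
    areas[k] <- sum(acc) / n_points * 4 * pi * r[k]^2
  }
  names(areas) <- selection
  areas
}

#' Partition per-atom SASA into polar and apolar residue classes
#'
#' Polar = residues classed polar or charged; apolar = hydrophobic residues
#' (the split is by residue class, not atom chemistry). The partition sums to
#' the total exactly.
#'
#' @param per_atom named per-atom areas from [sasa()].
#' @param system a classified `mdsystem`.
#' @return list with `total`, `polar`, `apolar` (Angstrom^2) and
#'   `per_residue` (data frame residue, area).
#' @export
sasa_partition <- function(per_atom, system) {
  idx <- as.integer(names(per_atom))
  resi <- system$atoms$residue_index[idx]
  pol <- system$residues$polarity_class[resi]
  per_res <- tapply(per_atom, resi, sum)
  total <- sum(per_atom)
  polar <- sum(per_atom[pol %in% c("polar", "charged")])
  apolar <- sum(per_atom[pol %in% "hydrophobic"])
  list(total = total, polar = polar, apolar = apolar,
       per_residue = data.frame(residue = as.integer(names(per_res)),
                                area = as.numeric(per_res)))
}

#' SASA series over a trajectory, with polar/apolar split
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param ... passed to [sasa()].
#' @return data frame (time_ns, total, polar, apolar).
#' @export
sasa_series <- function(traj, system, ...) {
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    p <- sasa_partition(sasa(traj$coords[, , f], system, ...), system)
    data.frame(time_ns = traj$times[f], total = p$total, polar = p$polar,
               apolar = p$apolar)
  })
  do.call(rbind, rows)
}

#' Normalize a SASA series by the mean of a water-reference series
#'
#' Each value is divided by the mean of the reference run (the native-state
#' water simulation), so that 1 means "as exposed as the native ensemble".
#' A delta variant (value minus reference mean) is available via
#' `mode = "delta"`.
#'
#' @param series a `metric_series`.
#' @param water_reference a `metric_series` from the reference condition.
#' @param mode "ratio" (default) or "delta".
#' @return a `metric_series`.
#' @export
sasa_normalize <- function(series, water_reference, mode = c("ratio", "delta")) {
  mode <- match.arg(mode)
  if (length(water_reference$values) == 0L) stop("empty reference series")
  m <- mean(water_reference$values)
  if (mode == "ratio") {
    if (abs(m) < 1e-12) stop("zero reference mean")
    metric_series(paste0(series$name, "_norm"), series$values / m,
                  series$times, "dimensionless")
  } else {
    metric_series(paste0("d", series$name), series$values - m,
                  series$times, series$units)
  }
}
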