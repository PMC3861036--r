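#' Simplified DSSP secondary-structure assignment for one frame
#'
#' Three-state assignment per protein residue. Backbone hydrogen bonds are
#' scored with the Kabsch-Sander electrostatic model,
#' E = 0.084 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol, a bond being
#' E < -0.5 kcal/mol. The amide H is reconstructed 1 Angstrom from N along
#' the direction opposite the bisector of N->C(prev) and N->CA when not
#' present in the file. Labels: H for residues inside runs of consecutive
#' i -> i+4 bonds (alpha helix; 3-10/pi folded into H by construction of the
#' rule), E for residues in parallel/antiparallel bridge ladders of length
#' >= 2, C otherwise. Residues with missing backbone atoms are labelled C
#' with a warning.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param system a classified `mdsystem`.
#' @return character vector of labels ("H", "E", "C") named by protein
#'   residue index.
#' @export
assign_ss <- function(frame, system) {
  bb <- backbone_table(system)
  res_idx <- bb$residue
  nres <- length(res_idx)
  labels <- rep("C", nres)
  names(labels) <- res_idx
  if (nres < 5L) return(labels)
  frame <- as.matrix(frame)

  getxyz <- function(col, k) {
    i <- bb[[col]][k]
    if (is.na(i)) return(NULL)
    frame[i, ]
  }
  missing_bb <- is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O)
  if (any(missing_bb)) {
    warning("residue(s) with missing backbone atoms labelled C: ",
            paste(res_idx[missing_bb], collapse = ", "))
  }

  # amide H per residue (NULL if the residue cannot donate)
  hpos <- vector("list", nres)
  for (k in seq_len(nres)) {
    if (missing_bb[k]) next
    if (bb$name[k] == "PRO") next
    if (!is.na(bb$H[k])) {
      hpos[[k]] <- frame[bb$H[k], ]
      next
    }
    if (k == 1L || missing_bb[k - 1L] || !contiguous(bb, k)) next
    n <- getxyz("N", k); ca <- getxyz("CA", k); cprev <- getxyz("C", k - 1L)
    dir <- -(unit(cprev - n) + unit(ca - n))
    hpos[[k]] <- n + unit(dir)
  }

  # Kabsch-Sander H-bond matrix: hb[i, j] TRUE when CO of i accepts from NH
  # of j
  hb <- matrix(FALSE, nres, nres)
  for (i in seq_len(nres)) {
    if (missing_bb[i]) next
    o <- getxyz("O", i); cc <- getxyz("C", i)
    for (j in seq_len(nres)) {
      if (abs(i - j) < 2L || missing_bb[j] || is.null(hpos[[j]])) next
      n <- getxyz("N", j)
      if (sum((o - n)^2) > 25) next  # O..N beyond 5 A cannot pass -0.5
      h <- hpos[[j]]
      e <- 0.084 * (1 / vnorm(o - n) + 1 / vnorm(cc - h) -
                      1 / vnorm(o - h) - 1 / vnorm(cc - n)) * 332
      if (e < -0.5) hb[i, j] <- TRUE
    }
  }

  # alpha helix: two consecutive i -> i+4 turns make residues i+1..i+4 H
  turn4 <- rep(FALSE, nres)
  for (i in seq_len(nres - 4L)) turn4[i] <- hb[i, i + 4L]
  is_h <- rep(FALSE, nres)
  for (i in seq_len(nres - 5L)) {
    if (turn4[i] && turn4[i + 1L]) is_h[(i + 1L):(i + 4L)] <- TRUE
  }

  # bridges (DSSP definitions), then ladders of >= 2 consecutive bridges
  bridge <- list()
  for (i in 2:(nres - 1L)) {
    for (j in 2:(nres - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[i - 1L, j] && hb[j, i + 1L]) ||
        (hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) {
        bridge[[length(bridge) + 1L]] <- c(i, j, if (anti) -1L else 1L)
      }
    }
  }
  is_e <- rep(FALSE, nres)
  if (length(bridge) > 0) {
    bm <- do.call(rbind, bridge)
    for (r in seq_len(nrow(bm))) {
      i <- bm[r, 1]; j <- bm[r, 2]; sgn <- bm[r, 3]
      jn <- if (sgn < 0) j - 1L else j + 1L
      nxt <- which(bm[, 1] == i + 1L & bm[, 2] == jn & bm[, 3] == sgn)
      if (length(nxt) > 0) {
        is_e[c(i, i + 1L, j, jn)] <- TRUE
      }
    }
  }

  labels[is_e] <- "E"
  labels[is_h] <- "H"  # helix takes precedence
  labels
}

contiguous <- function(bb, k) {
  bb$residue[k] - bb$residue[k - 1L] == 1L && bb$chain[k] == bb$chain[k - 1L]
}

# one row per protein residue with atom indices of N, CA, C, O, H (NA when
# absent)
backbone_table <- function(system) {
  prot <- system$residues[system$residues$species %in% "protein", ,
                          drop = FALSE]
  if (nrow(prot) == 0L) {
    # unclassified systems: any residue with N, CA, C is treated as protein
    a <- system$atoms
    has_bb <- vapply(split(a$name, a$residue_index),
                     function(nm) all(c("N", "CA", "C") %in% nm), logical(1))
    prot <- system$residues[system$residues$index %in%
                              as.integer(names(has_bb)[has_bb]), ,
                            drop = FALSE]
  }
  a <- system$atoms
  find <- function(resi, nm) {
    i <- which(a$residue_index == resi & a$name == nm)
    if (length(i) == 0L) NA_integer_ else i[1]
  }
  data.frame(
    residue = prot$index,
    name = prot$name,
    chain = prot$chain,
    N = vapply(prot$index, find, integer(1), nm = "N"),
    CA = vapply(prot$index, find, integer(1), nm = "CA"),
    C = vapply(prot$index, find, integer(1), nm = "C"),
    O = vapply(prot$index, find, integer(1), nm = "O"),
    H = vapply(prot$index, find, integer(1), nm = "H")
  )
}

#' Native secondary-structure index S2
#'
#' Fraction of residues natively labelled H or E that carry the same label in
#' the current frame. Degenerate case (no native H/E) returns 1 with a
#' warning.
#'
#' @param current,native label vectors from [assign_ss()] over the same
#'   residues.
#' @return number in `[0, 1]`.
#' @export
s2_index <- function(current, native) {
  if (length(current) != length(native) ||
      !identical(names(current), names(native)))
    stop("residue-set mismatch between current and native assignments")
  struct <- native %in% c("H", "E")
  if (!any(struct)) {
    warning("no native H/E residues; S2 defined as 1")
    return(1)
  }
  mean(current[struct] == native[struct])
}

#' S2 series over a trajectory
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param native native-frame assignment from [assign_ss()].
#' @return a `metric_series` plus attribute "labels" (residues x frames).
#' @export
s2_series <- function(traj, system, native) {
  labs <- vapply(seq_len(n_frames(traj)), function(f) {
    assign_ss(traj$coords[, , f], system)
  }, character(length(native)))
  vals <- apply(labs, 2, s2_index, native = native)
  out <- metric_series("S2", vals, traj$times, "dimensionless")
  attr(out, "labels") <- labs
  out
}

#' Secondary-structure content (% of residues H or E) for one assignment
#' @param labels vector from [assign_ss()].
#' @export
ss_content <- function(labels) 100 * mean(labels %in% c("H", "E"))
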