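# Donor/acceptor chemistry. Donors are N/O heavy atoms with at least one
# attached hydrogen (bonded H = same residue, within 1.25 A); the backbone
# amide H is reconstructed geometrically when absent. Acceptors are oxygens
# plus the HIS imidazole nitrogens; sulfur is excluded.
hbond_sites <- function(frame, system) {
  a <- system$atoms
  frame <- as.matrix(frame)
  sp <- system$residues$species[a$residue_index]

  is_N <- a$element == "N"
  is_O <- a$element == "O"
  acceptor <- is_O |
    (is_N & a$residue_name == "HIS" & a$name %in% c("ND1", "NE2"))

  hyd <- which(!a$is_heavy)
  donors <- list()
  cand <- which((is_N | is_O) & !(a$role %in% "ion"))
  for (d in cand) {
    same_res <- hyd[a$residue_index[hyd] == a$residue_index[d]]
    if (length(same_res) > 0) {
      dd <- sqrt(colSums((t(frame[same_res, , drop = FALSE]) - frame[d, ])^2))
      att <- same_res[dd < 1.25]
      for (h in att) {
        donors[[length(donors) + 1L]] <- c(d, h)
      }
      if (length(att) > 0) next
    }
    # backbone amide N: reconstruct H from C(prev), N, CA
    if (sp[d] == "protein" && a$name[d] == "N" &&
        a$residue_name[d] != "PRO") {
      resi <- a$residue_index[d]
      ca <- which(a$residue_index == resi & a$name == "CA")
      cprev <- which(a$residue_index == (resi - 1L) & a$name == "C")
      if (length(ca) == 1L && length(cprev) == 1L) {
        n <- frame[d, ]
        hp <- n + unit(-(unit(frame[cprev, ] - n) + unit(frame[ca, ] - n)))
        donors[[length(donors) + 1L]] <- c(d, -1L)
        attr(donors[[length(donors)]], "hpos") <- hp
      }
    }
  }
  list(donors = donors, acceptors = which(acceptor))
}

#' Geometric hydrogen-bond detection for one frame
#'
#' A hydrogen bond requires donor-acceptor heavy-atom distance
#' <= `dist_cutoff` and donor-H-acceptor angle >= `angle_cutoff_deg` (bonds
#' more linear than the cutoff are accepted; this convention is a config
#' switch because tools differ -- with `convention = "ADH"` the criterion
#' becomes angle(H-D-A) <= 180 - cutoff instead).
#'
#' @param frame n_atoms x 3 coordinates.
#' @param system a classified `mdsystem`.
#' @param dist_cutoff donor-acceptor heavy distance, Angstrom.
#' @param angle_cutoff_deg angle cutoff, degrees.
#' @param convention "DHA" (angle at the hydrogen, default) or "ADH" (angle
#'   at the donor).
#' @param intermolecular_only drop bonds within one residue (default TRUE).
#' @return data frame donor, hydrogen (NA when reconstructed), acceptor,
#'   distance, angle, donor_species, acceptor_species, donor_part,
#'   acceptor_part.
#' @export
detect_hbonds <- function(frame, system, dist_cutoff = 3.50,
                          angle_cutoff_deg = 120.0,
                          convention = c("DHA", "ADH"),
                          intermolecular_only = TRUE) {
  convention <- match.arg(convention)
  frame <- as.matrix(frame)
  sites <- hbond_sites(frame, system)
  a <- system$atoms
  sp <- system$residues$species[a$residue_index]
  out <- list()
  if (length(sites$donors) == 0L || length(sites$acceptors) == 0L)
    return(empty_hbonds())
  acc <- sites$acceptors
  accx <- frame[acc, , drop = FALSE]
  for (dn in sites$donors) {
    d <- dn[1]
    h <- if (dn[2] > 0) frame[dn[2], ] else attr(dn, "hpos")
    dx <- frame[d, ]
    dd <- sqrt(colSums((t(accx) - dx)^2))
    near <- which(dd <= dist_cutoff & acc != d)
    for (k in near) {
      aidx <- acc[k]
      if (intermolecular_only &&
          a$residue_index[aidx] == a$residue_index[d]) next
      ang <- if (convention == "DHA") angle3(dx, h, accx[k, ])
      else 180 - angle3(h, dx, accx[k, ])
      if (ang >= angle_cutoff_deg) {
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = if (dn[2] > 0) dn[2] else NA_integer_,
          acceptor = aidx, distance = dd[k], angle = ang,
          donor_species = sp[d], acceptor_species = sp[aidx],
          donor_part = part_of(a, d, sp), acceptor_part = part_of(a, aidx, sp))
      }
    }
  }
  if (length(out) == 0L) return(empty_hbonds())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

part_of <- function(a, i, sp) {
  if (sp[i] != "protein") return("n/a")
  if (a$role[i] == "backbone") "backbone" else "sidechain"
}

empty_hbonds <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
             distance = numeric(0), angle = numeric(0),
             donor_species = character(0), acceptor_species = character(0),
             donor_part = character(0), acceptor_part = character(0))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Bonds are keyed by (donor atom, acceptor atom). Total time is the number
#' of frames detected times dt; a bond is retained when its total time is
#' strictly larger than `min_occupancy_ns` (stable solvent contacts per the
#' 0.5 ns occupancy criterion). Longest continuous lifetime from maximal
#' runs.
#'
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param min_occupancy_ns retention threshold, ns.
#' @param ... passed to [detect_hbonds()].
#' @return data frame donor, acceptor, total_ns, longest_ns, n_frames,
#'   retained plus the classification columns.
#' @export
hbond_occupancy <- function(traj, system, min_occupancy_ns = 0.5, ...) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("dt unknown (need at least 2 frames)")
  dt <- traj$times[2] - traj$times[1]
  frames_of <- list()
  meta <- list()
  for (f in seq_len(nf)) {
    hb <- detect_hbonds(traj$coords[, , f], system, ...)
    if (nrow(hb) == 0L) next
    keys <- paste(hb$donor, hb$acceptor)
    for (r in seq_len(nrow(hb))) {
      k <- keys[r]
      frames_of[[k]] <- c(frames_of[[k]], f)
      if (is.null(meta[[k]])) meta[[k]] <- hb[r, ]
    }
  }
  if (length(frames_of) == 0L) {
    out <- empty_hbonds()
    out$total_ns <- numeric(0); out$longest_ns <- numeric(0)
    out$retained <- logical(0)
    return(out)
  }
  rows <- lapply(names(frames_of), function(k) {
    fr <- sort(unique(frames_of[[k]]))
    pres <- rep(FALSE, nf); pres[fr] <- TRUE
    r <- rle(pres)
    longest <- max(c(0, r$lengths[r$values]))
    m <- meta[[k]]
    data.frame(donor = m$donor, acceptor = m$acceptor,
               donor_species = m$donor_species,
               acceptor_species = m$acceptor_species,
               donor_part = m$donor_part, acceptor_part = m$acceptor_part,
               n_frames = length(fr), total_ns = length(fr) * dt,
               longest_ns = longest * dt)
  })
  out <- do.call(rbind, rows)
  out$retained <- out$total_ns > min_occupancy_ns
  out[order(-out$total_ns), , drop = FALSE]
}

#' Partition of solvent-protein hydrogen bonds
#'
#' Among retained solvent-protein bonds: urea vs water share; per solvent
#' species, the share where the solvent acts as donor vs acceptor; and per
#' species, the backbone vs sidechain share on the protein side. All
#' partitions sum to 100%.
#'
#' @param bonds output of [hbond_occupancy()] (or [detect_hbonds()]);
#'   typically filtered to `retained` bonds.
#' @return nested list of counts and percentage fractions.
#' @export
hbond_partition <- function(bonds) {
  solv <- bonds[(bonds$donor_species %in% c("urea", "water") &
                   bonds$acceptor_species == "protein") |
                  (bonds$acceptor_species %in% c("urea", "water") &
                     bonds$donor_species == "protein"), , drop = FALSE]
  if (nrow(solv) == 0L) stop("no solvent-protein hydrogen bonds")
  species <- ifelse(solv$donor_species %in% c("urea", "water"),
                    solv$donor_species, solv$acceptor_species)
  solvent_is_donor <- solv$donor_species %in% c("urea", "water")
  protein_part <- ifelse(solvent_is_donor, solv$acceptor_part,
                         solv$donor_part)
  n <- nrow(solv)
  per_species <- function(spc) {
    sel <- species == spc
    m <- sum(sel)
    list(n = m,
         pct_of_solvent_bonds = 100 * m / n,
         donor_pct = if (m > 0) 100 * sum(solvent_is_donor[sel]) / m else NA,
         acceptor_pct = if (m > 0)
           100 * sum(!solvent_is_donor[sel]) / m else NA,
         backbone_pct = if (m > 0)
           100 * sum(protein_part[sel] == "backbone") / m else NA,
         sidechain_pct = if (m > 0)
           100 * sum(protein_part[sel] == "sidechain") / m else NA)
  }
  list(n_total = n,
       urea = per_species("urea"),
       water = per_species("water"))
}
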