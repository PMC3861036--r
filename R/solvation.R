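# solvent molecule bookkeeping: one row per water/urea residue
solvent_molecules <- function(system, include_ions = FALSE) {
  sp <- system$residues$species
  keep <- sp %in% c("water", "urea", if (include_ions) "ion")
  data.frame(molecule = system$residues$index[keep],
             species = sp[keep])
}

#' Assign solvent molecules to solvation shells for one frame
#'
#' A molecule is in the first solvation shell (FSS) when any of its heavy
#' atoms lies within `fss_cutoff` of any protein heavy atom; in the bulk when
#' all its heavy atoms are beyond `bulk_cutoff`; otherwise in the
#' intermediate band, which belongs to neither shell. Membership is per
#' molecule via the nearest heavy-atom distance.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param system a classified `mdsystem`.
#' @param fss_cutoff FSS distance, Angstrom (default 5).
#' @param bulk_cutoff bulk minimum distance, Angstrom (default 6).
#' @param box optional periodic box for this frame.
#' @param include_ions count ions as solvent (off by default).
#' @return data frame molecule, species, shell ("FSS", "intermediate",
#'   "bulk").
#' @export
shell_assign <- function(frame, system, fss_cutoff = 5.0, bulk_cutoff = 6.0,
                         box = NULL, include_ions = FALSE) {
  if (fss_cutoff > bulk_cutoff) stop("fss_cutoff must be <= bulk_cutoff")
  mols <- solvent_molecules(system, include_ions)
  prot <- protein_heavy_atoms(system)
  a <- system$atoms
  solv_atoms <- which(a$residue_index %in% mols$molecule & a$is_heavy)
  pd <- pair_distances(frame, solv_atoms, prot, bulk_cutoff, box = box)
  shell <- rep("bulk", nrow(mols))
  if (nrow(pd) > 0) {
    mol_of_pair <- a$residue_index[pd$i]
    near <- tapply(pd$distance, mol_of_pair, min)
    hit <- match(as.integer(names(near)), mols$molecule)
    shell[hit] <- ifelse(near <= fss_cutoff, "FSS", "intermediate")
  }
  data.frame(molecule = mols$molecule, species = mols$species, shell = shell)
}

#' Water/urea ratio in FSS and bulk over a trajectory
#'
#' The ratio is (# water molecules) / (# urea molecules) per shell per
#' frame. Frames with zero urea in a shell yield an undefined ratio for that
#' frame; they are excluded from the averages and counted.
#'
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param ... passed to [shell_assign()].
#' @return list with `per_frame` (data frame time_ns, fss_ratio, bulk_ratio,
#'   fss_water, fss_urea, bulk_water, bulk_urea) and `summary` (mean, sd,
#'   n_excluded per shell).
#' @export
shell_ratio_series <- function(traj, system, ...) {
  sp <- system$residues$species
  if (!any(sp %in% "water") || !any(sp %in% "urea"))
    stop("both water and urea molecules must be present")
  nf <- n_frames(traj)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    sa <- shell_assign(traj$coords[, , f], system,
                       box = if (is.null(traj$box)) NULL else traj$box[f, ],
                       ...)
    cnt <- function(sp, sh) sum(sa$species == sp & sa$shell == sh)
    fw <- cnt("water", "FSS"); fu <- cnt("urea", "FSS")
    bw <- cnt("water", "bulk"); bu <- cnt("urea", "bulk")
    rows[[f]] <- data.frame(
      time_ns = traj$times[f],
      fss_ratio = if (fu > 0) fw / fu else NA_real_,
      bulk_ratio = if (bu > 0) bw / bu else NA_real_,
      fss_water = fw, fss_urea = fu, bulk_water = bw, bulk_urea = bu)
  }
  per_frame <- do.call(rbind, rows)
  smry <- data.frame(
    shell = c("FSS", "bulk"),
    mean_ratio = c(mean(per_frame$fss_ratio, na.rm = TRUE),
                   mean(per_frame$bulk_ratio, na.rm = TRUE)),
    sd_ratio = c(stats::sd(per_frame$fss_ratio, na.rm = TRUE),
                 stats::sd(per_frame$bulk_ratio, na.rm = TRUE)),
    n_excluded = c(sum(is.na(per_frame$fss_ratio)),
                   sum(is.na(per_frame$bulk_ratio))))
  list(per_frame = per_frame, summary = smry)
}

#' Urea-preference contact coefficient CC_UW
#'
#' Per protein group, the ratio between the time-averaged number of
#' protein-heavy-atom / urea-heavy-atom pairs closer than `cutoff` and the
#' same count against water. Values above the bulk urea:water atom ratio mean
#' preference for urea. Reported raw by default; set
#' `normalize_bulk = TRUE` to divide by the bulk urea:water heavy-atom count
#' ratio for cross-concentration comparisons.
#'
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param cutoff contact cutoff, Angstrom.
#' @param group_by one of "residue", "polarity_class", "role", "core".
#' @param normalize_bulk divide by bulk urea:water atom-count ratio.
#' @return data frame group, urea_contacts, water_contacts, cc_uw (NA and
#'   flagged when a group has zero water contacts).
#' @export
cc_uw <- function(traj, system, cutoff = 3.5,
                  group_by = c("residue", "polarity_class", "role", "core"),
                  normalize_bulk = FALSE) {
  group_by <- match.arg(group_by)
  a <- system$atoms
  prot <- protein_heavy_atoms(system)
  urea_atoms <- select_atoms(system, species = "urea", heavy_only = TRUE)
  water_atoms <- select_atoms(system, species = "water", heavy_only = TRUE)
  if (length(urea_atoms) == 0L || length(water_atoms) == 0L)
    stop("both urea and water must be present")

  group_of_atom <- switch(group_by,
    residue = a$residue_index[prot],
    polarity_class = system$residues$polarity_class[a$residue_index[prot]],
    role = a$role[prot],
    core = {
      core <- system$residues$is_core[a$residue_index[prot]]
      if (all(is.na(core))) stop("is_core not set; run assign_core() first")
      ifelse(core, "core", "non_core")
    })

  nf <- n_frames(traj)
  groups <- sort(unique(group_of_atom))
  ucnt <- stats::setNames(numeric(length(groups)), groups)
  wcnt <- ucnt
  for (f in seq_len(nf)) {
    bx <- if (is.null(traj$box)) NULL else traj$box[f, ]
    pu <- pair_distances(traj$coords[, , f], prot, urea_atoms, cutoff,
                         box = bx)
    pw <- pair_distances(traj$coords[, , f], prot, water_atoms, cutoff,
                         box = bx)
    if (nrow(pu) > 0) {
      tb <- table(group_of_atom[match(pu$i, prot)])
      ucnt[names(tb)] <- ucnt[names(tb)] + tb
    }
    if (nrow(pw) > 0) {
      tb <- table(group_of_atom[match(pw$i, prot)])
      wcnt[names(tb)] <- wcnt[names(tb)] + tb
    }
  }
  ucnt <- ucnt / nf; wcnt <- wcnt / nf
  cc <- ifelse(wcnt > 0, ucnt / wcnt, NA_real_)
  if (normalize_bulk) cc <- cc / (length(urea_atoms) / length(water_atoms))
  out <- data.frame(group = groups, urea_contacts = as.numeric(ucnt),
                    water_contacts = as.numeric(wcnt),
                    cc_uw = as.numeric(cc))
  if (any(is.na(cc)))
    attr(out, "undefined_groups") <- groups[is.na(cc)]
  out
}

#' Solvent residence events on the protein (or a residue set)
#'
#' An event is a maximal run of frames in which one solvent molecule has at
#' least one heavy-atom contact (< `cutoff`) with the target; runs separated
#' by gaps of at most `gap_tolerance_frames` frames are merged. Durations are
#' run length times dt.
#'
#' @param traj an `mdtraj`.
#' @param system a classified `mdsystem`.
#' @param species "urea" or "water".
#' @param target residue indices of the target (default: all protein
#'   residues).
#' @param cutoff contact cutoff, Angstrom.
#' @param gap_tolerance_frames merge gaps up to this many frames.
#' @return data frame molecule, species, start_ns, end_ns, duration_ns,
#'   n_frames; attribute "contact_frames" holds the per-molecule contact
#'   frame lists (used for per-molecule maps).
#' @export
residence_events <- function(traj, system, species = "urea", target = NULL,
                             cutoff = 3.5, gap_tolerance_frames = 0) {
  if (is.null(target))
    target <- system$residues$index[system$residues$species %in% "protein"]
  a <- system$atoms
  tgt_atoms <- which(a$residue_index %in% target & a$is_heavy)
  mol_res <- system$residues$index[system$residues$species %in% species]
  sol_atoms <- which(a$residue_index %in% mol_res & a$is_heavy)
  nf <- n_frames(traj)
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else stop("dt unknown")

  contact <- matrix(FALSE, nrow = length(mol_res), ncol = nf)
  rownames(contact) <- mol_res
  pair_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    pd <- pair_distances(traj$coords[, , f], sol_atoms, tgt_atoms, cutoff,
                         box = if (is.null(traj$box)) NULL else traj$box[f, ])
    if (nrow(pd) > 0) {
      mols <- unique(a$residue_index[pd$i])
      contact[as.character(mols), f] <- TRUE
      pair_rows[[f]] <- unique(data.frame(
        molecule = a$residue_index[pd$i],
        residue = a$residue_index[pd$j], frame = f))
    }
  }

  rows <- list()
  for (m in seq_along(mol_res)) {
    p <- contact[m, ]
    if (gap_tolerance_frames > 0) p <- fill_gaps(p, gap_tolerance_frames)
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    for (k in on) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule = mol_res[m], species = species,
        start_ns = traj$times[starts[k]],
        end_ns = traj$times[ends[k]] + dt,
        duration_ns = r$lengths[k] * dt,
        n_frames = r$lengths[k])
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(molecule = integer(0), species = character(0),
                  start_ns = numeric(0), end_ns = numeric(0),
                  duration_ns = numeric(0), n_frames = integer(0))
  attr(out, "contact_map") <- do.call(rbind, pair_rows)
  attr(out, "dt") <- dt
  out
}

fill_gaps <- function(p, tol) {
  r <- rle(p)
  inner <- which(!r$values & r$lengths <= tol)
  inner <- inner[inner > 1 & inner < length(r$values)]
  r$values[inner] <- TRUE
  inverse.rle(r)
}

#' Long-residence solvent molecules with per-molecule contact maps
#'
#' Ranks molecules by their longest residence event and reports every
#' molecule with at least one event of duration >= `min_duration_ns`,
#' together with its residue x frame dot map.
#'
#' @param events output of [residence_events()].
#' @param min_duration_ns threshold in ns.
#' @return list with `ranked` (data frame molecule, longest_ns, total_ns)
#'   and `maps` (named list of data frames residue, frame).
#' @export
long_residence_report <- function(events, min_duration_ns) {
  if (nrow(events) == 0L)
    return(list(ranked = data.frame(molecule = integer(0),
                                    longest_ns = numeric(0),
                                    total_ns = numeric(0)),
                maps = list()))
  longest <- tapply(events$duration_ns, events$molecule, max)
  total <- tapply(events$duration_ns, events$molecule, sum)
  keep <- longest >= min_duration_ns
  ranked <- data.frame(molecule = as.integer(names(longest))[keep],
                       longest_ns = as.numeric(longest)[keep],
                       total_ns = as.numeric(total)[keep])
  ranked <- ranked[order(-ranked$longest_ns), , drop = FALSE]
  rownames(ranked) <- NULL
  cmap <- attr(events, "contact_map")
  maps <- lapply(ranked$molecule, function(m) {
    sub <- cmap[cmap$molecule == m, c("residue", "frame"), drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(maps) <- ranked$molecule
  list(ranked = ranked, maps = maps)
}

#' Pairwise nonbonded interaction energy between two atom groups
#'
#' Direct-sum cutoff electrostatics (no Ewald) plus Lennard-Jones with
#' Lorentz-Berthelot mixing:
#' elec = sum 332.0636 q_i q_j / r_ij (kcal/mol, charges in e, r in
#' Angstrom); vdw = sum 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6). Pairs with
#' r <= cutoff only; intended as a per-molecule diagnostic of relative
#' energies, not a simulation engine.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param params data frame with per-atom `charge` (e), `sigma` (Angstrom),
#'   `epsilon` (kcal/mol), one row per atom of the system.
#' @param group_a,group_b disjoint atom index sets.
#' @param cutoff interaction cutoff, Angstrom.
#' @param box optional periodic box.
#' @return list elec, vdw (kcal/mol), n_pairs.
#' @export
nonbonded_energy <- function(frame, params, group_a, group_b, cutoff = 9.0,
                             box = NULL) {
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups must be disjoint")
  pd <- pair_distances(frame, group_a, group_b, cutoff, box = box)
  if (nrow(pd) == 0L) return(list(elec = 0, vdw = 0, n_pairs = 0L))
  if (any(pd$distance < 0.1))
    stop("atomic clash: pair distance below 0.1 Angstrom")
  qi <- params$charge[pd$i]; qj <- params$charge[pd$j]
  si <- (params$sigma[pd$i] + params$sigma[pd$j]) / 2
  ei <- sqrt(params$epsilon[pd$i] * params$epsilon[pd$j])
  sr6 <- (si / pd$distance)^6
  list(elec = sum(332.0636 * qi * qj / pd$distance),
       vdw = sum(4 * ei * (sr6^2 - sr6)),
       n_pairs = nrow(pd))
}

#' Mark protein-core residues by relative solvent accessibility
#'
#' Core residues (PC) are those whose native-frame SASA, relative to the
#' residue type's maximum accessibility (Tien et al. theoretical values), is
#' below `threshold`. Complement is the non-core (NPC).
#'
#' @param system a classified `mdsystem`.
#' @param frame native-frame coordinates.
#' @param threshold relative accessibility below which a residue is core.
#' @return the `mdsystem` with `residues$is_core` filled for protein
#'   residues.
#' @export
assign_core <- function(system, frame, threshold = 0.25) {
  areas <- sasa(frame, system)
  part <- sasa_partition(areas, system)
  maxacc <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
  res <- system$residues
  for (k in seq_len(nrow(res))) {
    if (!identical(res$species[k], "protein")) next
    row <- part$per_residue[part$per_residue$residue == res$index[k], ]
    area <- if (nrow(row) == 1L) row$area else 0
    mx <- maxacc[res$name[k]]
    if (is.na(mx)) mx <- 200
    system$residues$is_core[k] <- (area / mx) < threshold
  }
  system
}
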