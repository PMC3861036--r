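#' Specification for a synthetic trajectory
#'
#' Collects every knob of the ground-truth generator. The generator is
#' kinematic, not physical: unfolding and solvent behavior are scripted so
#' the analyses can be validated against exactly known answers. It is not an
#' MD engine and must not be used as one.
#'
#' @param seed RNG seed (recorded in the ground truth).
#' @param dt_ns frame spacing, ns.
#' @param n_frames number of frames.
#' @param protein list: `kind` ("beads", "helix", "hairpin"),
#'   `n_residues`, and `schedule` -- one of
#'   `list(type = "static")`,
#'   `list(type = "telegraph", n_pairs, k_open, k_close, closed_dist,
#'   open_dist)` (two-state Markov native contacts; rates in 1/ns; optional
#'   per-pair rate vectors), or
#'   `list(type = "interpolate", phi_psi_from, phi_psi_to)` (deterministic
#'   dihedral-space unfolding of a helix).
#' @param n_water,n_urea solvent molecule counts.
#' @param box orthorhombic box lengths, Angstrom (required when solvent
#'   present).
#' @param d_water,d_urea diffusion constants, Angstrom^2/ns. Defaults are
#'   deliberately slow "scaled-down solvent" values chosen so shell crossings
#'   are resolved at the default frame spacing.
#' @param solvent_mode "brownian" (random walks, wrapped in the box) or
#'   "equilibrium" (frames drawn independently from the stationary density;
#'   use for shell-composition statistics).
#' @param fss_enrichment urea density multiplier inside the first solvation
#'   shell (1 = no preference).
#' @param sticky list `list(enabled, capture_prob, k_off, targets)`: urea
#'   entering the FSS of a target residue is tethered at contact distance
#'   with probability `capture_prob` until an exponential escape at rate
#'   `k_off` (1/ns), then displaced just outside the shell (jump process).
#' @param long_binder optional `list(molecule, start_frame, n_frames)`
#'   scripting one urea molecule to stay bound for a fixed stretch.
#' @param urea_hydrogens build urea with explicit N-H hydrogens (needed for
#'   hydrogen-bond fixtures).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, dt_ns = 0.1, n_frames = 100,
                           protein = list(kind = "beads", n_residues = 12,
                                          schedule = list(type = "static")),
                           n_water = 0, n_urea = 0, box = NULL,
                           d_water = 1.0, d_urea = 0.5,
                           solvent_mode = c("brownian", "equilibrium"),
                           fss_enrichment = 1.0,
                           sticky = list(enabled = FALSE, capture_prob = 1,
                                         k_off = 1, targets = NULL),
                           long_binder = NULL,
                           urea_hydrogens = FALSE) {
  solvent_mode <- match.arg(solvent_mode)
  stopifnot_scalar_pos(dt_ns, "dt_ns")
  stopifnot_scalar_pos(n_frames, "n_frames")
  if ((n_water > 0 || n_urea > 0) && is.null(box))
    stop("box required when solvent molecules are present")
  if (!is.null(box) && any(box <= 0)) stop("box lengths must be positive")
  structure(list(seed = as.integer(seed), dt_ns = dt_ns,
                 n_frames = as.integer(n_frames), protein = protein,
                 n_water = n_water, n_urea = n_urea, box = box,
                 d_water = d_water, d_urea = d_urea,
                 solvent_mode = solvent_mode,
                 fss_enrichment = fss_enrichment, sticky = sticky,
                 long_binder = long_binder,
                 urea_hydrogens = urea_hydrogens),
            class = "synthetic_spec")
}

#' Brownian (Wiener) position series
#'
#' Per-axis increments are independent normal with standard deviation
#' sqrt(2 D dt); returned coordinates are unwrapped.
#'
#' @param n_molecules number of walkers.
#' @param D diffusion constant, Angstrom^2/ns.
#' @param dt_ns time step, ns.
#' @param n_frames number of frames.
#' @param box optional box used only to draw uniform start positions
#'   (otherwise starts at the origin).
#' @param seed optional RNG seed.
#' @return array n_molecules x 3 x n_frames (unwrapped).
#' @export
brownian_positions <- function(n_molecules, D, dt_ns, n_frames, box = NULL,
                               seed = NULL) {
  if (D < 0 || dt_ns <= 0) stop("D must be >= 0 and dt_ns > 0")
  if (!is.null(seed)) set.seed(seed)
  out <- array(0, dim = c(n_molecules, 3, n_frames))
  start <- if (is.null(box)) matrix(0, n_molecules, 3)
  else cbind(stats::runif(n_molecules, 0, box[1]),
             stats::runif(n_molecules, 0, box[2]),
             stats::runif(n_molecules, 0, box[3]))
  out[, , 1] <- start
  if (n_frames > 1) {
    sdv <- sqrt(2 * D * dt_ns)
    for (f in 2:n_frames) {
      out[, , f] <- out[, , f - 1] +
        matrix(stats::rnorm(3 * n_molecules, sd = sdv), n_molecules, 3)
    }
  }
  out
}

# exact two-state Markov (telegraph) sampling on the frame grid; state TRUE =
# closed. Returns list(states = logical n_frames, events = data frame).
telegraph_states <- function(k_open, k_close, n_frames, dt,
                             p_init = k_close / (k_open + k_close)) {
  t_end <- n_frames * dt
  state <- stats::runif(1) < p_init
  t <- 0
  jumps_t <- numeric(0)
  jumps_s <- logical(0)
  s <- state
  while (t < t_end) {
    rate <- if (s) k_open else k_close
    t <- t + stats::rexp(1, rate)
    if (t >= t_end) break
    s <- !s
    jumps_t <- c(jumps_t, t)
    jumps_s <- c(jumps_s, s)
  }
  times <- (seq_len(n_frames) - 1) * dt
  states <- rep(state, n_frames)
  if (length(jumps_t) > 0) {
    idx <- findInterval(times, jumps_t)
    states <- ifelse(idx == 0, state, jumps_s[pmax(idx, 1)])
  }
  list(states = states, n_jumps = length(jumps_t))
}

# Water: one heavy O + 2 H. Urea: four heavy pseudo-atoms. By default the
# urea heavy offsets are compact (scaled well below chemical bond lengths) so
# that the *molecule-level* first-shell volume of urea matches that of the
# single-point water -- otherwise a size artifact alone shifts the FSS
# water/urea ratio even with no preference (the null calibration, FSS = bulk
# at enrichment 1, requires matched shell volumes). With explicit hydrogens
# (H-bond fixtures) chemically realistic planar urea geometry is used
# instead.
solvent_templates <- function(urea_hydrogens = FALSE) {
  water <- rbind(O = c(0, 0, 0),
                 H1 = c(0.9572, 0, 0),
                 H2 = c(-0.2399, 0.9266, 0))
  if (urea_hydrogens) {
    urea <- rbind(C = c(0, 0, 0),
                  O = c(0, 1.23, 0),
                  N1 = c(1.161, -0.67, 0),
                  N2 = c(-1.161, -0.67, 0),
                  H11 = c(2.024, -0.157, 0), H12 = c(1.18, -1.676, 0),
                  H21 = c(-2.024, -0.157, 0), H22 = c(-1.18, -1.676, 0))
  } else {
    s <- 0.10
    urea <- rbind(C = c(0, 0, 0),
                  O = c(0, 1.23, 0) * s,
                  N1 = c(1.161, -0.67, 0) * s,
                  N2 = c(-1.161, -0.67, 0) * s)
  }
  list(water = water, urea = urea)
}

#' Generate a synthetic trajectory with exact ground truth
#'
#' Realizes a [synthetic_spec()]: a toy protein whose native contacts open
#' and close on telegraph schedules (or whose backbone unfolds by dihedral
#' interpolation), plus Brownian water and urea pseudo-molecules with
#' optional first-shell urea enrichment and sticky-urea capture/escape
#' kinetics. Everything random is driven by the spec seed, so output is
#' bit-reproducible.
#'
#' @param spec a `synthetic_spec`.
#' @param dir optional output directory; when given, writes
#'   `trajectory.pdb` (multi-model), `ground_truth.json` and `spec.yaml`.
#' @return list with `system` (classified `mdsystem`), `traj` (`mdtraj`),
#'   `truth` (ground-truth list), and `files` (paths, when written).
#' @export
synthesize_trajectory <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames
  dt <- spec$dt_ns
  truth <- list(seed = spec$seed, dt_ns = dt, n_frames = nf)

  ## ---- protein part ----------------------------------------------------
  sched <- spec$protein$schedule %||% list(type = "static")
  prot_frames <- NULL  # n_atoms x 3 x nf, or NULL when static
  if (identical(sched$type, "telegraph")) {
    np <- sched$n_pairs %||% 8L
    built <- telegraph_protein(np)
    psys <- built$system
    pframe <- built$frame
    k_open <- rep_len(sched$k_open %||% 1, np)
    k_close <- rep_len(sched$k_close %||% 1, np)
    closed_d <- sched$closed_dist %||% 3.0
    open_d <- sched$open_dist %||% 8.0
    states <- matrix(NA, nrow = np, ncol = nf)
    for (p in seq_len(np)) {
      states[p, ] <- telegraph_states(k_open[p], k_close[p], nf, dt)$states
    }
    prot_frames <- array(rep(pframe, nf), dim = c(nrow(pframe), 3, nf))
    for (p in seq_len(np)) {
      # the mobile bead of pair p slides along x: closed_d when closed,
      # open_d when open
      i_mobile <- built$pairs$atom_j[p]
      x0 <- pframe[built$pairs$atom_i[p], 1]
      prot_frames[i_mobile, 1, ] <- x0 + ifelse(states[p, ], closed_d, open_d)
    }
    truth$schedule <- list(
      type = "telegraph",
      pairs = data.frame(res_i = built$pairs$res_i,
                         res_j = built$pairs$res_j,
                         k_open = k_open, k_close = k_close),
      closed_fraction = rowMeans(states),
      states = states)
  } else if (identical(sched$type, "interpolate")) {
    nres <- spec$protein$n_residues %||% 16L
    from <- sched$phi_psi_from %||% c(-57, -47)
    # default unfolding path runs through the beta/PPII quadrant towards the
    # fully extended chain; the (+180, +180) representation of the same
    # endpoint would pass through the compact left-handed helix region
    to <- sched$phi_psi_to %||% c(-180, -180)
    built <- build_toy_protein("helix", nres)
    psys <- built$system
    pframe <- built$frame
    prot_frames <- array(NA_real_, dim = c(nrow(pframe), 3, nf))
    for (f in seq_len(nf)) {
      w <- (f - 1) / max(1, nf - 1)
      ph <- from[1] + w * (to[1] - from[1])
      ps <- from[2] + w * (to[2] - from[2])
      bb <- build_backbone(rep(ph, nres), rep(ps, nres))
      prot_frames[, , f] <- residues_to_system(bb)$frame
    }
    truth$schedule <- list(type = "interpolate", from = from, to = to)
  } else {
    kind <- spec$protein$kind %||% "beads"
    nres <- spec$protein$n_residues %||% 12L
    built <- if (identical(kind, "cluster")) bead_cluster(nres)
    else build_toy_protein(kind, nres)
    psys <- built$system
    pframe <- built$frame
    truth$schedule <- list(type = "static")
  }
  truth$native_ss <- tryCatch(
    unname(assign_ss(pframe, psys)), warning = function(w) NULL,
    error = function(e) NULL)

  ## ---- solvent part ----------------------------------------------------
  tmpl <- solvent_templates(spec$urea_hydrogens)
  n_sol <- spec$n_water + spec$n_urea
  sol_atoms <- NULL
  sol_frames <- NULL
  if (n_sol > 0) {
    box <- spec$box
    if (n_sol * 10 > prod(box))
      stop("box too small for requested solvent count")
    center_shift <- box / 2 - colMeans(pframe[psys$atoms$is_heavy, ,
                                              drop = FALSE])
    pframe <- sweep(pframe, 2, center_shift, "+")
    if (!is.null(prot_frames)) {
      for (f in seq_len(nf))
        prot_frames[, , f] <- sweep(prot_frames[, , f], 2, center_shift, "+")
    }
    prot_heavy_xyz <- pframe[psys$atoms$is_heavy, , drop = FALSE]
    sol <- simulate_solvent(spec, psys, pframe, prot_heavy_xyz, tmpl)
    sol_atoms <- sol$atoms
    sol_frames <- sol$frames
    truth$residence_log <- sol$residence_log
    truth$d_water <- spec$d_water
    truth$d_urea <- spec$d_urea
    truth$fss_enrichment <- spec$fss_enrichment
  }

  ## ---- assemble system + trajectory ------------------------------------
  atoms <- psys$atoms
  atoms$x <- pframe[, 1]; atoms$y <- pframe[, 2]; atoms$z <- pframe[, 3]
  if (!is.null(sol_atoms)) atoms <- rbind(atoms, sol_atoms)
  assembled <- build_system_from_atoms(atoms)
  sys <- assembled$system
  nat <- nrow(sys$atoms)
  coords <- array(NA_real_, dim = c(nat, 3, nf))
  npa <- nrow(psys$atoms)
  for (f in seq_len(nf)) {
    coords[seq_len(npa), , f] <- if (is.null(prot_frames)) pframe
    else prot_frames[, , f]
    if (!is.null(sol_frames)) coords[(npa + 1):nat, , f] <- sol_frames[, , f]
  }
  traj <- new_mdtraj(coords, times = (seq_len(nf) - 1) * dt,
                     box = if (n_sol > 0) spec$box else NULL)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pdb <- file.path(dir, "trajectory.pdb")
    gt <- file.path(dir, "ground_truth.json")
    sy <- file.path(dir, "spec.yaml")
    write_trajectory_pdb(sys, traj, pdb)
    tr <- truth
    if (!is.null(tr$schedule$states)) {
      tr$schedule$states <- apply(tr$schedule$states, 1, function(s)
        paste(as.integer(s), collapse = ""))
    }
    jsonlite::write_json(tr, gt, auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(unclass(spec), sy)
    files <- list(trajectory = pdb, ground_truth = gt, spec = sy)
  }
  list(system = sys, traj = traj, truth = truth, files = files)
}

# bead protein dedicated to telegraph contacts: pair p occupies residues
# (4p-3, 4p) (|i-j| = 3, the minimum counted separation), each pair in its
# own spatial cluster 25 A from the next, spacers parked out of contact range
telegraph_protein <- function(n_pairs) {
  n <- 4L * n_pairs
  rows <- list()
  pairs <- data.frame(res_i = integer(0), res_j = integer(0),
                      atom_i = integer(0), atom_j = integer(0))
  for (p in seq_len(n_pairs)) {
    ox <- ((p - 1) %% 4) * 25
    oy <- ((p - 1) %/% 4) * 25
    r0 <- 4L * (p - 1L)
    pos <- rbind(c(ox, oy, 0),            # res 4p-3 (anchor)
                 c(ox, oy + 10, 0),       # spacer
                 c(ox, oy - 10, 0),       # spacer
                 c(ox + 3.0, oy, 0))      # res 4p (mobile)
    for (k in 1:4) {
      rows[[r0 + k]] <- data.frame(
        serial = r0 + k, name = "CA", element = "C", is_heavy = TRUE,
        residue_index = r0 + k, residue_name = "ALA", chain = "A",
        role = NA_character_, x = pos[k, 1], y = pos[k, 2], z = pos[k, 3],
        stringsAsFactors = FALSE)
    }
    pairs <- rbind(pairs, data.frame(res_i = r0 + 1L, res_j = r0 + 4L,
                                     atom_i = r0 + 1L, atom_j = r0 + 4L))
  }
  built <- build_system_from_atoms(do.call(rbind, rows))
  built$pairs <- pairs
  built
}

# compact 3x3x3 bead cluster used as a generic solute for solvation fixtures
bead_cluster <- function(n_residues = 27L, spacing = 3.8) {
  k <- ceiling(n_residues^(1 / 3))
  grid <- as.matrix(expand.grid(seq_len(k), seq_len(k), seq_len(k)))
  grid <- grid[seq_len(n_residues), , drop = FALSE] * spacing
  rows <- lapply(seq_len(n_residues), function(i) {
    data.frame(serial = i, name = "CA", element = "C", is_heavy = TRUE,
               residue_index = i, residue_name = "ALA", chain = "A",
               role = NA_character_,
               x = grid[i, 1], y = grid[i, 2], z = grid[i, 3],
               stringsAsFactors = FALSE)
  })
  build_system_from_atoms(do.call(rbind, rows))
}

# solvent simulation: returns atom table, frames array, residence log
simulate_solvent <- function(spec, psys, pframe, prot_xyz, tmpl) {
  box <- spec$box
  nf <- spec$n_frames
  dt <- spec$dt_ns
  n_w <- spec$n_water
  n_u <- spec$n_urea
  n_res_prot <- nrow(psys$residues)

  # FSS indicator for a molecule center given its heavy-atom template
  heavy_w <- which(!grepl("^H", rownames(tmpl$water)))
  heavy_u <- which(!grepl("^H", rownames(tmpl$urea)))
  fss_indicator <- function(centers, template_heavy, target_xyz,
                            cutoff = 5.0) {
    # centers: n x 3; TRUE when any template heavy atom is within cutoff of
    # any target atom (minimum image)
    n <- nrow(centers)
    out <- rep(FALSE, n)
    for (t in seq_len(nrow(template_heavy))) {
      pts <- sweep(centers, 2, template_heavy[t, ], "+")
      pd <- pairs_dense(rbind(pts, target_xyz),
                        seq_len(n), n + seq_len(nrow(target_xyz)),
                        cutoff, box)
      out[unique(pd$i)] <- TRUE
      if (all(out)) break
    }
    out
  }

  orient <- function(n) lapply(seq_len(n), function(i) random_rotation())
  rot_w <- orient(n_w)
  rot_u <- orient(n_u)

  draw_uniform <- function(n) {
    cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
          stats::runif(n, 0, box[3]))
  }
  # rejection-sample centers from the stationary density (urea: weight f in
  # the FSS)
  draw_equilibrium <- function(n, template_heavy, f) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      cand <- draw_uniform(2 * (n - nrow(out)) + 8)
      if (f > 1) {
        ins <- fss_indicator(cand, template_heavy, prot_xyz)
        keep <- ins | (stats::runif(nrow(cand)) < 1 / f)
        cand <- cand[keep, , drop = FALSE]
      }
      out <- rbind(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  }
  # initial placement: avoid protein overlap (< 2.5 A from protein atoms)
  place_initial <- function(n, template_heavy, f) {
    out <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(out) < n) {
      tries <- tries + 1
      if (tries > 200) stop("box too small for requested solvent count")
      cand <- draw_equilibrium(n - nrow(out), template_heavy, f)
      pd <- pairs_dense(rbind(cand, prot_xyz), seq_len(nrow(cand)),
                        nrow(cand) + seq_len(nrow(prot_xyz)), 2.5, box)
      ok <- !(seq_len(nrow(cand)) %in% pd$i)
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }

  cw <- if (n_w > 0) place_initial(n_w, tmpl$water[heavy_w, , drop = FALSE], 1)
  else matrix(0, 0, 3)
  cu <- if (n_u > 0) place_initial(n_u, tmpl$urea[heavy_u, , drop = FALSE],
                                   spec$fss_enrichment)
  else matrix(0, 0, 3)

  sticky <- spec$sticky %||% list(enabled = FALSE)
  sticky_on <- isTRUE(sticky$enabled)
  k_off <- sticky$k_off %||% 1
  p_cap <- sticky$capture_prob %||% 1
  targets <- sticky$targets %||% psys$residues$index
  tgt_xyz <- pframe[psys$atoms$residue_index %in% targets &
                      psys$atoms$is_heavy, , drop = FALSE]

  prot_center <- colMeans(prot_xyz)
  bound_until <- rep(0L, n_u)      # frame until which molecule is tethered
  tether_pos <- matrix(NA_real_, n_u, 3)
  res_log <- list()
  log_start <- rep(NA_integer_, n_u)

  lb <- spec$long_binder
  sdw <- sqrt(2 * spec$d_water * dt)
  sdu <- sqrt(2 * spec$d_urea * dt)
  f_enr <- spec$fss_enrichment
  tmpl_uh <- tmpl$urea[heavy_u, , drop = FALSE]

  wrap <- function(x) x - floor(sweep(x, 2, box, "/")) * rep(box,
                                                             each = nrow(x))

  nw_at <- nrow(tmpl$water)
  nu_at <- nrow(tmpl$urea)
  n_atoms_sol <- n_w * nw_at + n_u * nu_at
  frames <- array(NA_real_, dim = c(n_atoms_sol, 3, nf))
  stack_w <- if (n_w > 0)
    do.call(rbind, lapply(rot_w, function(r) tmpl$water %*% t(r)))
  stack_u <- if (n_u > 0)
    do.call(rbind, lapply(rot_u, function(r) tmpl$urea %*% t(r)))

  new_tether <- function() {
    for (try in 1:50) {
      ti <- sample(nrow(tgt_xyz), 1)
      dir <- unit(stats::rnorm(3))
      pos <- tgt_xyz[ti, ] + 2.9 * dir
      dmin <- min(sqrt(rowSums(sweep(prot_xyz, 2, pos)^2)))
      if (dmin > 2.0) return(list(pos = pos, anchor = ti, dir = dir))
    }
    list(pos = tgt_xyz[1, ] + c(2.9, 0, 0), anchor = 1L, dir = c(1, 0, 0))
  }

  for (f in seq_len(nf)) {
    if (f > 1) {
      if (spec$solvent_mode == "equilibrium") {
        if (n_w > 0) cw <- draw_equilibrium(n_w,
                                            tmpl$water[heavy_w, , drop = FALSE],
                                            1)
        if (n_u > 0) cu <- draw_equilibrium(n_u, tmpl_uh, f_enr)
      } else {
        if (n_w > 0)
          cw <- wrap(cw + matrix(stats::rnorm(3 * n_w, sd = sdw), n_w, 3))
        if (n_u > 0) {
          prop <- wrap(cu + matrix(stats::rnorm(3 * n_u, sd = sdu), n_u, 3))
          if (f_enr > 1 && !sticky_on) {
            # Metropolis step targeting density f inside the FSS
            ins_old <- fss_indicator(cu, tmpl_uh, prot_xyz)
            ins_new <- fss_indicator(prop, tmpl_uh, prot_xyz)
            acc_p <- f_enr^(as.numeric(ins_new) - as.numeric(ins_old))
            acc <- stats::runif(n_u) < pmin(1, acc_p)
            cu[acc, ] <- prop[acc, , drop = FALSE]
          } else {
            free <- bound_until < f
            cu[free, ] <- prop[free, , drop = FALSE]
          }
        }
      }
    }

    if (sticky_on && n_u > 0) {
      # scripted long binder starts its window
      if (!is.null(lb) && f == lb$start_frame &&
          bound_until[lb$molecule] < f) {
        m <- lb$molecule
        th <- new_tether()
        tether_pos[m, ] <- th$pos
        bound_until[m] <- lb$start_frame + lb$n_frames - 1L
        log_start[m] <- f
      }
      bound <- which(bound_until >= f)
      for (m in bound) {
        cu[m, ] <- tether_pos[m, ] + stats::rnorm(3, sd = 0.05)
      }
      # molecules whose dwell ended between the previous frame and this one:
      # jump to just outside the protein's first shell (so the event ends and
      # re-binding requires diffusing back in); no capture test this frame
      released <- which(bound_until == f - 1L & !is.na(log_start))
      for (m in released) {
        res_log[[length(res_log) + 1L]] <-
          data.frame(molecule = m, start_frame = log_start[m],
                     end_frame = bound_until[m])
        log_start[m] <- NA_integer_
        dir <- unit(tether_pos[m, ] - prot_center)
        pos <- tether_pos[m, ]
        for (r in seq(3, 20, by = 1)) {
          cand <- tether_pos[m, ] + r * dir
          dmin <- min(sqrt(rowSums(sweep(prot_xyz, 2, cand)^2)))
          pos <- cand
          if (dmin > 5.8) break
        }
        cu[m, ] <- wrap(matrix(pos, 1, 3))
      }
      # free molecules: capture test on FSS entry
      free <- which(bound_until < f & !(seq_len(n_u) %in% released))
      if (length(free) > 0) {
        ins <- fss_indicator(cu[free, , drop = FALSE], tmpl_uh, prot_xyz)
        hits <- free[ins & stats::runif(length(free)) < p_cap]
        for (m in hits) {
          th <- new_tether()
          tether_pos[m, ] <- th$pos
          dwell <- stats::rexp(1, k_off)
          bound_until[m] <- f + max(1L, as.integer(round(dwell / dt))) - 1L
          log_start[m] <- f
          cu[m, ] <- tether_pos[m, ] + stats::rnorm(3, sd = 0.05)
        }
      }
    }

    # realize atoms (pre-rotated templates + per-molecule centers)
    if (n_w > 0) {
      frames[seq_len(n_w * nw_at), , f] <-
        stack_w + cw[rep(seq_len(n_w), each = nw_at), , drop = FALSE]
    }
    if (n_u > 0) {
      frames[n_w * nw_at + seq_len(n_u * nu_at), , f] <-
        stack_u + cu[rep(seq_len(n_u), each = nu_at), , drop = FALSE]
    }
  }
  # close out tethers still bound at the end
  if (sticky_on && n_u > 0) {
    for (m in seq_len(n_u)) {
      if (!is.na(log_start[m]) && bound_until[m] >= nf) {
        res_log[[length(res_log) + 1L]] <-
          data.frame(molecule = m, start_frame = log_start[m],
                     end_frame = nf)
      }
    }
  }

  # atom table
  serial0 <- nrow(psys$atoms)
  res0 <- n_res_prot
  rows <- list()
  ridx <- res0
  srl <- serial0
  add_mol <- function(tm, resname) {
    ridx <<- ridx + 1L
    out <- data.frame(
      serial = srl + seq_len(nrow(tm)), name = rownames(tm),
      element = ifelse(grepl("^H", rownames(tm)), "H",
                       substr(rownames(tm), 1, 1)),
      is_heavy = !grepl("^H", rownames(tm)),
      residue_index = ridx, residue_name = resname, chain = "S",
      role = NA_character_, x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
    srl <<- srl + nrow(tm)
    out
  }
  for (m in seq_len(n_w)) rows[[length(rows) + 1L]] <- add_mol(tmpl$water,
                                                               "HOH")
  for (m in seq_len(n_u)) rows[[length(rows) + 1L]] <- add_mol(tmpl$urea,
                                                               "URE")
  atoms <- if (length(rows) > 0) do.call(rbind, rows) else NULL

  log_df <- if (length(res_log) > 0) do.call(rbind, res_log)
  else data.frame(molecule = integer(0), start_frame = integer(0),
                  end_frame = integer(0))
  if (nrow(log_df) > 0) {
    # molecule ids -> residue indices in the assembled system
    log_df$residue_index <- res0 + n_w + log_df$molecule
    log_df$duration_ns <- (log_df$end_frame - log_df$start_frame + 1) * dt
  }
  list(atoms = atoms, frames = frames, residence_log = log_df)
}
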