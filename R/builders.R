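# Ideal backbone geometry (Engh-Huber-style values) used by the toy-protein
# builders.
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, omega = 180)

# Build backbone coordinates (N, CA, C, O, CB per residue) from phi/psi
# vectors; poly-ALA. Returns list of per-residue named coordinate lists.
build_backbone <- function(phi, psi, with_cb = TRUE) {
  g <- BB_GEOM
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  res <- vector("list", n)
  # first residue in a canonical pose
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  ang <- deg2rad(g$ang_n_ca_c)
  C1 <- CA1 + g$ca_c * c(-cos(ang), sin(ang), 0)
  res[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    prev <- res[[i - 1]]
    Ni <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n,
                     psi[i - 1])
    CAi <- place_atom(prev$CA, prev$C, Ni, g$n_ca, g$ang_c_n_ca, g$omega)
    Ci <- place_atom(prev$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i])
    res[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    psi_i <- if (i < n) psi[i] else 140  # last residue: arbitrary psi
    r$O <- place_atom(r$N, r$CA, r$C, g$c_o, g$ang_ca_c_o, psi_i + 180)
    if (with_cb) {
      u1 <- unit(r$N - r$CA)
      u2 <- unit(r$C - r$CA)
      b <- unit(-(u1 + u2))
      nv <- unit(cross3(u1, u2))
      cosang <- cos(deg2rad(109.5))
      alpha <- cosang / sum(b * u1)
      beta <- sqrt(max(0, 1 - alpha^2))
      r$CB <- r$CA + 1.53 * (alpha * b + beta * nv)
    }
    res[[i]] <- r
  }
  res
}

residues_to_system <- function(res_list, resname = "ALA",
                               start_index = 1L) {
  rows <- list()
  serial <- 0L
  for (i in seq_along(res_list)) {
    for (nm in names(res_list[[i]])) {
      serial <- serial + 1L
      p <- res_list[[i]][[nm]]
      el <- substr(nm, 1, 1)
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, element = el,
        is_heavy = !el %in% c("H", "D"),
        residue_index = start_index + i - 1L,
        residue_name = resname, chain = "A", role = NA_character_,
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  build_system_from_atoms(atoms)
}

#' Assemble a molecular system from an atom table
#'
#' Low-level constructor used by the fixtures and the generator: takes a data
#' frame with columns serial, name, element, is_heavy, residue_index,
#' residue_name, chain, role, x, y, z and returns the classified system plus
#' the coordinate frame.
#'
#' @param atoms atom data frame as described above.
#' @return list with `system` (classified `mdsystem`) and `frame`
#'   (n_atoms x 3 matrix).
#' @export
build_system_from_atoms <- function(atoms) {
  first <- !duplicated(atoms$residue_index)
  residues <- data.frame(
    index = atoms$residue_index[first],
    name = atoms$residue_name[first],
    chain = atoms$chain[first],
    species = NA_character_, polarity_class = NA_character_, is_core = NA,
    stringsAsFactors = FALSE)
  frame <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(frame) <- NULL
  sys <- new_mdsystem(atoms[, setdiff(names(atoms), c("x", "y", "z"))],
                      residues)
  sys <- classify_system(sys)
  list(system = sys, frame = frame)
}

#' Build an idealized toy protein
#'
#' Fixtures with known structure for exercising the analysis stages without
#' an MD engine: an alpha helix from ideal internal geometry
#' (phi = -57, psi = -47), a two-strand antiparallel hairpin with ideal beta
#' dihedrals (phi = -139, psi = 135), a 4-residue turn and rigid-body
#' placement of the second strand refined so the cross-strand H-bond rungs
#' sit at 2.9 Angstrom, or a CA-only bead chain. Backbone atoms N, CA, C, O
#' and CB are built (beads: CA only).
#'
#' @param kind "helix", "hairpin" or "beads".
#' @param n_residues chain length (>= 6; hairpin needs >= 14).
#' @return list with `system` (classified `mdsystem`) and `frame` (native
#'   coordinates).
#' @export
build_toy_protein <- function(kind = c("helix", "hairpin", "beads"),
                              n_residues = 12) {
  kind <- match.arg(kind)
  if (n_residues < 6) stop("n_residues must be >= 6")
  switch(kind,
         helix = build_helix(n_residues),
         hairpin = build_hairpin(n_residues),
         beads = build_beads(n_residues))
}

build_helix <- function(n, phi = -57, psi = -47) {
  res <- build_backbone(rep(phi, n), rep(psi, n))
  residues_to_system(res)
}

build_beads <- function(n, spacing = 3.8) {
  rows <- lapply(seq_len(n), function(i) {
    data.frame(serial = i, name = "CA", element = "C", is_heavy = TRUE,
               residue_index = i, residue_name = "ALA", chain = "A",
               role = NA_character_,
               x = (i - 1) * spacing, y = 0, z = 0, stringsAsFactors = FALSE)
  })
  build_system_from_atoms(do.call(rbind, rows))
}

build_hairpin <- function(n) {
  if (n < 14) stop("hairpin needs at least 14 residues")
  ns <- (n - 4L) %/% 2L
  n <- 2L * ns + 4L
  beta_phi <- -139; beta_psi <- 135
  strand_a <- build_backbone(rep(beta_phi, ns), rep(beta_psi, ns))
  strand_b <- build_backbone(rep(beta_phi, ns), rep(beta_psi, ns))

  flatten <- function(rl) {
    do.call(rbind, lapply(rl, function(r) do.call(rbind, r)))
  }
  names_of <- function(rl) unlist(lapply(rl, names))
  resid_of <- function(rl) rep(seq_along(rl), vapply(rl, length, integer(1)))

  xa <- flatten(strand_a)
  xb <- flatten(strand_b)
  # chain residue i (strand A) pairs with chain residue n + 1 - i (strand B);
  # built strand-B residue k maps to chain position ns + 4 + k, so B residue
  # k pairs with A residue ns + 1 - k. Initial guess: 180 deg flip about z
  # (reverses the strand direction), shifted alongside strand A.
  axis_len <- max(xa[, 1]) - min(xa[, 1])
  init <- c(0, 0, pi, axis_len + 2.5, 4.8, 0)
  rot_euler <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  namev <- names_of(strand_a)
  resv <- resid_of(strand_a)
  atom_xyz <- function(x, resid, nm) x[which(resv == resid & namev == nm), ]

  # H-bonded rungs: every second pair starting nearest the turn
  rung_a <- seq(ns, 2, by = -2)
  score <- function(p) {
    xb2 <- xb %*% t(rot_euler(p[1:3]))
    xb2 <- sweep(xb2, 2, p[4:6], "+")
    s <- 0
    for (ia in rung_a) {
      kb <- ns + 1L - ia
      if (kb < 1L || kb > ns) next
      oa <- atom_xyz(xa, ia, "O"); nb <- atom_xyz(xb2, kb, "N")
      ob <- atom_xyz(xb2, kb, "O"); na_ <- atom_xyz(xa, ia, "N")
      s <- s + (vnorm(oa - nb) - 2.9)^2 + (vnorm(ob - na_) - 2.9)^2
    }
    # keep register: all CA pairs near 5.0 A, and avoid steric overlap
    for (ia in seq_len(ns)) {
      kb <- ns + 1L - ia
      d <- vnorm(atom_xyz(xa, ia, "CA") - atom_xyz(xb2, kb, "CA"))
      s <- s + 0.1 * (d - 5.0)^2
    }
    s
  }
  opt <- stats::optim(init, score, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  opt <- stats::optim(opt$par, score, method = "BFGS",
                      control = list(maxit = 500))
  xb_fit <- sweep(xb %*% t(rot_euler(opt$par[1:3])), 2, opt$par[4:6], "+")

  # reassemble: strand A (chain 1..ns), turn (ns+1..ns+4), strand B reversed
  # in chain order (built residue k -> chain ns + 4 + k)
  to_list <- function(x) {
    out <- vector("list", ns)
    for (i in seq_len(ns)) {
      nm <- namev[resv == i]
      out[[i]] <- stats::setNames(
        lapply(which(resv == i), function(r) x[r, ]), nm)
    }
    out
  }
  la <- to_list(xa)
  lb <- to_list(xb_fit)

  # turn: arc between C-terminus of A (residue ns) and N-terminus of B
  # (built residue 1); labelled C by construction, geometry only plausible
  p0 <- la[[ns]]$CA
  p1 <- lb[[1]]$CA
  mid <- (p0 + p1) / 2 + c(6, 0, 2)
  turn <- vector("list", 4)
  for (k in 1:4) {
    t1 <- k / 5
    ca <- (1 - t1)^2 * p0 + 2 * (1 - t1) * t1 * mid + t1^2 * p1
    turn[[k]] <- list(N = ca + c(-0.8, 0.9, 0.3), CA = ca,
                      C = ca + c(0.8, 0.9, -0.3), O = ca + c(0.9, 1.9, -0.4),
                      CB = ca + c(0, -1.2, 0.9))
  }
  residues_to_system(c(la, turn, lb))
}
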