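# Independent brute-force oracles. Deliberately written as plain double loops
# so they share no code path with the package implementations they check.

brute_pairs <- function(frame, set_a, set_b, cutoff, box = NULL) {
  res <- list()
  for (i in set_a) {
    for (j in set_b) {
      if (i == j) next
      d <- frame[i, ] - frame[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      dist <- sqrt(sum(d * d))
      if (dist < cutoff) res[[length(res) + 1]] <- c(i, j, dist)
    }
  }
  if (length(res) == 0)
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  m <- do.call(rbind, res)
  same <- length(set_a) == length(set_b) && all(set_a == set_b)
  out <- data.frame(i = m[, 1], j = m[, 2], distance = m[, 3])
  if (same) out <- out[out$i < out$j, ]
  out[order(out$i, out$j), ]
}

brute_residue_contacts <- function(frame, system, cutoff, min_seq_sep = 3) {
  res <- system$residues$index[system$residues$species == "protein"]
  hits <- list()
  for (ai in seq_along(res)) {
    for (bi in seq_along(res)) {
      i <- res[ai]; j <- res[bi]
      if (j - i < min_seq_sep) next
      ii <- which(system$atoms$residue_index == i & system$atoms$is_heavy)
      jj <- which(system$atoms$residue_index == j & system$atoms$is_heavy)
      found <- FALSE
      for (x in ii) for (y in jj) {
        if (sqrt(sum((frame[x, ] - frame[y, ])^2)) < cutoff) found <- TRUE
      }
      if (found) hits[[length(hits) + 1]] <- c(i, j)
    }
  }
  if (length(hits) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, hits)
}

brute_hbonds <- function(frame, system, dist_cutoff = 3.5,
                         angle_cutoff = 120) {
  # donors: N/O with an attached H in the file (no reconstruction, so only
  # use on systems with explicit hydrogens)
  a <- system$atoms
  found <- list()
  for (d in which(a$element %in% c("N", "O"))) {
    hs <- which(!a$is_heavy & a$residue_index == a$residue_index[d])
    hs <- hs[vapply(hs, function(h)
      sqrt(sum((frame[h, ] - frame[d, ])^2)) < 1.25, logical(1))]
    for (h in hs) {
      for (acc in which(a$element == "O" |
                        (a$element == "N" & a$residue_name == "HIS" &
                         a$name %in% c("ND1", "NE2")))) {
        if (acc == d) next
        if (a$residue_index[acc] == a$residue_index[d]) next
        dda <- sqrt(sum((frame[d, ] - frame[acc, ])^2))
        if (dda > dist_cutoff) next
        v1 <- frame[d, ] - frame[h, ]
        v2 <- frame[acc, ] - frame[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= angle_cutoff)
          found[[length(found) + 1]] <- c(d, h, acc)
      }
    }
  }
  if (length(found) == 0) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, found)
}

# random solvated toy system with explicit-H water around a short helix
random_water_system <- function(n_water = 8, seed = 1, spread = 12) {
  set.seed(seed)
  hx <- build_toy_protein("helix", 6)
  at <- hx$system$atoms
  at$x <- hx$frame[, 1]; at$y <- hx$frame[, 2]; at$z <- hx$frame[, 3]
  ctr <- colMeans(hx$frame)
  rows <- list()
  serial <- max(at$serial)
  for (m in seq_len(n_water)) {
    c0 <- ctr + runif(3, -spread, spread)
    rot <- ureatraj:::random_rotation()
    tmpl <- rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2399, 0.9266, 0))
    pos <- sweep(tmpl %*% t(rot), 2, c0, "+")
    rows[[m]] <- data.frame(
      serial = serial + 3 * (m - 1) + 1:3,
      name = c("O", "H1", "H2"), element = c("O", "H", "H"),
      is_heavy = c(TRUE, FALSE, FALSE),
      residue_index = 6 + m, residue_name = "HOH", chain = "S",
      role = NA_character_,
      x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
  }
  build_system_from_atoms(rbind(at, do.call(rbind, rows)))
}

# constant-coordinate trajectory from a single frame
static_traj <- function(frame, n = 5, dt = 0.1) {
  coords <- array(rep(as.matrix(frame), n),
                  dim = c(nrow(frame), 3, n))
  ureatraj:::new_mdtraj(coords, times = (seq_len(n) - 1) * dt)
}

# trajectory from a list of frames
traj_from_frames <- function(frames, dt = 0.1, box = NULL) {
  n <- length(frames)
  coords <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, n))
  for (f in seq_len(n)) coords[, , f] <- as.matrix(frames[[f]])
  ureatraj:::new_mdtraj(coords, times = (seq_len(n) - 1) * dt, box = box)
}

# timeline object built directly from a presence matrix (for kinetics units)
timeline_from_presence <- function(presence, pairs, dt = 0.1) {
  structure(list(contacts = pairs, presence = presence, dt = dt,
                 times = (seq_len(ncol(presence)) - 1) * dt),
            class = "contact_timeline")
}
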