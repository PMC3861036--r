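#' All atom pairs within a distance cutoff
#'
#' Exact neighbor search between two atom index sets in one frame. With a box,
#' distances use the minimum-image convention for orthorhombic cells. Two
#' methods are available and return identical pair sets: a dense vectorized
#' distance matrix (good for small sets) and a cell-list spatial grid (linear
#' scaling for large sets); `"auto"` picks by problem size.
#'
#' When `set_a` and `set_b` are identical, each unordered pair is returned
#' once with `i < j`; otherwise `i` indexes `set_a` and `j` indexes `set_b`
#' (self pairs dropped).
#'
#' @param frame n_atoms x 3 coordinate matrix (Angstrom).
#' @param set_a,set_b integer atom index vectors.
#' @param cutoff distance cutoff in Angstrom (strictly-less-than criterion).
#' @param box optional length-3 orthorhombic box (Angstrom).
#' @param method "auto", "dense" or "grid".
#' @return data frame with columns `i`, `j`, `distance`.
#' @export
pair_distances <- function(frame, set_a, set_b, cutoff, box = NULL,
                           method = c("auto", "dense", "grid")) {
  method <- match.arg(method)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number")
  if (length(set_a) == 0L || length(set_b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  if (max(set_a, set_b) > nrow(frame) || min(set_a, set_b) < 1L)
    stop("atom index out of range")
  same <- length(set_a) == length(set_b) && all(set_a == set_b)
  if (method == "auto") {
    method <- if (as.double(length(set_a)) * length(set_b) <= 4e6)
      "dense" else "grid"
  }
  out <- if (method == "dense") {
    pairs_dense(frame, set_a, set_b, cutoff, box)
  } else {
    pairs_grid(frame, set_a, set_b, cutoff, box)
  }
  if (same) {
    keep <- out$i < out$j
    out <- out[keep, , drop = FALSE]
  } else {
    out <- out[out$i != out$j, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

min_image_delta <- function(d, box_len) d - box_len * round(d / box_len)

pairs_dense <- function(frame, set_a, set_b, cutoff, box) {
  xa <- frame[set_a, , drop = FALSE]
  xb <- frame[set_b, , drop = FALSE]
  d2 <- matrix(0, nrow(xa), nrow(xb))
  for (dim_i in 1:3) {
    dd <- outer(xa[, dim_i], xb[, dim_i], "-")
    if (!is.null(box)) dd <- min_image_delta(dd, box[dim_i])
    d2 <- d2 + dd * dd
  }
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  data.frame(i = set_a[hit[, 1]], j = set_b[hit[, 2]],
             distance = sqrt(d2[hit]))
}

# Cell-list neighbor search. Cells have side >= cutoff; only the 27
# neighboring cells of each occupied cell are scanned. With a periodic box the
# grid tiles the box and neighbor lookups wrap.
pairs_grid <- function(frame, set_a, set_b, cutoff, box) {
  all_idx <- union(set_a, set_b)
  x <- frame[all_idx, , drop = FALSE]
  if (is.null(box)) {
    lo <- apply(x, 2, min) - 1e-9
    span <- pmax(apply(x, 2, max) - lo, cutoff) + 1e-6
    ncell <- pmax(1L, floor(span / cutoff))
    wrap <- FALSE
  } else {
    lo <- c(0, 0, 0)
    x <- x - floor(sweep(x, 2, box, "/")) * rep(box, each = nrow(x))
    span <- box
    ncell <- pmax(1L, floor(box / cutoff))
    wrap <- TRUE
  }
  size <- span / ncell
  cell_of <- function(xx) {
    ix <- pmin(ncell, pmax(1L, 1L + floor((xx - rep(lo, each = nrow(xx))) /
                                            rep(size, each = nrow(xx)))))
    matrix(as.integer(ix), ncol = 3)
  }
  cells <- cell_of(x)
  code <- (cells[, 1] - 1L) + ncell[1] * ((cells[, 2] - 1L) +
                                            ncell[2] * (cells[, 3] - 1L))
  in_a <- all_idx %in% set_a
  in_b <- all_idx %in% set_b
  members <- split(seq_along(all_idx), code)

  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  occupied <- as.integer(names(members))
  occ_cells <- cbind(occupied %% ncell[1],
                     (occupied %/% ncell[1]) %% ncell[2],
                     occupied %/% (ncell[1] * ncell[2])) + 1L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (ci in seq_along(occupied)) {
    here <- members[[ci]]
    ai <- here[in_a[here]]
    if (length(ai) == 0L) next
    neigh <- integer(0)
    for (o in seq_len(nrow(offs))) {
      cc <- occ_cells[ci, ] + offs[o, ]
      if (wrap) {
        cc <- ((cc - 1L) %% ncell) + 1L
      } else if (any(cc < 1L | cc > ncell)) next
      ccode <- as.character((cc[1] - 1L) + ncell[1] *
                              ((cc[2] - 1L) + ncell[2] * (cc[3] - 1L)))
      m <- members[[ccode]]
      if (!is.null(m)) neigh <- c(neigh, m)
    }
    neigh <- unique(neigh)
    bj <- neigh[in_b[neigh]]
    if (length(bj) == 0L) next
    sub <- pairs_dense(frame, all_idx[ai], all_idx[bj], cutoff, box)
    res_i <- c(res_i, sub$i); res_j <- c(res_j, sub$j)
    res_d <- c(res_d, sub$distance)
  }
  out <- data.frame(i = res_i, j = res_j, distance = res_d)
  out[!duplicated(paste(out$i, out$j)), , drop = FALSE]
}
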