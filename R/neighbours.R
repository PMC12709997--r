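# Internal neighbour-search utilities shared by the clustering code.
# Point sets are n x 2 numeric matrices (columns x, y). Searches use a
# uniform grid of cell size eps (fixed-radius) or chunked dense distances
# (k-nearest), keeping memory linear in n.

# Fixed-radius neighbour lists via grid binning. Returns a list of integer
# vectors; each includes the point itself.
.radius_neighbours <- function(xy, eps) {
  n <- nrow(xy)
  cx <- floor(xy[, 1] / eps)
  cy <- floor(xy[, 2] / eps)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  cell_xy <- do.call(rbind, strsplit(names(cells), " "))
  cell_cx <- as.numeric(cell_xy[, 1])
  cell_cy <- as.numeric(cell_xy[, 2])
  cell_of <- match(key, names(cells))
  # neighbouring cell lookup table
  cell_index <- setNames(seq_along(cells), names(cells))
  out <- vector("list", n)
  eps2 <- eps^2
  for (ci in seq_along(cells)) {
    cand <- integer(0)
    for (dx in -1:1) {
      for (dy in -1:1) {
        k <- paste(cell_cx[ci] + dx, cell_cy[ci] + dy)
        j <- cell_index[k]
        if (!is.na(j)) cand <- c(cand, cells[[j]])
      }
    }
    pts <- cells[[ci]]
    dx <- outer(xy[pts, 1], xy[cand, 1], "-")
    dy <- outer(xy[pts, 2], xy[cand, 2], "-")
    within <- dx * dx + dy * dy <= eps2
    for (r in seq_along(pts)) {
      out[[pts[r]]] <- cand[within[r, ]]
    }
  }
  out
}

# Distance to the k-th nearest neighbour, the query point itself counting as
# the first. Chunked so memory stays O(chunk * n).
.kth_nn_dist <- function(xy, k, chunk = 2048L) {
  n <- nrow(xy)
  k <- min(k, n)
  out <- numeric(n)
  sq <- rowSums(xy^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    d2 <- outer(sq[idx], sq, "+") - 2 * xy[idx, , drop = FALSE] %*% t(xy)
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1L, function(v) sqrt(sort.int(v, partial = k)[k]))
  }
  out
}
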