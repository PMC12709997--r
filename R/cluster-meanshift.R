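#' Mean-shift clustering on a 2-D point set
#'
#' Flat-kernel mean-shift: every seed is iteratively moved to the mean of
#' the points inside its bandwidth ball until convergence; converged modes
#' closer than one bandwidth are merged (keeping the mode with more
#' supporting points), and every point is assigned to its nearest surviving
#' mode. The bandwidth is estimated from the data as the average distance
#' to the `floor(quantile * n)`-th nearest neighbour (self included), the
#' usual quantile heuristic.
#'
#' @param xy Numeric matrix or data frame with two columns (x, y).
#' @param bandwidth_quantile Quantile for bandwidth estimation, in (0, 1).
#' @param bandwidth Optional explicit bandwidth overriding the estimate.
#' @param max_iter Iteration cap per seed.
#' @param bin_seeding Seed from bandwidth-sized grid bins instead of every
#'   point (automatic for large point sets).
#' @return Integer vector of cluster labels (all points are assigned;
#'   mean-shift has no noise class).
#' @export
meanshift_points <- function(xy, bandwidth_quantile = 0.1, bandwidth = NULL,
                             max_iter = 300L, bin_seeding = nrow(xy) > 2000L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  bw <- bandwidth %||% estimate_bandwidth(xy, bandwidth_quantile)
  if (bw <= 0) bw <- sqrt(.Machine$double.eps)
  seeds <- if (bin_seeding) {
    gx <- round(xy[, 1] / bw)
    gy <- round(xy[, 2] / bw)
    key <- paste(gx, gy)
    keep <- !duplicated(key)
    cbind(gx[keep] * bw, gy[keep] * bw)
  } else {
    xy
  }
  tol <- 1e-3 * bw
  modes <- matrix(NA_real_, nrow(seeds), 2L)
  support <- integer(nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    m <- seeds[s, ]
    for (it in seq_len(max_iter)) {
      d2 <- (xy[, 1] - m[1])^2 + (xy[, 2] - m[2])^2
      inside <- d2 <= bw^2
      if (!any(inside)) break
      nm <- c(mean(xy[inside, 1]), mean(xy[inside, 2]))
      if (sqrt(sum((nm - m)^2)) < tol) {
        m <- nm
        break
      }
      m <- nm
    }
    d2 <- (xy[, 1] - m[1])^2 + (xy[, 2] - m[2])^2
    modes[s, ] <- m
    support[s] <- sum(d2 <= bw^2)
  }
  ok <- support > 0L
  modes <- modes[ok, , drop = FALSE]
  support <- support[ok]
  if (!nrow(modes)) return(rep(1L, n))
  # merge modes within one bandwidth, strongest support first
  o <- order(-support, seq_along(support))
  kept <- matrix(numeric(0), 0L, 2L)
  for (i in o) {
    if (!nrow(kept) ||
      min((kept[, 1] - modes[i, 1])^2 + (kept[, 2] - modes[i, 2])^2) > bw^2) {
      kept <- rbind(kept, modes[i, ])
    }
  }
  # assign every point to the nearest mode
  lab <- integer(n)
  best <- rep(Inf, n)
  for (k in seq_len(nrow(kept))) {
    d2 <- (xy[, 1] - kept[k, 1])^2 + (xy[, 2] - kept[k, 2])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- k
  }
  .renumber_labels(lab)
}

#' Quantile bandwidth estimate for mean-shift
#'
#' Average over all points of the distance to the `floor(quantile * n)`-th
#' nearest neighbour (the point itself counting as the first).
#'
#' @param xy Two-column point matrix.
#' @param quantile Neighbour quantile in (0, 1).
#' @return Estimated bandwidth (>= 0).
#' @export
estimate_bandwidth <- function(xy, quantile = 0.1) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  k <- max(2L, floor(n * quantile))
  mean(.kth_nn_dist(xy, k))
}
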