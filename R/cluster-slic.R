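#' SLIC superpixels of a binary mask
#'
#' Simple Linear Iterative Clustering on the binary image: cluster centres
#' are initialised on a regular grid with spacing `S = sqrt(H * W / n_segments)`
#' and pixels are assigned, within a 2S window around each centre, by the
#' combined colour-plus-space distance
#' `D = sqrt(d_c^2 + (d_s / S)^2 * m^2)` with compactness `m`. Intensities
#' are put on a 0-100 scale (background 0, root 100) so boundaries adhere
#' to the root/background edge. Ten assignment/update sweeps are run.
#'
#' @param mask A [root_mask()] or logical matrix.
#' @param n_segments Target superpixel count.
#' @param compactness Spatial regularisation weight `m`.
#' @param n_iter Number of assignment/update sweeps.
#' @return Integer matrix of superpixel labels (same shape as the mask).
#' @export
slic_segments <- function(mask, n_segments = 50, compactness = 10, n_iter = 10L) {
  px <- if (inherits(mask, "root_mask")) mask$pixels else mask
  h <- nrow(px)
  w <- ncol(px)
  intens <- matrix(0, h, w)
  intens[px] <- 100
  S <- sqrt(h * w / n_segments)
  gy <- seq(S / 2, h, by = S)
  gx <- seq(S / 2, w, by = S)
  centres <- expand.grid(y = gy, x = gx)
  k <- nrow(centres)
  cy <- centres$y
  cx <- centres$x
  ci <- vapply(seq_len(k), function(i) {
    intens[min(h, max(1, round(cy[i]))), min(w, max(1, round(cx[i])))]
  }, numeric(1))
  rowm <- matrix(seq_len(h), h, w)
  colm <- matrix(seq_len(w), h, w, byrow = TRUE)
  label <- matrix(1L, h, w)
  for (it in seq_len(n_iter)) {
    bestd <- matrix(Inf, h, w)
    for (i in seq_len(k)) {
      r0 <- max(1L, floor(cy[i] - S))
      r1 <- min(h, ceiling(cy[i] + S))
      c0 <- max(1L, floor(cx[i] - S))
      c1 <- min(w, ceiling(cx[i] + S))
      dc <- intens[r0:r1, c0:c1, drop = FALSE] - ci[i]
      ds2 <- outer((r0:r1 - cy[i])^2, rep(1, c1 - c0 + 1)) +
        outer(rep(1, r1 - r0 + 1), (c0:c1 - cx[i])^2)
      D <- dc^2 + ds2 / S^2 * compactness^2
      win_best <- bestd[r0:r1, c0:c1, drop = FALSE]
      upd <- D < win_best
      win_best[upd] <- D[upd]
      bestd[r0:r1, c0:c1] <- win_best
      win_lab <- label[r0:r1, c0:c1, drop = FALSE]
      win_lab[upd] <- i
      label[r0:r1, c0:c1] <- win_lab
    }
    if (it < n_iter) {
      for (i in seq_len(k)) {
        hit <- label == i
        if (any(hit)) {
          cy[i] <- mean(rowm[hit])
          cx[i] <- mean(colm[hit])
          ci[i] <- mean(intens[hit])
        }
      }
    }
  }
  label
}
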