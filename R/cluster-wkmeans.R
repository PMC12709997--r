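# Weighted K-means (Lloyd with sample weights and a weighted k-means++
# initialisation). Used by the custom extractor, where kernel-density
# estimates enter as per-point weights; base stats::kmeans has no weights.

#' K-means with per-point sample weights
#'
#' @param xy Two-column point matrix.
#' @param w Non-negative sample weights (need not sum to 1).
#' @param k Number of clusters (at most the number of distinct points).
#' @param nstart Restarts; the solution with the lowest weighted
#'   within-cluster sum of squares is kept.
#' @param max_iter Lloyd iteration cap per start.
#' @param seed Integer seed for the weighted k-means++ initialisation.
#' @return List with `cluster` (labels 1..k), `centers`, and `tot_withinss`
#'   (weighted).
#' @export
weighted_kmeans <- function(xy, w = rep(1, nrow(xy)), k, nstart = 10L,
                            max_iter = 100L, seed = 0L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  stopifnot(length(w) == n, all(w >= 0), k >= 1)
  distinct <- nrow(unique(xy))
  if (k > distinct) {
    abort(sprintf("k = %d exceeds the %d distinct points", k, distinct))
  }
  if (all(w == 0)) w <- rep(1, n)
  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(nstart)) {
      centers <- .wkmpp_init(xy, w, k)
      lab <- integer(n)
      for (it in seq_len(max_iter)) {
        d2 <- .dist2_to_centers(xy, centers)
        newlab <- max.col(-d2, ties.method = "first")
        if (identical(newlab, lab)) break
        lab <- newlab
        for (j in seq_len(k)) {
          hit <- lab == j
          if (any(hit)) {
            wj <- w[hit]
            if (sum(wj) == 0) wj <- rep(1, sum(hit))
            centers[j, ] <- c(
              weighted.mean(xy[hit, 1], wj),
              weighted.mean(xy[hit, 2], wj)
            )
          } else {
            # re-seed an empty cluster at the worst-fit point
            d2c <- .dist2_to_centers(xy, centers)
            centers[j, ] <- xy[which.max(apply(d2c, 1, min)), ]
          }
        }
      }
      d2 <- .dist2_to_centers(xy, centers)
      obj <- sum(w * d2[cbind(seq_len(n), lab)])
      if (is.null(best) || obj < best$tot_withinss) {
        best <- list(cluster = lab, centers = centers, tot_withinss = obj)
      }
    }
  })
  best
}

.dist2_to_centers <- function(xy, centers) {
  outer(xy[, 1], centers[, 1], "-")^2 + outer(xy[, 2], centers[, 2], "-")^2
}

# weighted k-means++ seeding
.wkmpp_init <- function(xy, w, k) {
  n <- nrow(xy)
  p <- w / sum(w)
  idx <- sample.int(n, 1L, prob = p)
  centers <- xy[idx, , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(.dist2_to_centers(xy, centers), 1, min)
    pr <- w * d2
    if (sum(pr) == 0) {
      cand <- setdiff(seq_len(n), idx)
      nxt <- cand[sample.int(length(cand), 1L)]
    } else {
      nxt <- sample.int(n, 1L, prob = pr / sum(pr))
    }
    idx <- c(idx, nxt)
    centers <- rbind(centers, xy[nxt, , drop = FALSE])
  }
  centers
}
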