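#' OPTICS ordering and xi-based cluster extraction
#'
#' Computes the OPTICS reachability ordering (unbounded generating radius)
#' and extracts clusters with the steep-area xi method: a cluster is a
#' region of the reachability plot bounded by a steep-down area on the left
#' and a steep-up area on the right, where "steep" means a relative drop or
#' rise of at least a factor `1 - xi`.
#'
#' @param xy Numeric matrix or data frame with two columns (x, y).
#' @param min_samples Smoothing parameter: core distances are distances to
#'   the `min_samples`-th nearest neighbour (self included), and steep areas
#'   tolerate at most `min_samples` consecutive non-steep points.
#' @param xi Steepness threshold in (0, 1).
#' @param min_cluster_size Minimum extracted cluster size; defaults to
#'   `min_samples`.
#' @return Integer vector of cluster labels in original point order
#'   (0 = unassigned/noise). Nested xi clusters are resolved to their
#'   innermost (leaf) cluster; the full-span root is never a cluster.
#' @export
optics_points <- function(xy, min_samples = 10, xi = 0.05,
                          min_cluster_size = min_samples) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  if (n <= min_samples) return(integer(n))
  ord <- .optics_order(xy, min_samples)
  segs <- .xi_segments(ord$reachability, xi, min_samples, min_cluster_size)
  labels <- integer(n)
  if (nrow(segs)) {
    # leaf resolution: wider segments first so innermost clusters overwrite
    # their parents, matching the usual xi labelling
    segs <- segs[order(-(segs$end - segs$start)), , drop = FALSE]
    for (i in seq_len(nrow(segs))) {
      labels[ord$order[segs$start[i]:segs$end[i]]] <- i
    }
  }
  .renumber_labels(labels)
}

# Reachability ordering; O(n^2) time, O(n) memory.
.optics_order <- function(xy, min_samples) {
  n <- nrow(xy)
  core <- .kth_nn_dist(xy, min_samples)
  processed <- logical(n)
  reach <- rep(Inf, n)
  order_out <- integer(n)
  reach_out <- numeric(n)
  current <- 1L
  for (step in seq_len(n)) {
    order_out[step] <- current
    reach_out[step] <- reach[current]
    processed[current] <- TRUE
    d <- sqrt((xy[, 1] - xy[current, 1])^2 + (xy[, 2] - xy[current, 2])^2)
    newreach <- pmax(core[current], d)
    upd <- !processed & newreach < reach
    reach[upd] <- newreach[upd]
    if (step < n) {
      nxt <- which(!processed)
      current <- nxt[which.min(reach[nxt])]
    }
  }
  list(order = order_out, reachability = reach_out, core = core)
}

# Steep-area cluster extraction from a reachability profile (ordering space).
# Returns a data.frame(start, end) of 1-based inclusive ordering indices.
.xi_segments <- function(r, xi, min_samples, min_cluster_size) {
  n_pts <- length(r)
  out <- list()
  if (n_pts < 2L) return(data.frame(start = integer(0), end = integer(0)))
  rr <- r
  rr[!is.finite(rr)] <- max(r[is.finite(r)], 1) * 1e6
  # terminal sentinel: the end of the plot acts as an infinitely steep rise,
  # so a cluster running to the last point can close
  rr <- c(rr, max(rr) * 2)
  n <- length(rr)
  steep_down <- function(i) rr[i] * (1 - xi) >= rr[i + 1L]
  down <- function(i) rr[i] >= rr[i + 1L]
  steep_up <- function(i) rr[i] <= rr[i + 1L] * (1 - xi)
  up <- function(i) rr[i] <= rr[i + 1L]

  extend <- function(i, is_steep, is_weak) {
    # extend a steep region starting at i; tolerate up to min_samples
    # consecutive merely-weak (non-steep but monotone) points
    end <- i
    j <- i + 1L
    bad <- 0L
    while (j <= n - 1L) {
      if (is_steep(j)) {
        end <- j
        bad <- 0L
      } else if (is_weak(j)) {
        bad <- bad + 1L
        if (bad > min_samples) break
      } else {
        break
      }
      j <- j + 1L
    }
    end
  }

  sdas <- list() # each: list(start, end, mib)
  mib <- 0
  index <- 1L
  while (index <= n - 1L) {
    mib <- max(mib, rr[index])
    if (steep_down(index)) {
      sdas <- purrr::keep(sdas, function(D) rr[D$start] * (1 - xi) >= mib)
      sdas <- purrr::map(sdas, function(D) {
        D$mib <- max(D$mib, mib)
        D
      })
      end <- extend(index, steep_down, down)
      sdas[[length(sdas) + 1L]] <- list(start = index, end = end, mib = 0)
      index <- end + 1L
      mib <- rr[index]
    } else if (steep_up(index)) {
      sdas <- purrr::keep(sdas, function(D) rr[D$start] * (1 - xi) >= mib)
      sdas <- purrr::map(sdas, function(D) {
        D$mib <- max(D$mib, mib)
        D
      })
      u_start <- index
      u_end <- extend(index, steep_up, up)
      index <- u_end + 1L
      mib <- rr[index]
      end_val <- if (u_end + 1L <= n) rr[u_end + 1L] else rr[n]
      for (D in sdas) {
        # significance: the in-between maximum must be dominated
        if (end_val * (1 - xi) < D$mib) next
        s <- D$start
        e <- u_end
        if (rr[s] * (1 - xi) >= end_val) {
          # left side higher: shrink start to the last point above end_val
          cand <- which(rr[s:D$end] > end_val)
          if (length(cand)) s <- s + max(cand) - 1L
        } else if (end_val * (1 - xi) >= rr[s]) {
          # right side higher: shrink end to the first point below start value
          cand <- which(rr[u_start:u_end] < rr[s])
          if (length(cand)) e <- u_start + min(cand) - 1L
        }
        if (e - s + 1L >= min_cluster_size && s < e) {
          out[[length(out) + 1L]] <- c(start = s, end = e)
        }
      }
    } else {
      index <- index + 1L
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  segs <- as.data.frame(do.call(rbind, out))
  segs$end <- pmin(segs$end, n_pts)
  segs <- segs[segs$start < segs$end, , drop = FALSE]
  # the full-span root segment (all points are one cluster at the coarsest
  # resolution) is never a useful cluster; exclude it, as HDBSCAN excludes
  # its root
  segs <- segs[!(segs$start == 1L & segs$end == n_pts), , drop = FALSE]
  unique(segs)
}
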