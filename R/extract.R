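#' The nine trait-extraction algorithms
#'
#' @return Character vector of algorithm names, in the fixed column order
#'   used by [extract_all()].
#' @export
art_algorithms <- function() {
  c(
    "DBSCAN", "GMM", "Kmeans", "HDBSCAN", "Meanshift",
    "OPTICS", "SLIC", "FCM", "Custom"
  )
}

#' Names of the 27 trait columns
#'
#' Nine algorithms times three traits, named
#' `<Algorithm>_density_points`, `<Algorithm>_centre_x`,
#' `<Algorithm>_centre_y`. The naming is load-bearing: downstream
#' algorithm-level grouping (importance, ablation) parses it.
#'
#' @return Character vector of length 27.
#' @export
art_trait_names <- function() {
  as.vector(vapply(
    art_algorithms(),
    function(a) paste0(a, c("_density_points", "_centre_x", "_centre_y")),
    character(3)
  ))
}

#' Extraction parameters
#'
#' Defaults follow the published settings of each algorithm: DBSCAN
#' (`eps = 5`, `min_samples = 10`), GMM (`n_components = 2`), K-means
#' (`n_clusters = 5`), HDBSCAN (`min_cluster_size = 10`), mean-shift
#' (bandwidth `quantile = 0.1`), OPTICS (`min_samples = 10`), SLIC
#' (`n_segments = 50`), fuzzy C-means (5 clusters, fuzzifier 2), and the
#' custom procedure (200-pixel density cap, up to 5 clusters, 3x3 local
#' neighbourhood). `subsample_cap` bounds the point set handed to the
#' quadratic-cost algorithms; when a mask exceeds it, a seeded uniform
#' subsample of exactly that many root pixels is analysed and the event is
#' recorded in the provenance.
#'
#' @param ... Named overrides of any default listed above, e.g.
#'   `dbscan = list(eps = 4)` or `subsample_cap = 5000`.
#' @return A named list of per-algorithm parameter lists.
#' @export
art_params <- function(...) {
  p <- list(
    dbscan = list(eps = 5, min_samples = 10),
    gmm = list(n_components = 2),
    kmeans = list(n_clusters = 5, nstart = 10),
    hdbscan = list(min_cluster_size = 10),
    meanshift = list(bandwidth_quantile = 0.1),
    optics = list(min_samples = 10, xi = 0.05),
    slic = list(n_segments = 50, compactness = 10),
    fcm = list(n_clusters = 5, fuzzifier = 2, nstart = 10),
    custom = list(pixel_cap = 200, max_clusters = 5),
    subsample_cap = 20000L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p)) abort(sprintf("unknown parameter group '%s'", nm))
    if (is.list(over[[nm]])) {
      p[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      p[[nm]] <- over[[nm]]
    }
  }
  p
}

#' Root-pixel coordinates of a mask, optionally subsampled
#'
#' Returns the (x, y) coordinates (0-based; x = column, y = row) of all
#' root pixels, or a seeded uniform subsample of exactly `subsample_cap`
#' of them when the mask has more. The provenance attribute records the
#' original and used counts and the seed.
#'
#' @param mask A [root_mask()].
#' @param subsample_cap Maximum number of points returned.
#' @param seed Integer seed for the subsample.
#' @return Numeric matrix with columns `x`, `y`; attribute `"provenance"`
#'   is a list (`n_root_pixels`, `n_used`, `subsampled`, `seed`).
#' @export
points_from_mask <- function(mask, subsample_cap = 20000L, seed = 0L) {
  stopifnot(inherits(mask, "root_mask"))
  idx <- which(mask$pixels)
  n <- length(idx)
  rows <- (idx - 1L) %% mask$height
  cols <- (idx - 1L) %/% mask$height
  xy <- cbind(x = as.numeric(cols), y = as.numeric(rows))
  sub <- FALSE
  if (n > subsample_cap) {
    keep <- withr::with_seed(seed, sort(sample.int(n, subsample_cap)))
    xy <- xy[keep, , drop = FALSE]
    sub <- TRUE
  }
  attr(xy, "provenance") <- list(
    n_root_pixels = n, n_used = nrow(xy), subsampled = sub, seed = seed
  )
  xy
}

#' Largest cluster of a labelled point set
#'
#' Picks the cluster label with the most member points (noise, label 0, is
#' never a candidate) and returns its members and arithmetic-mean centroid.
#' Ties are broken towards the smallest label value, so the choice is
#' deterministic.
#'
#' @param xy Two-column point matrix.
#' @param labels Integer cluster labels per point; 0 means noise.
#' @return List with `members` (indices), `size`, `centre_x`, `centre_y`,
#'   `label`; or `NULL` when every point is noise.
#' @export
largest_cluster <- function(xy, labels) {
  stopifnot(nrow(xy) == length(labels))
  pos <- labels > 0L
  if (!any(pos)) return(NULL)
  sizes <- tabulate(labels[pos])
  lab <- which.max(sizes) # first maximum = smallest label
  members <- which(labels == lab)
  list(
    members = members, size = length(members),
    centre_x = mean(xy[members, 1]), centre_y = mean(xy[members, 2]),
    label = lab
  )
}

.trait <- function(algorithm, size = .missing_trait, cx = .missing_trait,
                   cy = .missing_trait, status = "ok", reason = NA_character_) {
  list(
    algorithm = algorithm, density_points = as.numeric(size),
    centre_x = as.numeric(cx), centre_y = as.numeric(cy),
    status = status, reason = reason
  )
}

.trait_from_labels <- function(algorithm, xy, labels) {
  top <- largest_cluster(xy, labels)
  if (is.null(top)) {
    return(.trait(algorithm, status = "no_cluster", reason = "all points noise"))
  }
  .trait(algorithm, top$size, top$centre_x, top$centre_y)
}

#' Run one partition-type extractor (K-means, GMM or fuzzy C-means)
#'
#' K-means partitions the root-pixel point cloud into `n_clusters` hard
#' clusters (best of `nstart` seeded k-means++-initialised restarts by
#' total within-cluster sum of squares); GMM fits a full-covariance Gaussian mixture and assigns
#' each point to its maximum-posterior component; fuzzy C-means assigns by
#' maximum membership. The largest resulting cluster supplies the traits.
#'
#' @param algo `"kmeans"`, `"gmm"` or `"fcm"`.
#' @param xy Two-column point matrix from [points_from_mask()].
#' @param params An [art_params()] list.
#' @param seed Integer seed.
#' @return A trait record (list: `algorithm`, `density_points`, `centre_x`,
#'   `centre_y`, `status`, `reason`).
#' @export
extract_partition <- function(algo = c("kmeans", "gmm", "fcm"), xy,
                              params = art_params(), seed = 0L) {
  algo <- match.arg(algo)
  name <- c(kmeans = "Kmeans", gmm = "GMM", fcm = "FCM")[[algo]]
  k <- switch(algo,
    kmeans = params$kmeans$n_clusters,
    gmm = params$gmm$n_components,
    fcm = params$fcm$n_clusters
  )
  if (nrow(xy) < k) {
    return(.trait(name, status = "insufficient_pixels",
      reason = sprintf("%d points < %d clusters", nrow(xy), k)))
  }
  labels <- tryCatch(
    switch(algo,
      kmeans = weighted_kmeans(xy,
        w = rep(1, nrow(xy)), k = k,
        nstart = params$kmeans$nstart, seed = seed
      )$cluster,
      gmm = {
        mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller
        fit <- NULL
        for (mod in c("VVV", "VII", "EII")) {
          fit <- suppressWarnings(
            mclust::Mclust(xy, G = k, modelNames = mod, verbose = FALSE)
          )
          if (!is.null(fit)) break
        }
        if (is.null(fit)) abort("mixture fit did not converge")
        as.integer(fit$classification)
      },
      fcm = withr::with_seed(seed, {
        distinct <- unique(xy)
        if (nrow(distinct) < k) abort("fewer distinct points than clusters")
        best <- NULL
        for (s in seq_len(params$fcm$nstart)) {
          init <- distinct[sample.int(nrow(distinct), k), , drop = FALSE]
          fit <- e1071::cmeans(xy, centers = init, m = params$fcm$fuzzifier)
          if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
        }
        as.integer(best$cluster)
      })
    ),
    error = function(e) e
  )
  if (inherits(labels, "error")) {
    return(.trait(name, status = "no_cluster", reason = conditionMessage(labels)))
  }
  .trait_from_labels(name, xy, labels)
}

#' Run one density-type extractor (DBSCAN, HDBSCAN, OPTICS or mean-shift)
#'
#' Noise points (label 0) are excluded from candidacy; the largest non-noise
#' cluster supplies the traits. Mean-shift estimates its bandwidth from the
#' point set at the configured quantile and assigns every point, so it has
#' no noise class.
#'
#' @param algo `"dbscan"`, `"hdbscan"`, `"optics"` or `"meanshift"`.
#' @inheritParams extract_partition
#' @return A trait record; see [extract_partition()].
#' @export
extract_density <- function(algo = c("dbscan", "hdbscan", "optics", "meanshift"),
                            xy, params = art_params(), seed = 0L) {
  algo <- match.arg(algo)
  name <- c(
    dbscan = "DBSCAN", hdbscan = "HDBSCAN",
    optics = "OPTICS", meanshift = "Meanshift"
  )[[algo]]
  min_n <- switch(algo,
    dbscan = params$dbscan$min_samples,
    hdbscan = params$hdbscan$min_cluster_size,
    optics = params$optics$min_samples,
    meanshift = 2
  )
  if (nrow(xy) < min_n) {
    return(.trait(name, status = "insufficient_pixels",
      reason = sprintf("%d points < minimum %d", nrow(xy), min_n)))
  }
  labels <- tryCatch(
    switch(algo,
      dbscan = dbscan_points(xy, params$dbscan$eps, params$dbscan$min_samples),
      hdbscan = hdbscan_points(xy, params$hdbscan$min_cluster_size),
      optics = optics_points(xy, params$optics$min_samples, params$optics$xi),
      meanshift = meanshift_points(xy, params$meanshift$bandwidth_quantile)
    ),
    error = function(e) e
  )
  if (inherits(labels, "error")) {
    return(.trait(name, status = "no_cluster", reason = conditionMessage(labels)))
  }
  .trait_from_labels(name, xy, labels)
}

#' Run the SLIC superpixel extractor
#'
#' Superpixels are computed on the binary image itself ([slic_segments()]);
#' each superpixel's root-pixel subset is a candidate cluster, the
#' superpixel containing the most root pixels wins, and the traits are the
#' count and centroid of the root pixels inside it. Superpixels with no
#' root pixels are never candidates.
#'
#' @param mask A [root_mask()].
#' @param params An [art_params()] list.
#' @return A trait record; see [extract_partition()].
#' @export
extract_slic <- function(mask, params = art_params()) {
  if (root_pixel_count(mask) == 0L) {
    return(.trait("SLIC", status = "insufficient_pixels", reason = "empty mask"))
  }
  seg <- slic_segments(mask,
    n_segments = params$slic$n_segments,
    compactness = params$slic$compactness
  )
  root_seg <- seg[mask$pixels]
  counts <- tabulate(root_seg)
  win <- which.max(counts)
  hit <- mask$pixels & seg == win
  idx <- which(hit)
  rows <- (idx - 1L) %% mask$height
  cols <- (idx - 1L) %/% mask$height
  .trait("SLIC", length(idx), mean(cols), mean(rows))
}

#' Local density of every root pixel
#'
#' The score of a root pixel is the number of root pixels in its 3x3
#' neighbourhood, itself included; border pixels use only the in-image part
#' of the window. Background pixels score 0.
#'
#' @param mask A [root_mask()].
#' @return Integer matrix of scores, same shape as the mask.
#' @export
local_density <- function(mask) {
  stopifnot(inherits(mask, "root_mask"))
  px <- mask$pixels
  h <- nrow(px)
  w <- ncol(px)
  acc <- matrix(0L, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      r_src <- max(1, 1 - dr):min(h, h - dr)
      c_src <- max(1, 1 - dc):min(w, w - dc)
      acc[r_src + dr, c_src + dc] <- acc[r_src + dr, c_src + dc] +
        px[r_src, c_src]
    }
  }
  acc[!px] <- 0L
  acc
}

#' Select the most locally dense root pixels
#'
#' If the mask has at most `cap` root pixels they are all returned;
#' otherwise exactly `cap` pixels with the highest [local_density()] scores
#' are kept. Ties at the cut are resolved in row-major order (top row
#' first, left to right), so the selection is deterministic.
#'
#' @param mask A [root_mask()].
#' @param cap Maximum number of pixels retained (200 by default).
#' @return Numeric matrix with columns `x`, `y` (0-based).
#' @export
select_top_dense <- function(mask, cap = 200L) {
  stopifnot(inherits(mask, "root_mask"))
  idx <- which(mask$pixels)
  rows <- (idx - 1L) %% mask$height
  cols <- (idx - 1L) %/% mask$height
  if (length(idx) > cap) {
    score <- local_density(mask)[idx]
    # order: score desc, then row-major (y, then x)
    o <- order(-score, rows, cols)
    keep <- o[seq_len(cap)]
    rows <- rows[keep]
    cols <- cols[keep]
  }
  cbind(x = as.numeric(cols), y = as.numeric(rows))
}

# Gaussian KDE evaluated at its own support points; bandwidth by Scott's
# rule with the full sample covariance (factor n^(-1/6) in 2-D). Returns
# equal weights when the covariance is degenerate.
.kde_weights <- function(xy) {
  n <- nrow(xy)
  if (n < 3L || nrow(unique(xy)) < 3L) return(rep(1, n))
  f <- n^(-1 / 6)
  S <- cov(xy) * f^2
  det_s <- det(S)
  if (!is.finite(det_s) || det_s <= 1e-12) return(rep(1, n))
  Sinv <- solve(S)
  dens <- numeric(n)
  for (i in seq_len(n)) {
    d <- cbind(xy[, 1] - xy[i, 1], xy[, 2] - xy[i, 2])
    q <- rowSums((d %*% Sinv) * d)
    dens[i] <- sum(exp(-q / 2))
  }
  dens / (n * 2 * pi * sqrt(det_s))
}

#' Run the custom kernel-density-guided extractor
#'
#' The procedure: (1) identify all root pixels; (2) if more than
#' `pixel_cap` exist, keep the `pixel_cap` most locally dense
#' ([select_top_dense()]); (3) weight the selected pixels by a Gaussian
#' kernel density estimate evaluated at each pixel; (4) cluster the
#' density-weighted coordinates with weighted K-means using
#' `min(max_clusters, number of distinct selected pixels)` clusters;
#' (5) take the largest cluster by member count; (6) report its size and
#' geometric centre. If all selected pixels coincide, they form a single
#' cluster at that coordinate.
#'
#' @param mask A [root_mask()].
#' @param params An [art_params()] list.
#' @param seed Integer seed.
#' @return A trait record; see [extract_partition()].
#' @export
extract_custom <- function(mask, params = art_params(), seed = 0L) {
  if (root_pixel_count(mask) == 0L) {
    return(.trait("Custom", status = "insufficient_pixels", reason = "empty mask"))
  }
  sel <- select_top_dense(mask, params$custom$pixel_cap)
  distinct <- nrow(unique(sel))
  if (distinct == 1L) {
    return(.trait("Custom", nrow(sel), sel[1, 1], sel[1, 2]))
  }
  k <- min(params$custom$max_clusters, distinct)
  w <- .kde_weights(sel)
  fit <- weighted_kmeans(sel, w, k, nstart = 10L, seed = seed)
  .trait_from_labels("Custom", sel, fit$cluster)
}

#' Extract all 27 algorithmic root traits from one mask
#'
#' Runs the nine extractors and assembles a one-row tibble with the 27
#' trait columns (see [art_trait_names()]). Extractor failures never raise:
#' they are recorded as statuses (`insufficient_pixels`, `no_cluster`) and
#' the corresponding traits carry `NA`. Statuses and the subsampling
#' provenance are attached as attributes `"statuses"` and `"provenance"`.
#'
#' @param mask A [root_mask()].
#' @param params An [art_params()] list.
#' @param seed Integer seed controlling subsampling and all seeded
#'   extractors.
#' @return One-row tibble: `sample_id`, `environment`, then the 27 traits.
#' @export
#'
#' @examples
#' sim <- simulate_root_mask(60, 60,
#'   blobs = data.frame(centre_x = 30, centre_y = 30, n_pixels = 120),
#'   seed = 1
#' )
#' extract_all(sim$mask, seed = 1)
extract_all <- function(mask, params = art_params(), seed = 0L) {
  stopifnot(inherits(mask, "root_mask"))
  xy <- points_from_mask(mask, params$subsample_cap, seed = seed)
  prov <- attr(xy, "provenance")
  empty <- nrow(xy) == 0L
  run <- function(fn) {
    if (empty) {
      return(NULL)
    }
    fn()
  }
  traits <- list(
    DBSCAN = run(function() extract_density("dbscan", xy, params, seed)),
    GMM = run(function() extract_partition("gmm", xy, params, seed)),
    Kmeans = run(function() extract_partition("kmeans", xy, params, seed)),
    HDBSCAN = run(function() extract_density("hdbscan", xy, params, seed)),
    Meanshift = run(function() extract_density("meanshift", xy, params, seed)),
    OPTICS = run(function() extract_density("optics", xy, params, seed)),
    SLIC = run(function() extract_slic(mask, params)),
    FCM = run(function() extract_partition("fcm", xy, params, seed)),
    Custom = run(function() extract_custom(mask, params, seed))
  )
  traits <- purrr::imap(traits, function(t, nm) {
    t %||% .trait(nm, status = "insufficient_pixels", reason = "empty mask")
  })
  vals <- purrr::imap(traits, function(t, nm) {
    v <- c(t$density_points, t$centre_x, t$centre_y)
    names(v) <- paste0(nm, c("_density_points", "_centre_x", "_centre_y"))
    v
  })
  row <- tibble::as_tibble(as.list(unlist(unname(vals))))
  row <- dplyr::bind_cols(
    tibble::tibble(sample_id = mask$sample_id, environment = mask$environment),
    row
  )
  attr(row, "statuses") <- vapply(traits, function(t) t$status, character(1))
  attr(row, "reasons") <- vapply(traits, function(t) t$reason, character(1))
  attr(row, "provenance") <- prov
  row
}

#' Extract traits for a set of masks
#'
#' @param masks List of [root_mask()] objects (optionally named).
#' @param params An [art_params()] list.
#' @param seed Integer seed (shared across masks; each mask's extraction is
#'   independent and deterministic).
#' @param include_status Add a `<Algorithm>_status` column per algorithm.
#' @return Tibble with one row per mask: metadata, 27 traits and optional
#'   status columns. The per-mask provenance list is attached as attribute
#'   `"provenance"`.
#' @export
extract_arts <- function(masks, params = art_params(), seed = 0L,
                         include_status = FALSE) {
  if (inherits(masks, "root_mask")) masks <- list(masks)
  rows <- purrr::map(masks, extract_all, params = params, seed = seed)
  out <- dplyr::bind_rows(rows)
  if (include_status) {
    st <- purrr::map_dfr(rows, function(r) {
      s <- attr(r, "statuses")
      tibble::as_tibble(as.list(setNames(s, paste0(names(s), "_status"))))
    })
    out <- dplyr::bind_cols(out, st)
  }
  attr(out, "provenance") <- purrr::map(rows, attr, "provenance")
  out
}
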