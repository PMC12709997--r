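#' Simulate a binary root mask with planted dense clusters
#'
#' Generates a ground-truthed synthetic mask: one or more dense blobs of
#' known pixel count and centre, optionally laid over a background of thin
#' (1 px) root strands and sparse speckle noise. The blobs emulate the dense
#' root aggregations the trait extractors are meant to find; the strands
#' emulate fine roots that should *not* dominate dense-cluster detection.
#'
#' Blob shapes:
#' * `"disc"` — the `n_pixels` grid cells nearest the centre;
#' * `"ellipse"` — nearest cells under an anisotropic (2:1, randomly
#'   oriented) metric;
#' * `"ragged"` — a disc whose boundary is randomly eroded, giving the
#'   irregular outlines produced by real root mats.
#'
#' The returned truth is *recomputed from the emitted pixel grid*, never
#' assumed from the request: per blob, the exact pixel count and the
#' arithmetic-mean centroid of its generated pixels (0-based `x` = column,
#' `y` = row).
#'
#' @param height,width Canvas size in pixels.
#' @param blobs Data frame with columns `centre_x`, `centre_y`, `n_pixels`
#'   and optionally `shape` (default `"disc"`). Centres are 0-based pixel
#'   coordinates and must lie inside the canvas.
#' @param background_strands Number of thin root strands to draw (0 = none).
#' @param speckle_rate Fraction of canvas pixels turned on as isolated
#'   speckle, in `[0, 0.01]`.
#' @param require_separation If `TRUE`, fail unless every pair of blob
#'   centres is at least 3 times the largest blob radius apart
#'   (well-separated layout, used by planted-truth recovery tests).
#' @param seed Integer seed; the same spec and seed give a bit-identical mask.
#' @param sample_id Identifier stored on the mask.
#'
#' @return A list with elements `mask` (a [root_mask()]) and `truth`
#'   (a tibble: `blob`, `n_pixels`, `centroid_x`, `centroid_y`, plus the
#'   attribute-free `total_root_pixels` column repeated for convenience).
#' @export
#'
#' @examples
#' sim <- simulate_root_mask(80, 80,
#'   blobs = data.frame(centre_x = 40, centre_y = 40, n_pixels = 100),
#'   seed = 1
#' )
#' sim$truth
simulate_root_mask <- function(height, width,
                               blobs = data.frame(
                                 centre_x = (width - 1) / 2,
                                 centre_y = (height - 1) / 2,
                                 n_pixels = 100
                               ),
                               background_strands = 0L,
                               speckle_rate = 0,
                               require_separation = FALSE,
                               seed = 0L,
                               sample_id = "synthetic") {
  stopifnot(height >= 1, width >= 1, nrow(blobs) >= 1)
  blobs <- as.data.frame(blobs)
  if (is.null(blobs$shape)) blobs$shape <- "disc"
  if (!all(blobs$shape %in% c("disc", "ellipse", "ragged"))) {
    abort("blob shape must be one of 'disc', 'ellipse', 'ragged'")
  }
  if (speckle_rate < 0 || speckle_rate > 0.01) {
    abort("speckle_rate must lie in [0, 0.01]")
  }
  if (any(blobs$centre_x < 0 | blobs$centre_x > width - 1 |
    blobs$centre_y < 0 | blobs$centre_y > height - 1)) {
    abort("blob centres must lie inside the canvas")
  }
  if (sum(blobs$n_pixels) > height * width) {
    abort("planted pixels exceed canvas capacity")
  }
  radii <- sqrt(blobs$n_pixels / pi)
  if (require_separation && nrow(blobs) > 1) {
    ctr <- as.matrix(blobs[, c("centre_x", "centre_y")])
    dmin <- min(dist(ctr))
    if (dmin < 3 * max(radii)) {
      abort(sprintf(
        "blobs are not well separated: min centre distance %.1f < 3 x max radius %.1f",
        dmin, max(radii)
      ))
    }
  }

  label <- matrix(0L, height, width) # 0 = background, -1 = strand/speckle, i = blob i
  # 0-based coordinate grids: x = column, y = row
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)

  withr::with_seed(seed, {
    for (i in seq_len(nrow(blobs))) {
      dx <- xs - blobs$centre_x[i]
      dy <- ys - blobs$centre_y[i]
      d2 <- switch(blobs$shape[i],
        disc = dx^2 + dy^2,
        ellipse = {
          th <- runif(1, 0, pi)
          u <- dx * cos(th) + dy * sin(th)
          v <- -dx * sin(th) + dy * cos(th)
          u^2 / 4 + v^2 # 2:1 aspect
        },
        ragged = dx^2 + dy^2 + runif(length(dx), 0, (0.9 * radii[i])^2)
      )
      # deterministic ordering: distance, then row-major position
      ord <- order(d2, ys, xs)
      take <- ord[seq_len(blobs$n_pixels[i])]
      if (any(label[take] != 0L)) {
        abort(sprintf("blob %d overlaps previously planted pixels", i))
      }
      label[take] <- i
    }
    if (background_strands > 0) {
      for (s in seq_len(background_strands)) {
        x <- sample.int(width, 1L)
        for (r in seq_len(height)) {
          if (label[r, x] == 0L) label[r, x] <- -1L
          x <- min(max(x + sample(c(-1L, 0L, 1L), 1L), 1L), width)
        }
      }
    }
    if (speckle_rate > 0) {
      free <- which(label == 0L)
      k <- min(length(free), round(speckle_rate * height * width))
      if (k > 0) label[sample(free, k)] <- -1L
    }
  })

  truth <- purrr::map_dfr(seq_len(nrow(blobs)), function(i) {
    hit <- label == i
    tibble::tibble(
      blob = i,
      n_pixels = sum(hit),
      centroid_x = mean(xs[hit]),
      centroid_y = mean(ys[hit])
    )
  })
  truth$total_root_pixels <- sum(label != 0L)

  mask <- root_mask(label != 0L,
    sample_id = sample_id,
    environment = "synthetic"
  )
  list(mask = mask, truth = truth)
}

#' Simulate a labelled two-class feature table
#'
#' Draws a samples-by-features tibble with two classes whose informative
#' features differ by a controllable standardised mean difference
#' (`effect_size`, in within-class standard deviations); noise features are
#' class-independent standard normals. This is the substrate for classifier
#' tests: `effect_size = 0` gives a pure null, large values give separable
#' classes with known Gaussian overlap.
#'
#' @param n_per_class Samples per class (two classes).
#' @param n_informative,n_noise Numbers of informative and noise features.
#' @param effect_size Standardised class-mean difference on each informative
#'   feature (>= 0).
#' @param class_labels Length-2 character vector; the second entry is the
#'   "positive" class downstream.
#' @param seed Integer seed.
#'
#' @return A tibble with `sample_id`, `label` (factor) and numeric feature
#'   columns `inf_*`, `noise_*`.
#' @export
simulate_feature_table <- function(n_per_class = 200L, n_informative = 5L,
                                   n_noise = 10L, effect_size = 1,
                                   class_labels = c("susceptible", "tolerant"),
                                   seed = 0L) {
  stopifnot(n_per_class >= 2, effect_size >= 0, length(class_labels) == 2)
  n <- 2L * n_per_class
  withr::with_seed(seed, {
    lab <- factor(rep(class_labels, each = n_per_class), levels = class_labels)
    shift <- ifelse(lab == class_labels[2L], effect_size / 2, -effect_size / 2)
    inf <- matrix(rnorm(n * n_informative), n, n_informative) + shift
    noi <- matrix(rnorm(n * n_noise), n, n_noise)
  })
  colnames(inf) <- sprintf("inf_%d", seq_len(n_informative))
  colnames(noi) <- if (n_noise > 0) sprintf("noise_%d", seq_len(n_noise)) else NULL
  out <- tibble::as_tibble(cbind(as.data.frame(inf), as.data.frame(noi)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)), label = lab),
    out
  )
}

#' Simulate a labelled set of root masks for classification tests
#'
#' Builds two classes of synthetic masks whose dominant dense cluster
#' differs either in *position* (pairwise-identical size draws, different
#' placement: total root pixels carry no class signal by construction) or
#' in *size* (same placement, different pixel counts). Both include thin background
#' strands so the masks are not trivially blob-only.
#'
#' @param n_per_class Masks per class.
#' @param height,width Canvas size.
#' @param class_diff `"position"` or `"size"`.
#' @param class_labels Length-2 character vector of class names.
#' @param seed Integer seed.
#'
#' @return A list with `masks` (named list of [root_mask()]) and `labels`
#'   (tibble: `sample_id`, `label`).
#' @export
simulate_labelled_masks <- function(n_per_class = 20L, height = 120L, width = 120L,
                                    class_diff = c("position", "size"),
                                    class_labels = c("susceptible", "tolerant"),
                                    seed = 0L) {
  class_diff <- match.arg(class_diff)
  masks <- list()
  labels <- character(0)
  withr::with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, 2L * n_per_class)
    # one size draw per pair: in position mode both classes reuse it, so
    # total root-pixel count carries no class signal by construction
    pair_sizes <- round(runif(n_per_class, 250, 350))
  })
  for (i in seq_len(2L * n_per_class)) {
    cls <- if (i <= n_per_class) 1L else 2L
    withr::with_seed(sub_seeds[i], {
      jx <- runif(1, -width * 0.08, width * 0.08)
      jy <- runif(1, -height * 0.08, height * 0.08)
    })
    size <- pair_sizes[(i - 1L) %% n_per_class + 1L]
    if (class_diff == "position") {
      ctr <- if (cls == 1L) {
        c(width * 0.28 + jx, height * 0.28 + jy)
      } else {
        c(width * 0.72 + jx, height * 0.72 + jy)
      }
    } else {
      ctr <- c(width * 0.5 + jx, height * 0.5 + jy)
      if (cls == 2L) size <- size * 2L
    }
    id <- sprintf("m_%s_%03d", class_labels[cls], i)
    sim <- simulate_root_mask(height, width,
      blobs = data.frame(centre_x = ctr[1], centre_y = ctr[2], n_pixels = size),
      background_strands = 2L, seed = sub_seeds[i], sample_id = id
    )
    masks[[id]] <- sim$mask
    labels <- c(labels, class_labels[cls])
  }
  list(
    masks = masks,
    labels = tibble::tibble(
      sample_id = names(masks),
      label = factor(labels, levels = class_labels)
    )
  )
}
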