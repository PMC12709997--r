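#' Root mask objects
#'
#' A `root_mask` wraps a binary segmented root image as a logical pixel grid
#' (`TRUE` = root pixel) together with its provenance. The coordinate
#' convention used throughout the package is fixed: `x` is the column index,
#' `y` is the row index, the origin is the top-left pixel, and both are
#' 0-based, so the top-left pixel is `(x = 0, y = 0)` and the bottom-right
#' pixel of an `h x w` mask is `(w - 1, h - 1)`.
#'
#' @param pixels Logical matrix, `TRUE` where a pixel belongs to a root.
#' @param sample_id Identifier for the imaged sample.
#' @param source_path Path the mask was read from, if any.
#' @param environment One of `"glasshouse"`, `"field"`, `"synthetic"`.
#'
#' @return A `root_mask` object.
#' @export
#'
#' @examples
#' m <- root_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' root_pixel_count(m)
root_mask <- function(pixels, sample_id = "mask", source_path = NA_character_,
                      environment = c("synthetic", "glasshouse", "field")) {
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  stopifnot(is.logical(pixels), is.matrix(pixels))
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("a root mask needs at least one row and one column")
  }
  pixels[is.na(pixels)] <- FALSE
  environment <- match.arg(environment)
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      sample_id = sample_id,
      source_path = source_path,
      environment = environment
    ),
    class = "root_mask"
  )
}

#' @export
print.root_mask <- function(x, ...) {
  cat(sprintf(
    "<root_mask> %s: %d x %d px, %d root pixels (%s)\n",
    x$sample_id, x$height, x$width, root_pixel_count(x), x$environment
  ))
  invisible(x)
}

#' Number of root pixels in a mask
#'
#' @param mask A [root_mask()].
#' @return Integer count of `TRUE` pixels. Zero (an empty mask) is legal.
#' @export
root_pixel_count <- function(mask) {
  stopifnot(inherits(mask, "root_mask"))
  sum(mask$pixels)
}

#' Load a binary segmented root image
#'
#' Reads an 8-bit grayscale or RGB PNG/TIFF and binarises it at the midpoint
#' of its intensity range. Segmentation tools conventionally store root
#' pixels as the dark (black) class; `polarity` controls how foreground is
#' decided:
#'
#' * `"dark_is_root"` — pixels below the mid-intensity threshold are roots;
#' * `"light_is_root"` — pixels above it are roots;
#' * `"auto"` — the minority class after thresholding is taken to be the
#'   roots, since roots occupy a minority of a well-framed image.
#'
#' Images with more than two distinct values (e.g. anti-aliased
#' segmentations) are thresholded at mid-range and a message is emitted.
#'
#' @param path Path to a PNG or TIFF file.
#' @param polarity `"dark_is_root"`, `"light_is_root"` or `"auto"`.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param environment Capture environment recorded on the mask.
#'
#' @return A [root_mask()].
#' @export
load_mask <- function(path, polarity = c("auto", "dark_is_root", "light_is_root"),
                      sample_id = NULL,
                      environment = c("synthetic", "glasshouse", "field")) {
  polarity <- match.arg(polarity)
  environment <- match.arg(environment)
  if (!file.exists(path)) {
    abort(sprintf("cannot read mask: no such file '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format '%s' for '%s' (PNG or TIFF expected)", ext, path))
  )
  if (length(dim(img)) == 3L) {
    # RGB(A): luminance average of the colour channels
    img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE], c(1, 2), mean)
  }
  vals <- unique(as.vector(img))
  if (length(vals) == 1L && polarity == "auto") {
    abort(sprintf(
      "mask '%s' has a single uniform intensity; polarity = 'auto' is ambiguous",
      path
    ))
  }
  if (length(vals) > 2L) {
    inform(sprintf(
      "mask '%s' has %d distinct intensities; thresholding at mid-range",
      path, length(vals)
    ))
  }
  rng <- range(img)
  # uniform image: fall back to the representable mid-intensity so an
  # all-light frame stays empty under dark_is_root
  thr <- if (rng[1] == rng[2]) 0.5 else mean(rng)
  dark <- img <= thr
  root <- switch(polarity,
    dark_is_root = dark,
    light_is_root = !dark,
    auto = if (sum(dark) <= sum(!dark)) dark else !dark
  )
  root_mask(root,
    sample_id = sample_id %||% tools::file_path_sans_ext(basename(path)),
    source_path = path, environment = environment
  )
}

#' Write a mask as an 8-bit PNG (root = black, background = white)
#'
#' @param mask A [root_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "root_mask"))
  img <- matrix(1, mask$height, mask$width)
  img[mask$pixels] <- 0
  png::writePNG(img, path)
  invisible(path)
}

#' Merge scans of one sample into a composite mask
#'
#' Field minirhizotron tubes are imaged as several scans per tube; the scans
#' are stacked vertically, in list order (first scan on top), into one
#' composite whose height is the sum of scan heights. Root-pixel counts are
#' conserved exactly.
#'
#' @param scans List of [root_mask()] objects sharing a common width.
#' @param sample_id Identifier for the composite (default: first scan's id).
#' @return A composite [root_mask()].
#' @export
#'
#' @examples
#' a <- root_mask(matrix(FALSE, 4, 3))
#' b <- root_mask(matrix(TRUE, 2, 3))
#' merge_scans(list(a, b))$height
merge_scans <- function(scans, sample_id = NULL) {
  if (inherits(scans, "root_mask")) scans <- list(scans)
  stopifnot(length(scans) >= 1L, all(vapply(scans, inherits, logical(1), "root_mask")))
  widths <- vapply(scans, function(m) m$width, integer(1))
  if (length(unique(widths)) > 1L) {
    abort(sprintf(
      "cannot merge scans with mismatched widths: %s",
      paste(widths, collapse = ", ")
    ))
  }
  pixels <- do.call(rbind, lapply(scans, function(m) m$pixels))
  env <- scans[[1L]]$environment
  root_mask(pixels,
    sample_id = sample_id %||% scans[[1L]]$sample_id,
    environment = env
  )
}

#' Merge a directory-load worth of scans triplet-wise
#'
#' Groups an ordered list of masks into consecutive groups of `per_composite`
#' scans and merges each group with [merge_scans()]. The list length must be
#' an exact multiple of `per_composite`.
#'
#' @param scans Ordered list of [root_mask()] objects.
#' @param per_composite Scans per composite (3 for the usual field triplets).
#' @param sample_ids Optional character vector of composite ids.
#' @return List of composite [root_mask()] objects.
#' @export
merge_scan_groups <- function(scans, per_composite = 3L, sample_ids = NULL) {
  n <- length(scans)
  if (n %% per_composite != 0L) {
    abort(sprintf("%d scans cannot be grouped into composites of %d", n, per_composite))
  }
  n_out <- n %/% per_composite
  ids <- sample_ids %||% sprintf("composite_%03d", seq_len(n_out))
  lapply(seq_len(n_out), function(i) {
    idx <- ((i - 1L) * per_composite + 1L):(i * per_composite)
    merge_scans(scans[idx], sample_id = ids[[i]])
  })
}
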