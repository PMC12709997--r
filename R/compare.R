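#' Feature-column matrix utilities
#'
#' The comparison statistics in this module treat *features as the units of
#' analysis*: each feature column (over samples) is z-scored and the
#' Euclidean distances between feature columns are studied. This is the
#' reading under which a 27-trait set and a 23-trait set each yield a
#' population of feature-pair distances, and under which a PERMANOVA
#' grouping of trait-set labels (labels attach to features, not samples)
#' is coherent.
#'
#' @param data Data frame; non-numeric columns are dropped with a message.
#' @return Numeric matrix (samples x features) of z-scored columns;
#'   constant columns are dropped with a warning.
#' @keywords internal
.feature_matrix <- function(data) {
  num <- dplyr::select(as.data.frame(data), dplyr::where(is.numeric))
  if (ncol(num) < ncol(as.data.frame(data))) {
    dropped <- setdiff(names(data), names(num))
    inform(sprintf("ignoring non-numeric columns: %s", paste(dropped, collapse = ", ")))
  }
  m <- as.matrix(num)
  if (anyNA(m)) {
    keep <- complete.cases(m)
    warn(sprintf("dropping %d rows with missing values", sum(!keep)))
    m <- m[keep, , drop = FALSE]
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf(
      "excluding constant features (z-score undefined): %s",
      paste(colnames(m)[sds == 0], collapse = ", ")
    ))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(m)
}

#' Internal variability of a feature set
#'
#' Mean and standard deviation of the Euclidean distances between all
#' unordered pairs of z-scored feature columns. Higher values mean the
#' features are more mutually dissimilar, i.e. the set carries more
#' non-redundant information.
#'
#' @param data Data frame of samples x features (numeric columns used).
#' @return Tibble with `n_features`, `n_pairs`, `mean_distance`,
#'   `sd_distance`.
#' @export
#'
#' @examples
#' internal_variability(as.data.frame(matrix(rnorm(200), 20)))
internal_variability <- function(data) {
  m <- .feature_matrix(data)
  if (ncol(m) < 2L) abort("need at least two non-constant feature columns")
  d <- dist(t(m))
  tibble::tibble(
    n_features = ncol(m),
    n_pairs = length(d),
    mean_distance = mean(d),
    sd_distance = stats::sd(d)
  )
}

#' PERMANOVA between feature sets
#'
#' Permutational multivariate analysis of variance on the matrix of
#' Euclidean distances between z-scored feature columns, grouped by a
#' per-feature label (e.g. which trait set a feature belongs to). The
#' pseudo-F statistic is computed from the distance matrix by the standard
#' decomposition (total and within-group sums of squared distances), and
#' its null distribution by permuting the feature labels; the p-value uses
#' the add-one estimator `(1 + #{F* >= F}) / (n_permutations + 1)`.
#'
#' @param data Data frame of samples x features (numeric columns used).
#' @param groups Per-feature group labels, recycled against the *retained*
#'   numeric feature columns, or a named vector matched by column name.
#' With `method = "exhaustive"` (two groups only) every distinct relabelling
#' is enumerated instead and the p-value is the exact proportion of
#' relabellings (the observed one included) with `F* >= F`.
#'
#' @param n_permutations Number of label permutations (default 999;
#'   ignored for the exhaustive method).
#' @param seed Integer seed for the permutations.
#' @param method `"sampled"` Monte-Carlo permutations or `"exhaustive"`
#'   enumeration (feasible for small feature counts, two groups).
#' @return A `rootart_permanova` object: list with `pseudo_f`, `p_value`,
#'   `n_permutations`, `df_between`, `df_within`, `seed`.
#' @export
permanova_features <- function(data, groups, n_permutations = 999L, seed = 0L,
                               method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  m <- .feature_matrix(data)
  if (!is.null(names(groups))) {
    groups <- groups[colnames(m)]
  }
  if (length(groups) != ncol(m)) {
    abort(sprintf(
      "groups has length %d but %d feature columns were retained",
      length(groups), ncol(m)
    ))
  }
  g <- factor(groups)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    abort("need at least two groups with at least two features each")
  }
  d2 <- as.matrix(dist(t(m)))^2
  if (all(d2 == 0)) abort("degenerate input: all feature distances are zero")
  f_obs <- .pseudo_f(d2, g)
  if (method == "exhaustive") {
    if (nlevels(g) != 2L) {
      abort("exhaustive enumeration is implemented for two groups")
    }
    n1 <- sum(g == levels(g)[1])
    picks <- utils::combn(length(g), n1)
    if (ncol(picks) > 1e5) abort("too many relabellings to enumerate")
    fs <- apply(picks, 2, function(idx) {
      gg <- factor(replace(rep(levels(g)[2], length(g)), idx, levels(g)[1]),
        levels = levels(g))
      .pseudo_f(d2, gg)
    })
    p <- mean(fs >= f_obs - 1e-12)
    n_permutations <- ncol(picks)
  } else {
    perm_f <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        .pseudo_f(d2, sample(g))
      }, numeric(1))
    })
    p <- (1 + sum(perm_f >= f_obs)) / (n_permutations + 1)
  }
  structure(
    list(
      pseudo_f = f_obs,
      p_value = p,
      n_permutations = as.integer(n_permutations),
      df_between = nlevels(g) - 1L,
      df_within = ncol(m) - nlevels(g),
      seed = seed
    ),
    class = "rootart_permanova"
  )
}

# pseudo-F from a squared-distance matrix and a grouping factor:
# SS_total = sum_{i<j} d2_ij / N; SS_within = sum over groups of the same
# quantity inside the group; F = (SS_between/(g-1)) / (SS_within/(N-g)).
.pseudo_f <- function(d2, g) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (nlevels(g) - 1)) / (ss_within / (n - nlevels(g)))
}

#' @export
print.rootart_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (feature-column distances)\n  pseudo-F = %.3f (df %d, %d)\n  p = %.4g (%d permutations)\n",
    x$pseudo_f, x$df_between, x$df_within, x$p_value, x$n_permutations
  ))
  invisible(x)
}

#' @export
tidy.rootart_permanova <- function(x, ...) {
  tibble::tibble(
    statistic = x$pseudo_f, p.value = x$p_value,
    df = x$df_between, df.residual = x$df_within,
    n.permutations = x$n_permutations
  )
}

#' Pearson correlation matrix with p-values
#'
#' All pairwise Pearson correlations between numeric columns, with
#' two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Constant columns give `NA`.
#'
#' @param data Data frame of samples x features.
#' @return List with matrices `r` (diagonal exactly 1) and `p`
#'   (diagonal `NA`), plus `n` (sample count).
#' @export
correlation_matrix <- function(data) {
  num <- dplyr::select(as.data.frame(data), dplyr::where(is.numeric))
  m <- as.matrix(num)
  n <- nrow(m)
  if (n < 3L) abort("need at least 3 samples for correlation p-values")
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Cluster-separation indices
#'
#' Four standard internal validation indices for a labelled point set:
#' mean silhouette width, Davies-Bouldin (lower is better),
#' Calinski-Harabasz, and the Dunn index (minimum between-cluster
#' point-pair distance over maximum within-cluster diameter). Singleton
#' classes take silhouette 0 by the usual convention (a message notes it).
#'
#' @param data Data frame or matrix of numeric coordinates/features.
#' @param labels Class labels (>= 2 classes).
#' @return Tibble with `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`, `dunn`.
#' @export
separation_scores <- function(data, labels) {
  m <- as.matrix(dplyr::select(as.data.frame(data), dplyr::where(is.numeric)))
  g <- factor(labels)
  stopifnot(nrow(m) == length(g))
  if (nlevels(g) < 2L) abort("need at least two classes")
  if (any(table(g) < 1L)) abort("empty class")
  if (any(table(g) == 1L)) inform("singleton class: silhouette 0 by convention")
  d <- dist(m)
  sil <- mean(cluster::silhouette(as.integer(g), d)[, "sil_width"])
  dm <- as.matrix(d)
  k <- nlevels(g)
  n <- nrow(m)
  centroids <- apply(m, 2, function(col) tapply(col, g, mean))
  if (is.null(dim(centroids))) centroids <- matrix(centroids, nrow = k)
  grand <- colMeans(m)
  # Davies-Bouldin: within-cluster mean distance to centroid, pairwise worst ratio
  s_i <- vapply(seq_len(k), function(i) {
    idx <- which(as.integer(g) == i)
    mean(sqrt(rowSums((m[idx, , drop = FALSE] -
      matrix(centroids[i, ], length(idx), ncol(m), byrow = TRUE))^2)))
  }, numeric(1))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      mij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      (s_i[i] + s_i[j]) / mij
    }, numeric(1)))
  }, numeric(1)))
  # Calinski-Harabasz
  sizes <- as.integer(table(g))
  ssb <- sum(sizes * rowSums((centroids -
    matrix(grand, k, ncol(m), byrow = TRUE))^2))
  ssw <- sum(vapply(seq_len(k), function(i) {
    idx <- which(as.integer(g) == i)
    sum((m[idx, , drop = FALSE] -
      matrix(centroids[i, ], length(idx), ncol(m), byrow = TRUE))^2)
  }, numeric(1)))
  ch <- (ssb / (k - 1)) / (ssw / (n - k))
  # Dunn
  gi <- as.integer(g)
  between <- Inf
  within <- 0
  for (i in seq_len(k)) {
    ii <- gi == i
    within <- max(within, max(dm[ii, ii, drop = FALSE]))
    for (j in seq_len(k)) {
      if (j > i) between <- min(between, min(dm[ii, gi == j, drop = FALSE]))
    }
  }
  tibble::tibble(
    silhouette = sil, davies_bouldin = db,
    calinski_harabasz = ch, dunn = between / within
  )
}

#' Two-dimensional ordination of a sample-by-feature table
#'
#' Thin wrappers around the standard routines: principal component
#' analysis (`prcomp`, centred, optionally scaled) and classical
#' multidimensional scaling (`cmdscale` on Euclidean distances). PCA
#' additionally reports per-component explained-variance fractions.
#' A t-SNE backend is not bundled; requesting it raises an informative
#' error naming the gap rather than silently substituting another method.
#'
#' @param data Data frame of samples x features (numeric columns used).
#' @param method `"pca"` or `"mds"` (`"tsne"` is recognised but has no
#'   backend).
#' @param scale. Scale columns to unit variance before PCA (default TRUE).
#' @param seed Unused for the deterministic methods; kept for interface
#'   stability.
#' @return Tibble with `dim1`, `dim2` (one row per sample); for PCA the
#'   attribute `"explained_variance"` holds all component fractions.
#' @export
ordinate <- function(data, method = c("pca", "mds", "tsne"), scale. = TRUE,
                     seed = 0L) {
  method <- match.arg(method)
  num <- as.matrix(dplyr::select(as.data.frame(data), dplyr::where(is.numeric)))
  if (nrow(num) < 3L) abort("need at least 3 samples to ordinate")
  if (method == "tsne") {
    abort(paste(
      "no t-SNE backend is available in this installation;",
      "use method = 'pca' or 'mds'"
    ))
  }
  if (method == "pca") {
    keep <- apply(num, 2, sd) > 0
    fit <- prcomp(num[, keep, drop = FALSE], center = TRUE, scale. = scale.)
    k <- min(2L, ncol(fit$x))
    out <- tibble::tibble(
      dim1 = fit$x[, 1],
      dim2 = if (k >= 2) fit$x[, 2] else 0
    )
    ev <- fit$sdev^2 / sum(fit$sdev^2)
    attr(out, "explained_variance") <- ev
    return(out)
  }
  xy <- cmdscale(dist(num), k = 2)
  tibble::tibble(dim1 = xy[, 1], dim2 = xy[, 2])
}
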