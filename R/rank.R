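#' Trimmed mean
#'
#' Drops `floor(trim * n)` smallest and as many largest observations, then
#' averages the rest. `trim = 0` is the ordinary mean. All robust drought
#' metrics in this module use the 10 % trimmed mean.
#'
#' @param x Numeric vector (non-empty; `NA` removed with a warning).
#' @param trim Per-tail trim fraction in `[0, 0.5)`.
#' @return Scalar trimmed mean.
#' @export
#'
#' @examples
#' trimmed_mean(1:10, 0.10) # mean of 2..9 = 5.5
trimmed_mean <- function(x, trim = 0.10) {
  if (anyNA(x)) {
    warn("removing missing values before trimming")
    x <- x[!is.na(x)]
  }
  if (!length(x)) abort("trimmed_mean of an empty vector")
  stopifnot(trim >= 0, trim < 0.5)
  k <- floor(trim * length(x))
  if (k > 0) {
    x <- sort(x)[(k + 1):(length(x) - k)]
  }
  mean(x)
}

#' Robust drought-response metrics per genotype and trait
#'
#' From replicate physiological measurements under control and drought,
#' computes per genotype `i` and trait `j` (on 10 % trimmed means `M`):
#'
#' * Robust Difference: `RD_ij = |M_ij,control - M_ij,drought|`
#' * Robust Stress Susceptibility Index:
#'   `SSI_ij = 1 - M_ij,drought / M_ij,control`
#'
#' SSI is undefined (reported `NA`, with a warning) when the control
#' trimmed mean is zero. Negative SSI (improvement under drought) is
#' retained, not clipped.
#'
#' @param data Long data frame of replicate measurements with columns
#'   `genotype`, `treatment` (values `control` / `drought`), plus one
#'   numeric column per trait.
#' @param traits Character vector of trait column names; defaults to all
#'   numeric columns.
#' @param trim Per-tail trim fraction (default 0.10).
#' @return Tibble with columns `genotype`, `trait`, `m_control`,
#'   `m_drought`, `rd`, `ssi`.
#' @export
drought_metrics <- function(data, traits = NULL, trim = 0.10) {
  data <- as.data.frame(data)
  stopifnot(all(c("genotype", "treatment") %in% names(data)))
  if (!all(data$treatment %in% c("control", "drought"))) {
    abort("treatment must be 'control' or 'drought'")
  }
  traits <- traits %||%
    names(dplyr::select(data, dplyr::where(is.numeric)))
  missing_both <- setdiff(
    unique(data$genotype),
    intersect(
      unique(data$genotype[data$treatment == "control"]),
      unique(data$genotype[data$treatment == "drought"])
    )
  )
  if (length(missing_both)) {
    abort(sprintf(
      "genotypes lacking one treatment: %s",
      paste(missing_both, collapse = ", ")
    ))
  }
  out <- tidyr::expand_grid(
    genotype = unique(data$genotype), trait = traits
  )
  out <- dplyr::mutate(
    out,
    m_control = purrr::map2_dbl(.data$genotype, .data$trait, function(g, tr) {
      trimmed_mean(data[data$genotype == g & data$treatment == "control", tr], trim)
    }),
    m_drought = purrr::map2_dbl(.data$genotype, .data$trait, function(g, tr) {
      trimmed_mean(data[data$genotype == g & data$treatment == "drought", tr], trim)
    }),
    rd = abs(.data$m_control - .data$m_drought),
    ssi = dplyr::if_else(
      .data$m_control != 0,
      1 - .data$m_drought / .data$m_control,
      NA_real_
    )
  )
  if (any(is.na(out$ssi))) {
    warn("SSI undefined where the control trimmed mean is zero; reported NA")
  }
  out
}

#' Default trait weights for rank scores
#'
#' Stomatal conductance traits carry weight 2 (they respond earliest and
#' most specifically to water deficit); relative water content and tiller
#' number carry weight 1.
#'
#' @return Named numeric vector.
#' @export
default_trait_weights <- function() {
  c(g_s_1 = 2, g_s_2 = 2, RWC = 1, Tiller_no = 1)
}

#' Weighted genotype rank scores
#'
#' Within each trait, genotypes are ranked ascending on the metric
#' (smaller stress response = more tolerant = rank 1; ties receive average
#' ranks), then combined as weighted rank sums:
#'
#' * `RANK1_i = sum_j rank(RD_ij) * w_j`
#' * `RANK2_i = sum_j rank(SSI_ij) * w_j`
#' * `RANK3_i = RANK1_i + RANK2_i`
#'
#' Lower scores indicate higher drought tolerance. A trait with any
#' missing metric cell is omitted from the sums for all genotypes (logged).
#'
#' @param metrics Output of [drought_metrics()].
#' @param weights Named trait weights (default [default_trait_weights()];
#'   unnamed traits get weight 1).
#' @return A `rootart_rank` object: tibble with `genotype`, `rank1`,
#'   `rank2`, `rank3`, ordered by `rank3`.
#' @export
rank_scores <- function(metrics, weights = default_trait_weights()) {
  stopifnot(all(c("genotype", "trait", "rd", "ssi") %in% names(metrics)))
  if (length(unique(metrics$genotype)) < 2L) {
    abort("need at least two genotypes to rank")
  }
  bad <- unique(metrics$trait[is.na(metrics$rd) | is.na(metrics$ssi)])
  if (length(bad)) {
    inform(sprintf(
      "omitting traits with missing metric cells: %s",
      paste(bad, collapse = ", ")
    ))
    metrics <- metrics[!metrics$trait %in% bad, ]
  }
  w <- function(tr) {
    ifelse(tr %in% names(weights), unname(weights[tr]), 1)
  }
  ranked <- metrics |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(
      rank_rd = rank(.data$rd, ties.method = "average"),
      rank_ssi = rank(.data$ssi, ties.method = "average"),
      w = w(.data$trait)
    ) |>
    dplyr::ungroup()
  out <- ranked |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      rank1 = sum(.data$rank_rd * .data$w),
      rank2 = sum(.data$rank_ssi * .data$w),
      .groups = "drop"
    ) |>
    dplyr::mutate(rank3 = .data$rank1 + .data$rank2) |>
    dplyr::arrange(.data$rank3)
  class(out) <- c("rootart_rank", class(out))
  attr(out, "per_trait") <- ranked
  out
}

#' @export
tidy.rootart_rank <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rootart_rank")
  attr(out, "per_trait") <- NULL
  out
}

#' Cliff's delta effect size
#'
#' Nonparametric effect size between two samples:
#' `delta = (#{x_a > y_b} - #{x_a < y_b}) / (|x| * |y|)` over all cross
#' pairs, in `[-1, 1]`. Computed by full pair enumeration (its defining
#' formula).
#'
#' @param x,y Non-empty numeric samples.
#' @return Scalar in `[-1, 1]`.
#' @export
#'
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 2)) # 0
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  cmp <- sign(outer(x, y, "-"))
  sum(cmp) / (length(x) * length(y))
}

#' Normality-gated test battery
#'
#' For each trait: Shapiro-Wilk normality per group at alpha = 0.05; if all
#' groups pass, one-way ANOVA with Tukey's HSD post-hoc, otherwise
#' Kruskal-Wallis with Dunn's post-hoc (rank-sum z tests with tie
#' correction, Holm-adjusted). Groups with fewer than 3 observations skip
#' the normality test and force the nonparametric branch (logged in the
#' report).
#'
#' @param data Data frame with a grouping column and numeric trait columns.
#' @param group Name of the grouping column.
#' @param traits Trait column names (default: all numeric columns).
#' @param alpha Normality gate level.
#' @return Tibble with one row per trait: `trait`, `branch`
#'   (`"anova"`/`"kruskal"`), `statistic`, `p_value`, `all_normal`,
#'   `forced_nonparametric`, and a `posthoc` list-column of pairwise
#'   comparisons.
#' @export
test_battery <- function(data, group, traits = NULL, alpha = 0.05) {
  data <- as.data.frame(data)
  stopifnot(group %in% names(data))
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("need at least two groups")
  traits <- traits %||%
    setdiff(names(dplyr::select(data, dplyr::where(is.numeric))), group)
  purrr::map_dfr(traits, function(tr) {
    x <- data[[tr]]
    ok <- !is.na(x)
    xi <- x[ok]
    gi <- droplevels(g[ok])
    sizes <- table(gi)
    forced <- any(sizes < 3L)
    all_normal <- if (forced) {
      FALSE
    } else {
      all(vapply(levels(gi), function(lev) {
        v <- xi[gi == lev]
        if (length(unique(v)) == 1L) return(FALSE)
        shapiro.test(v)$p.value >= alpha
      }, logical(1)))
    }
    if (all_normal) {
      fit <- aov(xi ~ gi)
      an <- summary(fit)[[1]]
      tuk <- as.data.frame(TukeyHSD(fit)$gi)
      posthoc <- tibble::tibble(
        comparison = rownames(tuk),
        estimate = tuk$diff, p_adj = tuk$`p adj`
      )
      tibble::tibble(
        trait = tr, branch = "anova",
        statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
        all_normal = TRUE, forced_nonparametric = FALSE,
        posthoc = list(posthoc)
      )
    } else {
      kw <- kruskal.test(xi, gi)
      tibble::tibble(
        trait = tr, branch = "kruskal",
        statistic = unname(kw$statistic), p_value = kw$p.value,
        all_normal = FALSE, forced_nonparametric = forced,
        posthoc = list(dunn_test(xi, gi))
      )
    }
  })
}

#' Dunn's post-hoc test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with
#' the usual tie correction, and Holm-adjusted p-values.
#'
#' @param x Numeric response.
#' @param g Grouping factor.
#' @param method Multiplicity adjustment passed to [stats::p.adjust()].
#' @return Tibble: `comparison`, `z`, `p_adj`.
#' @export
dunn_test <- function(x, g, method = "holm") {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(p) {
    i <- p[1]
    j <- p[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    tibble::tibble(comparison = paste(i, j, sep = "-"), z = z)
  })
  res$p_adj <- p.adjust(2 * pnorm(abs(res$z), lower.tail = FALSE), method)
  res
}

#' Cluster genotypes into tolerant / susceptible groups
#'
#' Runs up to five clustering algorithms (K-means, agglomerative
#' hierarchical with Ward linkage, Gaussian mixture, spectral, and a
#' compact BIRCH: threshold-based cluster-feature absorption followed by
#' agglomerative merging of the CF centroids) on z-scored physiological
#' features, each producing exactly two clusters. Internal validation uses
#' [separation_scores()]; when reference labels are supplied, external
#' validation (adjusted Rand index, normalised mutual information,
#' Fowlkes-Mallows) is added, with cluster orientation chosen to maximise
#' agreement. Failures of individual algorithms are recorded and do not
#' stop the others.
#'
#' @param data Data frame of observations x numeric features (e.g. one row
#'   per plant with its physiological traits under one treatment).
#' @param algorithms Subset of
#'   `c("kmeans", "agglomerative", "gmm", "spectral", "birch")`.
#' @param reference Optional reference labels for external validation.
#' @param seed Integer seed.
#' @return List with `assignments` (tibble: one column per algorithm) and
#'   `validation` (tibble: one row per algorithm with internal and, when
#'   available, external metrics plus an `error` column).
#' @export
cluster_genotypes <- function(data,
                              algorithms = c(
                                "kmeans", "agglomerative", "gmm",
                                "spectral", "birch"
                              ),
                              reference = NULL, seed = 0L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  m <- as.matrix(dplyr::select(as.data.frame(data), dplyr::where(is.numeric)))
  if (nrow(m) < 4L) abort("need at least 4 observations")
  z <- scale(m[, apply(m, 2, sd) > 0, drop = FALSE])
  runs <- purrr::map(algorithms, function(alg) {
    tryCatch(
      list(labels = .cluster2(z, alg, seed), error = NA_character_),
      error = function(e) list(labels = NULL, error = conditionMessage(e))
    )
  })
  names(runs) <- algorithms
  assignments <- purrr::map_dfc(runs, function(r) {
    if (is.null(r$labels)) rep(NA_integer_, nrow(z)) else r$labels
  })
  validation <- purrr::imap_dfr(runs, function(r, alg) {
    if (is.null(r$labels) || length(unique(r$labels)) < 2L) {
      return(tibble::tibble(
        algorithm = alg, silhouette = NA_real_, davies_bouldin = NA_real_,
        calinski_harabasz = NA_real_, dunn = NA_real_,
        ari = NA_real_, nmi = NA_real_, fms = NA_real_,
        error = r$error %||% "single cluster"
      ))
    }
    sep <- separation_scores(as.data.frame(z), r$labels)
    ext <- if (!is.null(reference)) {
      external_validation(reference, r$labels)
    } else {
      tibble::tibble(ari = NA_real_, nmi = NA_real_, fms = NA_real_)
    }
    dplyr::bind_cols(
      tibble::tibble(algorithm = alg), sep, ext,
      tibble::tibble(error = r$error)
    )
  })
  list(assignments = assignments, validation = validation)
}

.cluster2 <- function(z, alg, seed) {
  switch(alg,
    kmeans = withr::with_seed(seed, {
      stats::kmeans(z, centers = 2, nstart = 10)$cluster
    }),
    agglomerative = cutree(hclust(dist(z), method = "ward.D2"), k = 2),
    gmm = {
      mclustBIC <- mclust::mclustBIC
      fit <- suppressWarnings(mclust::Mclust(z, G = 2, verbose = FALSE))
      if (is.null(fit)) abort("mixture fit failed")
      as.integer(fit$classification)
    },
    spectral = {
      if (!requireNamespace("kernlab", quietly = TRUE)) {
        abort("kernlab not available for spectral clustering")
      }
      withr::with_seed(seed, {
        as.integer(kernlab::specc(as.matrix(z), centers = 2))
      })
    },
    birch = birch_cluster(z, k = 2)
  )
}

#' Compact BIRCH clustering
#'
#' A single-level BIRCH: observations are absorbed in input order into
#' cluster features (count, linear sum, squared sum) whenever the radius of
#' the would-be merged CF stays under `threshold` (otherwise a new CF
#' opens); the CF centroids are then merged down to `k` groups by Ward
#' agglomeration and observations inherit their CF's group.
#'
#' @param x Numeric matrix.
#' @param k Final number of clusters.
#' @param threshold CF radius threshold (0.5 by default, on the z-scored
#'   feature scale used by [cluster_genotypes()]).
#' @return Integer labels 1..k.
#' @export
birch_cluster <- function(x, k = 2, threshold = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  cf_n <- integer(0)
  cf_ls <- NULL # linear sums, one row per CF
  cf_ss <- numeric(0) # squared norms
  assign_cf <- integer(n)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    placed <- FALSE
    if (length(cf_n)) {
      cent <- cf_ls / cf_n
      d2 <- rowSums((cent - matrix(xi, length(cf_n), ncol(x), byrow = TRUE))^2)
      j <- which.min(d2)
      # radius of merged CF: sqrt(E||x - mu||^2)
      nn <- cf_n[j] + 1L
      ls <- cf_ls[j, ] + xi
      ss <- cf_ss[j] + sum(xi^2)
      rad2 <- ss / nn - sum((ls / nn)^2)
      if (sqrt(max(rad2, 0)) <= threshold) {
        cf_n[j] <- nn
        cf_ls[j, ] <- ls
        cf_ss[j] <- ss
        assign_cf[i] <- j
        placed <- TRUE
      }
    }
    if (!placed) {
      cf_n <- c(cf_n, 1L)
      cf_ls <- rbind(cf_ls, xi)
      cf_ss <- c(cf_ss, sum(xi^2))
      assign_cf[i] <- length(cf_n)
    }
  }
  cents <- cf_ls / cf_n
  if (length(cf_n) <= k) {
    group <- seq_along(cf_n)
  } else {
    group <- cutree(hclust(dist(cents), method = "ward.D2"), k = k)
  }
  as.integer(group[assign_cf])
}

#' External cluster-validation metrics
#'
#' Adjusted Rand index, normalised mutual information (arithmetic-mean
#' normalisation) and Fowlkes-Mallows score between a reference labelling
#' and a clustering.
#'
#' @param reference,labels Two labellings of the same observations.
#' @return Tibble with `ari`, `nmi`, `fms`.
#' @export
external_validation <- function(reference, labels) {
  a <- factor(reference)
  b <- factor(labels)
  stopifnot(length(a) == length(b))
  ct <- table(a, b)
  n <- length(a)
  # ARI
  sum_comb <- function(v) sum(choose(v, 2))
  idx <- sum_comb(as.vector(ct))
  e1 <- sum_comb(rowSums(ct))
  e2 <- sum_comb(colSums(ct))
  expected <- e1 * e2 / choose(n, 2)
  ari <- if (abs((e1 + e2) / 2 - expected) < 1e-12) {
    1
  } else {
    (idx - expected) / ((e1 + e2) / 2 - expected)
  }
  # NMI
  p <- ct / n
  pa <- rowSums(p)
  pb <- colSums(p)
  hi <- function(v) -sum(v[v > 0] * log(v[v > 0]))
  mi <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
    }
  }
  denom <- (hi(pa) + hi(pb)) / 2
  nmi <- if (denom > 0) unname(mi / denom) else 1
  # Fowlkes-Mallows
  tp <- idx
  fp <- e2 - idx
  fn <- e1 - idx
  fms <- if ((tp + fp) > 0 && (tp + fn) > 0) {
    sqrt(tp / (tp + fp)) * sqrt(tp / (tp + fn))
  } else {
    0
  }
  tibble::tibble(ari = ari, nmi = nmi, fms = fms)
}
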