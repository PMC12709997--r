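test_that("internal variability matches a brute-force pairwise computation", {
  df <- data.frame(
    a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(10, 20, 15, 5)
  )
  z <- scale(as.matrix(df))
  manual <- c(
    sqrt(sum((z[, 1] - z[, 2])^2)),
    sqrt(sum((z[, 1] - z[, 3])^2)),
    sqrt(sum((z[, 2] - z[, 3])^2))
  )
  iv <- internal_variability(df)
  expect_equal(iv$mean_distance, mean(manual))
  expect_equal(iv$sd_distance, sd(manual))
  expect_equal(iv$n_pairs, 3)

  dup <- data.frame(a = 1:5, b = 1:5)
  expect_equal(internal_variability(dup)$mean_distance, 0)
})

test_that("internal variability is invariant to sample order and affine rescale", {
  withr::with_seed(3, {
    df <- as.data.frame(matrix(rnorm(80), 10))
  })
  base <- internal_variability(df)
  shuffled <- internal_variability(df[sample(10), ])
  rescaled <- internal_variability(
    as.data.frame(sweep(sweep(as.matrix(df), 2, c(2, 5, 1, 9, 3, 7, 4, 6), "*"), 2, 1:8, "+"))
  )
  expect_equal(shuffled$mean_distance, base$mean_distance)
  expect_equal(rescaled$mean_distance, base$mean_distance)

  cst <- cbind(df, k = 1)
  expect_warning(iv <- internal_variability(cst), "constant")
  expect_equal(iv$n_features, 8)
})

test_that("permanova matches exhaustive enumeration and an independent oracle", {
  withr::with_seed(5, {
    m <- cbind(
      matrix(rnorm(30, 0), 10, 3),
      matrix(rnorm(30, 2), 10, 3)
    )
  })
  colnames(m) <- paste0("f", 1:6)
  groups <- rep(c("A", "B"), each = 3)

  exact <- permanova_features(as.data.frame(m), groups, method = "exhaustive")
  expect_equal(exact$n_permutations, choose(6, 3))

  # independent exhaustive oracle written out directly
  z <- scale(m)
  d2 <- as.matrix(dist(t(z)))^2
  fs <- apply(utils::combn(6, 3), 2, function(idx) {
    g <- factor(ifelse(seq_len(6) %in% idx, "A", "B"))
    n <- 6
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      sub <- d2[i, i, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  })
  f_obs <- fs[1] # first combn column is the observed labelling
  expect_equal(exact$pseudo_f, f_obs)
  expect_equal(exact$p_value, mean(fs >= f_obs - 1e-12))

  # sampled p agrees with the exact p up to Monte-Carlo error
  sampled <- permanova_features(as.data.frame(m), groups,
    n_permutations = 9999, seed = 1
  )
  expect_equal(sampled$pseudo_f, exact$pseudo_f)
  expect_lt(abs(sampled$p_value - exact$p_value), 0.02)
})

test_that("permanova pseudo-F agrees with vegan on the transposed problem", {
  skip_if_not_installed("vegan")
  withr::with_seed(8, {
    m <- matrix(rnorm(96), 12, 8)
  })
  colnames(m) <- paste0("f", 1:8)
  groups <- rep(c("A", "B"), each = 4)
  ours <- permanova_features(as.data.frame(m), groups,
    n_permutations = 999, seed = 2
  )
  # vegan treats rows as observations: hand it the z-scored columns as rows
  z <- t(scale(m))
  fit <- vegan::adonis2(dist(z) ~ g, data = data.frame(g = groups),
    permutations = 999)
  expect_equal(ours$pseudo_f, fit$F[1], tolerance = 1e-10)
  expect_lt(abs(ours$p_value - fit$`Pr(>F)`[1]), 0.05)
})

test_that("permanova is invariant to column order and saturates under shift", {
  withr::with_seed(11, {
    m <- matrix(rnorm(60), 10, 6)
  })
  colnames(m) <- paste0("f", 1:6)
  g <- c("A", "A", "A", "B", "B", "B")
  a <- permanova_features(as.data.frame(m), g, n_permutations = 99, seed = 1)
  perm <- c(4, 1, 6, 2, 5, 3)
  b <- permanova_features(as.data.frame(m[, perm]), g[perm],
    n_permutations = 99, seed = 1
  )
  expect_equal(a$pseudo_f, b$pseudo_f)

  # strongly distinct groups: group A columns echo one latent signal,
  # group B another, so within-group column distances collapse
  withr::with_seed(12, {
    u <- rnorm(10)
    v <- rnorm(10)
    sep <- cbind(
      u + matrix(rnorm(60, sd = 0.05), 10, 6),
      v + matrix(rnorm(60, sd = 0.05), 10, 6)
    )
  })
  colnames(sep) <- paste0("f", 1:12)
  big <- permanova_features(as.data.frame(sep), rep(c("A", "B"), each = 6),
    n_permutations = 99, seed = 1
  )
  expect_equal(big$p_value, 1 / 100) # minimum attainable at 99 permutations
})

test_that("degenerate and undersized permanova inputs error", {
  df <- as.data.frame(matrix(rnorm(40), 10, 4))
  expect_error(
    permanova_features(df, c("A", "A", "A", "B")),
    "two groups"
  )
  same <- as.data.frame(matrix(1:10, 10, 4))
  expect_error(
    suppressWarnings(permanova_features(same, rep(c("A", "B"), each = 2))),
    "degenerate|feature columns"
  )
})

test_that("correlation matrix reproduces direct formulas", {
  df <- data.frame(x = c(1, 3, 2, 5, 4), y = c(2, 1, 4, 3, 5))
  cm <- correlation_matrix(df)
  expect_equal(cm$r["x", "x"], 1)
  expect_equal(cm$r["x", "y"], cor(df$x, df$y))
  ct <- cor.test(df$x, df$y)
  expect_equal(cm$p["x", "y"], ct$p.value)

  neg <- data.frame(x = 1:6, y = -(1:6))
  expect_equal(correlation_matrix(neg)$r["x", "y"], -1)

  cst <- data.frame(x = 1:5, k = rep(2, 5))
  expect_true(is.na(correlation_matrix(cst)$r["x", "k"]))
})

test_that("separation scores match hand computation on a 4-point layout", {
  # two pairs on a line: class 1 at 0 and 1, class 2 at 10 and 11
  pts <- data.frame(x = c(0, 1, 10, 11), y = 0)
  g <- c(1, 1, 2, 2)
  sc <- separation_scores(pts, g)
  # silhouette: for point 0: a=1, b=(10+11)/2=10.5, s=(10.5-1)/10.5
  s1 <- (10.5 - 1) / 10.5
  s2 <- (9.5 - 1) / 9.5
  expect_equal(sc$silhouette, mean(c(s1, s2, s2, s1)))
  # Dunn: min between = 9, max within diameter = 1
  expect_equal(sc$dunn, 9)
  # Davies-Bouldin: s_i = 0.5 both, centroid gap 10
  expect_equal(sc$davies_bouldin, (0.5 + 0.5) / 10)
  # Calinski-Harabasz: ssb = 4 * 5^2 = 100 (x), ssw = 4 * 0.25 = 1
  expect_equal(sc$calinski_harabasz, (100 / 1) / (1 / 2))
})

test_that("separation scores behave at the structure/no-structure extremes", {
  withr::with_seed(2, {
    tight <- rbind(
      cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1)),
      cbind(rnorm(20, 50, 0.1), rnorm(20, 50, 0.1))
    )
    g <- rep(1:2, each = 20)
    sc <- separation_scores(as.data.frame(tight), g)
    expect_gt(sc$silhouette, 0.9)
    expect_gt(sc$dunn, 1)

    cloud <- matrix(rnorm(200), 100, 2)
    rand <- separation_scores(as.data.frame(cloud), sample(1:2, 100, TRUE))
    expect_lt(abs(rand$silhouette), 0.1)
  })
})

test_that("ordination wrappers preserve the expected geometry", {
  withr::with_seed(6, {
    v <- c(1, -2)
    coefs <- rnorm(20)
    rank1 <- outer(coefs, v) # rank-1: PC1 explains everything
  })
  emb <- ordinate(as.data.frame(rank1), "pca", scale. = FALSE)
  ev <- attr(emb, "explained_variance")
  expect_equal(ev[1], 1)
  expect_equal(sum(ev), 1)

  withr::with_seed(7, {
    pts <- matrix(rnorm(30), 15, 2)
  })
  centred <- scale(pts, scale = FALSE)
  pca <- ordinate(as.data.frame(centred), "pca", scale. = FALSE)
  # rigid rotation/reflection: pairwise distances are preserved
  expect_equal(
    as.matrix(dist(cbind(pca$dim1, pca$dim2))),
    as.matrix(dist(centred)),
    ignore_attr = TRUE
  )

  dup <- as.data.frame(rbind(pts, pts[1, ]))
  mds <- ordinate(dup, "mds")
  expect_equal(unlist(mds[16, ]), unlist(mds[1, ]))

  expect_error(ordinate(as.data.frame(pts), "tsne"), "t-SNE|backend")
  expect_error(ordinate(as.data.frame(pts), "umap"), "arg")
})
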