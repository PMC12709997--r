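small_grid <- function() data.frame(num_trees = 100L, max_depth = 0L, min_node_size = 1L)

test_that("augmentation doubles the table and leaves originals untouched", {
  tab <- simulate_feature_table(n_per_class = 25, seed = 1)
  aug <- augment_traits(tab, seed = 2)
  expect_equal(nrow(aug), 50 * 2)
  expect_equal(sum(!aug$.augmented), 50)
  expect_equal(
    dplyr::select(aug[!aug$.augmented, ], -".augmented"),
    tab
  )
  one <- augment_traits(tab[1, ], seed = 3)
  expect_equal(nrow(one), 2)
  expect_false(identical(one[[3]][1], one[[3]][2])) # noise applied

  chr <- dplyr::mutate(tab, bad_col = "x")
  expect_error(augment_traits(chr, seed = 1), "bad_col")
})

test_that("augmentation noise follows the configured law on the z scale", {
  # sample_id is copied onto synthetic rows, so each one can be joined back
  # to its bootstrap source, exposing the added noise directly
  n <- 10000
  withr::with_seed(99, {
    tab <- tibble::tibble(
      sample_id = as.character(seq_len(n)),
      label = factor(rep(c("a", "b"), each = n / 2)),
      f = rnorm(n, sd = 37)
    )
  })
  aug <- augment_traits(tab, noise_sigma = 0.02, seed = 4)
  synth <- aug[aug$.augmented, ]
  src <- tab$f[match(synth$sample_id, tab$sample_id)]
  resid <- synth$f - src
  expect_lt(abs(sd(resid) / sd(tab$f) - 0.02), 0.001)
  expect_equal(mean(resid) / sd(tab$f), 0, tolerance = 5e-4)
})

test_that("stratified splitting reproduces the ceiling arithmetic", {
  tab <- simulate_feature_table(n_per_class = 434, seed = 5)
  aug <- augment_traits(tab, seed = 5)
  expect_equal(nrow(aug), 1736)
  sp <- split_dev(aug, test_fraction = 0.2, seed = 5)
  expect_equal(nrow(sp$train), 1388)
  expect_equal(nrow(sp$test), 348)
  # per-class proportions preserved within one row
  cls <- table(aug$label)
  expect_true(all(abs(as.integer(table(sp$test$label)) - 0.2 * as.integer(cls)) <= 1))
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0)

  ten <- simulate_feature_table(n_per_class = 5, seed = 6)
  sp10 <- split_dev(ten, seed = 6)
  expect_equal(as.integer(table(sp10$test$label)), c(1, 1))

  again <- split_dev(aug, test_fraction = 0.2, seed = 5)
  expect_identical(sp$test_idx, again$test_idx)

  solo <- ten[c(1, 6), ]
  solo$label <- factor(c("a", "a"), levels = c("a", "b"))
  solo2 <- ten[1:3, ]
  solo2$label <- factor(c("a", "a", "b"))
  expect_error(split_dev(solo2, seed = 1), "single row")
})

test_that("the pipeline recovers a strong planted signal in CV and held out", {
  tab <- simulate_feature_table(
    n_per_class = 200, n_informative = 3,
    n_noise = 10, effect_size = 3, seed = 7
  )
  sp <- split_dev(tab, seed = 7)
  mod <- fit_pipeline(sp$train, grid = small_grid(), n_folds = 5, seed = 7)
  prec <- mod$cv_stability$mean[mod$cv_stability$metric == "precision"]
  expect_gt(prec, 0.95)
  ev <- evaluate_model(mod, sp$test)
  expect_gt(ev$metrics$accuracy, 0.9)
  # informative features survive selection
  expect_true(any(grepl("^inf_", mod$selected_features)))
})

test_that("label-permuted data yields chance-level cross-validation", {
  withr::with_seed(8, {
    accs <- vapply(1:5, function(i) {
      tab <- simulate_feature_table(
        n_per_class = 60, n_informative = 3,
        n_noise = 5, effect_size = 2, seed = i
      )
      tab$label <- sample(tab$label)
      mod <- fit_pipeline(tab, grid = small_grid(), n_folds = 5, seed = i)
      mod$cv_stability$mean[mod$cv_stability$metric == "accuracy"]
    }, numeric(1))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("CV stability summarises fold dispersion correctly", {
  tab <- simulate_feature_table(
    n_per_class = 60, n_informative = 3,
    n_noise = 2, effect_size = 6, seed = 9
  )
  mod <- fit_pipeline(tab, grid = small_grid(), n_folds = 5, seed = 9)
  acc <- mod$cv_metrics$accuracy
  expect_true(all(acc == 1)) # trivially separable: every fold perfect
  st <- mod$cv_stability[mod$cv_stability$metric == "accuracy", ]
  expect_equal(st$cv_pct, 0) # zero dispersion means CV% exactly 0
  expect_equal(st$ci_lower, 1)
  expect_error(fit_pipeline(tab, grid = default_grid()[0, ], seed = 1), "grid")
})

test_that("evaluation metrics equal direct confusion-matrix arithmetic", {
  m <- confusion_metrics(tp = 89, fn = 11, tn = 93, fp = 7)
  expect_equal(m$accuracy, 0.91)
  expect_equal(m$precision, 89 / 96)
  expect_equal(m$precision, 0.9271, tolerance = 1e-4)
  expect_equal(m$recall, 0.89)
  expect_equal(m$specificity, 0.93)
  expect_equal(m$f1, 2 * 89 / (2 * 89 + 7 + 11))
})

test_that("a perfect model saturates metrics and gain/lift geometry", {
  tab <- simulate_feature_table(
    n_per_class = 80, n_informative = 2,
    n_noise = 1, effect_size = 8, seed = 10
  )
  sp <- split_dev(tab, seed = 10)
  mod <- fit_pipeline(sp$train, grid = small_grid(), n_folds = 5, seed = 10)
  ev <- evaluate_model(mod, sp$test)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(ev$metrics$roc_auc, 1)
  prevalence <- mean(sp$test$label == "tolerant")
  at_prev <- ev$curves[abs(ev$curves$fraction - prevalence) < 1e-9, ]
  expect_equal(at_prev$gain, 1) # all positives captured at the prevalence
  expect_equal(at_prev$lift, 1 / prevalence)
  expect_equal(ev$curves$gain[nrow(ev$curves)], 1)
})

test_that("probability reversal mirrors the ROC AUC", {
  withr::with_seed(11, {
    truth <- factor(sample(c("a", "b"), 60, TRUE), levels = c("a", "b"))
    prob <- runif(60)
  })
  auc <- rootart:::.metric_row(truth, prob, "b")$roc_auc
  auc_rev <- rootart:::.metric_row(truth, 1 - prob, "b")$roc_auc
  expect_equal(auc_rev, 1 - auc)
})

test_that("single-class truth reports AUC as missing", {
  truth <- factor(rep("b", 10), levels = c("a", "b"))
  m <- rootart:::.metric_row(truth, runif(10), "b")
  expect_true(is.na(m$roc_auc))
})

test_that("permutation importance separates signal from noise features", {
  tab <- simulate_feature_table(
    n_per_class = 100, n_informative = 1,
    n_noise = 6, effect_size = 3, seed = 12
  )
  sp <- split_dev(tab, seed = 12)
  mod <- fit_pipeline(sp$train,
    grid = small_grid(), n_folds = 5,
    select_features = FALSE, seed = 12
  )
  imp <- permutation_importance(mod, sp$test, n_repeats = 5, seed = 12)
  expect_equal(imp$term[1], "inf_1")
  noise_imp <- imp$importance[imp$term != "inf_1"]
  expect_gt(imp$importance[1], max(noise_imp) + 0.1)
  expect_lt(max(abs(noise_imp)), 0.1)
})

test_that("algorithm-grouped importance pinpoints the informative algorithm", {
  tab <- art_named_table(n_per_class = 80, informative = "FCM", seed = 13)
  sp <- split_dev(tab, seed = 13)
  mod <- fit_pipeline(sp$train,
    grid = small_grid(), n_folds = 5,
    select_features = FALSE, seed = 13
  )
  gimp <- permutation_importance(mod, sp$test,
    mode = "algorithm_grouped",
    n_repeats = 5, seed = 13
  )
  expect_equal(gimp$term[1], "FCM")
  others <- gimp$importance[gimp$term != "FCM"]
  expect_lt(max(abs(others)), 0.1)

  odd <- dplyr::mutate(tab, stray_feature = rnorm(nrow(tab)))
  mod2 <- fit_pipeline(odd,
    grid = small_grid(), n_folds = 5,
    select_features = FALSE, seed = 13
  )
  expect_warning(
    permutation_importance(mod2, odd,
      mode = "algorithm_grouped",
      n_repeats = 2, seed = 1
    ),
    "stray_feature"
  )
})

test_that("no training statistic leaks into held-out rows (canary)", {
  # canary feature: pure noise in training rows, equal to the label in test
  # rows; a leak-free model must ignore it entirely
  tab <- simulate_feature_table(
    n_per_class = 100, n_informative = 2,
    n_noise = 2, effect_size = 2, seed = 14
  )
  sp <- split_dev(tab, seed = 14)
  train <- dplyr::mutate(sp$train, canary = rnorm(nrow(sp$train)))
  test <- dplyr::mutate(sp$test, canary = as.numeric(label == "tolerant"))
  mod <- fit_pipeline(train,
    grid = small_grid(), n_folds = 5,
    select_features = FALSE, seed = 14
  )
  imp <- permutation_importance(mod, test, n_repeats = 5, seed = 14)
  expect_lt(abs(imp$importance[imp$term == "canary"]), 0.05)
})

test_that("the row-hash audit blocks contaminated validation sets", {
  tab <- simulate_feature_table(n_per_class = 30, seed = 15)
  sp <- split_dev(tab, seed = 15)
  mod <- fit_pipeline(sp$train, grid = small_grid(), n_folds = 5, seed = 15)
  expect_error(
    evaluate_model(mod, sp$train[1:5, ], audit_against = sp$train),
    "independent validation"
  )
  expect_s3_class(
    evaluate_model(mod, sp$test, audit_against = sp$train),
    "rootart_eval"
  )
})

test_that("ablation isolates the informative algorithm", {
  tab <- art_named_table(n_per_class = 60, informative = "HDBSCAN", seed = 16)
  sp <- split_dev(tab, seed = 16)
  ab <- ablate_algorithms(sp$train, sp$test,
    algorithms = c("HDBSCAN", "SLIC"),
    grid = small_grid(), n_folds = 5, seed = 16
  )
  expect_equal(ab$run, c("full", "drop_HDBSCAN", "drop_SLIC"))
  expect_equal(ab$delta_accuracy[1], 0) # the full row is its own reference
  # dropping the only informative algorithm collapses to chance
  expect_lt(ab$accuracy[2], 0.65)
  # dropping a pure-noise algorithm moves accuracy only within CV noise
  expect_lt(abs(ab$delta_accuracy[3]), 0.1)

  core <- ablate_algorithms(sp$train, sp$test,
    keep_only = "HDBSCAN",
    grid = small_grid(), n_folds = 5, seed = 16
  )
  expect_gt(core$accuracy[2], 0.8)
  expect_error(
    ablate_algorithms(sp$train, sp$test, keep_only = character(0)),
    "every algorithm"
  )
})

test_that("information density is plain accuracy per feature", {
  expect_equal(round(information_density(0.851, 4), 3), 0.213)
  expect_equal(round(information_density(0.856, 23), 3), 0.037)
  expect_equal(information_density(1, 1), 1)
  expect_equal(information_density(c(0.5, 0.9), c(5, 3)), c(0.1, 0.3))
})

test_that("the total-pixel baseline learns size differences and runs on empties", {
  set <- simulate_labelled_masks(
    n_per_class = 15, class_diff = "size",
    seed = 17
  )
  res <- baseline_total_pixels(set$masks, set$labels, seed = 17)
  expect_gt(res$evaluation$metrics$accuracy, 0.8)

  # empty masks in one class still run: count feature is simply 0
  masks <- c(
    set$masks[1:6],
    purrr::map(1:6, ~ root_mask(matrix(FALSE, 20, 20), sample_id = paste0("e", .x)))
  )
  names(masks)[7:12] <- paste0("e", 1:6)
  labels <- tibble::tibble(
    sample_id = names(masks),
    label = factor(rep(c("x", "y"), each = 6))
  )
  res0 <- baseline_total_pixels(masks, labels,
    test_fraction = 0.34,
    n_folds = 2, seed = 17
  )
  expect_s3_class(res0$evaluation, "rootart_eval")
})
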