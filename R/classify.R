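#' Bootstrap-plus-noise augmentation of a labelled trait table
#'
#' Doubles a development table: to the `n` original rows it appends `n`
#' rows drawn from them by bootstrap (with replacement), each perturbed by
#' independent Gaussian noise with standard deviation `noise_sigma` on the
#' z-scored feature scale (i.e. about `noise_sigma` of each feature's
#' spread), mapped back to raw units. Labels and metadata are copied from
#' the source rows; original rows are never altered. Synthetic rows are
#' flagged in the `.augmented` provenance column.
#'
#' @param data Labelled table; all columns except `label_col` and `id_cols`
#'   must be numeric features (a non-numeric feature is an error naming the
#'   column).
#' @param label_col Name of the class label column.
#' @param id_cols Metadata columns copied but never perturbed.
#' @param noise_sigma Noise standard deviation on the z-scored scale
#'   (default 0.02).
#' @param seed Integer seed.
#' @return Tibble with exactly `2n` rows: the originals
#'   (`.augmented = FALSE`) then the synthetic rows (`.augmented = TRUE`).
#' @export
#'
#' @examples
#' tab <- simulate_feature_table(n_per_class = 10, seed = 1)
#' nrow(augment_traits(tab, seed = 1)) # 40
augment_traits <- function(data, label_col = "label",
                           id_cols = intersect("sample_id", names(data)),
                           noise_sigma = 0.02, seed = 0L) {
  stopifnot(noise_sigma >= 0, nrow(data) >= 1)
  data <- tibble::as_tibble(data)
  feat <- setdiff(names(data), c(label_col, id_cols, ".augmented"))
  bad <- feat[!vapply(data[feat], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric feature column(s): %s", paste(bad, collapse = ", ")))
  }
  n <- nrow(data)
  centre <- vapply(data[feat], mean, numeric(1))
  spread <- vapply(data[feat], sd, numeric(1))
  spread[is.na(spread) | spread == 0] <- 1 # constant feature: raw-scale noise
  synth <- withr::with_seed(seed, {
    src <- sample.int(n, n, replace = TRUE)
    out <- data[src, , drop = FALSE]
    for (f in feat) {
      out[[f]] <- out[[f]] + rnorm(n, 0, noise_sigma) * spread[[f]]
    }
    out
  })
  orig <- dplyr::mutate(data, .augmented = FALSE)
  synth <- dplyr::mutate(synth, .augmented = TRUE)
  dplyr::bind_rows(orig, synth)
}

#' Stratified development split
#'
#' Splits a table into train and test sets with `ceiling(test_fraction * n)`
#' test rows, allocated across classes by largest remainder so per-class
#' proportions are preserved within one row. Deterministic per seed.
#'
#' @param data Labelled table.
#' @param test_fraction Test share (default 0.2).
#' @param stratify_on Label column to stratify by.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test` and the integer vector
#'   `test_idx`.
#' @export
split_dev <- function(data, test_fraction = 0.2, stratify_on = "label",
                      seed = 0L) {
  data <- tibble::as_tibble(data)
  g <- factor(data[[stratify_on]])
  sizes <- table(g)
  if (any(sizes < 2L)) {
    abort(sprintf(
      "cannot stratify: class(es) with a single row: %s",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  n_test <- ceiling(test_fraction * nrow(data))
  ideal <- as.numeric(sizes) * test_fraction
  base <- floor(ideal)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  test_idx <- withr::with_seed(seed, {
    unlist(purrr::map2(levels(g), base, function(lev, k) {
      idx <- which(g == lev)
      sample(idx, k)
    }))
  })
  test_idx <- sort(test_idx)
  list(
    train = data[-test_idx, , drop = FALSE],
    test = data[test_idx, , drop = FALSE],
    test_idx = test_idx
  )
}

#' Default random-forest hyperparameter grid
#'
#' @return Data frame of combinations of `num_trees`, `max_depth`
#'   (0 = unlimited) and `min_node_size`.
#' @export
default_grid <- function() {
  expand.grid(
    num_trees = c(100L, 300L, 500L),
    max_depth = c(0L, 10L, 20L),
    min_node_size = c(1L, 5L)
  )
}

# stratified k-fold assignment
.stratified_folds <- function(g, k, seed) {
  fold <- integer(length(g))
  withr::with_seed(seed, {
    for (lev in levels(g)) {
      idx <- sample(which(g == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# metric suite from truth, predicted class and positive-class probability
.metric_row <- function(truth, prob, positive, threshold = 0.5) {
  truth_pos <- truth == positive
  pred_pos <- prob >= threshold
  tp <- sum(truth_pos & pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  auc <- if (length(unique(truth_pos)) < 2L) {
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(
      response = truth_pos, predictor = prob,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
  }
  dplyr::bind_cols(
    confusion_metrics(tp = tp, fp = fp, tn = tn, fn = fn),
    tibble::tibble(roc_auc = auc)
  )
}

#' Classification metrics from a confusion matrix
#'
#' Direct arithmetic on the four cells: accuracy, precision, recall,
#' F1 and specificity (`TN / (TN + FP)`).
#'
#' @param tp,fp,tn,fn Confusion-matrix cell counts.
#' @return One-row tibble with the cells and the five derived metrics.
#' @export
#'
#' @examples
#' confusion_metrics(tp = 89, fn = 11, tn = 93, fp = 7)
confusion_metrics <- function(tp, fp, tn, fn) {
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Fit the three-stage classification pipeline
#'
#' Stage 1 z-scores the features, stage 2 selects features whose impurity
#' importance under an auxiliary random forest is at least the mean
#' importance, stage 3 fits the main random forest — with stages 1-2
#' computed inside each training fold during cross-validation, so no
#' statistic of a held-out fold ever reaches the model. Hyperparameters
#' are chosen by exhaustive grid search over `grid` with stratified
#' `n_folds`-fold cross-validation, optimising mean fold `optimise`
#' (precision by default). The winning combination is refit on the full
#' training data.
#'
#' @param data Labelled training table.
#' @param label_col Class label column (coerced to factor).
#' @param positive Positive class (default: last factor level).
#' @param grid Hyperparameter data frame (see [default_grid()]).
#' @param n_folds Cross-validation folds (default 10).
#' @param optimise Metric name to maximise.
#' @param select_features Run the stage-2 selector (TRUE) or keep all
#'   features.
#' @param id_cols Metadata columns ignored as features.
#' @param seed Integer seed.
#' @return A `rootart_model`: list with the fitted forest, scaler,
#'   selected features, best hyperparameters, per-fold CV metrics of the
#'   winning combination (`cv_metrics`), their stability summary
#'   (`cv_stability`: mean, CV% = 100 * sd / mean, and a 95 % t-interval
#'   per metric), and the full `grid_results`.
#' @export
fit_pipeline <- function(data, label_col = "label",
                         positive = NULL,
                         grid = default_grid(),
                         n_folds = 10L,
                         optimise = "precision",
                         select_features = TRUE,
                         id_cols = intersect(
                           c("sample_id", ".augmented"), names(data)
                         ),
                         seed = 0L) {
  data <- tibble::as_tibble(data)
  if (!nrow(grid)) abort("empty hyperparameter grid")
  y <- droplevels(factor(data[[label_col]]))
  if (nlevels(y) != 2L) abort("the pipeline is a two-class classifier")
  positive <- positive %||% levels(y)[2L]
  feat <- setdiff(names(data), c(label_col, id_cols))
  feat <- feat[vapply(data[feat], is.numeric, logical(1))]
  if (!length(feat)) abort("no numeric feature columns")
  x <- as.matrix(data[feat])
  if (min(table(y)) < n_folds) {
    abort("each class needs at least n_folds rows for stratified folding")
  }
  fold <- .stratified_folds(y, n_folds, seed)

  run_fold <- function(params, f) {
    tr <- fold != f
    prep <- .prep_stage(x[tr, , drop = FALSE], y[tr], select_features, seed)
    fit <- .fit_rf(prep$x, y[tr], params, seed)
    xte <- .apply_stage(x[!tr, , drop = FALSE], prep)
    prob <- predict(fit, data.frame(xte))$predictions[, positive]
    .metric_row(y[!tr], prob, positive)
  }

  grid_results <- purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    params <- grid[gi, , drop = FALSE]
    folds <- purrr::map_dfr(seq_len(n_folds), function(f) {
      dplyr::mutate(run_fold(params, f), fold = f)
    })
    dplyr::bind_cols(
      params,
      dplyr::summarise(folds, dplyr::across(
        c("accuracy", "precision", "recall", "f1", "specificity", "roc_auc"),
        ~ mean(.x, na.rm = TRUE)
      ))
    )
  })
  best_i <- which.max(grid_results[[optimise]])
  best <- grid[best_i, , drop = FALSE]
  cv_metrics <- purrr::map_dfr(seq_len(n_folds), function(f) {
    dplyr::mutate(run_fold(best, f), fold = f)
  })
  metric_names <- c("accuracy", "precision", "recall", "f1", "specificity", "roc_auc")
  cv_stability <- purrr::map_dfr(metric_names, function(mn) {
    v <- cv_metrics[[mn]]
    v <- v[!is.na(v)]
    m <- mean(v)
    s <- stats::sd(v)
    half <- qt(0.975, df = length(v) - 1) * s / sqrt(length(v))
    tibble::tibble(
      metric = mn, mean = m,
      cv_pct = if (m != 0) 100 * s / m else 0,
      ci_lower = m - half, ci_upper = m + half
    )
  })
  prep <- .prep_stage(x, y, select_features, seed)
  fit <- .fit_rf(prep$x, y, best, seed)
  structure(
    list(
      forest = fit, prep = prep, features = feat,
      selected_features = colnames(prep$x),
      label_col = label_col, positive = positive, levels = levels(y),
      best_params = best, grid_results = tibble::as_tibble(grid_results),
      cv_metrics = cv_metrics, cv_stability = cv_stability,
      n_folds = n_folds, optimise = optimise, seed = seed,
      train_hash = .row_hashes(data[feat])
    ),
    class = "rootart_model"
  )
}

.prep_stage <- function(x, y, select_features, seed) {
  centre <- colMeans(x)
  spread <- apply(x, 2, sd)
  spread[spread == 0] <- 1
  z <- scale(x, centre, spread)
  keep <- colnames(x)
  if (select_features && ncol(x) > 1L) {
    aux <- ranger::ranger(
      x = data.frame(z), y = y, num.trees = 500,
      importance = "impurity", seed = seed,
      num.threads = 1
    )
    imp <- aux$variable.importance
    keep <- names(imp)[imp >= mean(imp)]
    if (!length(keep)) keep <- names(imp)
  }
  list(centre = centre, spread = spread, keep = keep,
    x = z[, keep, drop = FALSE])
}

.apply_stage <- function(x, prep) {
  z <- scale(x, prep$centre, prep$spread)
  z[, prep$keep, drop = FALSE]
}

.fit_rf <- function(z, y, params, seed) {
  ranger::ranger(
    x = data.frame(z), y = y,
    num.trees = params$num_trees,
    max.depth = params$max_depth,
    min.node.size = params$min_node_size,
    probability = TRUE, seed = seed, num.threads = 1
  )
}

.row_hashes <- function(df) {
  apply(as.matrix(df), 1, function(r) paste(signif(as.numeric(r), 12), collapse = "|"))
}

#' @export
print.rootart_model <- function(x, ...) {
  cat(sprintf(
    "<rootart_model> random-forest pipeline: %d/%d features selected; best: %s\n",
    length(x$selected_features), length(x$features),
    paste(names(x$best_params), unlist(x$best_params), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' @export
predict.rootart_model <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  x <- as.matrix(tibble::as_tibble(newdata)[object$features])
  z <- .apply_stage(x, object$prep)
  prob <- predict(object$forest, data.frame(z))$predictions[, object$positive]
  if (type == "prob") {
    return(prob)
  }
  neg <- setdiff(object$levels, object$positive)
  factor(ifelse(prob >= 0.5, object$positive, neg), levels = object$levels)
}

#' Glance at a fitted pipeline
#' @param x A `rootart_model`.
#' @param ... Unused.
#' @return One-row tibble of the winning hyperparameters and mean CV
#'   metrics.
#' @export
glance.rootart_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$best_params),
    tidyr::pivot_wider(
      x$cv_stability[, c("metric", "mean")],
      names_from = "metric", values_from = "mean", names_prefix = "cv_"
    )
  )
}

#' Evaluate a fitted pipeline on labelled rows
#'
#' Confusion-matrix metrics at the 0.5 probability threshold, ROC AUC from
#' the predicted probabilities, and cumulative gain / lift curves (fraction
#' of positives captured versus fraction of samples, ranked by predicted
#' probability; lift is gain over the diagonal).
#'
#' @param model A `rootart_model`.
#' @param data Labelled evaluation rows.
#' @param audit_against Optional table (e.g. the development set): if any
#'   evaluation row's feature vector also occurs there, evaluation aborts —
#'   the row-hash audit guarding independent validation.
#' @return A `rootart_eval`: list with `metrics` (one-row tibble),
#'   `confusion` (2x2 table) and `curves` (tibble `fraction`, `gain`,
#'   `lift`).
#' @export
evaluate_model <- function(model, data, audit_against = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(audit_against)) {
    overlap <- intersect(
      .row_hashes(data[model$features]),
      .row_hashes(tibble::as_tibble(audit_against)[model$features])
    )
    if (length(overlap)) {
      abort(sprintf(
        "independent validation violated: %d evaluation row(s) occur in the audited table",
        length(overlap)
      ))
    }
  }
  truth <- factor(data[[model$label_col]], levels = model$levels)
  prob <- predict(model, data)
  metrics <- .metric_row(truth, prob, model$positive)
  pred <- predict(model, data, type = "class")
  confusion <- table(truth = truth, predicted = pred)
  o <- order(prob, decreasing = TRUE)
  pos <- truth[o] == model$positive
  n <- length(pos)
  curves <- tibble::tibble(
    fraction = seq_len(n) / n,
    gain = cumsum(pos) / max(1, sum(pos))
  )
  curves$lift <- curves$gain / curves$fraction
  structure(
    list(metrics = metrics, confusion = confusion, curves = curves),
    class = "rootart_eval"
  )
}

#' @export
print.rootart_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | specificity %.3f | ROC AUC %s\n",
    m$accuracy, m$precision, m$recall, m$f1, m$specificity,
    ifelse(is.na(m$roc_auc), "NA", sprintf("%.3f", m$roc_auc))
  ))
  invisible(x)
}

#' @export
tidy.rootart_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$metrics[, c("accuracy", "precision", "recall", "f1", "specificity", "roc_auc")],
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}

#' Permutation feature importance
#'
#' Mean drop in an evaluation metric over `n_repeats` shuffles of one
#' feature column (`mode = "feature_permutation"`), or of an algorithm's
#' three trait columns simultaneously (`mode = "algorithm_grouped"`,
#' preserving the within-row coupling of all other features). Grouped mode
#' parses the `<Algorithm>_density_points` / `_centre_x` / `_centre_y`
#' naming; columns that match no algorithm are skipped with a warning.
#'
#' @param model A `rootart_model`.
#' @param data Labelled evaluation rows.
#' @param mode `"feature_permutation"` or `"algorithm_grouped"`.
#' @param metric Metric whose drop is reported (default accuracy).
#' @param n_repeats Shuffles per feature/group.
#' @param seed Integer seed.
#' @return Tibble `term`, `importance` (mean metric drop), `sd`, sorted
#'   decreasing.
#' @export
permutation_importance <- function(model, data,
                                   mode = c("feature_permutation", "algorithm_grouped"),
                                   metric = "accuracy", n_repeats = 10L,
                                   seed = 0L) {
  mode <- match.arg(mode)
  data <- tibble::as_tibble(data)
  truth <- factor(data[[model$label_col]], levels = model$levels)
  base <- .metric_row(truth, predict(model, data), model$positive)[[metric]]
  groups <- if (mode == "feature_permutation") {
    setNames(as.list(model$features), model$features)
  } else {
    algs <- art_algorithms()
    hit <- purrr::map(algs, function(a) {
      cols <- paste0(a, c("_density_points", "_centre_x", "_centre_y"))
      intersect(cols, model$features)
    })
    names(hit) <- algs
    unmatched <- setdiff(
      model$features,
      c(unlist(hit), character(0))
    )
    if (length(unmatched)) {
      warn(sprintf(
        "columns outside the trait naming scheme skipped from grouping: %s",
        paste(unmatched, collapse = ", ")
      ))
    }
    hit[lengths(hit) > 0]
  }
  n <- nrow(data)
  withr::with_seed(seed, {
    res <- purrr::imap_dfr(groups, function(cols, nm) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        perm <- data
        sh <- sample.int(n)
        for (cl in cols) perm[[cl]] <- perm[[cl]][sh]
        base - .metric_row(truth, predict(model, perm), model$positive)[[metric]]
      }, numeric(1))
      tibble::tibble(term = nm, importance = mean(drops), sd = sd(drops))
    })
  })
  dplyr::arrange(res, dplyr::desc(.data$importance))
}

#' Algorithm ablation study
#'
#' Refits the full pipeline with each algorithm's three trait columns
#' removed in turn and reports the change in test metrics relative to the
#' full model; `keep_only` instead fits reduced models restricted to a
#' subset of algorithms (e.g. a candidate core trio).
#'
#' @param train,test Labelled trait tables (27-column block plus label).
#' @param label_col Label column name.
#' @param algorithms Algorithms to drop one at a time.
#' @param keep_only Optional character vector: fit one model using only
#'   these algorithms' columns instead of drop-one ablation.
#' @param grid,n_folds,seed Passed to [fit_pipeline()].
#' @return Tibble: `run`, metric columns, and `delta_*` columns against
#'   the full model.
#' @export
ablate_algorithms <- function(train, test, label_col = "label",
                              algorithms = art_algorithms(),
                              keep_only = NULL,
                              grid = default_grid()[1, ], n_folds = 5L,
                              seed = 0L) {
  trait_cols <- intersect(art_trait_names(), names(train))
  if (!length(trait_cols)) abort("no trait columns found")
  if (!is.null(keep_only) && !length(keep_only)) {
    abort("keep_only would drop every algorithm")
  }
  fit_on <- function(cols_gone, run) {
    tr <- dplyr::select(train, -dplyr::any_of(cols_gone))
    te <- dplyr::select(test, -dplyr::any_of(cols_gone))
    mod <- fit_pipeline(tr,
      label_col = label_col, grid = grid,
      n_folds = n_folds, seed = seed
    )
    ev <- evaluate_model(mod, te)
    dplyr::bind_cols(tibble::tibble(run = run), ev$metrics[
      ,
      c("accuracy", "precision", "recall", "f1", "specificity", "roc_auc")
    ])
  }
  full <- fit_on(character(0), "full")
  runs <- if (!is.null(keep_only)) {
    gone <- unlist(purrr::map(
      setdiff(art_algorithms(), keep_only),
      function(a) paste0(a, c("_density_points", "_centre_x", "_centre_y"))
    ))
    list(fit_on(gone, paste0("only_", paste(keep_only, collapse = "+"))))
  } else {
    purrr::map(algorithms, function(a) {
      fit_on(
        paste0(a, c("_density_points", "_centre_x", "_centre_y")),
        paste0("drop_", a)
      )
    })
  }
  out <- dplyr::bind_rows(c(list(full), runs))
  for (mn in c("accuracy", "precision", "recall", "f1", "specificity", "roc_auc")) {
    out[[paste0("delta_", mn)]] <- out[[mn]] - out[[mn]][1]
  }
  out
}

#' Accuracy per feature (information density)
#'
#' @param accuracy Classification accuracy in `[0, 1]` (vectorised).
#' @param n_features Number of features used (>= 1).
#' @return `accuracy / n_features`.
#' @export
#'
#' @examples
#' information_density(0.851, 4) # ~0.213
#' information_density(0.856, 23) # ~0.037
information_density <- function(accuracy, n_features) {
  stopifnot(all(n_features >= 1))
  accuracy / n_features
}

#' Total-root-pixel baseline classifier
#'
#' Builds a one-feature table (the total root-pixel count of each mask)
#' and runs the same split / fit / evaluate path as the trait models. The
#' baseline captures overall root-system size and nothing else, so classes
#' that differ only in *where* their dense cluster sits should defeat it.
#'
#' @param masks Named list of [root_mask()] objects.
#' @param labels Tibble with `sample_id`, `label` matching the mask names.
#' @param test_fraction,grid,n_folds,seed Pipeline settings.
#' @return List with `model`, `evaluation` (a `rootart_eval`) and the
#'   feature `table`.
#' @export
baseline_total_pixels <- function(masks, labels, test_fraction = 0.2,
                                  grid = default_grid()[1, ], n_folds = 5L,
                                  seed = 0L) {
  tab <- tibble::tibble(
    sample_id = names(masks),
    total_root_pixels = vapply(masks, root_pixel_count, integer(1))
  )
  tab <- dplyr::inner_join(tab, tibble::as_tibble(labels), by = "sample_id")
  sp <- split_dev(tab, test_fraction, "label", seed)
  mod <- fit_pipeline(sp$train,
    label_col = "label", grid = grid,
    n_folds = n_folds, select_features = FALSE, seed = seed
  )
  list(model = mod, evaluation = evaluate_model(mod, sp$test), table = tab)
}
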