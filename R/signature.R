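# Signature building: cohort splitting, t-test feature filtering, and
# grid-searched WSI-level classifiers.

#' Split a cohort into training and testing sets
#'
#' Case-level 7:3 split (all slides of a case share the assignment). The
#' training size is `round(train_fraction * n)` with halves rounded toward
#' the training set, reproducing the published 519 -> 363/156 and 400 ->
#' 280/120 splits. Stratification by class uses largest-remainder allocation
#' so the overall training size is exact.
#'
#' @param cohort Cohort table with `case_id` and the stratification column.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed controlling the random assignment.
#' @param stratify_by Column to stratify on (`"class_label"` by default;
#'   `NULL` for unstratified).
#' @return The cohort with a `split` column (`"train"` / `"test"`).
#' @export
split_cohort <- function(cohort, train_fraction = 0.7, seed = 1,
                         stratify_by = "class_label") {
  n <- nrow(cohort)
  if (n < 2) stopf("need at least 2 cases")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must lie in (0, 1)")
  }
  n_train <- floor(train_fraction * n + 0.5)  # half-up, ties toward training
  groups <- if (!is.null(stratify_by) && stratify_by %in% names(cohort)) {
    split(seq_len(n), as.character(cohort[[stratify_by]]))
  } else {
    list(all = seq_len(n))
  }
  # largest-remainder apportionment of n_train across strata
  exact <- vapply(groups, length, 0L) * train_fraction
  base <- floor(exact)
  rem <- exact - base
  short <- n_train - sum(base)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[bump] <- base[bump] + 1
  } else if (short < 0) {
    drop <- order(rem)[seq_len(-short)]
    base[drop] <- base[drop] - 1
  }
  base <- pmin(pmax(base, 0), vapply(groups, length, 0L))
  assign <- rep("test", n)
  with_seed(seed, {
    for (g in names(groups)) {
      take <- sample(groups[[g]], base[[g]])
      assign[take] <- "train"
    }
  })
  cohort$split <- assign
  cohort
}

#' Welch t-test feature filter
#'
#' Keeps features whose two-sample Welch t-test between the label groups has
#' `p < alpha`. For more than two classes the filter is the union of
#' one-vs-rest selections. Constant features are dropped with a warning.
#'
#' @param features Numeric matrix (documents x named features).
#' @param labels Group labels aligned with the rows.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of selected feature names.
#' @export
ttest_filter <- function(features, labels, alpha = 0.05) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stopf("need at least two label groups")
  tiny <- names(which(table(labels) < 2))
  if (length(tiny)) stopf("group(s) with fewer than 2 documents: %s",
                          paste(tiny, collapse = ", "))
  contrasts <- if (length(classes) == 2) {
    list(labels == classes[1])
  } else {
    lapply(classes, function(k) labels == k)
  }
  const <- apply(features, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warnf("dropping %d constant feature(s)", sum(const))
  }
  selected <- character(0)
  for (grp in contrasts) {
    p <- welch_p(features, grp)
    selected <- union(selected, colnames(features)[!const & !is.na(p) &
                                                     p < alpha])
  }
  selected[order(match(selected, colnames(features)))]
}

# Vectorized two-sided Welch t-test p-values of every column between
# rows where grp is TRUE and the rest. NA where the statistic is undefined.
welch_p <- function(features, grp) {
  x <- features[grp, , drop = FALSE]
  y <- features[!grp, , drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2, stats::var)
  v2 <- apply(y, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- NA
  p
}

#' Specification of a WSI-level classifier family and its search grid
#'
#' Tree-based families (`random_forest`, `extratrees`, `xgboost`,
#' `lightgbm`) default to the published grid: `n_estimators` from 10 to 50
#' in steps of 5 crossed with `max_depth` in {2, 3, 4, 5} (36
#' configurations). `svm` uses the RBF kernel with other settings at their
#' defaults (grid of size one), and `mlp` is a fixed fully connected
#' 128/64/32 perceptron.
#'
#' @param family One of `"svm"`, `"random_forest"`, `"extratrees"`,
#'   `"xgboost"`, `"lightgbm"`, `"mlp"`.
#' @param grid Optional data frame of hyperparameter combinations; defaults
#'   to the family's published grid.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("svm", "random_forest", "extratrees",
                                  "xgboost", "lightgbm", "mlp"),
                       grid = NULL, cv_folds = 5, seed = 1) {
  family <- match.arg(family)
  if (cv_folds < 2) stopf("cv_folds must be at least 2")
  tree_like <- family %in% c("random_forest", "extratrees", "xgboost",
                             "lightgbm")
  if (is.null(grid)) {
    grid <- if (tree_like) {
      expand.grid(n_estimators = seq(10L, 50L, 5L), max_depth = 2:5,
                  KEEP.OUT.ATTRS = FALSE)
    } else {
      data.frame(dummy = 1)[, 0, drop = FALSE]  # single default config
    }
  }
  if (tree_like && nrow(grid) == 0) stopf("tree families need a non-empty grid")
  structure(list(family = family, grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

fit_family <- function(family, X, y, params, seed) {
  ne <- params$n_estimators %||% 100L
  md <- params$max_depth %||% 3L
  fit <- switch(family,
    svm = fit_svm(X, y, seed = seed),
    random_forest = fit_forest(X, y, n_estimators = ne, max_depth = md,
                               bootstrap = TRUE, random_threshold = FALSE,
                               seed = seed),
    extratrees = fit_forest(X, y, n_estimators = ne, max_depth = md,
                            bootstrap = FALSE, random_threshold = TRUE,
                            seed = seed),
    xgboost = fit_boost(X, y, n_estimators = ne, max_depth = md,
                        growth = "depth", seed = seed),
    lightgbm = fit_boost(X, y, n_estimators = ne, max_depth = md,
                         growth = "leaf", seed = seed),
    mlp = fit_mlp(X, y, seed = seed),
    stopf("unknown family '%s'", family))
  structure(list(family = family, fit = fit, params = params,
                 feature_names = colnames(X),
                 classes = sort(unique(as.character(y)))),
            class = "wsi_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified k-fold assignment; errors when a class cannot reach every fold.
make_folds <- function(y, k, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  for (f in seq_len(k)) {
    if (length(unique(y[fold != f])) < length(unique(y))) {
      stopf("degenerate folds: a class is missing from fold %d's training part", f)
    }
  }
  fold
}

cv_metric_auc <- function(probs, labels) {
  classes <- colnames(probs)
  if (length(classes) == 2) {
    y <- as.integer(as.character(labels) == classes[2])
    if (length(unique(y)) < 2) return(NA_real_)
    delong_components(probs[, 2], y)$auc
  } else {
    micro_macro_auc(probs, labels)$macro
  }
}

#' Grid search with stratified cross-validation
#'
#' Exhaustively evaluates every grid configuration by stratified k-fold
#' cross-validation on the training documents, selects the configuration
#' with the highest mean CV AUC (macro one-vs-rest AUC for multiclass), and
#' refits it on the full training set.
#'
#' @param features Training feature matrix (documents x named features).
#' @param labels Training labels.
#' @param spec A [model_spec()].
#' @return List of class `grid_search_fit`: `model` (refit on all training
#'   documents), `best_params`, `cv_table` (one row per configuration with
#'   its mean and per-fold AUC).
#' @export
grid_search_fit <- function(features, labels, spec = model_spec("svm")) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(features)
  y <- as.character(labels)
  counts <- table(y)
  if (length(counts) < 2 || any(counts < spec$cv_folds)) {
    stopf("every class needs at least cv_folds (=%d) training documents",
          spec$cv_folds)
  }
  fold <- make_folds(y, spec$cv_folds, spec$seed)
  grid <- spec$grid
  n_cfg <- max(nrow(grid), 1)
  cv <- matrix(NA_real_, n_cfg, spec$cv_folds)
  for (cfg in seq_len(n_cfg)) {
    params <- if (ncol(grid)) as.list(grid[cfg, , drop = FALSE]) else list()
    for (f in seq_len(spec$cv_folds)) {
      tr <- fold != f
      m <- fit_family(spec$family, X[tr, , drop = FALSE], y[tr], params,
                      child_seed(spec$seed, cfg, f))
      pr <- predict_documents(m, X[!tr, , drop = FALSE])
      cv[cfg, f] <- cv_metric_auc(pr, y[!tr])
    }
  }
  mean_auc <- rowMeans(cv, na.rm = TRUE)
  best <- which.max(mean_auc)  # ties -> first configuration in grid order
  best_params <- if (ncol(grid)) as.list(grid[best, , drop = FALSE]) else list()
  model <- fit_family(spec$family, X, y, best_params, spec$seed)
  cv_table <- cbind(
    if (ncol(grid)) grid else data.frame(config = seq_len(n_cfg)),
    mean_cv_auc = mean_auc,
    stats::setNames(as.data.frame(cv), paste0("fold", seq_len(spec$cv_folds))))
  list(model = model, best_params = best_params, cv_table = cv_table)
}

#' Predict class probabilities for documents
#'
#' @param model A `wsi_model` (from [grid_search_fit()] or `fit_family`).
#' @param features Feature matrix whose columns match the training columns
#'   exactly (names and order).
#' @return Probability matrix (documents x classes), rows on the simplex.
#' @export
predict_documents <- function(model, features) {
  stopifnot(inherits(model, "wsi_model"))
  X <- as.matrix(features)
  if (!identical(colnames(X), model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(X))
    extra <- setdiff(colnames(X), model$feature_names)
    if (length(missing) || length(extra)) {
      stopf("feature columns differ from training: missing [%s], unexpected [%s]",
            paste(utils::head(missing, 5), collapse = ", "),
            paste(utils::head(extra, 5), collapse = ", "))
    }
    stopf("feature columns are ordered differently from training")
  }
  probs <- switch(model$family,
    svm = predict_svm(model$fit, X),
    random_forest = ,
    extratrees = predict_forest(model$fit, X),
    xgboost = ,
    lightgbm = predict_boost(model$fit, X),
    mlp = predict_mlp(model$fit, X))
  rownames(probs) <- rownames(X)
  probs
}
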