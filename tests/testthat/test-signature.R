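# cohort splitting, t-test filtering, grid search, prediction

test_that("split sizes reproduce the published cohorts exactly", {
  co <- function(n, labels = "okc") {
    data.frame(case_id = sprintf("c%04d", seq_len(n)),
               class_label = rep_len(labels, n))
  }
  s519 <- split_cohort(co(519, c(rep("okc", 400), rep("ooc", 60),
                                 rep("gs", 59))), 0.7, seed = 3)
  expect_equal(sum(s519$split == "train"), 363)
  expect_equal(sum(s519$split == "test"), 156)
  s400 <- split_cohort(co(400), 0.7, seed = 3)
  expect_equal(sum(s400$split == "train"), 280)
  expect_equal(sum(s400$split == "test"), 120)
  s10 <- split_cohort(co(10), 0.7, seed = 3)
  expect_equal(sum(s10$split == "train"), 7)
  expect_error(split_cohort(co(10), 1.3), "train_fraction")
  expect_error(split_cohort(co(1)), "at least 2")
  # stratification: per-class proportions near 0.7
  tab <- table(s519$class_label, s519$split)
  expect_true(all(abs(tab[, "train"] / rowSums(tab) - 0.7) < 0.01))
  # assignment is random given seed, reproducible
  expect_identical(split_cohort(co(50), seed = 9)$split,
                   split_cohort(co(50), seed = 9)$split)
  expect_false(identical(split_cohort(co(50), seed = 9)$split,
                         split_cohort(co(50), seed = 10)$split))
})

test_that("t-test filter keeps significant, drops constant features", {
  set.seed(21)
  n <- 100
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(
    planted = rnorm(n) + 3 * (y == "a"),     # 3-SD shift -> power ~ 1
    noise1 = rnorm(n),
    noise2 = rnorm(n),
    const = rep(1, n))
  expect_warning(sel <- ttest_filter(X, y), "constant")
  expect_true("planted" %in% sel)
  expect_false("const" %in% sel)
  # identical in both groups (zero t) excluded
  X2 <- cbind(same = rep(c(1, 2), n / 2), planted = X[, "planted"])
  expect_false("same" %in% ttest_filter(X2, y))
  # alpha = 1 keeps every non-constant feature
  expect_setequal(suppressWarnings(ttest_filter(X, y, alpha = 1)),
                  c("planted", "noise1", "noise2"))
  expect_error(ttest_filter(X[1:51, ], y[1:51]), "fewer than 2")
  # selected p-values agree with stats::t.test (Welch) oracle
  p_oracle <- stats::t.test(X[y == "a", "planted"],
                            X[y == "b", "planted"])$p.value
  expect_equal(unname(slidefuse:::welch_p(X, y == "a")["planted"]), p_oracle)
})

test_that("multiclass filter is the union of one-vs-rest selections", {
  set.seed(4)
  n <- 90
  y <- rep(c("a", "b", "c"), each = 30)
  X <- cbind(a_only = rnorm(n) + 2 * (y == "a"),
             c_only = rnorm(n) + 2 * (y == "c"),
             noise = rnorm(n))
  sel <- ttest_filter(X, y)
  expect_true(all(c("a_only", "c_only") %in% sel))
})

test_that("model_spec encodes the published grid", {
  sp <- model_spec("random_forest")
  expect_equal(nrow(sp$grid), 36)                       # 9 x 4 configurations
  expect_setequal(unique(sp$grid$n_estimators), seq(10, 50, 5))
  expect_setequal(unique(sp$grid$max_depth), 2:5)
  expect_error(model_spec("svm", cv_folds = 1), "cv_folds")
  expect_error(model_spec("xgboost", grid = data.frame()), "non-empty")
})

test_that("grid search enumerates the grid and refits the best", {
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, prognostic_config())
  tr <- gen$cohort$split == "train"
  X <- fm$features[tr, ]; y <- gen$cohort$class_label[tr]
  grid <- expand.grid(n_estimators = c(5L, 10L), max_depth = c(2L, 3L))
  fit <- grid_search_fit(X, y, model_spec("random_forest", grid = grid,
                                          seed = 5))
  expect_equal(nrow(fit$cv_table), 4)                   # every configuration
  expect_true(all(c("mean_cv_auc", "fold1", "fold5") %in%
                    names(fit$cv_table)))
  expect_true(all(unlist(fit$best_params) %in% unlist(grid)))
  # grid of size 1 equals direct training
  one <- grid_search_fit(X, y, model_spec("extratrees",
                                          grid = data.frame(n_estimators = 10L,
                                                            max_depth = 3L),
                                          seed = 5))
  direct <- slidefuse:::fit_family("extratrees", X, y,
                                   list(n_estimators = 10L, max_depth = 3L),
                                   5L)
  expect_equal(predict_documents(one$model, fm$features[!tr, ]),
               predict_documents(direct, fm$features[!tr, ]))
  # separable synthetic cohort: SVM training AUC > 0.95
  svm <- grid_search_fit(X, y, model_spec("svm", seed = 5))
  pr <- predict_documents(svm$model, X)
  expect_gt(auc_ci(pr[, "pos"], as.integer(y == "pos"))$auc, 0.95)
  expect_error(grid_search_fit(X[1:6, ], y[1:6], model_spec("svm")),
               "cv_folds")
})

test_that("prediction contract: determinism, simplex, column checks", {
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, prognostic_config())
  tr <- gen$cohort$split == "train"
  X <- fm$features[tr, ]; y <- gen$cohort$class_label[tr]
  m <- slidefuse:::fit_family("random_forest", X, y,
                              list(n_estimators = 10L, max_depth = 3L), 2L)
  p1 <- predict_documents(m, X)
  p2 <- predict_documents(m, X)
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-9))
  expect_error(predict_documents(m, X[, -1]), "missing")
  swapped <- X[, c(2, 1, 3:ncol(X))]
  expect_error(predict_documents(m, swapped), "ordered differently")
  # AUC computed by the evaluation module matches a rank-sum oracle
  te <- !tr
  pr <- predict_documents(m, fm$features[te, ])
  y_te <- as.integer(gen$cohort$class_label[te] == "pos")
  u <- sum(rank(pr[, "pos"])[y_te == 1]) - sum(y_te) * (sum(y_te) + 1) / 2
  expect_equal(auc_ci(pr[, "pos"], y_te)$auc,
               u / (sum(y_te) * sum(1 - y_te)))
})

test_that("no leakage: test-set mutations change nothing upstream", {
  gen <- fixture_cohort()
  cohort <- gen$cohort
  tr_ids <- cohort$case_id[cohort$split == "train"]
  te_ids <- cohort$case_id[cohort$split == "test"]
  mutate_test <- function(tab) {
    sel <- tab$case_id %in% te_ids
    tab$p_pos[sel] <- stats::runif(sum(sel))
    tab$p_neg[sel] <- 1 - tab$p_pos[sel]
    tab
  }
  set.seed(99)
  tab2 <- mutate_test(gen$table)
  fm1 <- build_feature_matrix(gen$table, cohort, prognostic_config())
  fm2 <- build_feature_matrix(tab2, cohort, prognostic_config())
  # TF-IDF fitted on training documents only -> identical idf
  expect_identical(fm1$tfidf$idf, fm2$tfidf$idf)
  # t-test filter consumes training rows only
  tr <- cohort$split == "train"
  expect_identical(
    suppressWarnings(ttest_filter(fm1$features[tr, ], cohort$class_label[tr])),
    suppressWarnings(ttest_filter(fm2$features[tr, ], cohort$class_label[tr])))
  # grid search on training rows is unchanged by test mutations
  g1 <- grid_search_fit(fm1$features[tr, ], cohort$class_label[tr],
                        model_spec("extratrees",
                                   grid = data.frame(n_estimators = 5L,
                                                     max_depth = 2L),
                                   seed = 1))
  g2 <- grid_search_fit(fm2$features[tr, ], cohort$class_label[tr],
                        model_spec("extratrees",
                                   grid = data.frame(n_estimators = 5L,
                                                     max_depth = 2L),
                                   seed = 1))
  expect_equal(g1$cv_table, g2$cv_table)
})

test_that("every model family trains and predicts on the simplex", {
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, prognostic_config())
  tr <- gen$cohort$split == "train"
  sel <- suppressWarnings(
    ttest_filter(fm$features[tr, ], gen$cohort$class_label[tr]))
  X <- fm$features[tr, sel]; y <- gen$cohort$class_label[tr]
  Xte <- fm$features[!tr, sel]
  yte <- as.integer(gen$cohort$class_label[!tr] == "pos")
  grid1 <- data.frame(n_estimators = 10L, max_depth = 3L)
  for (fam in c("svm", "random_forest", "extratrees", "xgboost",
                "lightgbm", "mlp")) {
    sp <- model_spec(fam, grid = if (fam %in% c("svm", "mlp")) NULL else grid1,
                     seed = 7)
    fit <- grid_search_fit(X, y, sp)
    pr <- predict_documents(fit$model, Xte)
    expect_true(all(abs(rowSums(pr) - 1) < 1e-9), label = fam)
    # the cohort is strongly separable; every family should score well
    expect_gt(auc_ci(pr[, "pos"], yte)$auc, 0.9)
  }
})
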