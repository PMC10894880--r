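# evaluation suite: AUC + CI, one-vs-rest, confusion, DeLong, decision
# curves, heatmaps, t-SNE

test_that("auc_ci equals the brute-force pairwise oracle", {
  expect_equal(auc_ci(c(5, 6, 7), c(0, 1, 1))$auc, 1)   # perfect separation
  # the small worked example, checked against the rank oracle
  expect_equal(auc_ci(c(0.1, 0.4, 0.2), c(1, 1, 0))$auc,
               brute_auc(c(0.1, 0.4, 0.2), c(1, 1, 0)))
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    s <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_ci(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }
  # CI contains the point estimate and stays in [0, 1]
  set.seed(3)
  s <- rnorm(60); y <- rbinom(60, 1, 0.4)
  ci <- auc_ci(s, y)
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
  expect_true(ci$ci_low >= 0 && ci$ci_high <= 1)
  expect_error(auc_ci(1:5, rep(1, 5)), "both classes")
  # permuted labels at large n: AUC near 1/2 within 3 SE
  set.seed(8)
  n <- 2000
  s <- rnorm(n); y <- sample(rep(0:1, n / 2))
  a <- auc_ci(s, y)
  expect_lt(abs(a$auc - 0.5), 3 * sqrt((n + 1) / (12 * (n / 2)^2)))
})

test_that("one-vs-rest and micro/macro AUCs", {
  # 3-class one-hot perfect predictor
  y <- rep(c("a", "b", "c"), each = 4)
  P <- outer(y, c("a", "b", "c"), "==") * 1
  colnames(P) <- c("a", "b", "c")
  expect_true(all(ovr_aucs(P, y) == 1))
  mm <- micro_macro_auc(P, y)
  expect_equal(mm$micro, 1); expect_equal(mm$macro, 1)
  # small worked example against the brute-force pairwise oracle
  set.seed(5)
  P2 <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  P2 <- P2 / rowSums(P2)
  y2 <- sample(c("a", "b", "c"), 10, replace = TRUE)
  while (length(unique(y2)) < 3) y2 <- sample(c("a", "b", "c"), 10, TRUE)
  per <- ovr_aucs(P2, y2)
  for (k in c("a", "b", "c")) {
    expect_equal(unname(per[k]), brute_auc(P2[, k], as.integer(y2 == k)))
  }
  expect_equal(micro_macro_auc(P2, y2)$macro, mean(per))
  onehot <- outer(y2, colnames(P2), "==") * 1
  expect_equal(micro_macro_auc(P2, y2)$micro,
               brute_auc(as.vector(P2), as.vector(onehot)))
  # macro on a balanced binary problem reduces to the binary AUC
  yb <- rep(c("a", "b"), 10)
  pb <- plogis(rnorm(20) + (yb == "b"))
  Pb <- cbind(a = 1 - pb, b = pb)
  expect_equal(micro_macro_auc(Pb, yb)$macro,
               auc_ci(pb, as.integer(yb == "b"))$auc)
  # absent class reported as NA, not fabricated
  expect_true(is.na(ovr_aucs(P2, rep("a", 10))["b"]))
})

test_that("confusion matrix and operating rates", {
  # all correct
  cr <- confusion_and_rates(c("a", "b", "a"), c("a", "b", "a"), "a")
  expect_equal(cr$accuracy, 1)
  expect_equal(cr$sensitivity, 1)
  expect_equal(cr$specificity, 1)
  # printed 2x2 table TP=9 FN=1 TN=50 FP=20
  truth <- rep(c("pos", "neg"), c(10, 70))
  pred <- c(rep("pos", 9), "neg", rep("neg", 50), rep("pos", 20))
  cr2 <- confusion_and_rates(pred, truth, "pos")
  expect_equal(cr2$sensitivity, 0.9)
  expect_equal(cr2$specificity, 50 / 70)
  expect_equal(cr2$accuracy, 59 / 80)
  # row sums equal per-class counts
  expect_equal(unname(rowSums(cr2$confusion)), c(70, 10))
  # swapping the positive class swaps sensitivity and specificity
  cr3 <- confusion_and_rates(pred, truth, "neg")
  expect_equal(cr3$sensitivity, cr2$specificity)
  expect_equal(cr3$specificity, cr2$sensitivity)
  expect_error(confusion_and_rates(pred, truth, "zz"), "unknown positive")
  # youden threshold maximizes J on a toy example
  sc <- c(0.1, 0.2, 0.6, 0.7, 0.9)
  yy <- c(0, 0, 1, 1, 1)
  expect_equal(operating_point(sc, yy, "youden"), 0.6)
})

test_that("delong test: antisymmetry, identity, permutation oracle", {
  set.seed(42)
  n <- 40
  y <- rep(c(1, 0), each = 20)
  sa <- y * 0.8 + rnorm(n)
  sb <- y * 0.3 + rnorm(n)
  dt <- delong_test(sa, sb, y)
  # antisymmetry
  rev <- delong_test(sb, sa, y)
  expect_equal(rev$z, -dt$z)
  expect_equal(rev$p, dt$p)
  # identical predictors
  same <- delong_test(sa, sa, y)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  expect_error(delong_test(sa, sb[1:10], y), "paired")
  # paired permutation oracle (10 000 swaps of the two scores per subject)
  obs <- abs(dt$auc_a - dt$auc_b)
  set.seed(7)
  hits <- 0
  for (b in 1:10000) {
    sw <- runif(n) < 0.5
    pa <- ifelse(sw, sb, sa); pb <- ifelse(sw, sa, sb)
    d <- abs(slidefuse:::delong_components(pa, y)$auc -
               slidefuse:::delong_components(pb, y)$auc)
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  expect_lt(abs(dt$p - hits / 10000), 0.02)
})

test_that("decision curves match direct arithmetic", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)          # prevalence 0.3
  p <- c(0.9, 0.8, 0.4, 0.6, 0.3, 0.2, 0.1, 0.1, 0.05, 0.0)
  dc <- decision_curve(p, y, thresholds = c(0.25, 0.5))
  # by hand at pt = 0.25: act = p >= 0.25 -> TP = 3, FP = 2
  expect_equal(dc$net_benefit[1], 3 / 10 - 2 / 10 * 0.25 / 0.75)
  # at pt = 0.5: TP = 2, FP = 1
  expect_equal(dc$net_benefit[2], 2 / 10 - 1 / 10 * 0.5 / 0.5)
  expect_equal(dc$treat_all, 0.3 - 0.7 * c(0.25, 0.5) / c(0.75, 0.5))
  expect_true(all(dc$treat_none == 0))
  # treat-all tends to prevalence as pt -> 0
  tiny <- decision_curve(p, y, thresholds = 1e-6)
  expect_equal(tiny$treat_all, 0.3, tolerance = 1e-5)
  # perfect classifier: net benefit = prevalence below all positive scores
  perf <- decision_curve(y * 0.9 + 0.05, y, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(perf$net_benefit, rep(0.3, 3))
  # always-positive classifier coincides with treat-all
  all_pos <- decision_curve(rep(1, 10), y, thresholds = c(0.2, 0.6))
  expect_equal(all_pos$net_benefit, all_pos$treat_all)
  expect_error(decision_curve(p, y, numeric(0)), "empty")
  expect_error(decision_curve(p, y, c(0, 0.5)), "inside")
})

test_that("probability heatmaps honor the tile grid", {
  tab <- data.frame(case_id = "c", slide_id = "s",
                    grid_col = c(0, 1, 2, 0), grid_row = c(0, 0, 0, 1),
                    p_x = c(0.1, 0.6, 0.9, 0.4), p_y = c(0.9, 0.4, 0.1, 0.6),
                    label = c("y", "x", "x", "y"))
  hm <- probability_heatmap(tab)
  expect_equal(dim(hm$prob_map), c(2, 3))        # (max_row+1, max_col+1)
  expect_equal(hm$prob_map[1, 3], 0.9)
  expect_true(is.na(hm$prob_map[2, 2]))          # background transparent
  expect_equal(hm$pred_map[1, 1], 2L)            # class "y"
  # single-tile slide
  one <- probability_heatmap(tab[1, ])
  expect_equal(dim(one$prob_map), c(1, 1))
  expect_equal(one$prob_map[1, 1], 0.1)
  # duplicate grid cells refused
  dup <- rbind(tab, tab[1, ])
  expect_error(probability_heatmap(dup), "duplicate")
  # PNG rendering
  base <- withr::local_tempfile()
  hm2 <- probability_heatmap(tab, file = base)
  expect_true(all(file.exists(hm2$paths)))
  img <- png::readPNG(hm2$paths["prob"])
  expect_equal(dim(img), c(2, 3, 4))
  expect_equal(img[2, 2, 4], 0)                  # NA cell is transparent
})

test_that("planted high-likelihood region dominates the probability map", {
  spec <- synthetic_spec(n_cases_per_class = c(a = 1, b = 1),
                         slides_per_case = c(1, 1),
                         tiles_per_slide = c(64, 64),
                         likelihood_law = list(a = c(20, 2), b = c(2, 20)),
                         recurrence_rate = 0, seed = 13)
  gen <- generate_likelihood_table(spec)
  s1 <- gen$table[gen$table$case_id == "case0001", ]
  hm <- probability_heatmap(s1, likelihood_class = "a")
  expect_gt(mean(hm$prob_map, na.rm = TRUE), 0.75)
})

test_that("tsne embedding: shape, determinism, class structure", {
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, prognostic_config())
  emb <- tsne_embed(fm$features, seed = 6)
  expect_equal(dim(emb), c(nrow(fm$features), 2))
  expect_identical(emb, tsne_embed(fm$features, seed = 6))
  # duplicated document lands on a near-coincident point
  X2 <- rbind(fm$features, fm$features[1, , drop = FALSE])
  e2 <- tsne_embed(X2, seed = 6)
  d_dup <- sqrt(sum((e2[1, ] - e2[nrow(e2), ])^2))
  d_typ <- stats::median(as.matrix(stats::dist(e2)))
  expect_lt(d_dup, d_typ / 4)
  # silhouette of the true classes in the embedding
  lab <- gen$cohort$class_label
  dmat <- as.matrix(stats::dist(emb))
  sil <- vapply(seq_len(nrow(emb)), function(i) {
    a <- mean(dmat[i, lab == lab[i] & seq_len(nrow(emb)) != i])
    b <- mean(dmat[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.2)
  expect_error(tsne_embed(fm$features[1:2, ]), "at least 3")
  bad <- fm$features; bad[1, 1] <- NA
  expect_error(tsne_embed(bad), "finite")
})

test_that("evaluate_predictions bundles a coherent report", {
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, prognostic_config())
  tr <- gen$cohort$split == "train"
  m <- slidefuse:::fit_family("svm", fm$features[tr, ],
                              gen$cohort$class_label[tr], list(), 1L)
  pr <- predict_documents(m, fm$features[!tr, ])
  rep_ <- evaluate_predictions(pr, gen$cohort$class_label[!tr],
                               positive_class = "pos")
  expect_s3_class(rep_, "eval_report")
  expect_true(rep_$auc$pos$ci_low <= rep_$auc$pos$auc)
  expect_equal(sum(rep_$confusion), sum(!tr))
  expect_true(all(rowSums(rep_$confusion) ==
                    table(factor(gen$cohort$class_label[!tr],
                                 levels = c("neg", "pos")))))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$accuracy, rep_$accuracy)
})
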