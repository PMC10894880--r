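# PLH / BoW multi-instance fusion

test_that("discretize rounds half-up with stripped trailing zeros", {
  expect_identical(discretize(0.386, 2), "0.39")
  expect_identical(discretize(0, 1), "0")
  expect_identical(discretize(0, 2), "0")
  expect_identical(discretize(1, 2), "1")
  expect_identical(discretize(0.25, 1), "0.3")    # half-up, not banker's
  expect_identical(discretize(0.285, 2), "0.29")
  expect_identical(discretize(0.9, 2), "0.9")     # 0.90 -> "0.9"
  expect_error(discretize(1.2, 1), "\\[0, 1\\]")
  expect_error(discretize(-0.1, 1), "\\[0, 1\\]")

  # decimal-arithmetic oracle: format the value at the given precision with
  # string-based half-up rounding, over a dense grid
  grid <- seq(0, 1, by = 0.005)
  for (d in 1:2) {
    oracle <- vapply(grid, function(p) {
      # exact rational arithmetic on thousandths avoids float ambiguity
      k <- round(p * 1000)
      unit <- 10^(3 - d)
      q <- (k %/% unit) + as.integer((k %% unit) >= unit / 2)
      s <- sub("0+$", "", sprintf(paste0("%.", d, "f"), q / 10^d))
      sub("\\.$", "", s)
    }, "")
    expect_identical(discretize(grid, d), oracle)
  }
})

test_that("vocabulary sizes and paper-style feature names", {
  expect_length(likelihood_vocabulary(1), 11)
  expect_length(likelihood_vocabulary(2), 101)
  expect_identical(likelihood_vocabulary(1)[1:3], c("0", "0.1", "0.2"))
  cfg <- prognostic_config()
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, cfg)
  expect_true(all(c("hist_-0.39", "bow_039", "bow_09", "hist_-0") %in%
                    colnames(fm$features)))
})

test_that("PLH features are relative frequencies over the fixed vocabulary", {
  cfg <- fusion_config(decimals = 1, include_labels = FALSE)
  doc <- list(case_id = "c1", lik_tokens = discretize(rep(0.7, 4), 1),
              label_tokens = character(), n_patches = 4)
  f <- plh_features(doc, cfg, classes = c("x", "y"))
  expect_equal(unname(f["hist_-0.7"]), 1)
  expect_equal(sum(f), 1)
  expect_length(f, 11)

  doc2 <- list(case_id = "c2",
               lik_tokens = discretize(c(0.14, 0.17, 0.86), 1),
               label_tokens = character(), n_patches = 3)
  f2 <- plh_features(doc2, cfg, classes = c("x", "y"))
  expect_equal(unname(f2[c("hist_-0.1", "hist_-0.2", "hist_-0.9")]),
               c(1, 1, 1) / 3)
  expect_error(plh_features(list(case_id = "bad", n_patches = 0), cfg,
                            c("x", "y")), "empty document")
})

test_that("TF-IDF matches the hand-computed oracle and smoothing contract", {
  cfg <- fusion_config(decimals = 1, include_labels = FALSE)
  classes <- c("x", "y")
  mk <- function(id, toks) list(case_id = id, lik_tokens = toks,
                                label_tokens = character(),
                                n_patches = length(toks))
  docs <- list(A = mk("A", c("0.1", "0.1", "0.9")), B = mk("B", "0.9"))
  model <- bow_fit(docs, cfg, classes)
  # token in every training document -> idf = 1 under the smoothing
  expect_equal(unname(model$idf["0.9"]), 1)
  # hand-computed oracle for document A: tf = (2/3, 1/3),
  # idf = (ln(3/2)+1, ln(3/3)+1), then L2 normalization
  vA <- c(2 / 3 * (log(3 / 2) + 1), 1 / 3 * 1)
  vA <- vA / sqrt(sum(vA^2))
  got <- bow_transform(docs$A, model, cfg, classes)
  expect_equal(unname(got[c("bow_01", "bow_09")]), vA, tolerance = 1e-12)
  expect_equal(sum(got^2), 1, tolerance = 1e-12)
  # token unseen in training contributes its smoothed idf, no error
  unseen <- mk("C", c("0.5", "0.5"))
  vc <- bow_transform(unseen, model, cfg, classes)
  expect_equal(unname(vc["bow_05"]), 1)
  expect_error(bow_transform(docs$A, list(), cfg, classes), "before")
  expect_error(bow_fit(docs["A"], cfg, classes), "at least 2")
})

test_that("TF-IDF equals a brute-force oracle on random small corpora", {
  cfg <- fusion_config(decimals = 1, include_labels = FALSE)
  classes <- c("x", "y")
  vocab <- likelihood_vocabulary(1)
  set.seed(14)
  for (rep in 1:5) {
    n_docs <- sample(2:5, 1)
    docs <- lapply(seq_len(n_docs), function(i) {
      toks <- sample(vocab[1:10], sample(1:10, 1), replace = TRUE)
      list(case_id = paste0("d", i), lik_tokens = toks,
           label_tokens = character(), n_patches = length(toks))
    })
    names(docs) <- vapply(docs, `[[`, "", "case_id")
    model <- bow_fit(docs, cfg, classes)
    # independent oracle: explicit counting over the token table
    df_oracle <- vapply(vocab, function(tk)
      sum(vapply(docs, function(d) tk %in% d$lik_tokens, TRUE)), 0)
    idf_oracle <- log((1 + n_docs) / (1 + df_oracle)) + 1
    expect_equal(unname(model$idf), unname(idf_oracle))
    for (d in docs) {
      tf_oracle <- vapply(vocab, function(tk)
        sum(d$lik_tokens == tk), 0) / length(d$lik_tokens)
      v <- tf_oracle * idf_oracle
      v <- v / sqrt(sum(v^2))
      expect_equal(unname(bow_transform(d, model, cfg, classes)), unname(v),
                   tolerance = 1e-12)
    }
  }
})

test_that("document assembly: pooling, single-slide selection, exclusions", {
  tab <- data.frame(
    case_id = c(rep("c1", 30), rep("c2", 5)),
    slide_id = c(rep("c1_s2", 10), rep("c1_s1", 20), rep("c2_s1", 5)),
    grid_col = 0, grid_row = 0,
    p_x = 0.8, p_y = 0.2, label = "x", stringsAsFactors = FALSE)
  cohort <- data.frame(case_id = c("c1", "c2"), class_label = "x")
  multi <- build_documents(tab, cohort, fusion_config())
  expect_equal(multi$c1$n_patches, 30)       # 10 + 20 pooled
  single <- build_documents(tab, cohort,
                            fusion_config(document_unit = "single_slide"))
  expect_equal(single$c1$n_patches, 20)      # larger slide wins
  expect_equal(single$c2$n_patches, 5)       # 1-slide case unchanged
  # tie on patch count -> lexicographically smallest slide id
  tie <- tab[tab$slide_id == "c1_s2", ]
  tie$slide_id[1:5] <- "c1_s0"
  one <- build_documents(tie, cohort[1, , drop = FALSE],
                         fusion_config(document_unit = "single_slide"))
  expect_equal(one$c1$n_patches, 5)
  # case with zero kept patches is excluded with a warning
  expect_warning(
    d0 <- build_documents(tab, rbind(cohort, data.frame(case_id = "c3",
                                                        class_label = "x")),
                          fusion_config()),
    "no kept patches")
  expect_named(d0, c("c1", "c2"))
  expect_error(build_documents(tab, cohort[2, , drop = FALSE],
                               fusion_config()), "unknown case ids")
})

test_that("feature matrix: column counts, invariants, patch-order invariance", {
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, prognostic_config())
  expect_equal(ncol(fm$features), 206)       # (101 + 2 labels) x 2 pipelines
  expect_equal(nrow(fm$features), nrow(gen$cohort))
  expect_true(all(is.finite(fm$features)) && all(fm$features >= 0))
  # PLH likelihood block sums to 1 per document
  lik_cols <- paste0("hist_-", likelihood_vocabulary(2))
  expect_equal(unname(rowSums(fm$features[, lik_cols])),
               rep(1, nrow(fm$features)))
  # BoW block has unit L2 norm per document
  bow_cols <- grep("^bow_", colnames(fm$features), value = TRUE)
  expect_equal(unname(sqrt(rowSums(fm$features[, bow_cols]^2))),
               rep(1, nrow(fm$features)))
  # permuting patch order never changes the features
  set.seed(8)
  perm <- gen$table[sample.int(nrow(gen$table)), ]
  fm2 <- build_feature_matrix(perm, gen$cohort, prognostic_config(),
                              tfidf = fm$tfidf)
  expect_equal(fm2$features, fm$features)

  # diagnostic configuration on a 3-class cohort: (11 + 3) PLH + 11 BoW
  spec3 <- synthetic_spec(n_cases_per_class = c(a = 4, b = 4, c = 4),
                          slides_per_case = c(1, 1),
                          tiles_per_slide = c(10, 20), seed = 6)
  g3 <- generate_likelihood_table(spec3)
  fm3 <- build_feature_matrix(g3$table, g3$cohort, diagnostic_config())
  expect_equal(ncol(fm3$features), 25)
  # empty cohort keeps the full column set
  empty <- suppressWarnings(build_feature_matrix(
    g3$table[0, ], g3$cohort[0, ], diagnostic_config(), tfidf = fm3$tfidf))
  expect_equal(dim(empty$features), c(0L, 25L))
})

test_that("tfidf round-trips through JSON", {
  gen <- fixture_cohort()
  fm <- build_feature_matrix(gen$table, gen$cohort, prognostic_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_tfidf(fm$tfidf, path)
  back <- read_tfidf(path)
  expect_equal(back$idf, fm$tfidf$idf)
  expect_identical(back$vocabulary, fm$tfidf$vocabulary)
})
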