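#' Fusion configuration for PLH / BoW multi-instance aggregation
#'
#' Controls how per-patch likelihoods are discretized into tokens and
#' aggregated into document-level (case or slide) feature vectors through the
#' patch-likelihood histogram (PLH) and the TF-IDF bag-of-words (BoW)
#' pipelines.
#'
#' Two presets reproduce the published configurations: the diagnostic setup
#' uses one-decimal tokens with predicted labels entering the histogram only
#' ([diagnostic_config()]), and the prognostic setup uses two-decimal tokens
#' with labels and probabilities entering both pipelines
#' ([prognostic_config()]). The latter yields exactly 206 feature columns on
#' a binary task: (101 likelihood tokens + 2 label tokens) x 2 pipelines.
#'
#' @param decimals Number of decimal places retained when discretizing patch
#'   likelihoods; 1 (vocabulary of 11 tokens) or 2 (101 tokens).
#' @param include_probabilities Include discretized likelihood tokens.
#' @param include_labels Include one token per predicted class label.
#' @param label_scope Where label tokens enter: `"plh"` (histogram only, the
#'   diagnostic convention) or `"both"` (histogram and bag-of-words, the
#'   prognostic convention).
#' @param document_unit `"case_multi_slide"` pools every slide of a case into
#'   one document; `"single_slide"` keeps only the slide with the most kept
#'   patches (ties broken by lexicographically smallest slide id).
#' @param likelihood_class Class whose probability is the scalar "likelihood"
#'   of a patch. Default `NULL`: the first class for binary tasks; for tasks
#'   with more than two classes, each document uses the probability of its
#'   majority predicted label (`"doc_majority"`). May also be `"max"` for the
#'   per-patch maximum probability.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(decimals = 1,
                          include_probabilities = TRUE,
                          include_labels = TRUE,
                          label_scope = c("plh", "both"),
                          document_unit = c("case_multi_slide", "single_slide"),
                          likelihood_class = NULL) {
  if (!decimals %in% c(1, 2)) stopf("`decimals` must be 1 or 2")
  if (!include_probabilities && !include_labels) {
    stopf("at least one of probabilities or labels must be included")
  }
  cfg <- list(
    decimals = as.integer(decimals),
    include_probabilities = isTRUE(include_probabilities),
    include_labels = isTRUE(include_labels),
    label_scope = match.arg(label_scope),
    document_unit = match.arg(document_unit),
    likelihood_class = likelihood_class
  )
  class(cfg) <- "fusion_config"
  cfg
}

#' @rdname fusion_config
#' @param ... Overrides passed on to [fusion_config()].
#' @export
diagnostic_config <- function(...) {
  args <- utils::modifyList(
    list(decimals = 1, include_labels = TRUE, label_scope = "plh"),
    list(...))
  do.call(fusion_config, args)
}

#' @rdname fusion_config
#' @export
prognostic_config <- function(...) {
  args <- utils::modifyList(
    list(decimals = 2, include_labels = TRUE, label_scope = "both"),
    list(...))
  do.call(fusion_config, args)
}

# ---------------------------------------------------------------------------
# Tokens

token_string <- function(k, decimals) {
  s <- sprintf(paste0("%.", decimals, "f"), k / 10^decimals)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Token vocabulary of discretized likelihoods
#'
#' All values in `[0, 1]` representable at the given precision, rendered with
#' trailing zeros stripped (`"0"`, `"0.1"`, ..., `"1"`). 11 tokens at one
#' decimal, 101 at two.
#'
#' @param decimals 1 or 2.
#' @return Character vector of tokens.
#' @export
likelihood_vocabulary <- function(decimals = 1) {
  if (!decimals %in% c(1, 2)) stopf("`decimals` must be 1 or 2")
  vapply(0:(10^decimals), token_string, "", decimals = decimals)
}

#' Discretize a likelihood into its token
#'
#' Rounds half-up (0.25 -> "0.3" at one decimal) on decimal-safe arithmetic,
#' then strips trailing zeros (0.90 -> "0.9").
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param decimals 1 or 2.
#' @return Character vector of tokens.
#' @examples
#' discretize(0.386, 2)  # "0.39"
#' discretize(0.25, 1)   # "0.3" (half-up)
#' @export
discretize <- function(p, decimals = 1) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stopf("likelihoods must lie in [0, 1]")
  }
  if (!decimals %in% c(1, 2)) stopf("`decimals` must be 1 or 2")
  # signif() collapses float representation error (0.285 * 100 ->
  # 28.499999...) before the half-up floor.
  k <- floor(signif(p * 10^decimals, 12) + 0.5)
  vapply(k, token_string, "", decimals = decimals)
}

# Paper-style feature names: PLH "hist_-<token>", BoW "bow_<digits>" with the
# decimal point dropped ("0.39" -> "bow_039", "0.9" -> "bow_09").
plh_name <- function(token) paste0("hist_-", token)
bow_name <- function(token) paste0("bow_", gsub(".", "", token, fixed = TRUE))
label_token <- function(class) paste0("label_", class)

# ---------------------------------------------------------------------------
# Documents

# The scalar likelihood of each patch row, given the class-probability
# matrix (columns named by class) and the document's majority label.
patch_likelihood_scalar <- function(probs, labels, cfg, classes) {
  lk <- cfg$likelihood_class
  if (is.null(lk)) lk <- if (length(classes) == 2) classes[1] else "doc_majority"
  if (identical(lk, "max")) {
    apply(probs, 1, max)
  } else if (identical(lk, "doc_majority")) {
    tab <- table(factor(labels, levels = classes))
    maj <- names(tab)[which.max(tab)]  # which.max ties -> first class
    probs[, maj]
  } else {
    if (!lk %in% classes) stopf("likelihood_class '%s' is not a class", lk)
    probs[, lk]
  }
}

#' Assemble token documents from a patch-likelihood table
#'
#' Groups patch rows into documents according to the configured document
#' unit. `case_multi_slide` pools every patch of every slide of a case;
#' `single_slide` keeps the slide with the most kept patches (ties ->
#' lexicographically smallest slide id).
#'
#' @param table A patch-likelihood table (see [predict_likelihoods()] /
#'   [generate_likelihood_table()]): columns `case_id`, `slide_id`,
#'   `grid_col`, `grid_row`, one `p_<class>` column per class, `label`.
#' @param cohort A cohort table with at least `case_id`; documents are
#'   restricted and ordered to its cases.
#' @param cfg A [fusion_config()].
#' @return Named list of documents, each with elements `case_id`,
#'   `lik_tokens`, `label_tokens` and `n_patches`. Cases with zero kept
#'   patches are dropped with a warning.
#' @export
build_documents <- function(table, cohort, cfg = fusion_config()) {
  stopifnot(inherits(cfg, "fusion_config"))
  classes <- plt_classes(table)
  probs <- as.matrix(table[paste0("p_", classes)])
  colnames(probs) <- classes
  bad <- setdiff(unique(table$case_id), cohort$case_id)
  if (length(bad)) stopf("patch table contains unknown case ids: %s",
                         paste(bad, collapse = ", "))
  docs <- list()
  for (cid in cohort$case_id) {
    idx <- which(table$case_id == cid)
    if (cfg$document_unit == "single_slide" && length(idx)) {
      sl <- table$slide_id[idx]
      cnt <- table(sl)
      best <- names(cnt)[cnt == max(cnt)]
      keep <- min(best)  # lexicographically smallest among ties
      idx <- idx[sl == keep]
    }
    if (!length(idx)) {
      warnf("case '%s' has no kept patches; excluded", cid)
      next
    }
    lik <- patch_likelihood_scalar(probs[idx, , drop = FALSE],
                                   table$label[idx], cfg, classes)
    docs[[cid]] <- list(
      case_id = cid,
      lik_tokens = if (cfg$include_probabilities)
        discretize(lik, cfg$decimals) else character(),
      label_tokens = if (cfg$include_labels)
        label_token(table$label[idx]) else character(),
      n_patches = length(idx)
    )
  }
  docs
}

# ---------------------------------------------------------------------------
# PLH

#' Patch-likelihood-histogram features of one document
#'
#' For every vocabulary token, the fraction of the document's patches whose
#' discretized likelihood equals that token; label tokens (when configured)
#' form a second relative-frequency block. Each block sums to one.
#'
#' @param doc One element of [build_documents()] output.
#' @param cfg A [fusion_config()].
#' @param classes Character vector of class labels (fixes label-token
#'   columns).
#' @return Named numeric vector of `hist_-*` features.
#' @export
plh_features <- function(doc, cfg, classes) {
  if (is.null(doc) || doc$n_patches < 1) {
    stopf("empty document%s", if (!is.null(doc$case_id))
      sprintf(" '%s'", doc$case_id) else "")
  }
  out <- numeric(0)
  if (cfg$include_probabilities) {
    vocab <- likelihood_vocabulary(cfg$decimals)
    cnt <- table(factor(doc$lik_tokens, levels = vocab))
    f <- as.numeric(cnt) / length(doc$lik_tokens)
    names(f) <- plh_name(vocab)
    out <- c(out, f)
  }
  if (cfg$include_labels) {
    lv <- label_token(classes)
    cnt <- table(factor(doc$label_tokens, levels = lv))
    f <- as.numeric(cnt) / length(doc$label_tokens)
    names(f) <- plh_name(lv)
    out <- c(out, f)
  }
  out
}

# ---------------------------------------------------------------------------
# BoW / TF-IDF

bow_tokens <- function(doc, cfg, classes) {
  toks <- character(0)
  if (cfg$include_probabilities) toks <- c(toks, doc$lik_tokens)
  if (cfg$include_labels && cfg$label_scope == "both") {
    toks <- c(toks, doc$label_tokens)
  }
  toks
}

bow_vocab <- function(cfg, classes) {
  v <- character(0)
  if (cfg$include_probabilities) v <- c(v, likelihood_vocabulary(cfg$decimals))
  if (cfg$include_labels && cfg$label_scope == "both") {
    v <- c(v, label_token(classes))
  }
  v
}

#' Fit a TF-IDF model on training documents
#'
#' Smoothed inverse document frequency, `idf = ln((1 + N) / (1 + df)) + 1`,
#' computed over the training corpus only. Tokens outside the fixed
#' vocabulary never enter; vocabulary tokens absent from training keep the
#' smoothed idf, so transforming unseen documents never errors.
#'
#' @param docs Documents from [build_documents()] (training split only).
#' @param cfg A [fusion_config()].
#' @param classes Character vector of class labels.
#' @return An object of class `tfidf_model` with fields `vocabulary`, `df`,
#'   `idf`, `n_documents`.
#' @export
bow_fit <- function(docs, cfg, classes) {
  if (length(docs) < 2) stopf("TF-IDF requires at least 2 training documents")
  vocab <- bow_vocab(cfg, classes)
  df <- stats::setNames(numeric(length(vocab)), vocab)
  for (doc in docs) {
    present <- unique(bow_tokens(doc, cfg, classes))
    present <- intersect(present, vocab)
    df[present] <- df[present] + 1
  }
  n <- length(docs)
  model <- list(vocabulary = vocab, df = df,
                idf = log((1 + n) / (1 + df)) + 1, n_documents = n)
  class(model) <- "tfidf_model"
  model
}

#' Transform one document into its TF-IDF feature block
#'
#' `tf` is the token count divided by document length; features are
#' `tf * idf`, L2-normalized per document. Never refits the idf.
#'
#' @param doc One element of [build_documents()] output.
#' @param model A fitted [bow_fit()] model.
#' @param cfg A [fusion_config()].
#' @param classes Character vector of class labels.
#' @return Named numeric vector of `bow_*` features.
#' @export
bow_transform <- function(doc, model, cfg, classes) {
  if (!inherits(model, "tfidf_model")) {
    stopf("bow_transform() called before bow_fit()")
  }
  toks <- bow_tokens(doc, cfg, classes)
  cnt <- table(factor(toks, levels = model$vocabulary))
  tf <- as.numeric(cnt) / max(length(toks), 1)
  v <- tf * model$idf
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  names(v) <- bow_name(model$vocabulary)
  v
}

#' Serialize / read a TF-IDF model as JSON
#' @param model A `tfidf_model`.
#' @param path File path.
#' @return `read_tfidf()` returns the model; `write_tfidf()` its path,
#'   invisibly.
#' @export
write_tfidf <- function(model, path) {
  # df/idf are stored unnamed, aligned with the vocabulary
  jsonlite::write_json(
    list(vocabulary = model$vocabulary, df = unname(model$df),
         idf = unname(model$idf), n_documents = model$n_documents),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tfidf
#' @export
read_tfidf <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(vocabulary = x$vocabulary,
                df = stats::setNames(as.numeric(x$df), x$vocabulary),
                idf = stats::setNames(as.numeric(x$idf), x$vocabulary),
                n_documents = x$n_documents)
  class(model) <- "tfidf_model"
  model
}

# ---------------------------------------------------------------------------
# Feature matrix

#' Build the document-by-feature fusion matrix
#'
#' Concatenates, for every document, the PLH block and the BoW block over the
#' fixed vocabulary; the column set is determined by the configuration alone,
#' never by token occupancy. The prognostic configuration on a binary task
#' yields 206 columns: (101 likelihood tokens + 2 label tokens) x 2
#' pipelines.
#'
#' @param table Patch-likelihood table.
#' @param cohort Cohort table (`case_id`, `class_label`, optionally `split`).
#' @param cfg A [fusion_config()].
#' @param tfidf Optional pre-fitted [bow_fit()] model. When `NULL`, one is
#'   fitted on the documents whose `cohort$split == "train"` (or on all
#'   documents when no split column exists).
#' @return A list of class `wsi_features`: `features` (numeric matrix,
#'   documents x named features), `tfidf`, `cfg`, `classes`, `document_ids`.
#' @export
build_feature_matrix <- function(table, cohort, cfg = fusion_config(),
                                 tfidf = NULL) {
  classes <- plt_classes(table)
  docs <- build_documents(table, cohort, cfg)
  if (is.null(tfidf)) {
    fit_ids <- if ("split" %in% names(cohort)) {
      intersect(cohort$case_id[cohort$split == "train"], names(docs))
    } else names(docs)
    if (length(fit_ids) < 2) fit_ids <- names(docs)
    tfidf <- bow_fit(docs[fit_ids], cfg, classes)
  }
  cols <- c(plh_colnames(cfg, classes), bow_name(bow_vocab(cfg, classes)))
  mat <- matrix(0, nrow = length(docs), ncol = length(cols),
                dimnames = list(names(docs), cols))
  for (id in names(docs)) {
    row <- c(plh_features(docs[[id]], cfg, classes),
             bow_transform(docs[[id]], tfidf, cfg, classes))
    mat[id, names(row)] <- row
  }
  structure(list(features = mat, tfidf = tfidf, cfg = cfg, classes = classes,
                 document_ids = names(docs)),
            class = "wsi_features")
}

plh_colnames <- function(cfg, classes) {
  v <- character(0)
  if (cfg$include_probabilities) v <- c(v, likelihood_vocabulary(cfg$decimals))
  if (cfg$include_labels) v <- c(v, label_token(classes))
  plh_name(v)
}

# Class labels encoded in a patch-likelihood table's p_<class> columns.
plt_classes <- function(table) {
  p <- grep("^p_", names(table), value = TRUE)
  if (!length(p)) stopf("no p_<class> probability columns found")
  sub("^p_", "", p)
}

#' Write a fusion feature matrix as CSV
#' @param x A `wsi_features` object or plain matrix.
#' @param path Output path.
#' @export
write_feature_matrix <- function(x, path) {
  m <- if (inherits(x, "wsi_features")) x$features else x
  df <- data.frame(document_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
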