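# Model evaluation: ROC-AUC with DeLong confidence intervals, one-vs-rest
# micro/macro AUC, confusion matrices, paired DeLong tests, decision-curve
# analysis, per-slide probability heatmaps, and t-SNE embeddings.

# Mann-Whitney placement components used by both the CI and the paired test.
# Returns AUC plus the V10 (per-positive) and V01 (per-negative) structural
# components of the DeLong decomposition.
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stopf("both classes must be present")
  # midranks give the tie-aware pairwise statistic without an m*n loop
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

as01 <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  lv <- sort(unique(as.character(labels)))
  if (is.null(positive)) {
    if (length(lv) != 2) stopf("labels must be binary (got %d levels)", length(lv))
    positive <- lv[2]
  }
  as.integer(as.character(labels) == positive)
}

#' ROC AUC with a DeLong 95 percent confidence interval
#'
#' The AUC is the tie-aware Mann-Whitney statistic (ties count half); the
#' confidence interval uses the DeLong structural-component variance and is
#' clipped to `[0, 1]`.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (0/1, logical, or 2-level character/factor
#'   whose larger level is positive unless `positive` is given).
#' @param positive Optional positive-class label.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
auc_ci <- function(scores, labels, positive = NULL, conf_level = 0.95) {
  y <- as01(labels, positive)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  d <- delong_components(scores, y)
  se <- sqrt(stats::var(d$v10) / d$m + stats::var(d$v01) / d$n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = d$auc,
       ci_low = max(0, d$auc - z * se),
       ci_high = min(1, d$auc + z * se),
       se = se)
}

#' One-vs-rest AUCs for a multiclass prediction
#'
#' Each class in turn is treated as positive against all others. Classes
#' absent from the labels are reported as `NA` rather than fabricated.
#'
#' @param probs Matrix of class probabilities, columns named by class.
#' @param labels True class labels.
#' @return Named numeric vector of per-class AUCs.
#' @export
ovr_aucs <- function(probs, labels) {
  classes <- colnames(probs)
  if (is.null(classes)) stopf("probability columns must be named by class")
  vapply(classes, function(k) {
    y <- as.integer(as.character(labels) == k)
    if (length(unique(y)) < 2) return(NA_real_)
    delong_components(probs[, k], y)$auc
  }, 0)
}

#' Micro- and macro-averaged one-vs-rest AUC
#'
#' Macro is the unweighted mean of per-class one-vs-rest AUCs; micro pools
#' every (document, class) decision into one binary problem.
#'
#' @inheritParams ovr_aucs
#' @return List with `micro` and `macro`.
#' @export
micro_macro_auc <- function(probs, labels) {
  per <- ovr_aucs(probs, labels)
  onehot <- outer(as.character(labels), colnames(probs), "==") * 1L
  micro <- delong_components(as.vector(probs), as.vector(onehot))$auc
  list(micro = micro, macro = mean(per, na.rm = TRUE), per_class = per)
}

#' Confusion matrix with accuracy, sensitivity and specificity
#'
#' @param predicted Predicted class labels.
#' @param truth True class labels.
#' @param positive_class Positive class for sensitivity/specificity (binary
#'   rates computed one-vs-rest for multiclass inputs).
#' @return List with `confusion` (rows = truth), `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_and_rates <- function(predicted, truth, positive_class = NULL) {
  classes <- sort(unique(c(as.character(predicted), as.character(truth))))
  unknown <- setdiff(as.character(predicted), as.character(truth))
  if (length(unknown) && !all(unknown %in% classes)) {
    stopf("unknown label values: %s", paste(unknown, collapse = ", "))
  }
  p <- factor(as.character(predicted), levels = classes)
  t_ <- factor(as.character(truth), levels = classes)
  cm <- table(truth = t_, predicted = p)
  if (is.null(positive_class)) positive_class <- classes[length(classes)]
  if (!positive_class %in% classes) {
    stopf("unknown positive class '%s'", positive_class)
  }
  tp <- sum(cm[positive_class, positive_class])
  fn <- sum(cm[positive_class, ]) - tp
  fp <- sum(cm[, positive_class]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(confusion = cm,
       accuracy = sum(diag(cm)) / sum(cm),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Choose an operating threshold
#'
#' `"fixed"` returns `threshold` unchanged (default 0.5); `"youden"` returns
#' the score threshold maximizing sensitivity + specificity - 1.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param method `"fixed"` or `"youden"`.
#' @param threshold Threshold used by `"fixed"`.
#' @export
operating_point <- function(scores, labels, method = c("fixed", "youden"),
                            threshold = 0.5) {
  method <- match.arg(method)
  if (method == "fixed") return(threshold)
  y <- as01(labels)
  cuts <- sort(unique(scores))
  j <- vapply(cuts, function(ct) {
    sens <- mean(scores[y == 1] >= ct)
    spec <- mean(scores[y == 0] < ct)
    sens + spec - 1
  }, 0)
  cuts[which.max(j)]
}

#' DeLong test for two correlated AUCs
#'
#' Compares two models scored on the same documents; the covariance between
#' the two AUCs is estimated from the paired DeLong structural components.
#'
#' @param scores_a,scores_b Paired score vectors (same documents, same
#'   order).
#' @param labels Binary labels shared by both.
#' @param positive Optional positive-class label.
#' @return List with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b)) {
    stopf("scores must be paired on identical documents")
  }
  y <- as01(labels, positive)
  da <- delong_components(scores_a, y)
  db <- delong_components(scores_b, y)
  v10 <- cbind(da$v10, db$v10)
  v01 <- cbind(da$v01, db$v01)
  s10 <- stats::cov(v10)
  s01 <- stats::cov(v01)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  diff <- da$auc - db$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0
  } else {
    z <- diff / sqrt(var_diff)
  }
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p = if (z == 0 && diff == 0) 1 else 2 * stats::pnorm(-abs(z)))
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability `pt`:
#' `TP/n - FP/n * pt / (1 - pt)`, with treat-all and treat-none references.
#'
#' @param probs Predicted probabilities of the positive class.
#' @param labels Binary labels.
#' @param thresholds Threshold grid, all in (0, 1).
#' @return Data frame with columns `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probs, labels, thresholds = seq(0.01, 0.99, 0.01)) {
  if (!length(thresholds)) stopf("threshold grid is empty")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stopf("thresholds must lie strictly inside (0, 1)")
  }
  y <- as01(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    act <- probs >= pt
    tp <- sum(act & y == 1)
    fp <- sum(act & y == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}

#' Probability and prediction heatmaps of one slide
#'
#' Lays each tile's positive-class probability (and its predicted label) out
#' on the slide's tile grid. Cells without a kept tile are `NA` and are
#' rendered transparent.
#'
#' @param table Patch-likelihood table rows of a single slide.
#' @param likelihood_class Class whose probability fills the probability
#'   map; default the first class.
#' @param file Optional base path; when given, `<file>_prob.png` and
#'   `<file>_pred.png` are written (viridis colormap plus alpha).
#' @return List with `prob_map` and `pred_map` matrices (`(max_row + 1) x
#'   (max_col + 1)`) and the paths written (or `NULL`).
#' @export
probability_heatmap <- function(table, likelihood_class = NULL, file = NULL) {
  if (length(unique(table$slide_id)) != 1) {
    stopf("expected rows of exactly one slide")
  }
  if (anyDuplicated(table[c("grid_col", "grid_row")])) {
    stopf("duplicate grid cells in slide '%s'", table$slide_id[1])
  }
  classes <- plt_classes(table)
  if (is.null(likelihood_class)) likelihood_class <- classes[1]
  nr <- max(table$grid_row) + 1
  nc <- max(table$grid_col) + 1
  prob_map <- matrix(NA_real_, nr, nc)
  pred_map <- matrix(NA_integer_, nr, nc)
  ij <- cbind(table$grid_row + 1, table$grid_col + 1)
  prob_map[ij] <- table[[paste0("p_", likelihood_class)]]
  pred_map[ij] <- match(table$label, classes)
  paths <- NULL
  if (!is.null(file)) {
    paths <- c(prob = paste0(file, "_prob.png"),
               pred = paste0(file, "_pred.png"))
    write_map_png(prob_map, paths["prob"], zlim = c(0, 1))
    write_map_png((pred_map - 1) / max(1, length(classes) - 1), paths["pred"],
                  zlim = c(0, 1))
  }
  list(prob_map = prob_map, pred_map = pred_map, classes = classes,
       paths = paths)
}

# Render a [0,1] matrix as an RGBA PNG (viridis; NA -> transparent).
write_map_png <- function(m, path, zlim = c(0, 1)) {
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmin(255, pmax(0, floor((m - zlim[1]) / diff(zlim) * 255))) + 1
  col <- grDevices::col2rgb(pal[idx], alpha = FALSE) / 255
  rgba <- array(0, c(nrow(m), ncol(m), 4))
  for (ch in 1:3) rgba[, , ch] <- matrix(col[ch, ], nrow(m), ncol(m))
  rgba[, , 4] <- !is.na(m)
  rgba[is.na(rgba)] <- 0
  png::writePNG(rgba, target = path)
  invisible(path)
}

#' t-SNE embedding of a feature matrix
#'
#' Thin, seeded wrapper around exact (theta = 0) Rtsne for visualizing how
#' fusion features separate the classes.
#'
#' @param features Numeric matrix (documents x features).
#' @param seed Integer seed; fixes the embedding.
#' @param perplexity t-SNE perplexity; shrunk automatically for tiny inputs.
#' @return Numeric matrix (documents x 2), row names preserved.
#' @export
tsne_embed <- function(features, seed = 1, perplexity = 30) {
  features <- as.matrix(features)
  if (nrow(features) < 3) stopf("need at least 3 documents")
  if (!all(is.finite(features))) stopf("features must be finite")
  perplexity <- min(perplexity, floor((nrow(features) - 1) / 3))
  perplexity <- max(perplexity, 1)
  emb <- with_seed(seed, Rtsne::Rtsne(
    features, dims = 2, perplexity = perplexity, theta = 0,
    check_duplicates = FALSE, pca = nrow(features) > 3, verbose = FALSE,
    max_iter = 500)$Y)
  rownames(emb) <- rownames(features)
  emb
}

#' Evaluate one fitted WSI-level model
#'
#' Bundles the evaluation-suite outputs for a set of predictions into a
#' single report.
#'
#' @param probs Class-probability matrix (columns named by class) or, for
#'   binary tasks, a vector of positive-class probabilities.
#' @param labels True labels.
#' @param positive_class Positive class for the binary rates.
#' @param threshold Operating threshold (binary).
#' @param level `"patch"` or `"wsi"` metadata tag.
#' @param document_unit Metadata tag.
#' @return An `eval_report` list: `auc` (per class, with CIs), `micro`,
#'   `macro`, `confusion`, `accuracy`, `sensitivity`, `specificity`,
#'   `decision_curve`, `metadata`.
#' @export
evaluate_predictions <- function(probs, labels, positive_class = NULL,
                                 threshold = 0.5, level = "wsi",
                                 document_unit = "case_multi_slide") {
  if (is.null(dim(probs))) {
    if (is.null(positive_class)) positive_class <- "positive"
    probs <- cbind(1 - probs, probs)
    colnames(probs) <- c(paste0("not_", positive_class), positive_class)
    labels <- ifelse(as01(labels) == 1, positive_class,
                     paste0("not_", positive_class))
  }
  classes <- colnames(probs)
  if (is.null(positive_class)) positive_class <- classes[length(classes)]
  aucs <- lapply(classes, function(k) {
    y <- as.integer(as.character(labels) == k)
    if (length(unique(y)) < 2) return(list(auc = NA, ci_low = NA, ci_high = NA))
    auc_ci(probs[, k], y)
  })
  names(aucs) <- classes
  mm <- micro_macro_auc(probs, labels)
  if (length(classes) == 2) {
    pred <- ifelse(probs[, positive_class] >= threshold, positive_class,
                   setdiff(classes, positive_class))
    dc <- decision_curve(probs[, positive_class],
                         as.integer(as.character(labels) == positive_class))
  } else {
    pred <- classes[max.col(probs, ties.method = "first")]
    dc <- NULL
  }
  cr <- confusion_and_rates(pred, labels, positive_class)
  structure(list(auc = aucs, micro = mm$micro, macro = mm$macro,
                 confusion = cr$confusion, accuracy = cr$accuracy,
                 sensitivity = cr$sensitivity, specificity = cr$specificity,
                 decision_curve = dc,
                 metadata = list(level = level, document_unit = document_unit,
                                 threshold = threshold,
                                 positive_class = positive_class)),
            class = "eval_report")
}

#' Write an evaluation report as JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  x$confusion <- list(labels = rownames(x$confusion),
                      counts = unclass(as.matrix(x$confusion)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
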