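# Association screen between fusion features and binary pathological
# findings (daughter cysts, active epithelial proliferation, inflammation,
# unilocular/multilocular, basal-cell lace-like proliferation in the
# original study; names are arbitrary here).

#' Screen fusion features for association with one binary finding
#'
#' Per feature, a two-sided two-sample Welch t-test between finding-positive
#' and finding-negative cases (equivalently a point-biserial association).
#' Raw p-values are reported, matching the original analysis; a
#' Benjamini-Hochberg column is added for honest reuse. Features whose
#' statistic is undefined (constant within both groups) are dropped with a
#' warning.
#'
#' @param features Numeric matrix or data frame (cases x named features).
#' @param finding Binary 0/1 vector aligned with the rows.
#' @return Data frame `feature`, `statistic`, `p`, `p_adjusted`, in feature
#'   order.
#' @export
associate <- function(features, finding) {
  features <- as.matrix(features)
  if (!all(finding %in% c(0, 1))) stopf("finding must be binary 0/1")
  if (length(finding) != nrow(features)) {
    stopf("finding length does not match the feature rows")
  }
  if (min(table(factor(finding, levels = 0:1))) < 2) {
    stopf("both finding levels need at least 2 cases")
  }
  grp <- finding == 1
  x <- features[grp, , drop = FALSE]
  y <- features[!grp, , drop = FALSE]
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2, stats::var)
  v2 <- apply(y, 2, stats::var)
  se2 <- v1 / nrow(x) + v2 / nrow(y)
  t_ <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / nrow(x))^2 / (nrow(x) - 1) +
                   (v2 / nrow(y))^2 / (nrow(y) - 1))
  p <- 2 * stats::pt(-abs(t_), df)
  bad <- !is.finite(t_)
  if (any(bad)) {
    warnf("dropping %d feature(s) with undefined statistic", sum(bad))
  }
  out <- data.frame(feature = colnames(features), statistic = t_, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)[!bad, ]
  out$p_adjusted <- stats::p.adjust(out$p, "BH")
  out
}

#' Summarize an association screen
#'
#' @param assoc Output of [associate()].
#' @param alpha Significance level (default 0.05).
#' @param top_k Number of top features to rank (default 10).
#' @return List with `n_significant` (count of `p < alpha`) and `top` (data
#'   frame of the `top_k` features, ascending by p, ties broken by feature
#'   name).
#' @export
summarize_associations <- function(assoc, alpha = 0.05, top_k = 10) {
  ord <- order(assoc$p, assoc$feature)
  ranked <- assoc[ord, , drop = FALSE]
  list(n_significant = sum(assoc$p < alpha),
       top = utils::head(ranked, top_k))
}

#' Run the association screen over a findings table
#'
#' @param features Matrix (cases x features), rows named/ordered by
#'   `findings$case_id`.
#' @param findings Data frame with `case_id` and one binary column per
#'   finding.
#' @return Long data frame `feature`, `finding`, `statistic`, `p`,
#'   `p_adjusted`.
#' @export
screen_findings <- function(features, findings) {
  stopifnot("case_id" %in% names(findings))
  cols <- setdiff(names(findings), "case_id")
  res <- lapply(cols, function(f) {
    a <- associate(features, findings[[f]])
    a$finding <- f
    a
  })
  out <- do.call(rbind, res)
  out[c("feature", "finding", "statistic", "p", "p_adjusted")]
}
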