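#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). This is
#' the statistic used to compare an individual sample profile against a
#' centroid reference signature.
#'
#' @param x,y numeric vectors of equal length >= 3, each with at least two
#'   distinct values.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. The exact null distribution is used
#' when there are no ties and the pooled size is at most 12; otherwise the
#' tie-corrected normal approximation with continuity correction. U is
#' reported for the first sample (number of pairs `(a_i, b_j)` with
#' `a_i > b_j`, counting ties as half).
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with elements `U` and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 12L
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # degenerate case: pooled values all tied, z = 0
  list(U = unname(ht$statistic), p = p)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive row
#'   and column margins.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  stats::fisher.test(tab)$p.value
}

#' Rank-based area under the ROC curve
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)` over all
#' positive/negative score pairs; equivalently the normalized Mann-Whitney
#' statistic of the positive-class scores.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks handle ties as half-concordant
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Summarize classifier performance against known status
#'
#' Builds the confusion table with disease (`"SLE"`) as the positive class
#' and derives PPV, NPV, sensitivity and specificity; ratios with a zero
#' denominator are reported as `NA`, never coerced to 0 or 1. If scores are
#' supplied, the rank AUC is included.
#'
#' @param calls character vector of predicted labels (`"SLE"`/`"HEALTHY"`).
#' @param truth character vector of true labels, same length.
#' @param scores optional numeric scores underlying the calls.
#' @return object of class `"performance_report"`.
#' @export
evaluate_predictions <- function(calls, truth, scores = NULL) {
  if (length(calls) == 0L) stop("no predictions to evaluate", call. = FALSE)
  if (length(calls) != length(truth)) {
    stop("calls and truth differ in length", call. = FALSE)
  }
  if (!all(truth %in% c("SLE", "HEALTHY"))) {
    stop("every sample needs a known status (SLE or HEALTHY)", call. = FALSE)
  }
  tp <- sum(calls == "SLE" & truth == "SLE")
  fp <- sum(calls == "SLE" & truth == "HEALTHY")
  tn <- sum(calls == "HEALTHY" & truth == "HEALTHY")
  fn <- sum(calls == "HEALTHY" & truth == "SLE")
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  # AUC needs both classes; with one-class truth it is undefined, not 0
  auc <- if (!is.null(scores) && length(unique(truth)) == 2L) {
    rank_auc(scores, truth == "SLE")
  } else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 auc = auc),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Prediction performance (positive class: SLE)\n")
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("  sensitivity:", fmt(x$sensitivity),
      " specificity:", fmt(x$specificity), "\n")
  cat("  PPV:", fmt(x$ppv), " NPV:", fmt(x$npv),
      " AUC:", fmt(x$auc), "\n")
  invisible(x)
}
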