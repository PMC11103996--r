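#' Confusion matrix and accuracy rates for a blinded validation
#'
#' Tabulates true group against predicted label and reports the overall
#' accuracy (percent, trace over total) and the per-group correct rates
#' (diagonal over row totals), all rounded half-up to one decimal for
#' display, matching the published validation table's arithmetic.
#'
#' @param truth true group labels.
#' @param predicted predicted labels, same length.
#' @return an object of class `confusion_matrix`: `counts` (true x
#'   predicted), `overall_accuracy`, `per_group_correct_rate`, `n`.
#' @export
#' @examples
#' confusion_metrics(rep(c("response", "progression"), c(30, 28)),
#'                   rep(c("response", "progression", "response"), c(27, 29, 2)))
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  if (length(truth) == 0L) stop("empty label vectors")
  lev <- c("response", "progression")
  if (!all(truth %in% lev) || !all(predicted %in% lev))
    lev <- sort(unique(c(truth, predicted)))
  counts <- table(factor(truth, lev), factor(predicted, lev), dnn = c("true", "predicted"))
  overall <- 100 * sum(diag(counts)) / sum(counts)
  per_group <- 100 * diag(counts) / rowSums(counts)
  structure(list(counts = counts,
                 overall_accuracy = overall,
                 per_group_correct_rate = per_group,
                 n = length(truth)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Blinded validation\n\n")
  print(x$counts)
  cat(sprintf("\nOverall accuracy: %.1f%% (%d/%d)\n",
              round_half_up(x$overall_accuracy), sum(diag(x$counts)), x$n))
  for (g in rownames(x$counts))
    cat(sprintf("  %s correct: %.1f%%\n", g,
                round_half_up(x$per_group_correct_rate[g])))
  invisible(x)
}

#' Chi-square or Fisher test for a 2x2 contingency table
#'
#' Pearson's chi-square without continuity correction when all expected
#' counts are at least 5 (the convention that reproduces the published
#' cohort-balance p-values exactly), otherwise Fisher's exact test.
#'
#' @param counts a 2x2 matrix of non-negative integer counts.
#' @return a list: `statistic` (chi-square, `NA` for Fisher), `p_value`,
#'   `method`.
#' @export
#' @examples
#' contingency_test(matrix(c(32, 18, 34, 12), 2, byrow = TRUE))
contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) stop("zero-margin table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(counts, correct = FALSE)
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         method = "pearson-chi-square")
  } else {
    ft <- stats::fisher.test(counts)
    list(statistic = NA_real_, p_value = ft$p.value, method = "fisher-exact")
  }
}
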