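# Validity battery: marginal reliability, ROC/AUC against a binary
# high-stress criterion, and per-rule criterion correlations.

#' Marginal reliability of a set of EAP estimates
#'
#' Default (`"empirical"`) form: `var(eap) / (var(eap) + mean(se^2))` — the
#' reliability of the realized trait estimates averaged over the cohort.
#' The `"population"` form `1 - mean(se^2)` assumes the prior variance of 1
#' as the total; the two agree when the EAP variance plus error variance
#' reproduces the prior.
#'
#' @param eaps Vector of trait estimates.
#' @param ses Vector of their posterior SDs (positive).
#' @param type `"empirical"` or `"population"`.
#' @return Scalar reliability in `[0, 1]` (0, with a warning, when the
#'   estimates have zero variance).
#' @export
marginal_reliability <- function(eaps, ses, type = c("empirical", "population")) {
  type <- match.arg(type)
  stopifnot(length(eaps) == length(ses), all(ses > 0))
  v <- stats::var(eaps)
  if (v <= 0 || is.na(v)) {
    warning("zero variance in trait estimates; reliability set to 0")
    return(0)
  }
  if (type == "empirical") v / (v + mean(ses^2)) else max(0, 1 - mean(ses^2))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive case scores above a randomly chosen negative one, ties counted
#' half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (0/1 or logical).
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                                   # average ranks: half-weight ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve over all distinct score thresholds
#'
#' @inheritParams auc
#' @return A `roc_result`: data frame `points` with `threshold`,
#'   `sensitivity`, `specificity` (declared positive when `score >=
#'   threshold`), plus the trapezoidal `auc` (equal to the Mann-Whitney
#'   [auc()] under half-weight ties).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  th <- c(sort(unique(scores)), Inf)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  sens <- vapply(th, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  spec <- vapply(th, function(t) sum(scores < t & labels == 0L) / n0, numeric(1))
  # order from (sens=1, spec=0) to (sens=0, spec=1)
  pts <- data.frame(threshold = c(-Inf, th), sensitivity = c(1, sens),
                    specificity = c(0, spec))
  fpr <- 1 - pts$specificity
  area <- -sum(diff(fpr) * (pts$sensitivity[-1] + pts$sensitivity[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = area), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: %d thresholds, AUC = %.3f>\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Criterion validity report for a simulated CAT cohort
#'
#' For each stopping rule in a [simulate_cohort()] result, reports the
#' Pearson correlation between the CAT trait estimates and an external
#' criterion sum score, and the AUC of the estimates against a binary
#' high-criterion label (the external-criteria table of a CAT validation).
#'
#' @param cohort A `cat_cohort` from [simulate_cohort()].
#' @param criterion_sum Numeric criterion total score per person.
#' @param high_label Binary label per person (e.g. criterion > 28).
#' @return Data frame: one row per rule with `rule`, `items_used_mean`,
#'   `mean_se`, `marginal_reliability`, `corr_with_full`,
#'   `corr_with_criterion`, `auc`.
#' @export
criterion_report <- function(cohort, criterion_sum, high_label) {
  stopifnot(inherits(cohort, "cat_cohort"))
  n <- nrow(cohort$full)
  if (length(criterion_sum) != n || length(high_label) != n)
    stop("criterion vectors must align with the cohort's persons")
  out <- cohort$summary
  out$corr_with_criterion <- vapply(cohort$persons, function(d)
    stats::cor(d$eap, criterion_sum), numeric(1))
  out$auc <- vapply(cohort$persons, function(d)
    auc(d$eap, high_label), numeric(1))
  out
}
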