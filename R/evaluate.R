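# Aggregation of repeated test decisions: matched percentages and ROC/AUC.

#' Matched percentage of trial decisions
#'
#' Fraction (in percent) of trial sampling segments whose hypothesis-test
#' decision matches the truth. For a true-class input the correct decision
#' is `accept_H0`; for a false-class input it is `reject_H0`, and both the
#' raw accept-rate and the correct-rejection rate are reported explicitly.
#'
#' @param decisions character vector of `"accept_H0"` / `"reject_H0"`.
#' @param truth `"true_class"` or `"false_class"`.
#' @return named numeric vector: `accept_pct` (accept-rate, %) and
#'   `correct_pct` (percentage of correct decisions, %).
#' @export
#' @examples
#' matchedPercentage(c(rep("reject_H0", 93), rep("accept_H0", 7)),
#'                   "false_class")
matchedPercentage <- function(decisions,
                              truth = c("true_class", "false_class")) {
  truth <- match.arg(truth)
  if (length(decisions) == 0L) stop("'decisions' must be nonempty")
  if (!all(decisions %in% c("accept_H0", "reject_H0")))
    stop("decisions must be 'accept_H0' or 'reject_H0'")
  acc <- 100 * mean(decisions == "accept_H0")
  c(accept_pct = acc,
    correct_pct = if (truth == "true_class") acc else 100 - acc)
}

#' ROC curve and AUC from recognition statistics
#'
#' Sweeps a threshold over the pooled statistic values of positive-class
#' and negative-class trials and reports the ROC curve plus the area under
#' it. The AUC is computed by the trapezoid rule and, independently, as the
#' Mann-Whitney probability that a positive-class statistic outranks a
#' negative-class one (ties half credit); the two must agree to 1e-12 and
#' the function stops otherwise.
#'
#' For the two-sided F statistic use `abs(log(F))` as the sweep score; the
#' ECDF statistic \eqn{\Lambda} is already one-sided.
#'
#' @param posStats statistics of positive-class trials (e.g. cross-class,
#'   mismatched pairs).
#' @param negStats statistics of negative-class trials (matched pairs).
#' @param higherIsPositive if TRUE (default) larger statistics indicate the
#'   positive class.
#' @param n sample size the statistics were computed at (stored, optional).
#' @return a [RocResult-class].
#' @export
#' @examples
#' r <- rocFromStatistics(c(2, 3, 4), c(1, 2, 3), higherIsPositive = TRUE)
#' auc(r)
rocFromStatistics <- function(posStats, negStats, higherIsPositive = TRUE,
                              n = NA_integer_) {
  if (length(posStats) == 0L || length(negStats) == 0L)
    stop("both statistic vectors must be nonempty")
  sgn <- if (higherIsPositive) 1 else -1
  pos <- sgn * posStats
  neg <- sgn * negStats
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  aucTrap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # Mann-Whitney route via midranks
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg))
  aucMW <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  if (abs(aucTrap - aucMW) > 1e-12)
    stop("internal error: trapezoid and Mann-Whitney AUC disagree")
  new("RocResult", thresholds = sgn * thr, tpr = tpr, fpr = fpr,
      auc = aucTrap, n = as.integer(n))
}
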