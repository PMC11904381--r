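# Evaluation metrics with the study's three confidence-interval
# constructions: Wald intervals for the four rates, a rank-statistic
# (Hanley-McNeil) standard error for AUC / average PPV / standardized net
# benefit, and a Hoeffding bound for the Brier score.

#' Metric estimate container
#'
#' @param name Metric identifier.
#' @param value Point estimate (`NA` when undefined).
#' @param ci_low,ci_high Confidence bounds.
#' @param ci_method One of `"wald"`, `"riley_se"`, `"hoeffding"`, `"none"`.
#' @param alpha Two-sided significance level of the interval.
#' @param n Sample size backing the estimate.
#' @param defined `FALSE` when the metric's denominator is empty; undefined
#'   metrics are reported explicitly, never as silent zeros.
#' @return A `metric_estimate` list.
#' @export
metric_estimate <- function(name, value, ci_low = NA_real_, ci_high = NA_real_,
                            ci_method = "none", alpha = 0.05, n = 0L,
                            defined = !is.na(value)) {
  structure(list(name = name, value = value, ci_low = ci_low,
                 ci_high = ci_high, ci_method = ci_method, alpha = alpha,
                 n = as.integer(n), defined = defined),
            class = "metric_estimate")
}

#' @export
format.metric_estimate <- function(x, digits = 3, ...) {
  if (!x$defined) return(sprintf("%s: —", x$name))
  if (x$ci_method == "none")
    return(sprintf("%s: %.*f", x$name, digits, x$value))
  sprintf("%s: %.*f (%.*f, %.*f)", x$name, digits, x$value,
          digits, x$ci_low, digits, x$ci_high)
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

undefined_estimate <- function(name, alpha = 0.05, n = 0L) {
  metric_estimate(name, NA_real_, NA_real_, NA_real_, "none", alpha, n, FALSE)
}

#' Confusion counts from binary decisions
#'
#' @param decisions Binary predictions: 0/1, logical, or the strings
#'   `"sepsis"`/`"no_sepsis"`. Abstentions must be removed by the caller.
#' @param labels Binary reference labels aligned with `decisions`.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(decisions, labels) {
  if (length(decisions) != length(labels))
    stop("confusion: decisions and labels differ in length")
  if (length(labels) == 0) stop("confusion: empty input")
  if (is.character(decisions) || is.factor(decisions)) {
    decisions <- as.character(decisions)
    if (any(decisions == "abstain"))
      stop("confusion: abstained rows must be excluded by the caller")
    decisions <- as.integer(decisions == "sepsis")
  }
  d <- as.integer(as.logical(as.numeric(decisions)))
  y <- as.integer(labels)
  structure(list(tp = sum(d == 1 & y == 1), fp = sum(d == 1 & y == 0),
                 tn = sum(d == 0 & y == 0), fn = sum(d == 0 & y == 1)),
            class = "confusion_counts")
}

wald_ci <- function(p, n, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - hw), min(1, p + hw))
}

#' Rate metrics with Wald confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' confusion table, each with the Wald interval
#' \eqn{p \pm z_{\alpha/2}\sqrt{p(1-p)/n}} over its own denominator, clipped
#' to [0, 1]. A metric whose denominator is zero is returned undefined.
#'
#' @param counts A [confusion()] result.
#' @param alpha Two-sided significance level (default 0.05 for 95% CIs).
#' @return Named list of four [metric_estimate()] objects.
#' @export
rate_metrics <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  one <- function(name, num, den) {
    if (den == 0) return(undefined_estimate(name, alpha))
    p <- num / den
    ci <- wald_ci(p, den, alpha)
    metric_estimate(name, p, ci[1], ci[2], "wald", alpha, den)
  }
  list(sensitivity = one("sensitivity", counts$tp, counts$tp + counts$fn),
       specificity = one("specificity", counts$tn, counts$tn + counts$fp),
       ppv = one("ppv", counts$tp, counts$tp + counts$fp),
       npv = one("npv", counts$tn, counts$tn + counts$fn))
}

# Hanley-McNeil standard error for a rank statistic v with n1 positives and
# n0 negatives; used as the SE behind the AUC / A-PPV / sNB intervals.
hanley_mcneil_se <- function(v, n1, n0) {
  v <- min(max(v, 1e-12), 1 - 1e-12)
  q1 <- v / (2 - v)
  q2 <- 2 * v^2 / (1 + v)
  sqrt((v * (1 - v) + (n1 - 1) * (q1 - v^2) + (n0 - 1) * (q2 - v^2)) /
         (n1 * n0))
}

# Mann-Whitney AUC via midranks: P(score+ > score-) + 0.5 P(tie).
auc_value <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a rank-statistic confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic
#' (probability that a random sepsis case scores above a random non-sepsis
#' case, ties counted half), with a Wald-form interval around the estimate
#' using the Hanley-McNeil standard error, clipped to [0, 1]. Undefined when
#' only one class is present.
#'
#' @param scores Numeric confidence scores.
#' @param labels Binary labels.
#' @param alpha Two-sided significance level.
#' @return A [metric_estimate()].
#' @export
auc_estimate <- function(scores, labels, alpha = 0.05) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(undefined_estimate("auc", alpha, length(y)))
  v <- auc_value(scores, y)
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * hanley_mcneil_se(v, n1, n0)
  metric_estimate("auc", v, max(0, v - hw), min(1, v + hw),
                  "riley_se", alpha, length(y))
}

# Average precision over the sensitivity-PPV curve, with tied scores grouped
# at distinct thresholds: sum over thresholds of (recall step) x precision.
average_ppv_value <- function(scores, labels) {
  y <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  # group boundaries at distinct score values
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  n_at <- seq_along(y)[last_of_group]
  prec <- tp / n_at
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Average PPV (average precision) with a rank-statistic interval
#'
#' Step-wise average of the positive predictive value across sensitivity
#' levels: positives are ranked by descending score and the precision at
#' each positive's rank is averaged. Tied scores are grouped at their common
#' threshold (the step-interpolation convention), which makes the value
#' independent of the ordering within ties. The interval reuses the
#' Hanley-McNeil standard error. Undefined with no positives.
#'
#' @inheritParams auc_estimate
#' @return A [metric_estimate()].
#' @export
average_ppv_estimate <- function(scores, labels, alpha = 0.05) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0) return(undefined_estimate("a_ppv", alpha, length(y)))
  v <- average_ppv_value(scores, y)
  if (n0 == 0) return(metric_estimate("a_ppv", v, v, v, "none", alpha, length(y)))
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * hanley_mcneil_se(v, n1, n0)
  metric_estimate("a_ppv", v, max(0, v - hw), min(1, v + hw),
                  "riley_se", alpha, length(y))
}

#' Brier score with a Hoeffding confidence interval
#'
#' Mean squared difference between confidence score and outcome (a
#' calibration measure), with the distribution-free Hoeffding half-width
#' \eqn{\sqrt{\ln(2/\alpha)/(2n)}}, clipped to [0, 1].
#'
#' @inheritParams auc_estimate
#' @return A [metric_estimate()].
#' @export
brier_estimate <- function(scores, labels, alpha = 0.05) {
  if (length(scores) == 0) return(undefined_estimate("brier", alpha))
  v <- mean((scores - as.numeric(labels))^2)
  hw <- sqrt(log(2 / alpha) / (2 * length(scores)))
  metric_estimate("brier", v, max(0, v - hw), min(1, v + hw),
                  "hoeffding", alpha, length(scores))
}

#' Standardized net benefit
#'
#' Decision-curve net benefit at decision threshold t,
#' \eqn{NB = sens\,\pi - (1-spec)(1-\pi)\,t/(1-t)}, standardized by the
#' prevalence: \eqn{sNB = NB/\pi}, so a perfect classifier scores 1 at any
#' prevalence. The interval reuses the Hanley-McNeil standard error (with
#' the value clamped into (0,1) for the SE computation); the upper bound is
#' clipped at 1, the lower bound is unrestricted.
#'
#' @param counts A [confusion()] result at the operating point implied by
#'   `decision_threshold`.
#' @param decision_threshold Probability threshold t of the decision rule
#'   (default 0.5).
#' @param alpha Two-sided significance level.
#' @return A [metric_estimate()].
#' @export
snb_estimate <- function(counts, decision_threshold = 0.5, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  n1 <- counts$tp + counts$fn
  if (n1 == 0) return(undefined_estimate("snb", alpha, n))
  pi_hat <- n1 / n
  sens <- counts$tp / n1
  spec <- if (n - n1 > 0) counts$tn / (n - n1) else 1
  t <- decision_threshold
  nb <- sens * pi_hat - (1 - spec) * (1 - pi_hat) * t / (1 - t)
  v <- nb / pi_hat
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * hanley_mcneil_se(v, n1, max(n - n1, 1))
  metric_estimate("snb", v, v - hw, min(1, v + hw), "riley_se", alpha, n)
}
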