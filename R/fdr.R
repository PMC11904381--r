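# Model-comparison machinery: chi-square tests on 2x2 success/failure
# tables for the rate metrics, and the Gavrilov-Benjamini-Sarkar optimal
# adaptive step-down false discovery rate procedure.

# Success/failure counts relevant to a rate metric.
metric_success_failure <- function(counts, metric) {
  stopifnot(inherits(counts, "confusion_counts"))
  switch(metric,
         sensitivity = c(counts$tp, counts$fn),
         specificity = c(counts$tn, counts$fp),
         ppv = c(counts$tp, counts$fp),
         npv = c(counts$tn, counts$fn),
         stop("chi_square_compare: no 2x2 table for metric '", metric,
              "' (rate metrics only)"))
}

#' Chi-square comparison of two classifiers on a rate metric
#'
#' Builds the 2x2 success/failure table for the chosen rate metric (e.g.
#' sensitivity: true positives vs false negatives per classifier, over each
#' classifier's positives) and applies Pearson's chi-square test without
#' continuity correction. For one-tailed use the two-tailed p is halved when
#' the observed difference lies in the hypothesized direction (group 1
#' better than group 2), and is `1 - p/2` otherwise.
#'
#' @param c1,c2 [confusion()] results for the two classifiers.
#' @param metric One of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`.
#' @param tails `"two"` (different performance) or `"one"` (group 1 better).
#' @param hypothesis_id Optional identifier carried through to the result.
#' @return A `hypothesis_result` list with `statistic`, `p_raw`, `defined`,
#'   and `p_adjusted`/`rejected` left unset for [gavrilov_adjust()].
#' @export
chi_square_compare <- function(c1, c2, metric, tails = c("two", "one"),
                               hypothesis_id = NULL) {
  tails <- match.arg(tails)
  sf1 <- metric_success_failure(c1, metric)
  sf2 <- metric_success_failure(c2, metric)
  if (sum(sf1) == 0 || sum(sf2) == 0) {
    return(structure(list(hypothesis_id = hypothesis_id, metric = metric,
                          tails = tails, statistic = NA_real_,
                          p_raw = NA_real_, defined = FALSE,
                          p_adjusted = NA_real_, rejected = NA),
                     class = "hypothesis_result"))
  }
  tab <- rbind(sf1, sf2)
  if (any(colSums(tab) == 0)) {
    # all successes (or all failures) in both groups: no evidence of
    # difference; statistic 0 by convention
    stat <- 0; p2 <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p2 <- unname(ct$p.value)
  }
  if (tails == "two") {
    p <- p2
  } else {
    direction_1_better <- sf1[1] / sum(sf1) > sf2[1] / sum(sf2)
    p <- if (direction_1_better) p2 / 2 else 1 - p2 / 2
  }
  structure(list(hypothesis_id = hypothesis_id, metric = metric,
                 tails = tails, statistic = stat, p_raw = p, defined = TRUE,
                 p_adjusted = NA_real_, rejected = NA),
            class = "hypothesis_result")
}

#' Gavrilov-Benjamini-Sarkar adaptive step-down FDR adjustment
#'
#' Step-down multiple-testing procedure with critical constants
#' \eqn{c_k = k\alpha / (m + 1 - k(1-\alpha))} applied to the increasingly
#' sorted p-values: the procedure rejects the largest prefix whose sorted
#' p-values all sit below their constants. At m = 1 the rule reduces to
#' comparing p against \eqn{\alpha/(1+\alpha)}. Adjusted p-values are the
#' smallest \eqn{\alpha} at which each sorted p-value would be rejected,
#' made non-decreasing along the sorted order (via the running maximum) and
#' capped at 1; results are returned in the original input order.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @param alpha Target false discovery rate in (0, 1).
#' @return Data frame with columns `p_raw`, `p_adjusted`, `rejected`, in
#'   input order.
#' @export
gavrilov_adjust <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("gavrilov_adjust: p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("gavrilov_adjust: alpha must be in (0, 1)")
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  k <- seq_len(m)
  crit <- k * alpha / (m + 1 - k * (1 - alpha))
  below <- ps <= crit
  n_rej <- if (all(below)) m else which(!below)[1] - 1L
  rejected_sorted <- k <= n_rej
  # smallest alpha with p_(k) <= c_k(alpha):  p(m+1-k) / (k(1-p))
  a_k <- ifelse(ps >= 1, 1, pmin(1, ps * (m + 1 - k) / (k * (1 - ps))))
  adj_sorted <- cummax(a_k)
  out <- data.frame(p_raw = p_values, p_adjusted = NA_real_, rejected = NA)
  out$p_adjusted[o] <- adj_sorted
  out$rejected[o] <- rejected_sorted
  out
}

#' Adjust a list of hypothesis results as one FDR family
#'
#' Applies [gavrilov_adjust()] to the raw p-values of a list of
#' [chi_square_compare()] results (undefined results are passed through
#' untouched and do not count toward the family size m).
#'
#' @param results List of `hypothesis_result` objects.
#' @param alpha Target false discovery rate.
#' @return The list with `p_adjusted` and `rejected` filled in.
#' @export
adjust_family <- function(results, alpha = 0.05) {
  ok <- vapply(results, function(r) isTRUE(r$defined), logical(1))
  if (any(ok)) {
    adj <- gavrilov_adjust(vapply(results[ok], `[[`, numeric(1), "p_raw"), alpha)
    j <- 0
    for (i in which(ok)) {
      j <- j + 1
      results[[i]]$p_adjusted <- adj$p_adjusted[j]
      results[[i]]$rejected <- adj$rejected[j]
    }
  }
  results
}
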