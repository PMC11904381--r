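# Cautious (abstaining) classification: threshold-based three-way decisions
# over any confidence-score vector, the two-feature partial decision rule
# (PDR) over MDW and neutrophils, coverage, and high-confidence (HC) metric
# evaluation on the non-abstained subset.

tri_levels <- c("no_sepsis", "sepsis", "abstain")

#' Three-region cautious prediction
#'
#' Converts confidence scores for sepsis into three-way decisions at an
#' upper threshold `th` (and implied lower threshold `1 - th`): score
#' >= `th` is called sepsis, score <= `1 - th` is called no sepsis, and
#' anything in the open interval between abstains. The default `th = 0.75`
#' abstains on scores strictly between 0.25 and 0.75.
#'
#' @param scores Numeric scores in [0, 1].
#' @param th Upper confidence threshold in (0.5, 1].
#' @return Character vector with values `"sepsis"`, `"no_sepsis"`,
#'   `"abstain"`.
#' @export
cautious_predict <- function(scores, th = 0.75) {
  if (th <= 0.5 || th > 1)
    stop("cautious_predict: th must lie in (0.5, 1]")
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1))
    stop("cautious_predict: scores must lie in [0, 1]")
  out <- rep("abstain", length(scores))
  out[scores >= th] <- "sepsis"
  out[scores <= 1 - th] <- "no_sepsis"
  out
}

#' Partial decision rule over MDW and neutrophils
#'
#' The interpretable cautious rule set distilled from the tuned decision
#' tree: sepsis when MDW > 24.1; no sepsis when MDW <= 24.1 and neutrophils
#' <= 8.6, or when MDW <= 20.5 and neutrophils > 8.6; abstain otherwise
#' (i.e. 20.5 < MDW <= 24.1 with neutrophils > 8.6). Comparisons are exactly
#' as printed (strict / non-strict). Units: MDW is unitless, neutrophils in
#' 10^9/L.
#'
#' @param mdw,neutrophils Numeric vectors, observed, finite, non-negative.
#' @return Character vector of three-way decisions.
#' @export
pdr_predict <- function(mdw, neutrophils) {
  if (length(mdw) != length(neutrophils))
    stop("pdr_predict: input lengths differ")
  bad <- !is.finite(mdw) | !is.finite(neutrophils) | mdw < 0 | neutrophils < 0
  if (any(bad))
    stop("pdr_predict: missing or invalid input at row ", which(bad)[1])
  out <- rep("abstain", length(mdw))
  out[mdw > 24.1] <- "sepsis"
  out[mdw <= 24.1 & neutrophils <= 8.6] <- "no_sepsis"
  out[mdw <= 20.5 & neutrophils > 8.6] <- "no_sepsis"
  out
}

#' Coverage of a three-way decision vector
#'
#' @param decisions Character vector of `"sepsis"`/`"no_sepsis"`/`"abstain"`.
#' @return Exact fraction of non-abstain decisions.
#' @export
coverage <- function(decisions) {
  if (length(decisions) == 0) stop("coverage: empty decision vector")
  if (!all(decisions %in% tri_levels))
    stop("coverage: decisions must be sepsis / no_sepsis / abstain")
  mean(decisions != "abstain")
}

#' High-confidence evaluation of a cautious classifier
#'
#' Applies [cautious_predict()] at threshold `th` and evaluates every study
#' metric (sensitivity, specificity, PPV, NPV, AUC, average PPV, Brier
#' score, standardized net benefit) restricted to the non-abstained
#' ("high-confidence") rows, together with the coverage. AUC, A-PPV and the
#' Brier score use the covered rows' raw scores (they are rank/calibration
#' metrics, not re-thresholded decisions); the sNB uses the covered
#' confusion table at `snb_threshold`. Metrics whose denominators are empty
#' on the covered subset are reported as undefined, never as zero.
#'
#' @param scores Confidence scores in [0, 1].
#' @param labels Binary labels aligned with `scores`.
#' @param th Abstention threshold in (0.5, 1].
#' @param alpha Significance level for all intervals.
#' @param snb_threshold Decision threshold for the net-benefit computation.
#' @return A `cautious_result` list with `decisions`, `coverage` and
#'   `hc_metrics` (named list of [metric_estimate()]).
#' @export
hc_evaluate <- function(scores, labels, th = 0.75, alpha = 0.05,
                        snb_threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("hc_evaluate: scores and labels differ in length")
  decisions <- cautious_predict(scores, th)
  cov <- coverage(decisions)
  keep <- decisions != "abstain"
  nm <- c("sensitivity", "specificity", "ppv", "npv",
          "auc", "a_ppv", "brier", "snb")
  if (!any(keep)) {
    hc <- stats::setNames(lapply(nm, undefined_estimate, alpha = alpha), nm)
  } else {
    cc <- confusion(decisions[keep], labels[keep])
    hc <- rate_metrics(cc, alpha)
    hc$auc <- auc_estimate(scores[keep], labels[keep], alpha)
    hc$a_ppv <- average_ppv_estimate(scores[keep], labels[keep], alpha)
    hc$brier <- brier_estimate(scores[keep], labels[keep], alpha)
    hc$snb <- if (sum(labels[keep]) > 0) {
      snb_estimate(cc, snb_threshold, alpha)
    } else undefined_estimate("snb", alpha, sum(keep))
  }
  structure(list(decisions = decisions, coverage = cov, hc_metrics = hc,
                 th = th),
            class = "cautious_result")
}

#' @export
print.cautious_result <- function(x, ...) {
  cat(sprintf("<cautious_result> th = %.2f, coverage = %.3f\n", x$th, x$coverage))
  for (m in x$hc_metrics) cat(" ", format(m), "\n")
  invisible(x)
}
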