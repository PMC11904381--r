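# Study orchestration: train and tune on one cohort, evaluate standard,
# cautious, decision-rule and biomarker-baseline variants across internal
# and external cohorts (imputing MDW first where it is missing), and
# assemble the model x cohort x metric grid with confidence intervals and
# FDR-adjusted hypothesis tests. External cohorts are never pooled into
# training: every validation set stays entirely blind.

#' Study configuration
#'
#' @param train_cohort Id of the training cohort.
#' @param eval_cohorts Ids of the external validation cohorts (must not
#'   include the training cohort — no dataset pooling).
#' @param families Model families to tune and fit.
#' @param budget Randomized-search budget per family.
#' @param folds Stratified CV folds.
#' @param th Abstention threshold of the cautious layer.
#' @param alpha Significance level for intervals and FDR.
#' @param snb_threshold Decision threshold for the net-benefit metric.
#' @param split_fraction Internal train fraction (default 0.75).
#' @param baselines List of `list(feature, threshold, direction)` biomarker
#'   baselines; defaults to MDW > 23.5 and CRP > 80.
#' @param non_mdw_cohorts Ids of evaluation cohorts whose MDW must be
#'   imputed before scoring.
#' @param seed Master seed for every stochastic stage.
#' @return A `study_config` list.
#' @export
study_config <- function(train_cohort, eval_cohorts, families = "logistic_regression",
                         budget = 25L, folds = 5L, th = 0.75, alpha = 0.05,
                         snb_threshold = 0.5, split_fraction = 0.75,
                         baselines = list(
                           list(feature = "mdw", threshold = 23.5, direction = "greater"),
                           list(feature = "crp", threshold = 80, direction = "greater")),
                         non_mdw_cohorts = character(0), seed = 1L) {
  if (train_cohort %in% eval_cohorts)
    stop("study_config: the training cohort cannot appear among ",
         "eval_cohorts (no dataset pooling)")
  families <- vapply(families, match.arg, "", choices = model_families())
  stopifnot(all(non_mdw_cohorts %in% eval_cohorts))
  structure(list(train_cohort = train_cohort, eval_cohorts = eval_cohorts,
                 families = unname(families), budget = as.integer(budget),
                 folds = as.integer(folds), th = th, alpha = alpha,
                 snb_threshold = snb_threshold,
                 split_fraction = split_fraction, baselines = baselines,
                 non_mdw_cohorts = non_mdw_cohorts, seed = as.integer(seed)),
            class = "study_config")
}

estimate_row <- function(model, cohort, variant, est) {
  data.frame(model = model, cohort = cohort, metric = est$name,
             variant = variant, value = est$value, ci_low = est$ci_low,
             ci_high = est$ci_high, ci_method = est$ci_method,
             n = est$n, defined = est$defined)
}

# All-metric evaluation of a score vector (standard variant, decisions at
# score >= 0.5).
standard_eval <- function(scores, labels, alpha, snb_threshold) {
  cc <- confusion(as.integer(scores >= 0.5), labels)
  ests <- rate_metrics(cc, alpha)
  ests$auc <- auc_estimate(scores, labels, alpha)
  ests$a_ppv <- average_ppv_estimate(scores, labels, alpha)
  ests$brier <- brier_estimate(scores, labels, alpha)
  ests$snb <- if (sum(labels) > 0) snb_estimate(cc, snb_threshold, alpha)
              else undefined_estimate("snb", alpha, length(labels))
  ests
}

# Rate-metric evaluation of a (possibly abstaining) decision vector;
# rank/calibration metrics are undefined without scores.
decision_eval <- function(decisions, labels, alpha) {
  keep <- decisions != "abstain"
  ests <- if (any(keep)) rate_metrics(confusion(decisions[keep], labels[keep]), alpha)
          else stats::setNames(lapply(c("sensitivity", "specificity", "ppv", "npv"),
                                      undefined_estimate, alpha = alpha),
                               c("sensitivity", "specificity", "ppv", "npv"))
  for (nm in c("auc", "a_ppv", "brier", "snb"))
    ests[[nm]] <- undefined_estimate(nm, alpha)
  ests
}

covered_confusion <- function(decisions, labels) {
  keep <- decisions != "abstain"
  if (!any(keep)) return(NULL)
  confusion(decisions[keep], labels[keep])
}

#' Run the full study
#'
#' Performs the stratified internal split of the training cohort, tunes
#' each requested family by randomized search, refits the best
#' configuration on the full training portion, evaluates every model on
#' the internal test split and on each external cohort (imputing MDW first
#' for `non_mdw_cohorts`, with the imputer trained on the pooled remaining
#' cohorts), evaluates the cautious variants at `th`, the partial decision
#' rule and the fixed biomarker baselines, then runs the three hypothesis
#' families (model vs model, cautious improvement, internal vs external)
#' with adaptive step-down FDR adjustment per family.
#'
#' @param cohorts Named list of [feature_table()]s covering every cohort id
#'   referenced by `config`.
#' @param config A [study_config()].
#' @return A `study_report` with `grid` (long data frame of
#'   model x cohort x metric estimates, standard and high-confidence
#'   variants), `coverage`, `comparisons`, `models`, `searches`,
#'   `imputation` and `provenance`.
#' @export
run_study <- function(cohorts, config) {
  stopifnot(inherits(config, "study_config"))
  need <- unique(c(config$train_cohort, config$eval_cohorts))
  absent <- setdiff(need, names(cohorts))
  if (length(absent))
    stop("run_study: cohort(s) not supplied: ", paste(absent, collapse = ", "))

  sp <- split_train_test(cohorts[[config$train_cohort]],
                         config$split_fraction,
                         substream_seed(config$seed, "split"))

  # blindness instrumentation: external cohorts share no rows with training
  for (id in config$eval_cohorts)
    stopifnot(!identical(cohorts[[id]], sp$train))

  searches <- list(); models <- list()
  for (fam in config$families) {
    sr <- tune_hyperparameters(sp$train, fam, config$budget, config$folds,
                               substream_seed(config$seed, paste0("tune:", fam)))
    searches[[fam]] <- sr
    models[[fam]] <- fit_pipeline(sr$best_config, sp$train)
  }

  imputation <- NULL
  eval_tables <- cohorts[config$eval_cohorts]
  if (length(config$non_mdw_cohorts)) {
    donors <- c(list(internal = cohorts[[config$train_cohort]]),
                cohorts[setdiff(config$eval_cohorts, config$non_mdw_cohorts)])
    imputation <- evaluate_imputer(donors, seed = substream_seed(config$seed, "imputer"))
    imp <- fit_imputer(donors, seed = substream_seed(config$seed, "imputer"))
    for (id in config$non_mdw_cohorts)
      eval_tables[[id]] <- impute_feature(imp, eval_tables[[id]])
  }
  sets <- c(list(internal = sp$test), eval_tables)

  grid <- list(); cover <- list()
  standard_cc <- list(); hc_cc <- list()
  for (set_id in names(sets)) {
    tab <- sets[[set_id]]
    y <- tab$labels
    for (fam in names(models)) {
      s <- predict_scores(models[[fam]], tab)
      for (est in standard_eval(s, y, config$alpha, config$snb_threshold))
        grid[[length(grid) + 1]] <- estimate_row(fam, set_id, "standard", est)
      hc <- hc_evaluate(s, y, config$th, config$alpha, config$snb_threshold)
      for (est in hc$hc_metrics)
        grid[[length(grid) + 1]] <- estimate_row(fam, set_id, "hc", est)
      cover[[length(cover) + 1]] <- data.frame(model = fam, cohort = set_id,
                                               coverage = hc$coverage)
      standard_cc[[set_id]][[fam]] <- confusion(as.integer(s >= 0.5), y)
      hc_cc[[set_id]][[fam]] <- covered_confusion(hc$decisions, y)
    }
    # partial decision rule (needs observed MDW and neutrophils)
    if (!any(tab$mask[, c("mdw", "neutrophils")])) {
      pdr <- pdr_predict(tab$values[, "mdw"], tab$values[, "neutrophils"])
      for (est in decision_eval(pdr, y, config$alpha))
        grid[[length(grid) + 1]] <- estimate_row("PDR", set_id, "standard", est)
      cover[[length(cover) + 1]] <- data.frame(model = "PDR", cohort = set_id,
                                               coverage = coverage(pdr))
    }
    for (b in config$baselines) {
      bid <- paste0(b$feature, ">", b$threshold)
      if (any(tab$mask[, b$feature])) next
      dec <- threshold_baseline(tab, b$feature, b$threshold, b$direction)
      for (est in decision_eval(dec, y, config$alpha))
        grid[[length(grid) + 1]] <- estimate_row(bid, set_id, "standard", est)
      cover[[length(cover) + 1]] <- data.frame(model = bid, cohort = set_id,
                                               coverage = 1)
    }
  }
  grid <- do.call(rbind, grid)
  cover <- do.call(rbind, cover)

  rates <- c("sensitivity", "specificity", "ppv", "npv")
  comparisons <- list()
  # family 1: model vs model on the internal test, two-tailed
  fams <- names(models)
  f1 <- list()
  if (length(fams) >= 2) {
    for (i in seq_len(length(fams) - 1)) for (j in (i + 1):length(fams))
      for (m in rates)
        f1[[length(f1) + 1]] <- chi_square_compare(
          standard_cc$internal[[fams[i]]], standard_cc$internal[[fams[j]]], m,
          tails = "two",
          hypothesis_id = sprintf("%s_vs_%s:%s:internal", fams[i], fams[j], m))
  }
  # family 2: cautious improvement over the standard model, one-tailed
  f2 <- list()
  for (set_id in names(sets)) for (fam in fams) {
    hc <- hc_cc[[set_id]][[fam]]
    if (is.null(hc)) next
    for (m in rates)
      f2[[length(f2) + 1]] <- chi_square_compare(
        hc, standard_cc[[set_id]][[fam]], m, tails = "one",
        hypothesis_id = sprintf("cautious_%s:%s:%s", fam, m, set_id))
  }
  # family 3: external performance not worse than internal, two-tailed
  f3 <- list()
  for (set_id in setdiff(names(sets), "internal")) for (fam in fams)
    for (m in rates)
      f3[[length(f3) + 1]] <- chi_square_compare(
        standard_cc$internal[[fam]], standard_cc[[set_id]][[fam]], m,
        tails = "two",
        hypothesis_id = sprintf("internal_vs_%s:%s:%s", set_id, fam, m))
  families3 <- list(model_vs_model_2tailed = f1,
                    cautious_improvement_1tailed = f2,
                    internal_vs_external_2tailed = f3)
  for (fname in names(families3))
    families3[[fname]] <- adjust_family(families3[[fname]], config$alpha)
  comparisons <- do.call(rbind, unlist(lapply(names(families3), function(fn) {
    lapply(families3[[fn]], function(r)
      data.frame(family = fn, hypothesis_id = r$hypothesis_id,
                 metric = r$metric, statistic = r$statistic,
                 p_raw = r$p_raw, p_adjusted = r$p_adjusted,
                 rejected = r$rejected, defined = r$defined))
  }), recursive = FALSE))

  structure(list(grid = grid, coverage = cover, comparisons = comparisons,
                 models = models, searches = searches,
                 imputation = imputation,
                 provenance = list(config = config,
                                   package_version =
                                     as.character(utils::packageVersion("cbcscreen")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d grid cells; %d cohorts; %d comparisons\n",
              nrow(x$grid), length(unique(x$grid$cohort)),
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons)))
  invisible(x)
}

#' Render a study report
#'
#' Deterministic rendering of the report grid: `"table"` produces a
#' fixed-width text table per cohort with `value (ci_low, ci_high)` cells
#' and an em-dash for undefined cells; `"json"` produces a lossless JSON
#' document of the grid, coverage and comparisons.
#'
#' @param report A [run_study()] result.
#' @param format `"table"` or `"json"`.
#' @return A character scalar.
#' @export
summarize_report <- function(report, format = c("table", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "study_report"))
  if (format == "json") {
    return(jsonlite::toJSON(
      list(grid = report$grid, coverage = report$coverage,
           comparisons = report$comparisons),
      dataframe = "rows", digits = NA, na = "null", auto_unbox = TRUE))
  }
  g <- report$grid
  cell <- function(r) {
    if (!r$defined || is.na(r$value)) return("—")
    if (r$ci_method == "none") return(sprintf("%.3f", r$value))
    sprintf("%.3f (%.3f, %.3f)", r$value, r$ci_low, r$ci_high)
  }
  out <- character(0)
  for (cohort in unique(g$cohort)) {
    out <- c(out, sprintf("== %s ==", cohort))
    gc <- g[g$cohort == cohort, ]
    for (model in unique(gc$model)) {
      gm <- gc[gc$model == model, ]
      out <- c(out, sprintf("-- %s --", model))
      for (i in seq_len(nrow(gm)))
        out <- c(out, sprintf("  %-12s %-8s %s", gm$metric[i], gm$variant[i],
                              cell(gm[i, ])))
    }
    cv <- report$coverage[report$coverage$cohort == cohort, ]
    for (i in seq_len(nrow(cv)))
      out <- c(out, sprintf("  coverage     %-8s %.3f", cv$model[i], cv$coverage[i]))
  }
  if (!is.null(report$comparisons) && nrow(report$comparisons)) {
    out <- c(out, "== comparisons ==")
    cm <- report$comparisons
    for (i in seq_len(nrow(cm)))
      out <- c(out, sprintf("  %-45s p=%.4g adj=%.4g %s", cm$hypothesis_id[i],
                            cm$p_raw[i], cm$p_adjusted[i],
                            ifelse(isTRUE(cm$rejected[i]), "*", "")))
  }
  paste(out, collapse = "\n")
}
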