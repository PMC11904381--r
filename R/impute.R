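# Random-forest regression imputation of MDW for cohorts whose analyzer
# does not report it: the imputer is trained on pooled rows from the other
# cohorts (MDW as target, every other feature as predictor), its goodness
# of fit is assessed by the adjusted R-squared on a held-out 25% split, and
# it is then applied as a preprocessing step to the MDW-missing cohort.

imputer_predictors <- function() setdiff(canonical_features(), "mdw")

pooled_complete_rows <- function(tables) {
  for (t in tables) stopifnot(inherits(t, "feature_table"))
  X <- do.call(rbind, lapply(tables, function(t) t$values))
  mask <- do.call(rbind, lapply(tables, function(t) t$mask))
  ok <- !mask[, "mdw"] & rowSums(mask[, imputer_predictors(), drop = FALSE]) == 0
  list(X = X[ok, imputer_predictors(), drop = FALSE],
       y = X[ok, "mdw"])
}

#' Fit the MDW imputation model
#'
#' Random-forest regression of MDW on all other features (the label is
#' never a predictor), fitted on the pooled rows of the supplied cohorts
#' where MDW is observed. Hyperparameters are pinned for stability: 100
#' trees, unlimited depth, floor(sqrt(p)) candidate features per split,
#' seeded.
#'
#' @param tables List of [feature_table()] cohorts with observed MDW.
#' @param seed Integer seed.
#' @return An `imputer_model` with `predictors`, the fitted forest and
#'   `n_train`.
#' @export
fit_imputer <- function(tables, seed = 1L) {
  pool <- pooled_complete_rows(tables)
  if (length(pool$y) < 50)
    stop("fit_imputer: fewer than 50 usable rows with observed MDW")
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = pool$X, y = pool$y, ntree = 100L,
    mtry = floor(sqrt(ncol(pool$X))))
  structure(list(predictors = imputer_predictors(), fit = fit,
                 n_train = length(pool$y), seed = as.integer(seed)),
            class = "imputer_model")
}

predict_imputer <- function(model, X) {
  pmax(as.numeric(stats::predict(model$fit, X[, model$predictors, drop = FALSE])), 0)
}

#' Evaluate the imputer by held-out adjusted R-squared
#'
#' Splits the pooled training rows 75/25 (seeded, at random), fits the
#' imputation forest on the 75% portion and computes the R-squared and
#' adjusted R-squared, \eqn{1 - (1-R^2)(n-1)/(n-p-1)}, between predicted
#' and true MDW on the held-out 25%.
#'
#' @param tables List of [feature_table()] cohorts with observed MDW.
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with `r2`, `adjusted_r2`, `n_eval`, `p_predictors`.
#' @export
evaluate_imputer <- function(tables, fraction = 0.75, seed = 1L) {
  pool <- pooled_complete_rows(tables)
  n <- length(pool$y)
  if (n < 50) stop("evaluate_imputer: fewer than 50 usable rows")
  set.seed(substream_seed(seed, "imputer-split"))
  idx <- sample.int(n)
  n_tr <- round(fraction * n)
  tr <- idx[seq_len(n_tr)]; ev <- idx[-seq_len(n_tr)]
  p <- length(imputer_predictors())
  if (length(ev) < p + 2)
    stop("evaluate_imputer: evaluation split too small for adjusted R2 (need > ",
         p + 1, " rows)")
  stopifnot(length(intersect(tr, ev)) == 0) # split disjointness
  set.seed(substream_seed(seed, "imputer-fit"))
  fit <- randomForest::randomForest(x = pool$X[tr, , drop = FALSE],
                                    y = pool$y[tr], ntree = 100L,
                                    mtry = floor(sqrt(p)))
  pred <- as.numeric(stats::predict(fit, pool$X[ev, , drop = FALSE]))
  truth <- pool$y[ev]
  r2 <- 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  list(r2 = r2, adjusted_r2 = adjusted_r2(r2, length(ev), p),
       n_eval = length(ev), p_predictors = p)
}

#' Adjusted R-squared
#'
#' @param r2 Coefficient of determination.
#' @param n Number of evaluation rows.
#' @param p Number of predictors.
#' @return \eqn{1 - (1-R^2)(n-1)/(n-p-1)}.
#' @export
adjusted_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Impute masked MDW cells
#'
#' Fills every masked MDW cell of a table with the imputer's prediction and
#' clears the mask there; observed MDW cells are untouched, so imputing an
#' already complete (or already imputed) table is a no-op. The derived NLR
#' and all other columns are unchanged.
#'
#' @param model A [fit_imputer()] result.
#' @param table A [feature_table()] whose predictors are observed.
#' @return The table with MDW completed.
#' @export
impute_feature <- function(model, table) {
  stopifnot(inherits(model, "imputer_model"), inherits(table, "feature_table"))
  todo <- which(table$mask[, "mdw"])
  if (length(todo) == 0) return(table)
  bad <- rowSums(table$mask[todo, model$predictors, drop = FALSE]) > 0
  if (any(bad))
    stop("impute_feature: masked predictor cells at row(s) ",
         paste(utils::head(todo[bad], 5), collapse = ", "))
  vals <- table$values
  vals[todo, "mdw"] <- predict_imputer(model,
                                       vals[todo, , drop = FALSE])
  mask <- table$mask
  mask[todo, "mdw"] <- FALSE
  feature_table(vals, mask, table$labels, table$ids)
}
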