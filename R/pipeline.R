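# Three-step classification pipelines: feature scaling, recursive feature
# elimination with a logistic-model scorer, and one of five classifier
# families (logistic regression, linear SVM with calibrated probabilities,
# random forest, gradient-boosted trees, decision tree), plus stratified
# splitting, randomized hyperparameter search under stratified k-fold
# cross-validation, and fixed-threshold biomarker baselines.

model_families <- function() {
  c("logistic_regression", "linear_svm", "random_forest",
    "gradient_boosted_trees", "decision_tree")
}

#' Stratified train/test split
#'
#' Partitions rows into train and test sets, stratified by the sepsis label
#' so that each split's class counts differ from exact proportionality by
#' at most one case. Reproducible from `seed`.
#'
#' @param table A [feature_table()].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables.
#' @export
split_train_test <- function(table, fraction = 0.75, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (fraction <= 0 || fraction >= 1)
    stop("split_train_test: fraction must be in (0, 1)")
  y <- table$labels
  if (length(unique(y)) < 2)
    stop("split_train_test: both classes must be present")
  set.seed(seed)
  train_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    n_tr <- round(fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, idx[seq_len(n_tr)])
  }
  train_idx <- sort(train_idx)
  list(train = subset_rows(table, train_idx),
       test = subset_rows(table, setdiff(seq_along(y), train_idx)))
}

# Stratified fold assignment: within each class, shuffled round-robin, so
# each fold's positive count differs from n_pos/k by at most 1.
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("stratified folding impossible: fewer than k = ", k,
         " cases in the minority class")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Pipeline configuration
#'
#' @param model_family One of `"logistic_regression"`, `"linear_svm"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`, `"decision_tree"`.
#' @param scaler `"standard"` (z-score), `"minmax"`, `"robust"`
#'   (median/IQR), or `"none"`.
#' @param n_features_selected Number of features retained by recursive
#'   feature elimination, in 1..19.
#' @param class_weighting `"none"` or `"balanced"`
#'   (weight n / (2 n_class)).
#' @param family_hyperparameters Named list; every key must belong to the
#'   family's documented grid (see [hyperparameter_grid()]).
#' @param seed Integer seed used by stochastic fits.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(model_family, scaler = "standard",
                            n_features_selected = 19L,
                            class_weighting = "none",
                            family_hyperparameters = list(), seed = 1L) {
  model_family <- match.arg(model_family, model_families())
  scaler <- match.arg(scaler, c("standard", "minmax", "robust", "none"))
  class_weighting <- match.arg(class_weighting, c("none", "balanced"))
  if (n_features_selected < 1 || n_features_selected > length(canonical_features()))
    stop("pipeline_config: n_features_selected must be in 1..",
         length(canonical_features()))
  grid <- hyperparameter_grid(model_family)$family
  bad <- setdiff(names(family_hyperparameters), names(grid))
  if (length(bad))
    stop("pipeline_config: unknown hyperparameter(s) for ", model_family,
         ": ", paste(bad, collapse = ", "))
  structure(list(model_family = model_family, scaler = scaler,
                 n_features_selected = as.integer(n_features_selected),
                 class_weighting = class_weighting,
                 family_hyperparameters = family_hyperparameters,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Documented hyperparameter grids
#'
#' The randomized search samples uniformly from these grids. Shared across
#' families: the scaler, the number of RFE-selected features
#' (5, 8, 10, 12, 15, 19) and the class weighting. Family grids:
#' regularization strength on a log grid 1e-4..1e4 (logistic ridge
#' `lambda`, SVM `cost`), tree depth 2..12, ensemble sizes
#' 50/100/200/400, learning rates 0.01/0.05/0.1/0.3, and decision-tree
#' complexity pruning.
#'
#' @param model_family Family name.
#' @return List with elements `shared` and `family`, each a named list of
#'   candidate values.
#' @export
hyperparameter_grid <- function(model_family) {
  model_family <- match.arg(model_family, model_families())
  shared <- list(scaler = c("standard", "minmax", "robust", "none"),
                 n_features_selected = c(5L, 8L, 10L, 12L, 15L, 19L),
                 class_weighting = c("none", "balanced"))
  family <- switch(model_family,
    logistic_regression = list(lambda = 10^seq(-4, 4)),
    linear_svm = list(cost = 10^seq(-4, 4)),
    random_forest = list(depth = 2:12, n_trees = c(50L, 100L, 200L, 400L)),
    gradient_boosted_trees = list(depth = 2:12,
                                  n_trees = c(50L, 100L, 200L, 400L),
                                  learning_rate = c(0.01, 0.05, 0.1, 0.3)),
    decision_tree = list(depth = 2:12, cp = c(1e-4, 1e-3, 1e-2)))
  list(shared = shared, family = family)
}

sample_config <- function(model_family, seed) {
  g <- hyperparameter_grid(model_family)
  pick <- function(v) v[[sample.int(length(v), 1)]]
  pipeline_config(model_family,
                  scaler = pick(g$shared$scaler),
                  n_features_selected = pick(g$shared$n_features_selected),
                  class_weighting = pick(g$shared$class_weighting),
                  family_hyperparameters = lapply(g$family, pick),
                  seed = seed)
}

# ---- scaling --------------------------------------------------------------

fit_scaler <- function(X, kind) {
  switch(kind,
    none = list(kind = "none"),
    standard = {
      s <- apply(X, 2, stats::sd); s[s == 0] <- 1
      list(kind = "standard", center = colMeans(X), scale = s)
    },
    minmax = {
      lo <- apply(X, 2, min); hi <- apply(X, 2, max)
      r <- hi - lo; r[r == 0] <- 1
      list(kind = "minmax", center = lo, scale = r)
    },
    robust = {
      med <- apply(X, 2, stats::median)
      iqr <- apply(X, 2, stats::IQR); iqr[iqr == 0] <- 1
      list(kind = "robust", center = med, scale = iqr)
    })
}

apply_scaler <- function(scaler, X) {
  if (scaler$kind == "none") return(X)
  sweep(sweep(X, 2, scaler$center[colnames(X)], "-"),
        2, scaler$scale[colnames(X)], "/")
}

# ---- recursive feature elimination ---------------------------------------

# Iteratively drops the feature with the smallest absolute standardized
# logistic coefficient (|coef| x SD of the scaled feature), one per
# iteration, until n_keep remain. Ties and degenerate (NA) coefficients
# drop the earliest column, for determinism.
rfe_select <- function(X, y, w, n_keep) {
  feats <- colnames(X)
  while (length(feats) > n_keep) {
    Xc <- X[, feats, drop = FALSE]
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, Xc), y, weights = w,
                     family = stats::binomial()))
    coefs <- fit$coefficients[-1]
    score <- abs(coefs) * apply(Xc, 2, stats::sd)
    score[!is.finite(score)] <- -Inf
    feats <- feats[-which.min(score)]
  }
  feats
}

# ---- classifier families --------------------------------------------------

case_weights <- function(y, class_weighting) {
  if (class_weighting == "none") return(rep(1, length(y)))
  n <- length(y)
  w1 <- n / (2 * sum(y == 1)); w0 <- n / (2 * sum(y == 0))
  ifelse(y == 1, w1, w0)
}

fit_classifier <- function(config, X, y) {
  w <- case_weights(y, config$class_weighting)
  hp <- config$family_hyperparameters
  set.seed(config$seed)
  switch(config$model_family,
    logistic_regression = {
      lambda <- if (is.null(hp$lambda)) 0 else hp$lambda
      if (ncol(X) >= 2) {
        fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                              lambda = lambda, weights = w,
                              standardize = FALSE)
        list(kind = "glmnet", fit = fit)
      } else {
        df <- data.frame(y = y, X)
        fit <- suppressWarnings(stats::glm(y ~ ., data = df, weights = w,
                                           family = stats::binomial()))
        list(kind = "glm", fit = fit)
      }
    },
    linear_svm = {
      cw <- if (config$class_weighting == "balanced") {
        n <- length(y)
        c("0" = n / (2 * sum(y == 0)), "1" = n / (2 * sum(y == 1)))
      } else NULL
      fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                        kernel = "linear",
                        cost = if (is.null(hp$cost)) 1 else hp$cost,
                        class.weights = cw, scale = FALSE)
      dv <- attr(stats::predict(fit, X, decision.values = TRUE),
                 "decision.values")[, 1]
      # Platt-style sigmoid calibration of the margin into [0, 1]
      cal <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial(),
                   data = data.frame(y = y, dv = dv)))
      list(kind = "svm", fit = fit, calibration = stats::coef(cal))
    },
    random_forest = {
      depth <- if (is.null(hp$depth)) 12L else hp$depth
      fit <- randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = if (is.null(hp$n_trees)) 100L else hp$n_trees,
        maxnodes = min(2^depth, nrow(X)),
        classwt = if (config$class_weighting == "balanced")
          c("0" = 0.5, "1" = 0.5) else NULL)
      list(kind = "rf", fit = fit)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
      params <- list(objective = "binary:logistic",
                     max_depth = if (is.null(hp$depth)) 6L else hp$depth,
                     eta = if (is.null(hp$learning_rate)) 0.3 else hp$learning_rate,
                     nthread = 1, seed = config$seed)
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = if (is.null(hp$n_trees)) 100L else hp$n_trees,
                                verbose = 0)
      list(kind = "xgb", fit = fit)
    },
    decision_tree = {
      df <- data.frame(y = factor(y, levels = c(0, 1)), X)
      fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = if (is.null(hp$depth)) 12L else hp$depth,
                            cp = if (is.null(hp$cp)) 0.01 else hp$cp,
                            xval = 0))
      list(kind = "rpart", fit = fit)
    })
}

predict_classifier <- function(clf, X) {
  scores <- switch(clf$kind,
    glmnet = as.numeric(stats::predict(clf$fit, newx = X, type = "response")),
    glm = as.numeric(stats::predict(clf$fit, newdata = as.data.frame(X),
                                    type = "response")),
    svm = {
      dv <- attr(stats::predict(clf$fit, X, decision.values = TRUE),
                 "decision.values")[, 1]
      b <- clf$calibration
      as.numeric(stats::plogis(b[1] + b[2] * dv))
    },
    rf = stats::predict(clf$fit, X, type = "prob")[, "1"],
    xgb = as.numeric(stats::predict(clf$fit, X)),
    rpart = stats::predict(clf$fit, as.data.frame(X), type = "prob")[, "1"])
  unname(pmin(pmax(scores, 0), 1))
}

# ---- fit / predict --------------------------------------------------------

#' Fit a classification pipeline
#'
#' Applies the three pipeline steps on fully observed training data: the
#' configured scaler (fitted on the training rows only), recursive feature
#' elimination down to `n_features_selected` features under a logistic
#' scorer, and the family classifier. Tables containing any masked cell are
#' rejected: imputation is an explicit upstream stage (see
#' [impute_feature()]), never implicit.
#'
#' @param config A [pipeline_config()].
#' @param train A fully observed [feature_table()] with both classes.
#' @return A `trained_model` with `config`, `selected_features`, the frozen
#'   scaler, the fitted classifier and a `training_summary`.
#' @export
fit_pipeline <- function(config, train) {
  stopifnot(inherits(config, "pipeline_config"), inherits(train, "feature_table"))
  if (any(train$mask))
    stop("fit_pipeline: training table has missing values; impute them ",
         "first with impute_feature() - the pipeline does not impute")
  y <- train$labels
  if (length(unique(y)) < 2)
    stop("fit_pipeline: both classes must be present")
  X <- train$values
  scaler <- fit_scaler(X, config$scaler)
  Xs <- apply_scaler(scaler, X)
  w <- case_weights(y, config$class_weighting)
  selected <- rfe_select(Xs, y, w, config$n_features_selected)
  clf <- fit_classifier(config, Xs[, selected, drop = FALSE], y)
  structure(list(config = config, selected_features = selected,
                 scaler = scaler, classifier = clf,
                 training_summary = list(n = nrow(X), prevalence = mean(y))),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s; %d features: %s\n",
              x$config$model_family, length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  invisible(x)
}

#' Predict confidence scores
#'
#' Scores each row of a table with a fitted pipeline: one confidence for
#' sepsis in [0, 1] per patient. All selected features must be present and
#' observed.
#'
#' @param model A [fit_pipeline()] result.
#' @param table A [feature_table()].
#' @return Numeric vector of scores in [0, 1].
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "trained_model"), inherits(table, "feature_table"))
  miss <- setdiff(model$selected_features, table$columns)
  if (length(miss))
    stop("predict_scores: feature column(s) absent: ",
         paste(miss, collapse = ", "))
  masked <- colSums(table$mask[, model$selected_features, drop = FALSE])
  if (any(masked > 0))
    stop("predict_scores: masked cells in selected feature(s): ",
         paste(names(masked)[masked > 0], collapse = ", "),
         "; impute them first with impute_feature()")
  Xs <- apply_scaler(model$scaler, table$values)
  predict_classifier(model$classifier, Xs[, model$selected_features, drop = FALSE])
}

# ---- randomized search ----------------------------------------------------

#' Randomized hyperparameter search under stratified cross-validation
#'
#' Samples `budget` configurations uniformly from the family's documented
#' grid and scores each by the mean AUC across `k` stratified
#' cross-validation folds of the training table. Ties are broken by the
#' earliest trial, and the whole search is deterministic given `seed`.
#'
#' @param train Fully observed [feature_table()] with both classes.
#' @param model_family Family name (see [hyperparameter_grid()]).
#' @param budget Number of sampled configurations (>= 1).
#' @param k Number of folds (>= 2); requires at least k minority cases.
#' @param seed Integer seed.
#' @return A `search_result` with `best_config`, `best_mean_auc` and a
#'   `trials` data frame (per-fold AUCs and the mean per trial).
#' @export
tune_hyperparameters <- function(train, model_family, budget = 50L, k = 5L,
                                 seed = 1L) {
  stopifnot(inherits(train, "feature_table"))
  if (budget < 1) stop("tune_hyperparameters: budget must be >= 1")
  if (k < 2) stop("tune_hyperparameters: k must be >= 2")
  y <- train$labels
  fold <- stratified_folds(y, k, substream_seed(seed, "folds"))
  set.seed(substream_seed(seed, "configs"))
  configs <- lapply(seq_len(budget), function(i)
    sample_config(model_family, seed = substream_seed(seed, paste0("trial", i))))
  fold_aucs <- matrix(NA_real_, budget, k)
  for (i in seq_len(budget)) {
    for (f in seq_len(k)) {
      tr <- subset_rows(train, which(fold != f))
      va <- subset_rows(train, which(fold == f))
      m <- fit_pipeline(configs[[i]], tr)
      fold_aucs[i, f] <- auc_value(predict_scores(m, va), va$labels)
    }
  }
  mean_auc <- rowMeans(fold_aucs)
  best <- which.max(mean_auc) # which.max returns the first maximum
  trials <- data.frame(trial = seq_len(budget), mean_auc = mean_auc)
  trials$fold_aucs <- lapply(seq_len(budget), function(i) fold_aucs[i, ])
  trials$config <- configs
  structure(list(best_config = configs[[best]],
                 best_mean_auc = mean_auc[best],
                 trials = trials),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d trials; best %s mean CV AUC = %.4f\n",
              nrow(x$trials), x$best_config$model_family, x$best_mean_auc))
  invisible(x)
}

# ---- fixed-threshold biomarker baselines ----------------------------------

#' Fixed-threshold biomarker baseline
#'
#' Single-feature decision rule: predicts sepsis when the feature exceeds
#' (or equals, for `"greater_equal"`) the threshold, no sepsis otherwise;
#' it never abstains. The study's baselines are MDW > 23.5 and CRP > 80.
#'
#' @param table A [feature_table()].
#' @param feature Canonical feature name.
#' @param threshold Numeric cut-point.
#' @param direction `"greater"` (strict) or `"greater_equal"`.
#' @return Character vector of `"sepsis"`/`"no_sepsis"` decisions.
#' @export
threshold_baseline <- function(table, feature, threshold,
                               direction = c("greater", "greater_equal")) {
  stopifnot(inherits(table, "feature_table"))
  direction <- match.arg(direction)
  if (!feature %in% table$columns)
    stop("threshold_baseline: unknown feature '", feature, "'")
  if (any(table$mask[, feature]))
    stop("threshold_baseline: masked cells in feature '", feature, "'")
  x <- table$values[, feature]
  hit <- if (direction == "greater") x > threshold else x >= threshold
  ifelse(hit, "sepsis", "no_sepsis")
}

#' Linear-model coefficients of a fitted pipeline
#'
#' Reports the logistic-regression coefficients on the scaled feature
#' space, sorted by decreasing magnitude — the plain linear feature
#' importances. Only defined for the linear family.
#'
#' @param model A [fit_pipeline()] result with
#'   `model_family == "logistic_regression"`.
#' @return Named numeric vector (no intercept), sorted by `abs()`.
#' @export
report_linear_coefficients <- function(model) {
  stopifnot(inherits(model, "trained_model"))
  if (model$config$model_family != "logistic_regression")
    stop("report_linear_coefficients: model family is not logistic_regression")
  clf <- model$classifier
  co <- if (clf$kind == "glmnet") {
    cm <- as.matrix(stats::coef(clf$fit))
    stats::setNames(cm[-1, 1], rownames(cm)[-1])
  } else {
    stats::coef(clf$fit)[-1]
  }
  names(co) <- model$selected_features
  co[order(abs(co), decreasing = TRUE)]
}
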