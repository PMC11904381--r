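# Shared synthetic fixtures, all generated in code.

drawn_features <- setdiff(canonical_features(), c("sex", "nlr"))

# A benign cohort spec: every feature ~ N(50, 5) far above its floor, so
# truncation is negligible and moments are easy to reason about.
toy_spec <- function(n, seed, effect_sizes = c(mdw = 0), prevalence = 0.3,
                     missingness = numeric(0), label_noise = 0,
                     sds = NULL) {
  feats <- lapply(drawn_features, function(f) {
    s <- if (!is.null(sds) && f %in% names(sds)) sds[[f]] else 5
    feature_spec(f, 50, s)
  })
  names(feats) <- drawn_features
  cohort_spec("toy", n, prevalence, 0.5, feats, effect_sizes = effect_sizes,
              missingness = missingness, label_noise = label_noise,
              seed = seed)
}

# Replace a column of a generated table with a deterministic function of the
# others (used to plant relations for the imputer and RFE tests).
with_column <- function(table, name, values) {
  v <- table$values
  v[, name] <- values
  feature_table(v, labels = table$labels)
}

# Brute-force AUC: mean over all positive-negative pairs, ties count half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force average precision: precision at each positive's rank,
# averaged (distinct scores only).
brute_ap <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  ranks <- which(y == 1)
  mean(vapply(ranks, function(r) sum(y[1:r]) / r, numeric(1)))
}
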