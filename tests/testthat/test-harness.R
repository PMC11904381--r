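make_small_study <- function(seed = 11, families = "logistic_regression") {
  cohorts <- list(
    train = generate_cohort(toy_spec(500, 1, effect_sizes = c(mdw = 2))),
    ext = generate_cohort(toy_spec(250, 2, effect_sizes = c(mdw = 2))),
    nomdw = generate_cohort(toy_spec(150, 3, effect_sizes = c(mdw = 2),
                                     missingness = c(mdw = 1))))
  cfg <- study_config("train", c("ext", "nomdw"), families = families,
                      budget = 4, folds = 4, non_mdw_cohorts = "nomdw",
                      seed = seed)
  list(cohorts = cohorts, cfg = cfg)
}

test_that("a study report covers every model x cohort x metric cell", {
  st <- make_small_study()
  rep <- run_study(st$cohorts, st$cfg)
  g <- rep$grid
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "auc", "a_ppv",
               "brier", "snb")
  cohorts <- c("internal", "ext", "nomdw")
  expect_setequal(unique(g$cohort), cohorts)
  # the tuned family carries standard + HC variants on every cohort
  for (ch in cohorts) {
    sub <- g[g$model == "logistic_regression" & g$cohort == ch, ]
    expect_setequal(sub$metric[sub$variant == "standard"], metrics)
    expect_setequal(sub$metric[sub$variant == "hc"], metrics)
  }
  # decision-only models: PDR wherever MDW is observed or imputed, baselines
  expect_true(all(c("PDR", "mdw>23.5", "crp>80") %in% g$model))
  expect_true(all(g$n[g$defined] >= 0))
  # coverage rows for every scored model
  expect_true(all(rep$coverage$coverage >= 0 & rep$coverage$coverage <= 1))
  # comparisons carry all three hypothesis families when >= 2 models exist
  expect_setequal(setdiff(unique(rep$comparisons$family),
                          "model_vs_model_2tailed"),
                  c("cautious_improvement_1tailed",
                    "internal_vs_external_2tailed"))
  # the imputation stage was evaluated
  expect_true(is.numeric(rep$imputation$adjusted_r2))
})

test_that("rerunning an identical config reproduces the report bit-for-bit", {
  st <- make_small_study()
  r1 <- run_study(st$cohorts, st$cfg)
  r2 <- run_study(st$cohorts, st$cfg)
  expect_identical(r1$grid, r2$grid)
  expect_identical(r1$coverage, r2$coverage)
  expect_identical(r1$comparisons, r2$comparisons)
})

test_that("report rendering is deterministic and marks undefined cells", {
  st <- make_small_study()
  rep <- run_study(st$cohorts, st$cfg)
  t1 <- summarize_report(rep, "table")
  t2 <- summarize_report(rep, "table")
  expect_identical(t1, t2)
  expect_match(t1, "—") # decision-only models have no AUC
  j <- summarize_report(rep, "json")
  back <- jsonlite::fromJSON(j)
  expect_equal(nrow(back$grid), nrow(rep$grid))
  expect_equal(back$grid$value, rep$grid$value, tolerance = 1e-12)
})

test_that("pooling the training cohort into evaluation is rejected", {
  expect_error(study_config("train", c("train", "ext")), "pooling")
})

test_that("linear coefficients surface a planted signal and only that", {
  tab <- generate_cohort(toy_spec(2000, 9, effect_sizes = c(mdw = 3)))
  cfg <- pipeline_config("logistic_regression", "standard", 10, seed = 2)
  m <- fit_pipeline(cfg, tab)
  co <- report_linear_coefficients(m)
  expect_length(co, length(m$selected_features))
  expect_identical(names(co)[1], "mdw")
  expect_false(is.unsorted(rev(abs(co))))

  # under the null (no signal anywhere) no coefficient dominates
  ratios <- vapply(1:20, function(seed) {
    null_tab <- generate_cohort(toy_spec(300, 100 + seed,
                                         effect_sizes = c(mdw = 0)))
    null_m <- fit_pipeline(pipeline_config("logistic_regression", "standard",
                                           19, seed = seed), null_tab)
    co0 <- abs(report_linear_coefficients(null_m))
    max(co0) / stats::median(co0)
  }, numeric(1))
  expect_lt(stats::median(ratios), 5)

  rf <- fit_pipeline(pipeline_config("random_forest", seed = 1),
                     generate_cohort(toy_spec(100, 1)))
  expect_error(report_linear_coefficients(rf), "logistic_regression")
})
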