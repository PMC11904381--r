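test_that("built-in cohort specs carry the published population parameters", {
  specs <- builtin_cohort_specs()
  expect_setequal(names(specs),
                  c("PA-ED", "AR-ED", "PA-ICU", "PD-ICU", "UD-ED", "OGSA-ICU"))
  pa <- specs[["PA-ED"]]
  expect_equal(pa$prevalence, 0.0459)
  expect_equal(pa$n, 1809L)
  expect_equal(pa$features$mdw$mean, 20.1)
  expect_equal(pa$features$mdw$sd, 3.2)
  expect_equal(pa$male_fraction, 0.4859)
  expect_equal(specs[["AR-ED"]]$prevalence, 0.247)
  expect_equal(specs[["AR-ED"]]$n, 308L)
  expect_equal(specs[["PA-ICU"]]$prevalence, 0.29)
  expect_equal(specs[["PD-ICU"]]$prevalence, 0.3354)
  expect_equal(specs[["PD-ICU"]]$n, 2114L)
  expect_equal(specs[["UD-ED"]]$prevalence, 0.067)
  expect_equal(specs[["OGSA-ICU"]]$prevalence, 0.06)
  expect_equal(specs[["OGSA-ICU"]]$missingness[["mdw"]], 1.0)
  # the anomalous printed OGSA-ICU MCHC summary is reproduced verbatim
  expect_equal(specs[["OGSA-ICU"]]$features$mchc$mean, 66.1)
  expect_equal(specs[["OGSA-ICU"]]$features$mchc$sd, 327.5)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(toy_spec(5, 1), "n")
  expect_error(cohort_spec("x", 100, 1.2, features = toy_spec(100, 1)$features),
               "prevalence")
  expect_error(toy_spec(100, 1, missingness = c(mdw = 1.5)), "missing")
  expect_error(toy_spec(100, 1, label_noise = 1), "label_noise")
  expect_error(toy_spec(100, 1, effect_sizes = c(bogus = 1)), "bogus")
  expect_error(feature_spec("not_a_feature", 1, 1), "unknown feature")
  expect_error(feature_spec("mdw", 1, -1), "sd")
  expect_error(feature_spec("mdw", 1, 1, lower_bound = 5), "lower_bound")
})

test_that("generation is bit-identical under a fixed spec and seed", {
  s <- toy_spec(200, 77, missingness = c(crp = 0.2), label_noise = 0.05)
  expect_identical(generate_cohort(s), generate_cohort(s))
  s2 <- s; s2$seed <- 78L
  expect_false(identical(generate_cohort(s), generate_cohort(s2)))
})

test_that("observed prevalence falls in the exact binomial 99% interval", {
  s <- toy_spec(1000, 11, prevalence = 0.0459)
  tab <- generate_cohort(s)
  k <- sum(tab$labels)
  lo <- qbinom(0.005, 1000, 0.0459)
  hi <- qbinom(0.995, 1000, 0.0459)
  expect_gte(k, lo)
  expect_lte(k, hi)
})

test_that("with zero effect sizes both classes match the reference means", {
  n <- 4000
  tab <- generate_cohort(toy_spec(n, 5, effect_sizes = c(mdw = 0)))
  tol <- 4 * 5 / sqrt(n * 0.2) # 4 sd / sqrt(smallest class size)
  for (f in drawn_features) {
    for (cls in 0:1) {
      m <- mean(tab$values[tab$labels == cls, f])
      expect_lt(abs(m - 50), tol)
    }
  }
})

test_that("class-conditional shift lands at the configured effect size", {
  tab <- generate_cohort(toy_spec(3000, 3, effect_sizes = c(mdw = 2.0)))
  d <- mean(tab$values[tab$labels == 1, "mdw"]) -
       mean(tab$values[tab$labels == 0, "mdw"])
  expect_lt(abs(d - 2 * 5), 0.2 * 5)
})

test_that("missingness masks have the configured marginals", {
  s <- toy_spec(800, 9, missingness = c(mdw = 1.0))
  tab <- generate_cohort(s)
  expect_true(all(tab$mask[, "mdw"]))
  expect_true(all(is.na(tab$values[, "mdw"])))
  expect_equal(sum(tab$mask[, setdiff(colnames(tab$mask), "mdw")]), 0)

  s2 <- toy_spec(2000, 13, missingness = c(crp = 0.3))
  k <- sum(generate_cohort(s2)$mask[, "crp"])
  expect_gte(k, qbinom(0.005, 2000, 0.3))
  expect_lte(k, qbinom(0.995, 2000, 0.3))
})

test_that("NLR equals neutrophils / lymphocytes wherever both are observed", {
  for (seed in c(1, 2)) {
    tab <- generate_cohort(toy_spec(500, seed))
    expect_equal(tab$values[, "nlr"],
                 tab$values[, "neutrophils"] / tab$values[, "lymphocytes"],
                 tolerance = 1e-9)
  }
  big <- generate_cohort(builtin_cohort_specs()[["PA-ED"]])
  expect_equal(big$values[, "nlr"],
               big$values[, "neutrophils"] / big$values[, "lymphocytes"],
               tolerance = 1e-9)
})

test_that("label noise flips exactly the rows nearest the MDW midpoint", {
  s_clean <- toy_spec(400, 21, effect_sizes = c(mdw = 2))
  s_noisy <- s_clean; s_noisy$label_noise <- 0.1
  clean <- generate_cohort(s_clean)
  noisy <- generate_cohort(s_noisy)
  expect_identical(clean$values, noisy$values)
  flipped <- which(clean$labels != noisy$labels)
  expect_length(flipped, round(0.1 * 400))
  boundary <- 50 + 2 * 5 / 2
  d <- abs(clean$values[, "mdw"] - boundary)
  expect_true(max(d[flipped]) <= min(d[-flipped]))
})

test_that("truncation respects physical floors", {
  feats <- lapply(drawn_features, function(f)
    feature_spec(f, 1, 3, lower_bound = if (f == "lymphocytes") 0.05 else 0))
  names(feats) <- drawn_features
  s <- cohort_spec("floor", 500, 0.3, 0.5, feats, effect_sizes = c(mdw = 0),
                   seed = 4)
  tab <- generate_cohort(s)
  for (f in drawn_features) expect_true(all(tab$values[, f] >= 0))
  expect_true(all(tab$values[, "lymphocytes"] >= 0.05))
})

test_that("CSV round trip is bit-exact, including masks and labels", {
  tab <- generate_cohort(toy_spec(120, 31, missingness = c(mdw = 0.4, crp = 0.1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_table(tab, f)
  back <- read_table(f)
  expect_identical(back$values, tab$values)
  expect_identical(back$mask, tab$mask)
  expect_identical(back$labels, tab$labels)
})

test_that("malformed CSV inputs fail with coordinates", {
  tab <- generate_cohort(toy_spec(10, 1))
  f <- withr::local_tempfile(fileext = ".csv")

  write_table(tab, f)
  lines <- readLines(f)
  writeLines(sub("^age,", "age_typo,", lines), f)
  expect_error(read_table(f), "age_typo")

  writeLines(c(paste0(lines[1], ",extra_col"),
               paste0(lines[-1], ",1")), f)
  expect_error(read_table(f), "extra_col")

  writeLines(sub(",sepsis", ",other", lines), f)
  expect_error(read_table(f), "sepsis|other")

  bad <- lines
  bad[3] <- sub("^[0-9.]+", "oops", bad[3])
  writeLines(bad, f)
  expect_error(read_table(f), "row 2.*age|age.*row 2")
})
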