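test_that("credibility intervals degrade gracefully and nest by level", {
  const <- rep(0.4, 50)
  ci <- credibility_interval(const, level = 0.95, n_boot = 500, seed = 1)
  expect_equal(c(ci$lower, ci$upper), c(0.4, 0.4))
  set.seed(20)
  risks <- runif(100)
  ci90 <- credibility_interval(risks, 0.90, n_boot = 1000, seed = 7)
  ci95 <- credibility_interval(risks, 0.95, n_boot = 1000, seed = 7)
  expect_lte(ci95$lower, ci90$lower)
  expect_gte(ci95$upper, ci90$upper)
  expect_lte(ci90$lower, ci90$point)
  expect_gte(ci90$upper, ci90$point)
  # bit-reproducible under a fixed seed, and seed scoping leaves the
  # caller's RNG stream untouched
  before <- runif(1)
  again <- credibility_interval(risks, 0.95, n_boot = 1000, seed = 7)
  expect_identical(c(ci95$lower, ci95$upper), c(again$lower, again$upper))
  bca <- credibility_interval(risks, 0.95, n_boot = 1000, seed = 7,
                              method = "bca")
  expect_lt(bca$lower, bca$upper)
  expect_error(credibility_interval(risks[1:5], 0.95),
               class = "domain_error")
  expect_error(credibility_interval(risks, 1.2), class = "domain_error")
  expect_error(credibility_interval(risks, 0.95, n_boot = 50),
               class = "domain_error")
})

test_that("applicability metrics satisfy their exact identities", {
  obs <- c(0.2, 0.4, 0.5, 0.7, 0.9)
  perfect <- applicability_metrics(obs, obs)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$mean_abs_residual, 0)
  offset <- applicability_metrics(obs + 0.1, obs)
  expect_equal(offset$rmse, 0.1, tolerance = 1e-12)
  expect_equal(offset$mean_abs_residual, 0.1, tolerance = 1e-12)
  expect_equal(offset$mean_residual, 0.1, tolerance = 1e-12)
  null_model <- applicability_metrics(rep(mean(obs), 5), obs)
  expect_equal(null_model$r_squared, 0, tolerance = 1e-12)
  expect_error(applicability_metrics(obs, rep(1, 5)),
               class = "degenerate_input")
  expect_error(applicability_metrics(obs, obs[1:3]),
               class = "domain_error")
  # RMSE dominates the mean absolute residual (Jensen) on random inputs
  set.seed(30)
  for (i in 1:50) {
    p <- rnorm(20); o <- rnorm(20)
    m <- applicability_metrics(p, o)
    expect_gte(m$rmse, m$mean_abs_residual - 1e-12)
    expect_gte(m$rmse^2, m$mean_abs_residual^2 - 1e-12)
  }
})

test_that("correlation screening handles exact, flipped and degenerate factors", {
  set.seed(40)
  risks <- runif(50)
  factors <- data.frame(same = risks, flipped = -risks,
                        constant = rep(1, 50), noise = runif(50))
  tab <- correlation_analysis(factors, risks)
  expect_equal(tab$r[tab$factor == "same"], 1, tolerance = 1e-12)
  expect_equal(tab$r[tab$factor == "flipped"], -1, tolerance = 1e-12)
  expect_true(is.na(tab$r[tab$factor == "constant"]))
  expect_equal(tab$flag[tab$factor == "constant"], "constant")
  expect_true(all(abs(tab$r) <= 1, na.rm = TRUE))
  # pairwise-complete handling of missing values, checked against cor()
  factors$noise[1:5] <- NA
  tab2 <- correlation_analysis(factors, risks)
  expect_equal(tab2$n[tab2$factor == "noise"], 45)
  expect_equal(tab2$r[tab2$factor == "noise"],
               cor(factors$noise, risks, use = "pairwise.complete.obs"),
               tolerance = 1e-12)
})

test_that("permutation test is exact at the floor and reproducible", {
  set.seed(50)
  risks <- runif(50)
  res <- significance_test(risks, risks, n_permutations = 999, seed = 3)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  again <- significance_test(risks, risks, n_permutations = 999, seed = 3)
  expect_identical(res$p_value, again$p_value)
  expect_gt(res$p_value, 0)  # add-one smoothing: never exactly zero
  expect_error(significance_test(rep(1, 50), risks),
               class = "degenerate_input")
  expect_error(significance_test(risks[1:5], risks[1:5]),
               class = "domain_error")
  expect_error(significance_test(risks, risks, n_permutations = 99),
               class = "domain_error")
  # statistic agrees with the built-in correlation
  x <- runif(50)
  res2 <- significance_test(x, risks, seed = 4)
  expect_equal(res2$statistic, abs(cor(x, risks)), tolerance = 1e-12)
})

test_that("the city report composes its sections from the component analyses", {
  recs <- make_records(60, seed = 60)
  assessments <- assess_batch(recs, default_fis_tree())
  observed <- pmin(pmax(assessments$risk +
                          rnorm(60, 0, 0.02), 0), 1)
  report <- evaluate_city(assessments, observed_risk = observed,
                          factors = recs[urbanhealth:::RECORD_VARIABLES],
                          n_boot = 500, n_permutations = 999, seed = 11)
  # sections match the component operations run with the same seeds
  expect_equal(report$credibility$level_0.95$lower,
               credibility_interval(assessments$risk, 0.95, 500,
                                    seed = 11)$lower)
  expect_equal(report$significance$iaqi$p_value,
               significance_test(assessments$iaqi, assessments$risk,
                                 999, seed = 12)$p_value)
  expect_equal(report$applicability$rmse,
               applicability_metrics(assessments$risk, observed)$rmse)
  corr <- correlation_analysis(
    cbind(recs[urbanhealth:::RECORD_VARIABLES],
          assessments[c("iaqi", "tci", "npi")]), assessments$risk)
  expect_equal(report$correlation$r, corr$r)
  expect_setequal(report$correlation$factor,
                  c(urbanhealth:::RECORD_VARIABLES, "iaqi", "tci", "npi"))
  # Holm adjustment is reported alongside raw p-values
  praw <- vapply(report$significance, `[[`, 0, "p_value")
  expect_equal(vapply(report$significance, `[[`, 0, "p_holm"),
               p.adjust(praw, "holm"))
  # no factor table: correlation covers the indices only, with a warning
  expect_warning(
    bare <- evaluate_city(assessments, n_boot = 500, seed = 11),
    class = "empty_factors")
  expect_setequal(bare$correlation$factor, c("iaqi", "tci", "npi"))
  expect_null(bare$applicability)
})

test_that("reports serialize to stable JSON", {
  recs <- make_records(30, seed = 70)
  assessments <- assess_batch(recs, default_fis_tree())
  report <- evaluate_city(assessments, observed_risk = assessments$risk,
                          factors = NULL, n_boot = 200, seed = 5) |>
    suppressWarnings()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(report, p1)
  write_report(report, p2)
  parsed <- jsonlite::read_json(p1)
  expect_named(parsed, c("credibility", "correlation", "significance",
                         "applicability", "config"))
  expect_equal(parsed$applicability$r_squared, 1)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
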