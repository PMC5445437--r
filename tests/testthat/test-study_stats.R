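test_that("deltas are exact per-animal changes from baseline", {
  res <- data.frame(
    animal_id = rep(c("A01", "A02"), each = 3),
    group = "FA",
    day_label = rep(c("baseline", "day1", "day2"), 2),
    endpoint = "RMSSD",
    value = c(5.0, 3.7, 4.0, 6.0, 6.5, NA))
  d <- make_deltas(res)
  expect_equal(d$delta[d$animal_id == "A01" & d$day_label == "day1"], -1.3)
  # missing endpoint on a day: missing delta, not zero
  expect_identical(nrow(d[d$animal_id == "A02" & d$day_label == "day2", ]), 0L)
})

test_that("animals without baseline are excluded with an audit note", {
  res <- data.frame(animal_id = c("A01", "A01", "A02"),
                    group = "FA",
                    day_label = c("baseline", "day1", "day1"),
                    endpoint = "SDNN", value = c(6, 7, 8))
  d <- make_deltas(res)
  expect_identical(unique(d$animal_id), "A01")
  expect_identical(attr(d, "no_baseline")$animal_id, "A02")
})

test_that("delta table dimensions follow the design", {
  set.seed(1)
  d <- simulate_delta_table(0, n_per_group = 6, n_days = 12)
  expect_identical(nrow(d), 12L * 12L)
})

test_that("identical groups give an exactly-zero LMM estimate", {
  base <- expand.grid(animal_id = sprintf("A%02d", 1:4),
                      day_label = paste0("day", 1:4),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$endpoint <- "X"
  set.seed(2)
  vals <- rnorm(nrow(base))
  d <- rbind(transform(base, group = "FA", delta = vals),
             transform(base, group = "PSOA", delta = vals,
                       animal_id = sub("A", "B", animal_id)))
  fit <- fit_lmm(d, "X", ref_group = "FA")
  expect_equal(fit$estimate, 0, tolerance = 1e-8)
})

test_that("LMM recovers an injected effect and reports per-day contrasts", {
  set.seed(5)
  est <- replicate(40, {
    d <- simulate_delta_table(-1.31)
    fit_lmm(d, "RMSSD", ref_group = "FA")$estimate
  })
  expect_lt(abs(mean(est) - (-1.31)), 0.2)
  set.seed(6)
  d <- simulate_delta_table(-1.31)
  daily <- fit_lmm(d, "RMSSD", contrast = "daily", ref_group = "FA")
  expect_identical(nrow(daily), 12L)
  expect_true(all(daily$SE > 0))
})

test_that("the AIC winner is reported and candidates are restrictable", {
  set.seed(7)
  d <- simulate_delta_table(1)
  fit <- fit_lmm(d, "RMSSD", ref_group = "FA")
  expect_true(fit$model %in% c("intercept", "intercept_day", "cs"))
  fit2 <- fit_lmm(d, "RMSSD", candidates = "intercept", ref_group = "FA")
  expect_identical(fit2$model, "intercept")
})

test_that("large-scale endpoint effects recover too (dP/dt max, -109)", {
  set.seed(14)
  est <- replicate(30, {
    d <- simulate_delta_table(-109, endpoint = "dPdt_max",
                              sd_animal = 40, sd_resid = 80)
    fit_lmm(d, "dPdt_max", ref_group = "FA")$estimate
  })
  expect_lt(abs(mean(est) - (-109)) / 109, 0.15)
})

test_that("group x diet interaction contrast is available", {
  set.seed(15)
  # exposure effect -2 in MetS, 0 in ND: interaction = -2
  parts <- list()
  for (diet in c("ND", "MetS")) {
    d <- simulate_delta_table(if (diet == "MetS") -2 else 0)
    d$diet <- diet
    d$animal_id <- paste(diet, d$animal_id)
    parts[[diet]] <- d
  }
  both <- do.call(rbind, parts)
  fit <- fit_lmm(both, "RMSSD", ref_group = "FA", diet_interaction = TRUE)
  expect_identical(fit$contrast, "group:diet")
  # diet reference is MetS (alphabetical), so the interaction is the ND
  # exposure effect minus the MetS one: 0 - (-2) = +2
  expect_lt(abs(fit$estimate - 2), 1)
  expect_true(fit$SE > 0)
})

test_that("Poisson GEE recovers equal rates as log-RR near zero", {
  set.seed(8)
  est <- replicate(40, {
    d <- simulate_daily_counts(rate_ratio = 1, base_mean = 3)
    fit_count_gee(d, ref_group = "FA")$estimate
  })
  expect_lt(abs(mean(est)), 0.1)
})

test_that("GEE flags degenerate inputs", {
  d <- simulate_daily_counts(1, 0.0001, n_per_group = 2, n_days = 3)
  d$count <- 0L
  expect_error(fit_count_gee(d, ref_group = "FA"), "inestimable")
  set.seed(9)
  d2 <- simulate_daily_counts(2, 3, n_per_group = 1, n_days = 6)
  fit <- fit_count_gee(d2, ref_group = "FA")
  expect_false(attr(fit, "fit")$robust_se_reliable)
})

test_that("GEE baseline handling supports covariate and offset modes", {
  set.seed(10)
  d <- simulate_daily_counts(rate_ratio = 3, base_mean = 2)
  f1 <- fit_count_gee(d, ref_group = "FA")
  f2 <- fit_count_gee(d, ref_group = "FA", baseline_as = "offset")
  expect_gt(f1$rate_ratio, 1.5)
  expect_gt(f2$rate_ratio, 1.5)
})

test_that("correlation handles exact, degenerate, and scaled inputs", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 3)$r, 1.0)
  expect_true(is.na(correlate(rep(1, 5), rnorm(5))$r))
  set.seed(11)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  r1 <- correlate(a, b)
  r2 <- correlate(10 * a + 2, -3 * b + 7)
  expect_equal(abs(r1$r), abs(r2$r), tolerance = 1e-12)
})

test_that("partial correlation removes a pure group confound", {
  set.seed(12)
  mean_pr <- replicate(50, {
    g <- rep(c("FA", "PSOA"), each = 60)
    pollutant <- ifelse(g == "PSOA", 50, 5) + rnorm(120, 0, 2)
    endpoint <- ifelse(g == "PSOA", -2, 0) + rnorm(120)  # no within-group link
    c(simple = correlate(pollutant, endpoint)$r,
      partial = correlate(pollutant, endpoint, group = g,
                          adjust_for_group = TRUE)$r)
  })
  expect_gt(abs(mean(mean_pr["simple", ])), 0.5)   # confounded
  expect_lt(abs(mean(mean_pr["partial", ])), 0.05) # removed
})
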