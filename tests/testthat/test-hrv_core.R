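test_that("ectopic filter removes intervals > 18% below the local mean", {
  # 120 < 0.82 * 150 = 123: removed
  nn <- filter_ectopic(c(150, 150, 150, 120, 150, 150, 150))
  expect_identical(nn$removed_idx, 4L)
  expect_identical(nn$n_removed, 1L)
  expect_equal(nn$intervals, rep(150, 6))
  # 125 > 123: kept
  nn2 <- filter_ectopic(c(150, 150, 150, 125, 150, 150, 150))
  expect_identical(nn2$n_removed, 0L)
  # exactly at the threshold: strict inequality keeps it
  x <- rep(150, 7); x[4] <- 0.82 * 150
  expect_identical(filter_ectopic(x)$n_removed, 0L)
})

test_that("filter is a single pass, order-preserving, and idempotent", {
  set.seed(42)
  x <- 180 + rnorm(300, 0, 3)
  x[c(50, 120, 200)] <- 120
  nn <- filter_ectopic(x)
  expect_identical(nn$removed_idx, c(50L, 120L, 200L))
  expect_identical(filter_ectopic(nn$intervals)$n_removed, 0L)
  expect_identical(nn$intervals, x[-nn$removed_idx])
})

test_that("generator APB injections are exactly the removed intervals", {
  set.seed(7)
  cfg <- synth_config()
  gb <- generate_beats(cfg, n_beats = 800, inject = c(APB = 20))
  iv <- beat_intervals(gb$beats)
  nn <- filter_ectopic(iv$intervals)
  expect_setequal(nn$removed_idx, gb$truth$interval_idx)
})

test_that("all-removed series warns and flags", {
  expect_warning(nn <- filter_ectopic(numeric(0)), NA)
  expect_identical(nn$n_removed, 0L)
})

test_that("time-domain metrics match hand values and handle degeneracy", {
  td <- time_domain(c(100, 110, 100, 110))
  expect_equal(td$RMSSD, 10)
  expect_equal(td$mean_RR, 105)
  expect_equal(td$HR, 60000 / 105)

  const <- time_domain(rep(180, 300))
  expect_equal(const$SDNN, 0)
  expect_equal(const$CV, 0)
  expect_equal(const$pNN15, 0)

  short <- time_domain(c(100, 120))
  expect_true(is.na(short$RMSSD))     # needs >= 3 intervals
  expect_false(is.na(short$SDNN))     # needs >= 2
})

test_that("time domain equals an independent brute-force oracle", {
  # oracle: explicit loops, no shared code with the implementation
  oracle <- function(x) {
    n <- length(x)
    m <- 0; for (v in x) m <- m + v; m <- m / n
    ss <- 0; for (v in x) ss <- ss + (v - m)^2
    sdnn <- sqrt(ss / (n - 1))
    sq <- 0; big <- 0
    for (i in 2:n) {
      d <- x[i] - x[i - 1]
      sq <- sq + d * d
      if (abs(d) > 15) big <- big + 1
    }
    list(RMSSD = sqrt(sq / (n - 1)), SDNN = sdnn, CV = sdnn / m,
         pNN15 = big / (n - 1))
  }
  set.seed(99)
  for (rep in 1:25) {
    x <- runif(300, 120, 260)
    got <- time_domain(x)
    want <- oracle(x)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
})

test_that("RMSSD/SDNN are shift-invariant, CV is not", {
  set.seed(3)
  x <- 180 + rnorm(200, 0, 5)
  a <- time_domain(x); b <- time_domain(x + 50)
  expect_equal(a$RMSSD, b$RMSSD)
  expect_equal(a$SDNN, b$SDNN)
  expect_gt(a$CV, b$CV)
})

test_that("a 1.2 Hz sinusoidal interval series concentrates power in HF", {
  t <- cumsum(rep(180, 1200)) / 1000
  x <- 180 + 5 * sin(2 * pi * 1.2 * t)
  fd <- frequency_domain(x)
  expect_gte(fd$HF / (fd$LF + fd$HF), 0.95)
})

test_that("constant intervals give zero band power; flags propagate", {
  fd <- frequency_domain(rep(180, 800))
  expect_equal(fd$LF, 0)
  expect_equal(fd$HF, 0)
  expect_true(is.na(fd$LF_HF))

  nn <- structure(list(intervals = 180 + rnorm(700), n_removed = 300L,
                       removed_idx = integer(0), removal_reasons = character(0),
                       source = "ecg", all_removed = FALSE),
                  class = "nn_series")
  fd2 <- frequency_domain(nn)
  expect_true(fd2$low_confidence)     # 30% removed > 20% default
})

test_that("white-noise LF/HF tracks the band-width ratio expectation", {
  set.seed(21)
  bands <- rat_bands()
  expect_ratio <- (bands$lf[2] - bands$lf[1]) / (bands$hf[2] - bands$hf[1])
  ratios <- replicate(60, {
    x <- 180 + rnorm(700, 0, 4)
    fd <- frequency_domain(x)
    fd$LF_HF
  })
  m <- mean(ratios)
  expect_gt(m, 0.5 * expect_ratio)
  expect_lt(m, 2.0 * expect_ratio)
})

test_that("pulse-mode and ECG-mode time-domain HRV agree on clean data", {
  set.seed(5)
  cfg <- synth_config(sd_sbp = 0.5, sd_rr = 0.5)
  gb <- generate_beats(cfg, n_beats = 1500)
  b <- gb$beats
  b$t_pulse <- b$t_R + 30              # systolic peak at fixed offset from R
  ecg <- time_domain(filter_ectopic(beat_intervals(b, "ecg")$intervals))
  pulse <- time_domain(filter_ectopic(beat_intervals(b, "pulse")$intervals))
  for (f in c("RMSSD", "SDNN", "CV", "mean_RR"))
    expect_lt(abs(ecg[[f]] - pulse[[f]]) / ecg[[f]], 0.02)
})
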