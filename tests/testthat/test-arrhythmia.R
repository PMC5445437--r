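test_that("APB rule: >18% RR shortening with normal PR", {
  # RR 148 amid neighbors averaging 182: 148 < 0.82 * 182 = 149.24 -> APB
  rr <- c(182, 182, 182, 148, 182, 182, 182, 182)
  t_R <- cumsum(c(0, rr))
  df <- make_beat_df(length(t_R))
  df$t_R <- t_R
  df$t_P <- t_R - 45; df$t_S <- t_R + 15
  df$t_Tpeak <- t_R + 45; df$t_Tend <- t_R + 60
  b <- beat_series(df)
  ev <- detect_apb(b, pr_ref = fixed_pr_ref(45, 1))
  expect_identical(ev$type, "APB")
  expect_identical(ev$beat, 5L)        # beat ending the shortened interval
  expect_lt(ev$RR_ratio, 0.82)

  # same shortening but PR prolonged: rule conjunct fails
  df2 <- df
  df2$t_P[5] <- df2$t_R[5] - 52        # PR 52 outside 45 +/- 2
  ev2 <- detect_apb(beat_series(df2), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(nrow(ev2), 0L)
})

test_that("clean generated streams produce zero events", {
  set.seed(2)
  gb <- generate_beats(synth_config(), 900)
  ev <- detect_arrhythmias(gb$beats)
  expect_identical(nrow(ev), 0L)
})

test_that("Mobitz II: on-time P, flat PRs, normal post PR, RR 2-3x", {
  b <- make_block_series(rr_block_mult = 2.1, pr_prior = c(45, 45, 46, 45),
                         pr_post = 45)
  i <- nc_index(b)
  ev <- classify_nonconducted_P(b, i, pr_ref = fixed_pr_ref(45, 1))
  expect_identical(ev$type, "MobitzII")
  expect_equal(ev$RR_block_ratio, 2.1, tolerance = 1e-6)
})

test_that("Mobitz I: PR prolongation before the block, or post shortening", {
  b <- make_block_series(pr_prior = c(45, 48, 52, 57), pr_post = 44)
  ev <- classify_nonconducted_P(b, nc_index(b), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(ev$type, "MobitzI")
  expect_equal(ev$PR_trend, 12)        # 57 - 45 > 2 SD

  # post-PR shortening alone also qualifies
  b2 <- make_block_series(pr_prior = c(45, 45, 45, 45), pr_post = 40)
  ev2 <- classify_nonconducted_P(b2, nc_index(b2), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(ev2$type, "MobitzI")
})

test_that("advanced AV block requires >= 3-fold RR increase", {
  b <- make_block_series(rr_block_mult = 3.4)
  ev <- classify_nonconducted_P(b, nc_index(b), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(ev$type, "AdvancedAVB")
  # just below the 3-fold line stays Mobitz II
  b2 <- make_block_series(rr_block_mult = 2.9)
  ev2 <- classify_nonconducted_P(b2, nc_index(b2), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(ev2$type, "MobitzII")
})

test_that("Mobitz I vs II disambiguation is driven solely by PR terms", {
  for (mult in c(2.2, 2.6)) {
    flat <- make_block_series(rr_block_mult = mult,
                              pr_prior = c(45, 45, 45, 45), pr_post = 45)
    trend <- make_block_series(rr_block_mult = mult,
                               pr_prior = c(45, 48, 52, 57), pr_post = 45)
    expect_identical(
      classify_nonconducted_P(flat, nc_index(flat),
                              pr_ref = fixed_pr_ref(45, 1))$type, "MobitzII")
    expect_identical(
      classify_nonconducted_P(trend, nc_index(trend),
                              pr_ref = fixed_pr_ref(45, 1))$type, "MobitzI")
  }
})

test_that("premature non-conducted P is an ncAPB regardless of PR history", {
  b <- make_block_series(pp_ratio = 0.75, pr_prior = c(45, 48, 52, 57))
  ev <- classify_nonconducted_P(b, nc_index(b), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(ev$type, "ncAPB")
  expect_lt(ev$PP_ratio, 0.82)    # premature well past the 18% threshold
})

test_that("sub-2-fold RR or missing history is unclassifiable, not mislabeled", {
  b <- make_block_series(rr_block_mult = 1.6)
  ev <- classify_nonconducted_P(b, nc_index(b), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(nrow(ev), 0L)
  expect_match(attr(ev, "unclassifiable_reason"), "RR across block")

  b2 <- make_block_series(n_before = 3)
  ev2 <- classify_nonconducted_P(b2, nc_index(b2), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(nrow(ev2), 0L)
})

test_that("the cascade assigns exactly one label per non-conducted P", {
  set.seed(17)
  gb <- generate_beats(synth_config(), 1700,
                       inject = c(ncAPB = 10, MobitzI = 10, MobitzII = 10,
                                  AdvancedAVB = 10))
  ev <- detect_arrhythmias(gb$beats)
  expect_identical(anyDuplicated(ev$beat), 0L)
  expect_identical(nrow(ev), 40L)
})

test_that("injected events are recovered with a diagonal confusion matrix", {
  set.seed(3)
  gb <- generate_beats(synth_config(), 1700,
                       inject = c(APB = 20, ncAPB = 20, MobitzI = 20,
                                  MobitzII = 20, AdvancedAVB = 20))
  ev <- detect_arrhythmias(gb$beats)
  tr <- gb$truth
  called <- vapply(seq_len(nrow(tr)), function(j) {
    hit <- ev$type[ev$beat == tr$beat[j]]
    if (length(hit)) hit[1] else "missed"
  }, character(1))
  expect_identical(called, tr$type)              # 100% sensitivity per type
  expect_identical(nrow(ev), nrow(tr))           # no false positives
})

test_that("exactly-at-threshold shortening is not flagged (strict rule)", {
  rr <- rep(180, 9)
  rr[5] <- 0.82 * mean(rep(180, 6))    # exactly 18% below neighbors
  t_R <- cumsum(c(0, rr))
  df <- make_beat_df(length(t_R)); df$t_R <- t_R; df$t_P <- t_R - 45
  df$t_S <- t_R + 15; df$t_Tpeak <- t_R + 45; df$t_Tend <- t_R + 60
  ev <- detect_apb(beat_series(df), pr_ref = fixed_pr_ref(45, 1))
  expect_identical(nrow(ev), 0L)
})

test_that("daily counts honor the APB audit-day restriction", {
  design <- expand.grid(animal_id = "A01",
                        day_label = c("baseline", paste0("day", 1:12)),
                        stringsAsFactors = FALSE)
  ev <- data.frame(type = c("APB", "APB", "MobitzII"),
                   beat = 1:3,
                   animal_id = "A01",
                   day_label = c("day1", "day2", "day2"),
                   stringsAsFactors = FALSE)
  dc <- count_events(ev, design)
  get <- function(day, type) dc$count[dc$day_label == day & dc$type == type]
  expect_identical(get("day1", "APB"), 1L)       # audit day: counted
  expect_true(is.na(get("day2", "APB")))         # non-audit day: missing
  expect_identical(get("day2", "MobitzII"), 1L)  # other types: all days
  expect_identical(get("day3", "MobitzII"), 0L)  # analyzed day, no events
})
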