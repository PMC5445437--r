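# Fixture builders shared across test files. Everything is constructed in
# code; no binary fixtures.

# Minimal conducted-beat table with regular geometry.
make_beat_df <- function(n = 10, rr = 180, pr = 45, sbp = 135, dbp = 87,
                         animal_id = "A01", day_label = "baseline",
                         segment_id = "seg1", group = "FA") {
  t_R <- (seq_len(n) - 1) * rr
  data.frame(animal_id = rep(animal_id, n), group = rep(group, n),
             day_label = rep(day_label, n),
             segment_id = rep(segment_id, n),
             t_P = t_R - pr, t_R = t_R, t_S = t_R + 15,
             t_Tpeak = t_R + 45, t_Tend = t_R + 60,
             conducted = rep(TRUE, n), SBP = rep(sbp, n), DBP = rep(dbp, n),
             stringsAsFactors = FALSE)
}

# Beat series with one non-conducted P at a chosen position, with full
# control over the rule terms.
# rr_block_mult: RR across the block as a multiple of baseline RR.
# pr_prior: PR values of the 4 conducted beats before the block.
# pr_post: PR of the first conducted beat after the block.
# pp_ratio: PP of the blocked P relative to prior PP (1 = on time).
make_block_series <- function(rr = 180, pr = 45, n_before = 8, n_after = 6,
                              rr_block_mult = 2.2, pr_prior = rep(pr, 4),
                              pr_post = pr, pp_ratio = 1) {
  t_R_before <- (seq_len(n_before) - 1) * rr
  block_end <- t_R_before[n_before] + rr_block_mult * rr
  t_R_after <- block_end + (seq_len(n_after) - 1) * rr
  t_R <- c(t_R_before, t_R_after)
  t_P <- t_R - pr
  if (n_before >= 4) {
    idx_prior <- (n_before - 3):n_before
    t_P[idx_prior] <- t_R[idx_prior] - pr_prior
  }
  t_P[n_before + 1] <- t_R[n_before + 1] - pr_post
  df <- data.frame(animal_id = "A01", group = "FA", day_label = "day1",
                   segment_id = "seg1",
                   t_P = t_P, t_R = t_R, t_S = t_R + 15,
                   t_Tpeak = t_R + 45, t_Tend = t_R + 60,
                   conducted = TRUE, SBP = 135, DBP = 87,
                   stringsAsFactors = FALSE)
  blocked_p <- data.frame(animal_id = "A01", group = "FA",
                          day_label = "day1", segment_id = "seg1",
                          t_P = t_P[n_before] + pp_ratio * rr,
                          t_R = NA_real_, t_S = NA_real_,
                          t_Tpeak = NA_real_, t_Tend = NA_real_,
                          conducted = FALSE, SBP = NA_real_, DBP = NA_real_,
                          stringsAsFactors = FALSE)
  df <- rbind(df, blocked_p)
  df <- df[order(ifelse(is.na(df$t_R), df$t_P, df$t_R)), ]
  rownames(df) <- NULL
  beat_series(df)
}

# PR reference with a known SD, bypassing estimation.
fixed_pr_ref <- function(mean = 45, sd = 1, k = 2) {
  list(mean = mean, sd = sd, lower = mean - k * sd, upper = mean + k * sd)
}

nc_index <- function(beats) which(!(beats$conducted %in% TRUE))
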