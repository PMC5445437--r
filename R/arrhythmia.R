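#' Per-animal PR reference from baseline-day beats
#'
#' The "normal PR" band and "PR prolongation" criteria are calibrated per
#' animal: the baseline day's conducted-beat PR mean and SD define
#' normal as mean +/- `k` SD, and prolongation as a monotone PR increase
#' totalling more than `k_trend` SD over the prior 4 conducted beats.
#'
#' @param beats `beat_series` (baseline-day recording for the animal).
#' @param k half-width of the normal band in SDs (default 2).
#' @return list with `mean`, `sd`, `lower`, `upper` (ms).
#' @export
pr_reference <- function(beats, k = 2) {
  pr <- beats$t_R - beats$t_P
  pr <- pr[beats$conducted %in% TRUE & !is.na(pr)]
  if (length(pr) < 2L)
    stop("need >= 2 conducted beats with PR to calibrate the reference",
         call. = FALSE)
  m <- mean(pr); s <- stats::sd(pr)
  list(mean = m, sd = s, lower = m - k * s, upper = m + k * s)
}

pr_is_normal <- function(pr, ref) !is.na(pr) & pr >= ref$lower & pr <= ref$upper

#' Detect atrial premature beats
#'
#' Flags conducted beats whose RR interval is shortened by more than
#' `frac` (default 18%) relative to the mean of the neighboring 6 RRs
#' (3 preceding and 3 following) while the beat's PR interval remains
#' within the animal's normal band. Beats with unmeasurable PR are skipped
#' with an audit note.
#'
#' @param beats a `beat_series`.
#' @param pr_ref PR reference from [pr_reference()]; when `NULL` it is
#'   calibrated from this segment itself.
#' @param frac RR-shortening threshold (default 0.18, strict `>`).
#' @return data.frame of events (class `arrhythmia_events`): type "APB",
#'   beat index, evidence columns (RR, local mean, RR ratio, PR), plus an
#'   attribute `skipped` listing beats not evaluable.
#' @export
detect_apb <- function(beats, pr_ref = NULL, frac = 0.18) {
  if (is.null(pr_ref)) pr_ref <- pr_reference(beats)
  cond_idx <- which(beats$conducted %in% TRUE & !is.na(beats$t_R))
  rr <- diff(beats$t_R[cond_idx])            # rr[j] ends at conducted beat j+1
  # an RR spanning a non-conducted P is a block gap, not a normal RR:
  # exclude it both as candidate and from neighbor averages
  nc_pos <- which(!(beats$conducted %in% TRUE) & !is.na(beats$t_P))
  spans_nc <- vapply(seq_along(rr), function(j)
    any(nc_pos > cond_idx[j] & nc_pos < cond_idx[j + 1L]), logical(1))
  nearest_valid <- function(j, dir) {
    out <- integer(0); i <- j + dir
    while (length(out) < 3L && i >= 1L && i <= length(rr) &&
           abs(i - j) <= 6L) {
      if (!spans_nc[i]) out <- c(out, i)
      i <- i + dir
    }
    out
  }
  events <- list(); skipped <- integer()
  for (j in seq_along(rr)) {
    if (spans_nc[j]) next
    lo <- rr[nearest_valid(j, -1L)]
    hi <- rr[nearest_valid(j, +1L)]
    if (length(lo) < 3L || length(hi) < 3L) next
    local_mean <- mean(c(lo, hi))
    if (rr[j] < (1 - frac) * local_mean - 1e-9) {   # strict at the threshold
      beat <- cond_idx[j + 1L]
      pr <- beats$t_R[beat] - beats$t_P[beat]
      if (is.na(pr)) { skipped <- c(skipped, beat); next }
      if (pr_is_normal(pr, pr_ref)) {
        events[[length(events) + 1L]] <- data.frame(
          type = "APB", beat = beat,
          RR = rr[j], local_mean_RR = local_mean,
          RR_ratio = rr[j] / local_mean, PR = pr,
          PP_ratio = NA_real_, RR_block_ratio = NA_real_,
          PR_trend = NA_real_, post_PR = NA_real_,
          animal_id = beats$animal_id[1L], day_label = beats$day_label[1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(events)) do.call(rbind, events) else empty_event_table()
  attr(out, "skipped") <- skipped
  class(out) <- c("arrhythmia_events", "data.frame")
  out
}

empty_event_table <- function() {
  data.frame(type = character(), beat = integer(), RR = numeric(),
             local_mean_RR = numeric(), RR_ratio = numeric(), PR = numeric(),
             PP_ratio = numeric(), RR_block_ratio = numeric(),
             PR_trend = numeric(), post_PR = numeric(),
             animal_id = character(), day_label = character(),
             stringsAsFactors = FALSE)
}

#' Classify one non-conducted P wave
#'
#' Decision cascade for a P wave without an associated QRS, applied in
#' order (exactly one label per event):
#' \enumerate{
#'   \item premature P — PP interval < (1 - frac) x mean of the prior 4
#'     PPs — is a non-conducted APB (`ncAPB`);
#'   \item P on time with the RR across the block at least `rr_floor`
#'     (default 2) times the local baseline RR (median of the prior 4
#'     conducted RRs), and either monotone PR prolongation totalling more
#'     than `k_trend` SD over the prior 4 conducted beats or shortening of
#'     the first conducted PR after the block — Mobitz I;
#'   \item as (2) but PR un-prolonged over the prior 4 and a normal first
#'     post-block PR: RR ratio in [2, 3) — Mobitz II;
#'   \item same with RR ratio >= 3 — advanced AV block (`AdvancedAVB`).
#' }
#'
#' @param beats a `beat_series`.
#' @param i row index of the non-conducted P (`conducted == FALSE`).
#' @param pr_ref PR reference from [pr_reference()].
#' @param frac prematurity threshold on PP (default 0.18).
#' @param rr_floor minimum RR-across-block fold increase for any AV-block
#'   call (default 2; applies to both Mobitz forms).
#' @param k_trend PR-trend threshold in SDs of the PR reference (default 2).
#' @return one-row event data.frame with the measured rule terms, or a
#'   zero-row table with attribute `unclassifiable_reason` when fewer than
#'   4 prior conducted beats exist or the P is on time but no rule fires.
#' @export
classify_nonconducted_P <- function(beats, i, pr_ref = NULL, frac = 0.18,
                                    rr_floor = 2, k_trend = 2) {
  stopifnot(i >= 1L, i <= nrow(beats))
  if (beats$conducted[i] %in% TRUE || is.na(beats$t_P[i]))
    stop("beat ", i, " is not a non-conducted P wave", call. = FALSE)
  if (is.null(pr_ref)) pr_ref <- pr_reference(beats)
  fail <- function(reason) {
    out <- empty_event_table()
    attr(out, "unclassifiable_reason") <- reason
    out
  }
  evd <- function(type, PP_ratio = NA_real_, RR_block_ratio = NA_real_,
                  PR_trend = NA_real_, post_PR = NA_real_) {
    data.frame(type = type, beat = i, RR = NA_real_,
               local_mean_RR = NA_real_, RR_ratio = NA_real_, PR = NA_real_,
               PP_ratio = PP_ratio, RR_block_ratio = RR_block_ratio,
               PR_trend = PR_trend, post_PR = post_PR,
               animal_id = beats$animal_id[1L],
               day_label = beats$day_label[1L], stringsAsFactors = FALSE)
  }
  has_p <- which(!is.na(beats$t_P))
  prior_p <- has_p[has_p < i]
  if (length(prior_p) < 5L) return(fail("fewer than 5 prior P waves"))
  pp_prior <- diff(beats$t_P[utils::tail(prior_p, 5L)])   # prior 4 PPs
  pp <- beats$t_P[i] - beats$t_P[utils::tail(prior_p, 1L)]
  pp_ratio <- pp / mean(pp_prior)
  if (pp_ratio < (1 - frac))
    return(evd("ncAPB", PP_ratio = pp_ratio))
  if (pp_ratio > (1 + frac))
    return(fail("P neither premature nor at a normal PP interval"))
  cond <- which(beats$conducted %in% TRUE & !is.na(beats$t_R))
  prior_c <- cond[cond < i]
  next_c <- cond[cond > i]
  if (length(prior_c) < 5L) return(fail("fewer than 4 prior conducted RRs"))
  if (!length(next_c)) return(fail("no conducted beat after the block"))
  last4 <- utils::tail(prior_c, 4L)
  rr_prior <- diff(beats$t_R[utils::tail(prior_c, 5L)])   # prior 4 RRs
  rr_block <- beats$t_R[next_c[1L]] - beats$t_R[utils::tail(prior_c, 1L)]
  rr_ratio <- rr_block / stats::median(rr_prior)
  if (rr_ratio < rr_floor)
    return(fail(sprintf("RR across block only %.2fx local baseline", rr_ratio)))
  pr4 <- beats$t_R[last4] - beats$t_P[last4]
  if (any(is.na(pr4))) return(fail("PR unmeasurable on prior conducted beats"))
  pr_trend <- pr4[4L] - pr4[1L]
  prolonged <- all(diff(pr4) >= 0) && pr_trend > k_trend * pr_ref$sd
  post_pr <- beats$t_R[next_c[1L]] - beats$t_P[next_c[1L]]
  post_shortened <- !is.na(post_pr) &&
    (pr4[4L] - post_pr) > k_trend * pr_ref$sd
  if (prolonged || post_shortened)
    return(evd("MobitzI", PP_ratio = pp_ratio, RR_block_ratio = rr_ratio,
               PR_trend = pr_trend, post_PR = post_pr))
  if (!prolonged && pr_is_normal(post_pr, pr_ref)) {
    type <- if (rr_ratio >= 3) "AdvancedAVB" else "MobitzII"
    return(evd(type, PP_ratio = pp_ratio, RR_block_ratio = rr_ratio,
               PR_trend = pr_trend, post_PR = post_pr))
  }
  fail("no AV-block rule satisfied")
}

#' Scan a beat series for all rule-based arrhythmia events
#'
#' Runs [detect_apb()] over conducted beats and
#' [classify_nonconducted_P()] over every non-conducted P wave.
#'
#' @param beats a `beat_series`.
#' @param pr_ref PR reference ([pr_reference()]); calibrated from `beats`
#'   when `NULL`.
#' @param ... passed to the per-event classifiers.
#' @return `arrhythmia_events` data.frame; attribute `unclassified` lists
#'   non-conducted P rows that no rule labelled, with reasons.
#' @export
detect_arrhythmias <- function(beats, pr_ref = NULL, ...) {
  if (is.null(pr_ref)) pr_ref <- pr_reference(beats)
  apb <- detect_apb(beats, pr_ref = pr_ref)
  nc <- which(!(beats$conducted %in% TRUE) & !is.na(beats$t_P))
  # consecutive non-conducted Ps inside one blocked gap (no conducted beat
  # between them) are one episode: classify the first P only
  if (length(nc) > 1L) {
    cond <- which(beats$conducted %in% TRUE)
    gap_id <- vapply(nc, function(i) sum(cond < i), integer(1))
    nc <- nc[!duplicated(gap_id)]
  }
  parts <- list(as.data.frame(apb))
  unclassified <- list()
  for (i in nc) {
    ev <- classify_nonconducted_P(beats, i, pr_ref = pr_ref, ...)
    if (nrow(ev)) parts[[length(parts) + 1L]] <- ev
    else unclassified[[length(unclassified) + 1L]] <-
      data.frame(beat = i, reason = attr(ev, "unclassifiable_reason"),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$beat), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unclassified") <-
    if (length(unclassified)) do.call(rbind, unclassified)
    else data.frame(beat = integer(), reason = character())
  class(out) <- c("arrhythmia_events", "data.frame")
  out
}

#' Default APB audit days
#'
#' APBs were counted only on a random half of study days: baseline and
#' exposure days 1, 4, 6, 8, 11, 12. All other event types are counted on
#' every analyzed day.
#' @export
apb_audit_days <- function() c("baseline", paste0("day", c(1, 4, 6, 8, 11, 12)))

#' Daily arrhythmia counts per animal
#'
#' Tallies events per type per animal-day (events per 5-h exposure day).
#' APB counts are restricted to the audit-day list; days the design marks
#' as analyzed but with zero events count as 0, while days with no
#' analyzed segments are absent (missing, not zero).
#'
#' @param events `arrhythmia_events` table (rows tagged animal_id,
#'   day_label).
#' @param design data.frame of analyzed animal-days (columns animal_id,
#'   day_label); one row per analyzed day.
#' @param apb_days character vector of APB audit day labels
#'   (default [apb_audit_days()]).
#' @param types event types to tally.
#' @return data.frame: animal_id, day_label, type, count.
#' @export
count_events <- function(events, design,
                         apb_days = apb_audit_days(),
                         types = c("APB", "ncAPB", "MobitzI", "MobitzII",
                                   "AdvancedAVB")) {
  design <- unique(design[, c("animal_id", "day_label")])
  grid <- merge(design, data.frame(type = types), by = NULL)
  ev <- as.data.frame(events)
  ev <- ev[ev$type %in% types, c("animal_id", "day_label", "type")]
  ev <- ev[!(ev$type == "APB" & !(ev$day_label %in% apb_days)), , drop = FALSE]
  if (nrow(ev)) {
    tab <- stats::aggregate(list(count = rep(1L, nrow(ev))),
                            ev, FUN = sum)
    out <- merge(grid, tab, all.x = TRUE,
                 by = c("animal_id", "day_label", "type"))
  } else {
    out <- grid; out$count <- NA_integer_
  }
  out$count[is.na(out$count)] <- 0L
  # APB on non-audit days was never examined: missing, not zero
  out$count[out$type == "APB" & !(out$day_label %in% apb_days)] <- NA_integer_
  out[order(out$animal_id, out$day_label, out$type), ]
}
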