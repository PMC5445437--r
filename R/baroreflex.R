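#' Find spontaneous baroreflex sequences
#'
#' Sequence method: scans paired systolic pressures and subsequent
#' inter-beat intervals for maximal monotone runs of at least `min_len`
#' beats in which every successive systolic step is at least `min_dSBP`
#' mmHg and every corresponding (lagged) interval step is at least
#' `min_dRR` ms, in the same direction. Each run gets a least-squares
#' slope of interval on SBP; runs whose interval-on-SBP correlation is
#' below `min_r` are rejected. Ectopic beats must be excluded upstream.
#'
#' The lag convention pairs the systolic peak of beat i with the following
#' interval i -> i + lag; zero pressure or interval steps break a run
#' (configurable via `ties_break`).
#'
#' @param sbp systolic pressures by beat (mmHg).
#' @param intervals inter-beat intervals (ms); `intervals[i]` is the
#'   interval beginning at beat i (i -> i+1).
#' @param min_len minimum run length in beats (default 3).
#' @param min_dSBP minimum absolute SBP step, mmHg (default 0.50).
#' @param min_dRR minimum absolute interval step, ms (default 0.30).
#' @param min_r minimum within-run correlation of interval on SBP
#'   (signed, matching the run direction; default 0.50).
#' @param lag beats between a systolic peak and the interval it drives
#'   (default 1).
#' @param ties_break logical; zero steps break runs (default TRUE).
#' @return data.frame of accepted sequences: start, length, direction
#'   ("up"/"down"), slope (ms/mmHg), r. Zero rows is a valid result.
#' @export
find_sequences <- function(sbp, intervals, min_len = 3, min_dSBP = 0.50,
                           min_dRR = 0.30, min_r = 0.50, lag = 1,
                           ties_break = TRUE) {
  stopifnot(lag >= 0)
  # pair SBP of beat i with interval starting at beat i + lag - 1
  n_pair <- min(length(sbp), length(intervals) - (lag - 1L))
  if (is.na(n_pair) || n_pair < min_len)
    return(empty_sequence_table())
  s <- sbp[seq_len(n_pair)]
  r <- intervals[seq_len(n_pair) + (lag - 1L)]
  ds <- diff(s); dr <- diff(r)
  step_dir <- function(dx, min_dx) {
    d <- ifelse(is.na(dx), 0, sign(dx))
    d[abs(dx) < min_dx] <- 0
    if (!ties_break) d[dx == 0] <- NA   # NA = tolerated tie, inherits run
    d
  }
  dir_s <- step_dir(ds, min_dSBP)
  dir_r <- step_dir(dr, min_dRR)
  step <- ifelse(dir_s == dir_r & dir_s != 0, dir_s, 0)
  step[is.na(step)] <- 0
  runs <- rle(step)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0 & runs$lengths + 1L >= min_len
  out <- list()
  for (q in which(keep)) {
    idx <- starts[q]:(ends[q] + 1L)    # beats spanned by the run of steps
    fit_r <- suppressWarnings(stats::cor(s[idx], r[idx]))
    slope <- stats::cov(s[idx], r[idx]) / stats::var(s[idx])
    if (!is.na(fit_r) && fit_r >= min_r) {
      out[[length(out) + 1L]] <- data.frame(
        start = starts[q], length = length(idx),
        direction = if (runs$values[q] > 0) "up" else "down",
        slope = slope, r = fit_r, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_sequence_table())
  do.call(rbind, out)
}

empty_sequence_table <- function() {
  data.frame(start = integer(), length = integer(), direction = character(),
             slope = numeric(), r = numeric(), stringsAsFactors = FALSE)
}

#' Spontaneous baroreflex sensitivity for one segment
#'
#' BRS slope is the unweighted mean of the accepted up- and down-sequence
#' slopes (pooled). With no accepted sequences the slope is `NA` and the
#' segment is excluded from downstream deltas.
#'
#' @param sequences data.frame from [find_sequences()].
#' @param segment_id optional segment identifier carried through.
#' @return list of class `brs_estimate`: slope (ms/mmHg), n_sequences,
#'   n_up, n_down, segment_id.
#' @export
estimate_brs <- function(sequences, segment_id = NA_character_) {
  n <- nrow(sequences)
  structure(list(
    slope = if (n >= 1L) mean(sequences$slope) else NA_real_,
    n_sequences = n,
    n_up = sum(sequences$direction == "up"),
    n_down = sum(sequences$direction == "down"),
    segment_id = segment_id), class = "brs_estimate")
}

#' Sequence-method BRS from a beat series
#'
#' Extracts SBP and intervals (ectopic-filtered) from a segment and runs
#' [find_sequences()] + [estimate_brs()].
#'
#' @param beats a `beat_series`.
#' @param ... passed to [find_sequences()].
#' @return a `brs_estimate`.
#' @export
brs_segment <- function(beats, ...) {
  cond <- beats$conducted %in% TRUE & !is.na(beats$t_R)
  b <- beats[cond, , drop = FALSE]
  if (nrow(b) < 4L)
    return(estimate_brs(empty_sequence_table(), beats$segment_id[1L]))
  intervals <- diff(b$t_R)
  nn <- filter_ectopic(intervals)
  keep_beats <- setdiff(seq_along(intervals), nn$removed_idx)
  sbp <- b$SBP[keep_beats]
  iv <- intervals[keep_beats]
  seqs <- find_sequences(sbp, iv, ...)
  estimate_brs(seqs, beats$segment_id[1L])
}
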