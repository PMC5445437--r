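#' Remove ectopically shortened inter-beat intervals
#'
#' An interval is removed when it is shortened by more than `frac` (default
#' 18%) relative to the average of its 3 preceding and 3 following
#' intervals, i.e. removed when `x[i] < (1 - frac) * local_mean`. This
#' controls for atrial premature beats before HRV and baroreflex analysis.
#'
#' Edge intervals without 3 neighbors on a side use the neighbors available
#' (at least 2 per side); with fewer than 2 on either side the interval is
#' left unfiltered. The comparison is made against the original (unfiltered)
#' series in a single pass, so filtering is idempotent on typical data.
#'
#' @param intervals numeric vector of inter-beat intervals, ms.
#' @param frac shortening threshold as a fraction (default 0.18).
#' @param source interval provenance tag, `"ecg"` or `"pulse"`.
#' @return object of class `nn_series`: list with `intervals` (retained,
#'   order preserved), `n_removed`, `removed_idx` (indices into the input),
#'   `removal_reasons`, `source`, and `all_removed` warning flag.
#' @export
filter_ectopic <- function(intervals, frac = 0.18, source = "ecg") {
  n <- length(intervals)
  removed <- logical(n)
  reasons <- character(0)
  if (n >= 5L) {                       # need >= 2 neighbors per side
    local_mean <- rep(NA_real_, n)
    if (n >= 7L) {
      # interior: centered 7-window sum minus self, vectorized
      cs <- cumsum(c(0, intervals))
      i <- 4L:(n - 3L)
      local_mean[i] <- (cs[i + 4L] - cs[i - 3L] - intervals[i]) / 6
    }
    edge <- c(seq_len(min(3L, n)), seq.int(max(1L, n - 2L), n))
    for (i in unique(edge)) {
      lo <- intervals[max(1L, i - 3L):(i - 1L)]
      hi <- if (i < n) intervals[(i + 1L):min(n, i + 3L)] else numeric(0)
      if (length(lo) >= 2L && length(hi) >= 2L)
        local_mean[i] <- mean(c(lo, hi))
    }
    # small epsilon so an interval at exactly (1 - frac) x mean is kept
    # (strict inequality) regardless of floating-point representation
    removed <- !is.na(local_mean) &
      intervals < (1 - frac) * local_mean - 1e-9
    reasons <- sprintf(
      "interval %d: %.6g ms < %.6g (%.0f%% of local mean %.6g)",
      which(removed), intervals[removed],
      (1 - frac) * local_mean[removed], 100 * (1 - frac),
      local_mean[removed])
  }
  out <- structure(list(
    intervals = intervals[!removed],
    n_removed = sum(removed),
    removed_idx = which(removed),
    removal_reasons = reasons,
    source = source,
    all_removed = n > 0L && all(removed)), class = "nn_series")
  if (out$all_removed)
    warning("all intervals removed by ectopic filter", call. = FALSE)
  out
}

#' Time-domain heart rate variability for one segment
#'
#' RMSSD = sqrt(mean(successive differences^2)); SDNN = sample (n-1)
#' standard deviation of the normal-to-normal intervals; CV = SDNN /
#' mean interval (rate-normalized SDNN, dimensionless); pNN15 = fraction of
#' successive absolute differences strictly greater than 15 ms.
#'
#' @param nn an `nn_series` from [filter_ectopic()] or a numeric vector of
#'   NN intervals (ms).
#' @param pnn_threshold_ms threshold for pNN (default 15 ms, strict `>`).
#' @return list of class `hrv_result` with RMSSD, SDNN, CV, pNN15, mean_RR,
#'   HR (beats/min, 60000/mean_RR), n_beats. Metrics below their minimum
#'   interval count are `NA`.
#' @export
time_domain <- function(nn, pnn_threshold_ms = 15) {
  x <- if (inherits(nn, "nn_series")) nn$intervals else as.numeric(nn)
  n <- length(x)
  d <- diff(x)
  mean_rr <- if (n >= 1L) mean(x) else NA_real_
  res <- list(
    RMSSD = if (n >= 3L) sqrt(mean(d^2)) else NA_real_,
    SDNN  = if (n >= 2L) stats::sd(x) else NA_real_,
    CV    = if (n >= 2L) stats::sd(x) / mean_rr else NA_real_,
    pNN15 = if (n >= 3L) mean(abs(d) > pnn_threshold_ms) else NA_real_,
    mean_RR = mean_rr,
    HR = if (!is.na(mean_rr) && mean_rr > 0) 60000 / mean_rr else NA_real_,
    n_beats = n)
  class(res) <- "hrv_result"
  res
}

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic Lomb normalisation with the time-offset tau per frequency.
#' Used for interval-series spectra where beat removal makes the sampling
#' uneven; no resampling or interpolation is involved.
#'
#' @param t sample times (seconds).
#' @param x sample values (mean is subtracted).
#' @param freq frequencies to evaluate (Hz), all > 0.
#' @return numeric vector of raw Lomb powers at `freq`.
#' @keywords internal
lomb_power <- function(t, x, freq, chunk = 500L) {
  xc <- x - mean(x)
  out <- numeric(length(freq))
  for (j0 in seq(1L, length(freq), by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, length(freq))
    W <- outer(t, 2 * pi * freq[jj])          # n x m phase matrix
    CW <- cos(W); SW <- sin(W)
    # double-angle sums reused for both tau and the denominators
    c2 <- colSums(2 * CW * CW - 1)
    s2 <- colSums(2 * SW * CW)
    theta <- atan2(s2, c2) / 2                # omega * tau per frequency
    ct <- cos(theta); st <- sin(theta)
    A <- drop(crossprod(xc, CW))              # sum xc cos(W), sin(W)
    B <- drop(crossprod(xc, SW))
    num_c <- A * ct + B * st                  # sum xc cos(W - theta)
    num_s <- B * ct - A * st
    n <- length(t)
    # sum cos^2(W - theta) = n/2 + (c2 cos 2theta + s2 sin 2theta)/2
    cross <- (c2 * cos(2 * theta) + s2 * sin(2 * theta)) / 2
    den_c <- n / 2 + cross
    den_s <- n / 2 - cross
    out[jj] <- 0.5 * (num_c^2 / den_c + num_s^2 / den_s)
  }
  out
}

#' Default rodent spectral bands (Hz)
#'
#' LF 0.20-0.75 Hz, HF 0.75-2.50 Hz; override per analysis.
#' @export
rat_bands <- function() list(lf = c(0.20, 0.75), hf = c(0.75, 2.50))

#' Frequency-domain heart rate variability for one segment
#'
#' Band powers of the interval series in low- and high-frequency bands,
#' expressed in ms^2. The default estimator is a Lomb-Scargle periodogram
#' evaluated at interval midpoint times, robust to ectopic removals; a
#' cubic-interpolation + FFT periodogram is available via
#' `method = "interp"`. Band power is the fraction of periodogram mass in
#' the band times the series variance, so LF + HF can never exceed the
#' total interval variance.
#'
#' @param nn an `nn_series` (with removal bookkeeping) or numeric intervals
#'   (ms).
#' @param bands list with `lf` and `hf` two-element ranges in Hz
#'   (default [rat_bands()]).
#' @param method `"lomb"` (default) or `"interp"`.
#' @param times optional interval start times (ms); reconstructed by
#'   cumulative summation when absent.
#' @param removal_warn_frac flag the result low-confidence when more than
#'   this fraction of intervals was removed upstream (default 0.20).
#' @param oversample frequency-grid oversampling factor.
#' @return list of class `hrv_result` with LF, HF (ms^2), LF_HF (NA when
#'   HF == 0), `low_confidence` flag, and `n_beats`.
#' @export
frequency_domain <- function(nn, bands = rat_bands(), method = c("lomb", "interp"),
                             times = NULL, removal_warn_frac = 0.20,
                             oversample = 4) {
  method <- match.arg(method)
  removed_frac <- 0
  if (inherits(nn, "nn_series")) {
    total <- length(nn$intervals) + nn$n_removed
    removed_frac <- if (total > 0) nn$n_removed / total else 0
    x <- nn$intervals
  } else x <- as.numeric(nn)
  n <- length(x)
  out <- list(LF = NA_real_, HF = NA_real_, LF_HF = NA_real_,
              low_confidence = removed_frac > removal_warn_frac,
              n_beats = n)
  class(out) <- "hrv_result"
  if (n < 4L) return(out)
  if (is.null(times)) times <- cumsum(c(0, x[-n]))
  tmid <- (times + x / 2) / 1000           # interval midpoints, seconds
  span <- max(tmid) - min(tmid)
  if (span < 100) {                         # need >= 100 s of usable data
    return(out)
  }
  v <- stats::var(x)
  if (v == 0) { out$LF <- 0; out$HF <- 0; return(out) }
  f_ny <- n / (2 * span)                    # mean-rate pseudo-Nyquist
  f_max <- min(max(unlist(bands)), f_ny)
  df <- 1 / (oversample * span)
  freq <- seq(df, f_max, by = df)
  if (method == "lomb") {
    p <- lomb_power(tmid, x, freq)
  } else {
    grid_dt <- 1 / (4 * f_max)
    tg <- seq(min(tmid), max(tmid), by = grid_dt)
    xg <- stats::spline(tmid, x, xout = tg)$y
    xg <- xg - mean(xg)
    sp <- Mod(stats::fft(xg))^2 / length(xg)
    fg <- (seq_along(xg) - 1) / (length(xg) * grid_dt)
    keep <- fg > 0 & fg <= f_max
    freq <- fg[keep]; p <- sp[keep]
  }
  tot <- sum(p)
  in_band <- function(b) freq >= b[1] & freq < b[2]
  out$LF <- v * sum(p[in_band(bands$lf)]) / tot
  out$HF <- v * sum(p[in_band(bands$hf)]) / tot
  out$LF_HF <- if (out$HF > 0) out$LF / out$HF else NA_real_
  out
}

#' Full HRV panel for one analysis segment
#'
#' Convenience wrapper: interval extraction, ectopic filtering, then time-
#' and frequency-domain metrics.
#'
#' @param beats a `beat_series` for one 5-min segment.
#' @param source interval source passed to [beat_intervals()].
#' @param bands,method passed to [frequency_domain()].
#' @return one-row data.frame of HRV metrics plus filtering bookkeeping.
#' @export
hrv_segment <- function(beats, source = "auto", bands = rat_bands(),
                        method = "lomb") {
  iv <- beat_intervals(beats, source = source)
  nn <- filter_ectopic(iv$intervals, source = iv$source)
  keep <- if (length(nn$removed_idx)) -nn$removed_idx else TRUE
  td <- time_domain(nn)
  fd <- frequency_domain(nn, bands = bands, method = method,
                         times = iv$times[keep])
  data.frame(segment_id = beats$segment_id[1L],
             animal_id = beats$animal_id[1L],
             day_label = beats$day_label[1L],
             source = iv$source,
             n_beats = td$n_beats, n_removed = nn$n_removed,
             RMSSD = td$RMSSD, SDNN = td$SDNN, CV = td$CV, pNN15 = td$pNN15,
             mean_RR = td$mean_RR, HR = td$HR,
             LF = fd$LF, HF = fd$HF, LF_HF = fd$LF_HF,
             low_confidence = fd$low_confidence,
             stringsAsFactors = FALSE)
}
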