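#' Construct a waveform chunk
#'
#' Uniformly sampled raw-signal excerpt (ECG, arterial pressure, or
#' respiratory flow) referenced by beat-level feature extractors.
#'
#' @param channel `"ecg"`, `"pressure"` or `"flow"`.
#' @param t0 time of first sample, ms from recording start.
#' @param dt sampling interval, ms (> 0).
#' @param samples numeric vector (mV, mmHg or mL/s), length >= 2.
#' @return list of class `waveform_chunk`.
#' @export
waveform_chunk <- function(channel = c("ecg", "pressure", "flow"),
                           t0, dt, samples) {
  channel <- match.arg(channel)
  stopifnot(dt > 0, length(samples) >= 2L)
  structure(list(channel = channel, t0 = t0, dt = dt,
                 samples = as.numeric(samples)),
            class = "waveform_chunk")
}

chunk_times <- function(chunk) chunk$t0 + (seq_along(chunk$samples) - 1L) * chunk$dt

#' Rate-correct a QT interval
#'
#' Fridericia: `QT / (RR/RR_ref)^(1/3)`; Bazett: `QT / (RR/RR_ref)^(1/2)`.
#' Both return QT unchanged at `RR == RR_ref`. The reference interval
#' normalizes RR so the formulas apply at rodent rates; default 150 ms.
#'
#' @param QT QT interval, ms (> 0).
#' @param RR inter-beat interval, ms (> 0).
#' @param formula `"fridericia"` (default) or `"bazett"`.
#' @param RR_ref normalization interval, ms.
#' @return corrected QT, ms.
#' @export
qt_correct <- function(QT, RR, formula = c("fridericia", "bazett"),
                       RR_ref = 150) {
  formula <- match.arg(formula)
  if (any(QT <= 0, na.rm = TRUE) || any(RR <= 0, na.rm = TRUE) || RR_ref <= 0)
    stop("QT, RR and RR_ref must be positive", call. = FALSE)
  expo <- if (formula == "fridericia") 1 / 3 else 1 / 2
  QT / (RR / RR_ref)^expo
}

#' ST-segment metrics after the S fiducial
#'
#' `S_min_slope` is the minimum first-difference slope within the first
#' 1.5 ms after S; `ST_amp` is the mean amplitude 2-4 ms after S.
#' Requires sampling at 0.5 ms or finer. Derivatives use adjacent-sample
#' first differences with no smoothing so analytic templates are matched
#' exactly.
#'
#' @param ecg_chunk `waveform_chunk` (channel "ecg").
#' @param t_S S fiducial time, ms.
#' @param slope_win_ms slope window length after S (default 1.5).
#' @param amp_win_ms two-element amplitude window after S (default c(2, 4)).
#' @return list with `S_min_slope` (mV/ms) and `ST_amp` (mV); both `NA`
#'   with a `missing_reason` when the window leaves the chunk.
#' @export
st_metrics <- function(ecg_chunk, t_S, slope_win_ms = 1.5,
                       amp_win_ms = c(2, 4)) {
  if (ecg_chunk$dt > 0.5)
    stop("ST metrics require sampling interval <= 0.5 ms", call. = FALSE)
  tt <- chunk_times(ecg_chunk)
  x <- ecg_chunk$samples
  if (t_S < tt[1L] || t_S + max(amp_win_ms) > tt[length(tt)])
    return(list(S_min_slope = NA_real_, ST_amp = NA_real_,
                missing_reason = "window exceeds chunk"))
  slopes <- diff(x) / ecg_chunk$dt
  mid <- tt[-length(tt)] + ecg_chunk$dt / 2
  in_slope <- mid > t_S & mid <= t_S + slope_win_ms
  in_amp <- tt >= t_S + amp_win_ms[1L] & tt <= t_S + amp_win_ms[2L]
  list(S_min_slope = if (any(in_slope)) min(slopes[in_slope]) else NA_real_,
       ST_amp = if (any(in_amp)) mean(x[in_amp]) else NA_real_,
       missing_reason = NA_character_)
}

#' Maximum rate of arterial pressure rise for one beat
#'
#' dP/dt max over the systolic upstroke, by central differences at native
#' sampling (no smoothing). An indirect index of left-ventricular
#' contractility.
#'
#' @param pressure_chunk `waveform_chunk` (channel "pressure").
#' @param window optional `c(start, end)` ms restricting the search to one
#'   beat; default uses the whole chunk.
#' @return dP/dt max in mmHg/s, or `NA` when no upstroke (positive slope)
#'   exists in the window.
#' @export
dpdt_max <- function(pressure_chunk, window = NULL) {
  tt <- chunk_times(pressure_chunk)
  x <- pressure_chunk$samples
  n <- length(x)
  d <- c(x[2L] - x[1L], (x[3:n] - x[1:(n - 2L)]) / 2, x[n] - x[n - 1L]) /
    pressure_chunk$dt
  keep <- rep(TRUE, n)
  if (!is.null(window)) keep <- tt >= window[1L] & tt <= window[2L]
  if (!any(keep)) return(NA_real_)
  dmax <- max(d[keep])
  if (dmax <= 0) return(NA_real_)       # no upstroke in window
  dmax * 1000                            # mmHg/ms -> mmHg/s
}

#' Segment-mean hemodynamics
#'
#' Per-segment means of systolic and diastolic pressure, pulse pressure
#' (SBP - DBP), heart rate, and the rate-pressure product
#' HR x SBP / 1000 (workload index).
#'
#' @param beats a `beat_series` with SBP/DBP annotations.
#' @return list of class `hemodynamics_result`: SBP, DBP, PP (mmHg),
#'   HR (beats/min), rate_pressure (beats/min x mmHg / 1000).
#' @export
hemodynamics <- function(beats) {
  sbp <- mean(beats$SBP, na.rm = TRUE)
  dbp <- mean(beats$DBP, na.rm = TRUE)
  iv <- beat_intervals(beats)
  hr <- if (length(iv$intervals)) 60000 / mean(iv$intervals) else NA_real_
  structure(list(SBP = sbp, DBP = dbp,
                 PP = sbp - dbp, HR = hr,
                 rate_pressure = hr * sbp / 1000), class = "hemodynamics_result")
}

#' Segment-mean ECG morphology
#'
#' PR = t_R - t_P; QTe = t_Tend - t_R (QRS reference to T end);
#' TpTe = t_Tend - t_Tpeak; QTc by Fridericia (`QTcF`) and Bazett
#' (`QTcB`) against the segment's mean RR.
#'
#' @param beats a `beat_series`.
#' @param RR_ref rate-correction reference interval, ms (default 150).
#' @return list of class `morphology_result` with PR, QTe, QTcF, QTcB,
#'   TpTe (ms).
#' @export
morphology <- function(beats, RR_ref = 150) {
  cond <- beats$conducted %in% TRUE
  pr <- mean(beats$t_R[cond] - beats$t_P[cond], na.rm = TRUE)
  qte <- mean(beats$t_Tend[cond] - beats$t_R[cond], na.rm = TRUE)
  tpte <- mean(beats$t_Tend[cond] - beats$t_Tpeak[cond], na.rm = TRUE)
  iv <- beat_intervals(beats)
  rr <- if (length(iv$intervals)) mean(iv$intervals) else NA_real_
  qtcf <- if (!is.na(qte) && !is.na(rr)) qt_correct(qte, rr, "fridericia", RR_ref)
          else NA_real_
  qtcb <- if (!is.na(qte) && !is.na(rr)) qt_correct(qte, rr, "bazett", RR_ref)
          else NA_real_
  structure(list(PR = pr, QTe = qte, QTcF = qtcf, QTcB = qtcb, TpTe = tpte),
            class = "morphology_result")
}
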