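#' Beat-annotation table column contract
#'
#' Canonical on-disk form for beat annotations: a flat CSV with one row per
#' beat (or per non-conducted P wave). All times are milliseconds from
#' recording start; empty cells are missing values, never zero.
#'
#' @format Character vector of mandatory column names.
#' @keywords internal
BEAT_COLUMNS <- c("animal_id", "group", "day_label", "segment_id",
                  "t_P", "t_R", "t_S", "t_Tpeak", "t_Tend",
                  "conducted", "SBP", "DBP")

#' Construct a validated beat series
#'
#' A beat series is one animal-recording's time-ordered beat annotations:
#' per-beat ECG fiducials (P onset, QRS reference R, QRS end S, T peak,
#' T end), a conducted flag (P followed by a QRS), and per-beat arterial
#' pressures. Rows with `conducted = FALSE` represent non-conducted P waves
#' and carry only `t_P` (QRS fiducials missing).
#'
#' @param df data.frame with the columns of [BEAT_COLUMNS]. Missing optional
#'   annotations are `NA`; `t_P` may be absent entirely in pulse-interval
#'   mode (set `pulse_mode = TRUE`).
#' @param pulse_mode logical; if `TRUE`, ECG fiducials may be absent and
#'   inter-beat intervals are derived from systolic-peak times.
#' @param validate logical; run integrity checks (default `TRUE`).
#' @return `df` with class `beat_series` and attribute `source` set to
#'   `"ecg"` or `"pulse"`.
#' @export
beat_series <- function(df, pulse_mode = FALSE, validate = TRUE) {
  stopifnot(is.data.frame(df))
  for (col in BEAT_COLUMNS) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  keep_cols <- c(BEAT_COLUMNS, intersect("t_pulse", names(df)))
  df <- df[, keep_cols]
  if (is.null(df$conducted) || all(is.na(df$conducted))) {
    df$conducted <- !is.na(df$t_R)
  }
  df$conducted <- as.logical(df$conducted)
  if (validate) validate_beat_series(df, pulse_mode = pulse_mode)
  structure(df,
            class = c("beat_series", "data.frame"),
            source = if (pulse_mode) "pulse" else "ecg")
}

#' Integrity checks for a beat series
#'
#' Enforces: t_R strictly increasing within each animal/segment; for
#' conducted beats t_P < t_R < t_S <= t_Tpeak <= t_Tend (where annotated);
#' SBP > DBP when both present. The first offending row is named in the
#' error message.
#'
#' @param df beat-table data.frame.
#' @param pulse_mode logical; in pulse mode a missing t_R column is only an
#'   error when SBP is also absent.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_beat_series <- function(df, pulse_mode = FALSE) {
  if (all(is.na(df$t_R))) {
    if (!pulse_mode)
      stop("beat table has no t_R annotations; set pulse_mode for ",
           "pressure-only input", call. = FALSE)
    if (all(is.na(df$SBP)))
      stop("pulse mode requires SBP annotations", call. = FALSE)
    return(invisible(TRUE))
  }
  key <- paste(df$animal_id, df$segment_id, sep = "\r")
  for (k in unique(key)) {
    tr <- df$t_R[key == k]
    tr <- tr[!is.na(tr)]
    if (length(tr) > 1L) {
      bad <- which(diff(tr) <= 0)
      if (length(bad))
        stop(sprintf("t_R not strictly increasing at beat row %d (segment %s)",
                     bad[1L] + 1L, strsplit(k, "\r")[[1]][2]), call. = FALSE)
    }
  }
  cond <- which(df$conducted %in% TRUE)
  chk <- function(a, b, lab, strict = TRUE) {
    i <- cond[!is.na(df[[a]][cond]) & !is.na(df[[b]][cond])]
    viol <- if (strict) df[[a]][i] >= df[[b]][i] else df[[a]][i] > df[[b]][i]
    if (any(viol))
      stop(sprintf("fiducial order violated (%s) at beat row %d",
                   lab, i[which(viol)[1L]]), call. = FALSE)
  }
  chk("t_P", "t_R", "t_P < t_R")
  chk("t_R", "t_S", "t_R < t_S")
  chk("t_S", "t_Tpeak", "t_S <= t_Tpeak", strict = FALSE)
  chk("t_Tpeak", "t_Tend", "t_Tpeak <= t_Tend", strict = FALSE)
  bp <- which(!is.na(df$SBP) & !is.na(df$DBP))
  if (length(bp) && any(df$SBP[bp] <= df$DBP[bp]))
    stop(sprintf("SBP <= DBP at beat row %d",
                 bp[which(df$SBP[bp] <= df$DBP[bp])[1L]]), call. = FALSE)
  invisible(TRUE)
}

#' Read a beat-annotation CSV
#'
#' @param path path to a beats.csv file (columns per [BEAT_COLUMNS]; empty
#'   cell = missing).
#' @param pulse_mode logical; accept files without ECG fiducial columns and
#'   derive intervals from systolic-peak times.
#' @return a named list of `beat_series`, one per animal x segment, in file
#'   order.
#' @export
read_beat_table <- function(path, pulse_mode = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "day_label", "segment_id")
  need <- c(need, if (pulse_mode) "SBP" else "t_R")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("beat table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("t_P", "t_R", "t_S", "t_Tpeak", "t_Tend", "SBP", "DBP",
                "t_pulse")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  key <- paste(df$animal_id, df$segment_id, sep = "\r")
  out <- lapply(split(df, factor(key, levels = unique(key))),
                beat_series, pulse_mode = pulse_mode)
  names(out) <- vapply(out, function(b)
    paste(b$animal_id[1L], b$segment_id[1L], sep = ":"), character(1))
  out
}

#' Write a beat series (or list of them) back to CSV
#'
#' Round-trips [read_beat_table()]: columns and values are reproduced
#' field-for-field, missing values as empty cells.
#'
#' @param beats a `beat_series` or list of them.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_beat_table <- function(beats, path) {
  if (inherits(beats, "beat_series")) beats <- list(beats)
  df <- do.call(rbind, lapply(beats, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a breath-segmentation CSV
#'
#' Columns: animal_id, day_label, t_start, t_insp_end, t_end (ms), pause (s).
#' Enforces t_start < t_insp_end < t_end per breath and non-overlapping
#' consecutive breaths within an animal-day.
#'
#' @param path path to breaths.csv.
#' @return data.frame of breaths with derived `T_I`, `T_E`, `T_T` (ms).
#' @export
read_breath_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "day_label", "t_start", "t_insp_end", "t_end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("breath table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"pause" %in% names(df)) df$pause <- NA_real_
  validate_breaths(df)
  df$T_I <- df$t_insp_end - df$t_start
  df$T_E <- df$t_end - df$t_insp_end
  df$T_T <- df$T_I + df$T_E
  df
}

validate_breaths <- function(df) {
  bad <- which(!(df$t_start < df$t_insp_end & df$t_insp_end < df$t_end))
  if (length(bad))
    stop("breath timing violated (need t_start < t_insp_end < t_end) at row ",
         bad[1L], call. = FALSE)
  key <- paste(df$animal_id, df$day_label, sep = "\r")
  for (k in unique(key)) {
    d <- df[key == k, ]
    d <- d[order(d$t_start), ]
    if (nrow(d) > 1L && any(d$t_start[-1L] < d$t_end[-nrow(d)] - 1e-6))
      stop("overlapping breaths within animal-day ", sub("\r", "/", k),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Split a beat series into fixed-width analysis windows
#'
#' Windows are half-open `[start, start + width)` from the first beat time,
#' contiguous within the recording. ECG/BP endpoints use 5-min windows,
#' respiratory endpoints 10-min. A trailing partial window is flagged
#' (`partial = TRUE`) and excluded from HRV by default downstream.
#'
#' @param beats a `beat_series`.
#' @param window_kind `"ecg_5min"` or `"resp_10min"` (sets the width), or a
#'   numeric width in ms.
#' @param min_beats minimum beat count for a window to be usable; windows
#'   below it are flagged partial. Recording dropouts are thereby excluded
#'   rather than silently averaged.
#' @return list with elements `index` (data.frame: segment_id, animal_id,
#'   day_label, start, end, n_beats, partial) and `segments` (list of
#'   `beat_series`, one per window).
#' @export
segment_windows <- function(beats, window_kind = "ecg_5min", min_beats = 0L) {
  width <- if (is.numeric(window_kind)) window_kind
           else switch(window_kind,
                       ecg_5min  = 5 * 60 * 1000,
                       resp_10min = 10 * 60 * 1000,
                       stop("unknown window_kind: ", window_kind))
  t <- beats$t_R
  if (all(is.na(t))) t <- beats$t_P
  if (!nrow(beats) || all(is.na(t)))
    return(list(index = empty_segment_index(), segments = list()))
  t0 <- min(t, na.rm = TRUE)
  span <- max(t, na.rm = TRUE) - t0
  n_win <- max(1L, ceiling((span + 1) / width))
  idx <- floor((t - t0) / width)
  rows <- lapply(seq_len(n_win) - 1L, function(w) which(idx == w))
  starts <- t0 + (seq_len(n_win) - 1L) * width
  # a window is partial only when the recording leaves a material gap at
  # its end: more than two typical beats or 0.5% of the window width
  med_iv <- stats::median(diff(sort(t[!is.na(t)])))
  if (!length(med_iv) || is.na(med_iv)) med_iv <- 0
  full_tol <- max(2 * med_iv, 0.005 * width)
  full <- starts + width <= t0 + span + full_tol + 1
  index <- data.frame(
    segment_id = sprintf("%s_w%03d", beats$segment_id[1L], seq_len(n_win)),
    animal_id = beats$animal_id[1L],
    day_label = beats$day_label[1L],
    start = starts, end = starts + width,
    n_beats = vapply(rows, length, integer(1)),
    partial = !full,
    stringsAsFactors = FALSE)
  index$partial <- index$partial | index$n_beats < min_beats
  segments <- lapply(seq_len(n_win), function(w) {
    s <- beats[rows[[w]], , drop = FALSE]
    s$segment_id <- index$segment_id[w]
    beat_series(as.data.frame(s), validate = FALSE,
                pulse_mode = attr(beats, "source") == "pulse")
  })
  list(index = index, segments = segments)
}

empty_segment_index <- function() {
  data.frame(segment_id = character(), animal_id = character(),
             day_label = character(), start = numeric(), end = numeric(),
             n_beats = integer(), partial = logical(),
             stringsAsFactors = FALSE)
}

#' Inter-beat intervals from a beat series
#'
#' In ECG mode intervals are successive differences of `t_R` over conducted
#' beats; in pulse mode, successive differences of systolic-peak times
#' (here, beat times carried in `t_R` absent ECG fiducials are not available,
#' so pulse mode uses the row order of SBP-bearing beats with `t_pulse`
#' column if present, else `t_R`).
#'
#' @param beats a `beat_series`.
#' @param source `"auto"`, `"ecg"` or `"pulse"`.
#' @return list with `intervals` (ms), `times` (ms, time of interval start),
#'   `source`.
#' @export
beat_intervals <- function(beats, source = "auto") {
  if (source == "auto")
    source <- if (!all(is.na(beats$t_R))) attr(beats, "source") %||% "ecg"
              else "pulse"
  if (source == "pulse") {
    tt <- if ("t_pulse" %in% names(beats)) beats$t_pulse else beats$t_R
    keep <- !is.na(tt) & !is.na(beats$SBP)
  } else {
    tt <- beats$t_R
    keep <- !is.na(tt) & beats$conducted %in% TRUE
  }
  tt <- tt[keep]
  list(intervals = diff(tt), times = tt[-length(tt)], source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a waveform CSV (t, value)
#'
#' Input adapter for raw-signal excerpts exported as two-column CSV with
#' uniform sampling; `t` in ms.
#'
#' @param path CSV path with columns `t` and `value`.
#' @param channel `"ecg"`, `"pressure"` or `"flow"`.
#' @return a `waveform_chunk`.
#' @export
read_waveform_csv <- function(path, channel = "ecg") {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "value") %in% names(df)), nrow(df) >= 2L)
  dt <- diff(df$t)
  if (diff(range(dt)) > 1e-6 * stats::median(dt))
    stop("waveform sampling is not uniform", call. = FALSE)
  waveform_chunk(channel, t0 = df$t[1L], dt = stats::median(dt),
                 samples = df$value)
}
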