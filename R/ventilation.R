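#' Window and daily summaries of respiratory timing
#'
#' Breath-by-breath inspiratory (T_I), expiratory (T_E) and total (T_T)
#' times are averaged over continuous 10-min windows; window means are then
#' averaged into daily values per animal. Respiratory frequency is
#' f = 60000 / mean(T_T) breaths/min. End-expiratory pause is averaged as
#' ingested (plethysmograph-defined, seconds). Windows with fewer than
#' `min_breaths` breaths are dropped; days with no usable windows are
#' missing, not zero.
#'
#' @param breaths data.frame from [read_breath_table()] (or with columns
#'   animal_id, day_label, t_start, T_I, T_E, T_T, pause).
#' @param window_ms averaging window width (default 10 min).
#' @param min_breaths minimum breaths per usable window (default 10).
#' @return list with `windows` (per-window means) and `daily` (per
#'   animal-day means of window means: T_I, T_E, T_T ms, f breaths/min,
#'   pause s, n_windows).
#' @export
summarize_breaths <- function(breaths, window_ms = 10 * 60 * 1000,
                              min_breaths = 10L) {
  if (!nrow(breaths))
    return(list(windows = data.frame(), daily = data.frame()))
  validate_breaths(breaths)
  if (!all(c("T_I", "T_E", "T_T") %in% names(breaths))) {
    breaths$T_I <- breaths$t_insp_end - breaths$t_start
    breaths$T_E <- breaths$t_end - breaths$t_insp_end
    breaths$T_T <- breaths$T_I + breaths$T_E
  }
  key <- interaction(breaths$animal_id, breaths$day_label, drop = TRUE)
  win_list <- lapply(split(breaths, key), function(d) {
    d <- d[order(d$t_start), ]
    w <- floor((d$t_start - min(d$t_start)) / window_ms)
    agg <- lapply(split(d, w), function(dw) {
      if (nrow(dw) < min_breaths) return(NULL)
      data.frame(animal_id = dw$animal_id[1L], day_label = dw$day_label[1L],
                 window = floor((dw$t_start[1L] - min(d$t_start)) / window_ms),
                 T_I = mean(dw$T_I), T_E = mean(dw$T_E), T_T = mean(dw$T_T),
                 f = 60000 / mean(dw$T_T),
                 pause = mean(dw$pause, na.rm = TRUE),
                 n_breaths = nrow(dw), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  windows <- do.call(rbind, win_list)
  rownames(windows) <- NULL
  if (is.null(windows) || !nrow(windows))
    return(list(windows = data.frame(), daily = data.frame()))
  dkey <- interaction(windows$animal_id, windows$day_label, drop = TRUE)
  daily <- do.call(rbind, lapply(split(windows, dkey), function(d) {
    data.frame(animal_id = d$animal_id[1L], day_label = d$day_label[1L],
               T_I = mean(d$T_I), T_E = mean(d$T_E), T_T = mean(d$T_T),
               f = mean(d$f), pause = mean(d$pause),
               n_windows = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(daily) <- NULL
  list(windows = windows, daily = daily)
}

#' Classify the ventilatory pattern immediately before an event
#'
#' Screens the `lookback_ms` window (default 3 s) before an arrhythmia for
#' ventilatory rhythm disturbances, against the day's own breathing:
#' \itemize{
#'   \item apnea — at least `apnea_breaths` (default 2) missed expected
#'     breaths: an onset-free gap of at least `(apnea_breaths + 1)` times
#'     the day's median T_T;
#'   \item braking — any expiratory time at least `braking_mult` (default
#'     2) times the day's median T_E;
#'   \item tachypnea — any instantaneous frequency at least
#'     `tachypnea_mult` (default 1.5) times the day's median f, i.e.
#'     T_T <= median T_T / 1.5;
#'   \item none — undisturbed rhythm.
#' }
#' Checked in that priority order; the thresholds are explicit
#' configuration, not established convention.
#'
#' @param breaths one animal-day of breaths (with T_I/T_E/T_T).
#' @param event_time event time, ms.
#' @param lookback_ms screen window before the event (default 3000).
#' @param apnea_breaths,braking_mult,tachypnea_mult thresholds as above.
#' @return character label: "apnea", "braking", "tachypnea", "none", or
#'   "unscreened" when breaths do not cover the lookback window.
#' @export
pre_event_screen <- function(breaths, event_time, lookback_ms = 3000,
                             apnea_breaths = 2, braking_mult = 2,
                             tachypnea_mult = 1.5) {
  if (!nrow(breaths)) return("unscreened")
  b <- breaths[order(breaths$t_start), ]
  win0 <- event_time - lookback_ms
  if (min(b$t_start) > win0 || max(b$t_end) < event_time) return("unscreened")
  med_tt <- stats::median(b$T_T)
  med_te <- stats::median(b$T_E)
  inwin <- b[b$t_end > win0 & b$t_start < event_time, , drop = FALSE]
  # apnea: longest onset-free span; a gap of g holds floor(g/T_T) - 1
  # missed onsets, so >= 2 missed breaths means g >= 3 median T_T
  onsets <- sort(c(win0, inwin$t_start[inwin$t_start >= win0], event_time))
  if (max(diff(onsets)) >= (apnea_breaths + 1) * med_tt) return("apnea")
  if (nrow(inwin) && any(inwin$T_E >= braking_mult * med_te)) return("braking")
  if (nrow(inwin) && any(inwin$T_T <= med_tt / tachypnea_mult))
    return("tachypnea")
  "none"
}

#' Screen many events and tabulate disturbance proportions by group
#'
#' @param breaths breath table covering the events' animal-days.
#' @param events data.frame with animal_id, day_label, event_time (ms) and
#'   optionally group.
#' @param ... passed to [pre_event_screen()].
#' @return `events` with a `screen` column; attribute `proportions` gives
#'   per-group fractions of each label among screened events (the fraction
#'   labelled "none" is the undisturbed-rhythm proportion).
#' @export
screen_events <- function(breaths, events, ...) {
  events$screen <- vapply(seq_len(nrow(events)), function(k) {
    b <- breaths[breaths$animal_id == events$animal_id[k] &
                 breaths$day_label == events$day_label[k], , drop = FALSE]
    pre_event_screen(b, events$event_time[k], ...)
  }, character(1))
  grp <- if ("group" %in% names(events)) events$group else "all"
  screened <- events$screen != "unscreened"
  props <- if (any(screened))
    prop.table(table(group = grp[screened], screen = events$screen[screened]),
               margin = 1)
  else NULL
  attr(events, "proportions") <- props
  events
}
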