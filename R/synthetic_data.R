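#' Synthetic-study configuration
#'
#' The stated world for the generator: a two-group inhalation study
#' (filtered-air control "FA" vs particulate-exposed "PSOA"), 6 animals
#' per group, a baseline day plus 12 exposure days. Beat dynamics follow
#' a baroreflex-coupled model: systolic pressure carries a slow
#' Mayer-band oscillation (0.1 Hz) and a respiratory oscillation (1.5 Hz)
#' plus noise, and each beat's following interval responds to the
#' systolic fluctuation with gain `G` (ms/mmHg) when the reflex is
#' engaged (Bernoulli flag), plus respiratory sinus arrhythmia and noise.
#'
#' Defaults take the study's measured baseline physiology as the stated
#' world: mean RR 180 ms (HR ~333 beats/min), SBP 135 / DBP 87 mmHg
#' (pulse amplitude 48), baroreflex gain 1.65 ms/mmHg, PR 45 ms, QT-end
#' 60 ms. The slow-oscillation amplitude (6 mmHg) is chosen so
#' spontaneous ramps exceed the 0.50-mmHg sequence threshold at this
#' heart rate; noise SDs of 1 ms / 1 mmHg represent clean telemetry.
#'
#' @param seed integer RNG seed.
#' @param n_per_group animals per exposure group.
#' @param n_days exposure days after baseline.
#' @param segments_per_day 5-min ECG/BP segments generated per animal-day
#'   (a scaled-down stand-in for the 5-h exposure window; 60 would
#'   reproduce the full day).
#' @param RR0,SBP0,pulse_amp,PR0,s_off,tpeak_off,tend_off beat geometry
#'   (ms / mmHg): mean interval, mean systolic pressure, SBP-DBP pulse
#'   amplitude, PR interval, and S / T-peak / T-end offsets from R.
#' @param G baroreflex gain, ms/mmHg.
#' @param coupling_prob per-beat probability the reflex is engaged.
#' @param A_slow,f_slow,A_resp,f_resp SBP oscillation amplitudes (mmHg)
#'   and frequencies (Hz).
#' @param A_rsa respiratory sinus arrhythmia amplitude in the interval
#'   series, ms.
#' @param sd_sbp,sd_rr,sd_pr additive noise SDs (mmHg, ms, ms).
#' @param T_I0,T_E0 mean inspiratory/expiratory times, ms; `sd_breath`
#'   their per-breath SD; `pause0` mean end-expiratory pause, s.
#' @param pulse_period_ms half-sine pressure-pulse duration (upstroke
#'   family for dP/dt truth); `st_amp_mV` flat ST-segment amplitude;
#'   `wave_dt_ms` waveform sampling interval.
#' @param effects injected group effects used by study-level scenarios:
#'   exposed-group deltas for generator parameters after baseline
#'   (`G_delta`, `A_rsa_delta`, `T_E_delta_ms`) and the day-4 Mobitz II
#'   rate pair (`mobitz2_day4` = c(control, exposed) events/day).
#' @param disturbance_coupling fraction of arrhythmia events preceded by
#'   a ventilatory disturbance in generated breath data.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_per_group = 6L, n_days = 12L,
                         segments_per_day = 3L,
                         RR0 = 180, SBP0 = 135, pulse_amp = 48,
                         PR0 = 45, s_off = 15, tpeak_off = 45, tend_off = 60,
                         G = 1.65, coupling_prob = 1.0,
                         A_slow = 6, f_slow = 0.1,
                         A_resp = 1.5, f_resp = 1.5, A_rsa = 1.5,
                         sd_sbp = 1.0, sd_rr = 1.0, sd_pr = 1.0,
                         T_I0 = 200, T_E0 = 200, sd_breath = 15, pause0 = 0.02,
                         pulse_period_ms = 40, st_amp_mV = 0.05,
                         wave_dt_ms = 0.25,
                         effects = list(G_delta = -0.3, A_rsa_delta = -0.5,
                                        T_E_delta_ms = -33.2,
                                        mobitz2_day4 = c(2, 8)),
                         disturbance_coupling = 0.64) {
  if (tend_off >= RR0 - 6 * sd_rr)
    stop("infeasible timing: QT-end offset must be well below mean RR",
         call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

#' Generate one beat-annotated segment with known truth
#'
#' Simulates `n_beats` beats under the baroreflex-coupled model of
#' [synth_config()], then rewrites local fiducial patterns to inject the
#' requested arrhythmia events so each exactly satisfies its
#' classification rule (well clear of every threshold). Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param config a `synth_config`.
#' @param n_beats number of conducted beats before injection.
#' @param animal_id,group,day_label,segment_id metadata stamped on rows.
#' @param inject named integer vector of event counts, e.g.
#'   `c(APB = 2, MobitzII = 1)`; supported names APB, ncAPB, MobitzI,
#'   MobitzII, AdvancedAVB.
#' @param t0 recording-time offset of the first beat, ms.
#' @param G override of the config gain (for effect scenarios).
#' @return list with `beats` (a `beat_series`) and `truth` (data.frame of
#'   injected events: type, beat row, interval index of any shortened
#'   interval, event time).
#' @export
generate_beats <- function(config, n_beats = 1000, animal_id = "A01",
                           group = "FA", day_label = "baseline",
                           segment_id = "seg1", inject = integer(0),
                           t0 = 0, G = NULL) {
  cfg <- config
  if (!is.null(G)) cfg$G <- G
  n <- n_beats
  tau <- (seq_len(n) - 1L) * cfg$RR0 / 1000          # nominal beat times, s
  sbp_fluct <- cfg$A_slow * sin(2 * pi * cfg$f_slow * tau) +
    cfg$A_resp * sin(2 * pi * cfg$f_resp * tau) +
    stats::rnorm(n, 0, cfg$sd_sbp)
  coupled <- stats::rbinom(n, 1L, cfg$coupling_prob)
  rsa <- cfg$A_rsa * sin(2 * pi * cfg$f_resp * tau + pi / 2)
  intervals <- cfg$RR0 + cfg$G * sbp_fluct * coupled + rsa +
    stats::rnorm(n, 0, cfg$sd_rr)
  intervals <- intervals[-n]
  if (any(intervals <= cfg$tend_off))
    stop("infeasible timing: generated interval <= QT end", call. = FALSE)
  t_R <- t0 + cumsum(c(0, intervals))
  pr <- cfg$PR0 + stats::rnorm(n, 0, cfg$sd_pr)
  df <- data.frame(
    animal_id = animal_id, group = group, day_label = day_label,
    segment_id = segment_id,
    t_P = t_R - pr, t_R = t_R, t_S = t_R + cfg$s_off,
    t_Tpeak = t_R + cfg$tpeak_off, t_Tend = t_R + cfg$tend_off,
    conducted = TRUE,
    SBP = cfg$SBP0 + sbp_fluct, DBP = cfg$SBP0 + sbp_fluct - cfg$pulse_amp,
    stringsAsFactors = FALSE)
  truth <- data.frame(type = character(), beat = integer(),
                      interval_idx = integer(), t_event = numeric(),
                      stringsAsFactors = FALSE)
  if (length(inject) && sum(inject) > 0)
    return(inject_events(df, inject, cfg))
  list(beats = beat_series(df), truth = truth)
}

# Rewrite local fiducial patterns to realize injected arrhythmia events.
# Positions are spaced >= 14 beats apart and away from the edges so each
# event's rule terms are computed from undisturbed neighbors.
inject_events <- function(df, inject, cfg) {
  n <- nrow(df)
  total <- sum(inject)
  gap <- 14L
  lo <- 10L; hi <- n - 10L
  if (hi - lo < total * gap)
    stop("segment too short for requested injections", call. = FALSE)
  pos <- sort(sample(seq(lo, hi, by = gap), total))
  pos <- pos + sample(0:(gap - 6L), total, replace = TRUE)
  types <- sample(rep(names(inject), inject))
  delay <- numeric(n)            # per-row time shift, applied at the end
  df$.orig <- seq_len(n)         # row identity, survives reordering
  tcols <- c("t_P", "t_R", "t_S", "t_Tpeak", "t_Tend")
  drop_qrs <- integer(0)
  nc_rows <- list()
  truth <- list()
  # events processed in increasing position: delay[k] already holds the
  # shifts of all earlier blocks when event at k is realized
  for (e in seq_len(total)) {
    k <- pos[e]; type <- types[e]
    if (type == "APB") {
      d <- 0.30 * (df$t_R[k] - df$t_R[k - 1L])   # 30% shortening: well past 18%
      delay[k] <- delay[k] - d
      truth[[e]] <- data.frame(type = "APB", orig = k,
                               t_event = df$t_R[k] + delay[k])
    } else if (type == "ncAPB") {
      pp <- mean(diff(df$t_P[(k - 4L):k]))
      tp <- df$t_P[k] + delay[k] + 0.70 * pp
      orig_id <- n + e
      nc_rows[[length(nc_rows) + 1L]] <- data.frame(
        animal_id = df$animal_id[1L], group = df$group[1L],
        day_label = df$day_label[1L], segment_id = df$segment_id[1L],
        t_P = tp, t_R = NA_real_, t_S = NA_real_, t_Tpeak = NA_real_,
        t_Tend = NA_real_, conducted = FALSE, SBP = NA_real_,
        DBP = NA_real_, .orig = orig_id, stringsAsFactors = FALSE)
      truth[[e]] <- data.frame(type = "ncAPB", orig = orig_id, t_event = tp)
    } else if (type %in% c("MobitzI", "MobitzII", "AdvancedAVB")) {
      dropped <- if (type == "AdvancedAVB") c(k, k + 1L) else k
      extra <- if (type == "AdvancedAVB") 0.5 * cfg$RR0 else 0.2 * cfg$RR0
      drop_qrs <- c(drop_qrs, dropped)
      after <- (max(dropped) + 1L):n
      prior <- (k - 4L):(k - 1L)
      post <- max(dropped) + 1L
      if (type == "MobitzI") {
        # monotone PR prolongation (0,2,4,6 ms) and post-block PR shortening
        df$t_P[prior] <- df$t_R[prior] - (cfg$PR0 + c(0, 2, 4, 6))
        df$t_P[post] <- df$t_R[post] - (cfg$PR0 - 4)
      } else {
        df$t_P[prior] <- df$t_R[prior] - cfg$PR0    # flat, un-prolonged
        df$t_P[post] <- df$t_R[post] - cfg$PR0      # normal first post PR
      }
      truth[[e]] <- data.frame(type = type, orig = k,
                               t_event = df$t_P[k] + delay[k])
      delay[after] <- delay[after] + extra
    } else stop("unknown injection type: ", type, call. = FALSE)
  }
  for (col in tcols) df[[col]] <- df[[col]] + delay
  if (length(drop_qrs)) {
    df$conducted[drop_qrs] <- FALSE
    for (col in c("t_R", "t_S", "t_Tpeak", "t_Tend", "SBP", "DBP"))
      df[[col]][drop_qrs] <- NA_real_
  }
  if (length(nc_rows)) df <- rbind(df, do.call(rbind, nc_rows))
  key <- ifelse(is.na(df$t_R), df$t_P, df$t_R)
  df <- df[order(key), ]
  rownames(df) <- NULL
  truth <- do.call(rbind, truth)
  truth$beat <- match(truth$orig, df$.orig)
  # interval index of APB-shortened intervals among conducted-beat RRs
  cond <- which(df$conducted %in% TRUE)
  truth$interval_idx <- ifelse(
    truth$type == "APB", match(truth$beat, cond) - 1L, NA_integer_)
  truth <- truth[, c("type", "beat", "interval_idx", "t_event")]
  df$.orig <- NULL
  list(beats = beat_series(df), truth = truth)
}

#' Half-sine arterial pressure pulse template
#'
#' `p(t) = DBP + A sin(pi t / T)` over one pulse of duration `T` ms, the
#' family whose analytic dP/dt max is `pi A / T` (mmHg/ms).
#'
#' @param amplitude pulse amplitude A, mmHg.
#' @param period_ms pulse duration T, ms.
#' @param dbp diastolic floor, mmHg.
#' @param dt sampling interval, ms.
#' @param t0 pulse start time, ms.
#' @return a `waveform_chunk` (pressure).
#' @export
pressure_pulse_chunk <- function(amplitude, period_ms, dbp = 85,
                                 dt = 0.25, t0 = 0) {
  t <- seq(0, period_ms, by = dt)
  waveform_chunk("pressure", t0 = t0, dt = dt,
                 samples = dbp + amplitude * sin(pi * t / period_ms))
}

#' ECG template around the S fiducial with an analytic ST segment
#'
#' Baseline 0 mV before S; after S the ST segment is `"flat"` at
#' `st_amp`, a linear `"ramp"` of `slope` mV/ms, or a `"cubic"`
#' `a3 x^3 + a2 x^2 + a1 x` of the time after S, so the slope-minimum and
#' amplitude-window truths have closed forms.
#'
#' @param shape "flat", "ramp" or "cubic".
#' @param st_amp flat amplitude, mV.
#' @param slope ramp slope, mV/ms.
#' @param coef cubic coefficients c(a3, a2, a1).
#' @param t_S S time within the chunk, ms.
#' @param span_ms chunk length after S, ms.
#' @param dt sampling interval, ms.
#' @return a `waveform_chunk` (ecg) with attribute `t_S`.
#' @export
ecg_st_chunk <- function(shape = c("flat", "ramp", "cubic"), st_amp = 0.05,
                         slope = 0.02, coef = c(-0.002, 0.006, 0),
                         t_S = 5, span_ms = 10, dt = 0.25) {
  shape <- match.arg(shape)
  t <- seq(0, t_S + span_ms, by = dt)
  x <- numeric(length(t))
  after <- t > t_S
  u <- t[after] - t_S
  x[after] <- switch(shape,
                     flat = st_amp,
                     ramp = slope * u,
                     cubic = coef[1] * u^3 + coef[2] * u^2 + coef[3] * u)
  out <- waveform_chunk("ecg", t0 = 0, dt = dt, samples = x)
  attr(out, "t_S") <- t_S
  out
}

#' Generate a breath table for one animal-day
#'
#' Breath trains with Gaussian inspiratory/expiratory times around the
#' configured means (exposed-group expiratory shift applied when
#' `T_E_delta` is nonzero), optional disturbance episodes placed before
#' given event times: apnea removes breaths to leave a >= 1.2 s
#' onset-free gap; braking merges a breath into its successor (one long
#' expiration); tachypnea shortens a run of four breaths.
#'
#' @param config a `synth_config`.
#' @param duration_ms day coverage, ms.
#' @param animal_id,day_label metadata.
#' @param T_E_delta additive expiratory-time effect, ms.
#' @param disturb data.frame with columns `time` (ms) and `type`
#'   ("apnea"/"braking"/"tachypnea"); episodes end ~200 ms before `time`.
#' @return data.frame of breaths (t_start, t_insp_end, t_end, pause,
#'   T_I, T_E, T_T).
#' @export
generate_breaths <- function(config, duration_ms = 30 * 60 * 1000,
                             animal_id = "A01", day_label = "baseline",
                             T_E_delta = 0, disturb = NULL) {
  cfg <- config
  tt0 <- cfg$T_I0 + cfg$T_E0 + T_E_delta
  n <- ceiling(duration_ms / tt0) + 1L
  ti <- pmax(50, cfg$T_I0 + stats::rnorm(n, 0, cfg$sd_breath))
  te <- pmax(50, cfg$T_E0 + T_E_delta + stats::rnorm(n, 0, cfg$sd_breath))
  t_start <- cumsum(c(0, (ti + te)[-n]))
  df <- data.frame(animal_id = animal_id, day_label = day_label,
                   t_start = t_start, t_insp_end = t_start + ti,
                   t_end = t_start + ti + te,
                   pause = pmax(0, cfg$pause0 + stats::rnorm(n, 0, 0.005)),
                   stringsAsFactors = FALSE)
  df <- df[df$t_start < duration_ms, ]
  if (!is.null(disturb) && nrow(disturb)) {
    for (j in seq_len(nrow(disturb))) {
      tev <- disturb$time[j]
      if (disturb$type[j] == "apnea") {
        df <- df[!(df$t_start > tev - 1500 & df$t_start < tev - 200), ]
      } else if (disturb$type[j] == "braking") {
        i <- which(df$t_start < tev - 400)
        if (length(i) >= 2L) {
          i <- i[length(i)] - 1L
          df$t_end[i] <- df$t_end[i + 1L]      # merge: one long expiration
          df <- df[-(i + 1L), ]
        }
      } else if (disturb$type[j] == "tachypnea") {
        i <- which(df$t_start > tev - 2000 & df$t_start < tev - 200)
        if (length(i)) {
          sc <- 1 / 1.8
          df$t_insp_end[i] <- df$t_start[i] +
            (df$t_insp_end[i] - df$t_start[i]) * sc
          df$t_end[i] <- df$t_insp_end[i] +
            (df$t_end[i] - df$t_insp_end[i]) * sc
        }
      }
    }
  }
  df$T_I <- df$t_insp_end - df$t_start
  df$T_E <- df$t_end - df$t_insp_end
  df$T_T <- df$T_I + df$T_E
  rownames(df) <- NULL
  df
}

#' Generate a complete synthetic study
#'
#' Two exposure groups x `n_per_group` animals x (baseline + `n_days`)
#' days. Each animal-day gets `segments_per_day` 5-min beat segments (a
#' scaled-down stand-in for the 5-h exposure window), one template
#' pressure pulse and ECG chunk per day for the waveform features, and a
#' breath table. Exposed animals receive the configured post-baseline
#' parameter shifts (baroreflex gain, RSA amplitude, expiratory time) and
#' the day-4 Mobitz II rate excess; a `disturbance_coupling` fraction of
#' injected AV-block events is preceded by a ventilatory disturbance.
#' Fully deterministic given `config$seed`.
#'
#' @param config a `synth_config`.
#' @return list of class `synth_study`: `design` (animal x day grid with
#'   group), `beats` (named list of per-animal-day `beat_series`),
#'   `breaths`, `waveforms` (per-day template chunks), `truth` (injected
#'   events, per-parameter effect truths, disturbance log).
#' @export
generate_study <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  animals <- data.frame(
    animal_id = sprintf("A%02d", seq_len(2L * cfg$n_per_group)),
    group = rep(c("FA", "PSOA"), each = cfg$n_per_group),
    stringsAsFactors = FALSE)
  days <- c("baseline", paste0("day", seq_len(cfg$n_days)))
  design <- merge(animals, data.frame(day_label = days), by = NULL)
  design <- design[order(design$animal_id, match(design$day_label, days)), ]
  rownames(design) <- NULL
  n_seg_beats <- floor(5 * 60 * 1000 / cfg$RR0)
  beats <- list(); breaths <- list(); waveforms <- list(); truths <- list()
  disturb_log <- list()
  for (r in seq_len(nrow(design))) {
    aid <- design$animal_id[r]; day <- design$day_label[r]
    grp <- design$group[r]
    exposed <- grp == "PSOA" && day != "baseline"
    G <- cfg$G + if (exposed) cfg$effects$G_delta else 0
    cfg_day <- cfg
    cfg_day$A_rsa <- cfg$A_rsa + if (exposed) cfg$effects$A_rsa_delta else 0
    # day-4 Mobitz II scenario: Poisson counts at the configured pair
    m2_mean <- if (day == "day4")
      cfg$effects$mobitz2_day4[if (grp == "PSOA") 2L else 1L] else 0.3
    m2 <- stats::rpois(1L, if (day == "baseline") 0.3 else m2_mean)
    segs <- list(); seg_truth <- list()
    for (s in seq_len(cfg$segments_per_day)) {
      inj <- integer(0)
      if (s == 1L && m2 > 0) inj <- c(MobitzII = m2)
      gb <- generate_beats(cfg_day, n_beats = n_seg_beats, animal_id = aid,
                           group = grp, day_label = day,
                           segment_id = sprintf("%s_%s_s%02d", aid, day, s),
                           inject = inj,
                           t0 = (s - 1L) * 5 * 60 * 1000, G = G)
      segs[[s]] <- gb$beats
      if (nrow(gb$truth)) {
        gb$truth$animal_id <- aid; gb$truth$day_label <- day
        gb$truth$group <- grp
        seg_truth[[length(seg_truth) + 1L]] <- gb$truth
      }
    }
    key <- paste(aid, day, sep = ":")
    beats[[key]] <- segs
    day_truth <- if (length(seg_truth)) do.call(rbind, seg_truth) else NULL
    truths[[key]] <- day_truth
    te_delta <- if (exposed) cfg$effects$T_E_delta_ms else 0
    disturb <- NULL
    if (!is.null(day_truth)) {
      couple <- stats::runif(nrow(day_truth)) < cfg$disturbance_coupling
      if (any(couple)) {
        disturb <- data.frame(
          time = day_truth$t_event[couple],
          type = sample(c("apnea", "braking", "tachypnea"), sum(couple),
                        replace = TRUE),
          stringsAsFactors = FALSE)
      }
      disturb_log[[key]] <- data.frame(
        day_truth[, c("type", "t_event", "animal_id", "day_label", "group")],
        disturbed = couple, stringsAsFactors = FALSE)
    }
    breaths[[key]] <- generate_breaths(
      cfg, duration_ms = cfg$segments_per_day * 5 * 60 * 1000,
      animal_id = aid, day_label = day, T_E_delta = te_delta,
      disturb = disturb)
    waveforms[[key]] <- list(
      pressure = pressure_pulse_chunk(cfg$pulse_amp, cfg$pulse_period_ms,
                                      dbp = cfg$SBP0 - cfg$pulse_amp,
                                      dt = cfg$wave_dt_ms),
      ecg = ecg_st_chunk("flat", st_amp = cfg$st_amp_mV,
                         dt = cfg$wave_dt_ms))
  }
  structure(list(
    design = design,
    beats = beats, breaths = breaths, waveforms = waveforms,
    truth = list(
      events = do.call(rbind, Filter(Negate(is.null), truths)),
      disturbances = do.call(rbind, Filter(Negate(is.null), disturb_log)),
      G = cfg$G, effects = cfg$effects,
      disturbance_coupling = cfg$disturbance_coupling),
    config = cfg), class = "synth_study")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Per segment: ectopic-filtered HRV (time + frequency domain),
#' sequence-method BRS, ECG morphology, hemodynamics, and the day's
#' template dP/dt max and ST metrics. Per animal-day: arrhythmia
#' classification (PR reference calibrated on the animal's baseline day)
#' and daily counts; respiratory summaries. Then deltas from baseline and
#' the inference layer for a small endpoint panel.
#'
#' @param study a `synth_study`.
#' @param endpoints endpoints passed to the mixed-model layer.
#' @param freq_oversample Lomb frequency-grid oversampling (2 keeps the
#'   full-study run fast; 4 for single-segment work).
#' @return list: `segment_results`, `daily_counts`, `ventilation`,
#'   `deltas`, `lmm_effects`, `gee_mobitz2`, `screen`.
#' @export
analyze_study <- function(study, endpoints = c("RMSSD", "SDNN", "BRS", "PP"),
                          freq_oversample = 2) {
  cfg <- study$config
  seg_rows <- list()
  ev_rows <- list()
  pr_refs <- list()
  for (key in names(study$beats)) {
    segs <- study$beats[[key]]
    aid <- segs[[1L]]$animal_id[1L]
    if (segs[[1L]]$day_label[1L] == "baseline" && is.null(pr_refs[[aid]]))
      pr_refs[[aid]] <- pr_reference(segs[[1L]])
  }
  for (key in names(study$beats)) {
    segs <- study$beats[[key]]
    aid <- segs[[1L]]$animal_id[1L]
    wf <- study$waveforms[[key]]
    dpdt <- dpdt_max(wf$pressure)
    st <- st_metrics(wf$ecg, attr(wf$ecg, "t_S"))
    day_events <- list()
    for (b in segs) {
      iv <- beat_intervals(b)
      nn <- filter_ectopic(iv$intervals)
      keep <- if (length(nn$removed_idx)) -nn$removed_idx else TRUE
      td <- time_domain(nn)
      fd <- frequency_domain(nn, times = iv$times[keep],
                             oversample = freq_oversample)
      brs <- brs_segment(b)
      hemo <- hemodynamics(b)
      morph <- morphology(b)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        animal_id = aid, group = b$group[1L], day_label = b$day_label[1L],
        segment_id = b$segment_id[1L],
        RMSSD = td$RMSSD, SDNN = td$SDNN, CV = td$CV, pNN15 = td$pNN15,
        HR = td$HR, LF = fd$LF, HF = fd$HF, LF_HF = fd$LF_HF,
        BRS = brs$slope, n_sequences = brs$n_sequences,
        SBP = hemo$SBP, DBP = hemo$DBP, PP = hemo$PP,
        rate_pressure = hemo$rate_pressure,
        PR = morph$PR, QTe = morph$QTe, QTcF = morph$QTcF,
        QTcB = morph$QTcB, TpTe = morph$TpTe,
        dPdt_max = dpdt, ST_amp = st$ST_amp, S_min_slope = st$S_min_slope,
        stringsAsFactors = FALSE)
      day_events[[length(day_events) + 1L]] <-
        as.data.frame(detect_arrhythmias(b, pr_ref = pr_refs[[aid]]))
    }
    ev <- do.call(rbind, day_events)
    if (nrow(ev)) ev_rows[[length(ev_rows) + 1L]] <- ev
  }
  segment_results <- do.call(rbind, seg_rows)
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    empty_event_table()
  daily_counts <- count_events(events, study$design)
  vent <- summarize_breaths(do.call(rbind, study$breaths))
  long <- stats::reshape(
    segment_results[, c("animal_id", "group", "day_label",
                        "RMSSD", "SDNN", "CV", "BRS", "PP", "HR",
                        "dPdt_max", "PR", "QTcF", "LF", "HF")],
    direction = "long",
    varying = c("RMSSD", "SDNN", "CV", "BRS", "PP", "HR",
                "dPdt_max", "PR", "QTcF", "LF", "HF"),
    v.names = "value", timevar = "endpoint",
    times = c("RMSSD", "SDNN", "CV", "BRS", "PP", "HR",
              "dPdt_max", "PR", "QTcF", "LF", "HF"))
  vlong <- vent$daily
  if (nrow(vlong)) {
    vlong <- merge(vlong, unique(study$design[, c("animal_id", "group")]),
                   by = "animal_id")
    vl <- stats::reshape(
      vlong[, c("animal_id", "group", "day_label", "T_I", "T_E", "T_T", "f")],
      direction = "long", varying = c("T_I", "T_E", "T_T", "f"),
      v.names = "value", timevar = "endpoint",
      times = c("T_I", "T_E", "T_T", "f"))
    long <- rbind(long[, c("animal_id", "group", "day_label",
                           "endpoint", "value")],
                  vl[, c("animal_id", "group", "day_label",
                         "endpoint", "value")])
  }
  deltas <- make_deltas(long)
  lmm <- do.call(rbind, lapply(intersect(endpoints, unique(deltas$endpoint)),
                               function(ep)
    fit_lmm(deltas, ep, ref_group = "FA")))
  m2 <- daily_counts[daily_counts$type == "MobitzII", ]
  m2 <- merge(m2, unique(study$design[, c("animal_id", "group")]),
              by = "animal_id")
  gee <- tryCatch(fit_count_gee(m2, contrast = "daily", ref_group = "FA"),
                  error = function(e) NULL)
  screen <- NULL
  if (!is.null(study$truth$events)) {
    evd <- study$truth$events
    evd$event_time <- evd$t_event
    screen <- screen_events(do.call(rbind, study$breaths), evd)
  }
  list(segment_results = segment_results, events = events,
       daily_counts = daily_counts, ventilation = vent, deltas = deltas,
       lmm_effects = lmm, gee_mobitz2 = gee, screen = screen)
}

#' Simulate a delta table with a known injected group effect
#'
#' Direct endpoint-level simulation for validating the inference layer:
#' `delta[a, d] = animal_re + effect x I(exposed) + noise`, one row per
#' animal x exposure day.
#'
#' @param effect injected overall exposed-minus-control effect (endpoint
#'   units).
#' @param endpoint endpoint label.
#' @param n_per_group animals per group.
#' @param n_days exposure days.
#' @param sd_animal between-animal SD of the random intercept.
#' @param sd_resid residual SD.
#' @return a `delta_table`-shaped data.frame.
#' @export
simulate_delta_table <- function(effect, endpoint = "RMSSD", n_per_group = 6,
                                 n_days = 12, sd_animal = 0.5, sd_resid = 1.0) {
  n_anim <- 2L * n_per_group
  animals <- sprintf("A%02d", seq_len(n_anim))
  group <- rep(c("FA", "PSOA"), each = n_per_group)
  re <- stats::rnorm(n_anim, 0, sd_animal)
  out <- expand.grid(animal_id = animals,
                     day_label = paste0("day", seq_len(n_days)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$group <- group[match(out$animal_id, animals)]
  out$endpoint <- endpoint
  out$delta <- re[match(out$animal_id, animals)] +
    effect * (out$group == "PSOA") +
    stats::rnorm(nrow(out), 0, sd_resid)
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Simulate daily arrhythmia counts with a known rate ratio
#'
#' Poisson counts per animal-day with a gamma animal frailty inducing
#' exchangeable within-animal correlation; exposed animals' exposure-day
#' rates are `rate_ratio` times control.
#'
#' @param rate_ratio exposed:control rate ratio.
#' @param base_mean control-group mean events/day.
#' @param n_per_group,n_days design size.
#' @param frailty_sd SD of the log-normal animal frailty (0 = none).
#' @return data.frame: animal_id, group, day_label, count (baseline day
#'   included at the control rate for both groups).
#' @export
simulate_daily_counts <- function(rate_ratio = 4, base_mean = 2,
                                  n_per_group = 6, n_days = 12,
                                  frailty_sd = 0.2) {
  n_anim <- 2L * n_per_group
  animals <- sprintf("A%02d", seq_len(n_anim))
  group <- rep(c("FA", "PSOA"), each = n_per_group)
  fr <- exp(stats::rnorm(n_anim, -frailty_sd^2 / 2, frailty_sd))
  out <- expand.grid(animal_id = animals,
                     day_label = c("baseline", paste0("day", seq_len(n_days))),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$group <- group[match(out$animal_id, animals)]
  mu <- base_mean * fr[match(out$animal_id, animals)] *
    ifelse(out$group == "PSOA" & out$day_label != "baseline", rate_ratio, 1)
  out$count <- stats::rpois(nrow(out), mu)
  out
}
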