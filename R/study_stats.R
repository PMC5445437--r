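#' Delta-from-baseline table
#'
#' For every endpoint, each animal's daily mean minus the same animal's
#' baseline-day mean. Deltas put every animal on its own scale so group
#' contrasts compare exposure responses rather than baseline physiology.
#'
#' @param results long data.frame: animal_id, group, day_label, endpoint,
#'   value (one or more rows per animal-day-endpoint; rows are averaged
#'   within animal-day first).
#' @param baseline_label day label identifying baseline (default
#'   "baseline").
#' @return data.frame (class `delta_table`): animal_id, group, day_label,
#'   endpoint, delta — exposure days only, one row per animal x day x
#'   endpoint where both values exist. Animals lacking a baseline value
#'   for an endpoint are excluded and listed in attribute `no_baseline`.
#' @export
make_deltas <- function(results, baseline_label = "baseline") {
  need <- c("animal_id", "group", "day_label", "endpoint", "value")
  stopifnot(all(need %in% names(results)))
  res <- results[!is.na(results$value), need]
  day_means <- stats::aggregate(value ~ animal_id + group + day_label + endpoint,
                                data = res, FUN = mean)
  base <- day_means[day_means$day_label == baseline_label,
                    c("animal_id", "endpoint", "value")]
  names(base)[3L] <- "baseline"
  expo <- day_means[day_means$day_label != baseline_label, ]
  merged <- merge(expo, base, by = c("animal_id", "endpoint"))
  merged$delta <- merged$value - merged$baseline
  dropped <- unique(expo[!paste(expo$animal_id, expo$endpoint) %in%
                           paste(base$animal_id, base$endpoint),
                         c("animal_id", "endpoint")])
  out <- merged[order(merged$endpoint, merged$animal_id, merged$day_label),
                c("animal_id", "group", "day_label", "endpoint", "delta")]
  rownames(out) <- NULL
  attr(out, "no_baseline") <- dropped
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Linear mixed model for exposure effects on deltas
#'
#' Fits the delta series of one endpoint with exposure group and day as
#' fixed effects, choosing among three candidate covariance structures by
#' REML AIC (fixed effects are identical across candidates, so the REML
#' comparison is valid): random animal intercept, random animal intercept
#' + day slope,
#' and compound-symmetric within-animal residual correlation (GLS). The
#' winning fit supplies the overall group contrast and, with
#' `contrast = "daily"`, per-day group contrasts from a group x day
#' interaction model. Non-convergent candidates fall back to the simplest
#' structure with a warning.
#'
#' @param deltas a `delta_table` (or long data.frame with animal_id,
#'   group, day_label, endpoint, delta).
#' @param endpoint endpoint name to analyze.
#' @param contrast "overall", "daily", or both.
#' @param candidates subset of c("intercept", "intercept_day", "cs") to
#'   compare (default all three).
#' @param ref_group reference (control) level of `group`; the reported
#'   effect is the other level minus this one.
#' @param diet_interaction when `TRUE` (requires a `diet` column in
#'   `deltas`), fits `delta ~ group * diet + day` and reports the
#'   group-by-diet interaction: how much larger the exposure effect is in
#'   the second diet level than in the first.
#' @return data.frame of class `effect_estimate`: endpoint, contrast
#'   ("overall", a day label, or "group:diet"), estimate, SE, p (Wald),
#'   model (winning structure), AIC.
#' @export
fit_lmm <- function(deltas, endpoint, contrast = "overall",
                    candidates = c("intercept", "intercept_day", "cs"),
                    ref_group = NULL, diet_interaction = FALSE) {
  d <- as.data.frame(deltas)
  d <- d[d$endpoint == endpoint & !is.na(d$delta), ]
  if (diet_interaction) {
    stopifnot("diet" %in% names(d))
    d$diet <- factor(d$diet)
  }
  if (!is.null(ref_group)) d$group <- stats::relevel(factor(d$group), ref_group)
  else d$group <- factor(d$group)
  if (nlevels(d$group) != 2L)
    stop("need exactly two exposure groups", call. = FALSE)
  if (min(table(unique(d[, c("animal_id", "group")])$group)) < 2L)
    stop("need >= 2 animals per group", call. = FALSE)
  d$day <- factor(d$day_label)
  d$day_num <- as.numeric(d$day)
  d$animal_id <- factor(d$animal_id)
  out <- list()
  if (diet_interaction) {
    fit <- select_lmm(delta ~ group * diet + day, d, candidates)
    b <- if (inherits(fit$fit, "lme")) nlme::fixef(fit$fit)
         else stats::coef(fit$fit)
    V <- stats::vcov(fit$fit)
    ia <- grep(":diet", names(b), value = TRUE)[1L]
    est <- b[[ia]]; se <- sqrt(V[ia, ia])
    df <- nlevels(d$animal_id <- factor(d$animal_id)) - 4L
    res <- data.frame(endpoint = endpoint, contrast = "group:diet",
                      estimate = est, SE = se,
                      p = 2 * stats::pt(-abs(est / se), max(df, 1L)),
                      model = fit$name, AIC = fit$aic,
                      stringsAsFactors = FALSE)
    class(res) <- c("effect_estimate", "data.frame")
    return(res)
  }
  if ("overall" %in% contrast) {
    fit <- select_lmm(delta ~ group + day, d, candidates)
    out[[length(out) + 1L]] <- lmm_contrast(fit, d, endpoint, "overall")
  }
  if ("daily" %in% contrast) {
    fit <- select_lmm(delta ~ group * day, d, candidates)
    for (lev in levels(d$day))
      out[[length(out) + 1L]] <- lmm_contrast(fit, d, endpoint, lev)
  }
  res <- do.call(rbind, out)
  class(res) <- c("effect_estimate", "data.frame")
  res
}

select_lmm <- function(fixed, d, candidates) {
  fits <- list()
  if ("intercept" %in% candidates)
    fits$intercept <- try(nlme::lme(fixed, random = ~ 1 | animal_id,
                                    data = d, method = "REML"), silent = TRUE)
  if ("intercept_day" %in% candidates)
    fits$intercept_day <- try(suppressWarnings(suppressMessages(
      nlme::lme(fixed, random = ~ 1 + day_num | animal_id, data = d,
                method = "REML",
                control = nlme::lmeControl(opt = "optim", returnObject = TRUE,
                                           msVerbose = FALSE)))),
      silent = TRUE)
  if ("cs" %in% candidates)
    fits$cs <- try(nlme::gls(fixed, data = d, method = "REML",
                             correlation = nlme::corCompSymm(form = ~ 1 | animal_id)),
                   silent = TRUE)
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) {
    warning("no mixed-model candidate converged; falling back to GLS",
            call. = FALSE)
    fit <- nlme::gls(fixed, data = d, method = "REML")
    return(list(fit = fit, name = "gls_independence", aic = stats::AIC(fit)))
  }
  aics <- vapply(fits[ok], stats::AIC, numeric(1))
  best <- names(aics)[which.min(aics)]
  list(fit = fits[[best]], name = best, aic = min(aics))
}

lmm_contrast <- function(sel, d, endpoint, which_day) {
  fit <- sel$fit
  b <- if (inherits(fit, "lme")) nlme::fixef(fit) else stats::coef(fit)
  V <- stats::vcov(fit)
  grp_term <- paste0("group", levels(d$group)[2L])
  cvec <- stats::setNames(numeric(length(b)), names(b))
  cvec[grp_term] <- 1
  if (which_day != "overall") {
    ia <- paste0(grp_term, ":day", which_day)
    if (ia %in% names(b)) cvec[ia] <- 1
  }
  est <- sum(cvec * b)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  df <- nlevels(d$animal_id) - 2L
  data.frame(endpoint = endpoint, contrast = which_day, estimate = est,
             SE = se, p = 2 * stats::pt(-abs(est / se), df),
             model = sel$name, AIC = sel$aic, stringsAsFactors = FALSE)
}

#' Poisson GEE for daily arrhythmia counts
#'
#' Events per 5-h exposure day, modelled marginally with a Poisson
#' log-link GEE and exchangeable within-animal correlation. Each animal's
#' baseline count enters as `log(baseline + 0.5)` covariate by default
#' (set `baseline_as = "offset"` to use it as an offset instead). The
#' exposure-group coefficient is reported as a rate ratio.
#'
#' @param counts data.frame: animal_id, group, day_label, count; the
#'   baseline day supplies per-animal baseline counts and is not modelled.
#' @param contrast "overall" or "daily" (group x day model with per-day
#'   rate ratios).
#' @param baseline_label baseline day label.
#' @param baseline_as "covariate" (default) or "offset".
#' @param ref_group reference group level.
#' @return data.frame of class `effect_estimate`: contrast, rate_ratio,
#'   log RR estimate, robust SE, p; attribute `fit` holds the `pois_gee`
#'   object.
#' @export
fit_count_gee <- function(counts, contrast = "overall",
                          baseline_label = "baseline",
                          baseline_as = c("covariate", "offset"),
                          ref_group = NULL) {
  baseline_as <- match.arg(baseline_as)
  stopifnot(all(c("animal_id", "group", "day_label", "count") %in%
                  names(counts)))
  base <- counts[counts$day_label == baseline_label, c("animal_id", "count")]
  names(base)[2L] <- "baseline_count"
  d <- counts[counts$day_label != baseline_label & !is.na(counts$count), ]
  d <- merge(d, base, by = "animal_id", all.x = TRUE)
  d$baseline_count[is.na(d$baseline_count)] <- 0
  d$log_base <- log(d$baseline_count + 0.5)
  if (!is.null(ref_group)) d$group <- stats::relevel(factor(d$group), ref_group)
  else d$group <- factor(d$group)
  d$day <- factor(d$day_label)
  if (all(d$count == 0))
    stop("endpoint has no events on exposure days: inestimable",
         call. = FALSE)
  form <- if (contrast == "daily") {
    if (baseline_as == "covariate") count ~ group * day + log_base
    else count ~ group * day
  } else {
    if (baseline_as == "covariate") count ~ group + log_base
    else count ~ group
  }
  off <- if (baseline_as == "offset") "log_base" else NULL
  fit <- pois_gee(form, d, id = "animal_id", offset = off)
  b <- stats::coef(fit); V <- stats::vcov(fit)
  grp_term <- paste0("group", levels(d$group)[2L])
  rows <- list()
  mk <- function(cvec, label) {
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(contrast = label, rate_ratio = exp(est), estimate = est,
               SE = se, p = 2 * stats::pnorm(-abs(est / se)),
               stringsAsFactors = FALSE)
  }
  zero <- stats::setNames(numeric(length(b)), names(b))
  if (contrast == "daily") {
    for (lev in levels(d$day)) {
      cvec <- zero; cvec[grp_term] <- 1
      ia <- paste0(grp_term, ":day", lev)
      if (ia %in% names(b)) cvec[ia] <- 1
      rows[[length(rows) + 1L]] <- mk(cvec, lev)
    }
  } else {
    cvec <- zero; cvec[grp_term] <- 1
    rows[[1L]] <- mk(cvec, "overall")
  }
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Simple or group-adjusted (partial) correlation between endpoints
#'
#' Pearson correlation with the regression p-value; with
#' `adjust_for_group = TRUE` both variables are first residualized on the
#' group indicators, giving the partial correlation accounting for group,
#' with degrees of freedom reduced accordingly.
#'
#' @param x,y paired numeric endpoint vectors (>= 3 complete pairs).
#' @param group optional grouping factor (required for the partial
#'   variant).
#' @param adjust_for_group logical.
#' @return list with `r`, `p`, `n`, `df`, `adjusted`. `r` is `NA` with a
#'   zero-variance input.
#' @export
correlate <- function(x, y, group = NULL, adjust_for_group = FALSE) {
  keep <- stats::complete.cases(x, y, if (is.null(group)) x else group)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, df = NA_integer_,
                adjusted = adjust_for_group))
  k <- 0L
  if (adjust_for_group) {
    if (is.null(group)) stop("partial correlation needs `group`",
                             call. = FALSE)
    g <- factor(group[keep])
    k <- nlevels(g) - 1L
    x <- stats::resid(stats::lm(x ~ g))
    y <- stats::resid(stats::lm(y ~ g))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_, n = n, df = NA_integer_,
                  adjusted = TRUE))
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n, df = df,
       adjusted = adjust_for_group)
}
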