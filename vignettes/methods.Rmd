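---
title: "Methods: cardiovascular autonomic analysis of rodent telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiovascular autonomic analysis of rodent telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioauto)
```

## Scope and data model

`cardioauto` analyzes beat-annotated telemetry from rodent inhalation
studies: per-beat ECG fiducials (P onset, R, S, T peak, T end), per-beat
arterial pressures, and breath-segmented respiratory timing, organized as
one flat CSV row per beat. All times are milliseconds from recording
start; analysis windows are half-open, 5 minutes for ECG/BP endpoints and
10 minutes for respiratory endpoints. When ECG fiducials are unavailable
(pressure-only animals), inter-beat intervals are taken from systolic-peak
times ("pulse mode") and results are tagged with their source; on clean
data the two modes agree to under 2% for time-domain HRV, which the test
suite asserts.

## Ectopic filtering

Before HRV or baroreflex analysis, any inter-beat interval shortened by
more than 18% relative to the average of its 3 preceding and 3 following
intervals is removed. The comparison is one pass over the raw series, so
filtering is idempotent; edge intervals use at least 2 neighbors per side
or are left unfiltered. The 18% rule is applied strictly (an interval at
exactly 82% of its local mean is kept), enforced with a 1e-9 ms epsilon so
floating-point representation cannot flip the boundary case.

## Heart rate variability

Time domain: RMSSD, SDNN (sample, n−1 denominator), CV = SDNN / mean
interval (reported as a fraction), pNN15 (strictly greater than 15 ms),
mean interval and heart rate. Frequency domain: the interval series is
unevenly sampled once beats are removed, so the default estimator is a
Lomb–Scargle periodogram evaluated at interval midpoint times; a
cubic-interpolation FFT periodogram is available behind
`method = "interp"`. Band power is the fraction of periodogram mass inside
the band times the series variance, so LF + HF never exceeds the total
interval variance and a pure oscillation allocates its variance to the
band containing it. Default rodent bands are LF 0.20–0.75 Hz and HF
0.75–2.50 Hz, both overridable; results are flagged low-confidence when
more than 20% of intervals were removed upstream. Segments need at least
100 s of usable data for spectral estimates.

## Spontaneous baroreflex sensitivity (sequence method)

Systolic pressure of beat *i* is paired with the following inter-beat
interval (*i* → *i*+1; lag configurable). Maximal monotone runs of ≥ 3
beats in which every systolic step is ≥ 0.50 mmHg and every interval step
is ≥ 0.30 ms in the same direction become candidate sequences; a sequence
is accepted when the within-run correlation of interval on pressure is
≥ 0.50, and its slope is the least-squares regression of interval on
pressure. Zero steps break runs (a `ties_break` switch tolerates them).
Up- and down-sequences are pooled into one unweighted mean slope per
segment; a segment with no accepted sequences yields a missing estimate.

The sequence method carries a known upward selection bias: runs are
selected for concordant steps, so noise that happens to align with
selection inflates the slope. Against the package's own generator the
measured recovery of an injected gain of 1.65 ms/mmHg is within +7% at
low noise (SD 0.2 ms / 0.2 mmHg), about +13% at the default noise (SD
1.0), and +16–18% when noise SD reaches a third to a half of the
slow-oscillation amplitude (SD 2–3). Recovery is monotone in the
injected gain and collapses to chance-level sequence counts when the
gain is zero.

## Arrhythmia classification

Atrial premature beats: an RR more than 18% below the mean of the
neighboring 6 RRs (3 each side) with a PR inside the animal's normal
band. Neighbor RRs that span a non-conducted P wave (block gaps) are
excluded from the average — the printed rule assumes normal neighboring
beats, and including a blocked gap would flag healthy beats next to every
AV block.

Non-conducted P waves go through a fixed cascade, each event receiving
exactly one label with all measured rule terms attached as evidence:

1. **ncAPB** — the P is premature (PP < 82% of the prior-4-PP mean);
2. **Mobitz I** — P on time, RR across the block ≥ 2× the local baseline
   RR (median of the prior 4 conducted RRs), with either monotone PR
   prolongation totalling more than 2 SD over the prior 4 conducted beats
   or shortening of the first conducted PR after the block;
3. **Mobitz II** — P on time, un-prolonged PR over the prior 4 and a
   normal first post-block PR, RR ratio in [2, 3);
4. **advanced AV block** — as Mobitz II with RR ratio ≥ 3.

The "normal PR" band is calibrated per animal from its baseline day
(mean ± 2 SD), mirroring a blinded reader's per-animal judgment; the
2-fold RR floor is applied to Mobitz II as well as Mobitz I (switchable
via `rr_floor`). Consecutive blocked Ps inside one gap are one episode.
APB counting is restricted to the audit-day list (baseline and exposure
days 1, 4, 6, 8, 11, 12); other types are counted on every analyzed day,
and days without analyzed segments are missing rather than zero.

## Morphology and hemodynamics

QT is corrected by Fridericia (cube root) or Bazett (square root) after
normalizing RR by a reference interval, 150 ms by default, so the
correction is the identity at the reference. QTe is measured R-to-T-end
and TpTe as T-peak-to-T-end. ST metrics follow their operational
definitions exactly — minimum first-difference slope in the 1.5 ms after
S and mean amplitude 2–4 ms after S — at native sampling (≤ 0.5 ms
required) with no smoothing, so template waveforms reproduce closed-form
truths. dP/dt max is the maximum central-difference pressure derivative
over the systolic upstroke. Pulse pressure is SBP − DBP and the
rate–pressure product HR × SBP / 1000.

## Ventilation

Breath tables carry inspiratory, expiratory and total times with
T_I + T_E = T_T exact by construction. Ten-minute window means are
averaged into daily values; windows with fewer than 10 breaths are
dropped and empty days propagate as missing. The pre-arrhythmia screen
labels the 3 s before an event as apnea (≥ 2 missed expected breaths,
i.e. an onset-free gap of ≥ 3× the day's median T_T), braking (an
expiratory time ≥ 2× the day's median), tachypnea (instantaneous
frequency ≥ 1.5× the day's median), or none, in that priority order.
These thresholds are explicit configuration defaults — the operational
definitions have no published values — and every screen result should be
read as conditional on them.

## Statistics

Each endpoint is converted to deltas: an animal's daily mean minus its
own baseline mean, computed exactly (no modelling). Group effects on
deltas are estimated by linear mixed models with group and day fixed
effects, selecting among three covariance candidates by REML AIC: random
animal intercept, random intercept plus day slope, and compound-symmetric
within-animal correlation (GLS). REML is used deliberately (it is the
SAS PROC MIXED default and gave empirical test size 0.047 versus 0.063
for ML at nominal 0.05 in 1000-replicate null simulations); the
candidates share fixed effects, so the REML AIC comparison is valid.
Per-day contrasts come from the group × day interaction model, and a
group × diet interaction option quantifies whether the exposure effect
differs between diet cohorts. Wald tests
use t references with animals-minus-2 degrees of freedom and no
multiplicity correction, matching per-endpoint reporting conventions —
a faithfulness choice, not a statistical endorsement.

Arrhythmia counts are modelled marginally by a Poisson log-link GEE with
exchangeable working correlation, implemented in-package with the
standard Liang–Zeger moment estimators and robust sandwich errors (no GEE
package is assumed). Each animal's baseline count enters as a
log(baseline + 0.5) covariate by default, with an offset switch — the
"baseline as its own intercept" phrasing is ambiguous between the two.
Robust SEs are flagged unreliable below 3 clusters. Endpoint–endpoint and
endpoint–pollutant associations use Pearson correlation, optionally
residualized on group indicators first (partial correlation accounting
for group) with degrees of freedom reduced accordingly.

## Synthetic data: what it emulates and what it does not

The generator produces the whole study — two groups × 6 animals ×
(baseline + 12 days) — with a truth log for every estimand. Beat
dynamics: systolic pressure carries a 0.1 Hz slow (Mayer-band analog)
oscillation, a 1.5 Hz respiratory oscillation, and Gaussian noise; the
next interval responds to the systolic fluctuation with the configured
gain when a Bernoulli engagement flag fires, plus respiratory sinus
arrhythmia and noise. Defaults state the measured baseline physiology:
RR 180 ms, SBP 135 / DBP 87 mmHg, gain 1.65 ms/mmHg, PR 45 ms, QT-end
60 ms. The slow-oscillation amplitude (6 mmHg) is the one
generator-design calibration dictated by the method itself: at this heart
rate, ramps must exceed the 0.50 mmHg sequence threshold or no sequences
exist at any gain.

Two design choices deserve emphasis. First, the central (non-reflex) RSA
component is in phase quadrature with the respiratory pressure
oscillation; with a coherent phase the sequence method cannot distinguish
RSA from reflex response and gain recovery is structurally biased
(+29% measured with a π/3 phase). Quadrature makes RSA steps orthogonal
to pressure steps, isolating the reflex pathway as the only coherent
coupling. Second, arrhythmia injection rewrites local fiducial patterns
to satisfy each rule well clear of its thresholds (30% RR shortening,
0.70 PP ratio, 2.2×/3.5× block ratios, 6 ms PR progression), so
classifier validation is against unambiguous events, as the acceptance
criteria specify.

The generator is beat-domain: waveforms exist only as analytic templates
(half-sine pressure pulses, flat/ramp/cubic ST segments) where waveform
features need closed-form truths. It does not emulate waveform noise,
fiducial-placement error, electrode artifacts, circadian drift, or
pathology beyond the injected rule signatures — so a green test
establishes correctness of the estimators against the stated model, not
robustness to real-world annotation failure modes. Study-level group
effects are injected as generator-parameter shifts (gain, RSA amplitude,
expiratory time, day-4 Mobitz II rates); the statistical-recovery
acceptance tests instead inject published effect sizes directly at the
delta/count level, which is the scale on which those numbers are defined.
`generate_study()` defaults to 3 five-min segments per animal-day as a
runtime-bounded stand-in for the 5-h exposure window (60 segments
reproduces it; the 60-window segmentation itself is tested on a full 5-h
stream).

## Numerical choices and degenerate inputs

Strict thresholds carry a 1e-9 ms epsilon; breath-overlap validation
tolerates 1e-6 ms (one ULP of cumulative-sum construction). Constant
interval series give zero SDNN/CV and zero band powers with an undefined
LF/HF flag; all-removed series return an empty result with a warning;
segments with no accepted baroreflex sequences, animals without baseline,
days without analyzed segments, and uncovered screen windows all
propagate as missing, never as zero. GEE scoring guards against singular
information (pseudo-inverse with a warning) and refuses all-zero
endpoints as inestimable. Mixed-model candidates that fail to converge
fall back to the simplest structure with a warning.

## Known limitations

R-peak detection, telemetry-vendor parsing, non-linear HRV, ventricular
arrhythmia taxonomies, transfer-function baroreflex methods,
plethysmographic volume calibration, and Bayesian or multiplicity-aware
inference are out of scope. The sequence-method bias curve above is a
property of the method, not removable by implementation; treat absolute
BRS levels as method-conditional and rely on contrasts.
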