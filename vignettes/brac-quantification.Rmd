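---
title: "Quantifying breath alcohol from fuel-cell sensor signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breath alcohol from fuel-cell sensor signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bracquant)
```

## The measurement problem

A fuel-cell breath analyzer oxidizes the ethanol in a breath sample at a
platinum anode; the cell needs no power source and produces an electric
potential roughly proportional to the breath alcohol content (BrAC, in
micrograms of ethanol per 100 mL of breath). The dominant reaction on
platinum is the four-electron oxidation of ethanol to acetic acid, and the
cell's theoretical ceiling — its open circuit potential — follows the Nernst
relation from the ratio of reactant to product partial pressures
(`nernst_ocp()`). The amplified cell voltage is digitized by a 10-bit ADC
against a 4.94 V reference, so one count is worth
`1000 * 4.94 / 1024 = 4.82` mV; with a sensor sensitivity of 13 mV per
mcg/100 mL, a count maps to roughly 0.37 mcg/100 mL. The divisor is the
number of quantization levels (1024), not the top code (1023): that is the
standard definition of the quantization step and it reproduces the 4.82 mV
figure; the 1023 convention (4.83 mV) remains reachable by configuration.

Quantification is a two-stage decision. Alcohol-free samples still produce
a small above-baseline transient — electrical noise plus the actuation of
the sampling pump perturbing the initial partial-pressure balance in the
cell — so a naive regression would report false positives at zero. A
rule-based classifier therefore first decides whether the sample contains
alcohol at all; only if it does is the peak of the digital signal mapped
through a linear calibration.

## The signal model behind the simulator

No public raw traces exist for this class of device, so the package ships a
simulator (`generate_trace()`, `generate_dataset()`) whose defaults define
the study conditions used throughout the tests: ten wet-bath concentrations
(0, 4, 10, 20, 30, 40, 50, 100, 150, 200 mcg/100 mL), twenty trials each,
readings sampled every 50 ms, traces of 60 samples (3 s).

The response shape is a design choice of this package, constrained by the
qualitative behavior of the real sensor: the digital output reacts within
200 ms of releasing the sampling pump, higher concentrations take longer to
reach their peak, and within the first 1.5 s the signal peaks and begins a
downtrend toward baseline. We model the noiseless response as a saturating
exponential rise (time constant `rise_tau_ms = 60` ms), normalized to hit
the full amplitude exactly at a concentration-dependent time-to-peak
(`200 + 4 * concentration` ms, snapped to the 50 ms grid, i.e. ~200 ms near
zero up to ~1.4 s at the 300 mcg/100 mL sensor ceiling), followed by an
exponential decay (`decay_rate = 3e-4` per ms). The amplitude is the
sensitivity mapped through the ADC step, so a noiseless trace at
concentration $c$ peaks at exactly $\mathrm{round}(13c/4.8242)$ counts
above baseline — 135 counts at 50 mcg/100 mL.

The normalized-rise form was chosen over a linear ramp deliberately: with a
linear ramp to a late peak, the first ten readings of a high-concentration
trace would all differ and sit well below the maximum, and the plateau rule
of the classifier (below) would wrongly reject genuine samples. The
saturating rise reproduces what the real cell does — near-immediate
response, with the exact integer maximum arriving later at higher
concentrations.

Noise is additive integer noise, uniform on ±1 count by default.
Alcohol-free samples additionally get a short pump-actuation bump, a
Gaussian transient of 2 counts centered at 100 ms. Its size is set so that
clean samples look like the real device's clean samples: a slight
above-baseline wiggle that every one of the four zero rules is designed to
catch.

What the simulator does *not* emulate: electrode degradation and long-term
drift, temperature and humidity effects, inter-sensor variation, breath
dynamics (the 5 s chamber feed and 0.35 mL pump draw are represented only
by the trace's time origin), and any amplification nonlinearity. Passing
tests on synthetic data therefore demonstrate that the algorithm is
implemented correctly and is self-consistent — not that the specific
accuracy figures would transfer to a physical sensor.

## Features and the four-rule zero classifier

All features come from the first 30 readings (0–1500 ms), the area of
interest containing the peak and the start of the downtrend
(`extract_features()`): the mode of the first 10 readings (`mode10`), the
maximum and minimum over 30 (`max30`, `min30`), the means over 20 and 30
readings (`avg20`, `avg30`), and the two differences `max30 - avg20`,
`max30 - avg30`. Averages are kept at full precision. When several values
are equally frequent in the first ten readings the *largest* is taken as
the mode: the classifier uses the closeness of `mode10` to `max30` to
detect a genuine peak plateau, and the largest modal value is the choice
least likely to reject a true positive; any fixed tie-break would do, but
it must be fixed and documented.

`classify_zero()` applies four rules in order, stopping at the first match:

1. `max30 == 0` — the signal never moved;
2. `mode10 == 0` — the early readings are dominated by baseline;
3. `mode10 / max30 < 0.8` — an isolated spike with no supporting plateau
   (a genuine response fluctuates near its peak during the first ten
   readings, so the ratio is close to 1);
4. `max30 - avg20 < 1` count — the "peak" never separates from the early
   average, i.e. plain electrical noise.

Rules 3 and 4 use strict inequalities; exact equality falls through. The
boundary cases (ratio exactly 0.8, difference exactly 1) are not observable
in integer-noise data at any realistic rate, but the convention is fixed so
the decision is total: for every feature vector exactly one of the five
branches (four rules or quantification) fires.

## Calibration and prediction

For each training concentration the `max30` peaks are averaged across
trials (`calibration_points()`), and concentration is regressed on the
averaged peak by ordinary least squares (`fit_calibration()`, via
`stats::lm`). Averaging before fitting keeps any single calibration point
from biasing the line. The zero point is excluded by default: alcohol-free
samples never reach the regression (the classifier intercepts them), and
keeping the zero point would bend the line in a region it is never used.
Predictions clamp to the physical range [0, 300] mcg/100 mL — negative
extrapolations read as zero and the sensor cannot resolve beyond its
ceiling. Single-point calibration is available as
`fit_calibration(points[i, , drop = FALSE], ...)` degenerates deliberately:
the function requires two distinct peaks, which documents why the
peak-averaged multi-point design is the default rather than an option.

## Validation metrics

`evaluate_group()` mirrors one row of a device validation table: the mean
prediction, the trial-averaged accuracy, MSE, MAE, RMSE, the sample SD of
the predictions and the relative standard deviation (RSD, 100·SD/mean).
Accuracy per trial is `100 - 100 * |actual - predicted| / actual`; the
absolute error is used so over-predictions cannot score above 100%, which
makes the group accuracy identically `100 - 100 * MAE / actual`. At an
actual concentration of zero the relative error is undefined; a prediction
of exactly 0 counts as 100% and anything else as 0%, so the zero group
reports 100% exactly when no false positive occurred. When a group's SD is
exactly zero the RSD is defined as zero even at mean zero (the all-correct
zero group); a single-trial group reports SD and RSD as `NA` since the
sample SD needs two values.

`evaluate_overall()` aggregates *unweighted* across groups: overall
accuracy, MSE and MAE are plain means of the group values, overall RMSE is
the square root of the overall MSE, and R² is computed from the pooled
pairs. Unweighted aggregation is the only rule consistent with the
published overall rows of this device class when group sizes are equal or
nearly so. Presentation rounding (`format_report()`) is half-away-from-zero
at two decimals; all internal computation is full precision.

`split_dataset()` reproduces the 90/10 train/validation design: the
training size is `floor(n * fraction + 0.5)` (half counts round toward
training), the partition is seeded and exact.

## The IoT gateway mock

The physical device talks to a cloud database over cellular HTTP GET
requests: first `get_name?id=<ID>` to fetch the participant's name for
on-screen confirmation, then `insert?id=<ID>&brac=<value>` to store the
measurement. `brac_store()` holds the two tables (participants,
measurements) in memory with JSON persistence; the transport is an abstract
`function(request) -> response` so the protocol logic is testable without
any network — `in_process_transport()` parses the same query strings a
server-side script would. Timestamps are assigned by the store on insert.
`run_session()` is the device's state machine: lookup, confirmation,
quantification, upload; nothing is persisted unless a confirmed lookup
preceded the upload in the same session, and a transport failure aborts as
retryable. Statelessness of the protocol is honored and tested: each
request is independent, so a server restart (store reloaded from disk)
between the two requests changes nothing.

## Numerical choices and problem sizes

- All randomness flows from one integer seed; trace-level seeds are derived
  as `(seed + 7919 * i) mod (2^31 - 1)` so datasets are reproducible
  element-wise and the caller's RNG stream is left untouched.
- Model and config JSON are written with 17 significant digits so doubles
  survive the decimal round-trip bit-exactly.
- The test suite runs the full 10 × 20 design for end-to-end checks and
  smaller 2–5-trial designs for properties iterated many times; oracle
  comparisons (feature extraction vs. brute force, OLS vs. normal
  equations) use 1000 and 25 random cases respectively at tolerances of 0
  and 1e-9.

## Known limitations

- At the lowest nonzero calibration concentration (4 mcg/100 mL, where the
  peak is only ~11 counts) default noise occasionally drives the plateau ratio
  below 0.8 and the trace is misread as zero — the same outlier sensitivity
  the physical device shows at its lowest concentrations. The zero class
  itself is unaffected: no false positives occur under default settings.
- The simulator's amplitude scale is derived from the nominal sensitivity
  and ADC constants; a real amplified sensor may differ by a gain factor,
  which the calibration absorbs but the simulator does not model.
- Accuracy figures computed on synthetic data characterize the algorithm,
  not any physical sensor; drift, recalibration scheduling and
  coulombic-efficiency estimation are out of scope.
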