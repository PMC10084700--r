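---
title: "Detecting parental brooding from multisensor chick-borne dataloggers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parental brooding from multisensor chick-borne dataloggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Precocial chicks such as lapwing chicks feed themselves from hatching but
cannot hold their body temperature on their own for the first weeks of life;
they depend on parental brooding — being pressed against the parent's
abdomen under its feathers. Quantifying when and how efficiently chicks are
brooded requires continuous behavioural records that direct observation
cannot provide. Miniature chick-borne dataloggers recording tri-axial
acceleration (25 Hz), on-body dorsal temperature (1 Hz) and light level
(1 Hz) can: during brooding the chick is still, the dorsal temperature
relaxes toward the parent's body temperature, and the light sensor is
covered. `broodetect` turns such recordings into labelled brooding bouts
and model-ready summary tables, and ships a simulator that generates
recordings with known ground truth so that every stage of the pipeline is
verifiable without field data.

```{r, eval = FALSE}
library(broodetect)

sim <- simulate_chick(sim_config("NL", duration_h = 24, seed = 42))
trace <- preprocess_chick(sim$raw, sim$ambient, sim$chick)
bouts <- detect_brooding(trace, sim$chick, seed = 1)
evaluate_detection(bouts, sim$truth, trace)
```

## Preprocessing: from raw acceleration to a 5-s trace

**Autocalibration.** Accelerometer offset and gain errors are estimated
from static periods, during which the measured vector must lie on the 1 g
gravity sphere. `find_static_windows()` selects 10-s windows whose
per-axis rolling SD is below 0.013 g; `autocalibrate()` then alternates
projecting the static means onto the unit sphere and re-estimating
per-axis gain and offset by least squares until the parameters stop
moving. At least 10 windows spanning at least 3 orientations more than
15° apart are required; otherwise the identity calibration is returned
with `converged = FALSE` rather than an error — field traces of highly
active chicks can lack orientation diversity, and the high-pass filter
downstream removes any residual static offset anyway. On simulated
traces with known distortions the recovery is better than 0.005 g /
0.005 (see `tests/testthat/test-calibrate.R`).

**ODBA.** Per axis, the gravitational component is a 0.2 Hz moving-median
estimate and is subtracted; the dynamic residual is smoothed by a 2 Hz
moving median; overall dynamic body acceleration is the sum of the three
absolute smoothed residuals. A median "cut-off frequency" `fc` is mapped
to a centred window of `round(fs / fc)` samples, forced odd (125 samples
at 0.2 Hz, 13 at 2 Hz at 25 Hz sampling): a median over a window of
duration `1/fc` suppresses variation faster than `fc` while preserving
edges, which is the property wanted here. Two numerical consequences are
worth knowing: the chain output is exactly zero for any motionless trace
(median of constants), and a sinusoid above the low-pass cut-off is
annihilated outright rather than attenuated smoothly — a 5 Hz sine at
25 Hz sampling has period 5 samples, and the median of 13 samples of a
5-sample-periodic signal is identically its central value pattern, which
sums to zero dynamic output. Below the cut-off roughly half of the mean
rectified amplitude passes. Edge windows are truncated (no reflection
padding, no invented values); the 30-min edge trim removes them anyway.

**Aggregation.** ODBA, temperature and light are averaged over 5-s bins
anchored at the deployment start; ambient temperature is interpolated to
bin centres from the site series (bins inside ambient gaps longer than
1 h stay missing, with a warning); sun elevation at bin centres comes
from a NOAA-style low-precision solar ephemeris (accuracy well within
±0.5°, verified against closed-form solstice/equinox geometry). The
first and last 30 min of every deployment are cut to exclude handling
disturbance.

## Segmentation: a per-chick two-state HMM

The 5-s ODBA series is segmented into "active" and "non-active" by an
unsupervised two-state hidden Markov model fitted separately for each
chick — individuals differ in logger placement and behaviour, so no
pooling is done. The emission model is a univariate Gaussian on
`log(ODBA + 1e-4 g)`: ODBA is strongly right-skewed with near-zero
values during rest, and the log transform turns the two activity regimes
into roughly symmetric modes; the offset keeps exact zeros finite and is
far below the rest-state ODBA scale. Fitting is Baum–Welch with a
deterministic initialisation (state means at the 20th/80th percentiles
of the series, both SDs at the overall SD, self-transition 0.95,
convergence when the log-likelihood gain drops below 1e-6, cap 200
iterations), so a fit is reproducible without any seed; the `seed`
argument only drives a single fallback re-initialisation used when a
state collapses below 1% occupancy, and a second collapse is reported as
"no two-state structure" rather than silently accepted. The state with
the lower emission mean is labelled non-active, which makes the
labelling invariant to state order. Decoding is exact Viterbi (C++ core,
ties broken toward the non-active state deterministically); maximal
non-active runs become candidate bouts.

## From candidate bouts to brooding: the rule chain

Low activity is necessary but not sufficient for brooding — chicks also
rest in plant shade and in the open. Three rules, applied by
`run_postprocess()`:

1. **Daylight 50 lx rule.** A candidate bout that overlaps daylight (any
   bin with sun elevation ≥ −6°) is kept only if at least one of its 5-s
   bins has mean light below 50 lx; otherwise it becomes
   `other_inactive`. Bouts entirely within civil-twilight night are
   exempt (light is uninformative at night). The "at least one bin"
   quantification is the weakest reading of "dark for at least part of
   the bout" and is configurable (`min_dark_bins`). Shade under plants
   is far brighter than 50 lx, so this rule removes the shade confounder
   by construction; shading by the parent's body without abdominal
   contact is not distinguishable this way and is deliberately counted
   as not-brooding, matching the contact-based definition of brooding.

2. **Temperature-guided boundary adjustment.** Chicks often fall still
   shortly before contact and resume activity around departure, so
   activity-defined bout edges can be off by a few bins. Per chick, the
   medians of consecutive-bin dorsal-temperature differences are pooled
   within brooding-labelled and active-labelled bins (at least 10
   difference values each, else the adjustment is skipped with a
   warning). Each bout start moves to the earliest bin — in a window
   from the midpoint of the preceding interval (capped at `search_s`,
   default 600 s) to the bout midpoint — whose temperature difference
   exceeds `max(median_brooding_diff, 0.05 °C/bin)`; the bout end moves
   to the first cooling onset after the bout, up to the midpoint of the
   following interval. The 0.05 °C/bin magnitude floor
   (`min_adjust_diff`) is essential: the brooding-difference median is
   near zero whenever bouts are mostly thermally stable, and without the
   floor sensor noise (±0.01 °C/bin here) and diel ambient drift (up to
   ~0.03 °C/bin) would let almost half of all pre-bout bins qualify,
   dragging every start to the window edge. Warming at parental contact
   (several tenths of a degree per bin for a cold chick) clears the
   floor easily; when nothing does — e.g. hot-ambient brooding, where
   contact cools the logger — the boundary is simply left where the HMM
   put it. The direction of the break rule is ambiguous in principle
   (cooling marks departure under the default `"falls_below"`; the
   mirrored `"rises_above"` is available as a config switch).

3. **20-s pruning.** Breaks in brooding of up to 20 s (inclusive) are
   merged into the surrounding bout, then brooding bouts of up to 20 s
   are relabelled to their flanking state; both repeat to a fixed point,
   merges first. Such events are typically position shifts during an
   uninterrupted bout.

The whole chain is iterated to a fixed point (bounded at 20 passes):
boundary moves change which bins feed the temperature statistics, so a
single pass is not idempotent, while the fixed point is — re-running
`run_postprocess()` on its own output changes nothing, which the tests
assert. Instead of a manual inspection pass, `qc_report()` lists
brooding bouts whose post-stabilisation temperature never rises above
ambient for human review; nothing is auto-corrected.

Chicks whose starting or ending mass reaches 65 g are flagged
(`flag_feathered()`): by then feathers cover the light sensor and
daytime brooding becomes undetectable, so flagged chicks should be
excluded from summaries.

## Summary tables

`hourly_table()` emits one row per local clock hour: brooded and
non-brooded minutes (exact fractional interval coverage, so bout
boundaries are never double-counted; integer rounding is an export
option), the previous hour's brooding proportion (to absorb temporal
autocorrelation), the night flag at the hour midpoint, mean ambient
temperature, the sine/cosine diel transform of clock time
(`2*pi*h/24`), the chick's head length (an age proxy) and a
`sqrt(minutes observed)` weight for partial hours. Clock hours in local
standard time (UTC+1 for the temperate site, UTC+4 for the desert site,
no DST) are used rather than deployment-relative hours, because time of
day is the biologically meaningful predictor. `efficiency_table()`
gives one row per brooding bout longer than 5 min with the median
dorsal temperature after the first 5 min — the on-body temperature
relaxes toward its equilibrium with a time constant of ~2 min, so the
5-min exclusion removes the transient. `ztransform()` (n−1 SD,
constants retained) prepares numeric predictors. Mixed-model fitting
itself is intentionally out of scope: the tables are schema-stable
inputs for `lme4`-style models downstream.

## The simulator: what it emulates, and what it does not

`simulate_chick()` generates: a diel ambient sinusoid (mean 15 °C,
amplitude 8 °C for the temperate preset; 32 °C/8 °C for the desert
preset — plausible testing values, not field estimates) with AR(1)
noise; an alternating semi-Markov behaviour sequence in which each rest
is brooding with probability
`plogis(0.5 − 0.12·(T_amb − 20) + 2.2·night)` and non-brooding daytime
rests fall under plant shade with probability 0.7; lognormal bout
durations (medians 15 min brooding, 10 min foraging, 8 min shade-rest,
5 min other rest); first-order dorsal-temperature relaxation
`dT/dt = (T_target − T)/τ` with τ = 120 s — so the temperature
stabilises well inside the 5-min efficiency window — toward 37.2 °C
(temperate preset) or 35.0 °C (desert preset) during brooding and
ambient + 1 °C otherwise; light that is log-uniform 10⁴–10⁵ lx
clear-sky scaled by sun elevation with a twilight floor, 200–2000 lx
under shade, below 20 lx during brooding and ~0 at night — so the
50 lx rule is informative by construction; and acceleration as a
per-bout random gravity orientation plus AR(1) band-limited dynamic
noise (0.15 g per axis active, 0.006 g at rest), distorted by a
configurable gain/offset miscalibration. The night effect of +2.2 keeps
night rests predominantly brooding, mirroring the high overnight
brooding rates of real lapwings. All randomness derives from the config
seed; identical configs give byte-identical output.

What the simulator does **not** emulate — and hence what passing
recovery tests cannot certify on real data: sensor dropouts and clock
drift, behavioural states beyond the four modelled ones, gradual feather
growth, within-family behavioural correlation, weather (cloud, rain)
light variation, and the ~1% of time that needed manual correction in
real deployments. Recovery numbers on the synthetic cohort (balanced
accuracy, bout F1, rate error) are upper bounds on field performance,
not estimates of it.

## Verification sizes and numerical choices

The test suite and the acceptance script verify, per run: exact
agreement of the Viterbi decoder with exhaustive path enumeration (50
random instances, T ≤ 12); non-decreasing Baum–Welch log-likelihood (20
datasets); equality of the ODBA chain with a naive brute-force
implementation to 1e-10 g (20 one-minute traces) and exact zeros for
motionless traces; calibration recovery within 0.005 from 50 random
distortions; detection recovery on a cohort of 10 chicks × 48 h (five
per species preset) — per-chick balanced accuracy ≥ 0.90, bout-level F1
at 50% overlap ≥ 0.85, median per-chick rate error ≤ 3 percentage
points; shade-scenario rejection (< 5% of shade time classified
brooding); efficiency recovery within 0.5 °C of the configured
equilibria; the post-processing invariants (no bout or gap ≤ 20 s,
daylight bouts contain a dark bin, light-rule monotonicity,
idempotence); and summary conservation (hourly minutes sum to total
brooding time; sin² + cos² = 1). The cohort size was chosen so the whole
verification runs in a few minutes on one CPU while still spanning both
presets and day/night regimes.

Other numerical details: interval endpoints are seconds since
deployment start (doubles; absolute time enters only through the
deployment start timestamp, the single conversion point for the solar
ephemeris); bins are half-open `[t, t+5)`; bout tables are validated
partitions (sorted, non-overlapping, positive length); missing slow
samples propagate as `NA` and are never zero-filled; logger clock drift
is assumed negligible over deployments of a few days.

## Interfaces

The package's functions, this vignette and the verification script are
the interface; no shell entry point is shipped, since every step is a
one-line R call on tabular data. All thresholds (50 lx, 20 s, 5 min,
−6°, filter cut-offs, 65 g) live in `brood_config()`, with YAML
round-tripping via `read_config()`/`write_config()` for
archivable analyses.
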