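# broodetect

Detection of parental brooding in precocial chicks from chick-borne
multisensor dataloggers.

Lapwing chicks (and precocial shorebird chicks generally) feed themselves
from hatching but cannot thermoregulate for their first weeks; they rely on
parental brooding — being pressed against the parent's abdomen under its
feathers. `broodetect` reconstructs when a chick was brooded from a
body-mounted logger recording tri-axial acceleration (25 Hz), dorsal
on-body temperature (1 Hz) and light level (1 Hz), exploiting three
signatures of brooding: low activity, dorsal temperature converging toward
the parent's body temperature, and a covered light sensor.

The pipeline:

1. **Preprocess** — sphere-fit autocalibration of the accelerometer from
   static windows; overall dynamic body acceleration
   ODBA = |a_x^dyn| + |a_y^dyn| + |a_z^dyn| with a 0.2 Hz median high-pass
   and 2 Hz median low-pass; aggregation to 5-s bins joined with ambient
   temperature and sun elevation; 30-min edge trim.
2. **Segment** — per chick, an unsupervised two-state Gaussian hidden
   Markov model on log(ODBA + ε), fitted by Baum–Welch and decoded by
   Viterbi, splits the series into active / non-active.
3. **Post-process** — non-active candidates become brooding bouts via a
   rule chain: daylight bouts must contain a 5-s bin below 50 lx
   (rejecting rest in plant shade), bout boundaries shift to
   temperature-change onsets (warming at contact, cooling at departure),
   and bouts or gaps up to 20 s are pruned, iterated to a fixed point.
4. **Summarise** — hourly brooding-rate and brooding-efficiency tables
   ready for mixed-model analysis, overall rates, and actogram plots.

A synthetic-data module (`sim_config()`, `simulate_chick()`,
`simulate_cohort()`) generates full multichannel recordings with
ground-truth behavioural states — diel ambient cycle, semi-Markov
behaviour, first-order thermal relaxation toward a species-specific
brooding equilibrium, sun-driven light with a plant-shade confounder —
so detection accuracy is measurable (`evaluate_detection()`).

## Worked example

```r
library(broodetect)

sim   <- simulate_chick(sim_config("NL", duration_h = 24, seed = 42))
trace <- preprocess_chick(sim$raw, sim$ambient, sim$chick)
bouts <- detect_brooding(trace, sim$chick, seed = 1)

attr(bouts, "hmm")
#> <brood_hmm> 2 states on log(ODBA + 0.0001), 16560 bins, 4 EM iterations, loglik 8560.12
#>   nonactive: mean -4.791 sd 0.133 (occupancy 0.55); active: mean -1.587 sd 0.146 (occupancy 0.45)

evaluate_detection(bouts, sim$truth, trace)[, c("balanced_accuracy", "bout_f1", "rate_error")]
#>   balanced_accuracy bout_f1 rate_error
#> 1            0.9914  0.9425     0.0085

eff <- efficiency_table(bouts, trace, sim$chick)
sprintf("%d bouts > 5 min, median %.1f degC", nrow(eff), median(eff$median_temp))
#> "41 bouts > 5 min, median 37.1 degC"

overall_rate(bouts, trace)$median
#> [1] 0.4852
```

The two emission modes are the resting and active ODBA regimes on the log
scale; balanced accuracy and bout-level F1 compare the detected bouts with
the simulator's ground truth on the 5-s grid; the efficiency median
recovers the configured 37.2 °C brooding equilibrium of the Northern
lapwing preset (first 5 min of each bout excluded while the dorsal
temperature stabilises); the brooding rate is the proportion of observed
time labelled brooding (true value here: 47.7%).

`plot_actogram(trace, bouts)` draws the five-channel actogram (ODBA,
on-body and ambient temperature, light, sun elevation) with detected
brooding shaded.

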