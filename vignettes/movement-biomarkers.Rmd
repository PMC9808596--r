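---
title: "Movement-velocity biomarkers from VR wearable sensors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-velocity biomarkers from VR wearable sensors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionmark)
```

## The problem

Chronic low back pain is commonly accompanied by kinesiophobia — fear of
movement and re-injury — and one target of rehabilitation is the
restoration of movement. A VR rehabilitation program delivered over
roughly 30 daily sessions produces, as a side effect of treatment, a
dense record of how each participant moves: the head-mounted display and
both hand controllers report 3D position at about 30 Hz, partitioned
into software-tagged segments. This package turns those streams into a
per-participant movement-velocity change score, extracts a phasic
electrodermal peak statistic and weekly activity trends from companion
wrist/palm wearables, and correlates the movement change with changes in
clinical endpoints: the Tampa Scale of Kinesiophobia (TSK, 17 items,
higher = more fear), the EQ-5D overall-health VAS (0–100, higher =
better) and the EQ-5D-5L summed index (higher = more problems).

Because no raw trial data are public, the package carries (a) a
synthetic-cohort generator with known ground truth, so every stage is
testable by parameter recovery, and (b) the published 12-participant
table of change scores, from which the published correlation matrices
are recomputed exactly.

## Movement velocity

For consecutive samples of one sensor, the speed at a timepoint is

$$v = \frac{\sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}}{\Delta t}\ \ \mathrm{(m/s)},$$

aggregated to the arithmetic mean per segment (`point_velocities()`,
`segment_mean_velocity()`). Two data-cleaning rules apply, both counted
and surfaced, never silent:

* **Gap threshold** (default 0.5 s, vs a nominal 1/30 s interval): a
  consecutive pair farther apart than this is skipped. Segments that end
  abnormally (headset switched off, software fault) otherwise contribute
  one enormous $\Delta t$ with a near-zero velocity that poisons the
  segment mean.
* **Velocity cap** (default off; 10 m/s is a reasonable setting):
  non-natural movement such as a dropped controller produces speeds no
  trunk or arm movement can reach. The cap is exposed as configuration
  because no principled universal constant exists; drops are logged.

Segments are classified from the software metadata tags into `action`
(a task was active) and task-free segments, the latter subdivided by
position within the study day: before the first action segment
(`start_of_day`), after the last (`end_of_day`), otherwise (`between`)
(`classify_segment_context()`). The distribution of segment velocities
by class (`velocity_by_class_summary()`) is the validity check for the
segmentation: action segments should be visibly faster.

Each participant's progression is summarized per sensor by ordinary
least squares of action-segment mean velocity on the 1-based VR
study-day ordinal, one observation per action segment
(`fit_daily_slope()`). Design choices made where the design was open:

* **One observation per segment, not per day-average** — the segment is
  the natural experimental unit and day averages would hide within-day
  variance.
* **Study-day ordinal, not calendar time** — sessions can span or skip
  calendar days; the ordinal is the treatment's own clock, and the fit
  is understood as a proxy for progression, not a growth model.
* **Unweighted OLS, linear trend only** — a single interpretable
  direction-of-change measure; duration weighting and nonlinear trends
  are deliberately out of scope.

The study-scale change is `slope * vr_study_day_count` (m/s over the
study), the movement analogue of a clinical change-from-baseline. The
day count is the participant's own number of distinct VR study days.

## Electrodermal phasic peaks

Skin conductance (4 Hz, microsiemens) is conventionally separated into
a slow tonic level and fast phasic fluctuations. The package isolates
the phasic part by first differencing, $\Delta_i = x_i - x_{i-1}$
(`phasic_differences()`), which removes any constant level exactly and
turns a linear tonic trend into a constant. Peaks are differenced
values strictly above a per-segment robust band,

$$\mathrm{threshold} = \mathrm{median}(\Delta) + 2\,\mathrm{MAD}(\Delta),
\qquad \mathrm{MAD}(x) = \mathrm{median}\,|x_i - \mathrm{median}(x)|,$$

normalized by segment duration (from timestamps, robust to dropped
samples) to peaks/minute (`count_peaks()`). Choices:

* **Median-anchored band.** A band of $2\,\mathrm{MAD}$ alone (without
  the median anchor) is also defensible; it is exposed as
  `band = "mad_only"`. The anchored band is the default because it is
  the one consistent with treating peaks as upper outliers of the
  $\Delta$ distribution.
* **Per-segment band** — the robust statistics range over one segment,
  matching the per-segment peak count.
* **Strict inequality, upper side only** — a peak is a rise, and ties
  at the threshold are not "higher than" it.
* **MAD without a consistency constant** — the band is defined in MAD
  units directly; it is not being used as a standard-deviation
  estimate.
* **Degenerate band**: if more than half the deltas are identical the
  MAD is 0 and the band collapses to the median; the segment is still
  counted but flagged (`degenerate_band`).

Active-arm sessions begin with preparation time before the first task;
those start-of-day segments are removed (`filter_start_of_day()`) so the
active phase is compared against the sham arm, whose sessions are
treated as entirely task-free. Per-participant peaks/minute
distributions are summarized and ordered by median
(`arm_peak_summary()`).

## Activity trends

Daily step counts are aggregated to study weeks
(`ceiling(study_day / 7)`, aligned to randomization rather than the
calendar, so arms are aligned on study time) and expressed as change
from each participant's week-1 mean (`weekly_step_changes()`); week-1
change is 0 by construction, and week means use only the days present.
Trend estimation (`participant_step_trends()`) is deliberately
two-stage: a per-participant OLS line of steps on study day, then
per-arm mean/sd of slopes and pairwise between-arm differences. A
mixed-effects model would be the obvious alternative; the two-stage
version was chosen because it is fully specified, directly testable by
parameter recovery, and keeps "each participant has their own line"
explicit. Heart rate and sleep are ingested and described only
(`activity_descriptives()`): daytime-aggregated heart rate is too
coarse for meaningful modeling.

## Correlating movement change with clinical change

Clinical change scores are end-of-treatment minus baseline
(`clinical_changes()`). The six change variables (three clinical, three
sensors) are correlated pairwise with **listwise deletion** — a
participant missing any of the six is dropped from the matrix entirely —
by both Pearson (product-moment on raw values) and Spearman (the same
computation on midranks, ties averaged) (`correlation_matrix()`).
Matrices keep full precision internally and are reported at 2 decimals
(`report_matrix()`). No p-values are attached: with n = 11 the
correlations are exploratory, and the robustness device is instead
`robustness_compare()`, which recomputes the matrix with and without
flagged participants (here the one participant with roughly a third of
the study days) and tabulates per-cell differences.

### Reproduction notes for the published matrices

The packaged change table prints movement changes at 3 decimals, which
creates one artifact the unrounded trial data did not have: two
participants tie at a head change of 0.046. With midranks this shifts
the head-sensor Spearman cells by up to 0.021 from the published values
(−0.45, 0.67, −0.66); breaking the tie in the direction the unrounded
data must have had reproduces all three printed cells exactly at
2 decimals. The same rounding moves the Pearson head-vs-VAS cell to
0.5554, one rounding step above the printed 0.55. All other published
cells are reproduced exactly at 2 decimals from the packaged table. The
acceptance tests assert exactly this state of affairs, including the
tie-break recomputation.

A related printed-precision note: a published example states a right-hand
slope of 0.0031 with a change of 0.095 m/s over 30 days, while
0.0031 × 30 = 0.093 — the published change was evidently computed from
the unrounded slope. The package always computes changes from unrounded
slopes.

## The synthetic cohort

`cohort_spec()` fixes the study conditions; all four generators are
fully deterministic given the spec, with independent sub-seeds per
stream. Defaults: 12 active-arm participants, 30 study days, 10 action
+ 3 task-free segments/day, 60 s segments, 30 Hz motion and 4 Hz EDA,
17 sham and 10 standard-care participants for the streams that use
those arms.

**Motion.** Participant $p$ carries a latent daily improvement
$\beta_p \sim N(0.003, 0.002^2)$ m/s per day, shared across sensors;
the latent action-level mean for sensor $s$ on day $d$ is
$v_0(s) + \beta_p d$ with baselines 0.5/0.7/0.8 m/s (head/left/right),
chosen as plausible magnitudes for head and hand movement in seated and
standing VR tasks and deliberately ordered so the dominant hand moves
most. Segment targets scatter around the latent mean (sd 0.05 m/s);
task-free segments use the latent mean divided by the action ratio
(default 2). Trajectories are random walks whose per-step displacement
is exactly `target / rate` in a uniformly random 3D direction: only
speed statistics matter downstream, so this is the simplest generator
that realizes them — and it realizes each segment's average velocity
*exactly*, which has two consequences used throughout the tests: the
noise-free cohort must be recovered to floating-point accuracy, and
slope estimation on segment-mean draws is literally the same computation
as on full trajectories, so Monte-Carlo studies can run on the cheap
layer without changing what is measured.

**Clinical link.** With $z_p$ the cohort-standardized latent change
$\beta_p \times$ days and $\rho$ the configured link strength, each
endpoint change is
$\mathrm{center} + \mathrm{scale}\,(s\,\rho\,z_p + \sqrt{1-\rho^2}\,\varepsilon_p)$,
$\varepsilon_p \sim N(0,1)$, with signs $s$ negative for TSK and the
EQ-5D index and positive for the VAS, then rounded to whole scale
points. Centers (−6, 20, −2) and scales (5, 25, 3) match the order of
magnitude of the published change table. The dial $\rho$ is what the
correlation stage must recover; integer rounding attenuates it by well
under 0.01 at these scales.

**Electrodermal.** Each segment is a slow tonic component plus sparse
phasic pulses (Poisson arrivals at the arm's configured rate, default
3/min active vs 1.5/min sham; instantaneous rise of 0.3 µS, exponential
decay with a 2 s constant) plus white noise. The tonic is a sinusoidal
wave (amplitude 0.4–0.8 µS, period 15–30 s, random phase per segment)
plus a small random walk. The wave, rather than a random walk alone, is
a deliberate choice: a median + 2·MAD band applied to *Gaussian*
differenced background flags a fixed ≈ 9% of samples regardless of the
noise scale (the Gaussian tail above 1.35σ), which would swamp any
sparse pulse signal; the differenced wave, by contrast, is bounded with
a maximum below the band, so peaks above the band are genuinely the
injected pulses. White noise and drift default to 5×10⁻⁴ µS per
sample — the order of the recording device's resolution — keeping the
background bounded in practice. With these defaults the detector
recovers injected pulse rates to within a few percent.

**Activity.** Daily steps are baseline (6000) plus the arm's weekly
trend accrued per day (default +200 steps/week active, 0 elsewhere)
plus Gaussian noise (sd 800), truncated at zero and rounded.

### What the generator does not emulate

No biomechanics or task structure (movements are direction-free random
walks), no physiological skin-conductance model (pulses are a shape, not
sudomotor activity), no wear-time gaps, day-level missingness or device
dropout beyond what the cleaning rules are tested with directly, and no
heavy-tailed artifact structure such as controller drops (the cap rule
is tested with constructed outliers instead). Passing recovery tests
therefore demonstrates that the *estimators* are correct and unbiased
under the assumed data-generating structure — not that the pipeline is
robust to every failure mode of real wearable data.

## Numerical choices and degenerate inputs

* Segments with fewer than two usable samples, or participant series
  with fewer than two action segments or a single study day, are
  excluded with counts/warnings, never silently and never fatally.
* Correlation matrices require at least 3 complete rows; zero-variance
  columns yield flagged `NA` entries.
* Timestamps must strictly increase within a segment; parsers never
  reorder samples. Malformed records are skipped and counted;
  structurally broken lines abort with a line number.
* Medians (and hence MADs) use the midpoint convention on even lengths.
* CSV writers emit doubles at 17 significant digits so that a
  write-then-read round trip is bit-exact and file-based and in-memory
  pipeline routes produce identical outputs.

## Problem sizes

The trial recorded over a million motion samples per participant. The
test suite and the analysis drivers use desk-scale cohorts instead —
the same 12 participants × 30 days × 13 segments/day structure with 2 s
segments, and minutes-scale EDA segments — because the exact-realization
property above makes segment duration irrelevant to every estimator
downstream. Monte-Carlo checks use 200 replicates for slope bias
(12 × 30 at default noise) and clinical-link recovery (n = 50,
ρ = 0.6), 100 replicates for the step-trend contrast, and 50
five-minute segments for pulse-rate recovery.

## Known limitations

* The linear slope is a crude summary of progression; phases of
  improvement within the study are invisible to it.
* The record-stream schema is repo-defined; it is a documented stand-in,
  not a reconstruction of any vendor export.
* Spearman cells recomputed from a rounded change table can differ from
  values computed on unrounded data when rounding creates rank ties (see
  the reproduction notes above).
* The between-arm activity contrast is a two-stage summary, not an
  inferential mixed model; it describes, it does not test.
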