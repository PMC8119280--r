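---
title: "Models and methods behind stairbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stairbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairbold)
```

`stairbold` simulates and analyses near-threshold visual detection
experiments of the kind run in event-related fMRI studies of visual
consciousness: a yes/no detection task whose stimulus duration is driven
by two interleaved adaptive staircases, a trial-classification rule that
identifies the at-threshold period, and the group-level behavioral and
voxelwise imaging statistics built on top of it.  This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic generators do and do not emulate.

## The observer model

A simulated participant is a parametric psychometric responder.  The
probability of reporting a grating of duration $d$ (ms) as seen is

$$p(\mathrm{yes} \mid d) \;=\; \gamma + (1 - \gamma - \lambda)\,
F\!\left(\frac{d - \theta}{\sigma}\right),$$

with threshold $\theta$ (`threshold_ms`, the duration of 50% detection
for the sigmoid term), spread $\sigma$ (`slope_ms`), guess rate $\gamma$
(probability of "yes" on a blank) and lapse rate $\lambda$ (probability
of "no" on an arbitrarily strong stimulus).  $F$ is a logistic sigmoid
by default (`family = "cnorm"` gives a cumulative normal); both satisfy
$F(0) = 0.5$, so $p(\mathrm{yes} \mid \theta)$ is exactly the midpoint
of the asymptotes.  Catch-trial behavior is governed by two further
rates: `catch_miss_rate` (a "no" on the full-contrast positive control)
and `no_response_rate` (no button press at all, drawn before the
psychometric decision).

Defaults ($\lambda = 0.02$, $\gamma = 0.05$, catch-miss $0.01$,
no-response $0.01$) are small, consistent with detection experiments in
which control-trial errors are negligible.  Published reports of this paradigm do not include psychometric slopes
or lapse behavior, so these are generator conveniences, not population
estimates; the cohort generator uses a
common slope of 6 ms.

## The adaptive session

One session has 60 trials: 48 staircase trials split evenly over two
descending staircases that are interleaved uniformly at random, plus 6
blank negative controls and 6 full-contrast (400 ms) positive controls
at positions drawn without replacement.  Durations are quantised to the
display refresh period (1000/75 ms for the 75 Hz scanner projector;
configurable for an 85 Hz training monitor) and stored internally as
integer refresh units.  Both staircases start at 400 ms (30 units).
Until a staircase's first response inversion, a "yes" lowers its
duration by the opening step of 70 ms, rounded to whole refresh periods
(5 units at 75 Hz).  The first "no" is the inversion; from that response
onward "yes"/"no" move the duration down/up by one refresh period — the
1-up/1-down regime whose fixed point is the 50% detection duration.
Durations are floored at one refresh period, and trials without a
response leave the staircase untouched.

Two readings of the opening rule were possible: the inversion response
itself could step by the opening 70 ms or by one refresh unit.  We step
it by one refresh unit.  Stepping back by the large step would fling the
staircase far above threshold after the (typical) overshoot of the
opening descent, producing long runs of seen trials and pushing the
at-threshold detection rate well away from its 50% target, which defeats
the design's stated purpose; the small step keeps the staircase in the
tracking regime from the first reversal on.  Similarly, the opening
phase is per staircase (each staircase keeps its 70 ms steps until its
own first inversion), since an inversion is undefined for a staircase
that has not yet reversed.

The event-related timeline gives every trial a constant wall-clock
length: a cue sound opens the trial, the stimulus onsets 550 ms plus a
uniform jitter in [0, 1100] ms later, the response sound plays at a
fixed offset (the post-stimulus interval absorbs jitter and stimulus
duration), and a 13.56 s fixation interval lets the hemodynamic
response relax between trials.

A note on arithmetic: with the per-trial constants above, 60 trials
occupy slightly more than the 304 volumes x 3 s of the default
acquisition geometry.  The printed acquisition length and the printed
trial timing are not mutually consistent at the second level; the
pipeline therefore sizes each simulated run from the generated timeline
(dummies + the session end + a 20 s hemodynamic tail) unless an explicit
volume count is configured, while `bold_geometry()` keeps the canonical
304-volume default.

## Trial classification and the detection threshold

For each staircase independently, an ordinary least-squares line is
fitted to every set of five consecutive staircase trials (sliding
windows, stride 1; a disjoint tiling is available as
`mode = "disjoint"` for sensitivity analysis).  A trial is *at
threshold* when at least one window covering it has zero slope.
Because durations are integer refresh units, a zero slope is attainable
exactly; the comparison uses an absolute guard of $10^{-9}$ units/trial
against floating-point dust only.  Categories follow from the
at-threshold flag and the response: seen/unseen at threshold (ST/UT),
seen/unseen not at threshold (SNT/UNT, with seen positive controls in
SNT), and other trials (OT: negative controls, missed positive
controls, and trials without a response).  The visual detection
threshold is the mean stimulus duration over ST and UT trials; a
session with no at-threshold trial returns `NA` with a warning rather
than a silent zero, and such subjects are excluded (and logged) by the
group stage.

Under the default cohort conditions the estimator recovers generative
thresholds across 20–70 ms to within a few milliseconds (well under one
refresh period) and is monotone in the generative threshold; the
package's acceptance tests measure this.  One behavior worth knowing:
the opening descent usually overshoots the threshold down to the
one-refresh floor, and the climb back contributes "no" responses, so
the realized post-inversion yes-rate sits slightly below the nominal
50% (the acceptance suite measures ~48% for a symmetric zero-lapse
observer at a 35 ms threshold — compare the published at-threshold
trial counts this design produced in practice, 14.1 seen vs 15.5
unseen, an implied 47.6%).

## Group behavioral statistics

Group comparisons use the classic pooled-variance two-sample Student
$t$ with $n_1 + n_2 - 2$ degrees of freedom.  `pooled_t()` accepts raw
per-subject vectors or printed summaries (mean, sd, n) — the latter
makes a published $t$ recomputable from its descriptives, which the
acceptance tests exercise against reported values.  The
pooled (not Welch) form is identified by the printed df
($32 = 19 + 15 - 2$).  Pearson correlations use the usual $t$-transform
on $n - 2$ df.  Catch-trial summaries report per-group mean ± sd misses
(of 6) and false alarms (of 6).

## Synthetic BOLD and preprocessing

`simulate_bold()` generates, voxel by voxel,

$$y(t) = \mathrm{baseline} + \textstyle\sum_e a_e \, x_{c(e)}(t)
\,[\text{voxel} \in R_e] + \mathrm{drift}(t) + \varepsilon(t),$$

where each effect $e$ plants amplitude $a_e$ times the HRF-convolved
impulse train $x_{c(e)}$ of one trial category in a region $R_e$
(negative amplitudes model deactivations, and effects can be restricted
to one simulated group), drift is a shared linear ramp plus a one-cycle
sinusoid scaled by `drift_amp`, and $\varepsilon$ is an AR(1) process
($\rho =$ `ar1`, default 0.3) driven by white innovations of sd
`white_sd`.  The HRF is a canonical double-gamma (peak 5 s, undershoot
15 s, peak:undershoot 6:1) with events modeled as impulses at stimulus
onset — appropriate for stimuli of at most 400 ms.  With all noise
terms zero the model is exactly linear, which the tests exploit for
machine-precision recovery checks.

`preprocess_bold()` implements the steps with a synthetic counterpart:
dummy-scan discard (default 4, turning a 304-volume run into 300),
temporal high-pass filtering by projecting out whole-run sine/cosine
pairs at frequencies strictly below the cutoff (default 3 cycles/run;
the run mean is kept), and isotropic Gaussian smoothing (default 6 mm
FWHM) with the kernel renormalised inside the mask so constants are
preserved.  Slice-timing, motion correction, coregistration and
stereotactic normalization are real-scanner concerns with no synthetic
counterpart here and are out of scope.

The default simulation grid is a desk-scale 24 x 24 x 18 at the
acquisition's 3.75 x 3.75 x 4 mm resolution rather than the full
scanner matrix; tests use smaller grids still (typically 6–20 voxels a
side) to keep the whole suite under a minute of imaging computation.
These sizes are package choices that preserve the statistics being
tested, whose calibrations are resolution-independent per voxel.

## GLM, group maps, and the mixed ANOVA

The first-level design has one predictor per trial category (ST, UT,
SNT, UNT, OT) — HRF-convolved onset trains sampled at volume times on a
0.1 s microtime grid — plus a constant.  Categories without events
yield all-zero columns that are flagged and dropped before the
voxelwise OLS fit; a rank-deficient design is an error naming the
collinear columns.  Voxels outside the mask carry `NA`, never 0.

Group inference is random effects: per voxel, a one-sample $t$
($n - 1$ df) on subject-level contrast values (e.g. ST−UT, the conscious
access contrast).  Zero between-subject variance with a nonzero mean is
reported as a signed infinite $t$, explicitly, rather than clipped.
Second-level covariates (e.g. medication, symptom scores) enter as
mean-centred regressors with per-covariate $t$ maps.

The whole-brain comparison is a voxelwise two-factor mixed ANOVA:
category (k = 5) within subjects, group between.  The between-group $F$
is tested against the subject-within-group mean square (df $1, n-2$);
condition and interaction share the subject-by-condition error term
(df $k-1,\,(n-g)(k-1)$) — $(1, 32)$ and $(4, 128)$ for 34 subjects.  No
sphericity correction is applied, matching the uncorrected printed dfs.
The implementation is a vectorised sums-of-squares decomposition,
verified voxel-by-voxel against `aov(y ~ group * cond + Error(subj))`
in the tests.

Post-hoc between-group maps are pooled-variance two-sample $t$ maps.
The degrees of freedom attached to such maps are genuinely ambiguous in
the literature this mirrors: a plain two-sample test gives $n - 2 = 32$,
whereas the reported post-hoc threshold this mirrors (df 132)
corresponds to
a cell-level pooled-error convention, $(n-1)(k-1) = 33 \times 4$.
Rather than guess one reading as uniquely correct, `posthoc_group_map()`
exposes both as `df_mode` (`"anova_pooled"`, the default reproducing
132, and `"two_sample"`) and records the mode on the map; the statistic
itself is identical, only the reference distribution for thresholds
changes (two-tailed critical $t$ at $p = 0.01$: 2.61 at df 132, 2.74 at
df 32).

## Monte-Carlo cluster-extent correction

`estimate_min_cluster()` estimates the minimum cluster size controlling
the family-wise error: for each of `n_iter` repetitions (default 1000),
white Gaussian noise is drawn on the grid, smoothed by the analysis
FWHM (the injected spatial correlation), re-standardised to unit
variance within the mask, thresholded two-tailed at the voxel-level
probability (default $p < 0.01$), and the largest suprathreshold
cluster recorded.  The minimum cluster size is the smallest $k$ with
$\Pr(\max \text{cluster} \ge k) \le \alpha$ (default 0.05).  Numerical
choices: connectivity defaults to 26 (vertex-touching), switchable to
18 or 6; thresholding is two-tailed because the maps are signed
(activations and deactivations); when `fwhm_mm = 0` the raw draws are
already standard normal and no re-standardisation is applied, which
keeps the independent-voxel case exactly comparable to an analytic
enumeration oracle (the tests do this on a 2 x 2 x 1 grid).  The null
sample of maximum cluster sizes is kept on the returned rule so that
other alphas can be read off without re-simulation.  Alpha below
`1/n_iter` triggers a warning (the quantile is unreliable there).

Specific reported minimum cluster sizes from real acquisitions depend
on the actual brain mask and smoothness and are not recoverable from
summary tables; the package instead verifies the procedure's calibration —
applying the fitted rule to fresh null maps must yield a family-wise
false-positive rate near $\alpha$ — plus the monotonicities (looser
alpha and stricter voxel threshold both shrink the minimum size).

## ROI analysis

ROIs are the suprathreshold clusters of a group map that survive the
cluster rule, with unweighted centres of gravity and volumes (mirroring
cluster-table conventions).  Subject-level ROI values are unweighted
voxel means of the beta (or contrast) maps — the simplest reading of
"extracting the beta weights" — and groups are compared per ROI with
`pooled_t()`.  `roi_condition_tests()` repeats the comparison per
condition, the decomposition used to attribute a contrast-level group
difference to its seen or unseen component.  One caveat is flagged
rather than fixed: defining ROIs on the pooled population and then
comparing the groups inside them in the same contrast is potentially
circular; the package's simulation tests therefore plant
condition-specific ground truth and verify the dissociation logic on
independent contrasts, and users of the pipeline should interpret the
population-defined ROI table with the same caution.

## Seeds and reproducibility

Every stochastic public operation takes an explicit `seed`; a seeded
call restores the caller's RNG state, so runs are bit-reproducible and
composable.  The pipeline derives per-stage seeds from one master seed
and the stage name, records them in its run log, and writes stage
artifacts (CSV trial logs, JSON summaries, NIfTI maps with JSON
sidecars) so any stage can be re-run from the declared files alone.
Running the default pipeline twice with the same master seed produces
byte-identical reports.

## What the generators do not emulate

Attention fluctuations, reaction times and eye movements on the
behavioral side; physiological noise, motion, distortion and
between-subject anatomical variability on the imaging side.  Passing
tests therefore demonstrate the correctness and calibration of the
estimators under the stated generative model, not robustness to
real-scanner artifacts.  The cohort generator draws true thresholds
from the printed group distributions (HC-like N(35.08, 8.16) ms,
SCZ-like N(52.17, 20.20) ms, truncated below at one refresh period), so
cohort-level checks inherit those study conditions.
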