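---
title: "Methods: cluster-based permutation analysis of multi-method gaze data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-based permutation analysis of multi-method gaze data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeperm)
```

## Scope

`gazeperm` implements the statistical stack used to compare eye-tracking
methods in visual-world-style experiments: infrared trackers and
appearance-based estimators that emit gaze **coordinates**, and manual
frame-by-frame annotation of webcam video that emits gaze **region
labels**. The package covers, end to end:

1. a synthetic multi-method gaze generator with known ground truth,
2. region-of-interest (ROI) binning and binarization of both stream types,
3. per-time-bin binomial-logit mixed models,
4. cluster-mass permutation inference under four label-shuffling schemes,
5. analysis-, cluster- and peak-window effect sizes,
6. smooth-pursuit spatial-offset analysis, and
7. simulation-based power analysis for binary look data.

This vignette explains the models, the default parameters and why they
hold their values, the numerical choices, and what the synthetic data can
and cannot tell you about real recordings.

## Gaze preprocessing

All positions are **screen proportions**: the origin is the top-left
corner, (1, 1) the bottom-right, so y grows downward and results are
independent of screen resolution. `normalize_coordinates()` maps pixels to
this space and flags off-screen points invalid rather than clipping them.

The display is partitioned into a central region and four quadrants.
The central region is a square whose side is 15% of the screen *height*
(`roi_geometry(center_fraction = 0.15)`); because coordinates are
proportions, its x-extent is scaled by `1/aspect_ratio` so the region is
physically square. Quadrants are the four screen quarters minus their
overlap with the central square; every valid sample belongs to exactly one
of the five regions (`assign_roi()`).

`bin_looks()` divides each trial into 100 ms bins (half-open intervals
`[k·100, (k+1)·100)`) and binarizes: an ROI indicator is 1 when **at least
30%** of the recorded looks in the bin fall in that region; screen-side
indicators (the two left or top quadrants, etc.; the central region counts
for neither side) use a **50%** threshold. Both thresholds are inclusive.
The denominator counts *all* recorded samples including off-screen or
unidentifiable ones — the annotation pathway necessarily dilutes ROI
proportions with `off_or_unknown` frames, and the coordinate pathway
mirrors it; `denominator = "valid"` switches to on-screen samples only.
Bins with no recorded sample are *missing*, not zero: estimators with low
or irregular sampling rates produce empty bins, and imputing zeros would
fabricate "no look" evidence. Missing bins are excluded from model fits.

Trials in which more than 50% (strictly) of the annotated frames are
off-screen or unidentifiable indicate insufficient attention;
`exclude_trials()` flags them and `apply_trial_exclusions()` removes them
from every co-recorded dataset of the same subject and trial. Trials
missing from one method for technical reasons (e.g. estimator trial loss)
are *not* mirrored into the other methods — trial loss is part of a
method's performance.

## Per-bin models and cluster-mass permutation inference

Each 100 ms bin is analysed with a binomial-logit mixed model
(`bin_model_spec()`, `fit_bin_model()`): crossed random intercepts for
subject and item, plus the task's fixed effect — none for
intercept-versus-chance analyses (target side against 50%), or a sum-coded
condition factor. Sum contrasts are ±1, so a two-level focal coefficient
is half the condition difference in log-odds; the contrast magnitude
rescales estimates but not z statistics, and is recorded in the model
metadata.

A bin is *reliable* when its focal `|z| = |estimate/SE|` exceeds 2.
Maximal runs of adjacent reliable bins with the same sign form clusters,
scored by the **z-sum** (the sum of `|z|` over member bins;
`find_clusters()`). Significance comes from a permutation null
(`cluster_permutation_test()`): labels are shuffled per the design —
condition within subject, method within subject, experiment between
subjects, or the per-trial target side redrawn and the side indicator
re-derived — and the permuted data are re-scanned with identical rules.
Each observed cluster's p-value is the proportion of permutation null
statistics at least as large as its z-sum; clusters with p < 0.05 are
significant, and a zero count is reported as `< 1/n_perm`.

Two conventions needed a decision:

* **Null statistic.** The package defaults to the *maximum* cluster z-sum
  per permutation (0 when a permuted scan has no cluster), the
  family-wise-error-controlling convention of cluster-mass tests. Pooling
  every permuted cluster z-sum is available via
  `null_statistic = "all"` for comparability with implementations that
  read the procedure that way.
* **Fallback rules.** When a bin's model does not converge or cannot be
  computed — complete separation, or no variation in the response overall
  or within a fixed-effect cell — the bin inherits the estimate and z
  *used* at the previous bin; a failure at the first bin yields (0, 0).
  Singular fits (a variance component estimated below 1e-6) are ordinary
  converged fits. The same rules apply inside every permutation.

Bin spans are reported in ms with the inclusive-label convention: a
cluster of bins 1–3 from a 0-start window spans 100–399 ms.

### Estimation backends

Permutation tests refit thousands of small GLMMs, so the default engine is
a compiled Laplace fitter (profiled PIRLS over the joint mode of fixed
effects and spherical random effects, with Nelder–Mead over the
random-effect SDs; models with two crossed intercepts take a block-sparse
solver that eliminates the larger factor analytically). Its contract is
checked three ways in the test suite: with variance components at zero it
reproduces pooled logistic regression to ≤ 1e-4 on the logit scale; it
agrees with `lme4::glmer` on simulated data; and on single-factor data it
agrees with an exact Gauss–Hermite marginal-likelihood fitter
(`fit_bin_exact()`, the reference implementation for tiny data).

The profiled fitter's Wald z is slightly conservative in small samples.
Permutation p-values are unaffected (the same statistic is used for the
observed and permuted data), but the power module's detection rule
(`|z| > 2`) is Wald-based, so power simulations refit with the
`"fast_full"` engine — a full Laplace fit whose outer optimisation runs
over fixed effects and variance parameters jointly, matching `glmer`'s
estimation target (agreement to ~1e-3 on estimates; null rejection rate
≈ 0.05).

Two numerical details matter for reproducibility. Permutation refits are
warm-started from the observed scan's variance estimates with a shorter
search; the residual optimizer noise on a z-sum is below ~1e-2, and null
statistics are counted as "greater or equal" with a 0.01 tie guard so a
permutation that reproduces the observed assignment always counts.
Permutation random streams derive from the master seed by a counter, so
results do not depend on evaluation order.

## Effect sizes

Because cluster timings differ across datasets, three windows are
reported (`proportion_effect_sizes()`, `cohens_d_effect_sizes()`):

* **analysis window** — the full scanned window; an *underestimate*, since
  it includes bins without any effect;
* **cluster window** — the significant cluster's bins (for target-side
  designs: the temporal overlap of the positive horizontal and vertical
  side clusters); with several disjoint significant clusters each is
  reported separately, never pooled;
* **maximum** — the single bin within the cluster window where the effect
  peaks; an *overestimate*.

For target-fixation tasks the metric is the grand-average proportion of
target-quadrant looks. For condition-effect tasks it is a Cohen's d from
a window-level logit mixed model (analysis- and cluster-window fits add a
random intercept for time bin), converted by `d = 2z / sqrt(n_obs -
n_fixed)` with the Wald z standing in for t. A binomial-logit fit has no
residual degrees of freedom, so the denominator is a convention; it is
recorded in every result and the window fit function accepts any window,
so alternative conventions are a one-line change.

## Smooth pursuit

For pursuit-style tasks only coordinate channels are informative. Gaze is
averaged per 100 ms bin (`bin_mean_coordinates()`), the Euclidean distance
to the stimulus position at the **bin midpoint** is computed in screen
proportions (`euclidean_offset()`), and offsets are aggregated over
subjects to one value per bin. Comparisons between channels use a paired
t-test on the bin-aligned series (within-experiment) or a two-sample
t-test (between experiments); `compare_offset_series()` refuses
zero-variance inputs rather than returning infinities.

`make_trajectory()` supplies a constant-speed piecewise-linear path
between uniform random waypoints in a rectangle. It is a synthetic
stand-in for whatever trajectory a real experiment used — the analysis
only needs positions over time, so any `time_ms`/`x`/`y` table can be
substituted.

## Power analysis

The post-hoc power procedure (`power_analysis()`) chains:

1. per-bin standardized effects (`per_bin_d()`), and the **3-bin peak
   window**: the bin with the largest d plus its neighbours, clipped
   inward at window boundaries, earliest bin on ties
   (`find_peak_window()`);
2. collapsing each trial to the proportion of non-missing window bins
   with the relevant look, binarized at 30% (`collapse_and_binarize()`;
   a flag switches to sample-count weighting, since "recorded looks" can
   be read at either level);
3. the **observed-effect model**: a trial-level logit mixed model with a
   sum-coded condition effect and maximal random effects (by-subject and
   by-item intercepts and condition slopes), simplified stepwise on
   non-convergence — correlations first, then slopes — with the step
   recorded (`fit_observed_effect_model()`, fitted with `glmer`);
4. parametric simulation (`simulate_power()`): for each candidate n,
   datasets are generated from the fitted fixed effects with fresh
   subject and item effects drawn from the fitted variance components
   (the item set keeps its original size — the default reading of
   enlarging the subject sample only), refitted, and detection counted
   when the focal `|z| > 2`. Power is the detected fraction of `n_sim`
   simulations; refit failures are counted and reported, never silently
   dropped.

Setting `beta = 0` gives the procedure's null calibration (detection
≈ the 5% size of the test), a standard sanity check before trusting the
curve.

## The synthetic generator

`simulate_experiment()` draws one latent gaze timeline per subject × trial
and renders it once through **each** channel, emulating a within-session
design where all methods record the same behavior simultaneously — the
property that lets method differences be attributed to the channels, not
the participants.

The latent behavior (`sample_timeline()`): gaze starts on the central
fixation region and switches to the target at latency `base + subject RE +
item RE + condition shift + trial noise`, Gaussian-truncated at 80 ms (a
physiological floor on saccade latency; defaults: base 300 ms, trial SD
60 ms, subject SD 40 ms, item SD 20 ms). Cohort-style conditions insert a
competitor glance (default 250 ms) at a uniform onset inside the
configured effect window with a per-condition probability. Independently,
with probability `explore_prob` (default 0.3) a trial contains one
exploratory glance to a random non-target quadrant at a uniform time —
real observers glance at distractors throughout a trial, and without this
baseline the out-of-window bins have zero variance, every one becomes
inestimable, and the carry-forward rule smears supra-threshold z values
across the window.

Channels (`method_model()`): samples at `k·1000/fps` ms (optional Gaussian
clock jitter for estimator-like irregularity); each sample reports the
centroid of the region active `latency_ms` earlier — quadrant centroids at
the 0.25/0.75 points, matching stimuli centered in the quadrants — plus
per-axis Gaussian error clipped to the unit square (real estimators return
on-screen coordinates), with per-sample track loss; label channels emit
the region label directly, with annotator error (a uniformly random other
visible label) and track loss (`off_or_unknown`). Whole trials are
dropped per channel with `trial_loss_rate`. The preset rates (60 fps
infrared-like, 25 fps annotation video, 12–26 fps estimator-like) reflect
typical hardware; the spatial error, lag and loss defaults are
*illustrative magnitudes*, not calibrated estimates of any particular
device.

`simulate_binned_experiment()` skips the channel layer and generates
binary per-bin indicators directly from the logistic mixed model the
cluster analyses assume — the right tool for calibration studies (type-I
error, effect-size ordering) where channel rendering is not under study.

**What passing tests show — and do not.** The generator produces
all-or-none fixations with ideal geometry, stationary Gaussian noise, and
independent track loss. Real recordings add calibration drift and
systematic per-subject bias, center-biased estimator error,
non-stationary noise, smooth pursuit between fixations, and annotator
idiosyncrasies. Validation against this generator therefore demonstrates
that the *inference machinery* is correct (error control, recovery,
ordering properties), not that any particular hardware will achieve a
given accuracy.

## Validation suite and problem sizes

The acceptance tests validate, on one CPU, with sizes chosen to keep the
full suite in the tens of minutes:

* Monte-Carlo permutation p-values against **exhaustive enumeration** of
  all label assignments on a 2-subject toy (36 condition assignments, 256
  target-side assignments; the |z| threshold is lowered to 1 there, since
  8-observation bins cannot exceed |z| = 2 without separating);
* family-wise error across 100 null simulations (12 subjects, 12 items,
  8 bins, subject SD 0.5; 100 permutations each) inside [0.01, 0.12];
* recovery of a 0.15 competitor-look excess injected at 400–900 ms in 50
  rendered experiments at n = 20 (≥ 80% detection; median cluster edges
  within ±200 ms);
* channel-degradation ordering: spatial SDs {0.02, 0.08, 0.15} at 10 fps
  strictly order the target-look proportions over the shared cluster
  window (minus its first, saccade-straddling bin), and a 250 ms channel
  lag shifts the detected cluster onset 200–300 ms (one-bin tolerance).
  Two properties of binarized looks shape this check: low-rate channels
  put one sample in most bins, which is what lets the indicators register
  spatial noise at all (binarization is otherwise deliberately
  noise-robust); and on bins where the latent gaze is still on the
  center, spatial noise *adds* spurious quadrant looks — the near-chance
  quadrant scatter noisy estimators show before target fixation — so the
  monotone-degradation ordering is a property of settled fixation bins,
  not of transition bins;
* the Rayleigh closed form (mean offset `σ√(π/2)` under per-axis Gaussian
  error, within 5% at 10,000 samples);
* analysis ≤ cluster ≤ maximum effect-size ordering in ≥ 90% of 100
  effect-bearing simulations, in both metrics;
* power-procedure calibration (β = 0 within 3 MC SE of 0.05 at
  n_sim = 500) and monotonicity in n for β = 0.6;
* the pooled-logit oracle and the carry-forward rules on constructed
  failure cases.

`scripts/acceptance.R` re-runs the main pipeline from scratch at a fixed
seed and writes its headline numbers (cluster z-sum, window, effect
sizes, pursuit offsets, null FWER, power values) as JSON.

## Known limitations

* Random slopes are fitted as uncorrelated (diagonal) blocks; correlated
  slope structures are available only through the `glmer` engine (the
  observed-effect model's maximal step).
* The exact Gauss–Hermite reference fitter supports one grouping factor
  and is intended for validation on small data, not analysis.
* Cluster onsets and offsets are descriptive: the permutation test
  licenses conclusions about cluster *existence*, not about the precise
  timing of effect boundaries.
* The pursuit trajectory generator and all channel noise defaults are
  synthetic stand-ins; conclusions about specific hardware require that
  hardware's data.
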