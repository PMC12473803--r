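---
title: "Methods: CoP sway features and the fixed classification protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CoP sway features and the fixed classification protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugcop)
```

## Scope and coordinate conventions

`tugcop` analyses per-foot center-of-pressure (CoP) trajectories recorded by
pressure-sensing insoles during the Timed Up and Go test, sampled at 100 Hz
in the insole firmware's normalized coordinate system: the medio-lateral
(ML) axis spans $[-0.5, 0.5]$ and the anterior-posterior (AP) axis
approximately $[-0.574, 0.426]$, identically for both feet. All features are
computed directly on these dimensionless coordinates — no conversion to
physical units — so values are comparable across participants regardless of
insole size. The `cop_trajectory` constructor enforces these bounds and a
uniform time base; violations are reported with the offending column and
row.

When raw 16-sensor force frames are supplied instead of firmware CoP, the
CoP is the force-weighted mean of the sensor positions
($CoP_x = \sum_i d_{xi} F_i / \sum_i F_i$, and analogously for $y$).
Exported CoP columns take precedence when both are present (`read_trial()`
has a `recompute_cop` flag). An all-zero frame is a swing-phase sample and
is flagged rather than raised as an error. Swing-phase behaviour of the
exported CoP signal is retained as-is: features are computed on the
continuous firmware-style CoP series without dropping no-contact samples.

## Scenarios and the walking junction

Scenario 1 is the full recording; scenario 2 keeps only the walk-out and
walk-back samples, concatenated in time order. The junction between the two
sub-walks is a physical discontinuity, so it is recorded as a *break* in the
trajectory and honoured throughout: finite-difference velocities drop the
bridging difference, Welch segments are drawn only from contiguous runs, and
mean-squared-displacement pairs never span a break. This is the one place
where a design choice had to be made without external guidance (how the two
sub-walks combine); concatenation-with-breaks keeps every downstream
statistic well-defined without inventing data at the junction.

## The 72-feature registry

The per-foot descriptor set is frozen in a versioned registry
(`feature_registry()`): 14 positional, 17 dynamic, 20 frequency and 21
stochastic features, named by the field's conventions with axis suffixes
`ML`, `AP` and `ML-AP`. Downstream code addresses features by name, never by
position, and the count of 72 is asserted at load time. Noteworthy
definitions:

* **95% confidence ellipse area**: $5.991\,\pi\sqrt{\det\Sigma}$ with
  $\Sigma$ the ML/AP covariance of the centered path; $5.991$ is the 95%
  quantile of $\chi^2_2$.
* **Principal sway direction**: orientation of the leading eigenvector of
  $\Sigma$, mapped to $(-90, 90]$ degrees relative to the ML axis. For a
  constant trajectory it is undefined and reported as `NA` (the designated
  missing value, carried with a per-feature flag).
* **Peak velocities**: means of the local extrema of the *signed* per-axis
  velocity — positive maxima and negative minima are separate features, so
  time reversal maps one onto the negated other (a property the tests
  exploit).
* **Sway area per second**: accumulated triangle areas swept by the centered
  position vector, per unit time.
* **Rotational mean frequencies** (dynamic family) follow the
  velocity-to-distance quotients $MV/(4\,MD)$ per axis and
  $MV/(2\pi\,MD)$ for the resultant, distinct from the PSD-based mean
  frequency in the frequency family.

All positional and dynamic features are computed after subtracting the
per-trajectory mean, which removes the foot-placement offset.

### Spectral estimation

Frequency features use a Welch PSD: Hann window, segment length
$\min(256, \lfloor n/2\rfloor)$ samples, 50% overlap, per-segment mean
detrend, one-sided density scaling. These are the field's default choices;
they are recorded in the returned `spectral_estimate` for reproducibility.
The DC bin is excluded from every spectral statistic, so the three band
energies ($\le 0.5$, $0.5$–$2$, $>2$ Hz) partition the spectrum and sum to
one. A zero-power channel yields `NA` spectral features. At 100 Hz and
256-sample segments the bin width is about 0.39 Hz, which bounds the
resolution of the mode and quantile frequencies. The *frequency quotient* is
defined as power above 2 Hz over power at or below 2 Hz (a high/low band
ratio); the spectrum is estimated on the raw (per-segment mean-detrended)
CoP signal, not on a globally detrended one.

### Stabilogram diffusion analysis

$MSD(\Delta t)$ is computed over all sample pairs per lag with an FFT
autocorrelation identity ($O(n\log n)$; a naive loop is the test oracle),
per axis and for the planar sum. Short-term and long-term ordinary
least-squares fits use lag windows $[0.02, 0.3]$ s and $[1.0, 2.5]$ s —
standard stabilogram-diffusion practice, exposed as arguments. Diffusion
coefficients are slope$/2$ per axis and slope$/4$ for the planar curve; the
critical point is the intersection of the two fitted lines (reported `NA`
when the fits are parallel or intersect at non-positive lag); scaling
exponents $H$ are half the log–log slopes, and the fractal dimension is
$2 - H_{short}$. The long-term window requires contiguous runs of at least
2.5 s; the full TUG (15 s by default) and each 4 s walking segment satisfy
this, which is why the walking scenario remains fully featured even though
it is shorter than 10 s.

## Bilateral aggregation

Each of the 72 features is summarized across feet as the average
$(L + R)/2$ and the asymmetry index $|L - R|/(|L| + |R|)$, giving 144
scenario features (all averages, then all asymmetries). The absolute-value
form guarantees the index lies in $[0, 1]$ and is well-defined for signed
features such as the principal sway direction; a signed variant
$(L - R)/(L + R)$ is available behind the `signed` argument for sensitivity
analysis. Both sides exactly zero defines the index as 0 (perfect symmetry
at null magnitude); a sub-`1e-12` denominator with unequal sides is floating
noise and yields `NA`. When a participant has several trials, feature values
are averaged across trials (the alternative — picking one trial — is
exposed simply by passing a single pair per participant).

## Density mapping

Spatial-occupancy maps pool all CoP samples of a group/foot stratum and
evaluate a 2-D Gaussian KDE on a 200×200 lattice over the full normalized
ranges. Comparability across the four group-by-foot panels is enforced by
construction: Scott's rule ($\sigma_j n^{-1/6}$ per axis) is computed once
on the pooled Control-left stratum and frozen for all panels, which share
the one grid. The trapezoidal integral of a map is ~1 for well-resolved
clouds; degenerate (all-identical) clouds are rejected.

## The synthetic cohort generator

No clinical recordings ship with the package; the generator exists so that
every downstream stage is testable. Per foot, CoP is the sum of three
parts:

1. a deterministic phase template (smooth AP ramps during sit-to-stand and
   turn-to-sit, a heel-to-toe AP oscillation at the participant's step
   frequency during the walks, a lateral ML excursion during the turn), with
   default phase durations 2/4/2/4/3 s chosen so a trial is long enough for
   the diffusion and spectral fits to be well-posed;
2. a band-limited oscillatory component: one tone at 0.25 Hz and one at
   1.1 Hz, with a fraction (0.30 in controls) of the oscillatory power in
   the low tone;
3. a first-order autoregressive component ($\phi = 0.95$) for the
   unstructured sway.

Group contrasts enter through an `effect_profile`: a multiplier on sway
magnitude (default 1.3), a gain on one randomly lateralized foot (default
1.4, PD only — reflecting unilateral motor-symptom onset), a shift of
oscillatory power below 0.5 Hz (default 0.3 of the above-band power) and a
reduction of AR innovation variance at preserved stationary variance
(default 0.3), which smooths the signal without changing its magnitude —
a minimal stand-in for reduced postural complexity. These defaults were
fixed once, as magnitudes a posturographer would call a clear but realistic
clinical contrast, and are not tuned thereafter; `effect_profile_zero()`
removes every contrast, making PD and control draws one generative law (the
basis of the null-calibration tests). Participant-level variability comes
from log-normal draws of the oscillatory amplitude and AR magnitude
(sd 0.2 on the log scale), a small natural left/right imbalance (sd 0.05)
and a per-participant step frequency. All draws are consumed identically
for both groups, so determinism is per `(config, group, participant_seed)`
and a cohort is reproducible byte for byte from its master seed.

What the generator does *not* emulate: true gait kinematics, double-support
load transfer between feet, swing-phase gaps, sensor noise or drift, and
any within-participant trial-to-trial structure. Passing calibration tests
on these cohorts therefore demonstrates that the pipeline recovers the
*statistical structure it assumes* — not clinical validity on real
recordings.

## The classification protocol

The protocol is deliberately rigid: a single participant-level stratified
80/20 split (per class, `round(0.2 n)` participants held out; 77
participants yield 16) reused across all models; per model, sequential
forward selection embedded in stratified 5-fold inner cross-validation
scored by F1 (positive class PD), with the subset size chosen over
$k \in [1, 36]$; a final refit on the complete training set; and exactly
one evaluation on the held-out participants. The greedy path is nested, so
one pass to $\max k$ yields the whole per-$k$ curve; greedy-gain ties break
toward the earlier registry column and best-$k$ ties toward the smaller $k$
(parsimony). Inner folds are seeded (42) and shared across models.

Leakage control: median imputation and z-scoring are fit on fold-training
data inside the inner CV, and on the full training set only at final refit;
the tests assert that corrupting the test rows leaves the selection path
bit-identical.

Model families and frozen hyperparameters: SVM-RBF (`e1071`, cost 1, gamma
$1/(p\,\mathrm{var}(X))$, balanced class weights, probability calibration
only at the final refit), L2-penalised logistic regression (in-package IRLS,
penalty equivalent to $C = 1$, balanced observation weights; `glmnet` is the
cross-check oracle in the tests), random forest (`randomForest`, 100 trees,
balanced class weights, seed 42), 5-NN (deterministic Euclidean vote;
`class::knn` is the cross-check oracle; ROC scores are PD vote fractions)
and Gaussian naive Bayes (in-package, variance smoothing $10^{-9}$ times
the largest feature variance, matching the stated hyperparameter — the
reason it is authored here rather than taken from `e1071`, which has no
such knob). Scale-sensitive families (SVM, LR, k-NN) consume z-scored
features; the forest and naive Bayes run unscaled.

## Calibration and problem sizes

The test suite calibrates the full pipeline on synthetic cohorts of 77
participants (39 PD / 38 control, mirroring the balanced cohort the
protocol is designed for): 20 null-effect cohorts must keep every model's
mean held-out accuracy within 0.35–0.65, and on 10 strong-effect cohorts
(sway ratio and asymmetry gain 1.5) logistic regression must reach at least
0.8 accuracy in at least 80% of the seeds. These runs use the selection
grid $k \in [1, 12]$; the grid cap trades selection depth for run count, and
at the observed effect sizes the inner-CV curve peaks well below 12, so the
cap does not bind. Parameter-recovery checks complete the calibration:
the short-term diffusion coefficient of simulated Brownian motion is
recovered within 15% (100 replicates), and the 95% ellipse area of an
isotropic Gaussian cloud within 5% of its closed form at $n = 10{,}000$.

## Known limitations

* The registry is one defensible instantiation of the standard
  posturographic taxonomy; other implementations differ in, e.g., the exact
  frequency-quotient bands or the diffusion fit windows. Both are exposed
  as arguments, but the frozen defaults define this package's results.
* The asymmetry index is undefined at near-zero denominators; such values
  propagate as `NA` and are median-imputed inside the classification
  pipeline.
* Small held-out sets (16 participants) quantize every test metric to
  1/16 steps; single-split results on real data should be read with that
  granularity in mind — the protocol evaluates comparability across models,
  not tight generalization bounds.
* The synthetic generator is a calibration instrument, not a gait model;
  conclusions about real PD cohorts require real recordings in the
  `read_trial()` CSV dialect.
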