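---
title: "Decoding heat intensity from simulated fMRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding heat intensity from simulated fMRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`heatdecode` reimplements, on fully synthetic data, the computational chain of
a pain-modulation fMRI experiment: a factorial heat x emotional-picture block
design under a two-session medication crossover, first-level GLM estimation of
condition beta maps, an MVPA decoder of heat intensity, and the factorial
mixed-model statistics applied to ratings and to the decoder's output. This
vignette explains each model, the tunable parameters and why their defaults
are what they are, what the generators do and do not emulate, and the design
decisions taken where the underlying analysis conventions leave room.

## 1. The simulated experiment

`generate_trial_sequence()` builds one session: every combination of
temperature (35.0, 44.7, 47.1 °C) and picture condition (negative, neutral,
positive, scrambled) occurs exactly three times (36 trials). Each trial is
cue (1 s), fixation (0.5 s), a 10 °C/s ramp, a 14 s plateau, ramp-down, a
rest interval drawn uniformly from 3–6 s, a fixed 14 s rating window, and a
3–6 s inter-trial fixation. With these constants a session lasts roughly
22–26 minutes, and at TR = 2 s a run comprises about 660–780 volumes, five
additional dummy volumes being acquired and discarded.

"Pseudo-randomized to avoid clustering" is not a formal constraint, so we
operationalize it: no more than `max_run` (default 2) consecutive trials may
share a temperature or a picture label, enforced by rejection sampling with a
bounded retry budget and an explicit error when the constraint is infeasible
(e.g. two two-level factors with `max_run = 1`). Single-level factors are
exempt, since clustering is then unavoidable and meaningless.

### Ground-truth pattern and BOLD signal

`make_ground_truth_pattern()` plants the "true" analogue of the weight map
the decoder is supposed to find: on a 2000-voxel lattice (10 x 10 x 20,
NIfTI-exportable; the dimensions are configurable), 10% of voxels are active
with Gaussian weights of SD `effect_scale` (signal units per °C); all other
weights are exactly zero. The default `effect_scale = 0.2` against a
beta-level noise SD of 1 makes the per-voxel signal across the full
4.8 °C training range comparable to the noise SD — the regime of robustly
heat-responsive voxels in smoothed single-subject data — and leaves the
multivariate decoding problem hard enough that performance depends on the
estimator, not trivially saturated.

`simulate_bold_run()` composes the voxel time series as
`baseline + X %*% A + AR(1) noise`, where `X` holds one HRF-convolved plateau
boxcar per condition and `A[c, v] = amplitude[c] + temperature[c] * w[v]`.
Because the simulator and `build_design_matrix()` share the same regressor
code, a noiseless run is recovered by the GLM to numerical precision — that
identity is an explicit test, not an assumption. Head-motion parameters are
simulated as slow random walks and enter only as nuisance columns; motion
never corrupts the signal (physiological noise, spikes and true motion
artefacts are out of scope).

### Two speeds of study simulation

`simulate_training_study()` and `simulate_test_study()` emit beta maps
directly (noise added at the beta level), which keeps a full
12-subject x 8-level x 2000-voxel study below a second of compute. A slower
`method = "bold"` path routes each subject through `simulate_bold_run()` and
`fit_glm()`, retaining an end-to-end integration check of the identical
quantities. The training study uses eight temperature levels; the source
protocol does not print them, so the default is eight equally spaced levels
spanning 42.3–47.1 °C — a flagged guess, configurable.

### Ratings

`simulate_ratings()` plants the marginal effect structure reported for the
emulated study directly as cell means: a 47.8 VAS noxious-vs-non-noxious
intensity effect (50.1 for unpleasantness), small valence offsets (negative
+1.51/+2.31 VAS vs neutral for intensity/unpleasantness), an
oxytocin-by-temperature effect on intensity (+3.54 VAS at non-noxious, −2.38
at noxious heat), and a three-way structure for unpleasantness in which the
negative-minus-positive difference at noxious heat is 7.08 VAS under oxytocin
but 3.26 under placebo. Trial values add a by-subject random intercept, a
by-subject random slope on the noxious indicator, and residual noise (SDs 10,
10, 10 VAS — chosen so that the implied standard error of the temperature
contrast at n = 30 matches the reported interval width) and are truncated to
[0, 100]. Truncation happens before aggregation; it slightly shrinks
recovered effects toward the scale centre, so exactness tests switch it off
via `truncate = FALSE`. Two unprinted constants had to be chosen once: the
35.0 °C baseline mean (5 VAS intensity, 2 unpleasantness) and a small
positive scrambled-picture offset (+1.5/+1.0 VAS), representing the reported
slight decrease of ratings under intact-picture viewing.

Binary pain judgments follow a logistic psychometric function of temperature,
`P(painful) = plogis((T - midpoint)/scale)`. Midpoint 46.33 °C and scale
0.474 are obtained by passing the reported painful proportions (3.1% at
44.7 °C, 83.6% at 47.1 °C) through the inverse logistic; at 35.0 °C the
implied probability is ~4e-11, so baseline stimuli are never painful.

## 2. First-level GLM

The design matrix has one condition column per (temperature, picture) cell —
the 14 s plateau boxcar shifted by 5 s (thermode onset latency), sampled at
TR/16, convolved with the canonical double-gamma HRF, and downsampled at
volume onsets — plus nuisance columns: a convolved boxcar over the rating
periods, six motion parameters, the discrete-cosine high-pass set, and a
constant. Two conventions are deliberate:

* **High-pass as regressors.** Instead of filtering the data, the DCT columns
  with periods above the 400 s cutoff (`k = floor(2 * n * TR / cutoff)`) are
  included as nuisance regressors; for the condition betas this is equivalent
  to the residual-forming filter and much easier to test.
* **HRF/regressor scaling.** The kernel is peak-normalized and the convolved
  regressor is additionally scaled so a sustained boxcar plateaus at 1; betas
  then read directly in planted signal units, making recovery tests exact.
* **Rating regressors** are convolved boxcars of the observed mean rating
  duration (7.5 s); whether the original analysis used boxcars or stick
  functions is unstated, and the choice only affects a nuisance column.

Serial correlation is handled by two-pass estimation: OLS, a single AR(1)
coefficient pooled over all in-mask voxels from the residuals, then
prewhitened least squares (first row scaled by `sqrt(1 - rho^2)`, later rows
`x_t - rho x_{t-1}`). Pooling globally rather than over supra-threshold
voxels, and using two deterministic passes rather than iterated ReML, are
simplifications chosen for desk-scale determinism; the prewhitened estimator
is verified against a brute-force GLS solve, and whitened residuals of
planted rho = 0.3 noise are checked to have |lag-1 autocorrelation| < 0.05.

## 3. The decoder

Training stacks all subjects' beta maps (observations x voxels) and proceeds:

1. **By-voxel z-transform.** Zero-variance voxels are set to 0 and recorded;
   they can never contribute to the decoder.
2. **PCA** on the z-stack (feature means removed), keeping the smallest
   number of components whose cumulative variance share reaches 0.999,
   capped at `min(n_obs - 1, n_voxels)`.
3. **Elastic net** on the component scores, objective
   `1/(2n) ||y - b0 - Zw||^2 + lambda [(1-alpha)/2 ||w||^2 + alpha ||w||_1]`,
   solved by cyclic coordinate descent with soft thresholding; the intercept
   is unpenalized, convergence is a 1e-10 sup-norm change, and lambda paths
   are warm-started. `alpha = 0` (pure ridge) is rejected: the method is a
   lasso-family decoder, and near-ridge behaviour is available via small
   positive alpha. The solver is validated against an independently written
   naive coordinate-descent oracle and (for alpha = 1, where the
   parameterizations coincide exactly) against glmnet.
4. **LOSO-CV tuning** over `alpha in {0.1, 0.5, 0.9, 1}` and 20
   logarithmically spaced lambdas in [1e-3, 10] (the source reports neither
   grid nor chosen values). Fold models compute standardization, PCA and the
   fit exclusively on the n−1 training subjects; the held-out subject is
   transformed with fold-internal parameters, which is asserted by
   corruption tests (any change to the held-out subject leaves fold models
   bit-identical). CV error is RMSE in °C (MAE available); the published
   analysis says only "CV error". Exact ties are broken toward sparsity:
   larger lambda first, then larger alpha.
5. **Back-projection.** `w_vox = R w` through the PCA loadings, so
   voxel-space and component-space predictions agree to machine precision
   (an exact linear-algebra identity, asserted to 1e-10).

**Applying the map.** The MHE of a beta map is the plain dot product
`<w_vox, z(b)>`. The intercept is excluded — it shifts every condition of a
subject equally and cancels in within-subject contrasts. Test stacks are
z-transformed over their own observations per subject
(`standardize_with = "self"`); transferring the training standardization is
available (`"training"`) but not the default, since nothing in a plain
by-voxel dot product presumes parameter transfer across scanners or samples.
Analogously, cross-validation uses fold-internal standardization/PCA by
default; whole-sample variants exist but would leak.

The printed figure of 469 components from 318,677 voxels in the emulated
study is data-dependent and not reproducible synthetically; it is treated as
descriptive only.

## 4. Evaluation and statistics

Validity of the decoder is quantified exactly as in the emulated analysis:
pooled Pearson correlations (Fisher-z 95% intervals) between MHE and heat
level/ratings, and median-split classification of noxious (47.1 °C) vs
non-noxious (44.7 °C) conditions, with ties at the median labelled negative
(the source does not specify a tie rule). With balanced classes a median
split forces accuracy to equal precision; the different published accuracy
and precision figures imply exclusions or pooling not described there — noted,
not resolved.

The statistics chain mirrors the published order: outliers are flagged per
subject-by-temperature group when the two-tailed normal probability of the
value falls below 1:5000 (|z| > 3.719); the group mean/SD include the
candidate value by default (the source is silent; a leave-one-out variant is
available). Surviving repetitions are averaged to one value per subject and
condition; the outcome is mean-centred and standardized (so fixed effects are
standardized βs, with raw-scale effects recovered through the stored scale);
and a factorial linear mixed model with medication x temperature x valence
fixed effects is fitted by REML (lme4), excluding the baseline temperature
and scrambled pictures. Sessions enter only through the medication factor —
crossover order is not modelled.

**Random-effects ladder.** The analysis aims for a maximal by-subject
structure but, with 12 observations per subject, the full
interaction-slope structure has as many random-effect columns as
observations and is unidentifiable; such rungs are skipped. The pre-declared
ladder is: full interaction slopes (unstructured covariance) → main-effect
slopes → intercept only. A rung is abandoned on optimizer error or
convergence failure; boundary (singular) fits are retained and flagged,
which follows the keep-it-maximal practice of tolerating zero-variance
estimates. lme4's double-bar syntax does not expand factors, so a separate
"drop correlations" rung is not offered; dropping interaction slopes first
serves the same purpose. The structure actually fitted is recorded in the
result.

Type III F-tests use Kenward-Roger denominator df (pbkrtest) by default,
matching the published tables; Satterthwaite is available and is what the
package uses in its 500-replicate null calibration study, where Kenward-Roger
would multiply compute a hundredfold for practically identical df on balanced
intercept-only fits. Estimated marginal means and pairwise contrasts
(emmeans, balanced cell weights) are reported on the raw outcome scale and as
standardized βs.

Control analyses: refitting with valence replaced by a two-level
scrambled-vs-pictures factor; a medication x picture model restricted to the
35.0 °C baseline rows; and painful-classification percentages per
temperature, which are pure counting.

## 5. Null probes and calibration checks

Two degenerate regimes need care:

* **Zero-signal decoding.** With `effect_scale = 0`, CV tuning correctly
  selects heavy penalties and the predictor collapses to a constant — whose
  correlation with temperature is undefined and whose MHEs cannot be
  median-split. Null checks therefore probe a fixed, minimally penalized grid
  cell (`alpha = 0.1, lambda = 1e-3`), where predictions vary but carry no
  signal: the LOSO correlation is then centred on zero and median-split
  accuracy falls inside the binomial 95% band around 0.5.
* **Type I error.** 500 replicates of a null rating study (all planted fixed
  effects zero, random intercept SD 10, residual SD 10, no truncation,
  12 subjects) are fitted with the intercept-only rung — the true structure —
  and every Type III term's rejection rate at alpha = 0.05 is required to lie
  inside the binomial 95% band.

## 6. Problem sizes and limitations

The shipped defaults — 2000 voxels, 12 training subjects x 8 levels,
30 test subjects x 24 conditions, 30 rating subjects — are the package's
chosen desk-scale study: large enough that decoding performance and
mixed-model calibration are meaningful, small enough that the entire test
suite and the acceptance pipeline run in minutes on one core.

What passing tests do **not** show about real data: the generators contain no
spatial autocorrelation or smoothing, no physiological or motion artefacts,
no between-subject anatomical misalignment, no scanner drift beyond what the
high-pass removes, and a literally linear temperature code; real decoding
accuracies and weight-map recovery will be worse and the printed effect sizes
of the emulated study are *inputs* to the generator, never reproduction
targets. NIfTI I/O uses a plain identity-scaled affine on a small lattice;
no registration or masking logic beyond a boolean vector is implemented.
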