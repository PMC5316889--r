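---
title: "Methods: developing and testing stimulus-intensity-independent pain signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developing and testing stimulus-intensity-independent pain signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painsig)
```

## The problem

Pain is not a read-out of stimulus intensity. Across repeated, calibrated
noxious heat stimuli, trial-to-trial pain reports vary widely even at a
fixed temperature, and nociceptive brain signatures (weight maps whose dot
product with an activation image predicts evoked pain) capture mainly the
intensity-tracking component of that variance. `painsig` implements the
complementary construct: a multivariate brain signature of the
*stimulus-intensity-independent* contribution to pain, derived from
trial-level activation maps after everything a stimulus-intensity model and
a reference nociceptive signature can explain has been removed, together
with the multilevel inferential machinery needed to ask whether
psychological manipulations (expectancy cues, perceived control) change
pain *through* that signature.

Because the original fMRI studies are not publicly deposited, the package
ships a first-class synthetic-data module that emulates their statistical
structure with a fully known ground truth, so every stage — single-trial
estimation, residualization, decoding, aggregation, application, mediation
— can be validated by parameter recovery rather than by eyeballing.

## The development pipeline

For each subject $s$ with trial images $X_s$ (trials $\times$ voxels) and
ratings $y_s$:

1. **Residualization.** Build the design
   $D_s = [\,1,\ \mathbb{1}(L=\ell_2),\dots,\ \mathbb{1}(L=\ell_K),\ r_s\,]$
   with one indicator per stimulus-intensity level above the lowest
   (modelling *all* differences among levels, not a linear trend) and the
   per-trial reference-signature response $r_s = X_s w_{\mathrm{ref}}$.
   Both $y_s$ and every voxel column of $X_s$ are projected onto the
   orthogonal complement of $D_s$. Residual orthogonality is an enforced
   contract (`1e-8`), tested against an explicit hat-matrix oracle.
2. **Per-subject decoding.** Principal component regression of the residual
   ratings on the residual images. With the default
   `n_components = "all"`, every component with a nonzero singular value is
   kept; on tall full-rank data this equals ordinary least squares, and with
   more voxels than trials it is the minimum-norm interpolating solution.
   The number of retained components is exposed as configuration because the
   choice is genuinely open; "all" is the least-tuned default.
3. **Precision.** Each subject's prediction–outcome correlation under
   seeded 10-fold cross-validation (`crossval_prediction_corr()`).
4. **Aggregation.** Subject maps are divided by the s.d. of their own
   weights (so scale differences across subjects and rating scales cannot
   dominate) and averaged with the cross-validated correlations, clipped at
   zero, as weights. A weighted one-sample t-test across subjects,
   Benjamini–Hochberg FDR at $q = 0.05$, and connected-component extraction
   (26-neighbourhood, minimum 15 voxels, with a per-label allowlist for
   smaller anatomically meaningful clusters) yield the thresholded map and
   its signed regions.

Application is deliberately dumb: `signature_response()` is a dot product
over in-mask voxels, `local_pattern_expression()` restricts it to a region
(with absolute weights by default, so a positive intensity correlation
always means intensity-tracking activity). Maps never resample images:
grids must match exactly, or the call errors.

## Single-trial estimation

`build_single_trial_design()` implements the beta-series approach: one
boxcar per trial convolved with the canonical double-gamma haemodynamic
response (peak parameter 6, undershoot 16, unit dispersions, 1/6 undershoot
ratio, 32 s support, unit peak — the de-facto convention, configurable),
plus intercept, linear drift, caller-supplied nuisance columns and spike
indicators. Each trial regressor's variance inflation factor,
$\mathrm{VIF} = 1/(1 - R^2)$ against all other columns, quantifies
design-induced uncertainty; trials with VIF $> 2.5$ are *flagged*, never
deleted, so downstream counts reconcile. Rank-deficient designs produce
infinite VIFs and minimum-norm estimates rather than exceptions.

Volume-level QC follows the slice-statistic recipe: per volume, slice-wise
means and standard deviations are concatenated, squared Mahalanobis
distances to their sample distribution are referred to a $\chi^2$ law with
df equal to the feature count (the conventional choice for this statistic;
no stronger justification is claimed), and a volume
is flagged only if it passes the stricter of Bonferroni and
Benjamini–Hochberg at $\alpha$. Since BH step-up rejections are always a
superset of Bonferroni rejections at the same level, the intersection is
effectively the Bonferroni set; we implement the "stricter of either" rule
literally anyway. For slow thermal responses, `flexible_basis_auc()` fits
three time-shifted canonical kernels (shifts 0, +2, +4 s by default — the
basis is configuration, since only "three curves shifted in time" is
specified) and summarizes each trial and voxel by the trapezoidal area
under the reconstructed response.

## Multilevel inference

`multilevel_glm()` fits per-subject OLS, then pools coefficients with
Empirical Bayes weights $\lambda_i = 1/(v_i + \tau^2)$, where $v_i$ is the
first-level sampling variance and $\tau^2$ the DerSimonian–Laird
method-of-moments between-subject variance floored at zero. The named
procedure's exact update is not published, so this standard scheme is our
documented stand-in, validated by its own type-I calibration tests rather
than by authority. Significance comes from resampling subjects with
replacement and recomputing the weighted mean (10,000 iterations by
default; p-values floored at $1/(n_{\mathrm{boot}}+1)$; one- and two-tailed
both reported). Unique variance of a predictor is the mean over subjects of
(full $R^2$ − reduced $R^2$); its permutation test shuffles that
predictor's trial labels within each subject (5,000 iterations by default)
and uses the exact partitioned-regression identity
$R^2_{\mathrm{full}} = R^2_{\mathrm{red}} + (1 - R^2_{\mathrm{red}})\,
r^2(y_\perp, x_\perp)$, so each iteration costs two small matrix products
per subject instead of a refit.

`mediate_multilevel()` estimates, per subject, $M_j \sim X$ (+ covariates)
for each mediator (path $a_j$), $Y \sim M + X$ (paths $b_j$, $c'$), and
$Y \sim X$ (path $c$); the group indirect effect summarizes the
*per-subject products* $a_i b_i$ — not the product of group means — because
the $a$–$b$ covariance across subjects is part of the phenomenon. With one
mediator and shared trials the decomposition $c = c' + ab$ holds to
machine precision per subject; excluded trials are dropped listwise within
subject precisely so that identity survives. `mediate_three_path()` chains
$X \to M_1 \to M_2 \to Y$ (e.g. control manipulation → perceived-control
rating → signature response → pain) with serial indirect $a\,d_j\,b_j$.
Anti-pain conditions are coded $+1$ and pro-pain conditions $-1$
throughout; stimulus intensity enters as a covariate where the design
crosses conditions with temperature.

## What the generator emulates

`make_ground_truth()` plants two unit-norm spatial patterns on the shared
grid: a nonnegative *nociceptive* pattern whose expression scales with
intensity level, and a piecewise-constant *endogenous* pattern over compact
spherical subregions with mixed signs (default 4 pro-pain, 2 anti-pain),
whose per-trial amplitude
$A_t = a \cdot \mathrm{condition}_t + \delta_s + \eta_t$ carries the
condition manipulations, a subject random effect, and trial noise. Ratings
combine an intensity effect, the mediated endogenous effect
$b \, g_E A_t$, a small direct condition effect, and noise; all
rating-side coefficients are specified on a 0–10 convention and rescaled to
each design's bounds, which resolves the open question of harmonizing
different rating scales (the models downstream are scale-free within
subject). Study presets reproduce the two test designs: an
expectancy-cue design whose medium-intensity trials alone enter mediation,
and a 2×2 control-by-expectancy design with 8 runs × 8 trials = 64 trials,
16 per cell, 50/50 high/low intensity everywhere, and per-trial
perceived-control ratings; a generic preset yields roughly 50 painful
trials per subject with a flagged 10% non-painful fraction.

Noise has four components, and the structure matters. Besides i.i.d. voxel
noise (s.d. 1), every trial receives three fixed spatial modes with random
amplitudes: the global signal (uniform, amplitude s.d. 3), a random mode
(s.d. 3), and a high-variance *salience-like* mode (s.d. 20) loading
positively on the pain-predictive subregions with spatial correlation 0.25
to the endogenous pattern. The salience mode is the generator's analogue of
arousal and attention fluctuations that co-activate pain-responsive
regions without changing pain: it is precisely what makes a mass-univariate
encoding map a contaminated decoder, while a multivariate pattern with
mixed-sign weights can cancel the mode. With purely isotropic noise the
encoding map would be the optimal decoder and the multivariate-vs-univariate
comparison would be decided in the wrong direction by construction.

Default effect sizes (endogenous brain gain 6, condition→amplitude path
0.1, amplitude→rating path 0.15, direct path 0.05, subject s.d. 0.3) were
calibrated once, at design time, so that the planted structure is
recoverable at the reference scale — 20 subjects × ~50 painful trials on a
12³ ellipsoidal grid (≈550 voxels) — while condition effects on pain stay
small, in the spirit of the designs emulated; they were then frozen. The
reference scales (20×50 for development, 29×64 for inference, 1,000
simulations with 1,000 bootstrap/permutation iterations for calibration
studies, 30 repeats for mediation recovery, 100 seeds for the
forced-choice monotonicity study) are the package's chosen desk-scale
study sizes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: anatomical structure and spatial smoothness,
haemodynamic variability across regions, temporal autocorrelation within
runs, motion and physiological artefacts beyond injected spikes, scanner
drift beyond a linear term, and rating-scale usage idiosyncrasies. Recovery
results here certify the estimators, not effect sizes in any real cohort.

## Numerical choices and edge cases

* PCR centres both matrices; a constant outcome gives zero weights; a
  requested component count above the rank is clamped with a warning.
* Cross-validation folds are a seeded random partition; an option for
  contiguous folds exists because trial autocorrelation inflates random-fold
  estimates on real runs. Because residualization precedes cross-validation
  (the operation contract takes residualized inputs), the prediction–outcome
  correlation is optimistic for interpolating decoders: on pure-noise
  fixtures it is biased upward, although permuting the outcome still
  centres it at zero. It is therefore used only as a *relative* precision
  weight, never reported as an accuracy estimate; held-out evaluation goes
  through `loso_develop_and_apply()`, which is leakage-free (tested by
  perturbation).
* The weighted t-test drops zero-weight subjects before normalizing the
  weights to sum to $n$ (the stated formula and the support-equivalence
  property cannot otherwise both hold); weighted variance uses the
  reliability-weights form with $n - 1$ degrees of freedom.
* Negative cross-validated correlations are clipped to zero in aggregation;
  an all-nonpositive set is an error, not a silent zero map.
* Quartile binning z-scores both series first and breaks rating ties by
  trial index (stable sort). Forced-choice comparisons take all high×low
  set pairs; ties count one half.
* Intensity indicators drop the lowest level for identifiability;
  zero-variance reference responses and single-trial levels degrade softly
  with warnings (the latter forcing exact-zero residuals).
* Spike detection ridge-inflates a singular slice-statistic covariance and
  warns; all-constant volumes flag nothing.
* Bootstrap resampling reuses one subject-index matrix across paths within
  a mediation fit, so paths are resampled jointly.

## Known limitations

The Empirical Bayes update and the three-basis set are documented
reconstructions, not ports; coefficient values on real data will differ
from any particular legacy implementation even where contracts agree. The
percentile bootstrap for the indirect effect runs slightly warm at small
subject counts (its measured type-I rate at the 29-subject scale sits near
the top of the nominal band — see the calibration tests). The cv_r
optimism noted above is inherited from the procedure's structure. The
region extractor labels components only by sign and size; anatomical
naming is out of scope, as are spatial normalization, smoothing, and
visualization beyond map export.
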