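---
title: "Measuring intervention-induced normalization of brain activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intervention-induced normalization of brain activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastimap)
```

## The scientific problem

Children with mathematical learning disability (MLD) show aberrant —
typically elevated — task-related activation across parietal, prefrontal
and ventral temporal-occipital cortex during arithmetic problem solving.
An effective behavioural intervention raises the question of *neural
normalization*: does the atypical group's brain activity converge to that
of typically developing (TD) peers, does it stay aberrant, or does it
recruit new compensatory systems? plastimap implements a complete
desk-scale analysis chain for this question in a two-group (MLD, TD) by
two-session (pre, post) design:

1. per-subject event-related GLM contrast maps (Addition vs Control
   verification trials),
2. voxelwise group inference with Monte-Carlo cluster-extent family-wise
   error (FWE) correction,
3. multivariate pattern classification (linear support-vector machine,
   leave-one-out cross-validation, permutation null) of MLD vs TD at each
   session within the pre-tutoring group-difference mask,
4. a Brain Plasticity Index (BPI) — one minus the in-mask spatial
   correlation between a subject's z-transformed pre and post maps —
   related to behavioural gains.

Because no subject-level imaging data are distributed with the original
study, the package ships a synthetic cohort generator whose statistical
structure matches what every downstream stage assumes. All calibration
claims in the test suite are statements about this generator, not about
any real cohort.

## The generative model

A session activation map for subject $i$ is

$$ m_{is}(v) \;=\; B(v) \; +\; P_i(v) \; +\; a_{is}\,\Phi_i(v)\; +\;
   \mathbf{1}[s=\mathrm{post}]\,R_i(v) \;+\; \varepsilon_{is}(v), $$

with

* $B$: a task-positive baseline pattern shared by everyone (two frontal
  task regions, plus a small shared activation of amplitude 0.5 inside
  the aberrant regions — they are task regions for both groups);
* $P_i$: a stable subject-specific pattern (smooth Gaussian field,
  SD 0.5), identical at pre and post — this is what makes two maps from
  the same child look alike;
* $a_{is}\Phi_i$: the group aberration. $\Phi_i$ is the spatial profile:
  three spherical regions (8 mm radius) with amplitudes
  (2.0, 2.6, 3.2), multiplicatively textured as
  $\bigl(1 + 0.7\,(\sqrt{0.3}\,S_g + \sqrt{0.7}\,S_i)\bigr)$ where $S_g$
  is one fixed group-level texture and $S_i$ a subject-level one, both
  smooth unit-SD fields and both stable across sessions. For TD subjects
  $a_{is}=0$; for MLD subjects $a_{i,\mathrm{pre}} = \sigma_i$ (a
  severity factor, $\mathcal{N}(1, 0.10)$) and
  $a_{i,\mathrm{post}} = \sigma_i\,r_i$ with retention $r_i$ a normal
  draw (SD 0.3) clamped to $[0,1]$, whose latent mean is solved so the
  *realized* mean retention equals the configured 0.2 despite clamping;
* $R_i$: idiosyncratic post-tutoring reorganization — a fresh smooth
  subject-specific pattern confined to the aberrant regions, scaled by
  the subject's normalization magnitude (so it vanishes when $r_i = 1$);
* $\varepsilon_{is}$: session noise, smooth (6 mm FWHM, matching the
  study's smoothing kernel) with in-mask SD 0.7.

The latent coupling between brain change and behavioural change is a
bivariate standard normal with correlation $\rho$ (default 0.6): one
component drives retention (less retention = more normalization), the
other drives the logit-scale accuracy change, squashed through the
logistic function so accuracies stay in $[0,1]$.

### Why the texture and reorganization terms exist

Two structural facts force them, and both are worth understanding before
interpreting any result of this pipeline on real data:

* **A spatially uniform group effect is invisible to the classifier.**
  The classifier input is z-transformed within the analysis mask, and the
  mask is precisely where the groups differ. A smooth spherical
  overactivation is nearly constant across its own suprathreshold mask,
  so demeaning deletes it. Discriminability of z-scored patterns requires
  *within-mask profile heterogeneity* of the group difference — which
  real aberrations have (different regions, different magnitudes, fine
  topography). The signature texture supplies exactly this; without it
  the generator would produce strong univariate group differences that
  are multivariately invisible, which real data do not.
* **A purely group-aligned residual effect stays decodable.** If the
  post map were exactly `retention x pre` with one shared topography,
  a classifier would still detect the consistent 20% residual, whereas
  the study's post-tutoring accuracy was at chance. Normalization in
  real cohorts is heterogeneous: children reorganize idiosyncratically.
  The $R_i$ term models this; it simultaneously restores post-session
  within-group variability and gives the BPI its subject-level change
  signal.

### What the generator does not emulate

Physiological noise structure, anatomy, registration error,
susceptibility artefacts, response-time-modulated BOLD amplitude, and any
form of model mismatch between the simulated HRF and the analysis HRF.
Passing calibration tests therefore demonstrates internal statistical
correctness of the pipeline (type-I error control, unbiased recovery,
monotone indices) — not robustness to the many ways real fMRI violates
these assumptions.

## GLM stage

Each trial is modelled as a 9.5 s boxcar at the problem onset (the trial
window; the 0.5 s fixation is unmodelled, as are rests) convolved with a
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1:6, 32 s
support), with a temporal-derivative regressor per sub-condition
orthogonalised to its HRF column. Four sub-conditions are modelled
(Addition/Control x correct/incorrect); contrasts use only
Addition-correct minus Control-correct. Drift is a discrete-cosine basis
with a 128 s cutoff plus intercept. Estimation is voxelwise OLS; runs are
combined by averaging contrast maps and recomputing t by fixed-effects
combination (t-averaging is available by flag). No prewhitening is
applied by default: at TR = 2 s with moderate AR(1) noise the t-maps are
mildly mis-scaled per run, which the calibration tests show does not
disturb group-level error control — group inference treats subjects, not
scans, as the sampling unit.

## Despiking and QC

Scan-to-scan displacement combines translations with rotations converted
to arc length at a 65 mm head radius (the common convention; the
source motion parameters are reported in degrees without a stated
conversion). Volumes with displacement above 0.5 voxels (1.562 mm) or
global-signal deviation above 5% of the run median are replaced by
linear interpolation between the nearest clean neighbours (edge volumes
copy the nearest clean volume). The inclusion gate excludes subjects with
at least 20% of frames interpolated or in-scanner accuracy not strictly
above 50%.

## Group inference and the cluster-extent null

Group maps are compared voxelwise (independent or paired t, optionally
with a centred covariate such as baseline accuracy). Smoothness is
estimated from standardised residual maps by the
variance-of-spatial-derivatives (Forman) estimator. The cluster-extent
threshold `k_min` is the smallest extent whose family-wise exceedance
probability under simulated null maps (white noise smoothed to the
estimated FWHM, standardised in-mask) is at most alpha. `height_p` is
interpreted two-sided (|z| thresholded at `qnorm(1 - p/2)`), components
are labelled within sign (26-connectivity default), and the null maximum
is taken over both signs, so the controlled family is "any cluster in
either direction".

A Gaussian-field null is anticonservative for cluster extent at the
degrees of freedom of a small-sample group analysis: the t statistic's
standard-error denominator is itself a smooth map, so wherever it dips
low a whole neighbourhood's t is inflated and exceedances clump more
than Gaussian theory predicts (in our own calibration runs the realised
family-wise rate was near 5% at a nominal 1% with df = 28). The engine
therefore accepts the analysis `df` and then simulates proper Student-t
fields (each from `df + 1` smoothed noise realisations); the pipeline
passes its group-test df by default, which roughly doubles `k_min`
relative to the Gaussian null and restores calibration. The printed
extent threshold of any particular study depends on its mask,
smoothness and df; the package's contract is that its own Monte-Carlo
engine matches an independent brute-force oracle (Gaussian case,
`fwhm = 0`) and controls the realised FWE rate of the complete pipeline
(t case), which the acceptance tests check.

Bayesian two-group estimation on cluster-mean values uses the standard
robust model: Student-t likelihoods per group with a shared normality
parameter (shifted-exponential prior, mean 30), normal priors on means
(SD = 1000 x pooled SD) and uniform priors on group SDs (pooled SD
x [1/1000, 1000]), sampled with JAGS; reported as the posterior mean
difference with a 95% highest-density interval, effective sample size
and split-chain PSRF convergence flag.

## Classification and permutation inference

Features are z-transformed (population SD) in-mask patterns of the
session t-maps, masked by the pre-tutoring group-difference clusters.
The classifier is a linear soft-margin SVM (C = 1, the common library
default) solved by SMO on a precomputed Gram matrix — numerically the
same classifier as libSVM, verified against it in the test suite, but
fast enough to re-run full LOOCV under thousands of label permutations.
The permutation p uses the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$,
never zero; labels are shuffled once per permutation and reused across
folds. Ties in the decision value count as errors, not coin flips, to
keep the procedure deterministic.

## BPI

For each MLD subject, both session maps are z-transformed in the same
mask and Pearson-correlated over voxels; BPI = 1 - r, so 0 means an
unchanged pattern and values above 1 mean pattern inversion. BPI is
invariant to positive affine rescaling of either map and symmetric in
its arguments. Gains are post minus pre Addition accuracy. The
baseline-covariate screen reports uncorrected Pearson r and p per
measure with listwise deletion.

## Numerical and design choices

* **Connectivity** 26 by default (6/18 available); ties in the cluster
  table are ordered by size.
* **Monte-Carlo resolution**: `n_sim` defaults to 10,000 in the engine
  (2,000 in the pipeline, where the t-field null is 29 times costlier
  per draw and `k_min` is stable to a couple of voxels) and must be at
  least 1,000; alpha below `1/n_sim` is refused rather than extrapolated.
* **Degenerate inputs** error loudly: constant maps in a mask,
  zero-variance t-tests, empty sub-conditions referenced by a contrast,
  all-flagged runs, covariates collinear with group.
* **Seeds**: one configuration seed; every stochastic stage derives a
  sub-stream seed by hashing the stage name (`substream_seed`), so
  stage-level results are reproducible independently of execution order,
  and the same configuration reproduces every number exactly.
* **z-scoring convention**: population (divisor N). The sample-SD variant
  only rescales each feature row by a common factor, which the margin
  geometry is not fully invariant to, hence the fixed convention.
* **Problem sizes in the validation suite**: the calibration studies use
  1,000-2,000 Monte-Carlo null maps, 50-seed sweeps for the
  normalization contrast (with the extent threshold computed once and
  shared across the sweep, since every cohort has the same mask and
  generative smoothness, and 999 label permutations per test so that
  permutation-resolution noise does not blur the 0.05 boundary),
  300-cohort sweeps (on a 16 x 18 x 16 grid with the same three-region
  structure) for BPI recovery, 200 null cohorts for FWE calibration,
  and shortened MCMC (2 chains x 700 retained draws) for the Bayesian
  coverage study. These sizes give Monte-Carlo
  standard errors comfortably inside each test's tolerance.

## Known limitations

* Maps-only mode generates session t-like maps directly; the full BOLD
  path (despike -> GLM -> averaging) is exercised by its own tests but
  the two modes are statistically matched only to first order
  (amplitudes and smoothness, not estimator covariance).
* The smoothness estimator is slightly biased downward on small masks;
  the cluster null uses the same estimator, so the bias largely cancels
  in the FWE calibration.
* The Bayesian stage reports cluster means of subject map values, not a
  full voxelwise posterior.
* With 15 subjects per group, single-cohort BPI-gain correlations are
  noisy (sampling SD of r around 0.25); only seed-swept medians are
  stable, which is how the validation suite treats them.
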