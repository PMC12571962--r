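---
title: "Bayesian parcel-wise analysis of emotional task fMRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian parcel-wise analysis of emotional task fMRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(bayesbold)
```

bayesbold implements a complete Bayesian analysis chain for block-design
emotional-picture fMRI experiments in which two groups (here called PATIENT
and HC) view negative, neutral and positive pictures and rate the elicited
emotion on 9-level Self-Assessment-Manikin (SAM) scales. The chain runs from
trial events and voxel time series to parcel-level group inference, and every
stage can be exercised on synthetic cohorts generated by the package itself.
This vignette explains the models, the tunable parameters, and the design
choices made where the methodology left the design open.

## The experimental design being modelled

One run consists of 54 picture trials: 18 per valence category (NEG, NEU,
POS), crossed with 27 low- and 27 high-arousal pictures. Each picture is
shown for 6 s, followed by a response-terminated rating period of up to 8 s;
successive picture onsets are 10--14 s apart. The scanner acquires 470
volumes at TR = 2 s. Analyses are carried out in 246 atlas parcels; the two
amygdala parcels act as connectivity seeds.

## First-level models

All first-level models share the same construction: neural signals are built
on a microtime grid (16 bins per TR by default), convolved with the
canonical double-gamma HRF (`canonical_hrf()`: peak delay 6 s, undershoot
delay 16 s, unit dispersions, peak:undershoot ratio 6, 32 s support,
positive lobe normalised to unit sum), and sampled at the middle microtime
bin of each volume. Every design contains one stick-function regressor
collecting the rating button presses, six motion regressors of no interest
and a constant.

* **Category model** (`build_model1_design()`): one unit-amplitude boxcar per
  picture category. The contrasts of interest are the category differences
  `NEG - NEU` and `POS - NEU`.
* **Rating-modulated model** (`build_model2_design()`): a mean picture-epoch
  boxcar plus two parametrically modulated epoch regressors whose per-trial
  amplitudes are the centred valence and arousal ratings. The modulators are
  mean-centred over the run but *not* orthogonalised against each other; the
  separation of category and rating effects into distinct models (rather
  than serial orthogonalisation within one model) is what keeps regressor
  collinearity manageable. The valence beta is the rating slope *m* in
  `BR = m x Rating + c`.
* **PPI model** (`build_ppi_design()`): the three task regressors, the
  observed seed eigenvariate, and two psychophysiological-interaction
  regressors (NEG−NEU, POS−NEU). The interaction is formed at the neural
  level: the seed BOLD signal is deconvolved, multiplied by a +1/−1/0
  psychological vector at microtime, and reconvolved -- the defining feature
  of deconvolution PPI as opposed to naive BOLD products. The seed column
  enters as observed BOLD (not the reconvolved neural estimate); left and
  right amygdala are analysed in separate models.

### High-pass filtering

Low-frequency drift is removed by regressing out an orthonormal
discrete-cosine basis (`dct_highpass()`, cutoff 1/128 Hz). The basis
contains every cosine with frequency at or below the cutoff *plus two guard
components above it*. With the textbook basis (components strictly below the
cutoff) a drift at exactly the 128 s cutoff period straddles the band edge
and survives almost untouched; the two guard components reduce the coherent
residual of such a drift below 5% of its amplitude at every phase. The same
residual-forming projection is applied to data and design, so estimates are
unaffected by where the filter is applied in the chain.

### Noise model and estimation

Serial correlation is modelled as AR(1). For each parcel, `fit_glm()`
maximises the restricted likelihood (REML) of the AR coefficient over a grid
(step 0.02), pooling the criterion over the parcel's voxels with per-voxel
variances profiled out; data and design are then prewhitened with the
estimated coefficient and betas are computed by generalised least squares.
The grid formulation lets the whitened-design factorisations be shared
across parcels, which is what makes fitting 246 parcels x 10 voxels x 470
volumes per subject take seconds. With the AR coefficient fixed at zero the
estimator reduces exactly to ordinary least squares. Rank-deficient designs
(for example a run without button presses) fall back to a pseudo-inverse
with a warning, and all-zero columns are flagged non-estimable; contrasts
touching them are refused.

### Deconvolution

`deconvolve_bold()` expands the neural series in a discrete-cosine basis at
microtime resolution (components up to the volume-level Nyquist), convolves
each basis function with the HRF, and solves a ridge problem whose penalty
grows quadratically with frequency relative to the HRF's −3 dB point
(≈ 0.072 Hz for the default kernel). The default ridge weight shrinks a
component at the −3 dB frequency by 5%; this value was chosen so that the
deconvolve-then-reconvolve round trip on noise-free boxcar-driven signals
stays below 5% relative RMS error (a 10% shrinkage, the other natural
candidate, measures about 7% and was rejected). Band-limited signals
round-trip well below 1%.

## Parcel-level group inference

Per-subject voxel contrasts are collapsed to parcel medians
(`extract_parcel_medians()`); the median over ten voxels is a deliberately
robust summary, which is why the synthetic parcels default to ten voxels
rather than one. The resulting subjects x parcels matrix is adjusted for
sex, age and depression score by pooled least-squares residualisation
*without* a group term -- adjusting within groups or with a group term would
remove part of the group signal itself -- and the parcel mean is restored so
group means stay interpretable (`adjust_covariates()`; pooling and intercept
restoration are exposed as choices because the methodology does not pin them
down).

`test_regions()` then applies the dual-threshold rule per parcel:

1. a two-sided JZS independent-samples Bayes factor on the group difference;
   `log10 BF10 > 1.0` (strong evidence) gives a *difference* verdict,
   `log10 BF10 < -0.5` (moderate evidence for H0) a *similarity* verdict,
   anything else *undecided*;
2. a difference parcel is *reported* only if at least one group shows at
   least moderate one-sided main-effect evidence
   (`max over groups and directions of log10 BF > 0.5`), implemented as the
   maximum over the two directions per group, matching the paired
   "effect > 0 | effect < 0" layout of the result tables.

No multiplicity correction is applied across the 246 parcels; this is
faithful to the reporting convention the rule comes from and should be kept
in mind when interpreting single-parcel verdicts.

One property of this rule deserves emphasis: the two-sample JZS Bayes factor
with prior scale $r = \sqrt{2}/2$ is bounded below by its value at $t = 0$,
which at 16 subjects per group is $\log_{10} \mathrm{BF}_{10} = -0.473$.
The similarity verdict therefore *cannot fire* at that sample size; it
becomes reachable from about 21 subjects per group, or earlier with a wider
prior (both the threshold and $r$ are arguments). Published similarity
values slightly below −0.5 at $n = 16/16$ are not attainable under this
exact test recipe.

## Bayes factors

All evidence is reported as common logarithms of Bayes factors, graded as
moderate beyond |0.5| (the favoured hypothesis is ≥ ~3.16 times more
probable) and strong beyond |1.0| (≥ 10 times).

* **JZS t tests** (`jzs_one_sample_bf()`, `jzs_two_sample_bf()`): a
  Cauchy(0, r) prior on the standardised effect, r = √2/2 by default. The
  Bayes factor is evaluated by adaptive quadrature of the noncentral-t
  likelihood directly against the Cauchy prior in effect-size space
  (relative tolerance 1e-8, integration variable centred on the maximum-
  likelihood effect so narrow likelihoods at large n are resolved). This is
  the same integral as the classical scale-mixture-over-g formulation --
  both routes agree to ten decimals -- but it makes one-sided factors plain
  prior truncations, so the identity
  BF10 = (BF+0 + BF−0)/2 holds by construction. Two-sample tests use the
  pooled-variance Student t, which is the statistic the JZS derivation
  assumes; summary-statistic input (means, SDs, n) is accepted alongside raw
  samples.
* **Binomial test** (`binomial_bf()`): closed form with a Beta(1, 1) prior
  against a point null; marginal likelihoods of the same data, so the
  binomial coefficient cancels.
* **Contingency test** (`contingency_bf()`): Gunel--Dickey independent-
  multinomial sampling with symmetric Dirichlet concentration a = 1 and the
  group margins fixed, closed form in gamma functions.
* **Correlation** (`bayes_correlation_bf()`): stretched-beta prior on the
  Pearson correlation (uniform at the default width 1), integrating the
  exact sampling density of the observed correlation coefficient; the Gauss
  hypergeometric function is evaluated by series with a z → 1−z linear
  transformation for arguments near one.

### Inclusion Bayes factors for the repeated-measures ANCOVA

`rmancova_inclusion_bf()` assesses, for each behavioural endpoint, the
evidence for the within-subject factor (picture category), the
between-subject factor (group) and their interaction. The model space is the
null model -- intercept, the nuisance covariates (age, sex, stimulus-set,
depression score) and a subject term -- plus the four admissible extensions
respecting marginality; all five models carry equal prior probability.
Factors are coded with orthonormal sum-to-zero contrasts, covariates are
standardised, and every effect class has a zero-centred scaled prior in the
Jeffreys--Zellner--Siow style: effect scale r = √2/2 for the factors of
interest, 1 for the subject term, and √2/4 for covariate slopes (the
covariate scale is a package choice; it is exposed as an argument because
the methodology does not state one).

Conditional on the per-class variance ratios g the marginal likelihood is
closed form (flat intercept, Jeffreys error variance); the remaining low-
dimensional mixture over g -- each g follows an InverseGamma(1/2, r²/2),
equivalent to the Cauchy effect prior -- is integrated by Monte Carlo with
`mcmc_passes` draws (5000 by default) shared across models, so errors
partially cancel in model comparisons. A split-half consistency check flags
unstable estimates, and per-model Monte-Carlo standard errors are reported.
The inclusion factor for a predictor is the ratio of posterior to prior
inclusion odds across all models; a matched-models variant (inclusion odds
formed only over model pairs differing in that predictor) is available but
off by default. Tiny-data brute-force quadrature over the full joint g-prior
reproduces these marginal likelihoods within Monte-Carlo error, which is how
the estimator is validated.

When the interaction earns at least moderate inclusion evidence
(`behavioral_analysis()`), one-sided two-sample Bayes factors per category
level follow up in the direction of the observed group difference.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study conditions: 16 subjects per group,
the full trial cross and timing above, 9-level ratings, 246 parcels of ten
voxels, 470 volumes at TR = 2 s. Its defaults are the generator's definition
of the study, not tuning knobs.

* **Ratings** follow a latent-Gaussian ordinal model: category mean +
  subject offset (SD 0.5) + trial noise (SD 1), rounded and clamped to 1--9.
  Default category means (NEG 2.8, NEU 5.0, POS 7.2 for valence; LOW 3.2,
  HIGH 6.2 for arousal) are typical normative values for standardised
  emotional picture sets. Flattened patient experience is emulated by
  shrinking patient NEG/POS means 1.5 rating points toward the neutral
  midpoint and shifting arousal means down 0.7 points; setting both to zero
  gives an exact behavioural null.
* **BOLD signals** are sums of HRF-convolved neural regressors (category
  boxcars with base amplitude 0.8, press sticks at 0.3, planted effects), a
  sinusoidal drift (amplitude 1, period 128 s -- deliberately at the
  high-pass cutoff so the filter demonstrably removes it, random phase per
  voxel), and AR(1) Gaussian noise with marginal SD 1 and lag-1 coefficient
  0.3. Planted magnitudes are therefore expressed in units of the noise SD.
  Voxels within a parcel share the parcel's task signal up to a ±10%
  multiplicative gain, and planted magnitudes vary between subjects with
  SD 0.05.
* **Connectivity** effects are injected at the neural level: seed parcels
  carry a smooth intrinsic fluctuation (unit SD, 4 s Gaussian smoothing) on
  top of their task drive, and `ppi_gain` targets receive
  gain x (seed neural x NEG-vs-NEU psychological vector) *before*
  convolution -- exactly the generative structure the PPI estimator assumes
  -- plus a task-independent baseline coupling (0.3) to the seed.
* **Covariates** mimic the demographic table: age ~ Normal(30.5, 8.5),
  balanced sex and stimulus-set, BDI-2 ~ truncated Normal(3.8, 4), and
  scalar recognition outcomes as plain Gaussian columns (the recognition
  paradigm itself is not modelled).
* **Reproducibility**: one root seed spawns one child seed per subject plus
  one for cohort metadata, in subject order; cohorts are bit-identical under
  a fixed root seed.

What the generator does *not* emulate: spatial voxel structure and smoothing
(voxels are exchangeable within a parcel), physiological noise spectra
beyond AR(1)+drift, non-ordinal rating behaviour such as scale anchoring,
scanner artefacts, or any image preprocessing. Passing tests on these
cohorts therefore validates the statistical chain -- regressor construction,
filtering, whitening, deconvolution, Bayes factors, selection rule -- not
robustness to real-scanner artefacts.

## Numerical choices and degenerate inputs

* Quadratures use adaptive routines at relative tolerance 1e-8; noncentral-t
  warnings about the last digits of extreme tail densities are suppressed
  inside integrands where they are harmless.
* The AR grid spans (−0.4, 0.9) in steps of 0.02; REML ties resolve to the
  first maximum.
* Zero-variance samples, empty tables, cutoffs at or above Nyquist, and
  infeasible trial timing raise classed errors (`bayesbold_argument_error`,
  `bayesbold_validation_error`, `bayesbold_config_error`,
  `bayesbold_format_error`). Degenerate parcels yield an `undecided` verdict
  with a flag rather than an error, so one bad parcel cannot sink a
  whole-brain run.
* Problem sizes used by the test suite: unit tests run on reduced geometries
  (6--34 parcels, 160--470 volumes, 18-trial designs); the end-to-end
  recovery checks run one planted and one null cohort at the full
  32 x 246 x 470 geometry; ANCOVA calibration uses 200 null and 50 planted
  replicate cohorts at 1500 Monte-Carlo passes; Monte-Carlo oracles use 10^6
  draws. These sizes are the package's validation design and are fixed in
  the test code.

## Known limitations

* AR order is fixed at 1 and pooled within parcel; no voxel-wise whitening,
  no FIR or derivative HRF bases.
* The rating epoch is modelled only through button-press sticks; the 6 s
  picture epoch alone carries category information.
* The PPI implementation covers the two stated contrasts only -- no
  generalised PPI with per-condition regressors, no seed-to-seed models.
* Inclusion-BF marginal likelihoods are Monte-Carlo estimates; with very
  strong effects their error grows (the split-half flag reports this), which
  matters little for threshold decisions but makes extreme log-BF magnitudes
  approximate.
* The similarity branch of the selection rule is unreachable at 16 subjects
  per group with the default prior scale, as explained above.
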