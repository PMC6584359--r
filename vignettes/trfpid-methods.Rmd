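---
title: "Methods: encoding models, copula information theory and PID in trfpid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding models, copula information theory and PID in trfpid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfpid)
```

## The problem

Continuous neural recordings during natural speech listening can be
predicted from the stimulus with linear temporal response functions (TRFs):
a filter `w(v, tau)` maps stimulus features `s(v, t - tau)` at lags `tau`
(`tau > 0` = past stimulus) onto the response,

    r_hat(t) = sum_v sum_{tau = tMin..tMax} w(v, tau) s(v, t - tau).

A recurring question is whether "higher-level" feature spaces (phoneme
onsets, articulatory features) predict anything that simpler acoustic
spaces (envelope, spectrogram, spectral derivatives, spectro-temporal
modulation energies) do not. trfpid provides the full comparison machinery:
feature extraction, per-subspace ridge TRFs under nested cross-validation
with black-box hyperparameter search, Gaussian-copula mutual information
(MI) and partial information decomposition (PID) of model predictions, and
hierarchical Bayesian comparison of per-fold performances — all exercisable
on synthetic data with known ground truth.

## The model and its estimator

`fit_ridge()` uses the closed-form solution `w = (S'S + Lambda)^-1 S'r`,
where `S` is the lagged design built by `build_lagged_design()` (zero-padded
at segment edges; columns organized as channel blocks within lag groups).
When a feature space carries several subspaces, each subspace has its own
lag window `(tMin, tMax)` and its own penalty on its diagonal block of
`Lambda`. No intercept is fitted; features and responses are z-scored
upstream (responses within each portion).

Numerical choices:

* The penalty is applied unscaled (no normalization by `trace(S'S)`), so
  lambda grids/bounds are data-scale dependent — deliberate, matching the
  fixed grids used in the field.
* Rank-deficient `S'S` with a zero penalty raises an error naming the
  problem; any positive penalty proceeds via Cholesky with a `1e-10`
  jitter fallback.
* Edge handling: lagged copies are zero-padded rather than trimmed, so all
  subspaces share a common row count regardless of their windows.

## Nested cross-validation and hyperparameter search

`nested_cv()` splits the data into 6 contiguous equal portions. Every
ordered (test, tune) pair of distinct portions is one assignment (30 in
total); the remaining 4 portions train. Per assignment, a derivative-free
optimizer (`optimize_blackbox()`) tunes per-subspace `(tMin, tMax,
log10 lambda)` against tuning-set Pearson correlation with a budget of 200
objective evaluations. Within an outer fold the 5 assignments' choices are
averaged — lag bounds in seconds, rounded toward the *wider* window;
lambda on the log10 scale (a design choice: the search box is log-scaled,
so averaging log-lambda matches the geometry of the search) — then weights
are retrained on all 5 train assignments with the averaged hyperparameters,
averaged, and applied once to the held-out portion.

The optimizer is a *contract*: proposals within bounds, determinism given a
seed, best point plus full trace returned. The reference implementation is
an RBF-surrogate-assisted pattern search with Latin-hypercube
initialization; reproducing any specific published optimizer's internals is
a non-goal, and the tests assert quality on known test functions rather
than a particular search trajectory. Default box per subspace: `tMin` in
[-0.3, 0] s, `tMax` in [0.05, 1] s, `log10 lambda` in [-3, 8] — repository
defaults (appropriate bounds for real recordings are dataset-specific),
fully user-configurable.

A practical caveat the tests surfaced deliberately: for low-dimensional
feature spaces the tuning-set correlation is nearly flat over several
decades of lambda, so individual lambda choices are weakly identified;
averaging across inner folds is what stabilizes the recovered TRF — with
real recordings the same flatness is typical for low-dimensional
subspaces.

`grid_search_cv()` is the EEG-style alternative: block rotation (each block
tests once, one validation block), a single shared lambda from the
exhaustive grid `0.1^k, k = -25..60` (86 values), fixed lags
`(-0.1, 0.4)` s, with a warning if an extreme grid value is ever selected.

## Feature spaces

| name | channels | construction |
|------|----------|--------------|
| Sg | 31 | log-mel spectrogram, centers 124.1–7284.1 Hz, 25 ms Hann / 10 ms hop |
| Env | 1 | channel-sum of Sg |
| Deriv | 31 | half-wave rectified first difference of Sg (one zero prepended) |
| Gabor | 455 | 2D Gabor modulation filterbank on Sg |
| PhOn | 1 | unit impulses at phoneme onsets |
| Art | 23 | impulses in binary articulatory-feature channels |
| Sg16 / Sg16c | 16 | Butterworth–Hilbert envelope bank (optionally power 0.3) |

All acoustic spaces are computed at their native frame rate, resampled to
40 Hz (Fourier resampling) and z-scored by `preprocess()`; event spaces are
built directly at 40 Hz. Onset-to-sample rounding is nearest-with-ties-
earlier, stated because a half-sample shift of impulse placement shifts TRF
latencies.

The Gabor bank reconstructs the published filterbank design: modulation
center frequencies descend multiplicatively from 0.25 cycles/unit with the
spacing factor `(nu + 4 d)/(nu - 4 d)` (`nu = 3.5`, spectral `d = 0.3`,
temporal `d = 0.2`), reproducing the documented sets
Omega = {0, 2.9, 6, 12.2, 25} and omega = {0, 6.2, 9.9, 15.7, 25} Hz, with
both spectral orientations where defined (41 filter shapes). Filter outputs
are subsampled across mel channels in proportion to the filter's spectral
extent, symmetric about the center channel; purely temporal filters keep
only the center channel. The subsampling proportionality constant (one
tenth of the uncapped extent) was calibrated once so that the default bank
emits exactly 455 channels at 31 mel channels — the reference bank's
documented dimensionality — and is asserted as a regression test. Because
the reference code was not available in this build environment, this is a
reconstruction from the published constants, not a copy; the modulation
sets match the printed values to their printed precision.

For the Gabor space, `autocorrelation_time()` and `allocate_gabor_lags()`
implement the lag-allocation heuristic: slow temporal-modulation groups get
the full lag window, fast groups a short one, intermediate groups windows
interpolated in proportion to their mean autocorrelation times (ACT = first
lag where the normalized absolute autocorrelation drops below 0.05; the
estimator uses unbiased normalization so that periodic series correctly
report *no* finite ACT instead of the artifact of the biased estimator).

## Copula MI and the I_ccs decomposition

All continuous variables are rank-transformed per channel
(`rank/(n + 1)`, average ties, then the inverse normal CDF), making MI
estimates invariant to monotone marginal transforms. Gaussian MI terms are
bias-corrected analytically (Wishart expectation of log-determinants).
Units are bits everywhere.

`pid_ccs()` decomposes the joint MI of two sources about a target into
redundancy, two unique terms and synergy following the common change in
surprisal construction: redundancy is the expectation of pointwise
co-information restricted to samples where (I) both sources carry pointwise
MI about the target with the same sign and (II) the pointwise
co-information shares that sign. The expectation is a Monte-Carlo integral
over the *fitted* model — a joint Gaussian for continuous targets, a
class-conditional Gaussian mixture (empirical class weights, per-class
covariances) for discrete targets. Unique terms and synergy follow from the
lattice, so the lattice identities hold to machine precision by
construction, and negative unique information (pointwise misinformation
unique to one source) is possible — which is also why redundancy normalized
by a benchmark's marginal MI (`normalize_pid()`) can exceed 1.

Degenerate-input policy: collinear channels *within* one variable raise an
error naming the problem; an exactly rank-degenerate *cross* dependence
(e.g. one source a monotone transform of the other, as with identical
sources) is handled by a `1e-12` diagonal regularization and reports the
estimator's ceiling rather than crashing. Covariances inside the PID are
regularized by `1e-8` of the mean diagonal for conditioning.

`permutation_threshold()` builds maximum-statistics noise thresholds from
circular shifts of at least 200 samples (and at most `n - 200`), taking the
95th percentile of the permutation maxima by default.

## Redundancy mapping and phoneme-locked analyses

`iterative_unique_mapping()` reproduces the iterative mapping logic: with
the currently selected grid points (repetition 1) as a multivariate first
source, every grid point contributes one PID with its own repetition-1
activity as second source and its repetition-2 activity as target; the
unique-information peak is appended and the scan repeats (10 iterations by
default). On leakage-only fixtures the peak unique information collapses
once the latent sources are covered — the L-shaped decay. One subtlety the
synthetic tests make explicit: if per-grid-point noise is large, a
neighbor's *own* recording genuinely carries extra information about the
latent source beyond a noisy seed point, so "leakage-only" fixtures must
use small sensor noise (0.1 of the source amplitude here) for near-zero
unique information to be the correct expectation.

`epoch_events()` cuts (-0.1, +0.6) s epochs (29 samples at 40 Hz) around
onsets; overlapping epochs are kept (at ~10 events/s overlap is the rule,
and all events are used), no baseline correction is applied, and events
whose window leaves the recording are dropped with a message.
`mi_timecourse()` uses 4 equipopulated bins per time point (plugin MI; a
Miller–Madow correction is available behind a flag and off by default);
`pid_timecourse()` runs the discrete-target PID with observed and
predicted epochs as sources.

## Hierarchical Bayesian comparison

`fit_hierarchical()` implements the zero-intercept model with fixed
feature-space effects (prior N(0, 10), read as *variance* 10 — flagged
because some tools parameterize by sd; `prior_is_sd = TRUE` switches) and
zero-mean random effects for participant:feature, participant:fold,
participant:hemisphere and hemisphere:feature sharing one half-t(3, 0, 10)
scale, residual sd half-t(3, 0, 10), with 4 chains x 4000 iterations (1000
warmup) by default. The sampler backend is pluggable in principle; the
shipped backend is a conjugate Gibbs sampler using the inverse-gamma
scale-mixture representation of the half-t priors, which is exact for this
model family, fast, and deterministic given a seed. Split-R-hat is reported
and non-convergence warns rather than fails (the CLI pipeline must survive
degenerate synthetic inputs). `hypothesis_fraction()` returns the fraction
of posterior draws supporting a directed contrast; the lognormal family
(log-response Gaussian model) serves skewed normalized PID ratios.

## What the synthetic world does and does not establish

`simulate_features()` produces Gaussian-kernel-smoothed white noise —
matching the 40 Hz rate and smoothness scale of spectrogram features but
*not* the modulation spectrum, harmonic structure or sparsity of real
speech. `simulate_events()` is a truncated-exponential renewal process
(~10 events/s, 30 ms refractory period), not language-driven phoneme
timing. Responses come from the exact forward model plus white Gaussian
noise, so `snr/(snr + 1)` is the exact repeat-correlation and
`sqrt(snr/(snr+1))` the exact prediction ceiling; real recordings violate
all of this (1/f noise, nonstationarity, nonlinearity). A green test
therefore establishes *estimator correctness under the stated model*, not
fidelity to any particular dataset. Defaults: snr on the variance scale as
stated per use (10 for recovery tests), 4 equiprobable event classes, one
global seed with per-operation derived substreams so stages can be
regenerated independently.

## Known limitations

* The articulatory mapping shipped in `inst/extdata` is a standard
  voicing/manner/place/vowel-position scheme covering ARPAbet — a
  documented, user-replaceable default rather than a claim about any
  particular annotation scheme.
* The hyperparameter search box defaults are declared repository choices,
  not values tied to a specific dataset.
* Serialization uses TSV/JSON containers instead of HDF5 (no HDF5 R
  bindings in the supported environment); the formats are self-describing
  and lossless for the package's data.
* Only two-source PIDs are implemented (the multivariate selected set in
  redundancy mapping enters as one multivariate source); other PID
  definitions are out of scope.
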