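---
title: "Methods: simulating and decoding object-space dimensions in RSVP EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding object-space dimensions in RSVP EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

A prominent proposal holds that high-level visual cortex organizes object
representations along a small number of "object-space" dimensions —
animacy, category, and shape aspect ratio (compact "stubby" versus
elongated/limbed "spiky" objects). Disentangling these dimensions is hard
because they are correlated in natural images, and because their neural
signatures evolve within a few hundred milliseconds. A time-resolved
multivariate approach addresses both problems: a rapid serial visual
presentation (RSVP) stream of objects whose category and aspect ratio are
orthogonalized by construction, recorded with EEG, and decoded timepoint
by timepoint. Presenting every object both *intact* (textured) and as a
uniform *silhouette* further manipulates how much internal (category
diagnostic) information is available while leaving outline shape
untouched.

`objspace` implements this full workflow as reusable, tested code: a
synthetic stimulus set and experiment design with the paradigm's exact
combinatorial structure, a generative simulator for multi-subject epoch
data with known embedded effects, the decoding and representational
similarity analyses, and Bayes-factor statistics. Because every effect in
the simulated data is injected explicitly, each analysis can be validated
by parameter recovery: the pipeline must find exactly the latencies,
amplitude orderings and model structure that were put in.

## Stimulus set and design

Each of 52 base objects belongs to one of four categories (body, face,
manmade, natural; bodies and faces are animate) and one of three shape
classes: 6 stubby, 6 spiky and 1 median object per category. Shapes are
random star-shaped regions on a 256 x 256 grid; stubby shapes are
perturbed, stretched ellipses, spiky shapes are multi-armed stars. The
aspect ratio statistic is the isoperimetric quotient

$$AR = \frac{P^2}{4\pi A},$$

with $P$ the outer-boundary perimeter and $A$ the foreground area; a disk
attains the minimum of 1. On rasters we estimate $P$ by Moore-neighbour
tracing of the boundary and measuring the closed polygon through every
4th contour point. A raw chain-code length (axis steps 1, diagonal steps
$\sqrt 2$) overestimates smooth perimeters by about 5% — enough to push a
disk's $AR$ to ~1.10 — while contour resampling brings the disk to
within 1% of 1 and leaves polygonal shapes essentially exact (a square
rasterized at side 120 scores within 3% of its true $4/\pi$). Median
objects are rejection-sampled until their $AR$ falls strictly between
their category's stubby maximum and spiky minimum, which makes the
median-exclusion rule of the shape-class analyses testable.

Silhouette renderings assign the constant value 0.2 to all object pixels
on a mid-gray background; intact renderings fill the same mask with a
seeded oriented-grating texture normalized to a fixed mean foreground
luminance of 0.5. We deliberately do not equalize full luminance
histograms or spatial-frequency spectra across images — the synthetic
stimuli control only mean luminance, and the pixel-level model RDM is
available to absorb residual low-level structure.

The design generator produces, per rendering, `n_runs_per_rendering` runs
of `52 x repeats_per_run` presentations at 5 Hz (200 ms per event), with
2–4 task-target events inserted as *extra* stream slots (presentations
are never replaced, so each run keeps its full object count; a run with
$k$ targets lasts $(208+k) \times 0.2$ s at the default 4 repeats).
Silhouette run $k$ is yoked to intact run $k$: identical object sequence
and target slots. Target temporal positions are drawn uniformly without
adjacency constraints. At the full-scale defaults this reproduces the
paradigm arithmetic exactly: 40 runs, 8,320 non-target trials, every
stimulus presented 80 times per rendering, run durations between 42 and
42.4 s.

## The generative epoch model

`simulate_subject()` produces baseline-demeaned 64-channel epochs from
-100 to 800 ms at 200 Hz (181 samples). Per trial the signal is a sum
over dimensions:

* **aspect ratio** — contrast +1/-1 for spiky/stubby (0 for medians),
  one occipitally weighted topography, peak 95 ms, transient
  (`sustained_fraction` 0.15);
* **animacy** — contrast +1/-1 for animate/inanimate, peak 118 ms,
  sustained (0.35);
* **category** — four zero-sum topography patterns (so genuine 4-way
  structure exists, not just one contrast), peak 125 ms, sustained;
* **identity** — 52 low-amplitude per-stimulus patterns, enabling
  pairwise decoding and neural RDMs.

The temporal kernel is a half-Gaussian rise to the peak (the
`duration_ms` parameter is the FWHM of the rising flank) followed by an
exponential decay to a `sustained_fraction` plateau, so a single
parameterization covers both transient and sustained profiles. An
optional `flip_ms` reverses the topography sign after a given latency,
which is how offset-locked pattern reversals (and the below-chance
temporal-generalization cells they produce) can be emulated; it is off by
default. Amplitudes are per rendering: silhouettes carry the stronger
aspect-ratio signal, intact stimuli the stronger animacy and category
signals.

Noise is Gaussian with per-channel standard deviation 3 uV, spatially
correlated across channels by a squared-exponential kernel over the 2-D
layout distances (length scale 0.45 head radii), temporally smoothed by a
variance-preserving Gaussian kernel (15 ms SD), plus a log-normal
per-trial gain jitter (SD 0.1) on the signal. Amplitudes (0.20/0.34 uV
for aspect ratio intact/silhouette, 0.26/0.15 for animacy, 0.36/0.22 for
category, 0.08 for identity) were calibrated once so that group-mean peak
decoding on the scaled design lands in the mid-50s to mid-60s percent
band for binary dimensions, and fixed thereafter. The simulator does
*not* model RSVP superposition of adjacent items (the design's
randomization argument is precisely that neighbours are not
systematically different), forward head geometry, ERP component families,
eye blinks or 1/f spectra. Consequently, passing parameter-recovery tests
demonstrates the correctness of the analysis chain, not the realism of
any particular ERP morphology.

The sensor layout is a schematic 2-D projection of the 64-channel 10-10
montage built in code (labels Fp1 ... Iz); it is used for searchlight
neighborhoods and noise correlation, where only relative geometry
matters.

## Decoding analyses

All classification uses multiclass linear discriminant analysis with a
pooled within-class covariance shrunk toward $\nu I$ ($\nu$ = mean
eigenvalue) with the analytic Ledoit–Wolf-type intensity estimated per
fold and timepoint — parameter-free and positive-definite even when
trials < channels. Priors are uniform; ties break toward the lowest
class index; classifiers are trained on single trials (no pseudo-trial
averaging; an optional switch was considered and rejected as the
single-trial reading is the plain one). Plain proportion correct is
reported — the design is balanced or nearly so by construction (26/26
animate/inanimate, 24/24 stubby/spiky after median removal, 13 per
category). Folding is leave-one-run-out throughout, and renderings are
always analyzed separately. Group-level results are unweighted subject
means.

* `decode_timecourse()` — whole-head accuracy per timepoint; chance 1/2,
  1/4 or 1/52.
* `temporal_generalization()` — train at each timepoint, test at all;
  the identical fold structure makes the matrix diagonal *exactly* equal
  to the standard time course (asserted bitwise in the tests).
* `cross_decode()` — train one dimension on one class of the other
  (e.g. stubby-vs-spiky on animate objects only), test on the held-out
  class, leave-one-run-out applied to the test class's runs, both
  directions averaged.
* `searchlight_decode()` — features restricted to each channel plus its
  3 nearest layout neighbours (ties in distance broken by label order);
  a binned view averages 100 ms windows starting at -50 ms.
* `pairwise_decode()` — one classifier per stimulus pair per timepoint;
  accuracies populate symmetric neural RDMs with zero diagonals.

The compiled (C++/Armadillo) cross-validation engine is verified
fold-by-fold against an independent brute-force R implementation of the
shrunk discriminant on small problems.

## RSA and model regression

Model RDMs are binary same/different matrices for aspect ratio, category
and animacy ("same" = 0), plus a pixel model: the Jaccard distance
between foreground pixel sets. Because intact and silhouette renderings
share masks, their default pixel models coincide; an intensity-binned
variant differentiates intact textures when requested. For the
aspect-ratio model, median objects are folded into a side by
thresholding their continuous $AR$ at the category midpoint, so all 52
objects enter the RSA (the classification analyses, in contrast, drop
them — the two choices are deliberately independent).

`fit_rdm_glm()` regresses the vectorized lower triangle (1,326 pairs) of
the neural RDM on all model regressors jointly plus an intercept,
per timepoint, by OLS — not rank correlation, as the linear-model
formulation is the specified one. Model regressors are z-scored across
pairs by default so betas are comparable across models; the neural
vector stays on its native accuracy scale and the intercept absorbs
overall decodability. Rank-deficient model sets abort with the offending
regressors named. With a single binary model and no z-scoring, the beta
equals the plain mean dissimilarity gap between "different" and "same"
pairs — a closed-form identity the tests exploit.

## Bayes factors

Evidence for above-chance decoding uses a one-sample Jeffreys–Zellner–
Siow test across subjects at each timepoint: the alternative places a
Cauchy prior (width 0.707) on the standardized effect $\delta$,
truncated to $|\delta| \ge 0.5$ (two-tailed, admitting only at least
medium effects in either direction); the null is a point mass at 0.
Marginal likelihoods integrate the noncentral-t likelihood over the
prior by adaptive quadrature (relative tolerance 1e-8), working in log
space throughout: each support interval is split at the likelihood
mode and integrated under a log-scale substitution toward its peak, so
the sharp boundary layers produced by overwhelming evidence are
resolved and the log Bayes factor stays finite at any $t$. Where R's
noncentral-t algorithm loses precision (deep tails), the log-density
falls back to a Laplace approximation of the chi-scale-mixture
representation with closed-form mode and curvature, accurate there to
well under 0.01 log-units. The whole computation is checked against an
independent Gauss–Legendre oracle on a grid of $t$ and $n$ to 1e-4
relative error. Intact-minus-silhouette differences are tested
pairwise against 0 with the same symmetric exclusion — we read the
stated asymmetric interval "(-0.5, 5)" as a typo for $(-0.5, 0.5)$, but
`prior_spec()` accepts any exclusion interval so the literal reading is
one argument away. RSA betas use the adjusted prior: full two-sided
Cauchy, no excluded interval, point null ("two-tailed without an
expected null prior value" is ambiguous between no-point-null and
no-exclusion; we chose no-exclusion and record the ambiguity here). An
`"interval"` null type (prior mass restricted to the excluded band) is
also implemented for sensitivity analyses.

One boundary case is worth stating: `bf_one_sample()` refuses
zero-variance inputs, but `bf_difference()` evaluates timepoints where
every paired difference is exactly zero at $t = 0$ — the limit of the
test as the difference variance shrinks with the mean at the null —
yielding BF < 1 rather than an error, which is the informative answer
for identical conditions.

## Peaks, onsets and the evidence flag

`summarize_peaks()` defines peak latency as the argmax of the group-mean
accuracy, and onset/offset as the first/last timepoint of the longest
stretch of at least 3 consecutive timepoints with BF > 1 (the source
analyses report "~" latencies without an explicit criterion; sustained-
evidence windows are our operationalization). A results bundle is
flagged `no_evidence` when no dimension shows 3 consecutive timepoints
of BF > 3 — isolated single-timepoint fluctuations, which arise by
chance among hundreds of tests, do not count.

With peaks injected at 118 and 125 ms on a 5 ms sampling grid, the
animacy/category peak *order* is intrinsically at the resolution limit:
group-level noise flips the argmax between adjacent samples. The
package's headline recovery property is therefore the one the data can
support: aspect ratio peaks strictly earliest in both renderings, each
dimension's latency is recovered within +-10 ms at its higher-SNR
rendering (silhouette for aspect ratio, intact for animacy and
category), and the amplitude flip (silhouette > intact for aspect ratio;
intact > silhouette for animacy and category) holds at the peaks.

## Problem sizes and numerical choices

The test suite and the acceptance script run scaled study conditions
chosen once: null calibration uses 5 subjects, 4 runs per rendering and
2 repeats per run (416 trials per rendering per subject); parameter
recovery uses 10 subjects under the same design; pipeline smoke and
determinism checks use 2–5 subjects with reduced analysis sets;
pairwise-decoding tests restrict the time axis to a handful of
timepoints, since each of the 1,326 pairs is its own cross-validated
problem. Full-scale simulation (8,320 trials per subject) allocates
multi-gigabyte arrays and is intended for workstation use, not the test
suite. Other numerical choices: covariance estimates divide by $n$
(MLE); the baseline window is $-100 \le t \le 0$ ms inclusive;
integration tolerances are stated above; all randomness flows from a
single session seed through deterministic 32-bit sub-seed derivation, so
every artifact — stimulus set, design, epochs, analyses — is bit-wise
reproducible from one integer.

## Known limitations

The synthetic stimuli are abstract shapes, not photographs; the
"category" structure is a labeled topography, not semantic content.
Real EEG violates several simulator assumptions (stationary noise, no
inter-trial overlap, fixed topographies), so quantitative accuracies
here do not predict empirical effect sizes — only the analysis chain's
correctness. The external-array adapter (`as_epochs()`) applies the same
analyses to real epoch arrays of matching shape, but no download or
BIDS logic is included. Scalp-map rendering, noise ceilings,
cross-validated RDM regression variants and cluster-permutation
statistics are out of scope.
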