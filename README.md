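# objspace

Time-resolved EEG decoding and representational similarity analysis of
object-space dimensions.

## The problem

Visual object processing is often described in terms of a low-dimensional
"object space" whose candidate axes are **animacy**, **category** (faces,
bodies, manmade and natural objects) and shape **aspect ratio** — compact
"stubby" versus elongated, limbed "spiky" objects, quantified by the
isoperimetric statistic

    AR = P² / (4 π A)

(P = outline perimeter, A = area; a disk attains the minimum of 1).
Disentangling these axes requires a stimulus set in which they are
orthogonal by construction, a presentation paradigm fast enough to sample
the first few hundred milliseconds of processing (5 Hz rapid serial
visual presentation), and a manipulation of available stimulus
information (intact textured images versus uniform silhouettes that
preserve only outline shape). `objspace` implements the complete analysis
pipeline for such experiments — and, because real recordings are not
always at hand, a fully parameterized generative simulator whose injected
effects the analyses must recover.

The analysis core:

* **Shrinkage-LDA decoding** at every timepoint with leave-one-run-out
  cross-validation: whole-head accuracy time courses (2-, 4- and 52-way),
  sensor searchlights on 4-channel neighborhoods, cross-decoding of one
  dimension across the classes of another, temporal generalization
  matrices (train at time t, test at all t'), and pairwise stimulus
  decoding. The pooled covariance is shrunk toward a scaled identity with
  the analytic Ledoit-Wolf intensity, so the classifier is well defined
  even with fewer trials than channels.
* **RSA with model-RDM regression**: pairwise decoding accuracies form
  neural representational dissimilarity matrices; binary model RDMs
  (aspect ratio, category, animacy) and a pixel-overlap Jaccard model are
  regressed jointly on the 1,326 stimulus pairs at each timepoint by OLS,
  yielding beta time courses.
* **Bayes-factor statistics**: Jeffreys-Zellner-Siow one-sample tests
  across subjects per timepoint, with a Cauchy(0, 0.707) prior truncated
  to |δ| ≥ 0.5 for decoding-vs-chance and condition differences, and a
  full two-sided Cauchy for RSA betas; marginal likelihoods by adaptive
  quadrature, verified against an independent quadrature oracle.

## Worked example

Simulate a scaled five-subject study (4 runs per rendering, 2 repeats per
run — 416 trials per rendering per subject) and decode two dimensions:

```r
library(objspace)

set    <- build_stimulus_set(seed = 1)
design <- build_design(set, n_runs_per_rendering = 4,
                       repeats_per_run = 2, seed = 2)

tcs_ar <- list(); tcs_an <- list()
for (i in 1:5) {
  epochs <- simulate_subject(design, set, subject_seed = 100 + i,
                             subject = i)
  tcs_ar[[i]] <- decode_timecourse(filter_medians(epochs),
                                   "shape_class", "silhouette")
  tcs_an[[i]] <- decode_timecourse(epochs, "animacy", "intact")
}
group_mean(tcs_ar)
#> Decoding 'shape_class' [silhouette]: peak 64.2% at 95 ms (chance 50.00%, 4 folds)
group_mean(tcs_an)
#> Decoding 'animacy' [intact]: peak 61.3% at 125 ms (chance 50.00%, 4 folds)
bf_timecourse(group_mean(tcs_ar), 0.5)
#> BF series (vs_chance): 181 timepoints, 50 with BF > 1, max log10 BF 4.50
```

The printed peaks recover the simulator's ground truth: the aspect-ratio
signal is injected at 95 ms and is strongest in silhouettes, the animacy
signal at 118 ms and strongest in intact stimuli; both decode in the
mid-50s to mid-60s percent range against their 50% chance level, and the
Bayes factors flag a sustained above-chance window around the peak.
`run_all(run_config(...))` chains the full study — stimuli, design,
simulation, every decoding analysis, RSA and Bayes factors — into one
reproducible bundle, and `summarize_peaks()` tabulates peak latencies,
accuracies and BF-supported onset/offset windows.

## Package layout

| Area | Functions |
| --- | --- |
| Stimuli & design | `build_stimulus_set`, `generate_shape`, `render_stimulus`, `compute_aspect_ratio`, `build_design`, `design_trials`, `write_stimuli` |
| Simulation | `make_layout`, `effect_spec`, `default_effect_spec`, `null_effect_spec`, `noise_spec`, `simulate_subject`, `as_epochs`, `save_epochs` |
| Decoding | `fit_lda`, `decode_timecourse`, `filter_medians`, `cross_decode`, `temporal_generalization`, `searchlight_decode`, `pairwise_decode`, `group_mean` |
| RSA | `model_rdm`, `pixel_rdm`, `jaccard_distance`, `fit_rdm_glm` |
| Statistics | `prior_spec`, `rsa_prior`, `bf_one_sample`, `bf_timecourse`, `bf_difference`, `bf_beta` |
| Orchestration | `run_config`, `run_all`, `summarize_peaks`, `write_config`, `read_config` |

The methods vignette (`vignettes/object-space-decoding.Rmd`) documents
the generative model, every tunable parameter with units and defaults,
the numerical choices, and what the simulation-based tests do and do not
establish about real EEG data.
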