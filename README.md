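# megrsa

Region-based decoding and representational similarity analysis (RSA) for
source-space MEG.

## What problem this solves

Time-resolved multivariate pattern analysis of MEG usually happens in sensor
space, where effects are hard to localize. An alternative is to work on
source-space data confined to cortical atlas regions: for each of 82
bilateral regions (a modified Destrieux scheme, packaged with the library),
the vertex time courses are reduced to **three spatial principal
components**, and a cross-validated linear classifier is run per region and
per 10-ms time bin for every pair of stimulus conditions. The pairwise
decoding accuracies form empirical representational dissimilarity matrices
(RDMs) that can be compared against hypothesis-driven model RDMs, giving
region-time maps of model-specific activity — e.g. where and when the cortex
distinguishes faces from nonsense images beyond low-level stimulus
differences.

`megrsa` implements that pipeline for experiments with 6 stimuli (2 faces,
2 tools, 2 nonsense images) presented in 2 experimental sections, which
yields 12 condition entries and 66 pairwise classifications. It is aimed at
MEG/EEG researchers who want region-resolved decoding with honest group
statistics, and it ships a synthetic-data generator with a ground-truth
manifest so the whole pipeline is testable without any recordings.

## The method in brief

For each subject, region *r* and time bin *t*:

1. **Reduction.** The region's vertex × (time · trials) matrix is
   vertex-mean centred; the top 3 spatial principal components are kept and
   all trials are projected onto them.
2. **Pseudo-trials.** Each (stimulus, section) condition's trials (up to 80;
   conditions under 50 trials are excluded) are randomly split into 10
   groups of 5–8 and averaged.
3. **Decoding.** For each pair of conditions, a pooled-covariance linear
   discriminant (ridge `λ = 10⁻³`) is trained on 18 pseudo-trials and tested
   on 2 held out, re-randomizing the pseudo-trial composition 100 times;
   accuracy is the dissimilarity measure `d(a, b)`.
4. **RSA.** The 12 × 12 empirical RDM is correlated (Spearman, average
   ranks) with three model RDM types — *stimulus recognizer*,
   *category-vs-nonsense*, and *one-vs-rest* (face / tool / meaningful) —
   and correlations are Fisher-transformed, `z = atanh(ρ)`.
5. **Group statistics.** One-sample t-tests at each region-time cell,
   Benjamini–Hochberg FDR over the full 82 × 81 grid (q = 0.01 for types
   1–2, q = 0.05 for type 3), onset = first significant post-stimulus bin;
   bootstrap (1000 resamples of participants) for decodability
   characteristics; a Bartlett dimensionality (MANOVA) test of whether the
   three models' spatial maps are genuinely distinct.
6. **Repetition effects.** Regional activity is projected onto the
   classifier boundary coefficients, trials are averaged in 10 sequential
   presentation-order segments, and the absolute window-mean amplitudes are
   regressed on segment index (pooled over subjects; slope *k*, F-test with
   df (1, 10·n − 2)).

## Worked example

Simulate a small study with an early stimulus-specific stage, a face-binding
stage at 140–170 ms and a tool-binding stage at 210–220 ms, then run the full
pipeline:

```r
library(megrsa)
library(dplyr)

cfg <- simulation_config(
  n_subjects = 4, n_regions = 6, vertices_per_region = 8,
  n_trials_per_condition = 60, noise_sd = 1, seed = 42,
  effects = list(
    effect_spec("stimulus_specific", target_regions = 1:2,
                window_ms = c(50, 250), amplitude = 2),
    effect_spec("category_binding", target_regions = 3,
                window_ms = c(140, 170), amplitude = 5, category = "face"),
    effect_spec("category_binding", target_regions = 4,
                window_ms = c(210, 220), amplitude = 5, category = "tool")))

res <- run_pipeline(cfg, n_randomizations = 20, one_sided = TRUE)
res
#> <pipeline_result> 4 subjects, 6 models, 6 regions x 81 time bins
#>   40 significant region-time cells; 8 region onsets found
#>   model specificity: chi2(20) = 37.07, p = 0.0115

res$onsets |> filter(!is.na(onset_ms)) |> arrange(model, region)
#> # A tibble: 8 × 3
#>   model            region onset_ms
#>   <chr>             <int>    <dbl>
#> 1 face_specific         3      140
#> 2 face_vs_nonsense      3      150
#> 3 recognizer            1       90
#> 4 recognizer            2      100
#> 5 recognizer            3      140
#> 6 recognizer            4      220
#> 7 tool_specific         4      210
#> 8 tool_vs_nonsense      4      210

glance(res$manova)
#> # A tibble: 1 × 7
#>    chi2    df p_value n_obs n_areas n_groups rank_deficient
#>   <dbl> <dbl>   <dbl> <int>   <int>    <int> <lgl>
#> 1  37.1    20  0.0115    24       6        6 FALSE
```

Reading the output: the *stimulus recognizer* model fires early in the
regions carrying stimulus-specific activity (onsets 90–100 ms), the
*face-specific* one-vs-rest model finds the injected face-binding window in
region 3 (onset 140 ms), the *tool-specific* model finds the tool window in
region 4 (onset 210 ms), and the Bartlett test confirms that the model maps
have genuinely different spatial structure (means of the model groups are
not collinear). `res$z_maps`, `res$significance` and `res$accuracy_maps` are
tidy tibbles; `plot_region_time_map()` and `plot_model_timecourses()` render
the standard displays, and `tidy()` / `glance()` work on the fitted objects.

Real parcellations plug in the same way: build a `parcellation` mapping your
source vertices to the packaged 82-region table (`load_region_table()`),
wrap each subject's vertices × time × trials array with per-trial labels,
and pass the dataset list to `run_pipeline()`.

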