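# rnc — relational neural control of in silico fMRI responses

Encoding models turn stimulus images into predicted ("in silico") fMRI
responses, voxel by voxel. **Relational neural control (RNC)** inverts that
machinery: given two cortical areas' encoding models, it searches or evolves
stimulus images that *jointly* control the two areas — aligning their
responses (both driven, both suppressed, or similar representational
geometries) or disentangling them (one driven while the other is suppressed,
or dissimilar geometries). Comparing how controllable each pair of areas is
reveals how much representational content they share.

The package is written for computational neuroscientists who want to run
RNC-style analyses against their own encoding models, and for methodologists
who want a fully synthetic, reproducible test bed: a built-in visual-cortex
simulator, toy image-computable encoders and a toy image generator let the
entire pipeline run end to end with no neuroimaging data.

## What it implements

**Univariate RNC.** For areas A and B with univariate profiles
`u_A(i), u_B(i)` (mean response across voxels for image `i`), a baseline is
the mean response of the random 25-image batch whose score lies closest to
the mean of a 1,000,000-batch null distribution. Controlling images are the
top-ranked images by `u_A + u_B` (alignment) or `u_A − u_B`
(disentanglement) among images beating each area's baseline by a margin of
at least 0.04 z-units, evaluated by participant-wise leave-one-out
cross-validation.

**Multivariate RNC.** Voxel patterns for a 50-image batch become a 50×50
representational similarity matrix (RSM) per area; the RSA score is the
Pearson correlation of the two areas' RSM lower triangles. An elitist
genetic search over batches (population 2,400; 200 elites; graded mutations
replacing 1, 5, 12, 25, 38 images; 1,200 fresh random batches; 2,000
generations) maximizes r (align) or minimizes |r| (disentangle).

**Generative univariate RNC.** Latent vectors of an image generator evolve
under a two-phase global score: below the response thresholds
(baseline ± 0.6) a candidate scores its condition-signed response objective
plus a 10¹⁰ penalty; above threshold it scores the PNG-compressed byte size
of its image, so evolution first achieves control, then simplifies the image
while elitism keeps control intact. Selection probabilities are a softmax of
z-scored fitness (scale 0.5); children mix two parents 75%/25% with
per-component mutation probability 0.25 (Gaussian, sd 0.75).

**Noise ceiling and model evaluation.** From repeated presentations,
`σ̂_noise² = mean over images of the across-repeat variance (n−1 estimator)`,
`σ̂_signal = sqrt(|1 − σ̂_noise²|₊)`, `NCSNR = σ̂_signal/σ̂_noise`, and
`NC = 100·NCSNR²/(NCSNR² + 1/n)` for `n` averaged trials. Encoding accuracy
is noise-ceiling-normalized explained variance: negative correlations are
rectified to zero before squaring, then divided by NC.

**Inference.** Within-participant permutation tests (100,000 permutations,
plain-proportion p-values), Benjamini–Hochberg correction, the population
prevalence test `P = 1 − BinomCDF(k; n, a = 0.05)` on the count `k` of
significant participants, and percentile bootstrap confidence intervals over
participants.

**Embeddings.** Metric MDS (SMACOF, 10 restarts, 1,000 iterations,
eps 1e-3) of areas from univariate profiles or RSM lower triangles, plus the
linear proximity-to-opacity rescale (nearest pair → 1.0, farthest → 0.1)
used for network plots.

## Worked example

Simulate a 4-area visual hierarchy for 4 participants, then disentangle the
most distant pair (drive V1, suppress V4) with cross-validation:

```r
library(rnc)

cfg <- synthetic_cortex_config(n_participants = 4, n_images = 800,
                               voxels_per_area = 60, seed = 42)
sim <- simulate_hierarchy(cfg)

profiles_v1 <- lapply(sim$responses, function(p) univariate_profile(p$V1))
profiles_v4 <- lapply(sim$responses, function(p) univariate_profile(p$V4))

cv <- crossval_univariate(profiles_v1, profiles_v4, "drive_A_suppress_B",
                          n_samples = 10000, seed = 1)
cv
#> <rnc_uni_cv> condition drive_A_suppress_B, 4 folds
#> # A tibble: 8 × 5
#>   fold  area  control_mean baseline_mean n_selected
#>   <chr> <chr>        <dbl>         <dbl>      <int>
#> 1 sub1  A            0.139      0.00997          25
#> 2 sub1  B           -0.167      0.00974          25
#> 3 sub2  A            0.143      0.00120          25
#> 4 sub2  B           -0.163      0.00544          25
#> 5 sub3  A            0.137     -0.000219         25
#> 6 sub3  B           -0.177      0.00264          25
#> 7 sub4  A            0.135     -0.00418          25
#> 8 sub4  B           -0.183     -0.00101          25
```

Every held-out participant's V1 response over the selected images sits above
its baseline while V4 sits below it: the 25 images disentangle the two
areas, and the effect generalizes across participants. Population-level
significance for, say, 3 within-participant-significant participants out of
8 is:

```r
prevalence_pvalue(k = 3, n = 8)
#> <rnc_prevalence> 3/8 significant at alpha 0.05: P = 0.0003718
```

`run_demo()` chains all stages (simulation, nulls, univariate and
multivariate control, inference, MDS) into one reproducible report, and
`inst/cli/rnc.R` exposes the same functionality as `simulate`, `uni`,
`multi`, `gen`, `stats`, `embed` and `demo` subcommands.

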