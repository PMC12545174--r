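---
title: "Relational neural control: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relational neural control: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rnc)
```

## The problem

A voxelwise encoding model maps a stimulus image to a predicted fMRI
response pattern for one participant and cortical area. Once such models
exist for two areas, the relationship between the areas becomes something
one can probe *experimentally in silico*: search a large image set — or
evolve synthetic images — for stimuli that drive both areas, suppress both,
or push them in opposite directions, and for image batches whose
representational geometries in the two areas are maximally similar or
maximally dissimilar. How far each of these control conditions can be pushed
beyond an unoptimized baseline measures how much representational content
the two areas share. This package implements that control machinery, the
noise-ceiling framework used to evaluate encoding models, the two-level
statistics used to draw population inferences from small densely sampled
cohorts, and a synthetic cortex that makes the whole pipeline runnable and
testable without any neuroimaging data.

The package assumes image-level responses are z-scored per voxel (the
trial-level path provides `zscore_per_session()`), that encoding models are
deterministic mappings, and that image identity — never row position — is
the stable key for selections.

## Univariate control

The univariate response of an area to an image is the mean across its
voxels. For a pair of areas the four control conditions are `drive_both`,
`suppress_both`, `drive_A_suppress_B` and `drive_B_suppress_A`.

**Baseline.** `build_univariate_null()` scores random batches
(`batch_size = 25`, drawn without replacement within a batch) by their mean
response and repeats this `n_samples = 1e6` times by default; the baseline
is the sampled batch whose score is closest to the null mean — "typical
images", operationalized. Analyses in the test suite run the identical code
path at 1e4–1e5 samples; the null mean stabilizes far below 1e6 samples, the
default simply pins the baseline batch more tightly.

**Selection.** Images must clear each area's baseline by
`margin = 0.04` z-units in the condition's direction; survivors are ranked
by the sum (alignment) or difference (disentanglement) of the two profiles,
and the best 25 returned. Filtering before ranking is equivalent to the
joint statement of the procedure but remains well defined when fewer than 25
images qualify — the solution is then returned short and flagged rather than
padded or errored, because downstream evaluation handles any batch size.
Rank ties break by image id, making selection a pure function of its inputs.

**Cross-validation.** `crossval_univariate()` selects on the profile
averaged over `n − 1` participants (baseline construction included) and
evaluates on the held-out participant, yielding `n` solutions. A pooled
mode — selection on the all-participant average — is what `run_demo()` uses
for the per-pair distance gradients.

## Multivariate control

`compute_rsm()` correlates voxel patterns for every image pair of a batch
(Pearson), and `rsa_score()` correlates the strictly-lower triangles of two
areas' RSMs. The diagonal is excluded: it is constantly 1 and would inflate
every comparison with a shared component.

`search_controlling_batches()` is an elitist genetic algorithm over
50-image batches. Per generation the population of 2,400 batches is scored;
the 200 best are kept (highest r for `align`, lowest |r| for
`disentangle`), each elite spawns five mutated copies with 1, 5, 12, 25 and
38 images replaced by fresh pool draws (duplicate-free within the batch),
and 1,200 new random batches keep exploration alive. Elite retention makes
the best score monotone, which the tests assert on every run. Ranking ties
break by a deterministic batch key. Internally the searcher precomputes the
full image-by-image pattern-correlation matrix per area, after which any
batch RSM is a submatrix lookup; this trades `O(n_images²)` memory for a
large constant-factor speedup and is the right regime for in-memory pools
(thousands of images). Cross-validation averages the *similarity matrices*
entry-wise across training participants — averaging RSMs, not voxel
patterns, so participants with different voxel counts contribute equally.

## Generative control

`evolve_controlling_image()` optimizes generator latents with a two-phase
global score (lower = better): candidates failing either area's threshold
(baseline ± `threshold_margin = 0.6` z-units, strict inequality) score
their condition-signed response objective plus `penalty = 1e10`; passing
candidates score the PNG byte size of their image. The signed objective
resolves an ambiguity — the procedure mixes a maximization quantity
(sum/difference of responses) with minimization quantities (penalty, file
size) — by negating the response objective for drive conditions so that
*lower is always better*; this reproduces every ordering property the
two-phase scheme requires (all passing scores beat all failing scores; among
failing candidates, better control ranks better). Fitness is the negated
score; probabilities are `softmax(0.5 · z)` with population-sd z-scoring
(the convention under which two candidates receive probabilities 0.269 and
0.731). Each generation keeps the 250 highest-probability latents untouched
and breeds 750 children: components come 75%/25% from the
higher-/lower-probability parent and mutate with probability 0.25 by an
*additive* zero-centred Gaussian of sd 0.75 (add-versus-replace being
unstated upstream, additive is chosen as the smoother operator). Elites are
not re-scored — models and generator are deterministic. PNG byte counts use
the png package's encoder; the encoder identity is recorded in the config
because byte counts are encoder-dependent (the package exposes no
compression-level knob, so the level is the libpng default).

`generator_baselines()` anchors the thresholds by building the univariate
random-batch null over unoptimized generator output, mirroring the
image-search baseline.

## Noise ceiling and evaluation

For z-scored betas the total per-voxel variance is 1, so
`σ̂_signal² = |1 − σ̂_noise²|₊` with `σ̂_noise²` the across-repeat variance
(n−1 estimator) averaged over images. `NCSNR = σ̂_signal/σ̂_noise` maps to a
noise ceiling `NC = 100·NCSNR²/(NCSNR² + 1/n)` for targets averaged over
`n` trials; `σ̂_noise = 0` maps to `NCSNR = +Inf` and `NC = 100` by the
limit. `evaluate_encoding()` rectifies negative voxel correlations to zero
before squaring and reports `nnev = 100·r²/(NC/100)`, capped at 100 — the
cap is a package choice (upstream behaviour is unstated) that keeps
estimation noise from producing >100% explained-variance claims.
Zero-variance prediction or target columns yield `r = 0` with a message
rather than an error: constant in silico voxels are legitimate degenerate
inputs. `noise_comparison()` implements the three-predictor analysis
(single other trial — 6 ordered pairs; average of the two others — 3
targets; in silico responses — 3 targets) at the single-trial ceiling.

## Statistics

`permutation_test()` reports the plain proportion of randomized statistics
as or more extreme than the observed one (add-one smoothing available by
flag, off by default), with exchange schemes as named presets over label
columns. `bh_adjust()` wraps the standard step-up implementation;
`prevalence_pvalue()` computes `P = 1 − BinomCDF(k; n, a)` — the upper tail
is evaluated directly (`lower.tail = FALSE`) to avoid catastrophic
cancellation at large `k`, where `1 − CDF` is below 1e-10. The alternative
tail convention `P(X ≥ k)` was considered and rejected: it is inconsistent
with the printed population-level bounds for high `k` that the formula as
stated reproduces exactly. `bootstrap_ci()` is the percentile bootstrap over
participants.

One calibration fact deserves honesty: the percentile bootstrap of a mean
over 8 participants is known to undercover (the bootstrap sd underestimates
the sampling sd by √(7/8) and the percentile interval implies z- rather
than t₇-quantiles), and the acceptance suite measures its coverage at about
0.88 rather than the nominal 0.95. The package implements the documented
procedure rather than silently substituting a t-interval; users needing
calibrated small-sample intervals should widen accordingly.

## Embeddings

`embed_univariate()`/`embed_rsm()` run metric MDS via SMACOF stress
majorization (2 output dimensions, 10 random restarts keeping the best
stress, 1,000 max iterations, relative stress tolerance 1e-3) on Euclidean
distances between area feature vectors. No installed package provides this
exact estimator, so the majorization loop is implemented in-package;
classical scaling (`cmdscale`) serves as an independent cross-check in the
tests on inputs with exact 2-D geometry. Coordinates are reported in a
canonical frame (centred, first area on the positive x-axis, second area's
y non-negative) purely for plotting; every comparison in tests and analyses
uses embedded *distances*, which are invariant to that choice.
`proximity_opacity()` linearly rescales pairwise distances so the nearest
pair is fully opaque (1.0) and the farthest nearly transparent (0.1).

A geometric caveat: for a 4-area chain with exponentially decaying shared
content, profile-space distances saturate with separation, the 2-D
embedding is a tight horseshoe, and orderings read off a single principal
axis (or strict monotonicity of all embedded distances) can swap
near-tied pairs. The structure-recovery tests therefore assert rank
agreement between chain separation and embedded distance, which is what
"recovering the chain ordering" robustly means in this geometry.

## The synthetic cortex

`simulate_hierarchy()` emulates the structural assumptions the analyses
rely on, nothing more: one image set shared across participants
(default 2,000 images, 50 latent dimensions), areas whose voxel tunings
follow an exponential-kernel process across hierarchy positions with
per-step correlation `1 − share_decay` (so planted cross-area signal
correlation is `(1 − share_decay)^distance` — the simplest monotone
construction consistent with a stepwise hierarchy), participant-specific
Gaussian voxel noise, and per-voxel z-scoring. Defaults — 8 participants,
4 areas, 100 voxels per area, `share_decay = 0.3` (planted adjacent-area
correlation 0.7, in the range typical of neighbouring visual areas),
`noise_sd = 0.2` (between-participant variability small relative to signal,
as expected for model-generated responses), 3 trial repeats — are the
simulated study conditions and are not tuned per analysis. The grouped
variant encodes two categorical-selectivity groups through positions
(1, 2, 4, 5), so within-group pairs are one hierarchy step apart and
between-group pairs two to four.

What the simulator does *not* emulate: retinotopy, receptive-field
structure, voxel count heterogeneity across areas, non-Gaussian noise,
session drift, or any pixel-to-response mapping (areas respond to abstract
latents, not image content). Passing structure-recovery tests therefore
demonstrates that the algorithms recover planted relational structure from
data with realistic correlation geometry — not that they would produce the
same area relationships from real cortex.

The toy encoders ground the generative loop in actual pixels:
`"freq"` voxels respond to mean absolute pixel-gradient magnitude and
`"blob"` voxels to counts of compact connected components (band threshold
±0.12 around mid-gray, area 20–150 px, border-touching components excluded
as clipped shapes) on a 4×4 subwindow lattice. Both standardize against a
frozen 256-image reference set generated from the toy generator under a
fixed internal seed — generating the reference programmatically keeps the
repository text-only while freezing the standardization exactly as a
shipped fixture would. The toy generator maps the first half of a
64-dimensional latent to a grid of signed Gaussian blobs (intensity and
size) and the second half to an additive sinusoid (frequency and
non-negative contrast, fixed phase); the zero latent yields a uniform
mid-gray image. Fixing the phase and contrast sign removes a symmetry under
which equally optimal images would be pixel-anticorrelated, which would make
cross-seed convergence unmeasurable by pixel correlation.

## Numerical and interface choices

- z-scoring divides by the population sd by default (`convention =
  "sample"` available); the NCSNR derivation independently uses the n−1
  estimator for the across-repeat noise variance, as its formula requires.
- NCSNR voxel filtering uses strict inequality ("above 0.5"); an empty
  survivor set is an error advising a lower threshold (0.4 is the
  conventional fallback) rather than a silent empty area.
- Stores are plain-text directory containers (JSON manifest with a schema
  version, one TSV group per participant × area); values round-trip within
  1e-12, identifiers exactly. Mismatched schema or shapes fail with
  expected-versus-found messages.
- All stochastic entry points take explicit seeds; simulators and searches
  are pure functions of (config, seed), which the suite asserts
  bit-exactly. Seeds and config hashes are recorded in all CLI and demo
  outputs.
- Test and acceptance problem sizes: nulls at 1e4 samples, genetic search
  oracle instances with 495 possible batches, structure recovery on the
  default 2,000-image hierarchy with 40-generation searches (population
  240), generative runs with 200 latents × 100 generations on 64×64
  images, permutation calibration at 2,000 × 1,000. These sizes make the
  full pipeline comfortably reproducible on a laptop while exercising the
  identical code paths as the full-scale defaults.

## Limitations

- The genetic searches are heuristics; outside the small-instance regime
  (where tests prove exhaustive optimality) they guarantee monotone
  improvement, not global optima.
- The multivariate searcher's precomputed similarity matrices scale
  quadratically in pool size; pools beyond ~20,000 images need a chunked
  scoring path that is out of scope here.
- Real encoding models are approximations of cortex; every "in silico"
  statement inherits their biases. The package deliberately treats models
  as black-box deterministic predictors and makes no attempt to correct
  them.
- The percentile bootstrap undercovers at n = 8 (see Statistics above).
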