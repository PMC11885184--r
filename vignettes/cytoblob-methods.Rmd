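---
title: "Multiscale LoG blob detection for cytology: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale LoG blob detection for cytology: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoblob)
```

## The detection model

Stained cell nuclei in a cytology field are, to first approximation, dark
isotropic blobs of unknown size on a brighter, unevenly stained
cytoplasm/background. `cytoblob` detects them with the scale-normalized
Laplacian of Gaussian. The image is smoothed with a 2D Gaussian
`g(x, y; σ) = 1/(2πσ²) · exp(−(x²+y²)/(2σ²))` at every scale of a schedule,
and the response

`∇²_norm L = σ² (Lxx + Lyy)`

is stacked into a 3D (x, y, σ) volume. The σ² factor is the variance-scale
normalization: for an ideal Gaussian blob of scale σb the peak response is
then independent of σb, so responses are comparable across scales and a
single threshold works for small and large nuclei alike. The response of a
dark Gaussian blob of scale σb, evaluated at its center, is proportional to
`σ² / (σ² + σb²)²`, which is maximal exactly at σ = σb — the basis of
simultaneous localization and scale selection. A detection is any voxel
strictly greater than all 26 neighbors in its 3×3×3 space–scale
neighborhood; interior scale layers only (an extremum over scale needs a
neighbor on both sides), and a 1-pixel spatial border is excluded.

Detected scale converts to disc radius by the radius law `r = √2·σ̂`: the
zero-crossing circle of the LoG fitted to a Gaussian blob. Crop windows are
squares with corners `(x̂ ± r′, ŷ ± r′)`, `r′ = scale_factor·r`, rasterized
by flooring minima and ceiling maxima so no covered pixel is lost, then
clipped to the frame.

### Assumptions

- Nuclei are approximately isotropic; strongly elliptical or folded nuclei
  yield a single blob at an intermediate scale.
- Nuclei are darker than their immediate surround (dark polarity is the
  default; bright-blob detection is available by negating the volume).
- The scale schedule brackets the true nucleus sizes; blobs at scales at or
  beyond the schedule ends are not detectable by construction.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `sigma_min`, `sigma_max` | 2, 8 | px | scale range; nuclei of radius ≈ 2.8–11.3 px are detectable |
| `n_sigmas` | 10 | — | scale sampling density; one schedule step is the scale resolution |
| `spacing` | log | — | geometric spacing keeps relative scale resolution constant |
| `threshold_rel` | 0.1 | fraction of volume max | rejects weak texture responses; adapts to stain intensity |
| `threshold_abs` | none | response units | optional absolute floor for cross-frame consistency |
| `overlap_max` | 0.5 | fraction of smaller disc | non-maximum suppression aggressiveness |
| `crop_scale_factor` | 1.0 | — | enlarge (>1) to include cytoplasm, shrink for tight nuclear crops |
| `truncate` | 4 | sigmas | kernel support; truncated mass < 1e-4 |
| `match_dist` | 10 px or `"radius"` | px | evaluation match threshold |

The relative threshold is deliberate: absolute LoG responses scale with
image contrast, which varies strongly across staining conditions, while the
ratio to the volume maximum is stable. When frames must be compared on an
absolute footing (e.g. counting across a sweep with empty frames),
`threshold_abs` should be set instead, since an empty frame's volume
maximum is noise.

## Numerical choices

- **Derivatives** are computed by convolution with sampled analytic
  Gaussian-derivative kernels (separable `g''⊗g` and `g⊗g''`), not by
  finite-differencing the smoothed image: better behaved at small σ. The
  second-derivative kernel is zero-sum-corrected so constant images are
  annihilated to machine precision.
- **Borders** use symmetric reflection padding everywhere, avoiding the
  spurious edge responses a zero pad would create; constants are preserved
  exactly at borders.
- **Strict inequality** in the extremum test matches the selection rule;
  response plateaus produce no detections there and are instead resolved by
  the deterministic suppression stage, whose ties break lexicographically
  by (y, x, σ).
- **No sub-pixel/sub-scale interpolation** by default: detections sit on
  the integer grid and on schedule scales. At the scale sampling densities
  used here the localization error this leaves is below 1 px (see the
  recovery measurements of `scripts/acceptance.R`).
- **Degenerate inputs**: constant images yield empty detection lists;
  schedules shorter than 3 scales, non-positive σ, and channel counts other
  than 1 or 3 raise errors; crop boxes clipped below 25% of their ideal
  area are dropped (and counted, so per-frame segment counts can be below
  cell counts).

## The synthetic generator

`generate_scene()` emulates what matters to a LoG detector in a stained
cytology field: a bright background (default level 0.85) modulated by a
smooth multiplicative stain gradient (±10%), dark isotropic Gaussian nuclei
with scale σ ∈ [3, 6] px and contrast 30–60%, additive Gaussian pixel noise
(sd 0.02), and an eosin-pink RGB tint so the color-to-luma path is always
exercised. Truth radii follow the detector's own radius law
(`r = √2·σ_nucleus`), making recovery comparisons unit-consistent. The
standard validation scene is 256×256 px with 20 non-overlapping nuclei,
seed 1 — sized so the full pipeline runs in under a second while leaving
room for 20 well-separated nuclei; placement is rejection-sampled with a
minimum center separation of 1.2× the summed radii. Scene rendering pins
the RNG algorithm (Mersenne-Twister/Inversion), so scenes are
bit-reproducible across platforms and do not disturb the caller's RNG
stream.

Nuclei are isotropic Gaussians rather than ellipses: this matches the LoG's
blob model and gives recovery tests a clean analytic target (the response
maximum is provably at the true center and scale). Overlapping and
elliptical nuclei, chromatin texture, debris, blood obscuration and focus
blur are **not** simulated. Passing the synthetic suite therefore
demonstrates that the operator, extremum search, radius law, cropping and
metrics are implemented correctly — not that real-slide performance reaches
any particular level; on real fields, touching nuclei merge below the
suppression threshold and out-of-schedule sizes are missed.

`generate_sequence()` translates one rendered scene with wrap-around to
emulate a slide sweep; it tests the frame pipeline's bookkeeping, not
scene dynamics.

## Evaluation conventions

Matching is greedy nearest-first one-to-one with a distance cap (fixed
pixels or the truth cell's annotated radius). Precision, recall and
F-measure are standard; **accuracy** for a pure detection task has no
true-negative count, so it is defined as tp/(tp+fp+fn) — the Jaccard-style
agreement between detected and annotated sets, which coincides with recall
whenever there are no false positives. Metrics with zero denominators are
reported as `NA`, never coerced. Percentages print rounded to two decimals.

## Design decisions that were genuinely open

- **26 vs 24 neighbors**: the full 3×3×3 neighborhood minus the center has
  26 voxels; the detector compares against all 26, the standard and
  strictly more conservative construction.
- **σ vs t**: all interfaces expose the standard deviation σ; the
  normalization uses the variance t = σ². Scale covariance consequently
  reads: rescaling the scene by s moves a maximum from (x₀, y₀; t₀) to
  (sx₀, sy₀; s²t₀), i.e. σ̂ doubles under 2× upsampling — asserted in the
  test suite.
- **Frame sources** are directories of numbered frame images, the portable
  export format of slide-sweep videos; per-frame outputs are a pure
  function of frame + configuration, so the pipeline streams with bounded
  memory and any frame subset reproduces exactly.
- **Problem sizes in the checks**: the validation suite uses 256×256
  scenes, 64×64 single-nucleus trials (200 of them), and 50 random 5×32×32
  volumes for the brute-force oracle — small enough to re-run constantly,
  large enough that borders and scale ends do not interact with the
  measurements.

## Known limitations

- No sub-scale interpolation: σ̂ quantizes to the schedule, so radius
  estimates inherit up to half a schedule step of relative error.
- Greedy suppression and greedy matching are order-dependent heuristics;
  both are deterministic, but neither is globally optimal in adversarial
  configurations.
- Video containers are not decoded; frames must be exported to images
  first.
- Heavily overlapping nuclei are reported as a single detection; watershed
  separation is out of scope.
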