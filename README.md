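# cytoblob

Multiscale blob detection for cell and nucleus localization in
cervical-cytology (Pap smear) micrographs and slide-sweep video frames.

Screening cytology slides means finding every visible cell in fields whose
staining quality, zoom level and focus vary widely. `cytoblob` localizes
stained nuclei — dark, roughly circular regions of unknown size — with the
scale-normalized Laplacian of Gaussian (LoG), a classical detector that
needs no training data: useful where annotated slides are scarce and
hardware is modest. Detected blobs drive automatic cropping of each cell
from the field, frame-by-frame counting over video sweeps, and quantitative
evaluation against manual annotations.

## Method

The image *f(x, y)* is smoothed by a Gaussian kernel at a schedule of
scales σ:

    L(x, y; σ) = g(x, y; σ) ∗ f(x, y),   g = 1/(2πσ²) · exp(−(x²+y²)/(2σ²))

The scale-normalized Laplacian

    ∇²_norm L = σ² (L_xx + L_yy)

responds positively to dark regions of size ≈ σ, with peak magnitude
comparable across scales thanks to the σ² (variance) normalization. Stacking
one response layer per scale gives a 3-D (x, y, σ) volume; a detection is
any voxel strictly greater than all 26 neighbors of its 3×3×3 space–scale
neighborhood:

    (x̂, ŷ; σ̂) = argmax_local (x,y;σ) ∇²_norm L(x, y; σ)

so position and scale are selected simultaneously. Each blob's disc radius
follows the radius law **r = √2·σ̂**, and its crop window is the square with
corners (x̂ ± r′, ŷ ± r′), r′ = scale_factor · r. Overlapping detections are
pruned by greedy non-maximum suppression on disc overlap. Detections are
scored against ground truth by greedy one-to-one nearest-center matching,
reporting precision, recall, F-measure, and detection accuracy
tp/(tp+fp+fn).

A synthetic cytology-field generator (bright eosin-toned background, smooth
stain gradient, dark Gaussian nuclei, pixel noise, exact ground truth) makes
every stage testable end to end without any slide data.

## Worked example

```r
library(cytoblob)

scene <- generate_scene(scene_spec(seed = 1))   # 256x256, 20 nuclei
blobs <- detect_blobs(scene$gray)               # default sigma 2..8, 10 scales
head(blobs, 5)
#>     x   y sigma radius response polarity
#> 1  33 213 5.040  7.127   0.1879     dark
#> 2 192 235 4.320  6.110   0.1857     dark
#> 3 186  61 5.879  8.314   0.1833     dark
#> 4  29  36 5.040  7.127   0.1812     dark
#> 5 193 140 4.320  6.110   0.1779     dark
```

Each row is one detected nucleus: 0-based center (x = column, y = row), the
scale σ̂ at which the normalized response peaked, the disc radius √2·σ̂, and
the response value (detection strength). Comparing against the generator's
ground truth and cropping the cells:

```r
report <- evaluate_detections(blobs, scene$truth, match_dist = "radius")
report
#> tp=20 fp=0 fn=0
#> precision 100.00%  recall 100.00%  F-measure 100.00%  accuracy 100.00%

segs <- extract_segments(scene$rgb, blobs)      # 20 color crops
```

All 20 synthetic nuclei are recovered with no false positives; crops are
taken from the original color field.

## Command line

A thin `Rscript` wrapper is installed at `exec/cytoblob`:

```sh
cytoblob synth  --output-dir scene --seed 1          # synthetic field + truth.csv
cytoblob detect scene/frame00000.png --output-dir det
cytoblob eval   det/blobs.csv scene/truth.csv --match-dist radius
cytoblob run-video frames/ --output-dir run --stride 1
```

Commands accept `--config run.yaml` with flag overrides (`--sigma-min`,
`--sigma-max`, `--n-sigmas`, `--threshold-rel`, `--overlap-max`,
`--crop-scale-factor`, ...). Exit codes: 0 success, 2 unreadable input,
3 invalid configuration.

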