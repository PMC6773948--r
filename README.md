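# cellularity

Automated tumour-cellularity (TC) scoring for breast-cancer digital
pathology. TC is the percentage of a region of interest — a 512 × 512 px
H&E patch at 0.5 µm/px, or a pathologist-annotated tumour bed on a whole
slide — occupied by malignant tumour cells (nuclei plus cytoplasm), on a
0–100 % scale. It is a core input to residual-cancer-burden assessment
after neoadjuvant therapy, and is normally estimated by eye to the nearest
5–10 %. This package is for image-analysis researchers and method
evaluators who want a fully inspectable, reproducible TC pipeline with
exact synthetic ground truth.

Two scoring routes are implemented:

* **Hand-engineered** — colour deconvolution onto hematoxylin/eosin
  vectors with percentile contrast stretch; Otsu + distance-transform
  watershed nucleus segmentation with an 8–250 µm² area filter; a
  three-class RBF-SVM cell map (lymphocyte / epithelial / malignant) over
  appearance, morphology, texture and spatial features; then
  `area_fraction(dilate(malignant mask, 2.5 µm))` mapped through an
  isotonic calibration anchored at 0 → 0.
* **Cascade** — stage 1 gates healthy versus cancerous (gated patches
  score exactly 0 %, matching the manual convention), stage 2 regresses a
  continuous TC in [0, 100] on the patches that pass. Stage models are
  seeded random forests over a fixed stain-histogram + granulometry patch
  descriptor; the family is pluggable. A **combined** route gates with
  stage 1 and scores with the hand-engineered branch.

Around them: whole-slide tiling over a tumour-bed polygon with
centre-inclusion membership, blue(0 %)→red(100 %) heatmap overlays, and
agreement analysis via the two-way intraclass correlation — ICC(2,1)
absolute agreement by default, ICC(3,1) consistency selectable — with
F-based 95 % confidence intervals, score-range stratification
(0 % / 1–30 % / 31–70 % / > 70 %) and binary healthy-vs-cancer accuracy.
A synthetic H&E generator supplies patches and slide mosaics with
per-pixel class labels and an exactly known true cellularity, so every
stage is testable without clinical data.

## Worked example

```r
library(cellularity)

# a seeded benchmark: train the hand-engineered route on 10 patches,
# score 20 held-out patches against exact synthetic truth
b <- run_he_benchmark(n_train = 10, n_test = 20, seed = 3, size_px = 256)
round(c(mae = b$mae, icc = b$icc_vs_truth), 3)
#>   mae   icc
#> 3.301 0.990

head(b$results, 3)
#>   patch_id    truth    score raw_fraction
#> 1 test_001 77.24915 74.62080    0.7719269
#> 2 test_002 71.72852 69.51320    0.7160187
#> 3 test_003 31.91376 38.07505    0.3182831
```

The mean absolute error is about 3 TC points and the intraclass
correlation against truth is ≈ 1: on clean synthetic tissue the pipeline
recovers cellularity almost exactly (real slides are harder; see the
methods vignette for what the generator does not model). Scoring one patch
end to end:

```r
p <- generate_patch(synthetic_patch_spec(seed = 7, n_malignant = 30))
s <- score_patch_hand_engineered(p$image, b$classifier, b$calibration)
s
#> TC score: 11.1% (hand_engineered, raw fraction 0.101)
100 * p$truth$true_tc_fraction
#> [1] 10.76965
```

A command-line wrapper (`inst/cli/tc-tool.R`) exposes the same pipeline
as subcommands (`synth`, `train-he`, `score-he`, `train-cascade`,
`score-cascade`, `score-combined`, `heatmap`, `evaluate`), each driven by
a JSON run configuration and a single seed; reruns are byte-identical.

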