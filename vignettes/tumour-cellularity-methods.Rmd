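---
title: "Methods: automated tumour-cellularity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tumour-cellularity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

Tumour cellularity (TC) is the percentage of a region of interest —
conventionally a 512 × 512 px patch at 0.5 µm/px, or a pathologist-annotated
tumour bed on a whole slide — occupied by malignant tumour cells, counting
both the nucleus and its surrounding cytoplasm, on a 0–100 % scale. Patches
containing no tumour cells are scored exactly 0 %. Tumour-infiltrating
lymphocytes and benign epithelium are excluded from the tumour area. TC
feeds residual-cancer-burden assessment after neoadjuvant therapy, where it
is normally estimated by eye and rounded to the nearest 5–10 %.

This package implements two automated scoring routes plus the evaluation
machinery around them, and a synthetic H&E generator that makes the whole
chain testable with exact per-pixel ground truth.

## Hand-engineered route

The pipeline mimics the pathologist's workflow:

1. **Stain separation.** RGB is converted to optical density and projected
   per pixel onto two stain colour vectors (least-squares colour
   deconvolution, Ruifrok–Johnson style), then each stain map is
   contrast-stretched between its 1st and 99th percentiles to [0, 1]. A
   global brightness rescale of the input shifts optical density by a
   constant which the stretch removes, so the maps are robust to
   illumination differences. The raw (unstretched) hematoxylin
   concentration is kept alongside: thresholding needs an absolute
   reference, otherwise the stretch would promote noise to foreground on
   nucleus-free patches.
2. **Nucleus segmentation.** Otsu threshold on the (lightly smoothed,
   σ = 1 px) stretched hematoxylin map, intersected with an absolute
   floor of 0.25 OD on the raw concentration; hole filling; a
   distance-transform watershed to split touching nuclei; then an area
   filter keeping 8–250 µm². The defaults suit nuclei from small
   lymphocytes (≈ 24 µm²) to large malignant nuclei (≈ 110 µm², with the
   filter tolerant of imperfect watershed splits up to a merged pair).
3. **Cell classification.** Per nucleus we extract appearance (RGB and
   hematoxylin mean/SD), morphology (area, moment eccentricity, solidity
   against the convex hull, perimeter-to-area), texture (8-level
   grey-level co-occurrence contrast and homogeneity over horizontal and
   vertical neighbour pairs, plus local 3 × 3 intensity variance) and
   spatial context (nearest-neighbour distance, mean distance to the 5
   nearest, local density within a 25 µm radius). Every feature has a
   plain per-pixel definition, deliberately, so the tests can recompute
   each one with an independent naive implementation. An RBF SVM (C = 1,
   γ = 1/p after standardisation, balanced class weights, pairwise-coupled
   probabilities) assigns lymphocyte / epithelial / malignant. Probability
   calibration inside the SVM library draws from R's RNG, so training is
   wrapped in a stored seed and is exactly reproducible.
4. **Scoring.** The union of malignant nuclei is dilated with a disk of
   radius 2.5 µm to account for cytoplasm, the covered area fraction is
   taken, and a monotone calibration maps the raw fraction to the
   pathologist scale. The calibration is isotonic regression
   (pool-adjacent-violators with linear interpolation between knots),
   anchored so that a raw fraction of 0 always maps to 0 %; a
   through-the-origin linear rescale is available as the alternative.
   Isotonic was chosen because the requirement is only that computed
   scores be brought closer to manual ones while preserving order — a
   non-parametric monotone map does exactly that and nothing more.

The dilation radius is a free parameter (the physical extent of cytoplasm
is not well defined); 2.5 µm is the package default and the synthetic
generator uses the same value for its halo ground truth, which makes
recovery well-posed on the benchmarks. On real tissue this radius would be
tuned against manual scores through the calibration step.

## Cascade route

The cascade splits the problem in two: stage 1 classifies a patch as
healthy versus cancerous; patches called healthy receive exactly 0 %
(mirroring the manual convention), and only cancerous patches reach
stage 2, a continuous 0–100 regressor whose output is clipped to range.
The gate threshold on the stage-1 cancer probability defaults to 0.5.

This two-network design is usually realised by fine-tuning large
pretrained convolutional networks. Here the stage models are desk-scale
learners —
random forests (300 trees; SVM and logistic families are pluggable) — over
a fixed 42-dimensional descriptor computed after resizing the patch to
128 px: 16-bin histograms of the raw hematoxylin and eosin concentrations
(histogram mass is an area fraction, the quantity TC is made of), a
morphological granulometry of the nuclear mask (surviving foreground after
opening with disks of radius 0–3 px, which separates small lymphocyte
profiles from large malignant ones), and per-channel colour statistics.
The cascade *contract* — gate, exact zeros, continuous clipped regression,
seeded reproducibility — is what the package commits to; the model family
behind each stage is configuration.

A combined route gates with stage 1 and scores surviving patches with the
hand-engineered branch; off the gate its output is bit-identical to the
hand-engineered score.

## Whole-slide heatmaps

A slide is tiled on a stride grid of half-open windows; a window belongs
to the tumour bed iff its centre lies inside the annotation polygon
(centre inclusion avoids double-counting boundary patches and is cheap to
verify against a ray-casting oracle), and windows extending past the slide
edge are excluded rather than clipped. Any scorer can be applied per
window; failures mark a window unscored and the run continues. Rendering
linearly interpolates pure blue (0 %) to pure red (100 %) and alpha-blends
at 0.4 over the tissue; unscored windows stay untinted. The core path
works on flat mosaics; pyramidal slide formats would enter through an
adapter that yields window-sized RGB arrays.

## Agreement statistics

Score tables are compared with a two-way intraclass correlation computed
from the ANOVA mean squares of the subjects × raters matrix. The default
is the two-way random-effects, single-rater, absolute-agreement form
ICC(2,1) — appropriate when methods are supposed to reproduce each other's
values — with the consistency form ICC(3,1) selectable (it is invariant to
per-rater constant offsets; the tests assert both behaviours). Confidence
intervals use the standard F-based formulas, exact for the consistency
form and Satterthwaite-approximate for the agreement form; 500-run
simulations at true ICC 0.8 show empirical 95 % coverage within the
nominal band. Missing scores are handled by listwise deletion with the
dropped count reported. Degenerate inputs follow documented conventions:
an all-identical matrix returns 1 (perfect-agreement limit); zero
between-subject variance returns 0 with a warning, CI undefined.

Score stratification uses the reporting bins [0, 0], (0, 30], (30, 70],
(70, 100] — the "0 %", "1–30 %", "31–70 %", "> 70 %" ranges, with the
integer labels generalised to half-open real intervals and 0 reserved for
tumour-free patches. Binary healthy-versus-cancer accuracy binarises both
vectors as healthy ⇔ score = 0.

## Synthetic generator: what it does and does not show

Each patch is built by rejection-sampling non-overlapping textured
ellipses (up to 200 placement attempts per nucleus; failures reduce the
realised count and are reported), with three classes separated by
construction: lymphocytes (radius 2.75 ± 0.25 µm, near-circular, darkest
hematoxylin), benign epithelial (4 ± 0.4 µm, moderate), malignant
(6 ± 0.6 µm, pleomorphic eccentricity up to 0.8, coarse texture).
Malignant cytoplasm is an explicit halo label (2.5 µm dilation of the
malignant nuclei into background), so the "area occupied by malignant
cells" has an exact ground truth: the stored fraction equals the pixel
count of labels {3, 4} over the patch area, and the tests assert this
identity. Rendering mixes per-pixel hematoxylin/eosin optical densities
through Beer–Lambert with the same stain vectors the deconvolution
assumes, plus Gaussian OD noise, quantised to 8 bits. Identical spec and
seed give bit-identical images.

Simulated pathologists score truth plus Gaussian noise (SD 5 points by
default), clipped to [0, 100] and rounded to the nearest 5 % — matching
how manual scores are actually reported — with tumour-free patches always
scored 0.

Because nuclei never overlap, packing saturates: with halos the true TC
tops out near 85–88 %, so the benchmarks span roughly 0–86 % rather than
the full range. Patch geometry uses the pixel-times-scale definition
(512 px × 0.5 µm/px = 256 µm square); descriptions of such patches as
"258 µm" squares presumably include a small margin or rounding and are not
reproduced. The generator does not attempt photorealism: no scanner
artefacts (folds, blur, fat), no stain variation between sites, no
overlapping nuclear sheets, no stromal texture. Consequently the benchmark
results — classifier accuracy near 1, hand-engineered MAE of a few points
— demonstrate that the pipeline is *correct and well-calibrated under its
own assumptions*, not that it reaches any particular accuracy on clinical
slides; agreement with pathologists on real tissue can only be measured
against a clinical cohort, which this package does not ship.

## Benchmarks and numerical choices

The packaged benchmarks (also used by the acceptance script) are seeded
end to end: per-patch sub-seeds are drawn from the benchmark seed, SVM and
forest training consume stored seeds, and every artefact regenerates
byte-identically. Problem sizes were chosen as the smallest that exercise
the claims on one CPU: 40 training / 100 test patches for the
hand-engineered route, 400/100 for the cascade (its forests want more
examples), 500 simulations for interval coverage, with 512 px patches
throughout.

Other fixed choices: watershed marker ties resolve by scan order, making
segmentation deterministic; feature standardisation guards zero-variance
columns; the stage-1 healthy label in training derives from exact-zero
true TC; descriptor histograms use fixed [0, 2] OD breaks (not per-image
stretch) because absolute mass, not contrast, carries the area signal;
isotonic calibration clamps its knot sequence non-decreasing after
anchoring (0, 0) so the map invariants hold even under pooling at the
origin.

## Known limitations

* Dense malignant sheets segment imperfectly — merged nuclei beyond the
  area filter are dropped — so the raw fraction under-tracks truth at
  high TC and the isotonic calibration carries the correction; on real
  tissue the high-cellularity regime is likewise the hardest for
  segmentation-based scoring.
* The ICC agreement-form interval is approximate in small samples; the
  consistency-form interval is exact under its model.
* No automatic tumour-bed detection: the polygon is an input.
* In-situ versus invasive disease is not distinguished; residual cancer
  burden itself (node status, bed size) is out of scope.
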