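---
title: "Methods: segmentation-based screening of laryngopharyngeal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-based screening of laryngopharyngeal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(laryngoscreen)
```

## The diagnostic problem

Laryngopharyngeal cancer (LPC) is screened by transnasal flexible
laryngoscopy under two illumination modes: conventional white-light imaging
(WLI) and narrow-band imaging (NBI), which enhances mucosal microvasculature.
Diagnosis from the endoscopic view is subjective and depends strongly on the
endoscopist's experience. `laryngoscreen` implements a three-stage automated
pipeline that turns per-pixel semantic segmentation into frame-level and then
video-level cancer calls:

1. **Segmentation.** A U-Net assigns each pixel a cancer probability.
2. **Frame decision.** The thresholded mask is cleaned morphologically;
   the frame is called cancer when the largest connected component's area
   strictly exceeds an area threshold (default $32 \times 32 = 1024$ px at
   the $512\times512$ working resolution).
3. **Video diagnosis.** A video is called cancer when the longest run of
   consecutive cancer frames strictly exceeds a duration threshold
   (default 2 s, computed as run length / fps).

The evaluation module provides the statistics this kind of diagnostic study
reports: accuracy, sensitivity, specificity, PPV and NPV with binomial
confidence intervals, ROC/AUC, segmentation intersection-over-union (IoU),
Cohen's kappa and the two-sided McNemar test.

## The segmentation network

The network is the classical U-Net layout: four encoder blocks, each two
$3\times3$ convolutions with ReLU followed by $2\times2$ max-pooling with
stride 2; a bottleneck; four decoder blocks, each a $2\times$
nearest-neighbour upsampling plus $3\times3$ convolution, concatenation with
the encoder feature map at the same resolution, and two further $3\times3$
convolutions with ReLU; and a final $1\times1$ convolution producing a
per-pixel cancer logit squashed through a sigmoid.

Design choices where the classical layout leaves freedom:

* **Padding.** All $3\times3$ convolutions use "same" padding, so the output
  has the input's spatial size and skip concatenation needs no cropping.
  Predicted masks then align directly with full-size annotations, which is
  what IoU is computed against.
* **Upsampling.** Nearest-neighbour $2\times$ followed by a $3\times3$
  convolution, rather than transposed convolution, avoiding checkerboard
  artifacts.
* **Loss.** Pixel-wise binary cross-entropy with logits (numerically
  stable form); an optional additive Dice term is available
  (`train_config(loss = "bce_dice")`) but off by default.
* **Optimizer.** Adam at learning rate $10^{-3}$ by default, seeded and
  fully deterministic; the verification split drives early stopping, and
  model selection returns the parameters with the best verification loss.
* **Binarization.** `predict_frame()` thresholds the probability map at 0.5
  by default. The downstream area rule, not this cutoff, is the decision
  layer, so results are insensitive to its exact value.
* **Modality handling.** The default multimodal model is one network pooled
  over WLI and NBI frames (`modality_fusion = "pooled"`), with
  single-modality variants obtained through
  `train_config(modality_filter = "WLI")` (or `"NBI"`). An alternative
  fusion (`modality_fusion = "embedding"`) adds a learned per-modality
  embedding merged into the bottleneck by a linear layer; it exists because
  multimodal fusion through linear layers is a natural refinement of the
  pooled model, and the two are selectable so their behaviour can be
  compared. Neither is claimed to be canonical.
* **Input size.** $512\times512$ is the reference inference resolution;
  any input divisible by 16 (four pooling halvings) is accepted, and the
  package's own experiments run at $128\times128$ for tractability on a
  single CPU.

The network, backpropagation and Adam are implemented natively: feature maps
are $(HW) \times C$ matrices, convolutions run through im2col gathering and
BLAS matrix multiplication with the gather/scatter kernels in C++
(Rcpp/RcppArmadillo). Augmentations follow the families used for endoscopy
training data — horizontal flips, rotations (quarter-turn), colour jitter,
blur, Gaussian noise — with conservative default strengths (`jitter_strength
= 0.08`, `noise_sd = 0.02`), all configurable. Rotations are restricted to
quarter-turns so image and mask transform exactly, with no interpolation
ambiguity at mask edges.

## Frame decision layer

`clean_mask()` applies morphological closing (fill interior voids) then
opening (remove speckle), both with the same square structuring element
(default $5\times5$). The operator pair and order follow the goal of
eliminating voids and noise from predicted tumour regions; the composition
is idempotent, which the tests verify. `classify_frame()` labels connected
components with 8-connectivity by default (diagonally touching tumour pixels
are one region; 4-connectivity is available) and applies the strict rule
*largest component area $>$ threshold*. Two conventions matter and are unit
tested at the boundary:

* "Exceeding" is strict: a component of exactly 1024 px is non-cancer.
* The area measured is that of the largest single component, not the summed
  area of all components (a `sum_areas` flag provides the pooled variant).

Thresholds are defined at the $512\times512$ working resolution. Masks at
other resolutions have areas rescaled by the pixel-count ratio before the
comparison, so a 64-px component at $128\times128$ is equivalent to 1024 px
at $512\times512$.

`select_area_threshold()` evaluates the candidate grid
$\{8^2, 16^2, 32^2, 64^2, 128^2, 256^2\}$ px on a verification set by
accuracy and reports the full threshold-metric table. Ties break toward the
smaller area: in a screening context the cheaper error is a false positive,
so the tie-break favours sensitivity. The selection metric and tie-break are
this package's choices; alternatives can be read off the reported table.

## Video diagnosis

`diagnose_video()` computes the longest maximal run of consecutive positive
frame calls, converts it to seconds as run length divided by fps, and calls
cancer when the duration strictly exceeds the threshold (default 2 s from
the candidate grid $\{0.5, 1, 1.5, 2, 2.5, 3\}$ s,
`select_duration_threshold()`). A single negative frame breaks a run; an
optional `gap_tolerance` can bridge short interior gaps but defaults to 0
(strict consecutiveness). `stream_diagnose()` composes the full per-frame
pipeline in order and logs per-frame latency (informational only — latency
depends on hardware and is not an evaluation surface here).

Because both decision layers use a strict `>` with thresholds monotone in
the call, raising either threshold can only turn positive calls negative:
sensitivity is non-increasing and specificity non-decreasing along either
grid. The tests assert this monotonicity.

## Statistics

* **Proportions.** accuracy $=(TP+TN)/N$, sensitivity $=TP/(TP+FN)$,
  specificity $=TN/(TN+FP)$, PPV $=TP/(TP+FP)$, NPV $=TN/(TN+FN)$; a zero
  denominator yields *undefined* (`NA`), never 0.
* **Intervals.** Clopper–Pearson (exact inversion of binomial tails in
  beta-quantile form) is the default; the Wald normal approximation
  $\hat p \pm z\sqrt{\hat p(1-\hat p)/n}$ is provided because published
  diagnostic tables are frequently Wald-formed even when Clopper–Pearson is
  stated — both are implemented, reports carry a method tag, and the exact
  method is verified by brute-force tail inversion and by a simulated
  coverage experiment.
* **ROC/AUC.** Pairwise concordance with half-credit for ties (the
  Mann–Whitney form), which equals trapezoidal integration of the empirical
  curve exactly; the equality is property-tested. The per-frame ROC score is
  the post-morphology largest-component area and the per-video score the
  longest run duration — continuous generalizations of the two discrete
  rules. (What score a deployed system would sweep is a free choice; these
  are the natural ones.)
* **IoU.** $|A\cap B|/|A\cup B|$, defined as 1 when both masks are empty
  (agreement on "no lesion"); the summary `median_iou()` is taken over
  truth-positive images only, since IoU on an empty-truth image measures
  nothing about delineation quality.
* **Kappa / McNemar.** Cohen's kappa with chance agreement from marginal
  products (undefined when both raters are constant and identical). McNemar
  on the discordant counts: exact doubled-tail binomial for $b+c < 25$,
  continuity-corrected $\chi^2_1$ otherwise, with the correction dropped when
  $b=c$ (matching the base-R reference implementation and avoiding a
  spurious positive statistic).

## The synthetic generator

Clinical laryngoscopy datasets are private, so the package ships a
seed-controlled generator whose outputs are pure functions of
`(config, seed, arguments)`. It emulates the *statistical structure* the
pipeline depends on, not the appearance of real tissue:

* **Backgrounds** are smooth low-frequency colour fields in a
  modality-dependent palette — broad pink/red for WLI, darker green/brown
  with curvilinear vessel-like streaks for NBI.
* **Lesions** are star-convex polygons (radial log-normal perturbation of a
  circle, circularly smoothed), irregular like carcinoma margins but with a
  contour that can be written exactly as a labelme polygon annotation, so
  mask-to-polygon round-trips stay testable (the tests require IoU
  $\ge 0.95$ after a write-rasterize round trip). Lesion pixel area is
  constrained to `lesion_area_range` by rescaling the polygon.
* **Distractors** are small blobs in the *same* palette as lesions, present
  in both classes. Only size separates the classes, which makes the
  area-threshold decision layer the load-bearing component, exactly as in
  the pipeline being exercised.
* **Videos** draw a duration uniformly from 8–25 s (one short clip per
  lesion); in cancer videos the lesion is visible in one contiguous run of
  at least `lesion_persistence` (default 0.8) of the frames, jittered in
  position and scale frame to frame. Per-frame truth follows visibility.

Default conditions: $128\times128$ frames, lesion area 600–1800 px
(4–11 % of the frame, matching the scaled working resolution of the area
rule: 600 px at $128^2$ is 9600 px at $512^2$, well above the 1024-px
threshold), distractors 8–64 px (at most 1024 px rescaled — never
area-positive), cancer prevalence 0.4 per patient (near the ~41 % prevalence
typical of a tertiary-centre test set), equal WLI/NBI mix, pixel noise 0.02,
25 fps. Patients receive at most 10 frames each and splits are
patient-disjoint, mirroring the dataset-construction rules the manifest
validator enforces.

What passing on this generator does **not** show: robustness to real
mucosal texture, specular highlights, motion blur, camera pose variation,
or lesions whose contrast with surrounding tissue is subtle. The generator
is a correctness and calibration fixture, not a clinical surrogate, and no
clinical performance claim follows from it.

## Desk-scale experiment sizes

The bundled end-to-end experiment trains the reduced network
(base 4 channels, $128\times128$ input, ~135k parameters) on a 300-frame /
30-patient synthetic dataset with patient-disjoint splits, 16 epochs with
early stopping (patience 4), then evaluates the held-out test split and 20
synthetic videos under the 2-s rule. On a single CPU this trains in a few
minutes and reaches held-out frame accuracy $\ge 0.9$ and median IoU
$\ge 0.6$ comfortably; it is a qualitative, scaled analogue of the clinical
pipeline, not a reproduction of clinical accuracy.

## Numerical and convention notes

* Polygon rasterization paints a pixel when its center (0-based, x = column,
  y = row) lies inside the polygon by even-odd counting; points exactly on
  an edge count as inside. The convention is brute-force checkable and the
  property tests compare against a per-pixel point-in-polygon scan.
* Degenerate zero-area polygons rasterize to nothing, with a warning;
  vertices outside the raster are clipped, not an error.
* Mask resizing is nearest-neighbour (classes must not be interpolated);
  image resizing is bilinear.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.
* Loss-curve monotonicity on the memorization fixture is asserted on a
  10-step moving average: individual Adam steps chatter even during healthy
  descent, and the smoothed trend is the meaningful property.
* Random seeds flow through a single integer-mixing derivation
  (always below $2^{31}$), so every generator output and training run is
  reproducible bit-for-bit from one seed.

## Limitations

* The video container is a frame directory (PNG frames plus a JSON sidecar
  with fps and ordering), not a compressed codec container; clinical AVI/MP4
  files must be exploded into frames upstream.
* The network trains on CPU via BLAS; $512\times512$ training at clinical
  scale is supported in principle but not practical without hardware
  acceleration.
* Quality-control exclusion of blurred/haloed frames is represented as
  manifest bookkeeping supplied by the user, not detected automatically —
  in the clinical workflow this screening is human review.
* No multiple-testing correction is applied to McNemar comparisons, and
  the head is strictly binary (cancer vs background).
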