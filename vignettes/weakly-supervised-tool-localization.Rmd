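---
title: "Weakly supervised surgical tool localization with camloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised surgical tool localization with camloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the approach

Annotating bounding boxes for surgical instruments in endoscopic video is
expensive; frame-level presence labels ("a grasper is visible in this frame")
are cheap. `camloc` implements a weakly supervised localization pipeline that
turns a multi-label presence classifier into a bounding-box detector without
ever training on a box:

1. **Classifier.** A convolutional image classifier is trained with a
   class-weighted binary cross-entropy on presence labels only. Laparoscopic
   tool distributions are heavily imbalanced (graspers appear in most frames,
   scissors in very few), so each class $k$ is weighted by
   $CW_k = N / (K\,n_k)$, where $N$ is the number of training frames, $K$ the
   number of classes and $n_k$ the number of frames containing class $k$.
   These weights are computed from the *training split only* and satisfy
   $\sum_k CW_k\,n_k = N$ exactly.
2. **Grad-CAM.** For each class predicted present, the gradient of the
   pre-sigmoid class logit with respect to the last spatial feature layer is
   spatially averaged into one importance weight per channel
   (`channel_weights()`); the feature maps are combined with those weights,
   rectified by ReLU, bilinearly upsampled to the input size and min-max
   normalized to $[0,1]$ (`cam()`, `upsample_normalize()`). We backpropagate
   the *logit*, not the probability, so gradients are not attenuated where the
   sigmoid saturates.
3. **Post-processing.** Each heat map is quantized to 8 bits, binarized with
   Otsu's threshold (foreground strictly above the threshold), decomposed into
   8-connected components, filtered by two domain rules — an instrument enters
   the field of view from outside, so its contour must touch a frame edge; and
   speckle below an area floor is discarded — then each surviving contour's
   tight box is kept and greedy non-maximum suppression removes duplicates.
   Every box inherits the classifier's presence probability as its confidence.

All coordinates are 0-based with x rightward and y downward, and boxes
`(x_min, y_min, x_max, y_max)` are half-open.

# The surrogate backbone

The published system fine-tunes a large pre-trained vision transformer. That
is out of scope here: this package validates the *mechanism* — weighted
training, Grad-CAM, Otsu/contour post-processing, the matching rules — on
problem sizes that run on one CPU in minutes. The classifier therefore uses a
small convolutional surrogate (`backbone = "surrogate_small"`):

- input 96×96×3, centered by subtracting 0.5;
- one 7×7 convolution with stride 3 into 32 ReLU channels (the 30×30×32
  feature layer that Grad-CAM taps);
- a linear per-position class-score map followed by **top-quantile average
  pooling**: the logit for class $k$ is the mean of the top 10% of its
  position scores, scaled by a fixed gain.

Top-quantile pooling matters for calibration: tools occupy a small fraction
of the frame, so global average pooling dilutes their evidence and the
sigmoid probabilities never cross 0.5 within a small training budget. Pooling
only the strongest positions fixes that. Crucially it does not change the
Grad-CAM semantics: the spatial average of the logit's gradient with respect
to the features — the only quantity Grad-CAM uses — is the same (up to the
positive gain) as under global average pooling, so the heat maps are those of
the standard CAM construction.

The forward/backward passes, Adam with linear warmup, and the loss are
written in plain R (im2col plus BLAS matrix products, analytic gradients).
This is deliberate: the learning machinery is the package's contribution and
is validated against oracles in the test suite, while standard primitives
(PNG I/O, Gaussian blur, JSON/YAML) come from established packages.

A second backbone, `identity_model()`, exposes the image luminance as its
feature layer with a constant gradient. It is a constructed oracle: Grad-CAM
on it must return exactly the normalized luminance, which the tests assert.

## Training hyperparameters

`train_config()` defaults to the published fine-tuning schedule (learning
rate 5e-5, batch 32, 1000 warmup steps, 8 epochs, Adam β = (0.9, 0.999)).
That schedule targets fine-tuning a pre-trained transformer on tens of
thousands of frames; training the ~5k-parameter surrogate from scratch on a
few hundred frames with it would leave most steps inside warmup at a rate far
too small. `surrogate_train_config()` therefore uses a conventional
from-scratch setting — learning rate 0.05, batch 8, 10 warmup steps — and
keeps the published epoch count and betas. This is a documented deviation,
not a tuned one: the values are standard for small-network Adam training and
were fixed before the evaluation thresholds were checked.

# The synthetic scene generator

Real endoscopic data cannot ship with the package, so `generate_scene()`
draws frames that reproduce the *structural* properties the pipeline relies
on:

- seven tool classes at prevalences proportional to the benchmark's per-tool
  occurrence counts (graspers most frequent, scissors rarest), at most three
  tools per frame;
- each tool is an elongated capsule anchored just outside a frame border —
  instruments enter from outside, which is exactly the assumption the
  edge-touch filter encodes — with a brighter tip disk;
- a dark reddish low-frequency background (upsampled noise grid), optional
  interior gray distractor blobs (which the filters should reject), additive
  uniform noise, and Gaussian blur;
- per-frame determinism: frame $i$ of a dataset with seed $s$ is generated
  from `derive_seed(s, i)`, so datasets regenerate byte-identically.

What the generator does **not** emulate: occlusion between instruments and
tissue, specular highlights, smoke, camera motion, class-dependent shape
beyond color, or any texture statistics of real laparoscopic video. Numbers
obtained on these scenes validate the mechanism and the code paths, never the
published benchmark metrics — the headline Cholec80 results require the real
datasets and GPU fine-tuning and are out of reach at desk scale by design.

# Evaluation protocols

`classification_report()` gives per-class recall, F1 at threshold 0.5, and
non-interpolated average precision
$AP = \sum_k P(k)\,\Delta R(k)$, with mAP the unweighted class mean (classes
with no positives have undefined AP and are skipped with a message). The
published formula prints an additional $1/n$ prefactor; applied literally it
would cap AP for a perfect ranking at $1/n$ of the per-tool values actually
printed, so it is treated as typographical and the standard non-interpolated
sum is implemented.

`match_detections()` matches detections to ground-truth boxes greedily per
frame and class by descending confidence, one truth per detection, requiring
IoU above the threshold. Two bookkeeping modes are provided side by side:

- **paper**: a detection is a true positive only if confident *and* matched;
  false negatives accumulate unmatched confident detections, all
  low-confidence detections, and unmatched truths; false positives are
  low-confidence detections that also fail the IoU test. Under this reading a
  low-confidence, poorly localized detection is counted in both FN and FP.
- **standard**: the COCO convention — only confident detections participate,
  matched = TP, unmatched = FP, unmatched truths = FN.

Both are reported because the published counting rules differ from the
conventional ones; keeping the two modes adjacent makes the difference
auditable instead of silent.

`make_splits()` performs video-level (group-aware) splitting so that frames
of one video never cross a split boundary: `kfold` partitions videos into
folds whose sizes differ by at most one (80 videos in 3 folds gives
27/27/26), and `fixed_fraction` 0.5 gives the conventional 40/40 split.

# Numerical choices

- **Otsu** maximizes the between-class variance over all 256 thresholds via
  cumulative histogram sums; ties break toward the smallest threshold, and a
  constant image returns `NA` (no two-class split exists) which callers treat
  as "no detections".
- **Bilinear upsampling** uses pixel-center alignment
  ($x_{in} = (x_{out}+0.5)\,w_{in}/w_{out} - 0.5$, clamped), matching the
  common image-library convention; the tests check agreement with EBImage to
  near machine precision.
- **Heat-map normalization**: a constant activation map carries no
  localization signal and maps to all zeros rather than dividing by ~0.
- **BCE-with-logits** uses the stable form
  $\max(z,0) - zy + \log(1+e^{-|z|})$, finite for any logit.
- **Connected components** use iterative minimum-label propagation over the
  eight neighbor shifts (vectorized), verified against an explicit flood-fill
  oracle.
- Otsu is applied to the quantized *heat map itself*, not to any overlay or
  product with the image: the heat map is the localization signal, and mixing
  in image intensity would reintroduce appearance into a step that the
  pipeline defines purely on attribution strength.
- ReLU rectification in `cam()` is on by default (locations arguing against
  the class are not evidence of it) and can be disabled for diagnostics.

# Scope notes and resolved ambiguities

- Phase-wise analysis of tool usage over surgical workflow (temporal
  clustering of presence patterns) is intentionally not implemented; the
  package covers the classification → attribution → localization →
  evaluation chain.
- With 80 videos and folds of 26/27 videos, three folds cover all videos;
  the splitter generalizes this to any $k$ with fold sizes differing by at
  most one.
- Detection confidence is the classifier's presence probability — the
  pipeline has no box-level score of its own, which is characteristic of
  weakly supervised localization.

# Running the study

```{r}
library(camloc)
study <- run_synthetic_study(seed = 1, n_frames = 500, n_videos = 10,
                             k = 3, epochs = 8)
study$classification   # fold-averaged recall / F1 / mAP, in percent
study$localization     # fold-averaged localization mean F1, both modes
```

The same protocol backs the acceptance script (`scripts/acceptance.R`) and
the acceptance tests; at this problem size the study runs in roughly three
minutes on one CPU.
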