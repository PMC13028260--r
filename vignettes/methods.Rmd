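---
title: "Dual-stream fusion with a prototype head: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream fusion with a prototype head: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mammofuse implements a hybrid mammography classifier in which a
convolutional stream and a window-attention stream are trained jointly,
exchange information through bi-directional cross-attention, and classify
through distances to learnable class prototypes. This vignette explains the
model, the parameters that matter, the synthetic data the package tests
itself on, and the numerical and design decisions a maintainer would want
stated explicitly.

## The model

**Local stream.** A patchified stem followed by inverted-bottleneck blocks:
a wide depthwise convolution (7×7 in the reference and tiny presets, 5×5
for micro) carries all spatial mixing, layer normalization over channels
replaces batch normalization, a pointwise expansion to 4C with a GELU feeds
a pointwise projection back to C, and the block is residual. Stages are
separated by 2× patch-merging downsamples. The final stage map `F_L`
(C = 1024 in the base preset) summarizes local texture — the scale of
microcalcifications and mass margins.

**Global stream.** Patch embedding followed by stages of shifted-window
attention blocks. Attention logits inside each M×M window are scaled cosine
similarities, `cos(q, k)/tau`, with a learnable per-head temperature
(clamped below at 0.01) plus a learnable relative-position bias indexed by
token offset. Alternating blocks shift the window grid by ⌊M/2⌋; wrapped
(and padded) positions are masked out with additive −1e9 logits, so a token
only ever attends within its true neighborhood. Post-norm placement is
used: residual add, then LN, for both the attention and MLP sub-blocks.

**Fusion.** Both final-stage maps are flattened to token sequences. The
local tokens query the global tokens through multi-head scaled dot-product
cross-attention, and vice versa, in parallel from the raw streams:
`F'_L = LN(F_L + MCA(Q_L, K_G, V_G))` and symmetrically for `F'_G`. Plain
dot-product softmax is deliberate here: the named mechanism is generic
cross-attention, and cosine attention is reserved for the global encoder.
Each refined stream is mean-pooled over tokens and the two pooled vectors
concatenated local-first into `Z` (2048-dimensional at base widths). The
pre-pool channel-concatenated spatial map is kept for saliency. Pooling
before concatenation is the only reading under which a 2048-dimensional
prototype is consistent with "concatenating the refined feature maps", so
that is what the package does.

**Prototype head.** Two learnable vectors `P_benign`, `P_malignant` live in
the fused space. Squared Euclidean distances are turned into a posterior by
a Student-t kernel, `p_k ∝ (1 + d_k/alpha)^(−(alpha+1)/2)`, computed in log
space; `alpha` (default 3, optionally learnable through a softplus) sets
how sharply probability reacts to distance. The loss is soft-label
cross-entropy on these posteriors plus 0.5 times a clustering term, the
label-weighted mean squared distance of each embedding to its own
prototype; the clustering form is a pull-only term, the simplest functional
consistent with promoting proximity to the class prototype. Prediction is
the posterior argmax, the posterior maximum is the confidence, and an exact
tie resolves deterministically to the benign index with an ambiguity flag.

**Saliency.** Grad-CAM weights each channel of a chosen spatial layer by
the spatial mean of the class-score gradient and rectifies the weighted
sum. The score backpropagated is the unnormalized log-kernel value
`−((alpha+1)/2)·log(1 + d_c/alpha)` — the analogue of a pre-softmax logit —
rather than the normalized posterior. The default layer is the pre-pool
fused map (it is the representation actually classified); the local and
global final stages are selectable, and the local stage is the more
spatially structured choice because its gradients arrive through the
cross-attention rather than through a spatially uniform pooling path.

## Implementation

No deep-learning framework is used: layers and their exact backward passes
(affine, layer norm, GELU, softmax attention with masks and bias tables,
depthwise convolution, patch rearrangements) are implemented directly on
BLAS-backed matrices, and the loss gradients are verified against central
finite differences in the test suite, for the head in isolation and for
score gradients through the full network. Training is plain AdamW (decoupled decay applied uniformly to all
parameters, biases included — at the default rates the effect on gains and
biases is negligible) with a cosine-annealed learning rate, linear warm-up
over 5% of the schedule by default, and an EMA shadow copy of the weights
(decay 0.999). Everything is seeded; two runs with the same seed produce
bit-identical loss trajectories on CPU.

## Presets

| preset | input | stem patch | stages (C) | window | fused dim |
|--------|-------|------------|------------|--------|-----------|
| micro  | 48    | 6          | 8, 16      | 4      | 32        |
| tiny   | 96    | 6          | 16, 32     | 4      | 64        |
| base   | 384   | 4          | 128…1024   | 7      | 2048      |

The base preset keeps every printed reference dimension — 384×384
single-channel input, stage-4 width 1024 per stream, 7×7 windows, 8 fusion
heads of width 128, prototype dimension 2048 — but with one block per
local stage and two per global stage so that a CPU forward pass completes
in seconds. Depth is a preset field; the architecture is otherwise
unchanged. micro and tiny are the desk-scale presets every training test
uses. Both streams share their total stride in all presets, so the fused
spatial map needs no resampling (an alignment path exists for custom
presets with unequal strides).

## Preprocessing and augmentation

CLAHE runs with clip limit 2.0 (relative to the uniform bin height, the
dominant convention) on an 8×8 tile grid with bilinear inter-tile blending;
a zero-dynamic-range image passes through unchanged. Min–max normalization
maps to [0, 1], sending a constant image to all zeros — deterministic and
range-preserving. Resizing is bilinear with pixel centers at half-integer
offsets, so same-size resizing is exactly the identity. Geometric
augmentation composes rotations within ±10°, bounded translations and
shears, and horizontal flips, with reflection padding so no artificial dark
rectangles appear at borders. The RandAugment-style policy (N = 2, M = 9 by
default) samples from a grayscale-safe, morphology-preserving pool; color
operations are excluded because lesion morphology must survive
augmentation. MixUp draws `lambda ~ Beta(0.3, 0.3)` per pair, pairs by a
random within-batch permutation, and shares each lambda between an image
and its label. All stochastic steps run online, training data only.

## Synthetic data

The generator emulates the coarse statistics that make the classification
problem well-posed: an elliptical breast region over a dark background,
band-limited Gaussian texture for fibroglandular tissue, and class-linked
lesions — malignant images carry either a bright blob with radial spicule
strokes or a cluster of 5–15 high-intensity dots, benign images a faint
smooth blob or nothing. Patients have 1–3 images (mean ≈ 1.5) with
patient-consistent class; the malignant fraction defaults to 0.3 to
exercise the chance-corrected metrics under imbalance. A brightness
threshold on the top 2% of pixels separates the default cohorts with
accuracy ≥ 0.8, so the learning problem provably has signal. What the
generator does **not** model: acquisition physics, film digitization
artifacts, breast density categories, pectoral muscle, or any radiographic
realism — passing tests show the pipeline learns and localizes the designed
signal, not that it would perform on clinical data.

## Desk-scale evaluation choices

Training tests run at sizes chosen so the whole suite stays interactive:
the overfit check trains the tiny preset on 32 synthetic images for 200
steps (batch 16, peak learning rate 3e−3, no augmentation, weight decay 0),
and reaches training accuracy 1.0; the learning rate is raised above the
reference 1e−4 because a 200-step budget at desk scale sits in a different
optimization regime than 80 epochs over thousands of images.

Prototype initialization defaults to scale 0.5. At a much smaller scale
both prototypes start nearly coincident, posteriors pin near one half, and
the head spends most of a short run disambiguating itself; 0.5 puts the
initial prototype separation on the order of the embedding spread.

Cross-validation and the ablation harness use the micro preset on cohorts
of 40–60 patients. At these sizes a held-out test partition contains around
a dozen images from a handful of patients, and we observed that held-out
accuracy there is dominated by majority-class collapse or memorization
noise rather than by architecture. The ablation ordering check (full model
versus passive fusion) is therefore run as a fitting-capacity comparison:
mean development-set accuracy after a fixed 100-step budget across three
seeds, a budget at which neither variant saturates. The held-out protocol
remains available (`run_ablation(..., eval_on = "test")`) and is the right
choice at realistic cohort sizes.

The Grad-CAM localization check trains the micro preset with geometric
augmentation (no RandAugment, no MixUp) for 300 steps with prototype scale
0.1: augmentation forces spatially robust features, and the slower head
separation at scale 0.1 keeps pressure on the encoders to learn the lesion
signal rather than memorize texture. Saliency is evaluated at the local
stage, whose gradients are spatially structured. Under pure memorization
(no augmentation, long training) localization degrades — an expected
property of Grad-CAM on overfit models, worth knowing before reading
saliency maps from small-data fits.

## Evaluation protocol

Splits are patient-level throughout: a patient's label is the majority
label of their images (ties resolve to malignant, the screening-conservative
choice), an 80/20 development/test split is stratified by that label with
largest-remainder rounding, and five-fold cross-validation deals shuffled
patients round-robin within class. Leakage is structurally impossible and
fuzz-tested over 100 seeds. Metrics treat malignant as positive: accuracy,
precision, recall, F1, MCC and Cohen's kappa from the 0.5-thresholded
confusion matrix (precision/recall fall back to 0 on empty denominators,
MCC to 0 on a zero marginal, kappa to 0 at chance agreement 1), AUROC as
the midrank pairwise statistic, AUPRC by step integration over descending
score thresholds with ties grouped. Fold aggregation reports the arithmetic
mean and the sample (n−1) standard deviation — a single fold reports SD 0
by convention. Confidence intervals are percentile bootstrap: resample the
fold values with replacement (10,000 iterations by default), take the 2.5th
and 97.5th percentiles of the resample means.

## Known limitations

- Per-stage depths at base scale are reduced; the package demonstrates the
  architecture and its contracts, not ImageNet-scale capacity.
- No pretrained weights exist and none can be loaded from published
  checkpoints; random initialization and user checkpoints are supported.
- The DICOM reader is absent (PNG/TIFF only).
- Generalization experiments at desk scale are data-limited by design;
  conclusions about clinical-scale behavior require clinical-scale data.
- Bootstrap intervals from five fold values are coarse; they are reported
  as described, not as inferential guarantees.
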