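---
title: "Semi-supervised multi-decoder U-Net for retinal lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised multi-decoder U-Net for retinal lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mdunet)
```

## The problem and the model

Diabetic retinopathy is screened from color fundus photographs, where four
lesion families matter for grading: microaneurysms (MA, tiny dark-red dots),
hemorrhages (HE, irregular dark-red blots), hard exudates (EX, vivid
yellow-white deposits) and soft exudates (SE, pale "cotton-wool" patches).
Pixel-accurate annotation is expensive, so labeled sets are small while
unlabeled photographs are abundant. **mdunet** addresses this with a
single-encoder, multi-decoder U-Net:

* one contracting encoder shared by all tasks; at each of `depth` resolution
  levels a block of `conv 3x3 -> batch-norm -> ReLU` (twice by default),
  with 2x2 max-pooling between levels and channels doubling per level;
* four segmentation decoders, one per lesion, each mirroring the encoder
  with 2x2 stride-2 transposed convolutions and concatenating the matching
  encoder level's features through skip connections;
* one reconstruction decoder with the same structure and a 3-channel output.

Training is in two phases. The *unsupervised* phase minimizes the
mean-squared reconstruction error

$$L_{rec} = \mathrm{mean}\,(x - \hat x)^2$$

over the unlabeled pool, updating only the encoder and the reconstruction
decoder. The *supervised* phase minimizes

$$L = \alpha\,L_{rec} + \beta\,L_{seg}^{(1)} +
      (1-\beta)\bigl(L_{seg}^{(2)} + L_{seg}^{(3)} + L_{seg}^{(4)}\bigr),$$

where $L_{seg}^{(1)}$ is the soft dice loss of the designated *primary*
lesion and the other three are *auxiliary* tasks that regularize the shared
encoder. Each per-task loss is the sigmoid-smoothed dice loss

$$L_{dice} = 1 - \frac{2\sum p\,g + \varepsilon}{\sum p + \sum g +
\varepsilon}, \qquad p = \sigma(\text{logits}).$$

One model is trained per lesion: to segment HE, HE is the primary task and
MA, EX, SE are auxiliary, and so on. `train_all_primaries()` pre-trains
once and branches the four supervised runs from the identical snapshot.

A note on the dice denominator: the textbook formula is often written with a
set union. A literal union would give two identical nonempty masks a dice of
2, contradicting the statistic's own [0, 1] range, so both the loss and
`dice_score()` use the standard mass sum $\sum|p| + \sum|g|$, which makes
`dice_score(m, m) == 1`.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | weight of $L_{rec}$ in the total loss | 1.0 | unit weight; MSE is a *mean*, so `alpha` is resolution-independent |
| `beta` | primary-vs-auxiliary trade-off, in [0,1] | 0.7 | primary dominates, auxiliaries still contribute; `beta = 1` reduces exactly to single-task training |
| `epsilon` | dice smoothing | 1e-6 | applied to numerator and denominator so empty-prediction/empty-target pairs give loss 0 |
| `learning_rate` | SGD step | 1e-4 (reference recipe) / 0.5 (desk-scale presets) | the reference recipe targets full-scale photographs; the tiny batch-normalized desk-scale networks need much larger steps |
| `batch_size` | images per step | 16 / 8 or 4 in presets | final incomplete batch dropped in training, kept in evaluation |
| `supervised_recon` | keep $\alpha L_{rec}$ during the supervised phase | `TRUE` | the total loss includes the term; setting `FALSE` updates only encoder + segmentation decoders, and both paths are tested |
| `threshold` | binarization of probability maps | 0.5 | exposed everywhere a mask is derived |

Design points that were genuinely open, and how they were decided:

* **Skip connections** are channel concatenation (the U-Net convention);
  an additive merge is available via `skip_mode = "add"`.
* **The reconstruction decoder gets skips too** by default (all decoders
  are structurally identical); `recon_skips = FALSE` forces reconstruction
  through the bottleneck alone, since skip-equipped reconstruction can
  shortcut representation learning.
* **Encoder "levels"** are double-conv blocks; `conv_per_block = 1` exposes
  the single-conv reading.
* **Split rounding.** `split_sizes()` uses train = ceiling, val = round,
  remainder to test: for 1842 images at 70/5/25 this gives (1290, 92, 460),
  matching the published partition of the labeled pool exactly (plain
  rounding would give 1289/92/461). The split is an unstratified seeded
  shuffle; stratification by lesion burden was considered and left out as
  the reference protocol does not state it.
* **Best-checkpoint selection** considers the initialization as epoch 0, so
  a run that never improves on validation returns its starting parameters
  rather than a degraded model.
* **Preprocessing order** is crop, then global per-channel histogram
  equalization restricted to the field of view, then aspect-preserving
  bicubic resize with symmetric padding, then per-image min-max
  normalization. Equalizing before cropping would let the blank border
  dominate the histogram; "resize based on aspect ratio" is read as
  scale-and-pad, not distortive stretching, to preserve lesion shape.
* **Sigmoid placement.** Segmentation decoders emit logits; the sigmoid is
  applied inside losses, metrics and `predict()`, keeping logits available.

## What the synthetic generator emulates — and what it does not

`generate_sample()` draws a circular orange-brown retinal field with a
radial shade, low-frequency color texture, curved dark vessels growing out
of a bright optic-disc ellipse, and the four lesion families with exact
painted-support masks. The family statistics mirror the clinical ordering:
EX largest and most conspicuous, MA smallest (1–3 px) and hardest, SE
rendered at deliberately low contrast. Same-family lesions never overlap
(bounded retries; a crowded image simply carries fewer lesions, logged),
masks never leave the field of view, and a fixed seed reproduces a dataset
bit-identically.

It does **not** emulate: acquisition artifacts (blur, over/under-exposure,
specular reflections), anatomical variation, vessel ground truth,
neovascularization or IRMA lesions, or the long-tailed lesion-size
distributions of real data. Passing tests therefore demonstrate that the
architecture, losses, training phases and evaluation machinery behave as
specified — not that the default configuration reaches clinical-grade
accuracy on real photographs.

The lesion `contrast` parameter tunes detectability. The default (1.0) was
calibrated during development so that a tiny network reaches a validation
dice of at least 0.6 on the default benchmark — training should be neither
trivial nor impossible at desk scale. `shift_domain()` lowers contrast
(x0.7) and raises noise (x1.5) to emulate a harder target domain for the
cross-dataset protocol.

## Numerical choices

* Batch-norm uses population statistics with momentum 0.1 and eps 1e-5;
  evaluation mode uses running statistics, making inference a pure
  deterministic function of parameters and input.
* Parameter initialization is He-scaled Gaussian, fully seeded; two builds
  from the same seed are bit-identical, and training is deterministic for a
  fixed seed and BLAS thread count.
* The backward pass is hand-derived and verified against central finite
  differences to ~1e-8 relative error in the unit tests.
* AUC-ROC uses the rank (Mann-Whitney) formulation with tie averaging;
  AUC-PR uses interpolation-free step summation with tied scores entering
  together. Single-class inputs are reported as undefined (`NA`) and
  excluded, with a warning, as is sensitivity on an empty ground truth.
* Degenerate inputs: an all-blank image is a hard error in cropping; a
  constant channel passes histogram equalization unchanged; masks with more
  than two levels are binarized at half scale with a warning.

## Desk-scale benchmarks

All shipped experiments run on one CPU core. The sizes are the package's
reference configurations, chosen so the full test suite stays in the
minutes range:

* `default_benchmark()`: 128x128 images, 40 labeled (32 train / 8 val) and
  200 unlabeled, depth-3 network with 8 base channels (~75k parameters),
  3 unsupervised + 12 supervised epochs, primary EX. Reaches validation
  dice ~0.85–0.9 in about five minutes.
* `trend_benchmark()`: 64x64 images, 16 labeled / 40 unlabeled, 4 base
  channels, shorter schedules; used with 5 seeds for the auxiliary-task
  ablation, the unlabeled-amount sweep and the cross-dataset protocol,
  where only one-sided "does not hurt by more than 0.02 dice" trend checks
  are asserted, never absolute effect sizes — those are dataset- and
  scale-specific.

At this reduced scale the *measured effects are small*: auxiliary tasks
help by well under 0.01 dice and two epochs of reconstruction pre-training
can land on either side of zero. The harness asserts the qualitative
claim (no degradation beyond the band), and the absolute improvements
reported for GPU-scale training on real data should not be expected here.

## Known limitations

* The native R/C++ implementation is single-threaded and desk-scale; it is
  not a GPU training framework, and full 512x512 five-level training on
  tens of thousands of photographs is out of its intended range.
* Only plain SGD (optional classical momentum) is provided — no schedules,
  weight decay or early stopping, which the reference recipe does not
  specify either.
* JPEG reading requires the suggested `jpeg` package; PNG and TIFF are the
  primary formats. DICOM is out of scope.
* Severity grading, lesion-instance detection metrics and baseline
  architectures (FCN, DeepLab, attention U-Nets) are out of scope.
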