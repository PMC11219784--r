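---
title: "LMBiS-Net: model, training schedule and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LMBiS-Net: model, training schedule and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Retinal blood vessels are thin, branching, low-contrast structures in fundus
photographs; segmenting them pixel by pixel is a standard primary step in
automated screening for diabetic retinopathy, glaucoma and related disease.
LMBiS-Net is a lightweight U-Net-style encoder–decoder built for this task
under a hard budget of 0.172 million trainable parameters, organised around
three ideas:

* **Few poolings.** The encoder has three convolution blocks but only two
  2×2 max-poolings, so feature maps never drop below a quarter of the input
  resolution and thin-vessel detail survives the contraction path.
* **A multipath feature-extraction block (MFEB)** between the last encoder
  block and the bottleneck. Each of its two stages passes its input through
  three parallel paths with kernel sizes $n = 2k-1$ for $k = 1..3$ (1×1,
  3×3, 5×5), each path being convolution → ReLU → batch-normalisation, and
  sums the three outputs elementwise:
  $$S_1 = \sum_{k=1}^{3} \beta\!\left(\mathrm{ReLU}\!\left(f^{n\times n}(I_{in})\right)\right),
  \qquad
  I_{out} = \sum_{k=1}^{3} \beta\!\left(\mathrm{ReLU}\!\left(f^{n\times n}(S_1)\right)\right).$$
  Summation (not concatenation) forces all paths to share one channel
  width and keeps the block cheap while mixing receptive-field scales.
* **Bidirectional skip connections.** Forward skips concatenate encoder
  features (E2, E1) into the decoder merges, as in a conventional U-Net.
  A reverse skip additionally *remaps decoded features back onto the
  encoder*: the first decoder block's output is projected by a 1×1
  convolution to the width of E1, upsampled (nearest-neighbour) across the
  scale gap, and added to the stored E1 features before the second decoder
  merge consumes them. Execution stays a single acyclic pass because the
  refined encoder features feed only later-executing merges.

The head is a 1×1 convolution to two channels followed by a per-pixel
softmax; training minimises the soft dice loss on the vessel channel.

The per-stage channel widths are not part of the published design — only
the topology and the parameter budget are. The default `channelPlan()`
(stem 8; encoder 8/16/32; multipath 32; bottleneck 32; decoder 32/16/8)
was chosen once so that the full graph comes to 113,370 parameters,
comfortably inside the budget; `buildNetwork()` refuses to build any plan
that exceeds 172,000 and prints the per-layer accounting when it does.
`countParameters()` uses the closed forms $k^2 C_{in} C_{out} + C_{out}$
per convolution (bias included, transpose convolutions alike) and $2C$ per
batch-normalisation layer, and always equals the summed length of the
weight arrays actually allocated.

Ablation variants mirror the architecture study axes:
`lightweight_baseline` (no MFEB, no reverse skip), `lbl_mfeb` (adds the
MFEB) and `full`; their parameter counts increase strictly in that order.
`baseline_unet` is the heavy single-path reference (widths scaled 8×,
exempt from the budget).

## Training schedule

`trainingConfig()` encodes the published recipe: Adam at initial learning
rate 0.001, dice loss, an epoch ceiling of 50, halving of the learning rate
after 7 consecutive epochs without improvement of the validation dice
(floor $10^{-6}$), and early stopping. The "ceiling of 50" is read as 50
*epochs*, consistent with per-epoch training-time reporting alongside the
schedule; this reading is configurable. Defaults left open by the recipe
and fixed here once: early-stop patience 15 epochs, batch size 2, Adam
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$, validation split
10% of the (augmented) training set, seeded. The weights returned are those
of the best-validation epoch.

The dice loss uses smoothing $\varepsilon = 1$ in numerator and
denominator; with $\varepsilon \to 0$ it is exactly one minus the dice
coefficient, and on binary masks one minus the F1 score — an identity the
test suite asserts.

## Augmentation policy

Each training image expands 38-fold: 36 rotations in 10° steps (0°–350°,
identity included) plus two contrast variants of the unrotated image with
factors 0.9 and 1.1. The published policy states the two transform families
and the factor 38; this 36 + 2 decomposition is the minimal composition
consistent with both and is encoded in `augmentationPolicy()` so it can be
swapped. Contrast is linear scaling about the per-channel mean intensity
inside the FOV, $x \mapsto \mu + f\,(x - \mu)$, clipped to $[0,1]$ — the
plainest reading of "contrast modification by a scalar factor". Rotations
interpolate the image bilinearly (fill 0, matching the black fundus
border) and the masks nearest-neighbour, then re-binarise. Public
augmented-image counts for two of the four benchmark datasets (608, 760)
are not 38× their leave-one-out training sizes; no reconciliation is
published, so the module implements the stated 38× policy and leaves those
two table cells unmatched.

## Evaluation

All metrics derive from pixel confusion counts, restricted to the FOV when
an FOV mask exists (standard DRIVE practice; togglable): sensitivity
$T_P/(T_P+F_N)$, specificity $T_N/(T_N+F_P)$, accuracy, F1
$2T_P/(2T_P+F_P+F_N)$, and the closed-form AUC
$$AUC = 1 - \tfrac12\!\left(\frac{F_P}{F_P+T_N} + \frac{F_N}{F_N+T_P}\right),$$
which is algebraically $(S_e+S_p)/2$ — balanced accuracy at the fixed
operating point, not a ROC sweep. It is implemented exactly in that closed
form; the conventional trapezoidal ROC AUC is available separately as
`rocAuc()`. A metric with a zero denominator is reported as `NA`, never
as 0, and dataset means are unweighted means over images with undefined
values excluded and counted (pooled-pixel aggregation is an option).
Probability maps are thresholded at 0.5 with strict inequality, ties to
background.

## The synthetic generator

`makeSyntheticDataset()` emulates exactly the features of fundus data the
pipeline touches: a circular FOV disc on a black background, a smooth
radial background gradient in a reddish tone, and branching curvilinear
vessel trees — biased random walks with probabilistic bifurcation — whose
stroke width tapers geometrically from 8 px trunks to 1 px capillaries (at
512 px; widths scale with the side). Vessels are darkened by a contrast
fraction (default 0.55) and Gaussian noise (sd 0.02) is added inside the
FOV. Default tree parameters (6 trees, depth 5) were chosen once to give a
vessel-pixel fraction of roughly 4–17% at 256 px, bracketing the ~8–12%
density of real fundus annotations. Everything derives deterministically
from the seed; sample $i$ of a dataset uses seed $s + i - 1$.

The generator does **not** emulate photographic realism: no optic disc,
fovea, lesions, exudates, camera vignetting or JPEG artefacts, and vessel
geometry is a random walk, not haemodynamics. Tests passing on this data
therefore demonstrate that the implementation is correct and the
architecture can learn vessel-like structure — they say nothing about
segmentation accuracy on real retinas, which the published benchmark
numbers address and which requires the real datasets and GPU-scale
training (out of scope here).

## Numerical choices

* **Engine.** The network runs on a dense-array engine written for this
  package (im2col convolutions dispatched to BLAS, with the patch
  gather/scatter in compiled code); analytic gradients for every primitive
  are checked against central finite differences in the test suite.
* **Operator order** is convolution → ReLU → batch-normalisation, following
  the block equations literally ($\beta$ outside the ReLU) even though
  BN-before-activation is more common; the choice is deliberate and
  localised in one helper.
* **Batch normalisation** uses biased batch variance, $\epsilon = 10^{-5}$;
  running statistics for inference use a cumulative average over the first
  ten updates, then an exponential moving average with momentum 0.9, so
  that inference-mode behaviour tracks training early without a long
  warm-up bias.
* **Initialisation** is He-uniform (variance $2/\mathrm{fan_{in}}$) for all
  convolutions — matched to the ReLU activations used throughout, and
  measurably faster to converge here than Glorot-uniform — with scale 1 /
  shift 0 for batch-norm, all under one seed; max-pooling breaks ties by
  first window position; rotation and resizing use a center-aligned pixel
  convention under which a 90° rotation of a square grid is an exact index
  permutation (asserted bit-exactly in tests).
* **Degenerate inputs.** Input sides must be divisible by 4 so the two
  poolings invert exactly; zero-variance images pass through contrast
  scaling unchanged; an all-zero-weight network emits the uniform
  probability map.

## Problem sizes used by the tests

The suite exercises the full pipeline at reduced scale, chosen as the
smallest sizes that still exercise every code path: gradient checks on an
8×8 frame with a narrow channel plan; the end-to-end
synth → train → predict → evaluate cycle on four 64×64 images for two
epochs; the learnability smoke test overfits two 128×128 synthetic images
for up to 200 optimizer steps over three seeds. The smoke test asserts
learnability (training dice ≥ 0.9), not performance.

## Known limitations

* CPU-only and sized for desk-scale experiments; training on the real
  benchmarks at 512×512 with 38× augmentation is out of reach of this
  engine and was never its goal.
* Binary (vessel/background) segmentation only; no attention mechanisms,
  pretrained weights or mixed precision.
* The reverse-skip wiring realises "remap decoded features onto the
  encoder" as a single-pass refinement (project, resize, add). Other
  consistent readings of the published figure exist; this one preserves
  acyclicity and is isolated behind `remapReverseSkip()`.
* Exact per-layer widths reproducing precisely 0.172 M parameters are not
  recoverable from the published description; the budget, not the widths,
  is treated as normative.
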