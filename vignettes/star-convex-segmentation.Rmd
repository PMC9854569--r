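---
title: "Star-convex polygon segmentation of adherent cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-convex polygon segmentation of adherent cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starseg)
```

## The problem

Adherent cells in stained smear images touch along shared borders without
overlapping.  Semantic (per-pixel, two-class) segmentation merges touching
cells into one blob; bounding-box instance detectors struggle because
axis-aligned boxes of adjacent round cells overlap heavily.  For
circular-like objects a *star-convex polygon* is a better primitive: a
center point plus radial distances $d_0,\dots,d_{n-1}$ along $n$ fixed
equiangular directions $\theta_k = 2\pi k/n$.  Every cell is represented
by the polygon traced from its interior, and instance segmentation becomes
dense polygon regression plus non-maximum suppression (NMS).

`starseg` implements this pipeline end to end:

1. **Label encoding** — an instance label map becomes the two regression
   targets: an object-probability map and an $n$-channel radial distance
   stack (`encode_targets()`).
2. **Network** — an encoder–decoder CNN with residual attention-embedding
   (RAE) encoder blocks and an atrous spatial pyramid pooling (ASPP)
   bottleneck predicts both maps (`spc_network()`, `spc_forward()`).
3. **Loss** — $\mathcal{L} = \alpha\,\mathrm{BCE} + \beta\,\mathrm{WMAE}$
   with $\alpha = 0.5$, $\beta = 1$ (`total_loss()`, `spc_train()`).
4. **Decoding** — each pixel whose predicted probability reaches 0.3
   becomes a scored polygon proposal; polygon-based adaptive NMS (PA-NMS)
   keeps one polygon per cell (`extract_proposals()`, `pa_nms()`).
5. **Evaluation** — pixel metrics (Dice, TPp, FPp) and object metrics
   (FN rate, AP at IoU threshold $\tau = 0.7$) (`evaluate_pair()`).

## Target encoding

**Object probability.** After hole-filling, each foreground pixel's target
is its Euclidean distance to the nearest background pixel (the image
border counts as background), normalized *per instance* so that every
cell — regardless of size — attains probability 1 at its core.
Per-instance (rather than per-image) normalization is a deliberate
choice: proposal extraction thresholds the probability map, and a global
normalization would let large cells mute small ones below the threshold.
The alternative is available via
`object_probability_map(labels, per_instance = FALSE)`.

**Radial distances.** The loss is defined per pixel, so every foreground
pixel receives its own polygon target: the distance from that pixel to
the instance boundary along each of the $n$ rays.  The ray is marched in
unit steps, sampling the label of the nearest pixel, and the final step
is refined at 0.01-px resolution; leaving the image ends the march.  The
default $n = 32$ balances boundary fidelity against computation: the
round-trip tests show that rasterizing the 32-vertex polygon decoded at
an instance's maximum-probability pixel recovers the instance mask with
IoU ≈ 0.95–0.98 on generated scenes (the acceptance suite requires
≥ 0.85 per instance, mean ≥ 0.90).

The network regresses *raw pixel distances*; the loss compares target and
prediction on one scale, so no normalization constant is introduced.
Display-oriented normalization of distance maps is left to the caller.

## Network

The network is fully convolutional: three 2×2 max-pool downsamplings with
encoder blocks, an ASPP bottleneck (parallel 3×3 convolutions at dilation
rates 1, 6, 12, 18 merged by a 1×1 convolution), bilinear 2× upsampling
with skip concatenation and two 3×3 conv-ReLU layers per decoder level,
and two independent 1×1 heads: a sigmoid probability channel and
$n$ ReLU distance channels.  Channel widths start at `base_channels`
(default 32) and double per level.  Arbitrary input sizes are handled by
reflect padding to a multiple of $2^{\text{levels}}$ and cropping the
outputs back.

The **RAE block** fuses deep features $F_e$ (two 3×3 conv-ReLU layers on
the previous module's output) with shallow features $F_o$ (the same
operation applied to the original image bilinearly resized to the block's
resolution) through a feature-fusion attention (FFA) unit:

$$
\psi = \varphi^\top\!\big(\sigma_1(W_e^\top F_e + W_o^\top F_o + b_o)\big) + b_\varphi,
\qquad
W_a = \sigma_2(\psi), \qquad F_a = W_a \cdot F_e,
$$

with $\sigma_1$ ReLU and $\sigma_2$ sigmoid; $W_a$ is a single-channel
spatial map in $(0,1)$ broadcast over channels (spatial attention).  A
residual shortcut adds a 1×1 projection of the block input.  The
ablation variants (`encoder_variant`) strip these parts: `TCB` is the
plain two-conv block, `TCB+RC` adds only the shortcut, `TCB+FFA` only
the attention, `RAE` both; parameter counts are monotone across the four.

Two details are not fixed by the reference design and are declared here
as this package's choices: channel widths / ASPP rates / decoder block
composition follow the U-Net and DeepLab conventions (all exposed in
`spc_network()`), and feature fusion inside FFA is additive, matching the
attention formula rather than the concatenation glyph in the reference
figure.  Initialization is He-normal; the probability head bias starts at
−1 (mostly-background prior) and the distance head bias at +3 so the
ReLU distance outputs begin alive.

## Loss

With $y_i$ the target probability, $x_i$ the prediction, $t_{ij}, p_{ij}$
the target/predicted distances, and $N$ the pixel count:

$$
\mathrm{BCE} = -\tfrac{1}{N}\sum_i \big[y_i \log x_i + (1-y_i)\log(1-x_i)\big],
\qquad
\mathrm{WMAE} = \tfrac{1}{N}\sum_i y_i \sum_{j=1}^{n} |t_{ij} - p_{ij}|.
$$

The per-pixel weight $y_i$ sits *inside* the pixel sum (the printed form
of the reference equation is typographically ambiguous about this; the
verbal description — center pixels weighted more, background contributing
nothing — forces this reading).  The BCE target is the soft probability
map, so a "perfect" prediction has an entropy floor rather than zero BCE;
zero loss occurs exactly for hard targets.  $N$ counts all image pixels
by default, which keeps both terms bounded for empty images; the
foreground-only normalization mentioned in the reference text is
available via `normalize_by = "foreground_pixels"`.

Training is plain SGD with the reference recipe (momentum 0.99, weight
decay $10^{-8}$, learning rate $10^{-3}$, batch 12, 650 epochs, 8:2
split).  The implementation is deterministic for a fixed seed: data
order, augmentation draws and initialization all derive from
`spc_train_config(seed = )`.

## Adaptive suppression and the density question

Thresholded pixels yield thousands of proposals describing a handful of
cells.  Standard greedy NMS at threshold $N_t$ suppresses everything
whose IoU with the current best polygon reaches $N_t$; in crowded scenes
this also deletes true neighbors.  The adaptive variant raises the
threshold for detection $M$ to $N_M = \max(N_t, d_M)$, where $d_M$ is the
*density* of the scene at $M$, so crowded true objects survive.

The reference pseudocode consumes the density list $D$ but never defines
it.  This is the one genuinely open design point in the method, and the
package's resolution is documented here:

* The naive self-contained proxy — $d_i$ = maximum IoU of proposal $i$
  against *all other proposals* — is unusable: within one cell, hundreds
  of near-duplicate proposals give every proposal a density near 1, so
  every $N_M \approx 1$ and suppression is disabled.  Measured on the
  scaled training setup this yields 300–500 "cells" per image and an
  object AP of 3% — a pathology, not an implementation bug.
* `proposal_density()` therefore follows the semantics of the
  adaptive-NMS lineage the method builds on, where density means crowding
  by *other objects*: the object set is first estimated with a standard
  NMS pre-pass at $N_t$, and $d_i$ is the maximum IoU of proposal $i$
  against the estimated objects excluding the one it itself represents
  (its best-matching object).  In uncrowded scenes all densities fall
  below $N_t$ and PA-NMS reduces *exactly* to standard NMS — a property
  the acceptance tests assert.

Suppression uses $\text{IoU} \ge N_M$ (as in the pseudocode), ties in
score break toward the lower proposal index, and the kept polygons are
rasterized in score order (earlier polygons win contested pixels) to form
the output label map.  One practical numerical consequence of the
$\ge$ comparison: PA-NMS re-run on its own output with *recomputed*
densities is not idempotent, because a kept pair whose IoU defines the
recomputed density sits exactly on the threshold; with retained
densities, idempotence holds and is tested.

### Polygon IoU

Star-convex polygons may be non-convex, so general polygon clipping is
easy to get wrong.  The package computes intersection areas exactly by
decomposing the second polygon into its triangle fan (the fan partitions
any polygon that is star-shaped about its center) and clipping the first
polygon against each triangle with Sutherland–Hodgman; signed areas
remain exact for non-convex subjects because each clip region is convex.
A supersampled rasterization backend (`polygon_iou(method = "raster")`)
serves as an independent oracle; the two agree to ~$10^{-4}$, well
inside the 0.01 acceptance tolerance.  The IoU of two degenerate
(zero-area) polygons is defined as 0.  The pairwise IoU matrix used by
density and suppression is filled entry-by-entry with the same
computation as per-pair calls so that exact-equality threshold
comparisons behave identically in both.

## Synthetic data: what it does and does not emulate

The generator (`generate_image()`) emulates the *geometry* of the
reference training scenes: 256×256 single-channel images with 3–9
adherent but never overlapping circular-like cells (defaults
`generator_config()`).  Cells are star-convex shapes — base radius 12–40
px, low-order harmonic radial perturbation of amplitude 0.25 — placed by
rejection sampling; under adhesion (default on, probability 0.6 per
placement) new cells are proposed tangent to an existing one, and a
candidate is accepted only if its rasterized mask shares no pixel with
previously placed cells.  Rendering uses a per-cell base intensity
(0.55–0.85) with a center-bright interior gradient on a darker
background (0.15) plus Gaussian noise (sd 0.05); the gradient dips at
shared borders, giving the network the same kind of boundary cue real
adherent cells provide.  Intensity parameters are declared, not inferred:
the reference dataset's texture model is not described.

What a green test on this data establishes: the encoding/decoding
round-trip, the optimization machinery, and the suppression logic work,
and the network can learn to separate touching convex-ish blobs.  What it
does not establish: performance on real stained cytology — no staining
variability, debris, blur, overlapping cells, or annotation noise is
simulated, and the headline numbers of the reference evaluation are out
of scope by design.

## Scaled-down verification

The acceptance suite trains the full RAE+ASPP variant at reduced scale
chosen once for a 1-CPU budget: 64×64 scenes (the 256×256 geometry
scaled by 4: 3–7 cells, radius 5–11 px), 200 training and 30 held-out
images, `base_channels = 8`, 30 epochs, batch 12, the reference
optimizer settings, histogram equalization on, augmentation off (the
generator supplies unlimited i.i.d. scenes; augmentation exists for
small fixed datasets and is exercised by its own tests).  On this world
the final-epoch loss falls below 30% of the first epoch's and the
held-out metrics reach DC ≈ 0.88 and AP(τ=0.5) ≈ 0.8, against acceptance
floors of 0.80 and 0.50.  Training takes ≈ 9 minutes on one CPU.

## Numerical and degenerate-input choices

* Ray march step 1 px with 0.01-px refinement; bounded error verified
  against a 0.01-px full march.
* Predictions are clamped to $[10^{-7}, 1-10^{-7}]$ inside BCE.
* Reflect padding for non-divisible input sizes at inference; training
  requires divisible sizes (the generator produces them).
* All-background inputs: encoding returns zero maps; an all-background
  prediction yields an empty label map, Dice 0 against non-empty truth,
  and FN rate 1.
* Degenerate polygons rasterize to nothing and have IoU 0.
* Label maps are exchanged as uncompressed 16-bit TIFF (ids ≤ 65535);
  the TIFF layer is a minimal built-in reader/writer because the
  execution environment provides no R image-I/O package.  Overlays are
  written as binary PPM for the same reason.

## Known limitations

* The density definition is this package's interpretation of an
  undefined quantity in the reference method; it is principled and
  validated behaviorally, but it is not guaranteed to be what the
  original authors computed.
* Cells are assumed star-convex about their probability peak; strongly
  concave or overlapping objects violate the representation.
* The training loop is CPU-bound R/BLAS; it is meant for method study
  and testing at reduced scale, not for full-scale training.
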