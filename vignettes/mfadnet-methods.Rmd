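---
title: "Weakly-supervised stone detection: model, losses and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised stone detection: model, losses and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Common bile duct (CBD) stones are small, often low-contrast objects in
abdominal CT slices, and the brightest structures in such slices are almost
never the stone — bone and calcified tissue dominate. Supervised detectors
need bounding-box annotations that are expensive to obtain; this package
implements a *weakly-supervised* detector trained only on image-level labels
$y \in \{0, 1\}$ (stone present / absent) that nevertheless emits a bounding
box at inference time.

## The network

For an input slice $I \in [0,1]^{H \times W}$ the model computes, in order:

* **Backbone** — three VGG-style blocks (two same-padded $3{\times}3$
  convolutions + ReLU each; $2{\times}2$ max pooling after blocks 1 and 2;
  dropout after every block in training). The default widths are 64/128/256,
  giving a backbone feature $f_b$ at $1/4$ resolution. Block-1 and block-2
  outputs are retained for the decoder's forward connections.
* **Multiple field-of-view (M-FOV) encoder** — four *cascaded* dilated
  $3{\times}3$ convolutions with rates 1, 2, 4, 8. The first sees $f_b$;
  each later one sees $f_b$ concatenated with the previous dilated feature:
  $f_d^k = \mathrm{dconv}^{2^{k-1}}(f_b \oplus f_d^{k-1})$. A $2{\times}2$
  max pooling of $f_b$ joins the concatenation:
  $f_E = f_d^1 \oplus f_d^2 \oplus f_d^3 \oplus f_d^4 \oplus f_p$.
* **Attention-driven decoder** — $f_E$ is restored to full resolution
  through three $3{\times}3$ conv + instance-norm + ReLU stages (bilinear
  $\times 2$ upsampling before the first and third) and a final
  $1{\times}1$ convolution with ReLU, giving the 64-channel decoder feature
  $f_U \ge 0$. Two *forward connections* modulate decoder channels
  multiplicatively: the spatial global average pooling (GAP) of block 2,
  mapped to 64 dimensions by a dense layer, scales the first stage; the GAP
  of block 1 scales the full-resolution stage.
* **Spatial-channel attention** — channel attention
  $m_c = \sigma(\mathrm{pool}^{max}_s(f_U) + \mathrm{pool}^{ave}_s(f_U))
  \in (0,1)^{64}$ and spatial attention
  $m_s = \sigma(\mathrm{conv}^{7}(\mathrm{pool}^{max}_c(f_U) \oplus
  \mathrm{pool}^{ave}_c(f_U))) \in (0,1)^{H \times W}$, fused into the
  probability map $m_p = \sigma(\mathrm{conv}^1(m_s \otimes (m_c \otimes
  f_U)))$.
* **Classification head** — $m_p$ (optionally average-pooled) is flattened
  into two 256-unit fully connected ReLU layers and a 2-way softmax;
  $\hat y$ is the stone-class probability.

## The four losses

Training minimises
$\ell = \omega_{fg}\,\ell_{fg} + \omega_{bg}\,\ell_{bg} +
\omega_{con}\,\ell_{con} + \omega_{cls}\,\ell_{cls}$
with default weights $(1, 0.5, 1, 1)$ — the background loss is suppressed
because over-weighting it depresses detection rate:

* $\ell_{fg} = \frac{1}{WH}\sum_{ij} (1 - m_s^{(ij)})\, m_p^{(ij)}$ couples
  the two maps: probability-map responses are only cheap where the spatial
  attention also responds.
* $\ell_{bg} = \frac{1}{WH}\sum_{ij} (1 - y)\, m_p^{(ij)}$ drives $m_p$
  toward zero on normal images and is *exactly* zero on stone images, so a
  stone can never be learned as background.
* $\ell_{con} = \mathrm{BCE}(y, \mathrm{GAP}(m_p))$ makes the dominant
  response of $m_p$ agree with the image label.
* $\ell_{cls} = \mathrm{BCE}(y, \hat y)$ trains the classifier.

**Sign correction.** The printed form of the consistency and classification
losses in the equation block reads $-y\log(\cdot) + (1-y)\log(1-\cdot)$;
taken literally the second term is unbounded below and training diverges to
a degenerate optimum. Both are implemented as standard binary cross-entropy
($-y\log(\cdot) - (1-y)\log(1-\cdot)$), which is what the surrounding
description ("consistent with the ground-truth image-level labels")
requires. The literal form is kept behind `loss_weights(literal_sign =
TRUE)` for audit only. Logarithms are clamped at $\varepsilon = 10^{-7}$.

## Localization at inference

The stone attention map is
$m_a = \mathrm{pool}^{ave}_c(m_s \otimes (m_c \otimes f_U)) \otimes w(m_p)$,
max-normalised to $[0,1]$. Pixels with $m_a > 0.6$ are grouped into
8-connected components; if the classifier score passes 0.5, the largest
component (ties broken by peak value) yields a tight half-open bounding
box.

**Probability-map polarity.** The surrounding narrative is ambiguous about
whether $m_p$ encodes stone probability (which the consistency loss
suggests) or background probability (which the $(1-m_p)$ factor and the
"high $m_s$, low $m_p$" description suggest), so both polarities are
implemented (`polarity = "one_minus_p"` or `"p"`) and the choice is
recorded in each run summary. Empirically, on the synthetic task the
trained $m_p$ develops a *low* response exactly at the stone (the
classification head carves a hole there) with diffuse moderate responses
elsewhere, so the literal $(1-m_p)$ weighting is also the better-behaved
one; it is the default throughout.

## Optimisation schedule

RMSProp ($\rho = 0.9$, $\varepsilon = 10^{-8}$), batch size 3, initial
learning rate $10^{-4}$, at most 100 epochs; when the validation loss has
not improved by at least $10^{-5}$ for 5 consecutive epochs the rate is
divided by 10, and training ends early after 10 non-improving epochs. The
weights of the best-validation epoch are kept. A validation set is carved
out of the training manifest (stratified, 10% by default) because the 7:3
train/test protocol defines no validation partition.

## The synthetic phantom generator

No public dataset exists for this task (the motivating data are private
hospital CT). The generator emulates the *statistical structure* the method
relies on, not anatomy:

* a smooth low-frequency background (random cosine field scaled to
  $[0.15, 0.45]$) plus i.i.d. Gaussian noise (sd 0.02), clipped to
  $[0,1]$ — the tissue field runs to the image edge (there is no dark
  air/body boundary, see the limitations below);
* in every image, bright bone-like distractors (discs/rings at intensity
  $0.85$–$1.0$, i.e. at least as bright as any stone) placed strictly
  outside the duct region — this reproduces the failure mode of pure
  saliency methods, where the brightest structure is not the target;
* in positive images only, a single elliptical stone with Gaussian-smoothed
  edge, semi-axes 2–6 px (at the default 96–128 px resolution; the source
  material states only that stones are "relatively small"), intensity
  `local background + 0.35`, confined to the central duct region
  ($[0.3, 0.7]^2$ normalised); its tight bounding box is the ground truth.

What passing tests on phantoms do **not** show: robustness to anatomy-scale
clutter, partial-volume effects, Hounsfield calibration, 3-D context, or
stones adjacent to bright structures. The phantoms make the task *well
posed* for a weak localizer while remaining download-free and fast.

## Desk-scale experiment defaults

The reference data regime (512×512 slices, ~1,300 images, GPU training) is
far beyond a CPU test suite, so `experiment_config()` fixes a deliberately
scaled-down study: 96×96 phantoms, 20 stone + 40 normal training slices and
10 + 20 test slices (keeping the curated 1:2 class ratio and 7:3-style
split), a slim backbone (16/32/64 channels, $C_d = 16$; the decoder keeps
its 64 channels, which are part of the architecture), and the probability
map average-pooled to 24×24 before the classification head. Because an
epoch here is ~20 optimiser steps rather than ~300 and the validation
carve-out is only 12 images, the schedule is rescaled: initial learning
rate $10^{-3}$, a 20% validation fraction, plateau patience 10, early-stop
patience 24 and at most 40 epochs (a 12-image validation loss is noisy
enough that the reference patiences cut the learning rate, or stop
training, before the classifier has separated the classes).
`model_config()` and `train_config()`
retain the architecture-faithful defaults (64/128/256, $C_d = 64$,
learning rate $10^{-4}$, patiences 5/10, 100 epochs) for users with real
data.

With a backbone slimmer than 64 block-1 channels, the block-1 forward
connection gets the same dimension-matching dense map the block-2
connection always has; at the default 64 channels the GAP vector is used
directly.

## Numerical choices and degenerate inputs

* Same padding everywhere; dilated convolutions pad by
  $\mathrm{rate} \cdot (k-1)/2$.
* The encoder pooling feature uses a stride-1 same-padded $2{\times}2$ max
  pool so its shape matches the dilated features it is concatenated with (a
  strided pool would halve the resolution and make the stated concatenation
  impossible); a stride-2 + upsample variant is available via
  `fp_mode = "stride2up"`.
* $m_s$ and $m_c$ are sigmoid-squashed. The defining equations state a
  sigmoid only for $m_p$, but $(1 - m_s)$ in the foreground loss requires
  $m_s \in [0,1]$, and $m_c$ acts as a multiplicative weight — both follow
  the convolutional-block-attention convention.
* The decoder feature passes a final ReLU, so $f_U \ge 0$ and the stone
  attention map is non-negative by construction; `normalize_map()` treats
  negative entries as an error (they indicate polarity misuse) and leaves an
  all-zero map unchanged.
* He-normal initialisation, every tensor from its own derived seed stream,
  so ablation variants share bit-identical weights in all untouched
  components.
* Instance normalisation uses $\varepsilon = 10^{-5}$ and per-channel
  affine parameters.
* Ties in the largest-component rule are broken by the higher peak
  attention value; connectivity is 8-connected. Both choices are fixed here
  because the upstream description ("same as CAM") does not pin them down.
* An all-zero attention map yields no box; a score below the decision
  threshold always yields no box, regardless of the map.

## Known limitations

At the desk scale of the bundled experiment (60 training images, random
initialisation) the method is markedly weaker than in its intended regime
(~900 images, an ImageNet-pretrained backbone):

* the classification head can memorise the small training set, and the
  best-validation checkpoint rule is noisy when the validation carve-out is
  ~12 images — a single confidently misclassified validation image shifts
  the mean validation loss by up to $-\log(10^{-7})/12 \approx 1.3$;
* weak-label localization is only partially reproducible across seeds: the
  attended feature map sometimes peaks at the stone, but it can also be
  dominated by zero-padding border responses (the phantom's tissue field
  runs to the image edge, unlike a real abdominal slice) or by the bright
  distractors, and the encoder's quarter-resolution features inflate any
  supra-threshold component by roughly ten pixels, which caps the
  achievable IoU for the small stones the generator draws;
* average precision at IoU 0.5 is usually 0 for the same reason.

These are properties of the data regime, not bugs: the test suite checks
the arithmetic of every component against independent oracles, and the
end-to-end experiment reports whatever the regime yields.

* 2-D, single-slice only; no DICOM reader (convert to 16-bit PNG).
* One box per image: multi-stone slices are out of scope by design.
* CPU training of the full-width architecture at 512×512 is not practical;
  the faithful defaults exist for completeness and for GPU-backed ports.
* The mIoU convention averages over *all* stone images (a missed stone
  counts 0), which is the stricter of the two possible readings and makes
  miss-detection visible in the localization number.
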