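---
title: "Cross-phase liver hemangioma segmentation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-phase liver hemangioma segmentation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Liver hemangiomas are conspicuous in portal-venous-phase CT, where contrast
agent makes the lesion strongly hypodense relative to enhancing parenchyma,
but subtle in non-contrast CT. Contrast agents carry real risks for patients
with allergies or renal insufficiency, so a segmentation model that works on
non-contrast images alone is clinically valuable. The difficulty is domain
shift: a model trained on venous-phase images degrades on non-contrast
images, and a model trained only on non-contrast images has little signal to
learn from.

`wlaunet` implements a three-part answer:

1. **Wavelet edge enhancement (WEEM).** Each input slice is decomposed by a
   one-level 2D discrete wavelet transform into four subbands (LL
   approximation, LH horizontal detail, HL vertical detail, HH diagonal
   detail). The two directional detail bands are multiplied by factors
   $\lambda_1, \lambda_2$ and the image is reconstructed by the inverse
   transform. Boundaries sharpen; the untouched LL band preserves anatomy and
   the untouched HH band avoids amplifying diagonal, noise-dominated detail.
   The tuned operating point is the `sym4` wavelet with
   $\lambda_1 = \lambda_2 = 2$, selected over the grid $[1.3, 2.2]$ in steps
   of $0.1$; `weem_sweep()` reproduces that search on phantoms.
2. **Cross-phase transfer (pre-train / freeze / transfer).** The CNN encoder
   is first trained on venous-phase images by minimizing the soft Dice loss;
   its weights are then frozen and transferred, and only the Gaussian
   attention, transformer and decoder continue to train on non-contrast
   data. Freezing regularizes the target phase: the encoder keeps the
   discriminative representation learned where lesions are visible.
3. **Gaussian position-sensitive attention (GPSA).** From the non-contrast
   feature map $I$ and the lesion mask, the package computes the tumor-region
   intensity statistics $\mu$ and $\sigma$ (with stabilizer
   $\epsilon = 10^{-5}$) and a multi-scale Gaussian weight map
   $$G = \tfrac13 \sum_{k \in \{0.5, 1, 2\}}
     \exp\!\Big(\frac{-(I - \mu)^2}{2 (k\sigma)^2 + \epsilon}\Big),$$
   flattened row-major into $g$ and injected into every self-attention layer
   as a rank-1 bias: $A = QK^\top/\sqrt{d_k} + \lambda\, g g^\top$, with
   $\lambda$ a single learnable scalar initialized at 0.5. An attention
   supervision loss (binary cross-entropy between each query's softmaxed
   attended mass and the binary token-level tumor map) with weight
   $\alpha = 0.3$ keeps attention on lesion tokens. At inference, when no
   mask exists, population averages of the per-case $\mu$ and $\sigma$
   collected during training take their place.

The architecture is a hybrid CNN–transformer encoder–decoder: a 4-stage
stride-2 3×3 CNN encoder (shared weights, applied to both phases; the paired
forward uses the venous features as transformer tokens and the non-contrast
features for skip connections and Gaussian statistics), linear token
projection with learned positional embeddings, a pre-norm transformer
(reference scale: 12 layers, 8 heads; 4× feed-forward expansion), and a
4-stage decoder of ×2 bilinear upsampling + skip concatenation + 3×3 ReLU
convolutions, ending in a 1×1 two-class head. The fourth decoder skip is the
enhanced input plane itself, the natural full-resolution feature on the
encoder pathway.

## What the phantom generator emulates — and what it does not

All training and evaluation in this package run on a synthetic paired-phase
phantom, because the clinical cohort the method targets is private. The
generator reproduces the statistical structure the method actually relies
on:

* paired slices with *identical anatomy* (a shared smooth parenchymal
  texture) and *independent noise* per phase;
* a tumor/parenchyma HU offset that is strong in the venous phase (−40 HU)
  and weak but nonzero without contrast (−12 HU) — the defining premise,
  enforced by a validity check;
* lesion maximum diameters from a truncated normal (mean 24.6 mm, sd
  18.3 mm, range 3.2–87.5 mm) with the Tiny (<10 mm) / Small ([10, 20) mm) /
  Big (≥20 mm) strata;
* calibrated geometry: 0.75 × 0.75 mm² pixels, 1.5 mm slices.

Lesions are axis-aligned ellipses with eccentricity in [1.0, 1.8]; parenchyma
sits at 60 HU with 5 HU of smooth texture and 8 HU of additive noise. There
is no canonical intensity model for such a phantom, so these values are the
package's own choice of a plausible regime: the non-contrast lesion contrast
(−12 HU against 8 HU noise) is visible but weak, the venous contrast
unmistakable. Each case records the *measured* maximum diameter of its
rasterized lesion (the clinical measurement), so strata always agree with
the mask.

What the phantom does **not** have: realistic liver shape, vessels,
neighboring organs, partial-volume effects, scanner artifacts, or
inter-patient appearance variability. Passing tests on phantoms therefore
demonstrates that the algorithms are implemented correctly and that the
pipeline learns the cross-phase structure it was designed for — not that the
reported clinical accuracy would be reproduced on real CT.

At the default 64-px desk-scale field of view (48 mm) lesions larger than
~44 mm cannot be placed and are resampled, so the *per-case* diameter
distribution is additionally truncated by geometry; diameter-distribution
statistics are validated on draws from `sample_tumor_diameters()`, which is
field-of-view independent.

## Numerical and design choices

**Wavelet boundary handling.** The transform supports two extension rules.
`"periodization"` (the default) treats each axis circularly; for orthogonal
families the resulting transform is orthonormal, so subband energies add
exactly and the enhancement energy obeys
$\lVert \mathrm{enhance}(x) - x \rVert^2 =
 (\lambda_1 - 1)^2 \lVert LH \rVert^2 + (\lambda_2 - 1)^2 \lVert HL \rVert^2$
to floating-point precision — a property the test suite asserts at
$10^{-6}$ relative. `"symmetric"` (half-sample reflection) is the common
default elsewhere and is provided as an option; its subbands are slightly
redundant, so the energy identity holds only approximately there. Both modes
reconstruct perfectly (`1e-8` max error, every supported family).

**Decomposition depth is one level** — the enhancement operates on exactly
four subbands. Filter taps for the twenty supported families (Daubechies
1–5, Symlets 2–10, biorthogonal splines 1.1–3.3, Coiflets 1–5) are the
published constants.

**LH/HL naming.** LH denotes the horizontal-detail band (lowpass along
rows, highpass along columns) and HL the vertical-detail band. Both bands
are amplified and the tuned factors are equal, so output is unaffected by
the labeling convention.

**Dice loss smoothing.** The soft Dice loss uses sums of probabilities with
a smoothing constant $10^{-6}$ in numerator and denominator, which defines
the empty-truth/empty-prediction case as loss 0 without branching.

**Sigma definition.** The tumor spread is
$\sigma = \sqrt{\mathrm{mean}((I-\mu)^2) + \epsilon}$ — a standard deviation
with a variance-floor stabilizer, so $\sigma \ge \sqrt{\epsilon} > 0$ even
for constant regions.

**Mask-to-token-grid reduction.** Gaussian statistics and supervision
targets live on the transformer's token grid (input side / 16). The mask is
reduced by area-fraction pooling with threshold 0.5. A Tiny lesion can cover
less than half of every token cell; the forward path then falls back to the
cell(s) with maximal tumor fraction so per-case statistics remain defined.
`mask_to_grid()` itself keeps the strict 0.5-threshold contract, and
`tumor_stats()` still refuses an empty mask, pointing callers at population
statistics.

**Attention supervision placement.** The supervision loss reads the
head-averaged logits of the final transformer layer; supervision is active
in the non-contrast phase only (the venous pre-training phase minimizes pure
Dice). The weight map $G$ is treated as a constant with respect to the
feature extractor — only $\lambda$ learns through the bias term — which
matches its role as an anatomical prior rather than a learned feature.

**Dual integration paths.** The bias matrix inside attention is the primary
integration of the Gaussian weights (it is the formulated one); a
multiplicative token gate (features × (1 + g)) exists behind the `gate`
flag for experimentation.

**Optimization.** AdamW (decoupled weight decay $10^{-2}$), initial learning
rate $3 \times 10^{-4}$, cosine annealing to zero over the run; batch
assembly pairs the two phases of the same case and never mixes cases. All
shuffles, weight draws and phantom draws run through one master seed with
counter-based derived streams, and the implementation is deterministic on a
fixed machine, which is what makes the freeze test *bit-exact* rather than
approximate.

**Pure-R training machinery.** Gradients come from a small reverse-mode tape
(`R/nn-ops.R`) with fused layer operations (im2col convolution + ReLU, layer
norm, biased softmax attention, bilinear upsampling); every operation is
validated against central finite differences in development and the
transformer against an independent plain-math forward in the tests. With a
frozen encoder the per-case encoder outputs are cached across epochs — an
exact reformulation, not an approximation.

## Scales used by the tests and the acceptance script

The reference-scale configuration (512 × 512 inputs, 64 base channels,
12 transformer layers, 8 heads, 200 epochs, batch 8) is expressed in
`model_config_full()` and documented defaults, but the packaged experiments
run the desk-scale instance: 64 × 64 inputs (feature grid 4 × 4), 2
transformer layers, 2 heads, 8 base channels, batch 4, 20 + 20 epochs. The
end-to-end acceptance check trains the full two-phase protocol on 200
phantom cases (160/20/20 split) for three seeds and requires the held-out
Dice to beat the untrained baseline in at least two; the companion
`scripts/acceptance.R` runs a single-seed 60-case, 10 + 10-epoch version of
the same protocol alongside the fast closed-form checks. Structural tests
(ablation harness, training dynamics) run at 32 px. These sizes are the
package's chosen desk-scale study conditions; at 64 px the protocol trains
in minutes on one CPU while leaving the tumor/parenchyma statistics of the
phantom intact.

## Known limitations

* Phantom-only validation: no claim transfers to clinical CT without
  retraining and re-evaluation on real data.
* The mask-classification query decoder sketched in some descriptions of
  the architecture family is not implemented; the decoder here is the
  bilinear-upsampling/skip-connection pathway with a 1×1 head.
* GPSA uses the channel-mean feature map (one scalar per location), an
  isotropic Gaussian in intensity only, and one shared $\lambda$ across
  heads and layers.
* Hausdorff distances are 2D per slice (averaged over slices for stacks);
  HD95 is available behind `percentile = 95`.
* The desk-scale model is far below the reference capacity; absolute Dice
  values on phantoms are not comparable to clinical figures.
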