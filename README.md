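# wlaunet

Cross-phase segmentation of liver hemangiomas in **non-contrast CT**,
implemented as a tested R package. Hemangiomas are easy to see in
portal-venous-phase CT (contrast agent makes them strongly hypodense) and
hard to see without contrast; contrast agents are risky for patients with
allergies or renal insufficiency. This package implements a hybrid
CNN–transformer segmentation pipeline built around three ideas:

1. **Wavelet edge enhancement** — a one-level 2D discrete wavelet transform
   splits each slice into four subbands (LL, LH, HL, HH); the directional
   detail bands LH/HL are amplified by λ₁ = λ₂ = 2 (sym4 wavelet) before
   inverse reconstruction, sharpening tumor boundaries while the untouched
   LL band preserves anatomy:

       x* = IDWT(LL, λ₁·LH, λ₂·HL, HH)

2. **Pre-train / freeze / transfer** — the CNN encoder is trained on
   venous-phase images with the soft Dice loss
   `L_Dice = 1 − 2|Y ∩ Ŷ| / (|Y| + |Ŷ|)`, then frozen and transferred;
   only the attention, transformer and decoder adapt to non-contrast data.

3. **Gaussian position-sensitive attention** — tumor-region intensity
   statistics (μ, σ; stabilizer ε = 1e−5) define a multi-scale Gaussian
   weight map `G = ⅓ Σₖ exp(−(I − μ)² / (2(kσ)² + ε))`, k ∈ {0.5, 1, 2},
   flattened to `g` and added to every attention layer as a rank-1 bias:
   `A = QKᵀ/√d_k + λ·ggᵀ` with learnable λ (init 0.5), plus an attention
   supervision loss weighted by α = 0.3
   (`L_total = L_Dice + α·L_attention`). At inference, population averages
   of μ and σ replace the per-case statistics.

Because the clinical cohort this method targets is private, the package
ships a **paired-phase CT phantom generator** that reproduces the structure
the method relies on — identical anatomy across phases, strong venous /
weak non-contrast tumor contrast, lesion diameters from a truncated normal
(24.6 ± 18.3 mm on [3.2, 87.5] mm), 0.75 × 0.75 mm² pixels, Tiny/Small/Big
size strata — so every component is testable end to end without any
download. Metrics (Dice, IoU, pixel accuracy, Hausdorff distance in mm),
size-stratified reporting, a wavelet/amplification sweep and an 8-way
ablation harness are included. The network and its training loop (AdamW,
cosine annealing, reverse-mode autodiff) are pure R.

## A worked example

```r
library(wlaunet)

# 60 paired-phase phantom cases, 48/6/6 split
ds  <- generate_dataset(phantom_config(image_size = 64, seed = 11), 60, seed = 11)
cfg <- model_config(input_size = 64)            # desk-scale: 2 layers, 2 heads
tc  <- train_config(epochs = 10, batch_size = 4, seed = 1)

m0  <- wlau_model(cfg, seed = 1, gpsa = TRUE, enhancement = enhancement_config())
pre <- pretrain_venous(ds$train, m0, tc)        # phase 1: venous, Dice loss
m1  <- transfer_and_freeze(pre$model)           # freeze the encoder
fit <- train_noncontrast(ds$train, m1, tc)      # phase 2: non-contrast, L_total

evaluate_model(fit$model, ds$test, mode = "paired")
#> <metrics_report> Dice 50.95%  IoU 41.97%  ACC 90.26%  HD 11.63 mm  (n=6)
#>   per-stratum Dice: Tiny 0.00%, Big 76.43%
```

Reading the numbers: after 10 + 10 epochs on 48 training cases the model
finds large lesions reliably (Big-stratum Dice 76%) while sub-10 mm lesions
are still missed at this tiny training scale — the familiar strong
size-dependence of lesion segmentation. An untrained model scores Dice 0 on
the same split. The per-case Gaussian statistics collected in phase 2 are
stored in the checkpoint (`fit$model$population_stats`), so
`predict_mask(fit$model, case, stats_mode = "population")` works without any
annotation at inference.

Other entry points: `enhance()` / `weem_sweep()` for the wavelet module,
`biased_attention()` and friends for the attention algebra,
`ablation_table()` for the 2×2×2 module ablation, `write_case_nifti()` for
NIfTI export, and a thin command-line wrapper in `inst/cli/wlaunet.R`
(`generate`, `enhance`, `sweep`, `train`, `evaluate`, `ablate`,
`describe`).

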