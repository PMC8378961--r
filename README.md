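# mcrn

Single-image super-resolution for 2-D grayscale images — in particular
short-axis cardiac magnetic-resonance (CMR) slices, whose limited native
resolution motivates the method — with a **multichannel residual attention
network (MCRN)**, implemented entirely in R/C++ with no deep-learning
runtime dependency.

The network combines four ideas:

* **Dilated multichannel residual feature extraction** — parallel 3×3
  convolutions at dilation rates 1/3/5, fused and residually connected, so
  early features see up to an 11×11 footprint without pooling.
* **Iterative back-projection with error feedback** — alternating learned
  up/down-sampling stages; stage *n* upsamples the reduced LR cascade
  (`H₀ⁿ`), re-downsamples it (`L₀ⁿ`), and corrects with the upsampled
  projection error `e_lⁿ = L₀ⁿ − Lⁿ⁻¹`, giving `Hⁿ = H₀ⁿ + H₁ⁿ`; the
  down-block mirrors this on the HR cascade.
* **Channel attention** — squeeze-excite gating (global average → 64→4→64
  bottleneck → logistic gate) inside three residual attention blocks.
* **Subpixel reconstruction** — a 3×3 convolution to `s²·64` channels,
  pixel shuffle by the scale factor `s ∈ {2,3,4}`, and a linear 3×3 output
  convolution.

Training follows the standard recipe: L1 loss, Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8), constant learning rate 1e-4, on LR/HR patch pairs produced by
bicubic degradation.  Reconstructions are scored by PSNR
(`10·log₁₀(L²/MSE)`), SSIM (11×11 Gaussian windows, σ = 1.5), gray-level
Shannon entropy, and average gradient, under a pinned evaluation
convention (8-bit quantization, border shave = scale).

Because the original training corpora and benchmark sets require
downloads, the package includes a **synthetic cardiac phantom generator**
(bright blood pool, darker myocardial ring, textured background, additive
Gaussian/Rician noise) plus the 16-fold rotation/scale corpus augmentation
(4 rotations × 4 scales, so 591 images become exactly 9456), making the
entire pipeline testable at desk scale.

## Worked example

Desk-scale experiment: train the scaled-down preset (16 channels, 2
back-projection stages, learning rate 1e-3) for 800 steps on patches from
20 synthetic phantoms, then compare against bicubic upsampling on 5
held-out phantoms.  Takes about 3–4 minutes on one CPU.

```r
library(mcrn)

train_ph <- phantom_corpus(20, size = 64, seed = 11)
test_ph  <- phantom_corpus(5,  size = 64, seed = 99)

pairs <- unlist(lapply(train_ph, extract_patch_pairs, scale = 2,
                       lr_patch = 12, stride = 12), recursive = FALSE)

preset <- desk_preset(scale = 2, max_steps = 800, seed = 1)
model  <- build_model(preset$model, seed = 1)
fit    <- train_model(model, pairs, preset$train)

ev <- evaluate_model(fit$model, test_ph)
cat(sprintf("SR PSNR %.3f vs bicubic %.3f\n",
            ev$summary$psnr_sr, ev$summary$psnr_bicubic))
```

Output from this exact script:

```
SR PSNR 28.522 vs bicubic 28.126
```

i.e. after 800 steps the learned model already out-resolves the bicubic
baseline by ~0.4 dB on held-out phantoms (the direction, not the
magnitude, of the full-scale benchmark ordering — closing the full gap
requires GPU-scale training on natural-image corpora, which is out of
scope).  Training loss over the same run fell from 0.759 (step 1) to
≈ 0.028 (step 800).

Inference on any grayscale PNG:

```r
sr <- mcrn_forward(load_image("slice.png"), fit$model)  # 32x32 -> 64x64
save_image(sr, "slice_sr.png")
```

## Command-line interface

The installed package ships a launcher at `exec/mcrn` (run it with
`Rscript $(Rscript -e 'cat(system.file("exec/mcrn", package="mcrn"))')`
or call `mcrn_main()` directly):

```sh
mcrn phantom --n 20 --size 128 --seed 7 --out phantoms/
mcrn train   --phantoms 20 --size 64 --preset desk --out run1/
mcrn sr      --ckpt run1/model.rds --in lr.png --out sr.png
mcrn eval    --ref hr/ --test sr/ --scale 2 --json report.json
```

Configuration precedence is flag > `--config file.json` > documented
default; unknown keys are rejected by name.  Every run writes a
`resolved_config.json` provenance record.  Exit codes: usage 2, config 3,
I/O 4, shape 5.

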