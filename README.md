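# mdunet

Lightweight tokenized-MLP U-Net (MD-UNet) for binary segmentation of
tumor-cell nuclei in H&E histology tiles and skin lesions in dermoscopy
images — built, trained and profiled entirely in R.

Medical segmentation models are usually too heavy for embedded or
real-time use. MD-UNet addresses this with a five-level encoder–decoder in
which every conv–BN–ReLU stack is replaced by a **Token-MLP block** (a 3×3
tokenizing projection followed by a residual shifted-MLP with a depthwise
3×3 positional encoding), skip connections are gated by a **depthwise
attention (DA)** block computing `x̂ = x_l · α · g` with
`α = σ(W₃ · ReLU(W_x,3 W_x,1 x_l + W_g,3 W_g,1 g + b))`, and the decoder
carries a **multi-branch feature-extraction (MFE)** module combining
asymmetric 1×3·3×1 and 1×5·5×1 convolutions, squeeze-and-excitation, and
two sigmoid spatial gates multiplied back onto the input. The reference
model has 0.72 M trainable parameters and a 0.212 GFLOP forward pass at
3×256×256 (one multiply-accumulate counted as one FLOP).

Training minimizes BCE + Dice loss, `DL = 1 − (2Σyŷ+1)/(Σy+Σŷ+1)`, with
Adam (β₁ = 0.9) and a cosine-annealed learning rate (1e-3 → 1e-5, batch
32, ≤500 epochs). Evaluation reports `IoU = TP/(TP+FN+FP)` and
`Dice = 2TP/(2TP+FN+FP)` per image and aggregated.

The package includes a synthetic generator of nuclei/lesion image–mask
pairs (circular, elliptical and filamentous nuclei; lesions with hair-like
occluders), so everything is testable without external data. Forward and
backward passes run on a small reverse-mode tape with compiled
(RcppArmadillo) convolution, layer-norm and resampling kernels.

## Worked example

```r
library(mdunet)

cfg <- model_config()               # calibrated reference configuration
model <- build_model(cfg, seed = 1)
print(complexity_report(model))

samples <- generate_samples(synthetic_config("nuclei", seed = 1L), 10)
sp <- split_dataset(samples, split_spec(seed = 1))
tc <- train_config(batch_size = 4L, seed = 1L)
r <- train_loop(model, sp$train, sp$val, tc, epochs = 40)
tail(r$history, 3)
evaluate(r$model, sp$test)
```

Output:

```
Params: 0.72 M   FLOPs: 0.212 G  (1 multiply-accumulate = 1 FLOP; elementwise ops counted once per element)
  dec5             443972 params     24346688 flops
  enc5             102680 params     26390528 flops
  ...
  head                  6 params       458752 flops

   epoch           lr train_loss   val_iou  val_dice
38    38 0.0009866838 0.05163666 0.9030313 0.9490452
39    39 0.0009859577 0.04442929 0.9150863 0.9556606
40    40 0.0009852127 0.04136735 0.9195929 0.9581124

IoU 0.9304  Dice 0.9640  (mean over 1 images)
```

The complexity report lists parameters and per-layer FLOPs of the analytic
profiler (the runtime tape meters the identical convention, and the tests
cross-check the two). The history shows the cosine-annealed learning rate,
the BCE+Dice training loss, and validation IoU/Dice per epoch; the final
line is the held-out test score after 40 epochs on 8 synthetic training
images — the model fits the synthetic nuclei domain almost perfectly at
this size.

Ablation variants reproduce the published complexity table:

```r
sapply(c("baseline", "baseline_da", "baseline_mfe", "full"), function(v) {
  m <- build_variant(v)
  c(params_M = round(count_parameters(m), 2), gflops = round(count_flops(m), 3))
})
#>          baseline baseline_da baseline_mfe  full
#> params_M     0.23        0.65         0.30  0.72
#> gflops       0.115       0.135        0.193 0.212
```

A command-line interface wrapping the same functions is installed at
`cli/mdunet` inside the package (`generate`, `info`, `train`, `eval`,
`heatmap` subcommands).

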