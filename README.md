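# polypvit

Colon-polyp segmentation with an adaptive deformable convolutional
feature extractor, conditional positional encoding, and a transformer
encoder–decoder with per-class query tokens — implemented from first
principles in R (forward *and* backward passes; no external deep-learning
runtime), together with the training regime, a segmentation metric suite
with a k-fold cross-validation harness, a seeded generator of
colonoscopy-like images with exact binary masks, paired image/mask dataset
I/O (PNG, TIFF, optional JPEG), and a command-line entry point.

## Who this is for

Researchers in biomedical image analysis who want a small, fully
inspectable reference implementation of this architecture family —
every equation is an ordinary R function with a unit test against a
brute-force oracle — and a pipeline that is trainable and testable on a
single CPU with no external downloads, via the built-in synthetic
colonoscopy-like data generator.

## The model

An RGB frame `I` (resized to 256×256; 64×64 in the desk profile) passes
through five stages:

1. **Adaptive deformable feature extraction (ADCN).** Four residual
   blocks. In each, a spatial attention map
   `phi = normalize(mean_channels |activations|)` (nonnegative, sum 1)
   drives the block's final convolution twice over:
   - *kernel modulation*: each tap's coefficient is generated from a
     trainable table contracted against phi,
     `k_ij = sum_mn k_ij^mn phi_mn`, then averaged over the map extent
     `k̄_ij = k_ij / (H·W)`;
   - *offsets*: sampling positions are displaced by
     `u_i = ½ sum_mn phi_mn (m − i)` (rows) and `v_j` likewise (columns),
     pulling the sampling grid toward the attention centroid. Fractional
     positions are read with bilinear interpolation.
2. **Conditional positional encoding (CPE).** The feature cells become
   tokens; a depthwise 3×3 convolution over the token grid (the position
   encoding generator, PEG) produces embeddings `e_i` *from the content*,
   which are added to the tokens.
3. **Encoder.** Four pre-norm transformer blocks:
   `Z1 = MHSA(LN(x)) + x`, `Z2 = MLP(LN(Z1)) + Z1`
   (`AS = softmax(QKᵀ/√d_k)V` per head, GELU MLP of width 4d).
4. **Decoder.** Two learnable query tokens `T = {T_background, T_polyp}`:
   `Z3 = MHSA(LN(T))` (deliberately without a residual), `Z4 = MHCA(LN(Z3), F) + Z3`,
   `Z5 = MLP(LN(Z4)) + Z4`; the rows of `Z5` are the query embeddings `qe`.
5. **Mask.** Per-patch class logits `⟨f_i, qe_c⟩` are laid on the token
   grid, bilinearly upsampled, and argmaxed (ties → background).

Training minimises per-pixel cross-entropy with Adam
(`lr0 = 0.001`, multiplied by 0.01 every 20 epochs), optional channel
dropout at the encoder or decoder output, and best-validation-Dice
checkpointing. Evaluation reports accuracy, sensitivity, specificity,
precision, Dice `2|M∩G|/(|M|+|G|)`, IoU `|M∩G|/|M∪G|` and
ground-truth-weighted IoU, as per-fold values and mean ± population sd.

## Worked example

```r
library(polypvit)

cfg   <- synthetic_config(image_size = 64)
train_set <- generate_dataset(200, cfg, seed = 101)
val_set   <- generate_dataset(50,  cfg, seed = 202)

model <- build_model(tiny_arch(), ablation = "full", seed = 11)
fit   <- train(model, train_set, val_set,
               train_config(epochs = 8, batch_size = 4,
                            dropout_site = "none", seed = 11))
tail(fit$history, 3)
```

```
  epoch    lr train_loss   val_loss  val_dice
6     5 0.001 0.05886265 0.05553492 0.9116502
7     6 0.001 0.05729457 0.05631651 0.9142576
8     7 0.001 0.05327664 0.05349207 0.9171016
```

The training loss falls from 0.372 (epoch 0) to 0.053, and the held-out
Dice — mean overlap between predicted and true polyp masks over the 50
validation frames — reaches **0.917**: on this synthetic world the model
recovers polyp boundaries almost exactly. Scoring a prediction by hand:

```r
mask <- predict_mask(fit$model, val_set[[1]]$image)
round(metrics_record(mask, val_set[[1]]$mask), 4)
#     accuracy  sensitivity  specificity    precision weighted_iou         dice
#       0.9570       0.9735       0.9521       0.8587       0.9203       0.9125
```

The first validation frame holds a large polyp covering 23 % of the
frame: 97 % of its polyp pixels are recovered (sensitivity) at
86 % precision, giving Dice 0.91. All values are reproducible from the
seeds above. The same run from the shell:

```sh
Rscript inst/cli/polypvit synth --seed 11 --out data  --set synth.n=200
Rscript inst/cli/polypvit train --seed 11 --out run   --set data.root=data
Rscript inst/cli/polypvit predict --out pred \
    --set predict.checkpoint=run/checkpoint.rds --set predict.images=data/images
```

Each command writes a `manifest.json` (resolved config, seed, outputs,
version) that reproduces the run bit-for-bit.

## Layout

- `R/synthetic.R` — seeded colonoscopy-like image/mask generator
- `R/data-io.R`, `R/image-io.R` — paired datasets, resize/augment/split,
  built-in PNG + TIFF codecs
- `R/adcn.R`, `R/nn-fast.R`, `src/` — deformable convolution (scalar C++
  reference kernels and the BLAS-backed training path)
- `R/cpe.R`, `R/transformer.R` — PEG, encoder, decoder, mask head
- `R/model.R`, `R/training.R` — assembly, Adam loop, checkpoints
- `R/evaluation.R` — metrics and k-fold cross-validation
- `R/cli.R`, `inst/cli/polypvit` — command-line entry point
- `vignettes/polypvit-methods.Rmd` — the methods vignette
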