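---
title: "polypvit: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polypvit: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open and a decision had to
be made. It states no empirical result that the test suite does not
itself compute.

## The problem

Colonoscopy frames show polyps — protrusions of the colonic mucosa with
heterogeneous shape, size, colour and texture, often with ill-defined
boundaries against the colonic wall, under specular highlights and uneven
illumination. The task is per-pixel binary segmentation: label each pixel
polyp or background. Plain convolutional feature extractors use fixed
sampling grids and fixed kernels, which adapt poorly to this morphological
diversity; the architecture implemented here makes both the kernel
coefficients and the sampling positions functions of a spatial attention
map computed from the image itself, and feeds the resulting features to a
transformer encoder–decoder that scores two class query tokens against
every patch.

## The model, stage by stage

**Attention map.** For each residual block, `phi` is the channel-wise
mean of absolute activations, normalised to sum to one
(`compute_attention_map()`). All-zero activations fall back to the
uniform map rather than erroring. The map is anchored to the block's
final convolutional activations; how those are reduced to a single
spatial map is an implementation decision, and the mean absolute
activation is the least-structured nonnegative reduction.

**Kernel modulation and averaging.** Each tap `(i, j)` of the deformable
kernel owns a trainable coefficient table `k_ij^{mn}` over the attention
map extent; the operative coefficient is the phi-weighted sum averaged
over the extent, `k̄_ij = (1/(H·W)) Σ_mn k_ij^{mn} φ_mn`
(`modulate_kernel()`, `average_kernel()`). The averaging step is
defined here as the modulation summed over every map position and divided
by the map extent `H·W` — the reading this package commits to, documents,
and unit-tests against direct summation.

**Offsets.** `u_i = ½ Σ_mn φ_mn (m − i)` over 0-based indices, and `v_j`
likewise: for a normalised map, half the distance from kernel index `i`
to the attention centroid. Offsets are shared per kernel row/column index
— *not* per 2-D tap as in standard deformable convolution — a deliberate
fidelity choice (`compute_offsets()`).

**Deformable convolution.** Sampling comes in two modes. Default
`base_grid` includes the conventional `(i − c_r, j − c_c)` grid term so
that zero offsets reduce exactly to ordinary cross-correlation (verified
against a brute-force oracle); `mode = "literal"` drops the grid term, so
each kernel index samples a single offset point. Both modes resolve
fractional coordinates by bilinear interpolation and read zero outside
the frame — the standard choices where a convention had to be picked.

**Attention extent in the backbone.** The formulas tie the coefficient
tables and offsets to the attention map extent, but a feature-grid-sized
map would give per-tap tables of the feature-grid size and offsets of up
to half the image — sampling positions would leave the frame. In the
backbone the block's map is therefore *sum-pooled* (mass-preserving, so
it still sums to one) onto the kernel extent (3×3 by default) before
driving modulation and offsets. This bounds offsets by about one pixel,
keeps the coefficient tables small, and respects the premise that the
attention map is centred on the target region: the pooled map retains the
centroid. The pooling is differentiable and gradients flow through it.

**Initialisation.** The natural "cover everything uniformly" start — an
all-ones coefficient table — is channel-permutation-symmetric: every
output channel would compute the same function forever, so gradient
training could never separate them. The standalone operations accept any
table (including all-ones); `build_model()` initialises tables He-scaled,
with
a `(MN)^{3/2}` factor compensating the contraction-plus-averaging
attenuation so the *effective* averaged kernel starts at He scale.

**CPE.** Tokens are the feature cells (patch size 1 by default; the
general patchify/unpatchify pair is provided and round-trip tested). The
position encoding generator is a depthwise 3×3 zero-padded convolution
over the token grid — the reference design for conditional positional
encoding (the kernel size is a free choice). The combine mode is additive
by default: the encoder operates at a fixed model dimension, which
addition preserves; concatenation-plus-projection is available as
`concat_project` for users who prefer dimension-expanding attachment.
The PEG runs once, before the first encoder block: positional encoding
precedes feature abstraction in the pipeline.

**Encoder.** Four pre-norm blocks by default (d = 512·(patch size)²,
8 heads, MLP ratio 4 at full scale). Layer normalisation is
`γ(v − μ)/(σ + ε) + β` with the population standard deviation and the
stabiliser *added to* σ (not inside a square root); ε defaults to 1e-5
and the layer-norm backward guards σ = 0. Attention is
`softmax(QKᵀ/√d_k)V` per head; the output projection `W^O` after head
concatenation (required for multi-head composition) is zero-initialisable
so the pass-through unit tests can silence a block exactly.

**Decoder.** One block by default: query self-attention *without* a
residual connection — a deliberate asymmetry of this design, covered by a
unit test asserting `Z3 = 0` under zeroed projections, with the
conventional residual available via `decode(self_residual = TRUE)` — then
cross-attention (queries from `Z3`, keys/values from the encoder
features) with a residual, then the MLP with a residual. The mask product
is realised as the inner product of each patch feature with each class
query embedding: the only composition that produces a two-class score per
patch from `n×d` features and `2×d` embeddings. The logit grid is
bilinearly upsampled to the output size and ties are broken toward
background — conservative for a screening tool.

## Training

The loss is the standard per-pixel negative log-likelihood of the true
class, clamped at 1e-12 (`cross_entropy_loss()`). A sign-free sum of
log-probabilities over both classes is sometimes written down for this
objective, but it is not trainable — it rewards confidence regardless of
correctness — so the negative log-likelihood reading is the one
implemented.

Adam starts at `lr0 = 0.001` and the rate is multiplied by
`decay_factor` (default 0.01) every `decay_period` (default 20) epochs
(`lr_at_epoch()`). The default decay is aggressive — it effectively
freezes training after epoch 40 — which is why the factor is a config
field (`decay_factor = 0.99` encodes the milder reduce-by-1 % schedule).
Channel dropout (inverted, survivors scaled by 1/(1−p)) can be placed at
the encoder or decoder output; tying the dropout probability to the
variance of the query tokens is a plausible refinement with no canonical
formula, so the probability is a plain config field, off by default
(`dropout_site = "none"`), which also makes training bit-reproducible
under a fixed seed.

The coupled kernel-update rule (the phi-gradient-product weight delta) is
implemented verbatim as a standalone, oracle-tested operation
(`literal_kernel_update()`): its update direction is unrelated to the
loss, so default training differentiates the full forward pass end to end
instead (hand-written reverse-mode through every stage, including the
attention map, pooling, modulation, offsets and bilinear sampling);
setting `literal_kernel_updates = TRUE` replaces the loss gradient of the
coefficient tables with the literal rule, stepped by the current learning
rate. Gradient correctness is asserted against central differences in
the test suite.

The full profile defaults to 100 epochs at batch 8; the desk profile
(64×64, d = 32, 4 heads, depth 2, output stride 4) uses 8 epochs at batch
4. Best validation Dice selects the retained checkpoint, in lieu of an
early-stopping rule. The ± figures reported by the cross-validation
harness are fold-wise mean ± *population* standard deviation; per-image
metrics are averaged within folds (image-averaged, the common convention;
pixel-pooled averaging is the alternative).

## The synthetic world

The generator (`synthetic_config()`, defaults in parentheses) emulates:
one to three (1–3) bright, reddish protrusions per 256² frame, radius
8–25 % of the frame side, with smooth irregular boundaries — ellipses
with a radial Fourier perturbation `r(θ) = r₀(1 + Σ a_k sin(kθ + φ_k))`,
4 harmonics of total amplitude 15 % — on a darker textured mucosa-like
background (low-frequency multiplicative shading plus Gaussian pixel
noise, sd 0.03), with 3 specular highlight blobs and radial vignetting
(strength 0.35), and an *exact* binary mask untouched by the photometric
effects. Colours (polyp ≈ (0.78, 0.48, 0.40), background ≈ (0.55, 0.30,
0.25)) and all other defaults are plausible stand-ins for colonoscopy
frames, chosen once and not revisited. One master seed
drives counter-derived per-image streams, so item k is bit-identical
regardless of how many items are generated.

What the generator does **not** emulate: real mucosal texture and vessel
patterns, instrument artefacts, motion blur, interlacing, video
redundancy, sessile-vs-pedunculated morphology, or ambiguous boundaries.
A green end-to-end test therefore establishes that the architecture,
gradients, optimiser and metrics interoperate and can fit a plausible
segmentation task on CPU — not that the published real-data accuracy is
reproduced. Consistent with that, on this easy synthetic world the
ablated comparison model (plain residual blocks plus learned absolute
positional embeddings) reaches held-out Dice within noise of the full
model; ablation gaps reported for this architecture family on real data
at full scale are much larger, so the desk-scale test reports both values
without asserting a margin.

## Numerical and I/O choices

* Coordinates are row-major, 0-based at the codec/warp level, origin
  top-left; affine transforms act on (row, col) about the image centre,
  with a 90° rotation mapping (r, c) to (c, N−1−r).
* Mask binarisation threshold is 128 on the 8-bit scale (masks are
  nominally {0, 255}, but compression-adjacent artefacts occur; the
  midpoint is the least surprising rule). Nearest-neighbour mask
  resampling creates no new values, so preprocessing is idempotent at the
  target size.
* Bilinear resizing uses half-pixel centres with edge clamping; the
  deformable sampler uses zero padding (the two ops have different
  conventions on purpose: resizing extends the image, sampling beyond the
  frame reads nothing).
* The package ships its own PNG (zlib via base R, CRC32 in C++) and
  uncompressed-TIFF codecs so dataset round trips have no external
  imaging dependency; they are cross-validated against Pillow in the test
  suite. JPEG is delegated to the optional 'jpeg' package.
* The training path evaluates convolutions as BLAS matrix products
  against tap-stacked shifted sample planes (possible because offsets are
  shared per kernel index); the scalar C++ kernels remain as the
  reference implementation, and the two are asserted equal to 1e-10 in
  the tests.

## Known limitations

* Per-tap 2-D offset fields (standard deformable convolution) and
  modulated scalar variants are out of scope by design.
* Exact ResNet-50 replication is not attempted: blocks are
  conv–deformable-conv residual pairs with projection shortcuts; widths
  and strides are configurable.
* Single-image processing (no batched tensors); CPU only.
* Multi-class (> 2) segmentation is not supported — the decoder carries
  exactly the two printed query tokens.
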