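# Model assembly: deformable residual backbone -> token grid -> conditional
# positional encoding -> transformer encoder -> query-token decoder -> mask.
# Two variants are built from one architecture description: the full model,
# and the ablated comparison pair (plain residual blocks, learned absolute
# positional embeddings in place of the PEG, identical encoder/decoder).

#' Architecture hyperparameters
#'
#' Defaults describe the full-scale network: 256x256 inputs, four residual
#' blocks of widths 64/128/256/512 with stride-2 transitions (output stride
#' 16, a 16x16 token grid, d = 512 tokens of model dimension 256 after the
#' final width), 3x3 kernels modulated by a 3x3 pooled attention map, and a
#' 4-block, 8-head encoder.
#'
#' @param image_size working input side in pixels.
#' @param widths channel widths of the four residual blocks; the last width
#'   is the transformer model dimension `d`.
#' @param strides per-block downsampling factors.
#' @param kernel_size spatial extent of the deformable kernels.
#' @param att_extent side of the pooled attention map driving modulation and
#'   offsets.
#' @param heads attention head count (`d` divisible by `heads`).
#' @param depth encoder block count.
#' @param mlp_ratio MLP hidden width as a multiple of `d`.
#' @param patch_size token patch size on the feature grid.
#' @return object of class `polypvit_arch`.
#' @export
polypvit_arch <- function(image_size = 256L, widths = c(64L, 128L, 256L, 512L),
                          strides = c(2L, 2L, 2L, 2L), kernel_size = 3L,
                          att_extent = 3L, heads = 8L, depth = 4L,
                          mlp_ratio = 4L, patch_size = 1L) {
  d <- widths[length(widths)] * patch_size^2
  assert_that(d %% heads == 0, "model dimension %d not divisible by %d heads",
              d, heads)
  grid <- image_size / prod(strides) / patch_size
  assert_that(grid == floor(grid) && grid >= 1,
              "image_size %d incompatible with strides/patch size", image_size)
  structure(list(image_size = as.integer(image_size),
                 widths = as.integer(widths), strides = as.integer(strides),
                 kernel_size = as.integer(kernel_size),
                 att_extent = as.integer(att_extent), heads = as.integer(heads),
                 depth = as.integer(depth), mlp_ratio = as.integer(mlp_ratio),
                 patch_size = as.integer(patch_size), d = as.integer(d),
                 grid = as.integer(grid), deformable = TRUE),
            class = "polypvit_arch")
}

#' Desk-scale architecture for CPU experiments and tests
#'
#' 64x64 inputs, widths 16/32/32/32 (d = 32), output stride 4 (16x16 token
#' grid), 4 heads, encoder depth 2.
#'
#' @param ... overrides forwarded to [polypvit_arch()].
#' @return object of class `polypvit_arch`.
#' @export
tiny_arch <- function(...) {
  args <- modifyList(list(image_size = 64L, widths = c(16L, 32L, 32L, 32L),
                          strides = c(2L, 2L, 1L, 1L), heads = 4L, depth = 2L),
                     list(...))
  do.call(polypvit_arch, args)
}

#' Build a model (full or ablated) with seeded initialisation
#'
#' `ablation = "full"` builds the deformable backbone plus PEG; `ablation =
#' "resnet_only"` builds plain residual blocks and a learned absolute
#' positional embedding table, with an identical encoder/decoder -- the
#' ablation comparison pair.
#'
#' @param arch a [polypvit_arch()].
#' @param ablation `"full"` or `"resnet_only"`.
#' @param seed integer seed; identical `(arch, ablation, seed)` give
#'   bit-identical parameters.
#' @return object of class `polypvit_model`.
#' @export
build_model <- function(arch = polypvit_arch(), ablation = c("full", "resnet_only"),
                        seed = 1L) {
  ablation <- match.arg(ablation)
  arch$deformable <- ablation == "full"
  n_tokens <- arch$grid^2
  params <- with_seed(seed, {
    p <- list(backbone = init_backbone(arch))
    if (ablation == "full") {
      p$peg <- init_peg(arch$d)
    } else {
      p$pos_embed <- matrix(rnorm(n_tokens * arch$d, sd = 0.02), n_tokens, arch$d)
    }
    p$encoder <- replicate(arch$depth,
                           init_encoder_block(arch$d, arch$heads, arch$mlp_ratio),
                           simplify = FALSE)
    p$queries <- matrix(rnorm(2 * arch$d, sd = 0.02), 2, arch$d)
    p$decoder <- init_decoder(arch$d, arch$heads, arch$mlp_ratio)
    p
  })
  structure(list(arch = arch, ablation = ablation, seed = as.integer(seed),
                 params = params,
                 backbone = list(arch = arch, blocks = params$backbone)),
            class = "polypvit_model")
}

#' @export
print.polypvit_model <- function(x, ...) {
  n_par <- sum(vapply(nested_leaves(x$params), length, 0L))
  cat(sprintf("<polypvit_model %s, %dx%d input, d=%d, %s parameters>\n",
              x$ablation, x$arch$image_size, x$arch$image_size, x$arch$d,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# Full forward pass.  `dropout` is NULL or list(p=, site=) and is only
# active when train = TRUE; dropout masks are drawn from the current RNG.
model_forward <- function(model, image, train = FALSE, dropout = NULL,
                          keep_cache = FALSE) {
  arch <- model$arch
  pr <- model$params
  bf <- backbone_forward(image, pr$backbone, arch, ablation = FALSE,
                         keep_cache = keep_cache)
  feat <- bf$out
  gs <- c(arch$grid, arch$grid)
  tokens <- grid_to_tokens(feat)
  if (model$ablation == "full") {
    grid_in <- feat
    e_grid <- depthwise_conv_grid(grid_in, pr$peg)
    tokens2 <- tokens + grid_to_tokens(e_grid)
  } else {
    tokens2 <- tokens + pr$pos_embed
  }
  X <- tokens2
  enc_caches <- if (keep_cache) vector("list", arch$depth) else NULL
  for (b in seq_along(pr$encoder)) {
    fb <- encoder_block_forward(X, pr$encoder[[b]], arch$heads)
    X <- fb$out
    if (keep_cache) enc_caches[[b]] <- fb$cache
  }
  drop_enc <- NULL
  if (train && !is.null(dropout) && dropout$site == "encoder_out" && dropout$p > 0) {
    X <- channel_dropout(X, dropout$p, training = TRUE)
    drop_enc <- attr(X, "mask")
    attr(X, "mask") <- NULL
  }
  Fmat <- X
  dec <- decoder_forward(Fmat, pr$queries, pr$decoder, arch$heads)
  qe <- dec$qe
  drop_dec <- NULL
  if (train && !is.null(dropout) && dropout$site == "decoder_out" && dropout$p > 0) {
    qe <- channel_dropout(qe, dropout$p, training = TRUE)
    drop_dec <- attr(qe, "mask")
    attr(qe, "mask") <- NULL
  }
  logits <- Fmat %*% t(qe)
  lgrid <- tokens_to_grid(logits, gs)
  up <- cpp_resize_bilinear(lgrid, arch$image_size, arch$image_size)
  prob <- softmax_pixelwise(up)
  labels <- matrix(as.double(up[, , 2] > up[, , 1]),
                   arch$image_size, arch$image_size)
  list(labels = labels, prob = prob, logits_up = up, logits_grid = lgrid,
       features = Fmat, qe = qe, decoder = dec,
       cache = if (keep_cache)
         list(bf = bf, feat = feat, tokens = tokens, enc = enc_caches,
              Fmat = Fmat, dec_cache = dec$cache, qe = qe, gs = gs,
              drop_enc = drop_enc, drop_dec = drop_dec) else NULL)
}

softmax_pixelwise <- function(logits_hwc) {
  m <- pmax(logits_hwc[, , 1], logits_hwc[, , 2])
  e1 <- exp(logits_hwc[, , 1] - m)
  e2 <- exp(logits_hwc[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim = dim(logits_hwc))
}

# Backward pass from the gradient of the loss w.r.t. the upsampled logits.
model_backward <- function(model, fwd, g_logits_up) {
  arch <- model$arch
  pr <- model$params
  cc <- fwd$cache
  gs <- cc$gs
  g_grid <- cpp_resize_bilinear_backward(g_logits_up, gs[1], gs[2])
  g_logits <- grid_to_tokens(g_grid)                    # n x 2
  gF <- g_logits %*% cc$qe                              # from mask product
  gqe <- crossprod(g_logits, cc$Fmat)                   # 2 x d
  if (!is.null(cc$drop_dec)) gqe <- gqe * cc$drop_dec
  db <- decoder_backward(gqe, cc$dec_cache, pr$decoder)
  gF <- gF + db$gF
  if (!is.null(cc$drop_enc)) gF <- gF * cc$drop_enc
  g_enc <- vector("list", length(pr$encoder))
  gX <- gF
  for (b in rev(seq_along(pr$encoder))) {
    eb <- encoder_block_backward(gX, cc$enc[[b]], pr$encoder[[b]])
    g_enc[[b]] <- eb$grads
    gX <- eb$gX
  }
  grads <- list()
  if (model$ablation == "full") {
    g_egrid <- tokens_to_grid(gX, gs)
    dwb <- depthwise_conv_grid_backward(cc$feat, pr$peg, g_egrid)
    grads$peg <- dwb$kernel
    g_feat <- dwb$input + tokens_to_grid(gX, gs)  # PEG path + identity path
  } else {
    grads$pos_embed <- gX
    g_feat <- tokens_to_grid(gX, gs)
  }
  bb <- backbone_backward(g_feat, cc$bf$caches, pr$backbone, arch)
  grads$backbone <- bb$grads
  grads$encoder <- g_enc
  grads$queries <- db$gT
  grads$decoder <- db$grads
  grads[names(model$params)]
}

#' Predict a segmentation mask for one image
#'
#' @param model a [build_model()] (or trained) model.
#' @param image `HxWx3` array at the model's working size (anything else is
#'   resized first).
#' @return `HxW` matrix in {0,1} at the working size.
#' @export
predict_mask <- function(model, image) {
  n <- model$arch$image_size
  if (is.matrix(image)) image <- array(rep(image, 3), dim = c(dim(image), 3L))
  if (!all(dim(image)[1:2] == n)) image <- cpp_resize_bilinear(image, n, n)
  model_forward(model, image)$labels
}

#' Save a model checkpoint
#'
#' The checkpoint holds the parameters, architecture, seed and any extra
#' metadata (fold id, history); loading reproduces forward outputs
#' bit-for-bit.
#'
#' @param model a `polypvit_model`.
#' @param path output file.
#' @param extra named list of metadata stored alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(model = model, extra = extra, format = 1L), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return the `polypvit_model`, with the stored metadata attached as
#'   attribute `extra`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_data("checkpoint not found: %s", path)
  ck <- readRDS(path)
  structure(ck$model, extra = ck$extra)
}

#' Write an array as an NPY file
#'
#' Minimal NPY (format 1.0) writer for dense float64 arrays, used to export
#' feature maps, attention maps and offset fields for external inspection.
#'
#' @param arr numeric array, matrix or vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(arr, path) {
  dims <- dim(arr) %||% length(arr)
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1) "," else "", ")")
  hdr <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }", shape)
  total <- 10L + nchar(hdr) + 1L
  pad <- (64L - total %% 64L) %% 64L
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2L, endian = "little")
  writeBin(charToRaw(hdr), con)
  writeBin(as.double(arr), con, size = 8L, endian = "little")
  invisible(path)
}

#' Export an attention map (or any nonnegative field) as a PNG heatmap
#'
#' @param phi matrix (e.g. an [compute_attention_map()] result).
#' @param path output PNG path.
#' @param upscale integer nearest-neighbour upscale factor for small grids.
#' @return `path`, invisibly.
#' @export
export_attention_png <- function(phi, path, upscale = 1L) {
  m <- unclass(phi)
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  if (upscale > 1) {
    m3 <- cpp_resize_nearest(array(m, dim = c(dim(m), 1L)),
                             nrow(m) * upscale, ncol(m) * upscale)
    m <- matrix(m3, nrow(m) * upscale, ncol(m) * upscale)
  }
  write_png(m, path)
}
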