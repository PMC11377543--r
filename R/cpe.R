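# Conditional positional encoding: tokens are cut from the backbone feature
# map, and their positional embeddings are *generated from the token content*
# by a small convolution over the token grid (the position encoding
# generator, PEG) instead of being looked up in a fixed table.  Because the
# generator is convolutional, the embeddings translate with the content.

#' Cut a feature map into non-overlapping patch tokens
#'
#' Tokens are ordered row-major over the patch grid; each token is the
#' flattened `p x p x C` block (column-major over row, col, channel).
#'
#' @param features `H'xW'xC` feature array (grid divisible by `p`).
#' @param p patch size (default 1: one token per feature cell).
#' @return `n x d` matrix of class `patch_sequence` with attributes
#'   `grid_shape`, `patch_size`, `channels`.
#' @export
patchify <- function(features, p = 1L) {
  if (is.matrix(features)) dim(features) <- c(dim(features), 1L)
  d <- dim(features)
  if (d[1] %% p != 0 || d[2] %% p != 0)
    stop_config("feature grid %dx%d not divisible by patch size %d", d[1], d[2], p)
  gr <- d[1] %/% p; gc <- d[2] %/% p
  n <- gr * gc
  dd <- p * p * d[3]
  tok <- matrix(0, n, dd)
  for (a in seq_len(gr))
    for (b in seq_len(gc)) {
      block <- features[((a - 1) * p + 1):(a * p), ((b - 1) * p + 1):(b * p), , drop = FALSE]
      tok[(a - 1) * gc + b, ] <- as.vector(block)
    }
  structure(tok, grid_shape = c(gr, gc), patch_size = as.integer(p),
            channels = d[3], class = c("patch_sequence", "matrix", "array"))
}

#' Reassemble patch tokens into their feature map
#'
#' Inverse of [patchify()] (exact round trip).
#'
#' @param tokens a [patchify()] result (or `n x d` matrix with the same
#'   attributes supplied explicitly).
#' @param grid_shape,p,channels layout, taken from attributes when missing.
#' @return `H'xW'xC` array.
#' @export
unpatchify <- function(tokens, grid_shape = attr(tokens, "grid_shape"),
                       p = attr(tokens, "patch_size"),
                       channels = attr(tokens, "channels")) {
  gr <- grid_shape[1]; gc <- grid_shape[2]
  out <- array(0, dim = c(gr * p, gc * p, channels))
  for (a in seq_len(gr))
    for (b in seq_len(gc)) {
      block <- array(tokens[(a - 1) * gc + b, ], dim = c(p, p, channels))
      out[((a - 1) * p + 1):(a * p), ((b - 1) * p + 1):(b * p), ] <- block
    }
  out
}

init_peg <- function(d, k = 3L) he_init(c(k, k, d), k * k)

# Depthwise convolution over the token grid, zero padded, channel by channel.
depthwise_conv_grid <- function(grid, kernel) {
  d <- dim(grid)[3]
  out <- array(0, dim = dim(grid))
  for (c in seq_len(d)) {
    w <- array(kernel[, , c], dim = c(dim(kernel)[1], dim(kernel)[2], 1L, 1L))
    out[, , c] <- cpp_conv2d_forward(grid[, , c, drop = FALSE], w, 0,
                                     1L, (dim(kernel)[1] - 1L) %/% 2L)
  }
  out
}

depthwise_conv_grid_backward <- function(grid, kernel, gout) {
  d <- dim(grid)[3]
  gg <- array(0, dim = dim(grid))
  gk <- array(0, dim = dim(kernel))
  for (c in seq_len(d)) {
    w <- array(kernel[, , c], dim = c(dim(kernel)[1], dim(kernel)[2], 1L, 1L))
    bw <- cpp_conv2d_backward(grid[, , c, drop = FALSE], w,
                              gout[, , c, drop = FALSE], 1L,
                              (dim(kernel)[1] - 1L) %/% 2L)
    gg[, , c] <- bw$input
    gk[, , c] <- bw$weight
  }
  list(input = gg, kernel = gk)
}

#' Generate conditional positional embeddings (PEG)
#'
#' Tokens are mapped back onto their 2-D grid, a depthwise `k x k`
#' convolution with zero padding is applied, and the result is flattened
#' back to one embedding per token.  Embeddings therefore depend on the
#' image content and translate with it.
#'
#' @param patches a [patchify()] result.
#' @param kernel depthwise generator weights, `k x k x d` (random
#'   He-initialised from the current RNG stream if `NULL`).
#' @return `n x d` matrix of embeddings with the generator kernel attached
#'   as attribute `generator_kernel`.
#' @export
peg_embed <- function(patches, kernel = NULL) {
  gs <- attr(patches, "grid_shape")
  stopifnot(!is.null(gs), nrow(patches) == prod(gs))
  d <- ncol(patches)
  if (is.null(kernel)) kernel <- init_peg(d)
  stopifnot(dim(kernel)[3] == d)
  grid <- tokens_to_grid(patches, gs)
  eg <- depthwise_conv_grid(grid, kernel)
  structure(grid_to_tokens(eg), generator_kernel = kernel)
}

# Token <-> grid reshapes for d-vector tokens (row-major token order).
tokens_to_grid <- function(tokens, gs) {
  arr <- array(t(tokens), dim = c(ncol(tokens), gs[2], gs[1]))
  aperm(arr, c(3, 2, 1))
}

grid_to_tokens <- function(grid) {
  gs <- dim(grid)[1:2]
  matrix(aperm(grid, c(3, 2, 1)), nrow = gs[1] * gs[2], byrow = TRUE)
}

#' Attach positional embeddings to tokens
#'
#' Default `add` mode preserves the model dimension (`token + embedding`);
#' `concat_project` concatenates and projects back to `d` with a learned
#' matrix.
#'
#' @param patches `n x d` token matrix.
#' @param emb `n x d` embedding matrix.
#' @param mode `"add"` or `"concat_project"`.
#' @param proj `2d x d` projection for `concat_project` (He-initialised from
#'   the current RNG stream if `NULL`).
#' @return `n x d` token matrix (attributes of `patches` preserved).
#' @export
attach_positions <- function(patches, emb, mode = c("add", "concat_project"),
                             proj = NULL) {
  mode <- match.arg(mode)
  if (!all(dim(patches) == dim(emb)))
    stop_config("token/embedding dimension mismatch")
  out <- if (mode == "add") unclass(patches) + unclass(emb)
  else {
    d <- ncol(patches)
    if (is.null(proj)) proj <- he_init(c(2L * d, d), 2L * d)
    cbind(unclass(patches), unclass(emb)) %*% proj
  }
  attributes(out)[c("grid_shape", "patch_size", "channels")] <-
    attributes(patches)[c("grid_shape", "patch_size", "channels")]
  out
}
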