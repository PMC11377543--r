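# Adaptive deformable convolution.
#
# A spatial attention map phi (nonnegative, summing to 1) is derived from the
# activations of each residual block.  It drives the block's final
# convolution twice over: the kernel coefficients are generated from
# trainable per-tap coefficient tables contracted against phi (modulation,
# then averaging over the map extent), and the sampling positions are
# displaced by offsets u_i (rows) and v_j (cols) computed as half the
# phi-weighted mean index distance, so the sampling grid is pulled toward
# the attention centroid.  Fractional positions are read with bilinear
# interpolation and out-of-frame samples read zero.

#' Derive the spatial attention map from block activations
#'
#' phi is the channel-wise mean of absolute activations normalised to sum 1.
#' All-zero activations fall back to the uniform map.
#'
#' @param features `HxWxC` activation array (or an `HxW` matrix).
#' @return `HxW` matrix of class `attention_map`, nonnegative, summing to 1.
#' @export
compute_attention_map <- function(features) {
  if (is.matrix(features)) dim(features) <- c(dim(features), 1L)
  stopifnot(length(dim(features)) == 3L, all(dim(features) > 0))
  d <- dim(features)
  m <- matrix(rowMeans(matrix(abs(features), d[1] * d[2], d[3])), d[1], d[2])
  s <- sum(m)
  phi <- if (s > 0) m / s else matrix(1 / length(m), nrow(m), ncol(m))
  structure(phi, class = c("attention_map", class(phi)))
}

phi_matrix <- function(phi) {
  m <- unclass(phi)
  stopifnot(is.matrix(m), all(m >= -1e-12))
  m
}

# Contract coefficient tables against phi over the trailing (M, N) dims.
contract_phi <- function(kernel, phi) {
  p <- phi_matrix(phi)
  if (is.matrix(kernel)) {
    if (!all(dim(kernel) == dim(p)))
      stop_config("kernel extent %s does not match attention map extent %s",
                  paste(dim(kernel), collapse = "x"),
                  paste(dim(p), collapse = "x"))
    return(sum(kernel * p))
  }
  d <- dim(kernel)
  nd <- length(d)
  if (!all(d[(nd - 1):nd] == dim(p)))
    stop_config("kernel trailing extent does not match attention map extent")
  lead <- d[seq_len(nd - 2)]
  km <- matrix(kernel, nrow = prod(lead), ncol = prod(dim(p)))
  out <- km %*% as.vector(p)
  if (length(lead) == 1) as.vector(out) else array(out, dim = lead)
}

#' Modulate kernel coefficients by the attention map
#'
#' Each coefficient table `k^{mn}` (trailing dims matching the map extent) is
#' contracted against phi: `k = sum_mn k^{mn} phi_mn`.
#'
#' @param kernel an `MxN` matrix (one coefficient table) or an array whose
#'   trailing two dims are the map extent.
#' @param phi an [compute_attention_map()] result (or any `MxN` map).
#' @return scalar, or array over the leading dims of `kernel`.
#' @export
modulate_kernel <- function(kernel, phi) contract_phi(kernel, phi)

#' Average the modulated kernel over the attention map extent
#'
#' The modulation of [modulate_kernel()] divided by `H * W`, the height and
#' width of the attention map.
#'
#' @inheritParams modulate_kernel
#' @return scalar, or array over the leading dims of `kernel`.
#' @export
average_kernel <- function(kernel, phi) {
  p <- phi_matrix(phi)
  contract_phi(kernel, phi) / (nrow(p) * ncol(p))
}

#' Sampling offsets from the attention map
#'
#' `u_i = 1/2 sum_mn phi_mn (m - i)` over 0-based indices (and `v_j`
#' likewise over columns): for a normalised map each offset is half the
#' distance from kernel index to the attention centroid, pulling samples
#' toward the attended region.
#'
#' @param phi attention map (`MxN`, normalised).
#' @param kernel_extent `c(rows, cols)` of the sampling kernel.
#' @return object of class `offset_field`: list with numeric `u` (length
#'   rows) and `v` (length cols), in pixels.
#' @export
compute_offsets <- function(phi, kernel_extent) {
  p <- phi_matrix(phi)
  m0 <- matrix(seq_len(nrow(p)) - 1, nrow(p), ncol(p))
  n0 <- matrix(seq_len(ncol(p)) - 1, nrow(p), ncol(p), byrow = TRUE)
  total <- sum(p)
  mm <- sum(p * m0); nn <- sum(p * n0)
  u <- 0.5 * (mm - (seq_len(kernel_extent[1]) - 1) * total)
  v <- 0.5 * (nn - (seq_len(kernel_extent[2]) - 1) * total)
  structure(list(u = u, v = v), class = "offset_field")
}

#' Deformable convolution with attention-generated kernel and offsets
#'
#' In `base_grid` mode (default) the sample for kernel tap `(i, j)` at output
#' `(x, y)` is read at `(x + (i - c_r) + u_i, y + (j - c_c) + v_j)` with `c`
#' the kernel center, so zero offsets recover ordinary cross-correlation.
#' `literal` mode drops the base grid term and samples at `(x + u_i, y +
#' v_j)` exactly as the printed modulation sum.  Stride 1; zero padding;
#' bilinear interpolation for fractional positions.
#'
#' @param input `HxW` matrix or `HxWxCin` array.
#' @param kernel averaged coefficients: `kh x kw` matrix (single channel) or
#'   `kh x kw x Cin x Cout` array.
#' @param offsets an [compute_offsets()] result (or list with `u`, `v`).
#' @param mode `"base_grid"` or `"literal"`.
#' @return `HxW` matrix or `HxWxCout` array matching the input layout.
#' @export
deformable_conv <- function(input, kernel, offsets,
                            mode = c("base_grid", "literal")) {
  mode <- match.arg(mode)
  if (any(!is.finite(offsets$u)) || any(!is.finite(offsets$v)))
    stop_data("non-finite offsets")
  was2d <- is.matrix(input)
  if (was2d) dim(input) <- c(dim(input), 1L)
  if (is.matrix(kernel)) dim(kernel) <- c(dim(kernel), 1L, 1L)
  stopifnot(dim(kernel)[3] == dim(input)[3],
            length(offsets$u) == dim(kernel)[1],
            length(offsets$v) == dim(kernel)[2])
  out <- cpp_deform_forward(input, kernel, offsets$u, offsets$v,
                            mode == "base_grid")
  if (was2d && dim(out)[3] == 1L) out <- matrix(out, dim(out)[1], dim(out)[2])
  out
}

#' Literal attention-driven kernel update rule
#'
#' The printed coupled update: `dW = sum_mn k^{mn} phi_mn (dphi/dx)_mn
#' (dphi/dy)_mn` with central-difference spatial gradients of phi (replicated
#' borders), then `k^{mn} <- k^{mn} - step * phi_mn * dW` using `dk^{mn}/dW =
#' phi_mn`.  Exposed as a standalone, oracle-testable operation; default
#' training differentiates the forward pass end-to-end instead.
#'
#' @param kernel coefficient table(s): `MxN` matrix or array with trailing
#'   dims `(M, N)`.
#' @param phi attention map (`MxN`).
#' @param step scale applied to the update (a learning rate), default 1.
#' @return list with `kernel` (updated, same shape) and `weight_delta`.
#' @export
literal_kernel_update <- function(kernel, phi, step = 1) {
  p <- phi_matrix(phi)
  gx <- central_diff(p, 1L)
  gy <- central_diff(p, 2L)
  w <- p * gx * gy
  if (is.matrix(kernel)) {
    dW <- sum(kernel * w)
    return(list(kernel = kernel - step * p * dW, weight_delta = dW))
  }
  d <- dim(kernel); nd <- length(d)
  stopifnot(all(d[(nd - 1):nd] == dim(p)))
  lead <- prod(d[seq_len(nd - 2)])
  km <- matrix(kernel, nrow = lead)
  dW <- as.vector(km %*% as.vector(w))
  upd <- km - step * outer(dW, as.vector(p))
  list(kernel = array(upd, dim = d), weight_delta = array(dW, dim = d[seq_len(nd - 2)]))
}

# Central differences with replicated borders along margin 1 (rows, the x
# direction) or 2 (cols).
central_diff <- function(m, margin) {
  n <- dim(m)[margin]
  lo <- c(1, seq_len(n - 1))
  hi <- c(seq_len(n - 1) + 1, n)
  if (margin == 1L) (m[hi, , drop = FALSE] - m[lo, , drop = FALSE]) / 2
  else (m[, hi, drop = FALSE] - m[, lo, drop = FALSE]) / 2
}

# --- backbone -------------------------------------------------------------

# Sum-pool a normalised map onto a coarse (M, N) grid; mass is preserved so
# the pooled map still sums to 1.
pool_phi <- function(phi, extent) {
  p <- unclass(phi)
  ri <- pmin(extent[1], 1L + ((seq_len(nrow(p)) - 1L) * extent[1]) %/% nrow(p))
  ci <- pmin(extent[2], 1L + ((seq_len(ncol(p)) - 1L) * extent[2]) %/% ncol(p))
  out <- matrix(0, extent[1], extent[2])
  for (a in seq_len(extent[1]))
    for (b in seq_len(extent[2]))
      out[a, b] <- sum(p[ri == a, ci == b, drop = FALSE])
  out
}

pool_phi_backward <- function(gpool, nr, nc) {
  ri <- pmin(nrow(gpool), 1L + ((seq_len(nr) - 1L) * nrow(gpool)) %/% nr)
  ci <- pmin(ncol(gpool), 1L + ((seq_len(nc) - 1L) * ncol(gpool)) %/% nc)
  gpool[ri, ci, drop = FALSE]
}

he_init <- function(dims, fan_in, gain = 2) {
  array(rnorm(prod(dims), sd = sqrt(gain / fan_in)), dim = dims)
}

# One deformable residual block's parameters.  `deformable = FALSE` builds
# the plain-convolution variant used by the ablated model.
init_block <- function(cin, cout, stride, k = 3L, att = 3L, deformable = TRUE) {
  bp <- list(W1 = he_init(c(k, k, cin, cout), k * k * cin), b1 = numeric(cout))
  if (deformable) {
    # base coefficient tables for the second (cout -> cout) convolution,
    # laid out [kh, kw, cout, cout, M, N]; the (M N)^1.5 factor undoes the
    # attenuation of contraction + averaging so the effective averaged
    # kernel starts at He scale
    mn <- att * att
    bp$B <- he_init(c(k, k, cout, cout, att, att), k * k * cout) * mn^1.5
  } else {
    bp$W2 <- he_init(c(k, k, cout, cout), k * k * cout)
  }
  bp$b2 <- numeric(cout)
  if (cin != cout || stride != 1L) {
    bp$Wsc <- he_init(c(1L, 1L, cin, cout), cin)
    bp$bsc <- numeric(cout)
  }
  bp
}

init_backbone <- function(arch, cin = 3L) {
  blocks <- list()
  for (b in seq_along(arch$widths)) {
    blocks[[b]] <- init_block(cin, arch$widths[b], arch$strides[b],
                              k = arch$kernel_size, att = arch$att_extent,
                              deformable = arch$deformable)
    cin <- arch$widths[b]
  }
  blocks
}

block_forward <- function(x, bp, stride, arch, ablation = FALSE) {
  k <- arch$kernel_size
  pad <- (k - 1L) %/% 2L
  att <- arch$att_extent
  c1 <- conv2d_forward_fast(x, bp$W1, bp$b1, stride, pad)
  a1pre <- c1$out
  a1 <- pmax(a1pre, 0)
  deform <- !is.null(bp$B)
  c2 <- NULL; df <- NULL
  if (deform) {
    if (ablation) {
      phi <- NULL
      phit <- matrix(1 / (att * att), att, att)
      off <- list(u = numeric(k), v = numeric(k))
    } else {
      phi <- compute_attention_map(a1)
      phit <- pool_phi(phi, c(att, att))
      off <- compute_offsets(phit, c(k, k))
    }
    mn <- att * att
    kdims <- dim(bp$B)[1:4]
    Bm <- matrix(bp$B, nrow = prod(kdims))
    kbar <- array(Bm %*% as.vector(phit) / mn, dim = kdims)
    df <- deform_forward_fast(a1, kbar, off$u, off$v, TRUE)
    z <- sweep(df$out, 3, bp$b2, `+`)
  } else {
    phi <- NULL; phit <- NULL; off <- NULL; kbar <- NULL
    c2 <- conv2d_forward_fast(a1, bp$W2, bp$b2, 1L, pad)
    z <- c2$out
  }
  if (is.null(bp$Wsc)) {
    sc <- x; csc <- NULL
  } else {
    csc <- conv2d_forward_fast(x, bp$Wsc, bp$bsc, stride, 0L)
    sc <- csc$out
  }
  pre <- z + sc
  out <- pmax(pre, 0)
  list(out = out,
       cache = list(x = x, a1pre = a1pre, a1 = a1, phi = phi, phit = phit,
                    off = off, kbar = kbar, pre = pre, stride = stride,
                    ablation = ablation, c1 = c1[c("cols", "sr")],
                    c2 = if (!is.null(c2)) c2[c("cols", "sr")],
                    dcols = if (!is.null(df)) df$cols,
                    csc = if (!is.null(csc)) csc[c("cols", "sr")]))
}

block_backward <- function(gout, cache, bp, arch) {
  k <- arch$kernel_size
  pad <- (k - 1L) %/% 2L
  att <- arch$att_extent
  g <- gout * (cache$pre > 0)
  grads <- list()
  # shortcut branch
  if (is.null(bp$Wsc)) {
    gx <- g
  } else {
    bw <- conv2d_backward_fast(cache$x, bp$Wsc, g, cache$stride, 0L,
                               cache$csc$cols, cache$csc$sr)
    grads$Wsc <- bw$weight; grads$bsc <- bw$bias
    gx <- bw$input
  }
  deform <- !is.null(bp$B)
  if (deform) {
    grads$b2 <- colSums(matrix(g, prod(dim(g)[1:2]), dim(g)[3]))
    dw <- deform_backward_fast(cache$a1, cache$kbar, cache$off$u, cache$off$v,
                               TRUE, g, cache$dcols)
    ga1 <- dw$input
    mn <- att * att
    lead <- prod(dim(bp$B)[1:4])
    gkbar <- as.vector(dw$kernel)
    phit_v <- as.vector(cache$phit)
    grads$B <- array(outer(gkbar, phit_v) / mn, dim = dim(bp$B))
    if (!cache$ablation) {
      Bm <- matrix(bp$B, nrow = lead)
      gphit <- matrix(crossprod(Bm, gkbar) / mn, att, att)
      # offsets: u_i = 0.5 sum_mn phit (m0 - i0), v_j likewise
      m0 <- matrix(seq_len(att) - 1, att, att)
      n0 <- matrix(seq_len(att) - 1, att, att, byrow = TRUE)
      i0 <- seq_len(k) - 1
      for (i in seq_len(k)) gphit <- gphit + dw$u[i] * 0.5 * (m0 - i0[i])
      for (j in seq_len(k)) gphit <- gphit + dw$v[j] * 0.5 * (n0 - i0[j])
      gphi <- pool_phi_backward(gphit, nrow(cache$phi), ncol(cache$phi))
      # phi = m / s with m the channel-mean absolute activation
      phi <- unclass(cache$phi)
      s <- sum(apply(abs(cache$a1), c(1, 2), mean))
      if (s > 0) {
        gm <- gphi / s - sum(gphi * phi) / s
        C <- dim(cache$a1)[3]
        ga1 <- ga1 + array(gm, dim = dim(cache$a1)) * sign(cache$a1) / C
      }
    }
  } else {
    bw2 <- conv2d_backward_fast(cache$a1, bp$W2, g, 1L, pad,
                                cache$c2$cols, cache$c2$sr)
    grads$W2 <- bw2$weight; grads$b2 <- bw2$bias
    ga1 <- bw2$input
  }
  ga1 <- ga1 * (cache$a1pre > 0)
  bw1 <- conv2d_backward_fast(cache$x, bp$W1, ga1, cache$stride, pad,
                              cache$c1$cols, cache$c1$sr)
  grads$W1 <- bw1$weight; grads$b1 <- bw1$bias
  gx <- gx + bw1$input
  list(gx = gx, grads = grads[names(bp)])
}

backbone_forward <- function(image, blocks, arch, ablation = FALSE,
                             keep_cache = FALSE) {
  x <- image
  caches <- if (keep_cache) vector("list", length(blocks)) else NULL
  for (b in seq_along(blocks)) {
    fb <- block_forward(x, blocks[[b]], arch$strides[b], arch, ablation)
    x <- fb$out
    if (keep_cache) caches[[b]] <- fb$cache
  }
  attr(x, "stride") <- prod(arch$strides)
  list(out = x, caches = caches)
}

backbone_backward <- function(gout, caches, blocks, arch) {
  grads <- vector("list", length(blocks))
  g <- gout
  for (b in rev(seq_along(blocks))) {
    bb <- block_backward(g, caches[[b]], blocks[[b]], arch)
    grads[[b]] <- bb$grads
    g <- bb$gx
  }
  list(gimage = g, grads = grads)
}

#' Run the four-block deformable residual feature extractor
#'
#' Each block applies a strided convolution, derives the attention map phi
#' from its activations, and replaces the usual second convolution with the
#' attention-modulated deformable convolution (plus a projection shortcut).
#' With `ablation = TRUE` the same weights are used with uniform modulation
#' and zero offsets, i.e. a plain residual pass.
#'
#' @param image `HxWx3` array at the working size.
#' @param backbone list with `arch` and `blocks` (see [build_model()]; the
#'   `backbone` element of a model works directly).
#' @param ablation disable attention modulation and offsets.
#' @return feature array `H' x W' x C` with attribute `stride`.
#' @export
adcn_forward <- function(image, backbone, ablation = FALSE) {
  backbone_forward(image, backbone$blocks, backbone$arch, ablation)$out
}
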