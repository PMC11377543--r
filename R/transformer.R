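# Transformer encoder-decoder.  The encoder is a stack of pre-norm blocks
# (multi-head self-attention and a GELU MLP, each with a residual
# connection).  The decoder holds one learnable query token per class
# (background, polyp): self-attention over the queries *without* a residual,
# cross-attention from queries to image features, and an MLP produce the
# query embeddings whose inner products with the patch features give the
# per-patch class logits.

#' Layer normalisation
#'
#' `gamma * (v - mu) / (sigma + eps) + beta` per token, with `mu` and
#' `sigma` the token's mean and population standard deviation.
#'
#' @param v numeric vector, or an `n x d` matrix normalised row-wise.
#' @param gamma,beta scale and bias (scalar or length-d).
#' @param eps stabiliser added to `sigma`.
#' @return same shape as `v`.
#' @export
layer_norm <- function(v, gamma = 1, beta = 0, eps = 1e-5) {
  if (is.matrix(v)) {
    mu <- rowMeans(v)
    sig <- sqrt(rowMeans((v - mu)^2))
    sweep(sweep((v - mu) / (sig + eps), 2, gamma, `*`), 2, beta, `+`)
  } else {
    mu <- mean(v)
    sig <- sqrt(mean((v - mu)^2))
    gamma * (v - mu) / (sig + eps) + beta
  }
}

ln_forward <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  cx <- X - mu
  sig <- sqrt(rowMeans(cx^2))
  xn <- cx / (sig + eps)
  out <- sweep(sweep(xn, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = out, cache = list(cx = cx, sig = sig, xn = xn, eps = eps))
}

ln_backward <- function(gout, cache, p) {
  d <- ncol(gout)
  gxn <- sweep(gout, 2, p$gamma, `*`)
  ggamma <- colSums(gout * cache$xn)
  gbeta <- colSums(gout)
  den <- cache$sig + cache$eps
  # d/dv of c/(sigma+eps): centring term and the sigma chain
  term1 <- (gxn - rowMeans(gxn)) / den
  dot <- rowSums(gxn * cache$cx)
  sig_safe <- pmax(cache$sig, 1e-12)
  term2 <- cache$cx * (dot / (d * sig_safe * den^2))
  gX <- term1 - term2
  list(gX = gX, grads = list(gamma = ggamma, beta = gbeta))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  e <- exp(S - m)
  e / rowSums(e)
}

init_attention <- function(d, heads) {
  stopifnot(d %% heads == 0)
  list(wq = he_init(c(d, d), d, gain = 1), wk = he_init(c(d, d), d, gain = 1),
       wv = he_init(c(d, d), d, gain = 1), wo = he_init(c(d, d), d, gain = 1))
}

init_ln <- function(d) list(gamma = rep(1, d), beta = rep(0, d))

init_mlp <- function(d, ratio = 4L) {
  h <- d * ratio
  list(W1 = he_init(c(d, h), d), b1 = numeric(h),
       W2 = he_init(c(h, d), h), b2 = numeric(d))
}

mhsa_forward <- function(Xq, Xkv, p, heads) {
  d <- ncol(Xq)
  dk <- d %/% heads
  Q <- Xq %*% p$wq; K <- Xkv %*% p$wk; V <- Xkv %*% p$wv
  A <- vector("list", heads)
  O <- matrix(0, nrow(Xq), d)
  for (t in seq_len(heads)) {
    idx <- ((t - 1) * dk + 1):(t * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    A[[t]] <- softmax_rows(S)
    O[, idx] <- A[[t]] %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$wo
  list(out = out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, A = A, O = O,
                    heads = heads, dk = dk),
       attention = A)
}

mhsa_backward <- function(gout, cache, p) {
  heads <- cache$heads; dk <- cache$dk
  gO <- gout %*% t(p$wo)
  gwo <- crossprod(cache$O, gout)
  gQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  gK <- matrix(0, nrow(cache$K), ncol(cache$K))
  gV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (t in seq_len(heads)) {
    idx <- ((t - 1) * dk + 1):(t * dk)
    At <- cache$A[[t]]
    gOt <- gO[, idx, drop = FALSE]
    gA <- gOt %*% t(cache$V[, idx, drop = FALSE])
    gV[, idx] <- crossprod(At, gOt)
    gS <- At * (gA - rowSums(gA * At))
    gQ[, idx] <- gS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    gK[, idx] <- crossprod(gS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  list(gXq = gQ %*% t(p$wq),
       gXkv = gK %*% t(p$wk) + gV %*% t(p$wv),
       grads = list(wq = crossprod(cache$Xq, gQ), wk = crossprod(cache$Xkv, gK),
                    wv = crossprod(cache$Xkv, gV), wo = gwo))
}

mlp_forward <- function(X, p) {
  H0 <- sweep(X %*% p$W1, 2, p$b1, `+`)
  H <- gelu(H0)
  out <- sweep(H %*% p$W2, 2, p$b2, `+`)
  list(out = out, cache = list(X = X, H0 = H0, H = H))
}

mlp_backward <- function(gout, cache, p) {
  gH <- gout %*% t(p$W2)
  gW2 <- crossprod(cache$H, gout)
  gb2 <- colSums(gout)
  gH0 <- gH * gelu_grad(cache$H0)
  gX <- gH0 %*% t(p$W1)
  gW1 <- crossprod(cache$X, gH0)
  gb1 <- colSums(gH0)
  list(gX = gX, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

init_encoder_block <- function(d, heads, mlp_ratio = 4L) {
  list(ln1 = init_ln(d), attn = init_attention(d, heads),
       ln2 = init_ln(d), mlp = init_mlp(d, mlp_ratio))
}

encoder_block_forward <- function(X, bp, heads) {
  l1 <- ln_forward(X, bp$ln1)
  at <- mhsa_forward(l1$out, l1$out, bp$attn, heads)
  Z1 <- at$out + X
  l2 <- ln_forward(Z1, bp$ln2)
  ml <- mlp_forward(l2$out, bp$mlp)
  Z2 <- ml$out + Z1
  list(out = Z2, cache = list(l1 = l1, at = at, l2 = l2, ml = ml),
       attention = at$attention)
}

encoder_block_backward <- function(gout, cache, bp) {
  mb <- mlp_backward(gout, cache$ml$cache, bp$mlp)
  lb2 <- ln_backward(mb$gX, cache$l2$cache, bp$ln2)
  gZ1 <- gout + lb2$gX
  ab <- mhsa_backward(gZ1, cache$at$cache, bp$attn)
  lb1 <- ln_backward(ab$gXq + ab$gXkv, cache$l1$cache, bp$ln1)
  gX <- gZ1 + lb1$gX
  list(gX = gX, grads = list(ln1 = lb1$grads, attn = ab$grads,
                             ln2 = lb2$grads, mlp = mb$grads))
}

#' One transformer encoder block
#'
#' Pre-norm: `Z1 = MHSA(LN(x)) + x`, `Z2 = MLP(LN(Z1)) + Z1` with a
#' two-layer GELU MLP of hidden width `mlp_ratio * d`.
#'
#' @param tokens `n x d` matrix.
#' @param params block parameters from `init_encoder_block` (via
#'   [build_model()] or [encode()]'s initialiser).
#' @param heads head count.
#' @return `n x d` matrix with self-attention matrices attached as attribute
#'   `attention`.
#' @export
encoder_block <- function(tokens, params, heads) {
  fb <- encoder_block_forward(unclass(tokens), params, heads)
  structure(fb$out, attention = fb$attention)
}

#' Run the transformer encoder
#'
#' Applies `depth` encoder blocks sequentially; the final block's output is
#' the feature set handed to the decoder.
#'
#' @param tokens `n x d` token matrix (positions already attached).
#' @param params list of block parameter sets, or `NULL` to He-initialise
#'   `depth` blocks from the current RNG stream.
#' @param depth block count (default 4).
#' @param heads head count.
#' @return object of class `encoder_state`: list with `F` (`n x d`
#'   features) and `attention` (per block, per head row-stochastic
#'   matrices).
#' @export
encode <- function(tokens, params = NULL, depth = 4L, heads = 8L) {
  X <- unclass(tokens)
  if (is.null(params))
    params <- replicate(depth, init_encoder_block(ncol(X), heads), simplify = FALSE)
  attn <- list()
  for (b in seq_along(params)) {
    fb <- encoder_block_forward(X, params[[b]], heads)
    X <- fb$out
    attn[[b]] <- fb$attention
  }
  structure(list(F = X, attention = attn), class = "encoder_state")
}

init_decoder <- function(d, heads, mlp_ratio = 4L) {
  list(ln1 = init_ln(d), self = init_attention(d, heads),
       ln2 = init_ln(d), cross = init_attention(d, heads),
       ln3 = init_ln(d), mlp = init_mlp(d, mlp_ratio))
}

decoder_forward <- function(Fmat, Tq, dp, heads, self_residual = FALSE) {
  l1 <- ln_forward(Tq, dp$ln1)
  sa <- mhsa_forward(l1$out, l1$out, dp$self, heads)
  # deliberately no residual around the query self-attention by default
  Z3 <- if (self_residual) sa$out + Tq else sa$out
  l2 <- ln_forward(Z3, dp$ln2)
  ca <- mhsa_forward(l2$out, Fmat, dp$cross, heads)
  Z4 <- ca$out + Z3
  l3 <- ln_forward(Z4, dp$ln3)
  ml <- mlp_forward(l3$out, dp$mlp)
  Z5 <- ml$out + Z4
  list(Z3 = Z3, Z4 = Z4, Z5 = Z5, qe = Z5, cross_attention = ca$attention,
       self_attention = sa$attention,
       cache = list(l1 = l1, sa = sa, l2 = l2, ca = ca, l3 = l3, ml = ml))
}

decoder_backward <- function(gZ5, cache, dp) {
  mb <- mlp_backward(gZ5, cache$ml$cache, dp$mlp)
  lb3 <- ln_backward(mb$gX, cache$l3$cache, dp$ln3)
  gZ4 <- gZ5 + lb3$gX
  cb <- mhsa_backward(gZ4, cache$ca$cache, dp$cross)
  gF <- cb$gXkv
  lb2 <- ln_backward(cb$gXq, cache$l2$cache, dp$ln2)
  gZ3 <- gZ4 + lb2$gX
  sb <- mhsa_backward(gZ3, cache$sa$cache, dp$self)
  lb1 <- ln_backward(sb$gXq + sb$gXkv, cache$l1$cache, dp$ln1)
  gT <- lb1$gX                       # no residual around Z3
  list(gF = gF, gT = gT,
       grads = list(ln1 = lb1$grads, self = sb$grads, ln2 = lb2$grads,
                    cross = cb$grads, ln3 = lb3$grads, mlp = mb$grads))
}

#' Decode class query tokens against encoded features
#'
#' `Z3 = MHSA(LN(T))` (deliberately without a residual), `Z4 = MHCA(LN(Z3), F) +
#' Z3` with queries from the class tokens and keys/values from the image
#' features, `Z5 = MLP(LN(Z4)) + Z4`.  The rows of `Z5` are the query
#' embeddings.
#'
#' @param features an [encode()] result (or an `n x d` feature matrix).
#' @param queries `C x d` matrix of class query tokens (row 1 background,
#'   row 2 polyp).
#' @param params decoder parameters (see [build_model()]), or `NULL` to
#'   He-initialise from the current RNG stream.
#' @param heads head count.
#' @param self_residual add the conventional residual connection around the
#'   query self-attention (off by default; the design omits it).
#' @return object of class `decoder_state`: `Z3`, `Z4`, `Z5`, `qe`, and the
#'   self/cross attention maps.
#' @export
decode <- function(features, queries, params = NULL, heads = 8L,
                   self_residual = FALSE) {
  Fmat <- if (inherits(features, "encoder_state")) features$F else unclass(features)
  if (ncol(Fmat) != ncol(queries)) stop_config("feature/query dimension mismatch")
  if (is.null(params)) params <- init_decoder(ncol(Fmat), heads)
  st <- decoder_forward(Fmat, unclass(queries), params, heads, self_residual)
  structure(st[c("Z3", "Z4", "Z5", "qe", "cross_attention", "self_attention")],
            class = "decoder_state")
}

#' Build the segmentation mask from features and query embeddings
#'
#' The per-patch class score is the inner product of the patch feature with
#' the class query embedding.  Scores are laid out on the token grid,
#' bilinearly upsampled to `out_size`, and converted to labels by argmax
#' with ties broken toward background.
#'
#' @param features an [encode()] result or `n x d` matrix.
#' @param state a [decode()] result (its `qe` rows are used) or a `C x d`
#'   matrix of query embeddings.
#' @param grid_shape token grid `c(rows, cols)` (taken from `n` assuming a
#'   square grid when `NULL`).
#' @param out_size side of the output label image.
#' @return object of class `segmentation_mask`: list with `logits` (grid
#'   `rows x cols x C`), `upsampled` (`out x out x C`), and `labels`
#'   (`out x out` in {0,1}).
#' @export
build_mask <- function(features, state, grid_shape = NULL, out_size = 256L) {
  Fmat <- if (inherits(features, "encoder_state")) features$F else unclass(features)
  qe <- if (inherits(state, "decoder_state")) state$qe else unclass(state)
  if (ncol(Fmat) != ncol(qe)) stop_config("feature/query dimension mismatch")
  n <- nrow(Fmat)
  if (is.null(grid_shape)) {
    side <- as.integer(round(sqrt(n)))
    stopifnot(side * side == n)
    grid_shape <- c(side, side)
  }
  logits <- Fmat %*% t(qe)                       # n x C
  grid <- tokens_to_grid(logits, grid_shape)     # rows x cols x C
  up <- cpp_resize_bilinear(grid, out_size, out_size)
  labels <- matrix(as.double(up[, , 2] > up[, , 1]), out_size, out_size)
  structure(list(logits = grid, upsampled = up, labels = labels),
            class = "segmentation_mask")
}
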