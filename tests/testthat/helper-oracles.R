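# Independent brute-force oracles used to freeze expected values.  These are
# deliberately naive (explicit loops, direct formula evaluation) and never
# share code with the implementation paths they check.

# Plain cross-correlation, zero padded, stride 1, by direct summation.
oracle_conv2d <- function(A, K) {
  if (is.matrix(A)) dim(A) <- c(dim(A), 1L)
  if (is.matrix(K)) dim(K) <- c(dim(K), 1L, 1L)
  H <- dim(A)[1]; W <- dim(A)[2]; Ci <- dim(A)[3]
  kh <- dim(K)[1]; kw <- dim(K)[2]; Co <- dim(K)[4]
  cr <- (kh - 1) / 2; cc <- (kw - 1) / 2
  out <- array(0, dim = c(H, W, Co))
  for (co in 1:Co) for (x in 1:H) for (y in 1:W) {
    s <- 0
    for (ci in 1:Ci) for (i in 1:kh) for (j in 1:kw) {
      r <- x + (i - 1) - cr; q <- y + (j - 1) - cc
      if (r >= 1 && r <= H && q >= 1 && q <= W)
        s <- s + K[i, j, ci, co] * A[r, q, ci]
    }
    out[x, y, co] <- s
  }
  out
}

# Single-head attention by direct formula evaluation on small matrices.
oracle_attention <- function(X, wq, wk, wv, wo) {
  Q <- X %*% wq; K <- X %*% wk; V <- X %*% wv
  dk <- ncol(K)
  S <- Q %*% t(K) / sqrt(dk)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  if (nrow(S) == 1) A <- matrix(A, 1)
  (A %*% V) %*% wo
}

# Central-difference gradient of f at x (elementwise), for gradient checks.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

make_test_image <- function(n = 64, seed = 1) {
  with_seed(seed, array(runif(n * n * 3), dim = c(n, n, 3)))
}

random_mask <- function(n, p = 0.3, seed = 1) {
  with_seed(seed, matrix(rbinom(n * n, 1, p), n, n))
}

# A small architecture for fast structural tests.
micro_arch <- function(...) {
  polypvit_arch(image_size = 16L, widths = c(4L, 8L, 8L, 8L),
                strides = c(2L, 2L, 1L, 1L), heads = 2L, depth = 1L,
                mlp_ratio = 2L, ...)
}
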