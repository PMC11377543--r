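# BLAS-backed convolution paths used by the training loop.  Because the
# deformable offsets (u_i, v_j) are shared across space, every kernel tap
# samples the input at one constant fractional shift; a tap's sample plane
# is therefore four integer-shifted copies of the input blended with
# constant bilinear weights, and the convolution itself is a single matrix
# product against the tap-stacked sample columns.  The scalar C++ kernels
# remain as the reference implementation and oracle.

# Memoised integer shifts of one array (zero fill).
make_shift_cache <- function(A) {
  env <- new.env(parent = emptyenv())
  function(dr, dc) {
    key <- paste0(dr, ",", dc)
    s <- env[[key]]
    if (is.null(s)) {
      s <- cpp_shift_image(A, as.integer(dr), as.integer(dc))
      env[[key]] <- s
    }
    s
  }
}

shift_image <- function(A, dr, dc) cpp_shift_image(A, as.integer(dr), as.integer(dc))

# Fractional global shift via bilinear blending of four integer shifts.
frac_shift <- function(sh, r_off, q_off) {
  r0 <- floor(r_off); q0 <- floor(q_off)
  fr <- r_off - r0; fq <- q_off - q0
  S <- (1 - fr) * (1 - fq) * sh(r0, q0)
  if (fq > 0) S <- S + (1 - fr) * fq * sh(r0, q0 + 1)
  if (fr > 0) S <- S + fr * (1 - fq) * sh(r0 + 1, q0)
  if (fr > 0 && fq > 0) S <- S + fr * fq * sh(r0 + 1, q0 + 1)
  S
}

# d frac_shift / d r_off and / d q_off (piecewise-linear interpolation).
frac_shift_dcoord <- function(sh, r_off, q_off) {
  r0 <- floor(r_off); q0 <- floor(q_off)
  fr <- r_off - r0; fq <- q_off - q0
  s00 <- sh(r0, q0); s01 <- sh(r0, q0 + 1)
  s10 <- sh(r0 + 1, q0); s11 <- sh(r0 + 1, q0 + 1)
  list(dr = (1 - fq) * (s10 - s00) + fq * (s11 - s01),
       dq = (1 - fr) * (s01 - s00) + fr * (s11 - s10))
}

# Tap displacement for tap (i, j) (1-based) of a kh x kw kernel.
tap_offsets <- function(kh, kw, u, v, base_grid) {
  cr <- (kh - 1) / 2; cc <- (kw - 1) / 2
  list(dr = if (base_grid) (seq_len(kh) - 1) - cr + u else u,
       dc = if (base_grid) (seq_len(kw) - 1) - cc + v else v)
}

# Stack per-tap sample planes into columns: H*W rows, taps (i fastest, then
# j) each contributing Ci columns.
deform_cols <- function(A, kh, kw, u, v, base_grid) {
  d <- dim(A)
  off <- tap_offsets(kh, kw, u, v, base_grid)
  sh <- make_shift_cache(A)
  cols <- matrix(0, d[1] * d[2], kh * kw * d[3])
  for (j in seq_len(kw))
    for (i in seq_len(kh)) {
      t <- i + (j - 1) * kh
      cols[, ((t - 1) * d[3] + 1):(t * d[3])] <- frac_shift(sh, off$dr[i], off$dc[j])
    }
  cols
}

# Kernel as a (Ci * kh * kw) x Co matrix matching deform_cols column order
# (channel fastest within tap).
kernel_mat <- function(K) {
  d <- dim(K)
  matrix(aperm(K, c(3, 1, 2, 4)), d[1] * d[2] * d[3], d[4])
}

kernel_unmat <- function(M, d) aperm(array(M, dim = d[c(3, 1, 2, 4)]),
                                     c(2, 3, 1, 4))

deform_forward_fast <- function(A, K, u, v, base_grid = TRUE) {
  d <- dim(A); dk <- dim(K)
  cols <- deform_cols(A, dk[1], dk[2], u, v, base_grid)
  out <- cols %*% kernel_mat(K)
  list(out = array(out, dim = c(d[1], d[2], dk[4])), cols = cols)
}

deform_backward_fast <- function(A, K, u, v, base_grid, gOut, cols) {
  d <- dim(A); dk <- dim(K)
  gmat <- matrix(gOut, d[1] * d[2], dk[4])
  Km <- kernel_mat(K)
  gK <- kernel_unmat(crossprod(cols, gmat), dk)
  gcols <- gmat %*% t(Km)
  off <- tap_offsets(dk[1], dk[2], u, v, base_grid)
  sh <- make_shift_cache(A)
  gA <- array(0, dim = d)
  gu <- numeric(dk[1]); gv <- numeric(dk[2])
  for (j in seq_len(dk[2]))
    for (i in seq_len(dk[1])) {
      t <- i + (j - 1) * dk[1]
      gS <- array(gcols[, ((t - 1) * d[3] + 1):(t * d[3])], dim = d)
      r0 <- floor(off$dr[i]); q0 <- floor(off$dc[j])
      fr <- off$dr[i] - r0; fq <- off$dc[j] - q0
      cpp_shift_add(gA, gS, -r0, -q0, (1 - fr) * (1 - fq))
      if (fq > 0) cpp_shift_add(gA, gS, -r0, -(q0 + 1), (1 - fr) * fq)
      if (fr > 0) cpp_shift_add(gA, gS, -(r0 + 1), -q0, fr * (1 - fq))
      if (fr > 0 && fq > 0) cpp_shift_add(gA, gS, -(r0 + 1), -(q0 + 1), fr * fq)
      dd <- frac_shift_dcoord(sh, off$dr[i], off$dc[j])
      gu[i] <- gu[i] + sum(gS * dd$dr)
      gv[j] <- gv[j] + sum(gS * dd$dq)
    }
  list(input = gA, kernel = gK, u = gu, v = gv)
}

# Row indices (in the flattened H*W output of the unstrided shift planes)
# of the strided output grid.
stride_rows <- function(H, W, stride, pad, kh, kw) {
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  xs <- (seq_len(Ho) - 1) * stride
  ys <- (seq_len(Wo) - 1) * stride
  list(idx = as.vector(outer(xs + 1, ys * H, `+`)), Ho = Ho, Wo = Wo)
}

conv2d_forward_fast <- function(A, K, bias, stride, pad) {
  d <- dim(A); dk <- dim(K)
  # tap (i, j) reads input at (x*stride - pad + i - 1, ...): an integer
  # shift by (i - 1 - pad) sampled on the stride grid
  sr <- stride_rows(d[1], d[2], stride, pad, dk[1], dk[2])
  cols <- matrix(0, length(sr$idx), dk[1] * dk[2] * d[3])
  for (j in seq_len(dk[2]))
    for (i in seq_len(dk[1])) {
      t <- i + (j - 1) * dk[1]
      S <- cpp_shift_image(A, i - 1L - pad, j - 1L - pad)
      cols[, ((t - 1) * d[3] + 1):(t * d[3])] <-
        matrix(S, d[1] * d[2], d[3])[sr$idx, , drop = FALSE]
    }
  out <- cols %*% kernel_mat(K)
  out <- out + rep(bias, each = nrow(out))
  list(out = array(out, dim = c(sr$Ho, sr$Wo, dk[4])), cols = cols, sr = sr)
}

conv2d_backward_fast <- function(A, K, gOut, stride, pad, cols, sr) {
  d <- dim(A); dk <- dim(K)
  gmat <- matrix(gOut, length(sr$idx), dk[4])
  gK <- kernel_unmat(crossprod(cols, gmat), dk)
  gb <- colSums(gmat)
  gcols <- gmat %*% t(kernel_mat(K))
  gA <- array(0, dim = d)
  full <- matrix(0, d[1] * d[2], d[3])
  for (j in seq_len(dk[2]))
    for (i in seq_len(dk[1])) {
      t <- i + (j - 1) * dk[1]
      full[] <- 0
      full[sr$idx, ] <- gcols[, ((t - 1) * d[3] + 1):(t * d[3])]
      cpp_shift_add(gA, array(full, dim = d), -(i - 1L - pad), -(j - 1L - pad), 1)
    }
  list(input = gA, weight = gK, bias = gb)
}
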