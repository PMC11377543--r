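test_that("attention map is the normalised channel-mean of |activations|", {
  # spatially constant -> uniform
  phi <- compute_attention_map(array(3, dim = c(4, 5, 2)))
  expect_equal(max(abs(phi - 1 / 20)), 0, tolerance = 1e-12)
  # delta activation -> delta map (mean-abs then normalise, by hand)
  f <- array(0, dim = c(3, 3, 4))
  f[2, 3, 1] <- -7
  phi <- compute_attention_map(f)
  expect_equal(phi[2, 3], 1)
  expect_equal(sum(phi), 1)
  # normalisation for random inputs
  for (s in 1:5) {
    phi <- compute_attention_map(with_seed(s, array(rnorm(60), dim = c(5, 4, 3))))
    expect_lt(abs(sum(phi) - 1), 1e-9)
    expect_true(all(phi >= 0))
  }
  # all-zero fallback: uniform, not an error
  phi0 <- compute_attention_map(array(0, dim = c(2, 2, 1)))
  expect_equal(as.vector(unclass(phi0)), rep(0.25, 4))
})

test_that("kernel modulation contracts the coefficient table against phi", {
  expect_equal(modulate_kernel(matrix(c(1, 3, 2, 4), 2, 2),
                               matrix(c(0.5, 0, 0.5, 0), 2, 2)), 1.5)
  # phi a delta picks out one coefficient
  phi <- matrix(0, 2, 2); phi[1, 2] <- 1
  expect_equal(modulate_kernel(matrix(c(1, 3, 2, 4), 2, 2), phi), 2)
  # all-ones kernel with normalised phi -> 1
  expect_equal(modulate_kernel(matrix(1, 3, 3), matrix(1 / 9, 3, 3)), 1)
  expect_error(modulate_kernel(matrix(1, 2, 2), matrix(1 / 9, 3, 3)),
               class = "polypvit_config_error")
})

test_that("kernel averaging divides the modulation by the map extent", {
  expect_equal(average_kernel(matrix(0, 2, 2), matrix(0.25, 2, 2)), 0)
  expect_equal(average_kernel(matrix(1:4, 2, 2), matrix(0.25, 2, 2)), 0.625)
  phi <- matrix(0, 2, 2); phi[1, 1] <- 1
  k <- matrix(0, 2, 2); k[1, 1] <- 1
  expect_equal(average_kernel(k, phi), 0.25)
  # array form: one table per tap, leading dims preserved
  K <- array(rnorm(2 * 2 * 3 * 3), dim = c(2, 2, 3, 3))
  phi3 <- matrix(1 / 9, 3, 3)
  got <- average_kernel(K, phi3)
  expect_equal(got[1, 2], average_kernel(K[1, 2, , ], phi3))
})

test_that("offsets follow the half-centroid-distance closed form", {
  # uniform 3x3, first row index -> 0.5
  off <- compute_offsets(matrix(1 / 9, 3, 3), c(3, 3))
  expect_equal(off$u[1], 0.5)
  expect_equal(off$v[1], 0.5)
  # delta on the row equal to the kernel index -> zero offset
  phi <- matrix(0, 3, 3); phi[2, 1] <- 1
  expect_equal(compute_offsets(phi, c(3, 3))$u[2], 0)
  # symmetric phi about the center row -> zero offset at the center index
  phi <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
  expect_equal(compute_offsets(phi, c(3, 3))$u[2], 0)
  # closed form u_i = (mean(m) - i) / 2 under uniform phi, M, N in {3, 5}
  for (M in c(3, 5)) for (N in c(3, 5)) {
    offu <- compute_offsets(matrix(1 / (M * N), M, N), c(3, 3))
    i0 <- 0:2
    expect_equal(offu$u, 0.5 * ((M - 1) / 2 - i0))
    expect_equal(offu$v, 0.5 * ((N - 1) / 2 - i0))
  }
})

test_that("deformable convolution reduces to identity and shifts", {
  I <- with_seed(1, matrix(rnorm(100), 10, 10))
  kid <- matrix(0, 3, 3); kid[2, 2] <- 1
  out <- deformable_conv(I, kid, list(u = numeric(3), v = numeric(3)))
  expect_equal(out, I, tolerance = 1e-12)
  # 1x1 kernel with unit row offset reads the next row
  out2 <- deformable_conv(I, matrix(1, 1, 1), list(u = 1, v = 0))
  expect_equal(out2[1:9, ], I[2:10, ], tolerance = 1e-12)
  # half-pixel offset bilinearly blends two samples
  I2 <- matrix(c(0, 1), 1, 2)
  out3 <- deformable_conv(I2, matrix(1, 1, 1), list(u = 0, v = 0.5))
  expect_equal(out3[1, 1], 0.5)
  # 3x3 averaging kernel on a row-ramp reproduces the ramp in the interior
  ramp <- matrix(rep(0:9, 10), 10, 10)
  out4 <- deformable_conv(ramp, matrix(1 / 9, 3, 3),
                          list(u = numeric(3), v = numeric(3)))
  expect_equal(out4[2:9, 2:9], ramp[2:9, 2:9], tolerance = 1e-12)
  expect_error(deformable_conv(I, kid, list(u = c(0, NA, 0), v = numeric(3))),
               class = "polypvit_data_error")
})

test_that("uniform modulation with zero offsets equals plain cross-correlation", {
  for (s in 1:5) {
    A <- with_seed(s, matrix(rnorm(256), 16, 16))
    K <- with_seed(s + 100, matrix(rnorm(9), 3, 3))
    got <- deformable_conv(A, K, list(u = numeric(3), v = numeric(3)))
    expect_lt(max(abs(got - oracle_conv2d(A, K)[, , 1])), 1e-6)
  }
})

test_that("deformable convolution is linear in its input", {
  with_seed(4, {
    A1 <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
    A2 <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
    K <- array(rnorm(3 * 3 * 2 * 2), dim = c(3, 3, 2, 2))
    off <- list(u = runif(3, -1, 1), v = runif(3, -1, 1))
  })
  lhs <- deformable_conv(2 * A1 + 3 * A2, K, off)
  rhs <- 2 * deformable_conv(A1, K, off) + 3 * deformable_conv(A2, K, off)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("literal mode drops the base sampling grid", {
  I <- with_seed(2, matrix(rnorm(64), 8, 8))
  K <- matrix(1 / 9, 3, 3)
  lit <- deformable_conv(I, K, list(u = numeric(3), v = numeric(3)),
                         mode = "literal")
  # every tap samples the same point: sum(K) * I
  expect_equal(lit, I * sum(K), tolerance = 1e-12)
})

test_that("fast BLAS paths agree with the scalar reference kernels", {
  with_seed(11, {
    A <- array(rnorm(12 * 14 * 3), dim = c(12, 14, 3))
    K <- array(rnorm(3 * 3 * 3 * 5), dim = c(3, 3, 3, 5))
    b <- rnorm(5)
    u <- runif(3, -1.5, 1.5); v <- runif(3, -1.5, 1.5)
    g <- array(rnorm(12 * 14 * 5), dim = c(12, 14, 5))
  })
  f_ref <- cpp_deform_forward(A, K, u, v, TRUE)
  f_fast <- deform_forward_fast(A, K, u, v, TRUE)
  expect_equal(f_fast$out, f_ref, tolerance = 1e-10)
  b_ref <- cpp_deform_backward(A, K, u, v, TRUE, g)
  b_fast <- deform_backward_fast(A, K, u, v, TRUE, g, f_fast$cols)
  expect_equal(b_fast$input, b_ref$input, tolerance = 1e-10)
  expect_equal(b_fast$kernel, b_ref$kernel, tolerance = 1e-10)
  expect_equal(b_fast$u, b_ref$u, tolerance = 1e-8)
  expect_equal(b_fast$v, b_ref$v, tolerance = 1e-8)
  for (stride in c(1L, 2L)) {
    c_ref <- cpp_conv2d_forward(A, K, b, stride, 1L)
    c_fast <- conv2d_forward_fast(A, K, b, stride, 1L)
    expect_equal(c_fast$out, c_ref, tolerance = 1e-10)
    gs <- with_seed(12, array(rnorm(length(c_ref)), dim = dim(c_ref)))
    d_ref <- cpp_conv2d_backward(A, K, gs, stride, 1L)
    d_fast <- conv2d_backward_fast(A, K, gs, stride, 1L, c_fast$cols, c_fast$sr)
    expect_equal(d_fast$input, d_ref$input, tolerance = 1e-10)
    expect_equal(d_fast$weight, d_ref$weight, tolerance = 1e-10)
    expect_equal(d_fast$bias, d_ref$bias, tolerance = 1e-10)
  }
})

test_that("averaged-kernel magnitude is bounded by max|k| / (H*W)", {
  for (s in 1:10) {
    k <- with_seed(s, matrix(rnorm(9), 3, 3))
    phi_raw <- with_seed(s + 50, matrix(runif(9), 3, 3))
    phi <- phi_raw / sum(phi_raw)
    expect_lte(abs(average_kernel(k, phi)), max(abs(k)) / 9 + 1e-12)
  }
})

test_that("the literal kernel-update rule matches a hand-evaluated oracle", {
  # constant phi: both spatial gradients vanish -> no update
  k <- matrix(1:9, 3, 3)
  upd <- literal_kernel_update(k, matrix(1 / 9, 3, 3))
  expect_equal(upd$kernel, k)
  expect_equal(upd$weight_delta, 0)
  # zero kernel -> zero delta
  expect_equal(literal_kernel_update(matrix(0, 3, 3),
                                     matrix(runif(9) / 9, 3, 3))$weight_delta, 0)
  # general case against an explicit double loop with central differences
  phi_raw <- with_seed(3, matrix(runif(9), 3, 3))
  phi <- phi_raw / sum(phi_raw)
  k <- with_seed(4, matrix(rnorm(9), 3, 3))
  gx <- matrix(0, 3, 3); gy <- matrix(0, 3, 3)
  for (mm in 1:3) for (nn in 1:3) {
    gx[mm, nn] <- (phi[min(mm + 1, 3), nn] - phi[max(mm - 1, 1), nn]) / 2
    gy[mm, nn] <- (phi[mm, min(nn + 1, 3)] - phi[mm, max(nn - 1, 1)]) / 2
  }
  dW <- 0
  for (mm in 1:3) for (nn in 1:3)
    dW <- dW + k[mm, nn] * phi[mm, nn] * gx[mm, nn] * gy[mm, nn]
  upd <- literal_kernel_update(k, phi, step = 0.5)
  expect_equal(upd$weight_delta, dW, tolerance = 1e-12)
  expect_equal(upd$kernel, k - 0.5 * phi * dW, tolerance = 1e-12)
})

test_that("the backbone honours its stride contract and is seed-stable", {
  arch <- micro_arch()
  m1 <- build_model(arch, seed = 6)
  m2 <- build_model(arch, seed = 6)
  expect_identical(m1$params, m2$params)
  img <- make_test_image(16, seed = 2)
  f1 <- adcn_forward(img, m1$backbone)
  expect_equal(dim(f1), c(4, 4, 8))
  expect_equal(attr(f1, "stride"), 4)
  expect_identical(f1, adcn_forward(img, m2$backbone))
})

test_that("ablated backbone equals the plain-convolution oracle", {
  arch <- micro_arch()
  m <- build_model(arch, seed = 8)
  img <- make_test_image(16, seed = 3)
  got <- adcn_forward(img, m$backbone, ablation = TRUE)
  # oracle: run each block with standard convolutions, uniform modulation
  x <- img
  for (b in seq_along(m$backbone$blocks)) {
    bp <- m$backbone$blocks[[b]]
    stride <- arch$strides[b]
    a1 <- pmax(cpp_conv2d_forward(x, bp$W1, bp$b1, stride, 1L), 0)
    kbar <- average_kernel(bp$B, matrix(1 / 9, 3, 3))
    z <- cpp_conv2d_forward(a1, kbar, bp$b2, 1L, 1L)
    sc <- if (is.null(bp$Wsc)) x else cpp_conv2d_forward(x, bp$Wsc, bp$bsc, stride, 0L)
    x <- pmax(z + sc, 0)
  }
  expect_lt(max(abs(got - x)), 1e-5)
})

test_that("attention maps export as NPY arrays and PNG heatmaps", {
  dir <- withr::local_tempdir()
  phi <- compute_attention_map(with_seed(5, array(rnorm(48), dim = c(4, 4, 3))))
  npy <- file.path(dir, "phi.npy")
  write_npy(unclass(phi), npy)
  got <- system2("python", "-", stdout = TRUE, input = sprintf(
    "import numpy as np; a = np.load(%s); print(a.shape, round(float(a.sum()), 6))",
    shQuote(npy)))
  expect_match(got, "\\(4, 4\\) 1\\.0")
  png <- file.path(dir, "phi.png")
  export_attention_png(phi, png, upscale = 4L)
  hm <- read_png(png)
  expect_equal(dim(hm)[1:2], c(16L, 16L))
  expect_equal(max(hm), 255L)
})
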