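test_that("layer norm follows its defining formula", {
  expect_equal(layer_norm(c(1, -1, 1, -1), eps = 0), c(1, -1, 1, -1))
  expect_equal(layer_norm(c(5, 5, 5), gamma = 1, beta = 2), rep(2, 3))
  expect_equal(layer_norm(c(0, 2), gamma = 2, beta = 1, eps = 0), c(-1, 3))
  # matrix form normalises row-wise
  X <- rbind(c(0, 2), c(4, 8))
  expect_equal(layer_norm(X, eps = 0), rbind(c(-1, 1), c(-1, 1)))
})

test_that("single-token attention weight is exactly 1", {
  p <- with_seed(1, init_attention(4, 2))
  X <- with_seed(2, matrix(rnorm(4), 1, 4))
  fw <- mhsa_forward(X, X, p, heads = 2)
  for (A in fw$attention) expect_equal(as.vector(A), 1)
  expect_equal(fw$out, (X %*% p$wv) %*% p$wo, tolerance = 1e-12)
})

test_that("zero query projection gives uniform attention over tokens", {
  p <- with_seed(3, init_attention(4, 2))
  p$wq <- matrix(0, 4, 4)
  X <- with_seed(4, matrix(rnorm(5 * 4), 5, 4))
  fw <- mhsa_forward(X, X, p, heads = 2)
  for (A in fw$attention) expect_equal(unname(A), matrix(1 / 5, 5, 5),
                                       tolerance = 1e-12)
  mean_v <- matrix(colMeans(X %*% p$wv), 5, 4, byrow = TRUE)
  expect_equal(fw$out, mean_v %*% p$wo, tolerance = 1e-12)
})

test_that("attention matches the brute-force oracle on small instances", {
  # scalar case: n = 2, one head, d = 1
  wq <- matrix(0.7); wk <- matrix(-1.2); wv <- matrix(0.9); wo <- matrix(1.3)
  X <- matrix(c(0.5, -1), 2, 1)
  got <- mhsa_forward(X, X, list(wq = wq, wk = wk, wv = wv, wo = wo), 1)$out
  expect_equal(got, oracle_attention(X, wq, wk, wv, wo), tolerance = 1e-12)
  # larger single-head case
  with_seed(5, {
    X <- matrix(rnorm(3 * 4), 3, 4)
    p <- init_attention(4, 1)
  })
  expect_equal(mhsa_forward(X, X, p, 1)$out,
               oracle_attention(X, p$wq, p$wk, p$wv, p$wo), tolerance = 1e-10)
})

test_that("encoder block is a pre-norm residual composition", {
  with_seed(6, {
    bp <- init_encoder_block(4, 2)
    X <- matrix(rnorm(6 * 4), 6, 4)
  })
  # zeroed output projections -> pure residual pass-through
  bp0 <- bp
  bp0$attn$wo[] <- 0
  bp0$mlp$W2[] <- 0; bp0$mlp$b2[] <- 0
  expect_equal(encoder_block(X, bp0, heads = 2), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  # equals the explicit composition of the unit operations
  l1 <- layer_norm(X, bp$ln1$gamma, bp$ln1$beta)
  Z1 <- mhsa_forward(l1, l1, bp$attn, 2)$out + X
  l2 <- layer_norm(Z1, bp$ln2$gamma, bp$ln2$beta)
  H <- gelu(sweep(l2 %*% bp$mlp$W1, 2, bp$mlp$b1, `+`))
  Z2 <- sweep(H %*% bp$mlp$W2, 2, bp$mlp$b2, `+`) + Z1
  expect_equal(unclass(encoder_block(X, bp, heads = 2)), Z2,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("encode stacks blocks sequentially", {
  with_seed(7, {
    blocks <- replicate(2, init_encoder_block(4, 2), simplify = FALSE)
    X <- matrix(rnorm(5 * 4), 5, 4)
  })
  st <- encode(X, blocks, heads = 2)
  step1 <- encoder_block(X, blocks[[1]], 2)
  step2 <- encoder_block(unclass(step1), blocks[[2]], 2)
  expect_equal(st$F, unclass(step2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dim(st$F), dim(X))
})

test_that("decoder follows the three-stage form (no Z3 residual)", {
  d <- 4
  with_seed(8, {
    dp <- init_decoder(d, 2)
    Fmat <- matrix(rnorm(6 * d), 6, d)
    Tq <- matrix(rnorm(2 * d), 2, d)
  })
  # zeroed projections: Z3 = Z4 = Z5 = 0 because the query self-attention
  # stage carries no residual
  dp0 <- dp
  dp0$self$wo[] <- 0
  dp0$cross$wo[] <- 0
  dp0$mlp$W2[] <- 0; dp0$mlp$b2[] <- 0
  st0 <- decode(Fmat, Tq, dp0, heads = 2)
  expect_equal(max(abs(st0$Z3)), 0)
  expect_equal(max(abs(st0$Z5)), 0)
  # identical query tokens give identical embeddings
  st_sym <- decode(Fmat, rbind(Tq[1, ], Tq[1, ]), dp, heads = 2)
  expect_equal(st_sym$qe[1, ], st_sym$qe[2, ], tolerance = 1e-12)
  # matches the hand-composed oracle
  st <- decode(Fmat, Tq, dp, heads = 2)
  l1 <- layer_norm(Tq, dp$ln1$gamma, dp$ln1$beta)
  Z3 <- mhsa_forward(l1, l1, dp$self, 2)$out
  l2 <- layer_norm(Z3, dp$ln2$gamma, dp$ln2$beta)
  Z4 <- mhsa_forward(l2, Fmat, dp$cross, 2)$out + Z3
  l3 <- layer_norm(Z4, dp$ln3$gamma, dp$ln3$beta)
  H <- gelu(sweep(l3 %*% dp$mlp$W1, 2, dp$mlp$b1, `+`))
  Z5 <- sweep(H %*% dp$mlp$W2, 2, dp$mlp$b2, `+`) + Z4
  expect_equal(st$Z5, Z5, tolerance = 1e-10)
})

test_that("build_mask scores patches by inner product and breaks ties to background", {
  # hand-set logits on a 2x2 grid via orthogonal features/queries
  Fmat <- rbind(c(1, 0), c(0, 1), c(2, 0), c(0, 3))
  qe <- rbind(c(0, 1), c(1, 0))  # row 1 background, row 2 polyp
  sm <- build_mask(Fmat, qe, grid_shape = c(2, 2), out_size = 2)
  # logits: patch (f . qe_c); row-major patches
  expect_equal(sm$logits[1, 1, ], c(0, 1))
  expect_equal(sm$logits[1, 2, ], c(1, 0))
  expect_equal(sm$labels, rbind(c(1, 0), c(1, 0)))
  # equal logits everywhere -> all background
  sm0 <- build_mask(matrix(0, 4, 2), matrix(0, 2, 2), out_size = 4)
  expect_equal(sum(sm0$labels), 0)
  # upsampling contract
  sm2 <- build_mask(Fmat, qe, grid_shape = c(2, 2), out_size = 8)
  expect_equal(dim(sm2$labels), c(8L, 8L))
  expect_true(all(sm2$labels %in% c(0, 1)))
})

test_that("all attention rows sum to one across random configurations", {
  for (s in 1:25) {
    with_seed(s, {
      d <- sample(c(4, 8), 1)
      h <- sample(c(1, 2, 4), 1)
      n <- sample(2:9, 1)
      p <- init_attention(d, h)
      X <- matrix(rnorm(n * d), n, d)
      Fmat <- matrix(rnorm(7 * d), 7, d)
    })
    fw <- mhsa_forward(X, X, p, h)
    for (A in fw$attention)
      expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
    cr <- mhsa_forward(X, Fmat, p, h)
    for (A in cr$attention)
      expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
  }
})

test_that("encoder is permutation-equivariant once positions are attached", {
  with_seed(9, {
    blocks <- replicate(2, init_encoder_block(6, 2), simplify = FALSE)
    X <- matrix(rnorm(8 * 6), 8, 6)
    perm <- sample(8)
  })
  F1 <- encode(X, blocks, heads = 2)$F
  F2 <- encode(X[perm, ], blocks, heads = 2)$F
  expect_equal(F2, F1[perm, ], tolerance = 1e-10)
})

test_that("zero-weight decoder output yields an all-background mask", {
  arch <- micro_arch()
  m <- build_model(arch, seed = 10)
  m$params$queries[] <- 0
  m$params$decoder$self$wo[] <- 0
  m$params$decoder$cross$wo[] <- 0
  m$params$decoder$mlp$W2[] <- 0
  m$params$decoder$mlp$b2[] <- 0
  fw <- model_forward(m, make_test_image(16, 4))
  expect_equal(sum(fw$labels), 0)
})

test_that("full-scale forward pass maps 256x256 to a clean binary mask", {
  m <- build_model(polypvit_arch(), seed = 1)
  img <- make_test_image(256, seed = 5)
  fw <- model_forward(m, img)
  expect_equal(dim(fw$labels), c(256L, 256L))
  expect_true(all(fw$labels %in% c(0, 1)))
  expect_false(any(is.na(fw$prob)))
  expect_equal(dim(fw$logits_grid), c(16L, 16L, 2L))
})
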