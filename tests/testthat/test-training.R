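tiny_train_arch <- function() {
  polypvit_arch(image_size = 32L, widths = c(8L, 16L, 16L, 16L),
                strides = c(2L, 2L, 1L, 1L), heads = 4L, depth = 1L,
                mlp_ratio = 2L)
}

test_that("cross-entropy loss matches analytic values", {
  mk_prob <- function(p2) array(c(1 - p2, p2), dim = c(dim(p2), 2))
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  # perfect one-hot predictions
  expect_lt(cross_entropy_loss(mk_prob(ones), ones), 1e-10)
  expect_lt(cross_entropy_loss(mk_prob(zeros), zeros), 1e-10)
  # uniform prediction: ln 2
  expect_equal(cross_entropy_loss(mk_prob(matrix(0.5, 3, 3)), matrix(1, 3, 3)),
               log(2), tolerance = 1e-9)
  # two pixels with P(true) = 0.8 and 0.5
  p2 <- matrix(c(0.8, 0.5), 1, 2)
  y <- matrix(1, 1, 2)
  expect_equal(cross_entropy_loss(mk_prob(p2), y), -(log(0.8) + log(0.5)) / 2,
               tolerance = 1e-9)
  expect_error(cross_entropy_loss(array(0.4, dim = c(2, 2, 2)), ones),
               class = "polypvit_data_error")
})

test_that("learning-rate schedule decays by the stated factor every period", {
  tc <- train_config()
  expect_equal(lr_at_epoch(0, tc), 0.001)
  expect_equal(lr_at_epoch(19, tc), 0.001)
  expect_equal(lr_at_epoch(20, tc), 1e-5)
  expect_equal(lr_at_epoch(40, tc), 1e-7)
  tc99 <- train_config(decay_factor = 0.99)
  expect_equal(lr_at_epoch(20, tc99), 0.001 * 0.99)
})

test_that("channel dropout zeroes whole channels and rescales survivors", {
  X <- matrix(1, 5, 8)
  expect_identical(channel_dropout(X, 0), X)
  expect_identical(channel_dropout(X, 0.4, training = FALSE), X)
  expect_equal(max(abs(with_seed(1, channel_dropout(X, 1)))), 0)
  out <- with_seed(2, channel_dropout(X, 0.5))
  cols <- colSums(abs(out)) > 0
  expect_true(all(out[, cols] == 2))         # 1 / (1 - 0.5)
  expect_true(all(out[, !cols] == 0))
  # empirical rate over many channels within 3 binomial sd
  big <- with_seed(3, channel_dropout(matrix(1, 1, 10000), 0.3))
  frac <- mean(big == 0)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # array form drops along the channel dimension
  arr <- with_seed(4, channel_dropout(array(1, dim = c(3, 3, 50)), 0.5))
  per_ch <- apply(arr, 3, function(m) length(unique(as.vector(m))))
  expect_true(all(per_ch == 1))
})

test_that("build_model variants differ structurally and are seed-stable", {
  arch <- micro_arch()
  full <- build_model(arch, "full", seed = 2)
  abl <- build_model(arch, "resnet_only", seed = 2)
  expect_true(!is.null(full$params$backbone[[1]]$B))
  expect_true(!is.null(full$params$peg))
  expect_null(full$params$pos_embed)
  expect_null(abl$params$backbone[[1]]$B)
  expect_true(!is.null(abl$params$backbone[[1]]$W2))
  expect_true(!is.null(abl$params$pos_embed))
  expect_identical(build_model(arch, "full", seed = 2)$params, full$params)
  img <- make_test_image(16, 1)
  expect_equal(dim(predict_mask(full, img)), c(16L, 16L))
  expect_equal(dim(predict_mask(abl, img)), c(16L, 16L))
})

test_that("one epoch trains, logs history and writes a checkpoint", {
  arch <- tiny_train_arch()
  cfg <- synthetic_config(image_size = 32)
  data <- generate_dataset(8, cfg, seed = 5)
  ck <- file.path(withr::local_tempdir(), "ck.rds")
  fit <- train(build_model(arch, seed = 3), data[1:6], data[7:8],
               train_config(epochs = 1, batch_size = 2, dropout_site = "none",
                            seed = 4),
               checkpoint_path = ck)
  expect_equal(nrow(fit$history), 1)
  expect_true(file.exists(ck))
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss", "val_dice") %in%
                    names(fit$history)))
  back <- load_checkpoint(ck)
  img <- data[[1]]$image
  expect_identical(predict_mask(back, img), predict_mask(fit$model, img))
})

test_that("fifty optimisation steps strictly reduce the training loss", {
  arch <- tiny_train_arch()
  cfg <- synthetic_config(image_size = 32)
  data <- generate_dataset(24, cfg, seed = 6)
  model <- build_model(arch, seed = 7)
  fit <- train(model, data,
               config = train_config(epochs = 10, batch_size = 4,
                                     dropout_site = "none", seed = 8,
                                     max_steps = 50))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("training is bit-reproducible with dropout off", {
  arch <- tiny_train_arch()
  cfg <- synthetic_config(image_size = 32)
  data <- generate_dataset(6, cfg, seed = 9)
  run <- function() {
    train(build_model(arch, seed = 1), data,
          config = train_config(epochs = 2, batch_size = 3,
                                dropout_site = "none", seed = 2))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$final$params, f2$final$params)
  expect_identical(f1$history, f2$history)
})

test_that("the literal kernel-update flag changes the ADCN trajectory", {
  arch <- tiny_train_arch()
  cfg <- synthetic_config(image_size = 32)
  data <- generate_dataset(4, cfg, seed = 10)
  base <- train_config(epochs = 1, batch_size = 4, dropout_site = "none",
                       seed = 3, max_steps = 1)
  lit <- base; lit$literal_kernel_updates <- TRUE
  f_auto <- train(build_model(arch, seed = 5), data, config = base)
  f_lit <- train(build_model(arch, seed = 5), data, config = lit)
  expect_gt(max(abs(f_auto$final$params$backbone[[1]]$B -
                      f_lit$final$params$backbone[[1]]$B)), 0)
  # non-ADCN parameters still follow the loss gradient in both runs
  expect_gt(max(abs(f_auto$final$params$queries)), 0)
})

test_that("checkpoints round-trip bitwise", {
  m <- build_model(micro_arch(), seed = 11)
  path <- file.path(withr::local_tempdir(), "m.rds")
  save_checkpoint(m, path, extra = list(fold = 2L))
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_equal(attr(back, "extra")$fold, 2L)
  img <- make_test_image(16, 3)
  expect_identical(model_forward(m, img)$logits_up,
                   model_forward(back, img)$logits_up)
})

test_that("autodiff through the deformable convolution matches numerics", {
  # 5x5 single-channel instance, smooth loss (sum of squares)
  with_seed(12, {
    A <- array(rnorm(25), dim = c(5, 5, 1))
    K <- array(rnorm(9), dim = c(3, 3, 1, 1))
    u <- runif(3, -0.7, 0.7); v <- runif(3, -0.7, 0.7)
  })
  fwd <- deform_forward_fast(A, K, u, v, TRUE)
  g <- 2 * fwd$out
  bk <- deform_backward_fast(A, K, u, v, TRUE, g, fwd$cols)
  loss_k <- function(kv) sum(deform_forward_fast(A, array(kv, dim = dim(K)),
                                                 u, v, TRUE)$out^2)
  nk <- numeric_grad(loss_k, as.vector(K))
  expect_lt(max(abs(nk - as.vector(bk$kernel)) /
                  pmax(abs(nk), abs(as.vector(bk$kernel)), 1e-6)), 1e-4)
  loss_u <- function(uv) sum(deform_forward_fast(A, K, uv, v, TRUE)$out^2)
  nu <- numeric_grad(loss_u, u)
  expect_lt(max(abs(nu - bk$u) / pmax(abs(nu), abs(bk$u), 1e-6)), 1e-4)
  loss_a <- function(av) sum(deform_forward_fast(array(av, dim = dim(A)),
                                                 K, u, v, TRUE)$out^2)
  na <- numeric_grad(loss_a, as.vector(A))
  expect_lt(max(abs(na - as.vector(bk$input)) /
                  pmax(abs(na), abs(as.vector(bk$input)), 1e-6)), 1e-4)
})

test_that("end-to-end parameter gradients match central differences", {
  arch <- micro_arch()
  m <- build_model(arch, ablation = "full", seed = 5)
  img <- make_test_image(16, 7)
  mask <- random_mask(16, 0.3, 8)
  lossfun <- function(model) {
    fw <- model_forward(model, img)
    -mean(log(pmax(ifelse(mask == 1, fw$prob[, , 2], fw$prob[, , 1]), 1e-12)))
  }
  fw <- model_forward(m, img, keep_cache = TRUE)
  g <- model_backward(m, fw, ce_grad_logits(fw$prob, mask))
  leaves_p <- nested_leaves(m$params)
  leaves_g <- nested_leaves(g)
  expect_identical(names(leaves_p), names(leaves_g))
  groups <- c("backbone.1.W1", "backbone.2.B", "peg", "encoder.1.attn.wq",
              "encoder.1.ln1.gamma", "queries", "decoder.cross.wk",
              "decoder.mlp.W1")
  with_seed(13, for (nm in groups) {
    n_par <- length(leaves_p[[nm]])
    for (ii in sample(n_par, min(3, n_par))) {
      perturb <- function(delta) {
        m2 <- m
        leaf <- nested_leaves(m2$params)[[nm]]
        path <- strsplit(nm, ".", fixed = TRUE)[[1]]
        node <- m2$params
        # walk down, modify, walk back up
        setval <- function(lst, path, idx, delta) {
          k <- path[1]
          k2 <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
          if (length(path) == 1) {
            lst[[k2]][idx] <- lst[[k2]][idx] + delta
          } else {
            lst[[k2]] <- setval(lst[[k2]], path[-1], idx, delta)
          }
          lst
        }
        m2$params <- setval(m2$params, path, ii, delta)
        m2$backbone$blocks <- m2$params$backbone
        m2
      }
      num <- (lossfun(perturb(1e-5)) - lossfun(perturb(-1e-5))) / 2e-5
      ana <- leaves_g[[nm]][ii]
      if (abs(num) + abs(ana) > 1e-9)
        expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 5e-3)
    }
  })
})
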