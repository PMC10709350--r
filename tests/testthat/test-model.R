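test_that("the classifier consumes 2-channel pairs and outputs a probability", {
  cfg <- tiny_cfg()
  m <- build_classifier(cfg, seed = 1)
  x <- rand_volume(c(8, 8, 8), seed = 1, channels = 2)
  fw <- forward_model(m, x)
  expect_true(fw$score >= 0 && fw$score <= 1)
  expect_error(forward_model(m, rand_volume(c(8, 8, 8), channels = 3)))
  # all-zero weights: sigmoid(0) = 0.5
  expect_equal(forward_model(zero_params(m), x)$score, 0.5)
})

test_that("grids too small for the stage count are rejected", {
  expect_error(encoder_config(input_shape = c(16, 16, 8),
                              channels = c(2, 2, 2, 2, 2)), "too small")
  expect_error(encoder_config(input_shape = c(16, 12, 8), channels = c(2, 2)),
               "square")
})

test_that("the equivariant classifier score is invariant under all 16 symmetries", {
  cfg <- tiny_cfg(shape = c(16, 16, 8), channels = c(2, 3), dropout = 0)
  m <- build_classifier(cfg, seed = 2)
  x <- rand_volume(c(16, 16, 8), seed = 3, channels = 2)
  s0 <- forward_model(m, x)$score
  for (g in 1:15)
    expect_lt(abs(forward_model(m, act_on_volume(g, x))$score - s0), 1e-4)
})

test_that("forward passes are deterministic with dropout disabled", {
  cfg <- tiny_cfg(dropout = 0.5)
  m <- build_classifier(cfg, seed = 4)
  x <- rand_volume(c(8, 8, 8), seed = 5, channels = 2)
  expect_identical(forward_model(m, x)$score, forward_model(m, x)$score)
})

test_that("baseline CNN and G-CNN are built from identical configurations", {
  cfg_g <- tiny_cfg(equivariant = TRUE)
  cfg_c <- tiny_cfg(equivariant = FALSE)
  expect_identical(cfg_g[setdiff(names(cfg_g), "equivariant")],
                   cfg_c[setdiff(names(cfg_c), "equivariant")])
  mg <- build_classifier(cfg_g, seed = 1)
  mc <- build_classifier(cfg_c, seed = 1)
  kinds_c <- vapply(mc$trunk, `[[`, "", "kind")
  kinds_g <- vapply(mg$trunk, `[[`, "", "kind")
  expect_identical(kinds_c[kinds_c %in% c("conv", "lift", "gconv")],
                   c("conv", "conv"))
  expect_identical(kinds_g[kinds_g %in% c("conv", "lift", "gconv")],
                   c("lift", "gconv"))
})

test_that("the autoencoder reconstructs at the input shape and learns", {
  cfg <- tiny_cfg(shape = c(8, 8, 6), channels = c(2, 3))  # odd halving on z
  m <- build_cae(cfg, seed = 6)
  x <- rand_volume(c(8, 8, 6), seed = 7, channels = 2)
  fw <- forward_model(m, x)
  expect_identical(dim(fw$recon), dim(x))
  # 50 optimization steps on one repeated input strictly decrease the error
  fit <- train_model(m, list(x), labels = NULL, train_idx = 1,
                     val_idx = integer(0),
                     cfg = train_config(lr = 0.05, epochs = 50, batch_size = 1,
                                        seed = 8, patience = Inf))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("encoder checkpoints transfer between architectures with integrity checks", {
  cfg <- tiny_cfg()
  cae <- build_cae(cfg, seed = 9)
  ckpt <- encoder_checkpoint(cae)
  m <- build_ae_regularized(cfg, init = "pretrained", checkpoint = ckpt,
                            seed = 10)
  for (i in seq_along(m$trunk))
    if (!is.null(m$trunk[[i]]$W))
      expect_identical(m$trunk[[i]]$W, cae$trunk[[i]]$W)
  cls <- build_classifier(cfg, seed = 11)
  cls2 <- init_encoder_from_checkpoint(cls, ckpt)
  expect_identical(cls2$trunk[[1]]$W, cae$trunk[[1]]$W)
  # incompatible shapes produce a layer-by-layer diff report
  other <- encoder_checkpoint(build_cae(tiny_cfg(channels = c(4, 3)), seed = 1))
  expect_error(init_encoder_from_checkpoint(cls, other), "layer 1")
  # round-trip through disk
  p <- tempfile(fileext = ".rds")
  save_checkpoint(ckpt, p)
  expect_identical(load_checkpoint(p)$weights[[1]]$W, ckpt$weights[[1]]$W)
})

test_that("the autoencoder-regularized model returns score and reconstruction", {
  cfg <- tiny_cfg()
  m <- build_ae_regularized(cfg, seed = 12)
  x <- rand_volume(c(8, 8, 8), seed = 13, channels = 2)
  fw <- forward_model(m, x)
  expect_true(fw$score >= 0 && fw$score <= 1)
  expect_identical(dim(fw$recon), dim(x))
  # alpha = 1: the combined objective reduces to the classification loss
  bce <- weighted_bce(fw$score, 1, c(1, 1))
  mse <- mean((fw$recon - x)^2)
  expect_identical(combined_loss(bce, mse, 1), bce)
  sp <- mismatchnet:::.sample_pass(m, x, 1, c(1, 1), alpha = 1,
                                   training = FALSE, backward = FALSE)
  expect_equal(sp$loss, bce)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_cfg()
  m <- build_ae_regularized(cfg, seed = 14)
  # random biases avoid exact ReLU kinks, where subgradients are ambiguous
  for (part in c("trunk", "cls_head", "rec_head"))
    for (i in seq_along(m[[part]]))
      if (!is.null(m[[part]][[i]]$b))
        m[[part]][[i]]$b <- stats::rnorm(length(m[[part]][[i]]$b), sd = 0.1)
  x <- rand_volume(c(8, 8, 8), seed = 15, channels = 2)
  y <- 1; wts <- c(1.2, 0.9); alpha <- 0.6
  loss_fn <- function(model) {
    fw <- forward_model(model, x)
    alpha * weighted_bce(fw$score, y, wts) + (1 - alpha) * mean((fw$recon - x)^2)
  }
  fw <- forward_model(m, x)
  bk <- mismatchnet:::.backward_model(
    m, fw$caches, dlogit = alpha * wts[2] * (fw$score - y),
    drecon = (1 - alpha) * 2 * (fw$recon - x) / length(x))
  eps <- 1e-6
  set.seed(16)
  for (part in c("trunk", "cls_head", "rec_head")) {
    for (i in seq_along(m[[part]])) {
      if (is.null(m[[part]][[i]]$W)) next
      j <- sample(length(m[[part]][[i]]$W), 1)
      m2 <- m; m2[[part]][[i]]$W[j] <- m2[[part]][[i]]$W[j] + eps
      m3 <- m; m3[[part]][[i]]$W[j] <- m3[[part]][[i]]$W[j] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      ana <- bk$grads[[part]][[i]]$W[j]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})
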