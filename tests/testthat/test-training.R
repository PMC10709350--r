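test_that("splits reproduce the printed cohort accounting at n = 489", {
  ids <- sprintf("P%03d", 1:489)
  plan <- make_splits(ids, seed = 42)
  tests <- lapply(1:4, function(f) fold_members(plan, f, "test"))
  expect_true(all(lengths(tests) == 122))
  # disjoint test sets covering all but n mod 4 patients
  expect_equal(length(unique(unlist(tests))), 488)
  leftover <- setdiff(ids, unlist(tests))
  expect_length(leftover, 1)
  for (f in 1:4) {
    expect_true(all(plan$assign[leftover, f] == "train"))
    tr <- fold_members(plan, f, "train"); va <- fold_members(plan, f, "val")
    te <- fold_members(plan, f, "test")
    expect_length(va, 92)        # floor(489 * 0.19)
    expect_length(tr, 275)       # 489 - 122 - 92 (floor remainder to train)
    expect_setequal(c(tr, va, te), ids)  # partition within each fold
  }
})

test_that("splits are deterministic in the seed and reject degenerate cohorts", {
  ids <- letters[1:8]
  p1 <- make_splits(ids, seed = 7)
  p2 <- make_splits(ids, seed = 7)
  expect_identical(p1$assign, p2$assign)
  p3 <- make_splits(ids, seed = 8)
  expect_false(identical(p1$assign, p3$assign))
  tests <- lapply(1:4, function(f) fold_members(p1, f, "test"))
  expect_true(all(lengths(tests) == 2))
  expect_equal(length(unique(unlist(tests))), 8)
  expect_error(make_splits(letters[1:3], seed = 1), "at least 4")
  expect_error(make_splits(c("a", "a", "b", "c"), seed = 1), "unique")
})

test_that("class weights balance the weighted class masses exactly", {
  expect_equal(class_weights(rep(0:1, 10)), c(w0 = 1, w1 = 1))
  # printed cohort counts: 212 early / 277 late of 489
  w <- class_weights(rep(c(1, 0), c(212, 277)))
  expect_equal(unname(w["w1"]), 489 / (2 * 212))
  expect_equal(unname(w["w0"]), 489 / (2 * 277))
  set.seed(31)
  for (rep in 1:100) {
    l <- c(0, 1, rbinom(sample(5:50, 1), 1, runif(1, 0.2, 0.8)))
    w <- class_weights(l)
    expect_equal(w["w0"] * sum(l == 0), w["w1"] * sum(l == 1),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(w["w0"] * sum(l == 0)), length(l) / 2)
  }
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("the weighted cross-entropy matches hand arithmetic", {
  expect_lt(weighted_bce(c(0.999999, 1e-6), c(1, 0)), 1e-5)
  s <- c(0.9, 0.2, 0.6, 0.4); y <- c(1, 0, 0, 1)
  expect_equal(weighted_bce(s, y), mean(-(y * log(s) + (1 - y) * log(1 - s))))
  w <- c(0.8827, 1.1533)
  byhand <- mean(c(-1.1533 * log(0.9), -0.8827 * log(0.8),
                   -0.8827 * log(0.4), -1.1533 * log(0.4)))
  expect_equal(weighted_bce(s, y, w), byhand)
  # clamping keeps degenerate scores finite
  expect_true(is.finite(weighted_bce(c(0, 1), c(1, 0))))
})

test_that("the aggregated loss interpolates its two components", {
  expect_identical(combined_loss(0.8, 0.2, 1), 0.8)
  expect_identical(combined_loss(0.8, 0.2, 0), 0.2)
  expect_identical(combined_loss(0.8, 0.2, 0.5), 0.5)
  expect_error(combined_loss(1, 1, 1.5), "alpha")
})

test_that("SGD training reduces the loss and is seed-deterministic", {
  cfg <- tiny_cfg(channels = c(2, 2), fc = c(4, 3))
  m <- build_classifier(cfg, seed = 40)
  set.seed(41)
  inputs <- lapply(1:4, function(i) rand_volume(c(8, 8, 8), channels = 2))
  labels <- c(0, 1, 0, 1)
  fit <- train_model(m, inputs, labels, train_idx = 1:4, val_idx = integer(0),
                     cfg = train_config(lr = 0.05, epochs = 50, batch_size = 4,
                                        seed = 42, alpha = 1))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  refit <- function() {
    train_model(build_classifier(cfg, seed = 40), inputs, labels, 1:4,
                integer(0), train_config(lr = 0.05, epochs = 3,
                                         batch_size = 2, seed = 43))
  }
  f1 <- refit(); f2 <- refit()
  expect_identical(f1$model$trunk[[1]]$W, f2$model$trunk[[1]]$W)
  expect_identical(f1$history, f2$history)
})

test_that("CAE pre-training consumes the combined cohorts and exports weights", {
  cohort <- generate_cohort(phantom_config(
    grid = c(16, 16, 8), n_labeled = 3, n_unlabeled = 2, seed = 50))
  expect_equal(nrow(cohort$table), 5)  # labeled + unlabeled
  inputs <- cohort_inputs(cohort, ids = cohort$table$patient_id)
  cae <- build_cae(tiny_cfg(shape = c(16, 16, 8), channels = c(2, 2),
                            bottleneck = 2), seed = 51)
  pt <- pretrain_cae(cae, inputs, train_config(lr = 0.01, epochs = 1,
                                               batch_size = 2, seed = 52))
  expect_identical(pt$checkpoint$format, "mismatchnet-encoder-v1")
  expect_equal(length(pt$checkpoint$weights), length(cae$trunk))
})
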