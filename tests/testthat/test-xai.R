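test_that("noise-free SmoothGrad is the plain absolute gradient, independent of n and seed", {
  m <- build_classifier(tiny_cfg(), seed = 90)
  x <- rand_volume(c(8, 8, 8), seed = 91, channels = 2)
  s1 <- smoothgrad(m, x, n = 1, sigma = 0, seed = 1)
  s5 <- smoothgrad(m, x, n = 5, sigma = 0, seed = 99)
  expect_identical(as.vector(s1), as.vector(s5))
  # bit-for-bit equal to the raw logit gradient
  fw <- forward_model(m, x)
  gin <- mismatchnet:::.backward_model(m, fw$caches, dlogit = 1)$gin
  expect_identical(as.vector(s1), as.vector(abs(gin)))
  expect_true(all(s1 >= 0))
  expect_identical(dim(s1), dim(x))
})

test_that("saliency is invariant to a constant shift of the logit", {
  m <- build_classifier(tiny_cfg(), seed = 92)
  x <- rand_volume(c(8, 8, 8), seed = 93, channels = 2)
  s1 <- smoothgrad(m, x, n = 1, sigma = 0)
  m2 <- m
  last <- length(m2$cls_head)
  m2$cls_head[[last]]$b <- m2$cls_head[[last]]$b + 3.7
  s2 <- smoothgrad(m2, x, n = 1, sigma = 0)
  expect_identical(as.vector(s1), as.vector(s2))
})

test_that("saliency of the invariant network commutes with the group action", {
  m <- build_classifier(tiny_cfg(shape = c(16, 16, 8), channels = c(2, 3)),
                        seed = 94)
  x <- rand_volume(c(16, 16, 8), seed = 95, channels = 2)
  s <- smoothgrad(m, x, n = 1, sigma = 0)
  for (g in c(1, 5, 8, 13)) {
    sg <- smoothgrad(m, act_on_volume(g, x), n = 1, sigma = 0)
    expect_lt(max(abs(sg - act_on_volume(g, unclass(s)))), 1e-4)
  }
})

test_that("heatmap thresholding is monotone with full and empty extremes", {
  set.seed(96)
  sal <- array(runif(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  expect_true(all(threshold_heatmap(sal, 0)))
  expect_false(any(threshold_heatmap(sal, 1.01)))
  lo <- threshold_heatmap(sal, 0.3)
  hi <- threshold_heatmap(sal, 0.7)
  expect_true(all(lo[hi]))  # higher threshold is a subset of lower
})

test_that("localization scoring reports coverage and Dice against lesion masks", {
  lesion <- array(FALSE, c(8, 8, 4))
  lesion[3:5, 3:5, 2:3] <- TRUE
  mask <- array(FALSE, c(8, 8, 4, 2))
  mask[, , , 1] <- lesion
  mask[, , , 2] <- lesion
  r <- localization_score(mask, lesion)
  expect_equal(unname(r$coverage), c(1, 1))
  expect_equal(unname(r$dice), c(1, 1))
  expect_true(r$well_localized)
  disjoint <- array(FALSE, c(8, 8, 4, 2))
  disjoint[7:8, 7:8, 1, ] <- TRUE
  r2 <- localization_score(disjoint, lesion)
  expect_equal(unname(r2$coverage), c(0, 0))
  expect_false(r2$well_localized)
})

test_that("saliency volumes are written as viewable NIfTI aligned to the input", {
  m <- build_classifier(tiny_cfg(), seed = 97)
  x <- rand_volume(c(8, 8, 8), seed = 98, channels = 2)
  sal <- smoothgrad(m, x, n = 2, sigma = 0.1, seed = 99)
  paths <- write_saliency(sal, tempfile())
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[1])
  expect_equal(dim(back), c(8L, 8L, 8L))
  expect_equal(as.numeric(max(abs(back - sal[, , , 1]))), 0, tolerance = 1e-6)
})
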