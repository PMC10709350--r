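test_that("lifting convolution produces 16 orientation channels and is equivariant", {
  spec <- gconv_spec(2, 3, c(3, 3, 3), "lifting")
  w <- gconv_init(spec, seed = 3)
  v <- rand_volume(c(16, 16, 8), seed = 2, channels = 2)
  L <- lifting_conv(v, spec, w)
  expect_identical(dim(L), c(16L, 16L, 8L, 16L, 3L))
  for (g in 0:15) {
    err <- max(abs(lifting_conv(act_on_volume(g, v), spec, w) -
                     act_on_oriented(g, L)))
    expect_lt(err, 1e-5)
  }
})

test_that("a 1x1x1 lifting kernel yields 16 identical orientation channels", {
  spec <- gconv_spec(2, 2, c(1, 1, 1), "lifting")
  w <- gconv_init(spec, seed = 5)
  L <- lifting_conv(rand_volume(c(6, 6, 4), seed = 6, channels = 2), spec, w)
  for (g in 2:16) expect_equal(L[, , , g, ], L[, , , 1, ])
})

test_that("group convolution is equivariant and stacks preserve equivariance", {
  sp1 <- gconv_spec(2, 3, c(3, 3, 3), "lifting")
  w1 <- gconv_init(sp1, seed = 3)
  sp2 <- gconv_spec(3, 2, c(3, 3, 3), "group")
  w2 <- gconv_init(sp2, seed = 4)
  sp3 <- gconv_spec(2, 2, c(3, 3, 3), "group")
  w3 <- gconv_init(sp3, seed = 5)
  v <- rand_volume(c(12, 12, 6), seed = 7, channels = 2)
  f <- lifting_conv(v, sp1, w1)
  G1 <- group_conv(f, sp2, w2)
  G2 <- group_conv(G1, sp3, w3)  # two stacked group convolutions
  for (g in 0:15) {
    fg <- act_on_oriented(g, f)
    expect_lt(max(abs(group_conv(fg, sp2, w2) - act_on_oriented(g, G1))), 1e-5)
    expect_lt(max(abs(group_conv(group_conv(fg, sp2, w2), sp3, w3) -
                        act_on_oriented(g, G2))), 1e-5)
  }
})

test_that("a delta kernel with only the identity-orientation tap is the identity map", {
  C <- 2
  spec <- gconv_spec(C, C, c(3, 3, 3), "group")
  w <- gconv_init(spec, seed = 8)
  w$W[] <- 0
  w$b[] <- 0
  for (c in seq_len(C)) w$W[2, 2, 2, 1, c, c] <- 1  # center tap, identity orientation
  f <- rand_volume(c(8, 8, 4), seed = 9, channels = c(16, C))
  expect_equal(group_conv(f, spec, w), f)
})

test_that("orientation pooling is symmetric and transform-consistent", {
  f <- rand_volume(c(6, 6, 4), seed = 10, channels = c(16, 2))
  cst <- array(1.5, c(4, 4, 2, 16, 1))
  expect_true(all(orientation_pool(cst, "max") == 1.5))
  expect_true(all(abs(orientation_pool(cst, "mean") - 1.5) < 1e-12))
  perm <- sample(16)
  expect_equal(orientation_pool(f[, , , perm, , drop = FALSE], "max"),
               orientation_pool(f, "max"))
  expect_equal(orientation_pool(f[, , , perm, , drop = FALSE], "mean"),
               orientation_pool(f, "mean"))
  for (g in 0:15)
    expect_identical(orientation_pool(act_on_oriented(g, f), "max"),
                     act_on_volume(g, orientation_pool(f, "max")))
})

test_that("invalid layer specifications are rejected", {
  expect_error(gconv_spec(2, 3, c(2, 2, 3), "lifting"), "odd")
  expect_error(gconv_spec(2, 3, c(3, 5, 3), "lifting"), "square")
  sp <- gconv_spec(3, 2, c(3, 3, 3), "group")
  w <- gconv_init(sp, seed = 1)
  bad <- rand_volume(c(6, 6, 4), channels = c(16, 2))  # 2 channels, spec wants 3
  expect_error(group_conv(bad, sp, w), "mismatch")
})

test_that("weights are shared across orientations, not replicated", {
  spl <- gconv_spec(2, 5, c(3, 3, 3), "lifting")
  expect_identical(gconv_param_count(spl), 27L * 2L * 5L + 5L)
  spg <- gconv_spec(4, 5, c(3, 3, 3), "group")
  # equals a plain 3D conv consuming the flattened 16 x 4 channels
  expect_identical(gconv_param_count(spg), 27L * (16L * 4L) * 5L + 5L)
  m <- build_classifier(tiny_cfg(equivariant = TRUE), seed = 1)
  expect_identical(length(m$trunk[[1]]$W), 3L * 3L * 3L * 2L * 2L)
})
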