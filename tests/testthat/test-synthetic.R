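test_that("cohort generation is reproducible down to the written CSV", {
  cfg <- phantom_config(grid = c(16, 16, 8), n_labeled = 4, n_unlabeled = 2,
                        seed = 60)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$patients, c2$patients)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_cohort(c1, d1); write_cohort(c2, d2)
  strip_paths <- function(d) {
    x <- readLines(file.path(d, "cohort.csv"))
    gsub(d, "", x, fixed = TRUE)
  }
  expect_identical(strip_paths(d1), strip_paths(d2))
})

test_that("FLAIR conspicuity rises with onset time; DWI lesions always visible", {
  cfg <- phantom_config(seed = 61)
  t <- seq(0.5, 24, by = 0.5)
  expect_true(all(diff(flair_contrast_curve(t, cfg)) > 0))
  co <- generate_cohort(phantom_config(grid = c(32, 32, 16), n_labeled = 40,
                                       n_unlabeled = 0, noise_sd = 0,
                                       seed = 62))
  lab <- co$table[co$table$cohort == "labeled", ]
  expect_gt(mean(lab$flair_contrast[lab$label == 0]),
            mean(lab$flair_contrast[lab$label == 1]))
  # recompute lesion contrast from the voxel data itself
  meas <- vapply(lab$patient_id, function(id) {
    p <- co$patients[[id]]
    mean(p$flair[p$lesion_mask]) - mean(p$flair[!p$lesion_mask & p$flair != 0])
  }, numeric(1))
  expect_gt(mean(meas[lab$label == 0]), mean(meas[lab$label == 1]))
  dwi_contrast <- vapply(lab$patient_id, function(id) {
    p <- co$patients[[id]]
    mean(p$dwi[p$lesion_mask]) - mean(p$dwi[!p$lesion_mask & p$dwi != 0])
  }, numeric(1))
  # far above the 0.08 noise floor (slack for lesions overlapping the
  # dark ventricle structures)
  expect_true(all(dwi_contrast > 0.6))
})

test_that("volumes are coregistered by construction and grids match the config", {
  co <- generate_cohort(phantom_config(grid = c(16, 16, 8), n_labeled = 2,
                                       n_unlabeled = 2, seed = 63))
  for (p in co$patients) {
    expect_identical(dim(p$dwi), c(16L, 16L, 8L))
    expect_identical(dim(p$dwi), dim(p$flair))
    expect_identical(dim(p$dwi), dim(p$lesion_mask))
  }
})

test_that("the labeled cohort prevalence tracks the configured class balance", {
  co <- generate_cohort(phantom_config(n_labeled = 4000, n_unlabeled = 0,
                                       p_acute = 0.4335, seed = 64),
                        volumes = FALSE)
  lab <- co$table[co$table$cohort == "labeled", ]
  expect_lt(abs(mean(lab$label) - 0.4335), 0.02)
  expect_true(all(lab$label == as.integer(lab$time_to_mri_h <= 4.5)))
})

test_that("the unlabeled cohort has shifted characteristics", {
  co <- generate_cohort(phantom_config(grid = c(16, 16, 8), n_labeled = 0,
                                       n_unlabeled = 400, seed = 65),
                        volumes = FALSE)
  un <- co$table[co$table$cohort == "unlabeled", ]
  expect_true(all(is.na(un$label)))
  expect_lt(mean(un$lesion_present), 0.8)    # a fraction lesion-free
  expect_gt(mean(is.na(un$time_to_mri_h)), 0.25)  # onset often unknown
})

test_that("synthetic raters hit their configured operating point", {
  set.seed(66)
  labels <- rbinom(10000, 1, 0.45)
  rt <- generate_raters(labels, model = rater_model(1, 1, 0, seed = 67))
  expect_identical(ratings_to_calls(rt$rating), as.integer(labels))
  rt0 <- generate_raters(labels, model = rater_model(0.5, 0.5, 1, seed = 68))
  expect_true(all(rt0$rating == "indeterminable"))
  rt2 <- generate_raters(labels, model = rater_model(0.62, 0.78, 0, seed = 69))
  calls <- ratings_to_calls(rt2$rating)
  expect_lt(abs(mean(calls[labels == 1] == 1) - 0.62), 0.02)
  expect_lt(abs(mean(calls[labels == 0] == 0) - 0.78), 0.02)
})

test_that("indeterminable selection is biased toward low-contrast cases", {
  set.seed(70)
  labels <- rbinom(4000, 1, 0.5)
  contrast <- runif(4000)
  rt <- generate_raters(labels, contrast,
                        rater_model(0.8, 0.8, 0.3, seed = 71))
  ind <- rt$rating == "indeterminable"
  expect_equal(mean(ind), 0.3, tolerance = 0.01)
  expect_lt(mean(contrast[ind]), mean(contrast[!ind]))
})
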