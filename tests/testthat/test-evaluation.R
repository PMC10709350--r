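# Exhaustive brute-force oracles for AUC and both thresholding rules.

auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

best_J_exhaustive <- function(scores, labels) {
  cand <- c(sort(unique(scores)) - 1e-9, max(scores) + 1)
  max(vapply(cand, function(t) {
    calls <- as.integer(scores >= t)
    sens <- sum(calls & labels) / sum(labels)
    spec <- sum(!calls & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1)))
}

test_that("AUC equals the Mann-Whitney pair-counting oracle exactly", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)  # ties likely
    expect_identical(roc_auc(scores, labels), auc_paircount(scores, labels))
  }
  # null behaviour at large n
  set.seed(22)
  labels <- rbinom(20000, 1, 0.5); scores <- runif(20000)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.02)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- rbinom(200, 1, 0.4); scores <- runif(200) + 0.3 * labels
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("the Youden threshold matches exhaustive search", {
  r <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$J, 1)
  expect_true(r$threshold > 0.2 && r$threshold < 0.8)
  expect_equal(youden_threshold(rep(0.5, 10), rep(0:1, 5))$J, 0)
  set.seed(24)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)
    r <- youden_threshold(scores, labels)
    expect_equal(r$J, best_J_exhaustive(scores, labels), tolerance = 1e-12)
    # the returned threshold actually achieves the reported J
    ss <- mismatchnet:::.sens_spec(as.integer(scores >= r$threshold), labels)
    expect_equal(unname(ss["sens"] + ss["spec"] - 1), r$J)
  }
})

test_that("sensitivity calibration returns the largest admissible threshold", {
  s <- c(0.1, 0.4, 0.6, 0.9); l <- c(0, 1, 0, 1)
  expect_gt(calibrate_to_sensitivity(s, l, 0), max(s))
  expect_lt(calibrate_to_sensitivity(s, l, 1), 0.4)  # below min positive score
  expect_error(calibrate_to_sensitivity(s, l, 1.2), "target")
  set.seed(25)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)
    target <- sample(c(0.3, 0.62, 0.9), 1)
    thr <- calibrate_to_sensitivity(scores, labels, target)
    sens_at <- function(t) {
      ss <- mismatchnet:::.sens_spec(as.integer(scores >= t), labels)
      unname(ss["sens"])
    }
    expect_gte(sens_at(thr), target)
    larger <- mismatchnet:::.threshold_candidates(scores)
    larger <- larger[larger > thr]
    for (t2 in larger) expect_lt(sens_at(t2), target)
  }
})

test_that("confusion metrics reproduce the human-benchmark arithmetic", {
  # an operating point with sensitivity 0.620 and specificity 0.780 has
  # balanced accuracy 0.700
  labels <- rep(c(1, 0), c(500, 500))
  calls <- calls_with_rates(labels, 0.62, 0.78)
  m <- confusion_metrics(calls, labels)
  expect_equal(m$sensitivity, 0.620)
  expect_equal(m$specificity, 0.780)
  expect_equal(m$balanced_accuracy, 0.700)
  # identity bAcc = (sens + spec)/2 and the all-correct case
  m2 <- confusion_metrics(labels, labels)
  expect_equal(unlist(m2[c("sensitivity", "specificity", "balanced_accuracy")]),
               c(sensitivity = 1, specificity = 1, balanced_accuracy = 1))
  set.seed(26)
  for (rep in 1:20) {
    l <- c(0, 1, rbinom(18, 1, 0.5)); cl <- rbinom(20, 1, 0.5)
    m3 <- confusion_metrics(cl, l)
    tp <- sum(cl & l); fn <- sum(!cl & l); tn <- sum(!cl & !l); fp <- sum(cl & !l)
    expect_equal(m3$sensitivity, tp / (tp + fn))
    expect_equal(m3$specificity, tn / (tn + fp))
    expect_equal(m3$balanced_accuracy,
                 (m3$sensitivity + m3$specificity) / 2)
  }
  expect_warning(confusion_metrics(c(0, 1), c(0, 0)), "NaN")
})

test_that("categorical ratings map to binary calls with indeterminable as late", {
  expect_identical(ratings_to_calls(rep("mismatch", 3)), rep(1L, 3))
  expect_identical(ratings_to_calls(rep("indeterminable", 3)), rep(0L, 3))
  expect_identical(
    ratings_to_calls(c("mismatch", "no_mismatch", "indeterminable")),
    c(1L, 0L, 0L))
  expect_error(ratings_to_calls("maybe"), "ratings")
})

test_that("augmentation replaces exactly the indeterminable entries", {
  r <- c("mismatch", "indeterminable", "no_mismatch", "indeterminable")
  dl <- c(0L, 1L, 1L, 0L)
  expect_identical(augment_ratings(r, dl), c(1L, 1L, 0L, 0L))
  # no indeterminables: identical to the plain mapping
  r2 <- c("mismatch", "no_mismatch")
  expect_identical(augment_ratings(r2, c(0L, 1L)), ratings_to_calls(r2))
  # all indeterminable: equals the model calls
  expect_identical(augment_ratings(rep("indeterminable", 4), dl), dl)
  set.seed(27)
  for (rep in 1:20) {
    rr <- sample(c("mismatch", "no_mismatch", "indeterminable"), 30, TRUE)
    dd <- rbinom(30, 1, 0.5)
    out <- augment_ratings(rr, dd)
    keep <- rr != "indeterminable"
    expect_identical(out[keep], ratings_to_calls(rr)[keep])
    expect_identical(out[!keep], as.integer(dd[!keep]))
  }
})

test_that("Cohen's kappa matches the closed form and its symmetries", {
  a <- rbinom(50, 1, 0.5)
  expect_equal(cohens_kappa(a, a), 1)
  expect_equal(cohens_kappa(rep(1, 50), a), 0)  # constant rater: p_o = p_e
  # 2x2 table (40, 10; 20, 30): p_o = 0.7, p_e = 0.5, kappa = 0.4
  x <- rep(c(0, 0, 1, 1), c(40, 10, 20, 30))
  y <- rep(c(0, 1, 0, 1), c(40, 10, 20, 30))
  expect_equal(cohens_kappa(x, y), 0.4)
  expect_equal(cohens_kappa(y, x), 0.4)          # symmetric
  expect_equal(cohens_kappa(1 - x, 1 - y), 0.4)  # consistent relabeling
  expect_warning(k <- cohens_kappa(rep(1, 5), rep(1, 5)), "constant")
  expect_equal(k, 1)
  # three-category mode keeps indeterminable separate
  r1 <- c("mismatch", "indeterminable", "no_mismatch")
  expect_equal(cohens_kappa(r1, r1, categories = "three"), 1)
})

test_that("bootstrap-Wilcoxon detects a real gap and not a null one", {
  set.seed(28)
  labels <- rbinom(500, 1, 0.45)
  a <- calls_with_rates(labels, 0.60, 0.85)
  b <- calls_with_rates(labels, 0.35, 0.85)
  bw <- bootstrap_wilcoxon(a, b, labels, metric = "sensitivity", N = 200,
                           M = 100, seed = 5)
  expect_true(bw$significant)
  expect_lt(abs(bw$boot_mean["a"] - bw$full["a"]), 0.01)
  expect_lt(abs(bw$boot_mean["b"] - bw$full["b"]), 0.01)
  expect_warning(bw0 <- bootstrap_wilcoxon(a, a, labels, N = 100, M = 20,
                                           seed = 6), "zero")
  expect_equal(bw0$p_value, 1)
  expect_false(bw0$significant)
})
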