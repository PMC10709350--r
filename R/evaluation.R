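#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outscores
#' a random negative, with ties counted 1/2 (rank formula).
#'
#' @param scores numeric scores, higher = more likely class 1.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Candidate thresholds: midpoints of consecutive sorted unique scores plus
# sentinels below the minimum and above the maximum. Calls use score >= t.
.threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(u[1] - 1, mids, u[length(u)] + 1)
}

.sens_spec <- function(calls, labels) {
  tp <- sum(calls == 1 & labels == 1); fn <- sum(calls == 0 & labels == 1)
  tn <- sum(calls == 0 & labels == 0); fp <- sum(calls == 1 & labels == 0)
  c(sens = if (tp + fn > 0) tp / (tp + fn) else NaN,
    spec = if (tn + fp > 0) tn / (tn + fp) else NaN)
}

#' Youden-index threshold
#'
#' Returns the threshold maximizing J = sensitivity + specificity - 1 over
#' all candidate thresholds (midpoints of sorted unique scores plus
#' sentinels). Ties are broken toward the larger threshold (higher
#' specificity).
#'
#' @inheritParams roc_auc
#' @return list with `threshold` and `J`.
#' @export
youden_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2)
    stop("Youden threshold undefined: both classes must be present")
  cand <- .threshold_candidates(scores)
  J <- vapply(cand, function(t) {
    ss <- .sens_spec(as.integer(scores >= t), labels)
    ss["sens"] + ss["spec"] - 1
  }, numeric(1))
  best <- max(J)
  thr <- max(cand[J >= best - 1e-12])
  list(threshold = thr, J = best)
}

#' Calibrate a threshold to a target sensitivity on validation data
#'
#' Returns the largest candidate threshold whose validation sensitivity is at
#' least `target` (the clinically calibrated operating point: match the
#' human-benchmark sensitivity on the validation set, then freeze the
#' threshold for the test set). Sensitivity is non-increasing in the
#' threshold, so the largest admissible threshold also has the highest
#' specificity among admissible ones.
#'
#' @param val_scores,val_labels validation scores and 0/1 labels.
#' @param target target sensitivity in \[0, 1\]; default 0.62, the
#'   multicenter human DWI-FLAIR mismatch benchmark.
#' @return the calibrated threshold.
#' @export
calibrate_to_sensitivity <- function(val_scores, val_labels, target = 0.62) {
  if (target < 0 || target > 1) stop("target sensitivity must be in [0, 1]")
  if (length(unique(val_labels)) < 2)
    stop("both classes must be present in the validation set")
  cand <- sort(.threshold_candidates(val_scores), decreasing = TRUE)
  for (t in cand) {
    ss <- .sens_spec(as.integer(val_scores >= t), val_labels)
    if (!is.nan(ss["sens"]) && ss["sens"] >= target) return(t)
  }
  cand[length(cand)]  # unreachable for target <= 1: the lowest threshold calls all positive
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and balanced accuracy
#' (their mean). Undefined metrics (a class absent) are NaN with a warning.
#'
#' @param calls 0/1 predicted calls.
#' @param labels 0/1 reference labels.
#' @param threshold threshold that produced the calls (bookkeeping only).
#' @return a `metrics_report` list: sensitivity, specificity,
#'   balanced_accuracy, threshold, n.
#' @export
confusion_metrics <- function(calls, labels, threshold = NA_real_) {
  stopifnot(length(calls) == length(labels))
  ss <- .sens_spec(calls, labels)
  if (any(is.nan(ss)))
    warning("a class is absent; the corresponding metric is NaN")
  structure(list(sensitivity = unname(ss["sens"]),
                 specificity = unname(ss["spec"]),
                 balanced_accuracy = unname((ss["sens"] + ss["spec"]) / 2),
                 threshold = threshold, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  sensitivity = %.3f  specificity = %.3f  balanced accuracy = %.3f\n",
    x$n, x$sensitivity, x$specificity, x$balanced_accuracy))
  invisible(x)
}

.check_ratings <- function(ratings) {
  ok <- ratings %in% c("mismatch", "no_mismatch", "indeterminable")
  if (!all(ok))
    stop("ratings must be 'mismatch', 'no_mismatch' or 'indeterminable'; got: ",
         paste(unique(ratings[!ok]), collapse = ", "))
  invisible(ratings)
}

#' Map categorical mismatch ratings to binary onset calls
#'
#' `mismatch` (lesion visible on DWI but not FLAIR) means onset within
#' 4.5 h, call 1. `no_mismatch` means later onset, call 0. `indeterminable`
#' is counted as call 0 (> 4.5 h), since such patients would be excluded
#' from thrombolysis.
#'
#' @param ratings character vector in
#'   `{mismatch, no_mismatch, indeterminable}`.
#' @return integer 0/1 vector.
#' @export
ratings_to_calls <- function(ratings) {
  .check_ratings(ratings)
  as.integer(ratings == "mismatch")
}

#' Augment human ratings with model predictions
#'
#' The "second opinion" scenario: where the human rating is indeterminable
#' the model's binary call is used; everywhere else the human rating stands.
#'
#' @param ratings character ratings (see [ratings_to_calls()]).
#' @param dl_calls 0/1 model calls, same patients in the same order.
#' @return integer 0/1 vector.
#' @export
augment_ratings <- function(ratings, dl_calls) {
  .check_ratings(ratings)
  stopifnot(length(ratings) == length(dl_calls))
  out <- ratings_to_calls(ratings)
  ind <- ratings == "indeterminable"
  out[ind] <- as.integer(dl_calls[ind])
  out
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' expected agreement from the marginal products. By default categorical
#' ratings are first mapped to binary calls (indeterminable counted as the
#' late-onset class); `categories = "three"` keeps indeterminable as its
#' own category.
#'
#' @param a,b rating vectors: either 0/1 calls or characters in
#'   `{mismatch, no_mismatch, indeterminable}`.
#' @param categories `"binary"` or `"three"`.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b, categories = c("binary", "three")) {
  categories <- match.arg(categories)
  stopifnot(length(a) == length(b))
  if (is.character(a) || is.factor(a)) {
    if (categories == "binary") {
      a <- ratings_to_calls(as.character(a)); b <- ratings_to_calls(as.character(b))
      lev <- c(0, 1)
    } else {
      lev <- c("mismatch", "no_mismatch", "indeterminable")
    }
  } else {
    lev <- c(0, 1)
  }
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  tab <- table(ta, tb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - 1e-12) {
    warning("both raters are constant with the same class; kappa defined as 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

.metric_value <- function(calls, labels, metric) {
  ss <- .sens_spec(calls, labels)
  switch(metric,
         sensitivity = unname(ss["sens"]),
         specificity = unname(ss["spec"]),
         balanced_accuracy = unname((ss["sens"] + ss["spec"]) / 2),
         stop("unknown metric: ", metric))
}

#' Bootstrap + Wilcoxon signed-rank comparison of two rating schemes
#'
#' Samples `N` patients with replacement from the cohort, computes the
#' performance metric for both schemes on the same sampled patients, and
#' repeats `M` times, forming paired metric values. `M` is doubled (up to
#' `max_M`) until the mean bootstrap metric of each scheme is within `tol`
#' of its full-cohort value. Significance of the paired differences is
#' assessed by a two-sided Wilcoxon signed-rank test (zero differences
#' dropped; exact distribution for <= 25 untied nonzero pairs, normal
#' approximation with tie correction otherwise, via [stats::wilcox.test()]).
#'
#' @param calls_a,calls_b 0/1 call vectors of the two schemes.
#' @param labels 0/1 reference labels.
#' @param metric `"balanced_accuracy"`, `"sensitivity"` or `"specificity"`.
#' @param N bootstrap subset size (default 200).
#' @param M initial number of bootstrap repetitions.
#' @param seed RNG seed.
#' @param tol convergence tolerance on the bootstrap mean (default 0.01).
#' @param max_M repetition cap for the auto-increase.
#' @param alpha significance level (default 0.05).
#' @return a `bootstrap_test` list: `p_value`, `significant`, `M`, `pairs`
#'   (data frame of per-bootstrap metric pairs), `full` and `boot_mean`
#'   per-scheme metric values.
#' @export
bootstrap_wilcoxon <- function(calls_a, calls_b, labels,
                               metric = c("balanced_accuracy", "sensitivity",
                                          "specificity"),
                               N = 200, M = 200, seed = 1, tol = 0.01,
                               max_M = 10000, alpha = 0.05) {
  metric <- match.arg(metric)
  n <- length(labels)
  stopifnot(length(calls_a) == n, length(calls_b) == n, M >= 10, N >= 1)
  full_a <- .metric_value(calls_a, labels, metric)
  full_b <- .metric_value(calls_b, labels, metric)
  set.seed(as.integer(seed))
  ma <- numeric(0); mb <- numeric(0)
  m_target <- as.integer(M)
  repeat {
    need <- m_target - length(ma)
    for (r in seq_len(need)) {
      idx <- sample.int(n, N, replace = TRUE)
      ma <- c(ma, .metric_value(calls_a[idx], labels[idx], metric))
      mb <- c(mb, .metric_value(calls_b[idx], labels[idx], metric))
    }
    converged <- is.finite(mean(ma)) && is.finite(mean(mb)) &&
      abs(mean(ma, na.rm = TRUE) - full_a) < tol &&
      abs(mean(mb, na.rm = TRUE) - full_b) < tol
    if (converged || m_target >= max_M) break
    m_target <- min(2L * m_target, as.integer(max_M))
  }
  d <- ma - mb
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warning("all paired differences are zero; p = 1")
    p <- 1
  } else {
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    p <- suppressWarnings(
      stats::wilcox.test(nz, mu = 0, exact = exact, correct = TRUE)$p.value)
  }
  structure(list(p_value = p, significant = p < alpha, M = length(ma),
                 pairs = data.frame(a = ma, b = mb),
                 full = c(a = full_a, b = full_b),
                 boot_mean = c(a = mean(ma, na.rm = TRUE),
                               b = mean(mb, na.rm = TRUE)),
                 metric = metric, N = N),
            class = "bootstrap_test")
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat(sprintf(
    "bootstrap (N = %d, M = %d) %s: full %.3f vs %.3f; Wilcoxon p = %.4g%s\n",
    x$N, x$M, x$metric, x$full["a"], x$full["b"], x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}
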