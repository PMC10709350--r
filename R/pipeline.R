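#' Pipeline configuration
#'
#' Bundles every stage's settings with preset problem sizes. `"smoke"` is a
#' minutes-scale end-to-end check; `"desk"` the default workstation-scale
#' study; `"paper-shape"` uses the clinical 192 x 192 x 50 working grid for
#' shape compatibility only (no training at that size).
#'
#' @param preset `"smoke"`, `"desk"` or `"paper-shape"`.
#' @param seed master seed; all stage seeds derive from it.
#' @param ... named overrides of any config field (phantom, model, train,
#'   eval settings).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("smoke", "desk", "paper-shape"),
                            seed = 1, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    smoke = list(
      phantom = phantom_config(grid = c(16, 16, 8), n_labeled = 24,
                               n_unlabeled = 8, seed = seed),
      work_grid = c(16, 16, 8),
      model = encoder_config(input_shape = c(16, 16, 8), channels = c(2, 4),
                             kernel = c(3, 3, 3), fc = c(8, 8),
                             dropout = 0.1, bottleneck = 4),
      train = train_config(lr = 0.02, epochs = 2, batch_size = 4, seed = seed),
      n_folds = 2, pretrain = FALSE, variant = "classifier"),
    desk = list(
      phantom = phantom_config(n_labeled = 200, n_unlabeled = 60, seed = seed),
      work_grid = c(32, 32, 16),
      model = encoder_config(input_shape = c(32, 32, 16), channels = c(4, 8),
                             kernel = c(3, 3, 3), fc = c(16, 8),
                             dropout = 0.1, bottleneck = 8),
      train = train_config(lr = 0.01, epochs = 12, batch_size = 8, seed = seed),
      n_folds = 4, pretrain = FALSE, variant = "classifier"),
    `paper-shape` = list(
      phantom = phantom_config(grid = c(192, 192, 64), n_labeled = 2,
                               n_unlabeled = 0, seed = seed),
      work_grid = c(192, 192, 50),
      model = encoder_config(input_shape = c(192, 192, 50)),
      train = train_config(seed = seed),
      n_folds = 2, pretrain = FALSE, variant = "classifier"))
  cfg <- utils::modifyList(base, list(...))
  cfg$preset <- preset
  cfg$seed <- as.integer(seed)
  cfg$target_sensitivity <- cfg$target_sensitivity %||% 0.62
  cfg$bootstrap_N <- cfg$bootstrap_N %||% 200
  cfg$bootstrap_M <- cfg$bootstrap_M %||% 100
  cfg$alpha_level <- cfg$alpha_level %||% 0.05
  cfg$raters <- cfg$raters %||% list(
    senior = rater_model(0.45, 0.88, 0.09, seed = seed + 101),
    junior = rater_model(0.35, 0.90, 0.18, seed = seed + 102))
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_stage <- function(con, stage, ...) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage, ...)
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con)
  message(sprintf("[%s] %s", stage, paste(names(list(...)), unlist(list(...)),
                                          sep = "=", collapse = " ")))
}

#' Run the full synthetic study end to end
#'
#' simulate -> preprocess -> (optional CAE pre-training) -> per-fold
#' training -> evaluation (Youden and sensitivity-calibrated operating
#' points, synthetic-rater augmentation, Cohen's kappa, bootstrap-Wilcoxon
#' tests) -> SmoothGrad explanation of example test cases -> report. All
#' outputs, a JSON-lines log and a manifest sufficient to reproduce the run
#' are written to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the metrics list (also written as `metrics.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out_dir, "log.jsonl"), open = "wt")
  on.exit(close(logcon))

  .log_stage(logcon, "simulate", preset = config$preset, seed = config$seed)
  cohort <- generate_cohort(config$phantom)
  lab <- cohort$table[cohort$table$cohort == "labeled", ]
  inputs <- cohort_inputs(cohort, target_shape = config$work_grid)
  labels <- lab$label

  .log_stage(logcon, "preprocess", n = length(inputs),
             grid = paste(config$work_grid, collapse = "x"))
  plan <- make_splits(lab$patient_id, seed = config$seed,
                      n_folds = config$n_folds)

  ckpt <- NULL
  if (isTRUE(config$pretrain)) {
    .log_stage(logcon, "pretrain", n = nrow(cohort$table))
    all_inputs <- cohort_inputs(cohort, ids = cohort$table$patient_id,
                                target_shape = config$work_grid)
    cae <- build_cae(config$model, seed = config$seed)
    pt <- pretrain_cae(cae, all_inputs, config$train)
    ckpt <- pt$checkpoint
    save_checkpoint(ckpt, file.path(out_dir, "cae_encoder.rds"))
    rm(all_inputs)
  }

  # standardize with the training statistics of fold 1 (one working scale
  # for all folds; per-fold refits change little on synthetic data)
  tr1 <- fold_members(plan, 1, "train", indices = TRUE)
  mu <- c(mean(unlist(lapply(inputs[tr1], function(x) x[, , , 1]))),
          mean(unlist(lapply(inputs[tr1], function(x) x[, , , 2]))))
  sd2 <- c(stats::sd(unlist(lapply(inputs[tr1], function(x) x[, , , 1]))),
           stats::sd(unlist(lapply(inputs[tr1], function(x) x[, , , 2]))))
  inputs <- lapply(inputs, function(x) {
    x[, , , 1] <- (x[, , , 1] - mu[1]) / sd2[1]
    x[, , , 2] <- (x[, , , 2] - mu[2]) / sd2[2]
    x
  })

  preds <- NULL
  models <- list()
  for (f in seq_len(config$n_folds)) {
    tr <- fold_members(plan, f, "train", indices = TRUE)
    va <- fold_members(plan, f, "val", indices = TRUE)
    te <- fold_members(plan, f, "test", indices = TRUE)
    model <- switch(config$variant,
      classifier = build_classifier(config$model, seed = config$seed + f),
      ae_regularized = build_ae_regularized(
        config$model, init = if (is.null(ckpt)) "random" else "pretrained",
        checkpoint = ckpt, seed = config$seed + f))
    cfg_f <- config$train
    cfg_f$seed <- config$train$seed + f
    fit <- train_model(model, inputs, labels, tr, va, cfg_f)
    models[[f]] <- fit$model
    val_scores <- predict_scores(fit$model, inputs[va])
    te_scores <- predict_scores(fit$model, inputs[te])
    if (length(unique(labels[va])) == 2) {
      thr_y <- youden_threshold(val_scores, labels[va])$threshold
      thr_c <- calibrate_to_sensitivity(val_scores, labels[va],
                                        config$target_sensitivity)
      val_auc <- roc_auc(val_scores, labels[va])
    } else {
      # degenerate (tiny) validation fold: fall back to the midpoint threshold
      thr_y <- thr_c <- 0.5
      val_auc <- NA_real_
    }
    preds <- rbind(preds, data.frame(
      patient_id = lab$patient_id[te], fold = f, score = te_scores,
      label = labels[te], call_youden = as.integer(te_scores >= thr_y),
      call_calibrated = as.integer(te_scores >= thr_c)))
    .log_stage(logcon, "train", fold = f, val_auc = round(val_auc, 3),
               thr_youden = round(thr_y, 3), thr_calibrated = round(thr_c, 3))
  }
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  .log_stage(logcon, "evaluate", n_test = nrow(preds))
  ord <- match(preds$patient_id, lab$patient_id)
  auc <- roc_auc(preds$score, preds$label)
  m_youden <- confusion_metrics(preds$call_youden, preds$label)
  m_cal <- confusion_metrics(preds$call_calibrated, preds$label)
  rater_rows <- list()
  kappa_rows <- list()
  rtabs <- list()
  for (rn in names(config$raters)) {
    rt <- generate_raters(preds$label, lab$flair_contrast[ord],
                          config$raters[[rn]], rater_id = rn,
                          patient_ids = preds$patient_id)
    rtabs[[rn]] <- rt
    human <- ratings_to_calls(rt$rating)
    augm <- augment_ratings(rt$rating, preds$call_calibrated)
    mh <- confusion_metrics(human, preds$label)
    ma <- confusion_metrics(augm, preds$label)
    bw <- bootstrap_wilcoxon(augm, human, preds$label,
                             N = min(config$bootstrap_N, nrow(preds)),
                             M = config$bootstrap_M, seed = config$seed,
                             alpha = config$alpha_level)
    rater_rows[[rn]] <- data.frame(
      rater = c(rn, paste0(rn, " + DL")),
      sensitivity = c(mh$sensitivity, ma$sensitivity),
      specificity = c(mh$specificity, ma$specificity),
      balanced_accuracy = c(mh$balanced_accuracy, ma$balanced_accuracy),
      delta_bacc = c(NA, ma$balanced_accuracy - mh$balanced_accuracy),
      p_value = c(NA, bw$p_value))
  }
  rater_table <- do.call(rbind, rater_rows)
  if (length(rtabs) >= 2) {
    nm <- names(rtabs)
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i >= j) next
      kappa_rows[[paste(nm[i], nm[j])]] <- data.frame(
        rater_1 = nm[i], rater_2 = nm[j],
        kappa = cohens_kappa(rtabs[[nm[i]]]$rating, rtabs[[nm[j]]]$rating),
        kappa_aug = cohens_kappa(
          augment_ratings(rtabs[[nm[i]]]$rating, preds$call_calibrated),
          augment_ratings(rtabs[[nm[j]]]$rating, preds$call_calibrated)))
    }
  }
  kappa_table <- if (length(kappa_rows)) do.call(rbind, kappa_rows) else NULL

  .log_stage(logcon, "explain", n_cases = min(2L, nrow(preds)))
  xai_rows <- list()
  for (i in seq_len(min(2L, nrow(preds)))) {
    pid <- preds$patient_id[i]
    sal <- smoothgrad(models[[preds$fold[i]]], inputs[[pid]], n = 8,
                      sigma = 0.1, seed = config$seed)
    write_saliency(sal, file.path(out_dir, paste0("saliency_", pid)))
    lm <- cohort$patients[[pid]]$lesion_mask
    lm_w <- array(resize_trilinear(as.vector(lm * 1), as.integer(dim(lm)),
                                   as.integer(config$work_grid)) > 0.5,
                  config$work_grid)
    loc <- localization_score(threshold_heatmap(sal, 0.25), lm_w)
    xai_rows[[pid]] <- data.frame(patient_id = pid,
                                  coverage_dwi = loc$coverage["dwi"],
                                  coverage_flair = loc$coverage["flair"],
                                  well_localized = loc$well_localized)
  }
  xai_table <- do.call(rbind, xai_rows)
  utils::write.csv(xai_table, file.path(out_dir, "localization.csv"),
                   row.names = FALSE)

  metrics <- list(
    auc = auc,
    youden = unclass(m_youden)[c("sensitivity", "specificity",
                                 "balanced_accuracy")],
    calibrated = unclass(m_cal)[c("sensitivity", "specificity",
                                  "balanced_accuracy")],
    raters = rater_table, kappa = kappa_table)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mismatchnet")),
                   preset = config$preset, seed = config$seed,
                   n_folds = config$n_folds, work_grid = config$work_grid,
                   phantom = unclass(config$phantom),
                   model = unclass(config$model), train = config$train,
                   target_sensitivity = config$target_sensitivity,
                   bootstrap = c(N = config$bootstrap_N, M = config$bootstrap_M))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  .log_stage(logcon, "report", auc = round(auc, 3),
             bacc_calibrated = round(m_cal$balanced_accuracy, 3))
  invisible(metrics)
}
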