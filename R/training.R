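#' Cross-validation split plan
#'
#' Random 4-fold cross-validation with train/validation/test ratios of
#' 56/19/25 percent. Each fold's three sets partition the cohort; test sets
#' are pairwise disjoint across folds. Set sizes use floor rounding with the
#' remainder assigned to the training set, so a 489-patient cohort yields
#' test folds of 122 patients. The plan is determined once from the seed and
#' reused by every model.
#'
#' @param patient_ids character or integer vector of unique patient ids.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param ratios train/validation/test fractions summing to 1.
#' @param n_folds number of folds (test fraction should be 1/n_folds for the
#'   test sets to tile the cohort).
#' @param stratify optional label vector (same length as `patient_ids`);
#'   when given, the random order interleaves classes so folds are
#'   approximately label-balanced.
#' @return a `split_plan`: list with `assign` (n x n_folds character matrix
#'   with entries train/val/test, rownames = patient ids), `ids`, `ratios`,
#'   `n_folds`, `seed`.
#' @export
make_splits <- function(patient_ids, seed, ratios = c(0.56, 0.19, 0.25),
                        n_folds = 4, stratify = NULL) {
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  if (n < n_folds) stop(sprintf("need at least %d patients for %d folds",
                                n_folds, n_folds))
  stopifnot(length(ratios) == 3, all(ratios > 0),
            isTRUE(all.equal(sum(ratios), 1)))
  set.seed(as.integer(seed))
  if (is.null(stratify)) {
    ord <- sample.int(n)
  } else {
    stopifnot(length(stratify) == n)
    # shuffle, then interleave classes by within-class rank
    sh <- sample.int(n)
    rk <- stats::ave(seq_along(sh), stratify[sh], FUN = seq_along)
    ord <- sh[order(rk, sample.int(n))]
  }
  tsize <- floor(n * ratios[3])
  vsize <- floor(n * ratios[2])
  remainder <- if (n_folds * tsize < n) ord[(n_folds * tsize + 1):n] else integer(0)
  assign <- matrix("train", n, n_folds,
                   dimnames = list(as.character(patient_ids),
                                   paste0("fold", seq_len(n_folds))))
  for (f in seq_len(n_folds)) {
    test_f <- ord[((f - 1) * tsize + 1):(f * tsize)]
    pool <- setdiff(ord, c(test_f, remainder))
    val_f <- pool[seq_len(vsize)]
    assign[test_f, f] <- "test"
    assign[val_f, f] <- "val"
  }
  structure(list(assign = assign, ids = patient_ids, ratios = ratios,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "split_plan")
}

#' Ids or indices of one fold/role of a split plan
#' @param plan a `split_plan`.
#' @param fold fold number.
#' @param role one of "train", "val", "test".
#' @param indices return integer positions instead of ids.
#' @export
fold_members <- function(plan, fold, role = c("train", "val", "test"),
                         indices = FALSE) {
  role <- match.arg(role)
  sel <- plan$assign[, fold] == role
  if (indices) which(sel) else plan$ids[sel]
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (2 * N_c)` for classes 0 and 1, so the weighted mass of
#' each class is balanced exactly: `w0 * N0 = w1 * N1 = N_total / 2`.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @return named numeric vector `c(w0, w1)`.
#' @export
class_weights <- function(labels) {
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0)
    stop("both classes must be present to define class weights")
  n <- n0 + n1
  c(w0 = n / (2 * n0), w1 = n / (2 * n1))
}

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of `-w_y * (y log s + (1 - y) log(1 - s))`. Scores are
#' clamped to `[eps, 1 - eps]` before the log.
#'
#' @param scores predicted probabilities in (0, 1).
#' @param labels 0/1 vector.
#' @param weights `c(w0, w1)` from [class_weights()]; default unweighted.
#' @param eps clamping epsilon.
#' @export
weighted_bce <- function(scores, labels, weights = c(1, 1), eps = 1e-7) {
  stopifnot(length(scores) == length(labels), all(weights > 0))
  s <- pmin(pmax(scores, eps), 1 - eps)
  w <- ifelse(labels == 1, weights[2], weights[1])
  mean(-w * (labels * log(s) + (1 - labels) * log(1 - s)))
}

#' Aggregate classification and reconstruction losses
#'
#' `L = alpha * L_bce + (1 - alpha) * L_mse`: the autoencoder-regularized
#' training objective. `alpha = 1` is pure classification, `alpha = 0` pure
#' reconstruction.
#'
#' @param bce,mse component loss values.
#' @param alpha weighting factor in \[0, 1\].
#' @export
combined_loss <- function(bce, mse, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * bce + (1 - alpha) * mse
}

#' Training hyperparameters
#'
#' @param lr learning rate of stochastic gradient descent.
#' @param momentum Nesterov momentum coefficient.
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size (gradients averaged over the batch).
#' @param alpha loss aggregation weight (used by autoencoder-regularized
#'   models; ignored otherwise).
#' @param seed master seed; fans out to shuffling and dropout.
#' @param patience early-stopping patience in epochs on the validation loss
#'   (`Inf` disables early stopping).
#' @param warmup number of initial epochs over which the learning rate ramps
#'   linearly from `lr / warmup` to `lr` (0 disables; guards against early
#'   ReLU die-off at high momentum).
#' @param verbose print one line per epoch.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, epochs = 10,
                         batch_size = 8, alpha = 0.5, seed = 1,
                         patience = Inf, warmup = 0, verbose = FALSE) {
  stopifnot(lr > 0, momentum >= 0, momentum < 1, epochs >= 1, batch_size >= 1,
            alpha >= 0, alpha <= 1, warmup >= 0)
  list(lr = lr, momentum = momentum, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), alpha = alpha,
       seed = as.integer(seed), patience = patience,
       warmup = as.integer(warmup), verbose = isTRUE(verbose))
}

# SGD + Nesterov momentum update (PyTorch convention):
# v <- mu*v + g ; step <- g + mu*v (nesterov) ; w <- w - lr*step
.sgd_update <- function(model, grads, state, cfg) {
  for (part in c("trunk", "cls_head", "rec_head")) {
    gpart <- grads[[part]]
    if (is.null(gpart)) next
    for (i in seq_along(gpart)) {
      gl <- gpart[[i]]
      if (is.null(gl)) next
      for (p in c("W", "b")) {
        v <- state[[part]][[i]][[p]]
        if (is.null(v)) v <- 0
        v <- cfg$momentum * v + gl[[p]]
        state[[part]][[i]][[p]] <- v
        step <- gl[[p]] + cfg$momentum * v
        model[[part]][[i]][[p]] <- model[[part]][[i]][[p]] - cfg$lr * step
      }
    }
  }
  list(model = model, state = state)
}

.add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (part in names(g)) {
    if (is.null(g[[part]])) next
    for (i in seq_along(g[[part]])) {
      if (is.null(g[[part]][[i]])) next
      acc[[part]][[i]]$W <- acc[[part]][[i]]$W + g[[part]][[i]]$W
      acc[[part]][[i]]$b <- acc[[part]][[i]]$b + g[[part]][[i]]$b
    }
  }
  acc
}

# Loss and (optionally) gradients of one sample under the combined objective.
.sample_pass <- function(model, x, y, wts, alpha, training, backward = TRUE) {
  fw <- forward_model(model, x, training = training)
  bce <- 0; mse <- 0
  dlogit <- NULL; drecon <- NULL
  if (!is.null(model$cls_head)) {
    bce <- weighted_bce(fw$score, y, wts)
    wy <- if (y == 1) wts[2] else wts[1]
    dlogit <- wy * (fw$score - y)
  }
  if (!is.null(model$rec_head)) {
    mse <- mean((fw$recon - x)^2)
    drecon <- 2 * (fw$recon - x) / length(x)
  }
  a <- if (is.null(model$cls_head)) 0 else if (is.null(model$rec_head)) 1 else alpha
  loss <- combined_loss(bce, mse, a)
  if (!backward) return(list(loss = loss, score = fw$score))
  if (!is.null(dlogit)) dlogit <- a * dlogit
  if (!is.null(drecon)) drecon <- (1 - a) * drecon
  if (is.null(model$cls_head)) drecon <- 2 * (fw$recon - x) / length(x)
  bk <- .backward_model(model, fw$caches,
                        dlogit = if (is.null(model$cls_head)) NULL else dlogit,
                        drecon = if (is.null(model$rec_head)) NULL else drecon)
  list(loss = loss, score = fw$score, grads = bk$grads)
}

.eval_loss <- function(model, inputs, labels, idx, wts, alpha) {
  if (!length(idx)) return(NA_real_)
  mean(vapply(idx, function(i) {
    y <- if (is.null(labels)) 0 else labels[i]
    .sample_pass(model, inputs[[i]], y, wts, alpha,
                 training = FALSE, backward = FALSE)$loss
  }, numeric(1)))
}

.scale_grads <- function(g, s) {
  for (part in names(g)) {
    if (is.null(g[[part]])) next
    for (i in seq_along(g[[part]])) {
      if (is.null(g[[part]][[i]])) next
      g[[part]][[i]]$W <- g[[part]][[i]]$W * s
      g[[part]][[i]]$b <- g[[part]][[i]]$b * s
    }
  }
  g
}

#' Train a model with SGD + Nesterov momentum
#'
#' Minimizes class-weighted binary cross-entropy (classifier), mean squared
#' reconstruction error (autoencoder), or their `alpha`-weighted aggregate
#' (autoencoder-regularized model). The best checkpoint by validation loss is
#' returned. Deterministic given `cfg$seed` under single-threaded execution.
#'
#' @param model a `mismatch_model`.
#' @param inputs list of input arrays (x, y, z, 2).
#' @param labels 0/1 vector (may be NULL for a pure autoencoder).
#' @param train_idx,val_idx integer indices into `inputs`.
#' @param cfg a [train_config()].
#' @param weights class weights; default computed from the training labels
#'   (NULL and no labels: unweighted).
#' @return list with `model` (best checkpoint), `history` (per-epoch data
#'   frame of train/val loss), `best_epoch`.
#' @export
train_model <- function(model, inputs, labels, train_idx, val_idx,
                        cfg = train_config(), weights = NULL) {
  has_cls <- !is.null(model$cls_head)
  if (has_cls && is.null(labels)) stop("labels required for a classifier")
  if (is.null(weights)) {
    weights <- if (has_cls && length(unique(labels[train_idx])) == 2)
      class_weights(labels[train_idx]) else c(1, 1)
  }
  set.seed(cfg$seed)
  state <- list(trunk = vector("list", length(model$trunk)),
                cls_head = vector("list", length(model$cls_head)),
                rec_head = vector("list", length(model$rec_head)))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, model = model, epoch = 0L)
  stall <- 0L
  for (ep in seq_len(cfg$epochs)) {
    cfg_ep <- cfg
    if (cfg$warmup > 0) cfg_ep$lr <- cfg$lr * min(1, ep / cfg$warmup)
    ord <- sample(train_idx)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      acc <- NULL
      bloss <- 0
      for (i in bidx) {
        y <- if (is.null(labels)) 0 else labels[i]
        sp <- .sample_pass(model, inputs[[i]], y, weights, cfg$alpha,
                           training = TRUE, backward = TRUE)
        if (!is.finite(sp$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d; ",
                       ep), "lower the learning rate")
        bloss <- bloss + sp$loss
        acc <- .add_grads(acc, sp$grads)
      }
      acc <- .scale_grads(acc, 1 / length(bidx))
      upd <- .sgd_update(model, acc, state, cfg_ep)
      model <- upd$model
      state <- upd$state
      ep_loss <- ep_loss + bloss / length(bidx)
      nb <- nb + 1L
    }
    vloss <- .eval_loss(model, inputs, labels, val_idx, weights, cfg$alpha)
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = vloss))
    if (cfg$verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss / nb, vloss))
    if (!is.na(vloss) && vloss < best$loss) {
      best <- list(loss = vloss, model = model, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  if (is.infinite(best$loss)) best$model <- model
  list(model = best$model, history = history, best_epoch = best$epoch)
}

#' Unsupervised pre-training of the convolutional autoencoder
#'
#' Trains a CAE (from [build_cae()]) on reconstruction of labeled plus
#' unlabeled volume pairs and returns the encoder checkpoint for transfer
#' into the supervised models.
#'
#' @param model a `mismatch_model` of type `"cae"`.
#' @param inputs list of input arrays (labeled + unlabeled cohorts).
#' @param cfg a [train_config()].
#' @param val_idx optional validation indices (checkpoint selection);
#'   defaults to all-train.
#' @return list with `model`, `checkpoint` (see [encoder_checkpoint()]),
#'   `history`.
#' @export
pretrain_cae <- function(model, inputs, cfg = train_config(),
                         val_idx = integer(0)) {
  if (model$type != "cae") stop("pretrain_cae expects a model from build_cae()")
  train_idx <- setdiff(seq_along(inputs), val_idx)
  fit <- train_model(model, inputs, labels = NULL, train_idx = train_idx,
                     val_idx = val_idx, cfg = cfg, weights = c(1, 1))
  list(model = fit$model, checkpoint = encoder_checkpoint(fit$model),
       history = fit$history)
}
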