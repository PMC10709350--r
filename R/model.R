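#' Encoder/architecture configuration
#'
#' Describes the shared encoder (stages of convolution + ReLU + 2x2x2
#' max-pooling, each stage halving the spatial dims), the classifier head
#' (global average pooling, two fully connected ReLU layers with dropout in
#' between, and a sigmoid output), and the autoencoder bottleneck/decoder.
#' Setting `equivariant = FALSE` swaps every group-equivariant layer for a
#' plain 3D convolution with the identical configuration; this flag is the
#' only difference between the baseline CNN and the G-CNN.
#'
#' @param input_shape working grid, default 192 x 192 x 50 (square in-plane).
#' @param channels feature channels per stage; its length sets the stage count.
#' @param kernel odd kernel extents (in-plane square).
#' @param equivariant build D4h group-equivariant layers (16 orientations).
#' @param dropout dropout probability between the two fully connected layers.
#' @param fc widths of the two fully connected layers.
#' @param bottleneck channel width of the 1x1x1 bottleneck convolution
#'   (autoencoder variants only).
#' @param norm apply instance normalization (per-sample, per-channel over
#'   space) after each encoder convolution; exactly preserves equivariance
#'   and stabilizes optimization when the discriminative signal is a small
#'   perturbation of a dominant background component.
#' @param width_factor multiplies all stage channel widths.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(input_shape = c(192, 192, 50),
                           channels = c(8, 16, 32, 64, 128),
                           kernel = c(3, 3, 3),
                           equivariant = TRUE,
                           dropout = 0.2,
                           fc = c(64, 32),
                           bottleneck = 32,
                           norm = TRUE,
                           width_factor = 1) {
  channels <- as.integer(ceiling(channels * width_factor))
  stages <- length(channels)
  stopifnot(stages >= 1, all(channels > 0), dropout >= 0, dropout < 1,
            length(kernel) == 3, all(kernel >= 1), length(fc) == 2,
            bottleneck >= 1)
  if (any(kernel %% 2 == 0))
    stop("kernel extents must be odd (centered 'same' padding)")
  if (equivariant && input_shape[1] != input_shape[2])
    stop("equivariant models require a square in-plane grid")
  if (any(input_shape %/% 2^stages < 1))
    stop(sprintf(
      "grid %s is too small to survive %d spatial halvings",
      paste(input_shape, collapse = "x"), stages))
  structure(list(input_shape = as.integer(input_shape), channels = channels,
                 stages = stages, kernel = as.integer(kernel),
                 equivariant = isTRUE(equivariant), dropout = dropout,
                 fc = as.integer(fc), bottleneck = as.integer(bottleneck),
                 norm = isTRUE(norm)),
            class = "encoder_config")
}

# Spatial shape after each encoder stage (floor halving).
.enc_shapes <- function(cfg) {
  shapes <- vector("list", cfg$stages)
  s <- cfg$input_shape
  for (i in seq_len(cfg$stages)) {
    s <- s %/% 2L
    shapes[[i]] <- s
  }
  shapes
}

.build_trunk <- function(cfg) {
  layers <- list()
  cin <- 2L
  for (s in seq_len(cfg$stages)) {
    conv <- if (!cfg$equivariant) .layer_conv(cin, cfg$channels[s], cfg$kernel)
            else if (s == 1L)     .layer_lift(cin, cfg$channels[s], cfg$kernel)
            else                  .layer_gconv(cin, cfg$channels[s], cfg$kernel)
    layers <- c(layers, list(conv))
    if (isTRUE(cfg$norm)) layers <- c(layers, list(.layer_inorm()))
    layers <- c(layers, list(.layer_relu(), .layer_maxpool()))
    cin <- cfg$channels[s]
  }
  if (cfg$equivariant) layers <- c(layers, list(.layer_orientpool("max")))
  layers
}

.build_cls_head <- function(cfg) {
  clast <- cfg$channels[cfg$stages]
  list(.layer_gap(),
       .layer_dense(clast, cfg$fc[1], "relu"),
       .layer_dropout(cfg$dropout),
       .layer_dense(cfg$fc[1], cfg$fc[2], "relu"),
       .layer_dense(cfg$fc[2], 1L, "linear"))
}

.build_rec_head <- function(cfg) {
  shapes <- .enc_shapes(cfg)
  targets <- c(rev(shapes)[-1], list(cfg$input_shape))
  clast <- cfg$channels[cfg$stages]
  dec_ch <- c(rev(cfg$channels[-cfg$stages]), cfg$channels[1])
  if (cfg$stages == 1L) dec_ch <- cfg$channels[1]
  layers <- list(.layer_conv(clast, cfg$bottleneck, c(1L, 1L, 1L)),
                 .layer_relu())
  cin <- cfg$bottleneck
  for (i in seq_len(cfg$stages)) {
    layers <- c(layers, list(.layer_upsample(target = targets[[i]]),
                             .layer_conv(cin, dec_ch[i], cfg$kernel),
                             .layer_relu()))
    cin <- dec_ch[i]
  }
  c(layers, list(.layer_conv(cin, 2L, cfg$kernel)))
}

.new_model <- function(cfg, type, trunk, cls_head, rec_head) {
  structure(list(cfg = cfg, type = type, trunk = trunk,
                 cls_head = cls_head, rec_head = rec_head,
                 cayley = as.character(cayley_to_json())),
            class = "mismatch_model")
}

#' Build the onset-time classifier
#'
#' A five-stage (by default) encoder followed by global average pooling and a
#' small fully connected head with a sigmoid output; the score is the
#' predicted probability that stroke onset was at most 4.5 hours before
#' imaging. With `cfg$equivariant = TRUE` the encoder is D4h-equivariant and
#' the classifier score is invariant under all 16 grid symmetries of the
#' input (exactly, when every intermediate grid dimension is even).
#'
#' @param cfg an [encoder_config()].
#' @param seed integer seed for weight initialization.
#' @return a `mismatch_model` object.
#' @export
build_classifier <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .new_model(cfg, "classifier", .build_trunk(cfg), .build_cls_head(cfg), NULL)
}

#' Build the convolutional autoencoder (pre-training proxy task)
#'
#' The classifier's encoder augmented with a 1x1x1 bottleneck convolution and
#' a mirrored decoder (nearest-neighbour upsampling + convolution per stage)
#' that reconstructs the 2-channel input. Trained on reconstruction only; its
#' encoder weights can initialize [build_classifier()] /
#' [build_ae_regularized()] models.
#'
#' @inheritParams build_classifier
#' @return a `mismatch_model` object of type `"cae"`.
#' @export
build_cae <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .new_model(cfg, "cae", .build_trunk(cfg), NULL, .build_rec_head(cfg))
}

#' Build the autoencoder-regularized classifier
#'
#' Shares one encoder between a classification head and a reconstruction head;
#' training aggregates both outputs in the loss
#' `L = alpha * L_bce + (1 - alpha) * L_mse`.
#'
#' @inheritParams build_classifier
#' @param init `"random"` or `"pretrained"`; the latter requires `checkpoint`.
#' @param checkpoint an encoder checkpoint from [encoder_checkpoint()].
#' @return a `mismatch_model` object of type `"ae_regularized"`.
#' @export
build_ae_regularized <- function(cfg, init = c("random", "pretrained"),
                                 checkpoint = NULL, seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  m <- .new_model(cfg, "ae_regularized", .build_trunk(cfg),
                  .build_cls_head(cfg), .build_rec_head(cfg))
  if (init == "pretrained") {
    if (is.null(checkpoint)) stop("init = 'pretrained' requires a checkpoint")
    m <- init_encoder_from_checkpoint(m, checkpoint)
  }
  m
}

#' Forward pass of a model
#'
#' @param model a `mismatch_model`.
#' @param x input array (x, y, z, 2).
#' @param training enable dropout (training mode).
#' @return list with `score` (sigmoid probability), `logit`, `recon`
#'   (reconstruction, or NULL), and the internal `caches` used by the
#'   backward pass.
#' @export
forward_model <- function(model, x, training = FALSE) {
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == 2L)
  tr <- .net_forward(model$trunk, x, training)
  logit <- NULL; score <- NULL; recon <- NULL
  cls_cache <- NULL; rec_cache <- NULL
  if (!is.null(model$cls_head)) {
    cl <- .net_forward(model$cls_head, tr$out, training)
    logit <- as.numeric(cl$out)
    score <- stats::plogis(logit)
    cls_cache <- cl$caches
  }
  if (!is.null(model$rec_head)) {
    rc <- .net_forward(model$rec_head, tr$out, training)
    recon <- rc$out
    rec_cache <- rc$caches
  }
  list(score = score, logit = logit, recon = recon,
       caches = list(trunk = tr$caches, cls = cls_cache, rec = rec_cache,
                     trunk_out_dim = dim(tr$out)))
}

# Backward pass: dlogit is dL/dlogit (scalar), drecon dL/drecon (array or NULL).
# Returns per-part gradient lists plus the gradient at the input volume.
.backward_model <- function(model, caches, dlogit = NULL, drecon = NULL) {
  gtr <- NULL
  grads <- list(trunk = NULL, cls_head = NULL, rec_head = NULL)
  if (!is.null(dlogit) && !is.null(model$cls_head)) {
    b <- .net_backward(model$cls_head, caches$cls, dlogit)
    grads$cls_head <- b$grads
    gtr <- b$gin
  }
  if (!is.null(drecon) && !is.null(model$rec_head)) {
    b <- .net_backward(model$rec_head, caches$rec, drecon)
    grads$rec_head <- b$grads
    gtr <- if (is.null(gtr)) b$gin else gtr + b$gin
  }
  if (is.null(gtr)) stop("no head gradient supplied")
  if (is.null(dim(gtr))) dim(gtr) <- caches$trunk_out_dim
  b <- .net_backward(model$trunk, caches$trunk, gtr)
  grads$trunk <- b$grads
  list(grads = grads, gin = b$gin)
}

#' Predict onset scores for a list of inputs
#'
#' @param model a trained `mismatch_model` with a classification head.
#' @param inputs list of input arrays (x, y, z, 2).
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, inputs) {
  if (is.null(model$cls_head)) stop("model has no classification head")
  vapply(inputs, function(x) forward_model(model, x)$score, numeric(1))
}

#' Total number of trainable parameters
#' @param model a `mismatch_model`.
#' @export
count_params <- function(model) {
  .net_nparams(model$trunk) +
    (if (is.null(model$cls_head)) 0 else .net_nparams(model$cls_head)) +
    (if (is.null(model$rec_head)) 0 else .net_nparams(model$rec_head))
}

#' Per-stage shape summary
#'
#' Runs a zero input through the model and prints the output shape of every
#' layer, mirroring the usual deep-learning `summary` utilities.
#'
#' @param model a `mismatch_model`.
#' @return invisibly, a data frame of layer kinds and output shapes.
#' @export
model_summary <- function(model) {
  x <- array(0, dim = c(model$cfg$input_shape, 2L))
  rows <- list()
  for (part in c("trunk", "cls_head", "rec_head")) {
    layers <- model[[part]]
    if (is.null(layers)) next
    xi <- if (part == "trunk") x else trunk_out
    for (l in layers) {
      r <- .lfwd(l, xi, training = FALSE)
      xi <- r$out
      shp <- if (is.null(dim(xi))) length(xi) else paste(dim(xi), collapse = "x")
      rows[[length(rows) + 1L]] <- data.frame(part = part, kind = l$kind,
                                              out_shape = as.character(shp))
    }
    if (part == "trunk") trunk_out <- xi
  }
  out <- do.call(rbind, rows)
  print(out, row.names = FALSE)
  invisible(out)
}

# ---- checkpoints -------------------------------------------------------------

#' Export / import encoder weights
#'
#' The checkpoint is a plain list container: a format tag, the encoder
#' configuration, the D4h Cayley table as JSON (integrity check: a checkpoint
#' trained under a different group convention refuses to load), and the
#' per-layer weight arrays of the shared encoder trunk.
#'
#' @param model a `mismatch_model`.
#' @return `encoder_checkpoint`: a list; `save_checkpoint` / `load_checkpoint`
#'   write/read it via RDS; `init_encoder_from_checkpoint` returns the model
#'   with encoder weights replaced (error with a layer-by-layer difference
#'   report on any shape mismatch).
#' @export
encoder_checkpoint <- function(model) {
  weights <- lapply(model$trunk, function(l) {
    if (is.null(l$W)) NULL else list(kind = l$kind, dims = dim(l$W),
                                     W = l$W, b = l$b)
  })
  list(format = "mismatchnet-encoder-v1", cayley = model$cayley,
       cfg = model$cfg, weights = weights)
}

#' @rdname encoder_checkpoint
#' @param ckpt a checkpoint list.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) saveRDS(ckpt, path)

#' @rdname encoder_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!identical(ckpt$format, "mismatchnet-encoder-v1"))
    stop("not a mismatchnet encoder checkpoint")
  ckpt
}

#' @rdname encoder_checkpoint
#' @export
init_encoder_from_checkpoint <- function(model, ckpt) {
  if (!identical(ckpt$format, "mismatchnet-encoder-v1"))
    stop("not a mismatchnet encoder checkpoint")
  if (!identical(cayley_from_json(ckpt$cayley)$compose,
                 cayley_from_json(model$cayley)$compose))
    stop("checkpoint was produced under a different group convention")
  if (length(ckpt$weights) != length(model$trunk))
    stop(sprintf("encoder layer count mismatch: checkpoint %d vs model %d",
                 length(ckpt$weights), length(model$trunk)))
  diffs <- character(0)
  for (i in seq_along(model$trunk)) {
    l <- model$trunk[[i]]
    w <- ckpt$weights[[i]]
    if (is.null(l$W) != is.null(w)) {
      diffs <- c(diffs, sprintf("layer %d: parameterized mismatch (%s vs %s)",
                                i, l$kind, if (is.null(w)) "none" else w$kind))
      next
    }
    if (is.null(w)) next
    if (!identical(l$kind, w$kind) || !identical(dim(l$W), w$dims))
      diffs <- c(diffs, sprintf(
        "layer %d: model %s [%s] vs checkpoint %s [%s]",
        i, l$kind, paste(dim(l$W), collapse = "x"),
        w$kind, paste(w$dims, collapse = "x")))
  }
  if (length(diffs))
    stop("incompatible checkpoint:\n", paste(diffs, collapse = "\n"))
  for (i in seq_along(model$trunk)) {
    w <- ckpt$weights[[i]]
    if (is.null(w)) next
    model$trunk[[i]]$W <- w$W
    model$trunk[[i]]$b <- w$b
  }
  model
}
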