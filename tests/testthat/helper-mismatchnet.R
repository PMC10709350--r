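# Shared fixtures: everything is generated in code at test time.

rand_volume <- function(dims, seed = NULL, channels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- if (is.null(channels)) dims else c(dims, channels)
  array(stats::rnorm(prod(d)), d)
}

tiny_cfg <- function(equivariant = TRUE, shape = c(8, 8, 8),
                     channels = c(2, 3), dropout = 0, fc = c(5, 4),
                     bottleneck = 3) {
  encoder_config(input_shape = shape, channels = channels,
                 kernel = c(3, 3, 3), equivariant = equivariant,
                 dropout = dropout, fc = fc, bottleneck = bottleneck)
}

# Calls with exact sensitivity/specificity against the given labels.
calls_with_rates <- function(labels, sens, spec) {
  out <- integer(length(labels))
  pos <- which(labels == 1); neg <- which(labels == 0)
  npos_correct <- round(sens * length(pos))
  nneg_correct <- round(spec * length(neg))
  out[pos] <- 0L; out[pos[seq_len(npos_correct)]] <- 1L
  out[neg] <- 1L; out[neg[seq_len(nneg_correct)]] <- 0L
  out
}

zero_params <- function(model) {
  for (part in c("trunk", "cls_head", "rec_head")) {
    for (i in seq_along(model[[part]])) {
      if (!is.null(model[[part]][[i]]$W)) {
        model[[part]][[i]]$W[] <- 0
        model[[part]][[i]]$b[] <- 0
      }
    }
  }
  model
}
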