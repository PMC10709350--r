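#' SmoothGrad saliency volume
#'
#' Averages the absolute input-gradient of the model's pre-sigmoid logit
#' over `n` noisy replicates of the input (Gaussian noise with standard
#' deviation `sigma` times the input intensity range). Attributing the
#' logit rather than the probability avoids vanishing gradients at
#' saturated outputs. With `sigma = 0` the result is the plain absolute
#' gradient, independent of `n` and `seed`.
#'
#' @param model a `mismatch_model` with a classification head.
#' @param x input array (x, y, z, 2).
#' @param n number of noisy replicates (>= 1).
#' @param sigma noise level as a fraction of the input intensity range.
#' @param seed RNG seed for the noise.
#' @return a `saliency_volume`: non-negative array (x, y, z, 2) with
#'   attributes `n` and `sigma`.
#' @export
smoothgrad <- function(model, x, n = 25, sigma = 0.1, seed = 1) {
  if (is.null(model$cls_head)) stop("model has no classification head")
  stopifnot(n >= 1, sigma >= 0)
  rng <- diff(range(x))
  sd <- sigma * rng
  set.seed(as.integer(seed))
  n_eff <- if (sd > 0) n else 1L  # noise-free saliency is replicate-free
  acc <- array(0, dim(x))
  for (i in seq_len(n_eff)) {
    xi <- if (sd > 0) x + array(stats::rnorm(length(x), sd = sd), dim(x)) else x
    fw <- forward_model(model, xi, training = FALSE)
    bk <- .backward_model(model, fw$caches, dlogit = 1)
    if (!all(is.finite(bk$gin)))
      stop("non-finite input gradient encountered in SmoothGrad")
    acc <- acc + abs(bk$gin)
  }
  structure(acc / n_eff, class = "saliency_volume", n = n, sigma = sigma)
}

#' Threshold a saliency volume into a binary heatmap mask
#'
#' Each channel is max-normalized to \[0, 1\] per volume, then thresholded
#' at the universal threshold (chosen once and reused for all patients so
#' heatmaps are comparable).
#'
#' @param sal a `saliency_volume` (or non-negative array (x, y, z, 2)).
#' @param threshold universal threshold in normalized units.
#' @return logical array (x, y, z, 2).
#' @export
threshold_heatmap <- function(sal, threshold) {
  d <- dim(sal)
  stopifnot(length(d) == 4L)
  out <- array(FALSE, d)
  for (ch in seq_len(d[4])) {
    v <- sal[, , , ch]
    m <- max(v)
    if (m > 0) v <- v / m
    out[, , , ch] <- v >= threshold
  }
  out
}

#' Automated localization score of a heatmap against known lesion masks
#'
#' Operationalizes the visual "well-localized" criterion on synthetic data:
#' the DWI heatmap should cover most of the acute lesion and the FLAIR
#' heatmap most of the same location. Reports per-channel lesion coverage
#' (fraction of lesion voxels inside the mask) and Dice overlap; the
#' `well_localized` flag requires coverage > 0.5 on both channels. This is
#' a surrogate for human visual rating, not a reproduction of it.
#'
#' @param mask logical array (x, y, z, 2) from [threshold_heatmap()].
#' @param lesion_mask_dwi logical 3D lesion mask on the same grid.
#' @param lesion_mask_flair logical 3D mask of the expected FLAIR region
#'   (defaults to the DWI lesion mask).
#' @return list with per-channel `coverage`, `dice`, and `well_localized`.
#' @export
localization_score <- function(mask, lesion_mask_dwi,
                               lesion_mask_flair = lesion_mask_dwi) {
  stopifnot(identical(dim(mask)[1:3], dim(lesion_mask_dwi)))
  les <- list(dwi = lesion_mask_dwi, flair = lesion_mask_flair)
  cov <- dice <- c(dwi = NA_real_, flair = NA_real_)
  for (ch in 1:2) {
    m <- mask[, , , ch]
    l <- les[[ch]]
    nl <- sum(l)
    cov[ch] <- if (nl > 0) sum(m & l) / nl else NA_real_
    denom <- sum(m) + nl
    dice[ch] <- if (denom > 0) 2 * sum(m & l) / denom else NA_real_
  }
  list(coverage = cov, dice = dice,
       well_localized = isTRUE(cov["dwi"] > 0.5 && cov["flair"] > 0.5))
}

#' Write a saliency volume as NIfTI
#'
#' One file per channel (`<prefix>_dwi.nii`, `<prefix>_flair.nii`), aligned
#' to the input grid so the heatmaps can be viewed next to the DWI/FLAIR
#' images in any NIfTI viewer.
#'
#' @param sal a `saliency_volume`.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_saliency <- function(sal, prefix) {
  paths <- paste0(prefix, c("_dwi.nii", "_flair.nii"))
  RNifti::writeNifti(RNifti::asNifti(sal[, , , 1]), paths[1])
  RNifti::writeNifti(RNifti::asNifti(sal[, , , 2]), paths[2])
  invisible(paths)
}
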