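# Synthetic DWI/FLAIR phantom cohorts. The generator is a statistical
# stand-in for clinical stroke MRI, not a biophysical simulator: what it
# reproduces is the decision-relevant structure of the DWI-FLAIR mismatch
# problem -- an acute lesion always conspicuous on DWI, FLAIR lesion
# conspicuity rising monotonically with time since onset, and the
# confounders (leukoaraiosis-like diffuse FLAIR hyperintensity, old
# lesions, susceptibility-like artifacts) that make human rating hard.

# FFT-based separable Gaussian smoothing (periodic boundary; fine for
# texture synthesis).
.smooth3d <- function(x, sigma) {
  d <- dim(x)
  k <- lapply(d, function(n) {
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-i^2 / (2 * sigma^2))
    g / sum(g)
  })
  K <- outer(outer(k[[1]], k[[2]]), k[[3]])
  dim(K) <- d
  Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / prod(d)
}

.ellipsoid_mask <- function(grid, center, radii) {
  x <- (seq_len(grid[1]) - center[1]) / radii[1]
  y <- (seq_len(grid[2]) - center[2]) / radii[2]
  z <- (seq_len(grid[3]) - center[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' FLAIR lesion contrast as a function of time since onset
#'
#' Sigmoid conspicuity curve: contrast =
#' `flair_contrast_max * plogis((t - t_mid) / t_slope)`. With the default
#' midpoint at the 4.5 h decision boundary the label boundary is the
#' hardest region, mirroring the clinical difficulty.
#'
#' @param t hours since onset.
#' @param cfg a [phantom_config()].
#' @export
flair_contrast_curve <- function(t, cfg = phantom_config()) {
  cfg$flair_contrast_max * stats::plogis((t - cfg$t_mid) / cfg$t_slope)
}

#' Configuration of the synthetic DWI/FLAIR phantom cohort
#'
#' @param grid voxel grid (square in-plane; the default 64 x 64 x 32 is
#'   divisible by 2^5 so full-network invariance is exact).
#' @param n_labeled,n_unlabeled cohort sizes.
#' @param p_acute probability of onset <= 4.5 h in the labeled cohort
#'   (default 0.4335, the labeled-cohort prevalence of the study this
#'   emulates).
#' @param t_range onset-to-MRI time range in hours.
#' @param t_mid,t_slope sigmoid midpoint (h) and slope (h) of the FLAIR
#'   conspicuity curve.
#' @param lesion_radius_xy,lesion_radius_z lesion semi-axis ranges in voxels
#'   (at 64 in-plane voxels; scaled with the grid).
#' @param dwi_contrast DWI lesion contrast (intensity units over a unit-scale
#'   background; far above the noise floor so the lesion is always visible).
#' @param flair_contrast_max asymptotic FLAIR lesion contrast.
#' @param leuko_rate,old_lesion_rate,artifact_rate per-patient confounder
#'   probabilities (leukoaraiosis-like diffuse FLAIR hyperintensity
#'   independent of onset time; old FLAIR-bright lesion; focal DWI-bright
#'   susceptibility-like artifact).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param random_orientation apply a random grid symmetry (of the 16) to each
#'   patient, emulating arbitrary patient positioning and laterality.
#' @param unlabeled_lesion_free fraction of the unlabeled cohort without any
#'   acute lesion.
#' @param unlabeled_lowz fraction of unlabeled lesions placed in the lowest
#'   slices (stand-in for infratentorial strokes excluded from labeling).
#' @param unlabeled_p_acute,unlabeled_t_unknown acute fraction and
#'   unknown-onset-time fraction in the unlabeled cohort.
#' @param seed master seed; everything is reproducible from it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid = c(64, 64, 32),
                           n_labeled = 200, n_unlabeled = 100,
                           p_acute = 0.4335,
                           t_range = c(0.5, 24), t_mid = 4.5, t_slope = 1.5,
                           lesion_radius_xy = c(5, 10),
                           lesion_radius_z = c(2, 5),
                           dwi_contrast = 1.2, flair_contrast_max = 1.0,
                           leuko_rate = 0.3, old_lesion_rate = 0.2,
                           artifact_rate = 0.1, noise_sd = 0.08,
                           random_orientation = TRUE,
                           unlabeled_lesion_free = 0.35,
                           unlabeled_lowz = 0.25,
                           unlabeled_p_acute = 0.2,
                           unlabeled_t_unknown = 0.37,
                           seed = 1) {
  rates <- c(p_acute, leuko_rate, old_lesion_rate, artifact_rate,
             unlabeled_lesion_free, unlabeled_lowz, unlabeled_p_acute,
             unlabeled_t_unknown)
  stopifnot(all(rates >= 0 & rates <= 1), t_mid > 0, t_slope > 0,
            noise_sd >= 0, grid[1] == grid[2], all(grid >= 8),
            t_range[1] > 0, t_range[2] > t_range[1])
  scale <- grid[1] / 64
  zscale <- grid[3] / 32
  if (max(lesion_radius_xy) * scale >= grid[1] / 2 ||
      max(lesion_radius_z) * zscale >= grid[3] / 2)
    stop("lesion radii do not fit inside the grid")
  structure(list(grid = as.integer(grid), n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled), p_acute = p_acute,
                 t_range = t_range, t_mid = t_mid, t_slope = t_slope,
                 lesion_radius_xy = lesion_radius_xy,
                 lesion_radius_z = lesion_radius_z,
                 dwi_contrast = dwi_contrast,
                 flair_contrast_max = flair_contrast_max,
                 leuko_rate = leuko_rate, old_lesion_rate = old_lesion_rate,
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 random_orientation = isTRUE(random_orientation),
                 unlabeled_lesion_free = unlabeled_lesion_free,
                 unlabeled_lowz = unlabeled_lowz,
                 unlabeled_p_acute = unlabeled_p_acute,
                 unlabeled_t_unknown = unlabeled_t_unknown,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# One patient's metadata draw (labels first so volumes can be skipped).
.draw_patient_meta <- function(cfg, cohort) {
  if (cohort == "labeled") {
    acute <- stats::runif(1) < cfg$p_acute
    t <- if (acute) stats::runif(1, cfg$t_range[1], cfg$t_mid)
         else stats::runif(1, cfg$t_mid, cfg$t_range[2])
    list(t = t, t_known = TRUE, lesion = TRUE, lowz = FALSE)
  } else {
    lesion <- stats::runif(1) >= cfg$unlabeled_lesion_free
    acute <- stats::runif(1) < cfg$unlabeled_p_acute
    t <- if (acute) stats::runif(1, cfg$t_range[1], cfg$t_mid)
         else stats::runif(1, cfg$t_mid, cfg$t_range[2])
    list(t = t, t_known = stats::runif(1) >= cfg$unlabeled_t_unknown,
         lesion = lesion, lowz = lesion && stats::runif(1) < cfg$unlabeled_lowz)
  }
}

.make_phantom <- function(cfg, meta) {
  g <- cfg$grid
  scale <- g[1] / 64
  zscale <- g[3] / 32
  center <- (g + 1) / 2
  brain <- .ellipsoid_mask(g, center, c(0.45 * g[1], 0.45 * g[2], 0.46 * g[3]))
  grf1 <- .smooth3d(array(stats::rnorm(prod(g)), g), 2 * scale)
  grf2 <- .smooth3d(array(stats::rnorm(prod(g)), g), 2 * scale)
  dwi <- ifelse(brain, 1 + 3 * grf1, 0)
  flair <- ifelse(brain, 1 + 3 * grf2, 0)
  # ventricle-like central CSF: dark on both sequences
  for (s in c(-1, 1)) {
    vent <- .ellipsoid_mask(g, center + c(0, s * 0.1 * g[2], 0.05 * g[3]),
                            c(0.06 * g[1], 0.16 * g[2], 0.2 * g[3]))
    dwi[vent] <- dwi[vent] - 0.6
    flair[vent] <- flair[vent] - 0.6
  }
  lesion_mask <- array(FALSE, g)
  flair_contrast <- 0
  if (meta$lesion) {
    rz <- max(cfg$lesion_radius_z) * zscale
    zlim <- if (meta$lowz) c(1 + rz, max(2 + rz, round(0.2 * g[3])))
            else round(c(0.3, 0.7) * g[3])
    cen <- c(center[1] + stats::runif(1, -0.22, 0.22) * g[1],
             center[2] + stats::runif(1, -0.22, 0.22) * g[2],
             stats::runif(1, zlim[1], zlim[2]))
    radii <- c(stats::runif(2, cfg$lesion_radius_xy[1],
                            cfg$lesion_radius_xy[2]) * scale,
               stats::runif(1, cfg$lesion_radius_z[1],
                            cfg$lesion_radius_z[2]) * zscale)
    lesion_mask <- .ellipsoid_mask(g, cen, radii) & brain
    flair_contrast <- flair_contrast_curve(meta$t, cfg)
    dwi[lesion_mask] <- dwi[lesion_mask] + cfg$dwi_contrast
    flair[lesion_mask] <- flair[lesion_mask] + flair_contrast
  }
  leuko <- stats::runif(1) < cfg$leuko_rate
  if (leuko) {
    # periventricular diffuse FLAIR hyperintensity, independent of onset time
    shell <- .ellipsoid_mask(g, center, c(0.22 * g[1], 0.3 * g[2], 0.32 * g[3])) &
      !.ellipsoid_mask(g, center, c(0.12 * g[1], 0.2 * g[2], 0.24 * g[3]))
    amp <- stats::runif(1, 0.3, 0.7)
    flair[shell & brain] <- flair[shell & brain] + amp
  }
  if (stats::runif(1) < cfg$old_lesion_rate) {
    cen <- c(center[1] + stats::runif(1, -0.3, 0.3) * g[1],
             center[2] + stats::runif(1, -0.3, 0.3) * g[2],
             stats::runif(1, round(0.25 * g[3]), round(0.75 * g[3])))
    old <- .ellipsoid_mask(g, cen, c(stats::runif(2, 3, 6) * scale,
                                     stats::runif(1, 1.5, 3))) & brain
    flair[old] <- flair[old] + stats::runif(1, 0.5, 0.9)
  }
  if (stats::runif(1) < cfg$artifact_rate) {
    cen <- c(center[1] + stats::runif(1, -0.35, 0.35) * g[1],
             center[2] + 0.35 * g[2],  # frontal-ish pole
             stats::runif(1, round(0.3 * g[3]), round(0.7 * g[3])))
    art <- .ellipsoid_mask(g, cen, c(2, 2, 1.5) * scale)
    dwi[art] <- dwi[art] + stats::runif(1, 1.0, 1.8)
  }
  if (cfg$noise_sd > 0) {
    dwi <- dwi + stats::rnorm(prod(g), sd = cfg$noise_sd)
    flair <- flair + stats::rnorm(prod(g), sd = cfg$noise_sd)
  }
  orient <- 0L
  if (cfg$random_orientation) {
    orient <- sample(0:15, 1)
    dwi <- act_on_volume(orient, structure(dwi, dim = g))
    flair <- act_on_volume(orient, structure(flair, dim = g))
    lesion_mask <- act_on_volume(orient, structure(lesion_mask, dim = g))
  }
  dim(dwi) <- g; dim(flair) <- g; dim(lesion_mask) <- g
  list(dwi = dwi, flair = flair, lesion_mask = lesion_mask,
       flair_contrast = flair_contrast, leuko = leuko, orientation = orient)
}

#' Generate a synthetic DWI/FLAIR phantom cohort
#'
#' Draws a labeled cohort (acute supratentorial-like lesions, known onset
#' time, label 1 iff t <= 4.5 h) and an unlabeled cohort with shifted
#' characteristics (a fraction lesion-free, a fraction with low-slice
#' lesions, onset time often unknown) for pre-training. DWI and FLAIR share
#' one grid by construction (coregistered). Deterministic per seed.
#'
#' @param cfg a [phantom_config()].
#' @param volumes generate voxel data (set FALSE for metadata-only cohorts,
#'   e.g. data accounting at full study size).
#' @param dir optional directory; when given, volumes, lesion masks (NIfTI)
#'   and `cohort.csv` are written there and the table gains path columns.
#' @return a `phantom_cohort`: list with `table` (one row per patient:
#'   patient_id, cohort, time_to_mri_h, label, lesion_present,
#'   flair_contrast, leuko, orientation), `patients` (named list of
#'   `dwi`/`flair`/`lesion_mask` arrays, if `volumes`), and `cfg`.
#' @export
generate_cohort <- function(cfg = phantom_config(), volumes = TRUE,
                            dir = NULL) {
  set.seed(cfg$seed)
  n <- cfg$n_labeled + cfg$n_unlabeled
  cohorts <- rep(c("labeled", "unlabeled"), c(cfg$n_labeled, cfg$n_unlabeled))
  ids <- sprintf("P%04d", seq_len(n))
  rows <- vector("list", n)
  patients <- if (volumes) stats::setNames(vector("list", n), ids) else NULL
  for (i in seq_len(n)) {
    meta <- .draw_patient_meta(cfg, cohorts[i])
    ph <- if (volumes) .make_phantom(cfg, meta) else
      list(flair_contrast = if (meta$lesion) flair_contrast_curve(meta$t, cfg) else 0,
           leuko = NA, orientation = NA_integer_)
    rows[[i]] <- data.frame(
      patient_id = ids[i], cohort = cohorts[i],
      time_to_mri_h = if (meta$t_known) meta$t else NA_real_,
      label = if (cohorts[i] == "labeled") as.integer(meta$t <= 4.5) else NA_integer_,
      lesion_present = meta$lesion,
      flair_contrast = ph$flair_contrast,
      leuko = ph$leuko, orientation = ph$orientation,
      stringsAsFactors = FALSE)
    if (volumes) patients[[i]] <- ph[c("dwi", "flair", "lesion_mask")]
  }
  table <- do.call(rbind, rows)
  out <- structure(list(table = table, patients = patients, cfg = cfg),
                   class = "phantom_cohort")
  if (!is.null(dir)) out <- write_cohort(out, dir)
  out
}

#' Write a phantom cohort to disk (NIfTI volumes + cohort CSV)
#'
#' Produces the exact on-disk layout the preprocessing module consumes:
#' `<id>_dwi.nii`, `<id>_flair.nii`, `<id>_mask.nii` and a `cohort.csv`
#' with columns patient_id, dwi_path, flair_path, time_to_mri_h, cohort.
#'
#' @param cohort a `phantom_cohort` with volumes.
#' @param dir output directory (created if needed).
#' @return the cohort, with path columns added to its table.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$patients)) stop("cohort has no volumes to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$table
  tab$dwi_path <- file.path(dir, paste0(tab$patient_id, "_dwi.nii"))
  tab$flair_path <- file.path(dir, paste0(tab$patient_id, "_flair.nii"))
  tab$mask_path <- file.path(dir, paste0(tab$patient_id, "_mask.nii"))
  for (i in seq_len(nrow(tab))) {
    p <- cohort$patients[[tab$patient_id[i]]]
    RNifti::writeNifti(RNifti::asNifti(p$dwi), tab$dwi_path[i])
    RNifti::writeNifti(RNifti::asNifti(p$flair), tab$flair_path[i])
    RNifti::writeNifti(RNifti::asNifti(p$lesion_mask * 1), tab$mask_path[i])
  }
  cohort$table <- tab
  utils::write.csv(tab[, c("patient_id", "dwi_path", "flair_path",
                           "time_to_mri_h", "cohort")],
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  cohort
}

#' Synthetic rater model
#'
#' @param sensitivity,specificity probability of a correct mismatch /
#'   no-mismatch call on determinable cases, with respect to the true label.
#' @param indeterminable_rate fraction of patients rated indeterminable
#'   (selection biased toward low-FLAIR-contrast cases, where real raters
#'   struggle).
#' @param seed RNG seed.
#' @export
rater_model <- function(sensitivity = 0.62, specificity = 0.78,
                        indeterminable_rate = 0.1, seed = 1) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, indeterminable_rate >= 0,
            indeterminable_rate <= 1)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 indeterminable_rate = indeterminable_rate,
                 seed = as.integer(seed)),
            class = "rater_model")
}

#' Generate a synthetic rating table
#'
#' Each patient is rated mismatch / no-mismatch with the configured
#' sensitivity and specificity relative to the true label; a fraction
#' (biased toward low FLAIR contrast) is rated indeterminable instead.
#' Deterministic per the model's seed.
#'
#' @param labels 0/1 true labels.
#' @param flair_contrasts per-patient FLAIR lesion contrast (drives the
#'   indeterminable bias); use a constant to disable the bias.
#' @param model a [rater_model()].
#' @param rater_id identifier written into the table.
#' @param patient_ids optional ids (default P0001...).
#' @return data frame with columns patient_id, rater_id, rating.
#' @export
generate_raters <- function(labels, flair_contrasts = rep(1, length(labels)),
                            model = rater_model(), rater_id = "rater1",
                            patient_ids = NULL) {
  n <- length(labels)
  stopifnot(length(flair_contrasts) == n)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  set.seed(model$seed)
  correct <- ifelse(labels == 1,
                    stats::runif(n) < model$sensitivity,
                    stats::runif(n) < model$specificity)
  rating <- ifelse(labels == 1,
                   ifelse(correct, "mismatch", "no_mismatch"),
                   ifelse(correct, "no_mismatch", "mismatch"))
  k <- round(model$indeterminable_rate * n)
  if (k > 0) {
    w <- 1 / (0.15 + pmax(flair_contrasts, 0))
    ind <- sample.int(n, k, prob = w)
    rating[ind] <- "indeterminable"
  }
  data.frame(patient_id = patient_ids, rater_id = rater_id, rating = rating,
             stringsAsFactors = FALSE)
}

#' Assemble network inputs from a phantom cohort
#'
#' Stacks DWI and FLAIR into the 2-channel input arrays, optionally resizing
#' to a working grid and standardizing with training-set statistics.
#'
#' @param cohort a `phantom_cohort` with volumes.
#' @param ids patient ids to include (default: the labeled cohort).
#' @param target_shape optional working grid for trilinear resizing.
#' @return named list of arrays (x, y, z, 2).
#' @export
cohort_inputs <- function(cohort, ids = NULL, target_shape = NULL) {
  if (is.null(cohort$patients)) stop("cohort has no volumes")
  if (is.null(ids))
    ids <- cohort$table$patient_id[cohort$table$cohort == "labeled"]
  out <- lapply(ids, function(id) {
    p <- cohort$patients[[id]]
    dwi <- p$dwi; flair <- p$flair
    if (!is.null(target_shape)) {
      d <- dim(dwi)
      dwi <- array(resize_trilinear(as.vector(dwi), as.integer(d),
                                    as.integer(target_shape)), target_shape)
      flair <- array(resize_trilinear(as.vector(flair), as.integer(d),
                                      as.integer(target_shape)), target_shape)
    }
    x <- array(0, c(dim(dwi), 2L))
    x[, , , 1] <- dwi
    x[, , , 2] <- flair
    x
  })
  stats::setNames(out, ids)
}
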