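#' Construct a coregistered DWI/FLAIR volume pair
#'
#' @param dwi,flair 3D voxel arrays.
#' @param spacing voxel spacing in mm (of the DWI grid).
#' @param patient_id identifier.
#' @param dwi_affine,flair_affine optional 4x4 voxel-to-world affines
#'   (0-based voxel indices); defaults to a diagonal affine from `spacing`.
#' @return a `volume_pair`.
#' @export
volume_pair <- function(dwi, flair, spacing = c(1, 1, 1), patient_id = NA,
                        dwi_affine = NULL, flair_affine = NULL) {
  if (length(dim(dwi)) != 3L || length(dim(flair)) != 3L)
    stop("dwi and flair must be 3D arrays")
  if (is.null(dwi_affine)) dwi_affine <- diag(c(spacing, 1))
  if (is.null(flair_affine)) flair_affine <- diag(c(spacing, 1))
  structure(list(dwi = dwi, flair = flair, spacing = as.numeric(spacing),
                 patient_id = patient_id, dwi_affine = dwi_affine,
                 flair_affine = flair_affine),
            class = "volume_pair")
}

.read_nifti_3d <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("unreadable NIfTI header in %s file %s: %s",
                                 what, path, conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) != 3L)
    stop(sprintf("%s image must be 3D, got %dD: %s",
                 what, length(dim(img)), path))
  img
}

#' Load a DWI/FLAIR pair from NIfTI files
#'
#' Images are loaded with their affine and spacing metadata; grids need not
#' match at load time (resampling is a later stage). Missing files,
#' non-3D images and unreadable headers raise distinct errors.
#'
#' @param dwi_path,flair_path NIfTI file paths (.nii or .nii.gz).
#' @param patient_id identifier stored in the pair.
#' @return a `volume_pair`.
#' @export
load_pair <- function(dwi_path, flair_path, patient_id = NA) {
  dwi <- .read_nifti_3d(dwi_path, "DWI")
  flair <- .read_nifti_3d(flair_path, "FLAIR")
  volume_pair(array(as.numeric(dwi), dim(dwi)),
              array(as.numeric(flair), dim(flair)),
              spacing = RNifti::pixdim(dwi)[1:3],
              patient_id = patient_id,
              dwi_affine = .affine0(dwi), flair_affine = .affine0(flair))
}

# NIfTI xform maps 0-based voxel indices to world mm; keep that convention.
.affine0 <- function(img) {
  x <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(x, "try-error") || is.null(x))
    diag(c(RNifti::pixdim(img)[1:3], 1)) else unclass(x)
}

#' Resample FLAIR onto the DWI grid
#'
#' The registration backend is pluggable. `"identity"` asserts the grids
#' already match (synthetic phantoms are generated coregistered);
#' `"rigid-resample"` maps every DWI voxel through the two affines and
#' samples the FLAIR volume trilinearly (resampling under the stored rigid
#' transforms; no deformable registration).
#'
#' @param pair a `volume_pair`.
#' @param backend `"identity"` or `"rigid-resample"`.
#' @return a `volume_pair` with `flair` on the DWI grid.
#' @export
coregister_resample <- function(pair, backend = c("identity", "rigid-resample")) {
  backend <- match.arg(backend)
  if (backend == "identity") {
    if (!identical(dim(pair$dwi), dim(pair$flair)))
      stop(sprintf(
        "identity backend requires matching grids (dwi %s vs flair %s)",
        paste(dim(pair$dwi), collapse = "x"),
        paste(dim(pair$flair), collapse = "x")))
    return(pair)
  }
  d <- dim(pair$dwi)
  vox <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  world <- cbind(vox, 1) %*% t(pair$dwi_affine)
  fvox <- world %*% t(solve(pair$flair_affine))
  vals <- sample_trilinear(as.vector(pair$flair), as.integer(dim(pair$flair)),
                           fvox[, 1:3, drop = FALSE], 0)
  pair$flair <- array(vals, d)
  pair$flair_affine <- pair$dwi_affine
  pair
}

#' Resize both channels to a working grid
#'
#' Trilinear interpolation to `target` (default 192 x 192 x 50, the working
#' grid of the clinical pipeline this package re-implements; the in-plane
#' dims must be square when feeding the equivariant model).
#'
#' @param pair a `volume_pair` (grids already matching).
#' @param target integer shape triple.
#' @return resized `volume_pair` (spacing scaled accordingly).
#' @export
resize_to_grid <- function(pair, target = c(192, 192, 50)) {
  target <- as.integer(target)
  d <- dim(pair$dwi)
  if (!identical(dim(pair$flair), d))
    stop("resize expects coregistered grids; run coregister_resample first")
  if (identical(d, target)) return(pair)
  pair$dwi <- array(resize_trilinear(as.vector(pair$dwi), as.integer(d),
                                     target), target)
  pair$flair <- array(resize_trilinear(as.vector(pair$flair), as.integer(d),
                                       target), target)
  pair$spacing <- pair$spacing * d / target
  pair
}

#' Fit intensity standardization statistics on the training set
#'
#' Mean and standard deviation per modality channel across all voxels of
#' all training pairs (per-channel by default so that neither modality's
#' scale dominates; `per_channel = FALSE` pools both). Validation and test
#' data must be standardized with these training statistics only.
#'
#' @param pairs list of `volume_pair` (the training set).
#' @param per_channel fit DWI and FLAIR separately.
#' @return a `standardization_stats` list with `mean` and `sd` (length 2:
#'   dwi, flair).
#' @export
fit_standardizer <- function(pairs, per_channel = TRUE) {
  stopifnot(length(pairs) >= 1)
  dwi <- unlist(lapply(pairs, function(p) as.vector(p$dwi)))
  fla <- unlist(lapply(pairs, function(p) as.vector(p$flair)))
  if (per_channel) {
    m <- c(dwi = mean(dwi), flair = mean(fla))
    s <- c(dwi = stats::sd(dwi), flair = stats::sd(fla))
  } else {
    all <- c(dwi, fla)
    m <- c(dwi = mean(all), flair = mean(all))
    s <- c(dwi = stats::sd(all), flair = stats::sd(all))
  }
  if (any(s <= 0) || any(!is.finite(s)))
    stop("zero-variance training data: standardization undefined")
  structure(list(mean = m, sd = s, per_channel = per_channel),
            class = "standardization_stats")
}

#' @rdname fit_standardizer
#' @param pair a `volume_pair` to standardize (any split).
#' @param stats statistics fitted on the training set.
#' @export
apply_standardizer <- function(pair, stats) {
  stopifnot(inherits(stats, "standardization_stats"))
  pair$dwi <- (pair$dwi - stats$mean["dwi"]) / stats$sd["dwi"]
  pair$flair <- (pair$flair - stats$mean["flair"]) / stats$sd["flair"]
  pair
}

#' Stack a volume pair into the 2-channel network input
#' @param pair a `volume_pair` with matching grids.
#' @return array (x, y, z, 2).
#' @export
pair_to_input <- function(pair) {
  stopifnot(identical(dim(pair$dwi), dim(pair$flair)))
  x <- array(0, c(dim(pair$dwi), 2L))
  x[, , , 1] <- pair$dwi
  x[, , , 2] <- pair$flair
  x
}

#' Read a cohort CSV (patient_id, dwi_path, flair_path, time_to_mri_h, cohort)
#' @param path CSV path.
#' @return data frame with a `label` column added (1 iff time <= 4.5 h; NA
#'   when the time is unknown).
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "dwi_path", "flair_path", "time_to_mri_h", "cohort")
  if (!all(need %in% names(tab)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  tab$label <- ifelse(is.na(tab$time_to_mri_h), NA_integer_,
                      as.integer(tab$time_to_mri_h <= 4.5))
  tab
}
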