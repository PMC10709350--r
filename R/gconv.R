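#' Specification of a group-equivariant convolution layer
#'
#' @param in_channels,out_channels feature channel counts (base channels; an
#'   equivariant layer additionally carries the 16 orientation channels).
#' @param kernel_size odd integer triple; the in-plane extent must be square
#'   so kernels can be rotated exactly.
#' @param layer_kind `"lifting"` (scalar channels in, 16 orientations out) or
#'   `"group"` (oriented in, oriented out).
#' @param bias include a bias term (shared across orientations; a per-
#'   orientation bias would break equivariance).
#' @return a `gconv_spec` list.
#' @export
gconv_spec <- function(in_channels, out_channels, kernel_size = c(3, 3, 3),
                       layer_kind = c("lifting", "group"), bias = TRUE) {
  layer_kind <- match.arg(layer_kind)
  kernel_size <- as.integer(kernel_size)
  stopifnot(in_channels >= 1, out_channels >= 1, length(kernel_size) == 3)
  if (any(kernel_size %% 2L == 0L))
    stop("kernel extents must be odd: the rotation center of an even kernel is undefined")
  if (kernel_size[1] != kernel_size[2])
    stop("kernel in-plane extent must be square for exact kernel rotation")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = kernel_size, layer_kind = layer_kind,
                 bias = isTRUE(bias)),
            class = "gconv_spec")
}

#' Initialize weights for a [gconv_spec()]
#'
#' @param spec a `gconv_spec`.
#' @param seed optional seed.
#' @return list with `W` (lifting: `[kx,ky,kz,cin,cout]`; group:
#'   `[kx,ky,kz,16,cin,cout]`) and `b` (length `cout`).
#' @export
gconv_init <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  l <- if (spec$layer_kind == "lifting")
    .layer_lift(spec$in_channels, spec$out_channels, spec$kernel_size)
  else
    .layer_gconv(spec$in_channels, spec$out_channels, spec$kernel_size)
  list(W = l$W, b = if (spec$bias) l$b else numeric(length(l$b)))
}

.as_gconv_layer <- function(spec, weights) {
  l <- if (spec$layer_kind == "lifting")
    .layer_lift(spec$in_channels, spec$out_channels, spec$kernel_size)
  else
    .layer_gconv(spec$in_channels, spec$out_channels, spec$kernel_size)
  stopifnot(identical(dim(l$W), dim(weights$W)))
  l$W <- weights$W
  if (!is.null(weights$b)) l$b <- weights$b
  l
}

#' Lifting convolution: scalar channels to 16 orientation channels
#'
#' Correlates the input with the kernel transformed by every D4h element,
#' producing one orientation channel per group element ("same" zero padding).
#' Satisfies `lifting_conv(act_on_volume(g, v)) ==
#' act_on_oriented(g, lifting_conv(v))` for all 16 elements.
#'
#' @param v input array (x, y, z, in_channels); square in-plane.
#' @param spec a `gconv_spec` with `layer_kind = "lifting"`.
#' @param weights from [gconv_init()] (or trained).
#' @return oriented feature map (x, y, z, 16, out_channels).
#' @export
lifting_conv <- function(v, spec, weights) {
  stopifnot(spec$layer_kind == "lifting")
  d <- dim(v)
  if (length(d) == 3L) { dim(v) <- c(d, 1L); d <- dim(v) }
  stopifnot(length(d) == 4L, d[4] == spec$in_channels)
  .check_square_inplane(v)
  l <- .as_gconv_layer(spec, weights)
  out <- .lfwd(l, v)$out
  dim(out) <- c(d[1:3], 16L, spec$out_channels)
  out
}

#' Group convolution: oriented features to oriented features
#'
#' Correlation over feature channels, the 16 orientations, and space, with
#' the kernel spatially transformed by each output orientation's group
#' element and its input-orientation axis permuted by the group
#' multiplication. Same equivariance contract as [lifting_conv()] under
#' [act_on_oriented()].
#'
#' @param f oriented feature map (x, y, z, 16, in_channels).
#' @param spec a `gconv_spec` with `layer_kind = "group"`.
#' @param weights from [gconv_init()].
#' @return oriented feature map (x, y, z, 16, out_channels).
#' @export
group_conv <- function(f, spec, weights) {
  stopifnot(spec$layer_kind == "group")
  d <- dim(f)
  if (length(d) == 4L && d[4] == 16L && spec$in_channels == 1L) {
    dim(f) <- c(d, 1L); d <- dim(f)
  }
  if (length(d) != 5L || d[4] != 16L)
    stop("oriented feature map must have dims (x, y, z, 16, channels)")
  if (d[5] != spec$in_channels)
    stop(sprintf("orientation/channel mismatch: input has %d channels, spec expects %d",
                 d[5], spec$in_channels))
  .check_square_inplane(f)
  l <- .as_gconv_layer(spec, weights)
  x <- f
  dim(x) <- c(d[1:3], 16L * d[5])
  out <- .lfwd(l, x)$out
  dim(out) <- c(d[1:3], 16L, spec$out_channels)
  out
}

#' Pool the orientation axis away
#'
#' Reduces an oriented feature map over its 16 orientation channels, giving a
#' feature volume that is invariant up to the spatial transform:
#' `orientation_pool(act_on_oriented(g, f)) ==
#' act_on_volume(g, orientation_pool(f))` (exact for both modes).
#'
#' @param f oriented feature map (x, y, z, 16) or (x, y, z, 16, channels).
#' @param mode `"max"` or `"mean"`.
#' @return array (x, y, z, channels) (channels dim kept, length 1 if absent).
#' @export
orientation_pool <- function(f, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  d <- dim(f)
  if (is.null(d) || length(d) < 4L || d[4] != 16L)
    stop("orientation axis of length 16 expected in position 4")
  if (length(d) == 4L) { dim(f) <- c(d, 1L); d <- dim(f) }
  x <- f
  dim(x) <- c(d[1:3], 16L * d[5])
  out <- .lfwd(.layer_orientpool(mode), x)$out
  dim(out) <- c(d[1:3], d[5])
  out
}

#' Parameter count of a layer specification
#'
#' Weights of an equivariant layer are shared across the 16 output
#' orientations, so a group layer has exactly the parameter count of a plain
#' 3D convolution consuming the same flattened (16 x channels) input.
#'
#' @param spec a `gconv_spec`.
#' @return integer parameter count (weights + bias).
#' @export
gconv_param_count <- function(spec) {
  k <- prod(spec$kernel_size)
  n <- if (spec$layer_kind == "lifting") k * spec$in_channels * spec$out_channels
       else k * 16L * spec$in_channels * spec$out_channels
  as.integer(n + if (spec$bias) spec$out_channels else 0L)
}
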