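#' @useDynLib mismatchnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Package-local cache (Cayley table is built once per session).
.mn_cache <- new.env(parent = emptyenv())

# Reverse one axis of an array, keeping all dims.
.rev_axis <- function(v, axis) {
  d <- dim(v)
  ix <- rep(list(TRUE), length(d))
  ix[[axis]] <- rev(seq_len(d[axis]))
  do.call(`[`, c(list(v), ix, list(drop = FALSE)))
}

# Quarter-turn rotation in the (x, y) plane, acting on dims 1-2 of an array
# with any number of trailing dims. Requires square in-plane extent.
.rot90_xy <- function(v) {
  d <- dim(v)
  perm <- seq_along(d)
  perm[1:2] <- c(2L, 1L)
  .rev_axis(aperm(v, perm), 1L)
}

.check_square_inplane <- function(v) {
  d <- dim(v)
  if (is.null(d) || length(d) < 3L)
    stop("expected an array with at least 3 dimensions (x, y, z)")
  if (d[1] != d[2])
    stop(sprintf(
      "in-plane dimensions must be square for D4h actions (got %d x %d): ",
      d[1], d[2]),
      "a quarter-turn rotation does not map a non-square grid to itself")
  invisible(d)
}

#' The 16 elements of the D4h point group
#'
#' Enumerates the order-16 point group generated by an in-plane quarter-turn
#' rotation, an in-plane mirror, and a through-plane flip. Each element is
#' parameterized as (r, m, z) with r in 0..3 quarter turns, m the mirror bit
#' and z the flip bit; the canonical index is \code{r + 4*m + 8*z}.
#'
#' @return A data frame with columns `index`, `r`, `m`, `z` (16 rows).
#' @export
d4h_elements <- function() {
  g <- expand.grid(r = 0:3, m = 0:1, z = 0:1)
  g$index <- g$r + 4L * g$m + 8L * g$z
  g[order(g$index), c("index", "r", "m", "z")]
}

#' Apply a D4h element to a voxel volume
#'
#' The element acts on the first three array dimensions: `r` quarter-turn
#' rotations in the (x, y) plane, then the in-plane mirror (x reversal) if
#' `m = 1`, then the through-plane flip (z reversal) if `z = 1`. Trailing
#' dimensions (channels) are carried along unchanged. The action is a pure
#' permutation of voxels.
#'
#' @param g element index in 0..15, or a one-row slice of [d4h_elements()].
#' @param v array with dims (x, y, z, ...); x and y extents must be equal.
#' @return the transformed array, same dims as `v`.
#' @export
act_on_volume <- function(g, v) {
  .check_square_inplane(v)
  el <- .as_element(g)
  out <- v
  if (el$r > 0) for (i in seq_len(el$r)) out <- .rot90_xy(out)
  if (el$m == 1) out <- .rev_axis(out, 1L)
  if (el$z == 1) out <- .rev_axis(out, 3L)
  out
}

.as_element <- function(g) {
  if (is.data.frame(g)) return(list(r = g$r[1], m = g$m[1], z = g$z[1]))
  if (is.list(g)) return(g)
  g <- as.integer(g)
  if (g < 0L || g > 15L) stop("group element index must be in 0..15")
  list(r = g %% 4L, m = (g %/% 4L) %% 2L, z = g %/% 8L)
}

#' Cayley table of the D4h group
#'
#' Builds the full composition table by realizing every element as a voxel
#' permutation on a reference grid with distinct entries and composing the
#' permutations, so the table is consistent with [act_on_volume()] by
#' construction. `compose[g+1, h+1]` is the index of "apply h first, then g".
#'
#' @return An object of class `cayley_d4h`: list with `elements` (data frame),
#'   `compose` (16 x 16 integer matrix of 0-based indices), `inverse`
#'   (length-16 0-based integer vector), and `order` (16).
#' @export
d4h_cayley <- function() {
  if (!is.null(.mn_cache$cayley)) return(.mn_cache$cayley)
  els <- d4h_elements()
  ref <- array(seq_len(4 * 4 * 2), dim = c(4, 4, 2))
  perms <- lapply(0:15, function(i) as.vector(act_on_volume(i, ref)))
  key <- vapply(perms, paste, character(1), collapse = ",")
  compose <- matrix(NA_integer_, 16, 16)
  for (g in 0:15) {
    for (h in 0:15) {
      # apply h first, then g: as vectors, (ref[p_h])[p_g] = ref[p_h[p_g]]
      comp <- perms[[h + 1]][perms[[g + 1]]]
      k <- match(paste(comp, collapse = ","), key)
      if (is.na(k)) stop("group is not closed; internal error")
      compose[g + 1, h + 1] <- k - 1L
    }
  }
  id <- match(paste(seq_len(32), collapse = ","), key) - 1L
  inverse <- vapply(0:15, function(g) which(compose[g + 1, ] == id) - 1L,
                    integer(1))
  out <- structure(
    list(elements = els, compose = compose, inverse = inverse, order = 16L),
    class = "cayley_d4h")
  .mn_cache$cayley <- out
  out
}

#' @rdname d4h_cayley
#' @param g,h element indices in 0..15.
#' @return `d4h_compose`: the index of the composite element (h applied
#'   first, then g). `d4h_inverse`: the index of the inverse element.
#' @export
d4h_compose <- function(g, h) {
  tab <- d4h_cayley()
  tab$compose[cbind(as.integer(g) + 1L, as.integer(h) + 1L)]
}

#' @rdname d4h_cayley
#' @export
d4h_inverse <- function(g) {
  tab <- d4h_cayley()
  tab$inverse[as.integer(g) + 1L]
}

#' Apply a D4h element to an orientation-indexed feature map
#'
#' An oriented feature map carries one spatial volume per group element
#' (dims `(x, y, z, 16)` or `(x, y, z, 16, channels)`). Acting with `g`
#' spatially transforms every orientation channel by `g` and moves the
#' content of orientation `h` to orientation `compose(g, h)` -- the regular
#' representation of the group on itself.
#'
#' @param g element index in 0..15.
#' @param f array with dims (x, y, z, 16) or (x, y, z, 16, channels).
#' @return the transformed array, same dims as `f`.
#' @export
act_on_oriented <- function(g, f) {
  d <- dim(f)
  if (is.null(d) || length(d) < 4L || d[4] != 16L)
    stop("oriented feature map must have an orientation axis of length 16 in position 4")
  tab <- d4h_cayley()
  fs <- act_on_volume(g, f)          # spatial part, orientation axis carried along
  dest <- tab$compose[g + 1, ] + 1L  # h -> g.h (1-based destinations)
  out <- fs
  ix_src <- rep(list(TRUE), length(d))
  ix_dst <- ix_src
  ix_dst[[4]] <- dest
  out <- do.call(`[<-`, c(list(out), ix_dst, list(value = do.call(`[`, c(list(fs), ix_src, list(drop = FALSE))))))
  out
}

#' Serialize / deserialize a Cayley table as JSON
#'
#' The JSON container (compose table plus inverse vector, 0-based) is embedded
#' in model checkpoints as an integrity check and used for golden-file
#' regression tests.
#'
#' @param tab a `cayley_d4h` object.
#' @return `cayley_to_json`: a JSON string; `cayley_from_json`: a list with
#'   `compose` and `inverse` matching the `cayley_d4h` fields.
#' @export
cayley_to_json <- function(tab = d4h_cayley()) {
  jsonlite::toJSON(list(group = "D4h", order = tab$order,
                        compose = tab$compose, inverse = tab$inverse),
                   auto_unbox = TRUE)
}

#' @rdname cayley_to_json
#' @param json a JSON string produced by [cayley_to_json()].
#' @export
cayley_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$compose <- matrix(as.integer(x$compose), 16, 16)
  x$inverse <- as.integer(x$inverse)
  x
}
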