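# Internal layer engine: explicit forward/backward passes for the handful of
# layer types the architectures need. Each layer is a plain list with a `kind`
# field plus parameters; `.lfwd` / `.lbwd` dispatch on `kind`. Volumes travel
# as arrays (x, y, z, channels); oriented feature maps keep the orientation
# axis flattened into the channel axis (orientation fastest), which makes a
# group-equivariant layer a plain 3D correlation with an expanded kernel bank.

# Scatter-accumulate: out[i] = sum of vals where idx == i, i in 1..n.
# Every index in 1..n is assumed present (true for kernel expansions, where
# each base weight appears exactly 16 times).
.accum_by_index <- function(vals, idx, n) {
  r <- rowsum(matrix(vals, ncol = 1L), group = idx, reorder = TRUE)
  stopifnot(nrow(r) == n)
  as.vector(r)
}

# ---- kernel expansion index maps --------------------------------------------

# Lifting kernel expansion: base W [kx,ky,kz,cin,cout] -> expanded
# [kx,ky,kz,cin,16*cout], expanded slice for (g, co) = act_on_volume(g, W[..co]).
# Returns the integer index vector idx with expanded_vec = base_vec[idx].
.expand_idx_lift <- function(k, cin, cout) {
  nb <- prod(k) * cin * cout
  A <- array(seq_len(nb), dim = c(k, cin, cout))
  E <- array(0L, dim = c(k, cin, 16L * cout))
  for (co in seq_len(cout)) {
    base <- A[, , , , co, drop = FALSE]
    for (g in 0:15) {
      E[, , , , (co - 1L) * 16L + g + 1L] <- act_on_volume(g, base)
    }
  }
  as.vector(E)
}

# Group-conv kernel expansion: base W [kx,ky,kz,16,cin,cout] (input-orientation
# axis h in position 4) -> expanded [kx,ky,kz,16*cin,16*cout] with
# expanded[.., (h,ci), (g,co)] = act_on_volume(g, W[.., compose(inv(g), h), ci, co]).
.expand_idx_gconv <- function(k, cin, cout) {
  tab <- d4h_cayley()
  nb <- prod(k) * 16L * cin * cout
  A <- array(seq_len(nb), dim = c(k, 16L, cin, cout))
  E <- array(0L, dim = c(k, 16L * cin, 16L, cout))
  for (g in 0:15) {
    inv_g <- tab$inverse[g + 1L]
    hsrc <- tab$compose[inv_g + 1L, ] + 1L   # source orientation for target h
    B <- A[, , , hsrc, , , drop = FALSE]
    B <- act_on_volume(g, B)
    dim(B) <- c(k, 16L * cin, cout)
    E[, , , , g + 1L, ] <- B
  }
  as.vector(E)
}

# ---- constructors ------------------------------------------------------------

.he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

.layer_conv <- function(cin, cout, k, equivariant_input = FALSE) {
  W <- array(.he_init(prod(k) * cin * cout, prod(k) * cin), dim = c(k, cin, cout))
  list(kind = "conv", k = k, cin = cin, cout = cout, W = W, b = numeric(cout))
}

.layer_lift <- function(cin, cout, k) {
  if (any(k %% 2L == 0L))
    stop("equivariant layers require odd kernel extents (rotation center undefined otherwise)")
  if (k[1] != k[2])
    stop("kernel in-plane extent must be square for exact kernel rotation")
  W <- array(.he_init(prod(k) * cin * cout, prod(k) * cin), dim = c(k, cin, cout))
  list(kind = "lift", k = k, cin = cin, cout = cout, W = W, b = numeric(cout),
       idx = .expand_idx_lift(k, cin, cout))
}

.layer_gconv <- function(cin, cout, k) {
  if (any(k %% 2L == 0L))
    stop("equivariant layers require odd kernel extents (rotation center undefined otherwise)")
  if (k[1] != k[2])
    stop("kernel in-plane extent must be square for exact kernel rotation")
  W <- array(.he_init(prod(k) * 16L * cin * cout, prod(k) * 16L * cin),
             dim = c(k, 16L, cin, cout))
  list(kind = "gconv", k = k, cin = cin, cout = cout, W = W, b = numeric(cout),
       idx = .expand_idx_gconv(k, cin, cout))
}

.layer_relu     <- function() list(kind = "relu")
# instance normalization: per-sample, per-channel standardization over space;
# exactly equivariant (spatial permutations leave channel stats unchanged and
# orientation-channel permutations carry them along)
.layer_inorm    <- function(eps = 1e-5) list(kind = "inorm", eps = eps)
.layer_maxpool  <- function() list(kind = "maxpool")
.layer_orientpool <- function(mode = c("max", "mean")) {
  list(kind = "orientpool", mode = match.arg(mode))
}
.layer_gap      <- function() list(kind = "gap")
.layer_dense    <- function(nin, nout, act = c("linear", "relu")) {
  act <- match.arg(act)
  W <- matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  list(kind = "dense", nin = nin, nout = nout, act = act, W = W, b = numeric(nout))
}
.layer_dropout  <- function(p) list(kind = "dropout", p = p)
.layer_upsample <- function(target = NULL) list(kind = "upsample", target = target)

# ---- forward -----------------------------------------------------------------

.conv_expand <- function(l) {
  if (l$kind == "conv") {
    list(W = l$W, b = l$b, kdim = c(l$k, l$cin, l$cout))
  } else if (l$kind == "lift") {
    Wexp <- array(l$W[l$idx], dim = c(l$k, l$cin, 16L * l$cout))
    list(W = Wexp, b = rep(l$b, each = 16L), kdim = c(l$k, l$cin, 16L * l$cout))
  } else {
    Wexp <- array(l$W[l$idx], dim = c(l$k, 16L * l$cin, 16L * l$cout))
    list(W = Wexp, b = rep(l$b, each = 16L),
         kdim = c(l$k, 16L * l$cin, 16L * l$cout))
  }
}

.lfwd <- function(l, x, training = FALSE) {
  switch(l$kind,
    conv = , lift = , gconv = {
      d <- dim(x)
      idim <- as.integer(c(d[1:3], prod(d[-(1:3)])))
      ex <- .conv_expand(l)
      ntap <- prod(ex$kdim[1:3]) * ex$kdim[4]
      nvox <- prod(d[1:3])
      if (nvox * ntap * 8 <= 3e8) {
        # im2col + BLAS GEMM path (fast at training sizes)
        cols <- im2col3d(as.vector(x), idim, as.integer(ex$kdim[1:3]))
        out <- cols %*% matrix(ex$W, ntap, ex$kdim[5])
        out <- out + rep(ex$b, each = nvox)
        dim(out) <- c(d[1:3], ex$kdim[5])
        list(out = out, cache = list(x = x, idim = idim, ex = ex, cols = cols))
      } else {
        out <- conv3d_fwd(as.vector(x), idim, as.vector(ex$W),
                          as.integer(ex$kdim), ex$b)
        dim(out) <- c(d[1:3], ex$kdim[5])
        list(out = out, cache = list(x = x, idim = idim, ex = ex))
      }
    },
    relu = {
      out <- x
      neg <- x < 0
      out[neg] <- 0
      list(out = out, cache = neg)
    },
    inorm = {
      d <- dim(x)
      nv <- prod(d[1:3])
      nc <- prod(d[-(1:3)])
      M <- matrix(x, nv, nc)
      mu <- colMeans(M)
      v <- colMeans(M^2) - mu^2
      inv_sd <- 1 / sqrt(pmax(v, 0) + l$eps)
      Y <- (M - rep(mu, each = nv)) * rep(inv_sd, each = nv)
      out <- Y
      dim(out) <- d
      list(out = out, cache = list(Y = Y, inv_sd = inv_sd, d = d, nv = nv))
    },
    maxpool = {
      d <- dim(x)
      idim <- as.integer(c(d[1:3], prod(d[-(1:3)])))
      r <- maxpool3d_fwd(as.vector(x), idim)
      out <- r$out
      dim(out) <- c(d[1:3] %/% 2L, d[-(1:3)])
      list(out = out, cache = list(argmax = r$argmax, idim = idim, d = d))
    },
    orientpool = {
      d <- dim(x)
      nC <- d[4] %/% 16L
      nv <- prod(d[1:3])
      M <- x
      dim(M) <- c(nv, 16L, nC)
      if (l$mode == "max") {
        out <- M[, 1L, ]
        amax <- matrix(1L, nv, nC)
        for (g in 2:16) {
          sl <- M[, g, ]
          upd <- sl > out
          out[upd] <- sl[upd]
          amax[upd] <- g
        }
        dim(out) <- c(d[1:3], nC)
        list(out = out, cache = list(amax = amax, d = d, nC = nC))
      } else {
        out <- M[, 1L, ]
        for (g in 2:16) out <- out + M[, g, ]
        out <- out / 16
        dim(out) <- c(d[1:3], nC)
        list(out = out, cache = list(d = d, nC = nC))
      }
    },
    gap = {
      d <- dim(x)
      nv <- prod(d[1:3])
      out <- colMeans(matrix(x, nv, d[4]))
      list(out = out, cache = list(d = d))
    },
    dense = {
      z <- drop(crossprod(l$W, x)) + l$b
      out <- if (l$act == "relu") pmax(z, 0) else z
      list(out = out, cache = list(x = x, z = z))
    },
    dropout = {
      if (training && l$p > 0) {
        mask <- (stats::runif(length(x)) >= l$p) / (1 - l$p)
        list(out = x * mask, cache = mask)
      } else {
        list(out = x, cache = NULL)
      }
    },
    upsample = {
      d <- dim(x)
      out <- x[rep(seq_len(d[1]), each = 2L),
               rep(seq_len(d[2]), each = 2L),
               rep(seq_len(d[3]), each = 2L), , drop = FALSE]
      du <- dim(out)
      crop <- NULL
      pad <- NULL
      if (!is.null(l$target)) {
        tgt <- l$target
        if (any(du[1:3] > tgt)) {
          out <- out[seq_len(min(du[1], tgt[1])), seq_len(min(du[2], tgt[2])),
                     seq_len(min(du[3], tgt[3])), , drop = FALSE]
          crop <- dim(out)
        }
        if (any(dim(out)[1:3] < tgt)) {
          padded <- array(0, dim = c(tgt, du[4]))
          dc <- dim(out)
          padded[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), ] <- out
          pad <- dc
          out <- padded
        }
      }
      list(out = out, cache = list(d = d, du = du, crop = crop, pad = pad))
    },
    stop("unknown layer kind: ", l$kind))
}

# ---- backward ----------------------------------------------------------------

.sum_halve_axis <- function(g, axis) {
  # collapse a factor-2 axis (axis indexes the expanded dim pair) by summation
  d <- dim(g)
  perm <- c(axis, setdiff(seq_along(d), axis))
  g2 <- aperm(g, perm)
  s <- colSums(matrix(g2, nrow = 2L))
  dim(s) <- d[-axis]
  s
}

.lbwd <- function(l, cache, g) {
  switch(l$kind,
    conv = , lift = , gconv = {
      ex <- cache$ex
      d3 <- cache$idim[1:3]
      nflat <- ex$kdim[5]
      if (!is.null(cache$cols)) {
        nvox <- prod(d3)
        ntap <- prod(ex$kdim[1:3]) * ex$kdim[4]
        gmat <- matrix(g, nvox, nflat)
        gWexp <- crossprod(cache$cols, gmat)
        gin <- col2im3d(gmat %*% t(matrix(ex$W, ntap, nflat)),
                        cache$idim, as.integer(ex$kdim[1:3]))
        dim(gin) <- dim(cache$x)
      } else {
        gin <- conv3d_bwd_input(as.vector(g), cache$idim, as.vector(ex$W),
                                as.integer(ex$kdim))
        dim(gin) <- dim(cache$x)
        gWexp <- conv3d_bwd_weights(as.vector(cache$x), cache$idim,
                                    as.vector(g), as.integer(ex$kdim))
      }
      gbflat <- colSums(matrix(g, prod(d3), nflat))
      if (l$kind == "conv") {
        gW <- array(gWexp, dim = dim(l$W))
        gb <- gbflat
      } else {
        gW <- array(.accum_by_index(gWexp, l$idx, length(l$W)), dim = dim(l$W))
        gb <- colSums(matrix(gbflat, 16L, l$cout))
      }
      list(gin = gin, grads = list(W = gW, b = gb))
    },
    relu = {
      g[cache] <- 0
      list(gin = g, grads = NULL)
    },
    inorm = {
      nv <- cache$nv
      G <- matrix(g, nv, length(cache$inv_sd))
      Y <- cache$Y
      gy_mean <- colMeans(G)
      gyy_mean <- colMeans(G * Y)
      gin <- (G - rep(gy_mean, each = nv) - Y * rep(gyy_mean, each = nv)) *
        rep(cache$inv_sd, each = nv)
      dim(gin) <- cache$d
      list(gin = gin, grads = NULL)
    },
    maxpool = {
      gin <- numeric(prod(cache$idim))
      gin[cache$argmax + 1L] <- as.vector(g)
      dim(gin) <- cache$d
      list(gin = gin, grads = NULL)
    },
    orientpool = {
      d <- cache$d
      nv <- prod(d[1:3])
      nC <- cache$nC
      gmat <- matrix(g, nv, nC)
      gin <- array(0, dim = c(nv, 16L, nC))
      if (!is.null(cache$amax)) {
        for (gg in 1:16) {
          sel <- cache$amax == gg
          if (any(sel)) {
            sl <- gin[, gg, ]
            sl[sel] <- gmat[sel]
            gin[, gg, ] <- sl
          }
        }
      } else {
        for (gg in 1:16) gin[, gg, ] <- gmat / 16
      }
      dim(gin) <- d
      list(gin = gin, grads = NULL)
    },
    gap = {
      d <- cache$d
      nv <- prod(d[1:3])
      gin <- array(rep(as.vector(g), each = nv) / nv, dim = d)
      list(gin = gin, grads = NULL)
    },
    dense = {
      dz <- if (l$act == "relu") as.vector(g) * (cache$z > 0) else as.vector(g)
      gW <- outer(cache$x, dz)
      gb <- dz
      gin <- drop(l$W %*% dz)
      list(gin = gin, grads = list(W = gW, b = gb))
    },
    dropout = {
      if (is.null(cache)) list(gin = g, grads = NULL)
      else list(gin = g * cache, grads = NULL)
    },
    upsample = {
      # undo pad, then crop (re-pad with zeros), then collapse the x2 axes
      if (!is.null(cache$pad)) {
        dc <- cache$pad
        g <- g[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), , drop = FALSE]
      }
      if (!is.null(cache$crop) || any(dim(g)[1:3] < cache$du[1:3])) {
        full <- array(0, dim = cache$du)
        dg <- dim(g)
        full[seq_len(dg[1]), seq_len(dg[2]), seq_len(dg[3]), ] <- g
        g <- full
      }
      du <- cache$du
      dim(g) <- c(2L, du[1] %/% 2L, 2L, du[2] %/% 2L, 2L, du[3] %/% 2L, du[4])
      g <- .sum_halve_axis(g, 1L)
      g <- .sum_halve_axis(g, 2L)
      g <- .sum_halve_axis(g, 3L)
      list(gin = g, grads = NULL)
    },
    stop("unknown layer kind: ", l$kind))
}

# ---- network helpers ---------------------------------------------------------

.net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- .lfwd(layers[[i]], x, training = training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

.net_backward <- function(layers, caches, g) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- .lbwd(layers[[i]], caches[[i]], g)
    grads[i] <- list(r$grads)
    g <- r$gin
  }
  list(gin = g, grads = grads)
}

.net_nparams <- function(layers) {
  sum(vapply(layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, numeric(1)))
}
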