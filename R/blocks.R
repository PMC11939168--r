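# Training-free reference implementations of the two architectural
# ingredients used by the detector: coordinate attention (direction-wise
# global pooling producing per-height and per-width channel attention
# factors) and additive reversible blocks/columns (inputs exactly
# recoverable from outputs, so feature information is preserved through
# depth).  Plain-array forward passes with structural invariants -- no
# autodiff, no training; the module exists for desk-scale verification.
#
# Feature maps are plain 3-D arrays with dim = c(channels, height, width).

check_feature_map <- function(x, what = "feature map") {
  if (!is.array(x) || length(dim(x)) != 3)
    stop_contract("%s must be a 3-D array (C, H, W)", what)
  if (any(dim(x) < 1)) stop_contract("%s dimensions must be >= 1", what)
  if (!all(is.finite(x))) stop_contract("%s must be finite", what)
  invisible(x)
}

sigmoid <- function(z) plogis(z)

# 1x1 "convolution" over channels: weights (out x in) applied at every
# spatial location of a (in x H x W) array.
conv1x1 <- function(w, b, x) {
  d <- dim(x)
  out <- w %*% matrix(x, d[1], d[2] * d[3]) + b
  array(out, c(nrow(w), d[2], d[3]))
}

#' Coordinate-attention parameters
#'
#' Deterministic Gaussian parameter arrays for the shared pooled-descriptor
#' transform and the two per-direction transforms, generated from a seed.
#' The shared transform reduces channels to `max(8, ceiling(C / reduction))`.
#'
#' @param channels input channel count C.
#' @param reduction channel reduction ratio r of the shared transform
#'   (default 32, the common choice).
#' @param seed parameter seed.
#' @return list of class `coord_att_params` with weight matrices `w1`
#'   (mid x C), `wh`, `ww` (C x mid) and biases `b1`, `bh`, `bw`.
#' @export
coord_att_params <- function(channels, reduction = 32, seed = 1L) {
  mid <- max(8L, as.integer(ceiling(channels / reduction)))
  withr::with_seed(seed, {
    structure(list(channels = channels, mid = mid,
                   w1 = matrix(rnorm(mid * channels, sd = 1 / sqrt(channels)),
                               mid, channels),
                   b1 = rnorm(mid, sd = 0.1),
                   wh = matrix(rnorm(channels * mid, sd = 1 / sqrt(mid)),
                               channels, mid),
                   bh = rnorm(channels, sd = 0.1),
                   ww = matrix(rnorm(channels * mid, sd = 1 / sqrt(mid)),
                               channels, mid),
                   bw = rnorm(channels, sd = 0.1)),
              class = "coord_att_params")
  })
}

#' Coordinate-attention forward pass
#'
#' Mean-pools the input over width (a C x H descriptor) and over height
#' (C x W), concatenates the descriptors along the spatial axis, applies a
#' shared 1x1 transform with ReLU, splits, applies per-direction 1x1
#' transforms with logistic squashing to obtain attention factors
#' `a_h` (C x H) and `a_w` (C x W), and returns
#' `y[c, i, j] = x[c, i, j] * a_h[c, i] * a_w[c, j]`.
#' Output shape equals input shape; attention factors are strictly in
#' (0, 1), so output magnitude never exceeds input magnitude element-wise.
#'
#' @param x 3-D array `(C, H, W)`.
#' @param p a [coord_att_params()] for the same C.
#' @return 3-D array of the same shape.
#' @export
coord_att_forward <- function(x, p) {
  check_feature_map(x)
  d <- dim(x)
  if (d[1] != ncol(p$w1))
    stop_contract("channel mismatch: x has %d channels, params expect %d",
                  d[1], ncol(p$w1))
  C <- d[1]; H <- d[2]; W <- d[3]
  pool_h <- apply(x, c(1, 2), mean)              # C x H (mean over width)
  pool_w <- apply(x, c(1, 3), mean)              # C x W (mean over height)
  if (H == 1) pool_h <- matrix(pool_h, C, H)
  if (W == 1) pool_w <- matrix(pool_w, C, W)
  z <- pmax(p$w1 %*% cbind(pool_h, pool_w) + p$b1, 0)   # mid x (H + W)
  a_h <- sigmoid(p$wh %*% z[, seq_len(H), drop = FALSE] + p$bh)        # C x H
  a_w <- sigmoid(p$ww %*% z[, H + seq_len(W), drop = FALSE] + p$bw)    # C x W
  ah_arr <- array(a_h, c(C, H, W))                       # recycles over W
  aw_arr <- aperm(array(a_w, c(C, W, H)), c(1, 3, 2))    # broadcast over H
  x * ah_arr * aw_arr
}

#' Reversible-block parameters
#'
#' Parameters of the additive coupling `F` (a 1x1 linear map over the half
#' channels followed by tanh), generated deterministically from a seed.
#'
#' @param channels input channel count (must be even).
#' @param seed parameter seed.
#' @param zero all-zero parameters, making `F == 0` (the block degenerates
#'   to a channel swap).
#' @return list of class `rev_block_params`.
#' @export
rev_block_params <- function(channels, seed = 1L, zero = FALSE) {
  if (channels %% 2 != 0)
    stop_contract("reversible blocks require an even channel count")
  h <- channels %/% 2
  if (zero) {
    wf <- matrix(0, h, h); bf <- numeric(h)
  } else {
    p <- withr::with_seed(seed, list(
      wf = matrix(rnorm(h * h, sd = 1 / sqrt(h)), h, h),
      bf = rnorm(h, sd = 0.1)))
    wf <- p$wf; bf <- p$bf
  }
  structure(list(channels = channels, wf = wf, bf = bf),
            class = "rev_block_params")
}

coupling_f <- function(p, u) tanh(conv1x1(p$wf, p$bf, u))

#' Additive reversible block
#'
#' Splits the channels into halves `(x1, x2)` and produces
#' `(y1, y2) = (x2, x1 + F(x2))`; `reversible_inverse` recovers the input
#' exactly up to float error.  With `F == 0` the block is a pure channel
#' swap.
#'
#' @param x 3-D array with an even channel count.
#' @param p a [rev_block_params()].
#' @return 3-D array of the same shape.
#' @export
reversible_forward <- function(x, p) {
  check_feature_map(x)
  C <- dim(x)[1]
  if (C != p$channels) stop_contract("channel mismatch")
  if (C %% 2 != 0) stop_contract("even channel count required")
  h <- C %/% 2
  x1 <- x[seq_len(h), , , drop = FALSE]
  x2 <- x[h + seq_len(h), , , drop = FALSE]
  y <- array(0, dim(x))
  y[seq_len(h), , ] <- x2
  y[h + seq_len(h), , ] <- x1 + coupling_f(p, x2)
  y
}

#' @rdname reversible_forward
#' @param y output of [reversible_forward()].
#' @export
reversible_inverse <- function(y, p) {
  check_feature_map(y)
  C <- dim(y)[1]
  if (C != p$channels) stop_contract("channel mismatch")
  h <- C %/% 2
  x2 <- y[seq_len(h), , , drop = FALSE]
  y2 <- y[h + seq_len(h), , , drop = FALSE]
  x <- array(0, dim(y))
  x[seq_len(h), , ] <- y2 - coupling_f(p, x2)
  x[h + seq_len(h), , ] <- x2
  x
}

#' Reversible-column parameters
#'
#' One reversible block for the lowest level plus a coupling map per higher
#' level connecting it to the level below (channel counts may differ across
#' levels; spatial dims must match).
#'
#' @param level_channels integer vector of channel counts, lowest level
#'   first; the first entry must be even.
#' @param seed parameter seed.
#' @return list of class `revcol_params`.
#' @export
revcol_params <- function(level_channels, seed = 1L) {
  k <- length(level_channels)
  couplings <- vector("list", k)
  couplings[[1]] <- rev_block_params(level_channels[1], seed = seed)
  if (k > 1) {
    for (l in 2:k) {
      cl <- level_channels[l]; cb <- level_channels[l - 1]
      p <- withr::with_seed(seed + l, list(
        w = matrix(rnorm(cl * cb, sd = 1 / sqrt(cb)), cl, cb),
        b = rnorm(cl, sd = 0.1)))
      couplings[[l]] <- p
    }
  }
  structure(list(level_channels = as.integer(level_channels),
                 couplings = couplings), class = "revcol_params")
}

#' One reversible column update
#'
#' Each level's new state combines the previous column's same-level state
#' with the current column's lower-level state through an additive
#' (hence invertible) link: the lowest level passes through a reversible
#' block, and level `l > 1` becomes
#' `new[l] = prev[l] + F_l(new[l - 1])`.  `revcol_column_inverse`
#' reconstructs the previous column's states from the new ones; composing
#' several column passes and inverting in reverse order recovers the
#' original states, so information injected at any level survives arbitrary
#' depth.  With a single level the pass is exactly [reversible_forward()].
#'
#' @param levels list of 3-D arrays, lowest level first; spatial dims must
#'   agree.
#' @param p a [revcol_params()] matching the level channel counts.
#' @return list of updated feature maps of the same shapes.
#' @export
revcol_column_pass <- function(levels, p) {
  check_levels(levels, p)
  out <- vector("list", length(levels))
  out[[1]] <- reversible_forward(levels[[1]], p$couplings[[1]])
  for (l in seq_along(levels)[-1]) {
    cp <- p$couplings[[l]]
    out[[l]] <- levels[[l]] + tanh(conv1x1(cp$w, cp$b, out[[l - 1]]))
  }
  out
}

#' @rdname revcol_column_pass
#' @param new output of [revcol_column_pass()].
#' @export
revcol_column_inverse <- function(new, p) {
  check_levels(new, p)
  prev <- vector("list", length(new))
  prev[[1]] <- reversible_inverse(new[[1]], p$couplings[[1]])
  for (l in seq_along(new)[-1]) {
    cp <- p$couplings[[l]]
    prev[[l]] <- new[[l]] - tanh(conv1x1(cp$w, cp$b, new[[l - 1]]))
  }
  prev
}

check_levels <- function(levels, p) {
  if (length(levels) != length(p$level_channels))
    stop_contract("level count mismatch")
  for (l in seq_along(levels)) {
    check_feature_map(levels[[l]], sprintf("level %d", l))
    if (dim(levels[[l]])[1] != p$level_channels[l])
      stop_contract("level %d channel mismatch", l)
  }
  sp <- vapply(levels, function(x) dim(x)[2:3], numeric(2))
  if (length(levels) > 1 && any(sp[, -1] != sp[, 1]))
    stop_contract("levels must share spatial dimensions")
  invisible(levels)
}
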