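# Dense kernels for the small convolutional hierarchy.  Convolutions use
# the im2col strategy: patches are gathered with a precomputed index map
# and the convolution becomes one BLAS matrix multiply, which is fast
# enough on a single CPU at 32 x 32 scale.  Activations are stored as
# (height, width, channels, batch) arrays; conv weights as
# (out_channels, k*k*in_channels) matrices.

# Precompute the patch index map for a 3x3 same-padded convolution over a
# (h, w, cin) volume replicated across a batch of n images.
conv_plan <- function(h, w, cin, n, k = 3) {
  p <- (k - 1) %/% 2
  hp <- h + 2 * p; wp <- w + 2 * p
  off <- expand.grid(dy = 0:(k - 1), dx = 0:(k - 1), ch = seq_len(cin))
  row_part <- off$dy + off$dx * hp + (off$ch - 1) * hp * wp
  out <- expand.grid(y = seq_len(h), x = seq_len(w))
  col_part <- out$y + (out$x - 1) * hp
  idx1 <- outer(row_part, col_part, "+")          # kkc x hw, 1-based
  per_img <- hp * wp * cin
  idx <- matrix(rep(idx1, n), nrow(idx1)) +
    rep((seq_len(n) - 1) * per_img, each = length(idx1))
  storage.mode(idx) <- "integer"
  # precomputed scatter for the adjoint (col2im): sorting the fixed index
  # map once turns per-batch gradient accumulation into one cumsum pass
  ord <- order(idx)
  sorted <- idx[ord]
  ends <- which(c(sorted[-1] != sorted[-length(sorted)], TRUE))
  list(idx = idx, ord = ord, ends = ends, targets = sorted[ends],
       h = h, w = w, cin = cin, n = n, k = k, p = p, hp = hp, wp = wp)
}

pad_input <- function(x, plan) {
  d <- dim(x)
  xp <- array(0, dim = c(plan$hp, plan$wp, d[3], d[4]))
  xp[(plan$p + 1):(plan$p + d[1]), (plan$p + 1):(plan$p + d[2]), , ] <- x
  xp
}

conv_forward <- function(x, w_mat, bias, plan) {
  d <- dim(x)
  xp <- pad_input(x, plan)
  a <- xp[plan$idx]
  dim(a) <- c(nrow(plan$idx), ncol(plan$idx))
  y <- w_mat %*% a + bias
  cout <- nrow(w_mat)
  dim(y) <- c(cout, plan$h * plan$w, d[4])
  y <- aperm(y, c(2, 1, 3))
  dim(y) <- c(plan$h, plan$w, cout, d[4])
  list(out = y, patches = a)
}

conv_backward <- function(d_out, w_mat, patches, plan) {
  d <- dim(d_out)
  cout <- d[3]; n <- d[4]
  dy <- d_out
  dim(dy) <- c(plan$h * plan$w, cout, n)
  dy <- aperm(dy, c(2, 1, 3))
  dim(dy) <- c(cout, plan$h * plan$w * n)
  dw <- tcrossprod(dy, patches)
  db <- rowSums(dy)
  da <- crossprod(w_mat, dy)
  cs <- cumsum(da[plan$ord])
  sums <- cs[plan$ends] - c(0, cs[plan$ends[-length(plan$ends)]])
  dxp <- numeric(plan$hp * plan$wp * plan$cin * n)
  dxp[plan$targets] <- sums
  dim(dxp) <- c(plan$hp, plan$wp, plan$cin, n)
  dx <- dxp[(plan$p + 1):(plan$p + plan$h),
            (plan$p + 1):(plan$p + plan$w), , , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

relu_forward <- function(x) x * (x > 0)

relu_backward <- function(d_out, x) d_out * (x > 0)

# Non-overlapping 2x2 average pooling (and its adjoint).  Average pooling
# is used throughout so the generic taps are average-pooled activations.
avgpool2_forward <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], 2); o2 <- seq(2, d[1], 2)
  e1 <- seq(1, d[2], 2); e2 <- seq(2, d[2], 2)
  (x[o1, e1, , , drop = FALSE] + x[o2, e1, , , drop = FALSE] +
   x[o1, e2, , , drop = FALSE] + x[o2, e2, , , drop = FALSE]) / 4
}

avgpool2_backward <- function(d_out, in_dim) {
  dx <- array(0, dim = in_dim)
  o1 <- seq(1, in_dim[1], 2); o2 <- seq(2, in_dim[1], 2)
  e1 <- seq(1, in_dim[2], 2); e2 <- seq(2, in_dim[2], 2)
  g <- d_out / 4
  dx[o1, e1, , ] <- g; dx[o2, e1, , ] <- g
  dx[o1, e2, , ] <- g; dx[o2, e2, , ] <- g
  dx
}

# Mean over the two spatial dimensions: (h, w, c, n) -> (c, n).
global_avgpool <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  m <- colMeans(x)
  matrix(m, d[3], d[4])
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
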