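# Low-level raster operations used by the synthetic world and the
# preprocessing pipeline.  Images are numeric matrices (rows = y, cols = x)
# with intensities in [0, 1].

#' Bilinear image resize
#'
#' @param img numeric matrix of intensities.
#' @param out_h,out_w output dimensions in pixels.
#' @return an `out_h` x `out_w` matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # pixel-centre alignment: target centre t maps to source (t + .5)*s - .5
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  y0 <- pmin(floor(sy), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(sx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- sy - y0; fx <- sx - x0
  a <- img[y0 + 1, x0 + 1, drop = FALSE]
  b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- img[y1 + 1, x0 + 1, drop = FALSE]
  d <- img[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w)
  wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  (a * (1 - wy) + c_ * wy) * (1 - wx) + (b * (1 - wy) + d * wy) * wx
}

# Sample a stamp under an inverse affine map (rotation + isotropic scale)
# and composite it onto the canvas with per-pixel max (later parts occlude
# rather than add, keeping intensities in [0, 1]).  Parts falling partly
# outside the canvas are clipped at the border.
#
# canvas: H x W matrix; stamp: h x w matrix; cy, cx: centre in canvas
# pixel coordinates; scale: stamp magnification; theta: rotation (radians).
place_stamp <- function(canvas, stamp, cy, cx, scale, theta) {
  sh <- nrow(stamp); sw <- ncol(stamp)
  H <- nrow(canvas); W <- ncol(canvas)
  half <- ceiling(sqrt(sh^2 + sw^2) * scale / 2) + 1
  y_rng <- max(1, floor(cy - half)):min(H, ceiling(cy + half))
  x_rng <- max(1, floor(cx - half)):min(W, ceiling(cx + half))
  if (length(y_rng) == 0 || length(x_rng) == 0) return(canvas)
  dy <- matrix(y_rng - cy, length(y_rng), length(x_rng))
  dx <- matrix(x_rng - cx, length(y_rng), length(x_rng), byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  # inverse map: un-rotate, un-scale, then shift to stamp-centre coords
  uy <- ( ct * dy + st * dx) / scale + (sh + 1) / 2
  ux <- (-st * dy + ct * dx) / scale + (sw + 1) / 2
  y0 <- floor(uy); x0 <- floor(ux)
  fy <- uy - y0; fx <- ux - x0
  val <- numeric(length(uy))
  pick <- function(yy, xx) {
    ok <- yy >= 1 & yy <= sh & xx >= 1 & xx <= sw
    v <- numeric(length(yy))
    v[ok] <- stamp[cbind(yy[ok], xx[ok])]
    v
  }
  val <- pick(y0, x0) * (1 - fy) * (1 - fx) +
    pick(y0, x0 + 1) * (1 - fy) * fx +
    pick(y0 + 1, x0) * fy * (1 - fx) +
    pick(y0 + 1, x0 + 1) * fy * fx
  patch <- canvas[y_rng, x_rng, drop = FALSE]
  canvas[y_rng, x_rng] <- pmax(patch, matrix(val, length(y_rng)))
  canvas
}
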