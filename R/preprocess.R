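#' Resize-and-crop preprocessing
#'
#' Scales the shortest edge of an image to `target_size` pixels while
#' preserving the aspect ratio, then takes a square
#' `target_size` x `target_size` crop: a random crop during training (for
#' augmentation) and a center crop during evaluation and feature
#' extraction.  A square image already at the target size passes through
#' unchanged.
#'
#' @param image numeric intensity matrix.
#' @param target_size square output edge in pixels.
#' @param crop_mode `"center"` or `"random"`; random crops consume the
#'   current RNG stream.
#' @return a `target_size` x `target_size` matrix.
#' @export
preprocess_image <- function(image, target_size,
                             crop_mode = c("center", "random")) {
  crop_mode <- match.arg(crop_mode)
  if (!is.matrix(image) || nrow(image) == 0 || ncol(image) == 0) {
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  if (h == target_size && w == target_size) return(image)
  s <- target_size / min(h, w)
  nh <- max(target_size, round(h * s))
  nw <- max(target_size, round(w * s))
  img <- resize_bilinear(image, nh, nw)
  slack_y <- nh - target_size
  slack_x <- nw - target_size
  if (crop_mode == "random") {
    oy <- if (slack_y > 0) sample.int(slack_y + 1, 1) - 1 else 0
    ox <- if (slack_x > 0) sample.int(slack_x + 1, 1) - 1 else 0
  } else {
    oy <- slack_y %/% 2
    ox <- slack_x %/% 2
  }
  img[(oy + 1):(oy + target_size), (ox + 1):(ox + target_size), drop = FALSE]
}

# Preprocess all images of a dataset into a (size, size, 1, n) input array.
preprocess_batch <- function(dataset, target_size, crop_mode = "center") {
  n <- length(dataset$ids)
  out <- array(0, dim = c(target_size, target_size, 1, n))
  for (i in seq_len(n)) {
    out[, , 1, i] <- preprocess_image(dataset$images[, , i], target_size,
                                      crop_mode)
  }
  out
}
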