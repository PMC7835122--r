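#' Signal-detection sensitivity index d-prime
#'
#' Computes \eqn{d' = \Phi^{-1}(HR) - \Phi^{-1}(FAR)} from confusion
#' counts, where HR is the hit rate over test positives and FAR the
#' false-alarm rate over test negatives.  Perfect or zero rates give
#' infinite quantiles, so a correction is applied first:
#'
#' * `clamp` (default): each rate is confined to
#'   `[1/(2N), 1 - 1/(2N)]` for its own trial count N, a standard
#'   convention for extreme proportions.
#' * `loglinear`: rates are `(count + 0.5) / (N + 1)` (add one half
#'   success and half failure).
#' * `none`: raw rates; an extreme rate is an error, signalling that a
#'   correction is required.
#'
#' Vectorised over counts.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative
#'   integer counts; `hits + misses >= 1` and
#'   `false_alarms + correct_rejections >= 1`.
#' @param correction `"clamp"`, `"loglinear"` or `"none"`.
#' @return d-prime value(s); 0 means chance performance.
#' @export
#' @examples
#' dprime(42, 8, 8, 42)                    # HR .84, FAR .16 -> about 1.99
#' dprime(10, 0, 0, 10)                    # perfect, clamped to .95/.05
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   correction = c("clamp", "loglinear", "none")) {
  correction <- match.arg(correction)
  counts <- cbind(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  n_pos <- hits + misses
  n_neg <- false_alarms + correct_rejections
  if (any(n_pos < 1) || any(n_neg < 1)) {
    stop("need at least one test positive and one test negative",
         call. = FALSE)
  }
  hr <- hits / n_pos
  far <- false_alarms / n_neg
  if (correction == "clamp") {
    hr <- pmin(pmax(hr, 1 / (2 * n_pos)), 1 - 1 / (2 * n_pos))
    far <- pmin(pmax(far, 1 / (2 * n_neg)), 1 - 1 / (2 * n_neg))
  } else if (correction == "loglinear") {
    hr <- (hits + 0.5) / (n_pos + 1)
    far <- (false_alarms + 0.5) / (n_neg + 1)
  } else {
    if (any(hr %in% c(0, 1)) || any(far %in% c(0, 1))) {
      stop("rate of 0 or 1 with correction = \"none\" gives an infinite ",
           "quantile; choose a correction", call. = FALSE)
    }
  }
  stats::qnorm(hr) - stats::qnorm(far)
}
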