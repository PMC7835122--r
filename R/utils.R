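#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Streams of randomness for different roles (world building, per-role
#' dataset rendering, per-cell benchmark splits) are decoupled by hashing
#' the master seed together with a descriptive key.  The hash is a plain
#' polynomial string hash evaluated in double precision modulo the Mersenne
#' prime 2^31 - 1, so it is exactly reproducible across platforms and never
#' exceeds the range of a 32-bit integer seed.  Inserting a new category or
#' training-set size therefore never perturbs the draws of any other cell.
#'
#' @param master integer master seed.
#' @param ... further keys (coerced to character) identifying the stream.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(7, "dataset", "base-train")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "\r")
  bytes <- utf8ToInt(key)
  m <- 2147483647  # 2^31 - 1
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# Run an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so library internals never disturb user streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single positive integer", name),
         call. = FALSE)
  }
}
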