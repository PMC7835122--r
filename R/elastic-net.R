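#' Elastic-net logistic regression configuration
#'
#' The few-shot classifiers are one-vs-all binary logistic regressions
#' with an elastic-net penalty, fitted by monotone proximal gradient
#' descent on the objective
#' \deqn{\frac{1}{n}\sum_i \log(1 + e^{-y_i(w \cdot x_i + b)}) +
#'   \lambda\left(\alpha \|w\|_1 + \frac{1-\alpha}{2}\|w\|_2^2\right)}
#' with an unpenalised intercept.  At the tiny training sizes of the
#' few-shot protocol no cross-validation is possible (n can be 2), so the
#' defaults are scale-free and deterministic: an even L1/L2 mix
#' (`mix = 0.5`) and `penalty = 1/n` set at fit time.
#'
#' @param mix L1 fraction alpha in [0, 1]; 0 is ridge, 1 is lasso.
#' @param penalty overall penalty lambda >= 0, or `NULL` for `1/n`.
#' @param max_iterations iteration cap; fits that hit it are flagged
#'   unconverged.
#' @param tolerance convergence threshold on the per-iteration objective
#'   decrease.
#' @param standardize center/scale features using the training examples
#'   only (features with zero training variance get scale 1).
#' @param seed recorded for provenance; the solver itself is
#'   deterministic (fixed update order, zero initialisation).
#' @return an object of class `enet_config`.
#' @export
enet_config <- function(mix = 0.5, penalty = NULL, max_iterations = 1000,
                        tolerance = 1e-7, standardize = TRUE, seed = 1) {
  if (mix < 0 || mix > 1) stop("mix must lie in [0, 1]", call. = FALSE)
  if (!is.null(penalty) && penalty < 0) {
    stop("penalty must be non-negative", call. = FALSE)
  }
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  stop_if_not_count(max_iterations, "max_iterations")
  structure(list(mix = mix, penalty = penalty,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "enet_config")
}

#' Elastic-net logistic objective
#'
#' Mean logistic loss plus the elastic-net penalty on the weights (the
#' intercept is unpenalised).  Exposed so fits can be compared against
#' independent optimisers.
#'
#' @param x n x p feature matrix.
#' @param y labels in {-1, +1}.
#' @param weights,intercept classifier parameters.
#' @param mix,penalty elastic-net hyperparameters.
#' @export
enet_objective <- function(x, y, weights, intercept, mix, penalty) {
  m <- y * (drop(x %*% weights) + intercept)
  mean(log1p(exp(-m))) +
    penalty * (mix * sum(abs(weights)) +
                 (1 - mix) / 2 * sum(weights^2))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Fit an elastic-net logistic classifier
#'
#' Proximal gradient descent (gradient step on the smooth logistic +
#' ridge part, soft-thresholding for the L1 part) with a Lipschitz step
#' size from a power iteration and halving backtracking, so the objective
#' is non-increasing at every iteration.  The fit is deterministic: zero
#' initialisation, fixed update order.
#'
#' @param x n x p numeric feature matrix (n >= 2, finite).
#' @param y numeric labels in {-1, +1}, at least one of each class.
#' @param config an [enet_config()].
#' @return an object of class `enet_fit`: `weights` and `intercept` on the
#'   (standardized) fit scale, `center`/`scale` used at fit time,
#'   `converged`, `n_iter`, `objective` (final value) and `objective_path`.
#' @export
enet_fit <- function(x, y, config = enet_config()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be coded -1/+1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("training labels are single-class; need at least one example of ",
         "each class", call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n)
  penalty <- config$penalty %||% (1 / n)
  lam1 <- penalty * config$mix
  lam2 <- penalty * (1 - config$mix)

  if (config$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  } else {
    center <- rep(0, p); scale_ <- rep(1, p)
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  # Lipschitz bound for the smooth part: sigma_max([X 1])^2 / (4n) + lam2,
  # with the top singular value from a short power iteration on Z Z'.
  z1 <- cbind(xs, 1)
  zz <- tcrossprod(z1)
  v <- rep(1, n)
  for (i in 1:30) {
    v <- zz %*% v
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
  }
  smax2 <- drop(crossprod(v, zz %*% v))
  lip <- smax2 / (4 * n) + lam2
  step0 <- 1 / max(lip, 1e-12)

  w <- numeric(p); b <- 0
  obj <- function(w, b) {
    m <- y * (drop(xs %*% w) + b)
    mean(log1p(exp(-m))) + lam1 * sum(abs(w)) + lam2 / 2 * sum(w^2)
  }
  grad <- function(w, b) {
    m <- y * (drop(xs %*% w) + b)
    q <- stats::plogis(-m)           # 1 / (1 + exp(m))
    list(w = -drop(crossprod(xs, y * q)) / n + lam2 * w,
         b = -mean(y * q))
  }
  # Accelerated proximal gradient (FISTA) made monotone: the prox step is
  # taken from the momentum point, but an iterate that would increase the
  # objective triggers a momentum restart and a plain proximal step, so
  # the recorded objective path is non-increasing by construction.
  f <- obj(w, b)
  vw <- w; vb <- b
  tk <- 1
  path <- numeric(config$max_iterations)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(config$max_iterations)) {
    g <- grad(vw, vb)
    w_new <- soft_threshold(vw - step0 * g$w, step0 * lam1)
    b_new <- vb - step0 * g$b
    f_new <- obj(w_new, b_new)
    if (f_new > f + 1e-12) {
      # restart from the last accepted iterate with a guarded plain step
      tk <- 1
      g <- grad(w, b)
      step <- step0
      repeat {
        w_new <- soft_threshold(w - step * g$w, step * lam1)
        b_new <- b - step * g$b
        f_new <- obj(w_new, b_new)
        if (f_new <= f + 1e-12 || step < 1e-16) break
        step <- step / 2
      }
      f_new <- min(f_new, f)
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    vw <- w_new + (tk - 1) / t_next * (w_new - w)
    vb <- b_new + (tk - 1) / t_next * (b_new - b)
    tk <- t_next
    n_iter <- it
    path[it] <- f_new
    dec <- f - f_new
    w <- w_new; b <- b_new; f <- f_new
    if (dec >= 0 && dec < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  structure(list(weights = w, intercept = b, center = center,
                 scale = scale_, converged = converged, n_iter = n_iter,
                 objective = f, objective_path = path[seq_len(n_iter)],
                 config = config, penalty_used = penalty),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf(
    "<enet_fit> p=%d, nonzero=%d, objective=%.6g, %s after %d iterations\n",
    length(x$weights), sum(x$weights != 0), x$objective,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Classify feature rows with a fitted elastic-net classifier
#'
#' Scores are logistic probabilities on fit-time-scaled features; an item
#' is labelled positive iff its score exceeds 0.5, so an exact tie at 0.5
#' (e.g. an all-zero classifier) is labelled negative.  This fixed
#' convention keeps hit/false-alarm bookkeeping deterministic.
#'
#' @param fit an [enet_fit()] result.
#' @param x feature matrix with the fit's dimensionality.
#' @return data frame with columns `score` in (0, 1) and logical
#'   `positive`.
#' @export
enet_decide <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(fit$weights)) {
    stop(sprintf("feature dimensionality %d does not match model (%d)",
                 ncol(x), length(fit$weights)), call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  score <- stats::plogis(drop(xs %*% fit$weights) + fit$intercept)
  data.frame(score = score, positive = score > 0.5)
}
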