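#' Configuration of the convolutional hierarchy
#'
#' The hierarchy is a plain three-stage convolutional network (3x3
#' convolution, ReLU, 2x2 average pooling per stage) followed by a global
#' average pool and one fully connected concept layer with one unit per
#' base category.  Four named taps expose activations at increasing depth:
#' `Generic3` (stage 1, average-pooled), `Generic2` (stage 2,
#' average-pooled), `Generic1` (globally average-pooled last stage, just
#' before the fully connected layer) and `Conceptual` (the pre-softmax
#' output of the concept layer).
#'
#' Training uses momentum SGD on softmax cross-entropy with a stepped
#' learning-rate schedule: after every `decay_interval` training images the
#' rate is multiplied by `1 - lr_decay_fraction`, i.e. the rate after k
#' completed intervals is `lr0 * (1 - lr_decay_fraction)^k`.  Defaults
#' mirror the classical schedule for deep hierarchies (initial rate 0.01
#' decaying by 4% per interval with 0.9 momentum); `decay_interval`
#' defaults to one pass over the training set.
#'
#' @param concept_width units in the concept layer; must equal the number
#'   of base categories.
#' @param input_size square input edge in pixels.
#' @param stage_widths channel counts of the three convolutional stages
#'   (early, mid, late).
#' @param lr0 initial learning rate.
#' @param lr_decay_fraction per-interval multiplicative decrease in (0, 1).
#' @param decay_interval training images between decays; `NULL` means one
#'   epoch.
#' @param momentum SGD momentum in [0, 1).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed seed for weight initialisation, shuffling and random crops.
#' @return an object of class `hierarchy_config`.
#' @export
hierarchy_config <- function(concept_width,
                             input_size = 32,
                             stage_widths = c(16, 32, 64),
                             lr0 = 0.01,
                             lr_decay_fraction = 0.04,
                             decay_interval = NULL,
                             momentum = 0.9,
                             epochs = 20,
                             batch_size = 32,
                             seed = 1) {
  stop_if_not_count(concept_width, "concept_width")
  stop_if_not_count(input_size, "input_size")
  stopifnot(length(stage_widths) == 3, all(stage_widths >= 1))
  if (lr_decay_fraction <= 0 || lr_decay_fraction >= 1) {
    stop("lr_decay_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (momentum < 0 || momentum >= 1) {
    stop("momentum must lie in [0, 1)", call. = FALSE)
  }
  if (input_size %% 8 != 0) {
    stop("input_size must be divisible by 8 (three 2x2 pooling stages)",
         call. = FALSE)
  }
  structure(list(
    concept_width = as.integer(concept_width),
    input_size = as.integer(input_size),
    stage_widths = as.integer(stage_widths),
    lr0 = lr0,
    lr_decay_fraction = lr_decay_fraction,
    decay_interval = decay_interval,
    momentum = momentum,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "hierarchy_config")
}

hierarchy_taps <- c("Conceptual", "Generic1", "Generic2", "Generic3")

#' Learning rate after a number of training images
#'
#' Closed form of the stepped schedule: `lr0 * (1 - d)^k` where `k` is the
#' number of completed decay intervals.
#'
#' @param config a [hierarchy_config()].
#' @param images_seen non-negative count of training images processed.
#' @param decay_interval images per decay interval; defaults to the
#'   config's value (which must then be set).
#' @export
learning_rate <- function(config, images_seen,
                          decay_interval = config$decay_interval) {
  stopifnot(images_seen >= 0, !is.null(decay_interval), decay_interval > 0)
  k <- floor(images_seen / decay_interval)
  config$lr0 * (1 - config$lr_decay_fraction)^k
}

# ---- parameter container --------------------------------------------------

init_params <- function(config) {
  sw <- config$stage_widths
  he <- function(cout, fan_in) {
    matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
  }
  list(
    w1 = he(sw[1], 9 * 1),  b1 = numeric(sw[1]),
    w2 = he(sw[2], 9 * sw[1]), b2 = numeric(sw[2]),
    w3 = he(sw[3], 9 * sw[2]), b3 = numeric(sw[3]),
    wfc = he(config$concept_width, sw[3]), bfc = numeric(config$concept_width)
  )
}

# Forward pass (compiled kernels).  Returns tap activations and, when
# `keep = TRUE`, the intermediate caches needed by the backward pass.
net_forward <- function(params, x, keep = FALSE) {
  c1 <- .cpp_conv3x3_forward(x, params$w1, params$b1)
  r1 <- .cpp_relu_forward(c1$out)
  s1 <- .cpp_avgpool2_forward(r1)
  c2 <- .cpp_conv3x3_forward(s1, params$w2, params$b2)
  r2 <- .cpp_relu_forward(c2$out)
  s2 <- .cpp_avgpool2_forward(r2)
  c3 <- .cpp_conv3x3_forward(s2, params$w3, params$b3)
  r3 <- .cpp_relu_forward(c3$out)
  s3 <- .cpp_avgpool2_forward(r3)
  g1 <- global_avgpool(s3)
  scores <- params$wfc %*% g1 + params$bfc
  out <- list(scores = scores, g1 = g1, s1 = s1, s2 = s2, s3 = s3)
  if (keep) {
    out$cache <- list(x = x, c1 = c1, c2 = c2, c3 = c3)
  }
  out
}

# Backward pass from d(scores); returns gradients for all parameters.
net_backward <- function(params, fwd, d_scores) {
  cache <- fwd$cache
  g <- list()
  g$wfc <- tcrossprod(d_scores, fwd$g1)
  g$bfc <- rowSums(d_scores)
  dg1 <- crossprod(params$wfc, d_scores)
  d3 <- dim(fwd$s3)
  cells <- d3[1] * d3[2]
  ds3 <- array(rep(as.vector(dg1) / cells, each = cells), dim = d3)
  dr3 <- .cpp_avgpool2_backward(ds3, 2 * d3[1], 2 * d3[2])
  dc3 <- .cpp_relu_backward(dr3, cache$c3$out)
  bk3 <- .cpp_conv3x3_backward(dc3, params$w3, cache$c3$patches,
                               ncol(params$w3) %/% 9L)
  g$w3 <- bk3$dw; g$b3 <- bk3$db
  d2 <- dim(bk3$dx)
  dr2 <- .cpp_avgpool2_backward(bk3$dx, 2 * d2[1], 2 * d2[2])
  dc2 <- .cpp_relu_backward(dr2, cache$c2$out)
  bk2 <- .cpp_conv3x3_backward(dc2, params$w2, cache$c2$patches,
                               ncol(params$w2) %/% 9L)
  g$w2 <- bk2$dw; g$b2 <- bk2$db
  d1 <- dim(bk2$dx)
  dr1 <- .cpp_avgpool2_backward(bk2$dx, 2 * d1[1], 2 * d1[2])
  dc1 <- .cpp_relu_backward(dr1, cache$c1$out)
  bk1 <- .cpp_conv3x3_backward(dc1, params$w1, cache$c1$patches, 1L)
  g$w1 <- bk1$dw; g$b1 <- bk1$db
  g
}

# ---- training -------------------------------------------------------------

#' Train the hierarchy on the base categories
#'
#' Momentum SGD on softmax cross-entropy over the base-training set, with
#' random square crops during training and per-epoch top-1/top-5
#' validation on the base-validation set (center crops).  Fully
#' deterministic given the config seed.
#'
#' @param base_train,base_val `image_dataset`s sharing the same base label
#'   set; `concept_width` must equal the number of distinct labels.
#' @param config a [hierarchy_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `trained_hierarchy` with elements `params`,
#'   `labels` (sorted base label set), `taps` (tap registry), `config` and
#'   `log` (per-epoch data frame with loss, top-1, top-5 and learning rate).
#' @export
train_hierarchy <- function(base_train, base_val, config, verbose = FALSE) {
  stopifnot(inherits(base_train, "image_dataset"),
            inherits(base_val, "image_dataset"),
            inherits(config, "hierarchy_config"))
  labels <- sort(unique(base_train$labels))
  if (!setequal(labels, unique(base_val$labels))) {
    stop("base_train and base_val must share the same label set",
         call. = FALSE)
  }
  if (length(labels) != config$concept_width) {
    stop(sprintf(
      "concept_width (%d) must equal the number of base categories (%d)",
      config$concept_width, length(labels)), call. = FALSE)
  }
  n_train <- length(base_train$ids)
  decay_interval <- config$decay_interval %||% n_train
  y_idx <- match(base_train$labels, labels)

  with_seed(derive_seed(config$seed, "train"), {
    params <- init_params(config)
    velocity <- lapply(params, function(p) p * 0)
    x_all <- preprocess_batch(base_train, config$input_size, "random")
    log_rows <- vector("list", config$epochs)
    images_seen <- 0

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_train)
      epoch_loss <- 0
      starts <- seq(1, n_train, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n_train)]
        nb <- length(idx)
        xb <- x_all[, , , idx, drop = FALSE]
        fwd <- net_forward(params, xb, keep = TRUE)
        probs <- softmax_cols(fwd$scores)
        yb <- y_idx[idx]
        picked <- probs[cbind(yb, seq_len(nb))]
        epoch_loss <- epoch_loss - sum(log(pmax(picked, 1e-12)))
        d_scores <- probs
        d_scores[cbind(yb, seq_len(nb))] <-
          d_scores[cbind(yb, seq_len(nb))] - 1
        d_scores <- d_scores / nb
        grads <- net_backward(params, fwd, d_scores)
        lr <- learning_rate(config, images_seen, decay_interval)
        for (nm in names(params)) {
          velocity[[nm]] <- config$momentum * velocity[[nm]] -
            lr * grads[[nm]]
          params[[nm]] <- params[[nm]] + velocity[[nm]]
        }
        images_seen <- images_seen + nb
      }
      model_now <- new_trained_hierarchy(params, labels, config)
      val_scores <- forward_dataset(model_now, base_val)$scores
      y_val <- match(base_val$labels, labels)
      top1 <- topk_from_scores(val_scores, y_val, 1)
      top5 <- topk_from_scores(val_scores, y_val, min(5, length(labels)))
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, loss = epoch_loss / n_train, top1 = top1,
        top5 = top5,
        lr = learning_rate(config, images_seen, decay_interval))
      if (verbose) {
        message(sprintf("epoch %2d  loss %.4f  top1 %.3f  top5 %.3f",
                        epoch, epoch_loss / n_train, top1, top5))
      }
    }
    model <- new_trained_hierarchy(params, labels, config)
    model$log <- do.call(rbind, log_rows)
    model
  })
}

new_trained_hierarchy <- function(params, labels, config) {
  structure(list(
    params = params,
    labels = labels,
    taps = list(
      Conceptual = "concept layer output, pre-softmax",
      Generic1 = "global average pool of stage 3 (pre-FC)",
      Generic2 = "2x2 average pool of stage 2 activations",
      Generic3 = "2x2 average pool of stage 1 activations"
    ),
    config = config,
    log = NULL
  ), class = "trained_hierarchy")
}

#' @export
print.trained_hierarchy <- function(x, ...) {
  cat(sprintf("<trained_hierarchy> %d base categories, input %dx%d\n",
              length(x$labels), x$config$input_size, x$config$input_size))
  if (!is.null(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d epochs: top-1 %.3f, top-5 %.3f on base-val\n",
                last$epoch, last$top1, last$top5))
  }
  invisible(x)
}

# Forward a dataset through the network in chunks, collecting requested
# activations.  Center crops; deterministic.
forward_dataset <- function(model, dataset, chunk = 128) {
  config <- model$config
  n <- length(dataset$ids)
  pieces <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  res <- lapply(pieces, function(idx) {
    nb <- length(idx)
    xb <- preprocess_batch(dataset_subset(dataset, idx), config$input_size,
                           "center")
    fwd <- net_forward(model$params, xb)
    g2 <- .cpp_avgpool2_forward(fwd$s2)
    g3 <- .cpp_avgpool2_forward(fwd$s1)
    list(scores = t(fwd$scores), g1 = t(fwd$g1),
         g2 = t(matrix(g2, prod(dim(g2)[1:3]), nb)),
         g3 = t(matrix(g3, prod(dim(g3)[1:3]), nb)))
  })
  list(scores = do.call(rbind, lapply(res, `[[`, "scores")),
       g1 = do.call(rbind, lapply(res, `[[`, "g1")),
       g2 = do.call(rbind, lapply(res, `[[`, "g2")),
       g3 = do.call(rbind, lapply(res, `[[`, "g3")))
}

#' Top-k accuracy on a base-labelled dataset
#'
#' Fraction of images whose true label is among the `k` highest
#' pre-softmax scores.  Score ties are broken in favour of the lower class
#' index (stable ordering), so the metric is deterministic.
#'
#' @param model a `trained_hierarchy`.
#' @param dataset an `image_dataset` whose labels are all base labels.
#' @param k number of top scores considered, `1 <= k <= concept_width`.
#' @return accuracy fraction in [0, 1].
#' @export
evaluate_topk <- function(model, dataset, k) {
  stopifnot(inherits(model, "trained_hierarchy"), k >= 1,
            k <= length(model$labels))
  if (!all(dataset$labels %in% model$labels)) {
    stop("dataset contains labels outside the model's base label set ",
         "(novel-role datasets cannot be scored)", call. = FALSE)
  }
  scores <- forward_dataset(model, dataset)$scores
  y <- match(dataset$labels, model$labels)
  topk_from_scores(scores, y, k)
}

# Rank of the true class among per-image scores; ties are resolved in
# favour of the lower class index (stable, deterministic ordering).
topk_from_scores <- function(scores, y, k) {
  hits <- vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    r <- sum(s > s[y[i]]) + sum(s[seq_len(y[i] - 1)] == s[y[i]]) + 1
    r <= k
  }, logical(1))
  mean(hits)
}

# ---- feature extraction ---------------------------------------------------

new_feature_matrix <- function(values, ids, labels, tap) {
  rownames(values) <- ids
  colnames(values) <- sprintf("f%04d", seq_len(ncol(values)) - 1)
  structure(list(values = values, ids = ids, labels = labels, tap = tap),
            class = "feature_matrix")
}

#' Extract a feature matrix from a named tap
#'
#' Images are center-cropped and forwarded through the trained hierarchy;
#' one row per image.  The `Conceptual` tap returns pre-softmax concept
#' scores (no softmax sharpening), with dimensionality equal to the number
#' of base categories; `Generic1`..`Generic3` return average-pooled
#' activations of progressively earlier stages.  Extraction is
#' deterministic given the model and dataset.
#'
#' @param model a `trained_hierarchy`.
#' @param dataset an `image_dataset`.
#' @param tap one of `"Conceptual"`, `"Generic1"`, `"Generic2"`,
#'   `"Generic3"`.
#' @return an object of class `feature_matrix`.
#' @export
extract_features <- function(model, dataset, tap) {
  stopifnot(inherits(model, "trained_hierarchy"),
            inherits(dataset, "image_dataset"))
  if (!tap %in% hierarchy_taps) {
    stop("unknown tap '", tap, "'; registered taps: ",
         paste(hierarchy_taps, collapse = ", "), call. = FALSE)
  }
  fw <- forward_dataset(model, dataset)
  values <- switch(tap, Conceptual = fw$scores, Generic1 = fw$g1,
                   Generic2 = fw$g2, Generic3 = fw$g3)
  new_feature_matrix(values, dataset$ids, dataset$labels, tap)
}

#' Concatenate two feature matrices column-wise
#'
#' Used to build the combined `Generic1+Conceptual` feature set; the two
#' inputs must cover the same images in the same order.
#'
#' @param a,b `feature_matrix` objects over identical image ids.
#' @param tap name for the combined set.
#' @export
combine_feature_sets <- function(a, b, tap = paste(a$tap, b$tap, sep = "+")) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (!identical(a$ids, b$ids)) {
    stop("feature matrices cover different images (id mismatch)",
         call. = FALSE)
  }
  new_feature_matrix(cbind(a$values, b$values), a$ids, a$labels, tap)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> tap=%s, %d images x %d features\n",
              x$tap, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Mean per-feature category selectivity of a feature matrix
#'
#' For each feature, the ratio of between-category variance of category
#' means to mean within-category variance; the average over features
#' summarises how category-sensitive a tap is.  Features that are
#' constant within every category are skipped.
#'
#' @param fm a `feature_matrix` with category labels.
#' @return a single non-negative number.
#' @export
category_selectivity <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  f <- factor(fm$labels)
  means <- apply(v, 2, function(col) tapply(col, f, mean))
  wvar <- apply(v, 2, function(col) mean(tapply(col, f, stats::var)))
  bvar <- apply(means, 2, stats::var)
  ok <- is.finite(wvar) & wvar > 1e-12
  mean(bvar[ok] / wvar[ok])
}
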