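#' Few-shot benchmark protocol configuration
#'
#' The factorial few-shot experiment: for every combination of feature
#' set, novel category, total training-set size and random split, a
#' balanced tiny training set is drawn (half positives from the target
#' category, half negatives from the other categories), a one-vs-all
#' classifier is fitted, and performance is scored on held-out items.
#'
#' The desk-scale default sizes are `{2, 4, 8, 16, 32}` total examples
#' with 20 splits per cell; the full-scale size list
#' `{2, 4, 8, 16, 32, 64, 128}` is one config edit away.
#'
#' @param training_sizes total training examples per cell; each must be
#'   even (balanced positive/negative halves) and at least 2.
#' @param n_splits random train/test splits per cell.
#' @param n_test_positives cap on test positives per split, or `NULL` for
#'   all held-out positives of the category.
#' @param negatives_per_test test negatives per split, or `NULL` to match
#'   the number of test positives (balanced test set).
#' @param master_seed seed from which every cell's seed is derived.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(training_sizes = c(2, 4, 8, 16, 32),
                            n_splits = 20,
                            n_test_positives = NULL,
                            negatives_per_test = NULL,
                            master_seed = 1) {
  if (any(training_sizes < 2) || any(training_sizes %% 2 != 0)) {
    stop("every training size must be even and >= 2 so the training set ",
         "can be split evenly between positives and negatives",
         call. = FALSE)
  }
  stop_if_not_count(n_splits, "n_splits")
  structure(list(training_sizes = as.integer(sort(training_sizes)),
                 n_splits = as.integer(n_splits),
                 n_test_positives = n_test_positives,
                 negatives_per_test = negatives_per_test,
                 master_seed = as.integer(master_seed)),
            class = "protocol_config")
}

#' Enumerate the factorial benchmark cells
#'
#' One row per (category, training size, split) combination — the
#' classifier jobs run per feature set.  At the full scale of 100
#' categories, 7 sizes and 20 splits this is 14,000 jobs per feature set.
#'
#' @param categories character vector of target categories.
#' @param training_sizes total training-set sizes.
#' @param n_splits splits per cell.
#' @return data frame with columns `category`, `n_total`, `split_index`.
#' @export
enumerate_jobs <- function(categories, training_sizes, n_splits) {
  jobs <- expand.grid(split_index = seq_len(n_splits),
                      n_total = as.integer(sort(training_sizes)),
                      category = categories,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jobs[, c("category", "n_total", "split_index")]
}

#' Draw the train/test splits for one benchmark cell
#'
#' Each split draws `n_total/2` training positives from the target
#' category and `n_total/2` training negatives from the other categories;
#' test positives are all remaining positives of the category (optionally
#' capped) and test negatives are drawn from the other categories,
#' disjoint from the training negatives.  The cell seed is derived from
#' `(master_seed, category, n_total, split_index)`, so every cell's
#' randomness is independent and reproducible, and adding a new size or
#' category never perturbs other cells.
#'
#' @param features a `feature_matrix` over the novel images (only ids and
#'   labels are used).
#' @param category target category label.
#' @param n_total total training examples (even).
#' @param n_splits number of splits to generate.
#' @param master_seed protocol master seed.
#' @param n_test_positives optional cap on test positives.
#' @param negatives_per_test test negatives per split (`NULL`: match test
#'   positives).
#' @return list of `split_spec` lists with the id sets and the cell seed.
#' @export
make_splits <- function(features, category, n_total, n_splits, master_seed,
                        n_test_positives = NULL, negatives_per_test = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!category %in% features$labels) {
    stop("category '", category, "' not present in the feature matrix",
         call. = FALSE)
  }
  if (n_total %% 2 != 0 || n_total < 2) {
    stop("n_total must be even and >= 2", call. = FALSE)
  }
  n_half <- n_total %/% 2
  pos_pool <- features$ids[features$labels == category]
  neg_pool <- features$ids[features$labels != category]
  if (n_half >= length(pos_pool)) {
    stop(sprintf(
      "category '%s' has %d exemplars; cannot draw %d training positives and keep a test set",
      category, length(pos_pool), n_half), call. = FALSE)
  }
  lapply(seq_len(n_splits), function(si) {
    cell_seed <- derive_seed(master_seed, "split", category, n_total, si)
    with_seed(cell_seed, {
      train_pos <- sample(pos_pool, n_half)
      train_neg <- sample(neg_pool, n_half)
      test_pos <- setdiff(pos_pool, train_pos)
      if (!is.null(n_test_positives) &&
          length(test_pos) > n_test_positives) {
        test_pos <- sample(test_pos, n_test_positives)
      }
      n_neg_test <- negatives_per_test %||% length(test_pos)
      neg_avail <- setdiff(neg_pool, train_neg)
      if (n_neg_test > length(neg_avail)) {
        stop(sprintf(
          "not enough negatives for category '%s' (need %d, have %d)",
          category, n_neg_test, length(neg_avail)), call. = FALSE)
      }
      test_neg <- sample(neg_avail, n_neg_test)
      list(category = category, n_total = as.integer(n_total),
           split_index = as.integer(si), cell_seed = cell_seed,
           train_pos_ids = train_pos, train_neg_ids = train_neg,
           test_pos_ids = test_pos, test_neg_ids = test_neg)
    })
  })
}

#' Run the factorial few-shot benchmark
#'
#' For every feature set and every (category, size, split) cell: fit an
#' elastic-net logistic classifier on the split's training rows, classify
#' its test rows, tally the confusion counts and compute d-prime.  Splits
#' are drawn once per cell and shared across feature sets, so comparisons
#' between feature sets are paired.  The output is deterministic given
#' `protocol$master_seed`.
#'
#' @param features_by_set named list of `feature_matrix` objects covering
#'   identical images (same ids and labels, same order).
#' @param protocol a [protocol_config()].
#' @param classifier an [enet_config()].
#' @param correction extreme-rate correction passed to [dprime()].
#' @param verbose print progress per category.
#' @return a `benchmark_result` data frame in long format: one row per
#'   (feature_set, category, n_pos, split_index) with confusion counts,
#'   `dprime` and `solver_converged`; the run configuration is attached as
#'   the `"manifest"` attribute.
#' @export
run_benchmark <- function(features_by_set, protocol = protocol_config(),
                          classifier = enet_config(),
                          correction = "clamp", verbose = FALSE) {
  stopifnot(is.list(features_by_set), length(features_by_set) >= 1,
            !is.null(names(features_by_set)))
  ref <- features_by_set[[1]]
  for (fm in features_by_set) {
    stopifnot(inherits(fm, "feature_matrix"))
    if (!identical(fm$ids, ref$ids) || !identical(fm$labels, ref$labels)) {
      stop("all feature sets must cover the same images in the same ",
           "order (the comparison must use identical splits)",
           call. = FALSE)
    }
  }
  categories <- sort(unique(ref$labels))
  rows <- list()
  for (category in categories) {
    if (verbose) message("category ", category)
    for (n_total in protocol$training_sizes) {
      splits <- make_splits(ref, category, n_total, protocol$n_splits,
                            protocol$master_seed,
                            protocol$n_test_positives,
                            protocol$negatives_per_test)
      for (sp in splits) {
        train_ids <- c(sp$train_pos_ids, sp$train_neg_ids)
        test_ids <- c(sp$test_pos_ids, sp$test_neg_ids)
        y_train <- rep(c(1, -1), c(length(sp$train_pos_ids),
                                   length(sp$train_neg_ids)))
        truth <- rep(c(TRUE, FALSE), c(length(sp$test_pos_ids),
                                       length(sp$test_neg_ids)))
        for (set_name in names(features_by_set)) {
          v <- features_by_set[[set_name]]$values
          fit <- enet_fit(v[train_ids, , drop = FALSE], y_train, classifier)
          dec <- enet_decide(fit, v[test_ids, , drop = FALSE])
          hits <- sum(dec$positive & truth)
          misses <- sum(!dec$positive & truth)
          fas <- sum(dec$positive & !truth)
          crs <- sum(!dec$positive & !truth)
          rows[[length(rows) + 1L]] <- data.frame(
            feature_set = set_name, category = category,
            n_pos = n_total %/% 2L, split_index = sp$split_index,
            hits = hits, misses = misses, false_alarms = fas,
            correct_rejections = crs,
            dprime = dprime(hits, misses, fas, crs, correction),
            solver_converged = fit$converged,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(match(out$feature_set, names(features_by_set)),
               out$category, out$n_pos, out$split_index)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "manifest") <- list(
    feature_sets = names(features_by_set),
    categories = categories,
    protocol = unclass(protocol),
    classifier = unclass(classifier),
    correction = correction
  )
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Write a benchmark result as TSV plus a JSON run manifest
#'
#' The TSV holds the long-format rows; the manifest records the feature
#' sets, categories, protocol and classifier configuration.  Output bytes
#' are stable given identical inputs.
#'
#' @param result a `benchmark_result`.
#' @param path output TSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @export
write_benchmark <- function(result, path) {
  df <- as.data.frame(result)
  df$dprime <- sprintf("%.10g", df$dprime)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  manifest <- attr(result, "manifest")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a benchmark TSV written by [write_benchmark()]
#' @param path TSV path.
#' @export
read_benchmark <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("benchmark_result", class(out))
  out
}
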