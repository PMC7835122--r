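#' Summarise a benchmark into per-category means and bootstrap CIs
#'
#' Split-level d-prime is averaged within (feature_set, n_pos, category);
#' the grand mean per (feature_set, n_pos) averages those category means,
#' with a percentile bootstrap confidence interval obtained by resampling
#' categories — category, not split, is the design's random-effect unit.
#' The summary is invariant to row order of the input.
#'
#' @param results a `benchmark_result` (complete factorial).
#' @param n_boot bootstrap replicates for the CI.
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return list of class `benchmark_summary` with data frames
#'   `per_category` (feature_set, n_pos, category, mean_dprime) and
#'   `grand` (feature_set, n_pos, mean_dprime, ci_lower, ci_upper).
#' @export
summarize_benchmark <- function(results, n_boot = 2000, seed = 1,
                                level = 0.95) {
  stopifnot(inherits(results, "benchmark_result") ||
              is.data.frame(results))
  check_complete(results)
  per_cat <- stats::aggregate(
    dprime ~ feature_set + n_pos + category, data = results, FUN = mean)
  names(per_cat)[names(per_cat) == "dprime"] <- "mean_dprime"
  per_cat <- per_cat[order(per_cat$feature_set, per_cat$n_pos,
                           per_cat$category), ]
  rownames(per_cat) <- NULL

  alpha <- (1 - level) / 2
  cells <- unique(per_cat[, c("feature_set", "n_pos")])
  grand <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- per_cat$feature_set == cells$feature_set[i] &
      per_cat$n_pos == cells$n_pos[i]
    v <- per_cat$mean_dprime[sel]
    boot_seed <- derive_seed(seed, "boot", cells$feature_set[i],
                             cells$n_pos[i])
    bm <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        mean(v[sample.int(length(v), replace = TRUE)])
      }, numeric(1))
    })
    data.frame(feature_set = cells$feature_set[i], n_pos = cells$n_pos[i],
               mean_dprime = mean(v),
               ci_lower = unname(stats::quantile(bm, alpha)),
               ci_upper = unname(stats::quantile(bm, 1 - alpha)),
               stringsAsFactors = FALSE)
  }))
  grand <- grand[order(grand$feature_set, grand$n_pos), ]
  rownames(grand) <- NULL
  structure(list(per_category = per_cat, grand = grand,
                 n_boot = n_boot, level = level, seed = seed),
            class = "benchmark_summary")
}

check_complete <- function(results) {
  tab <- table(results$feature_set, results$category, results$n_pos)
  if (length(unique(as.vector(tab))) > 1) {
    bad <- which(tab != max(tab), arr.ind = TRUE)
    stop("benchmark is not factorially complete; short cells include: ",
         paste(apply(bad, 1, function(r) {
           paste(dimnames(tab)[[1]][r[1]], dimnames(tab)[[2]][r[2]],
                 dimnames(tab)[[3]][r[3]], sep = "/")
         })[seq_len(min(5, nrow(bad)))], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary> grand means (d'):\n")
  print(x$grand, digits = 3)
  invisible(x)
}

#' Paired contrast between two feature sets at one training size
#'
#' The per-category mean d-primes of the two feature sets are paired
#' (identical splits underlie both), so the contrast is the mean paired
#' difference across categories.  Its two-sided p-value comes from a
#' sign-flip permutation of the paired differences: under the null of no
#' feature-set difference each category's difference is symmetric around
#' zero.  With `n_perm = NULL` and at most 20 categories all 2^k sign
#' assignments are enumerated exactly.
#'
#' @param results a `benchmark_result`.
#' @param set_a,set_b feature-set names; the contrast is mean(a - b).
#' @param n_pos number of positive training examples selecting the cell.
#' @param n_perm Monte-Carlo permutations, or `NULL` for exhaustive
#'   enumeration (category count <= 20).
#' @param seed permutation seed (ignored when exhaustive).
#' @return one-row data frame: `set_a`, `set_b`, `n_pos`,
#'   `mean_difference`, `p_value`, `n_permutations`, `seed`.
#' @export
contrast_feature_sets <- function(results, set_a, set_b, n_pos,
                                  n_perm = 10000, seed = 1) {
  for (s in c(set_a, set_b)) {
    if (!s %in% results$feature_set) {
      stop("feature set '", s, "' not present in results", call. = FALSE)
    }
  }
  sub <- results[results$n_pos == n_pos &
                   results$feature_set %in% c(set_a, set_b), ]
  if (nrow(sub) == 0) stop("no rows at n_pos = ", n_pos, call. = FALSE)
  per_cat <- stats::aggregate(dprime ~ feature_set + category, data = sub,
                              FUN = mean)
  names(per_cat)[names(per_cat) == "dprime"] <- "mean_dprime"
  a <- per_cat[per_cat$feature_set == set_a, ]
  b <- per_cat[per_cat$feature_set == set_b, ]
  if (!identical(sort(a$category), sort(b$category))) {
    stop("category sets differ between the two feature sets",
         call. = FALSE)
  }
  d <- a$mean_dprime[order(a$category)] - b$mean_dprime[order(b$category)]
  k <- length(d)
  t_obs <- mean(d)
  if (is.null(n_perm)) {
    if (k > 20) stop("exhaustive enumeration limited to 20 categories",
                     call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    t_null <- as.vector(signs %*% d) / k
    p <- mean(abs(t_null) >= abs(t_obs) - 1e-12)
    n_eff <- nrow(signs)
  } else {
    t_null <- with_seed(derive_seed(seed, "perm", set_a, set_b, n_pos), {
      vapply(seq_len(n_perm), function(i) {
        mean(d * sample(c(-1, 1), k, replace = TRUE))
      }, numeric(1))
    })
    # add-one estimate keeps p in (0, 1]
    p <- (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
    n_eff <- n_perm
  }
  data.frame(set_a = set_a, set_b = set_b, n_pos = n_pos,
             mean_difference = t_obs, p_value = p,
             n_permutations = n_eff, seed = seed,
             stringsAsFactors = FALSE)
}

#' Figure-style plot of benchmark performance
#'
#' Per-category mean d-primes as dots, grand means as cross bars with
#' bootstrap CIs, grouped by feature set along the training-size axis.
#'
#' @param summary a [summarize_benchmark()] result.
#' @return a ggplot object.
#' @export
plot_benchmark <- function(summary) {
  stopifnot(inherits(summary, "benchmark_summary"))
  pc <- summary$per_category
  gr <- summary$grand
  pc$n_pos_f <- factor(pc$n_pos)
  gr$n_pos_f <- factor(gr$n_pos)
  pos <- ggplot2::position_dodge(width = 0.75)
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$n_pos_f,
                                   y = .data$mean_dprime,
                                   colour = .data$feature_set)) +
    ggplot2::geom_point(position = pos, alpha = 0.45, size = 1) +
    ggplot2::geom_errorbar(
      data = gr,
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = pos, width = 0.5, linewidth = 0.7) +
    ggplot2::geom_point(data = gr, position = pos, shape = 3, size = 2.5,
                        stroke = 1.2) +
    ggplot2::labs(x = "positive training examples", y = "d'",
                  colour = "feature set") +
    ggplot2::theme_minimal()
}

#' Write report tables, figure and manifest
#'
#' Emits `summary.tsv` (per-category and grand rows), `contrasts.tsv`
#' (when contrasts are given), `figure_dprime.png` and `manifest.json`
#' into `out_dir`.  TSV bytes are stable given identical inputs.
#'
#' @param summary a [summarize_benchmark()] result.
#' @param contrasts data frame of [contrast_feature_sets()] rows, or
#'   `NULL`.
#' @param out_dir output directory (created if missing).
#' @param manifest optional named list stored in `manifest.json` alongside
#'   the summary settings.
#' @return invisibly, the paths written.
#' @export
write_report <- function(summary, contrasts = NULL, out_dir,
                         manifest = list()) {
  stopifnot(inherits(summary, "benchmark_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (nm in names(df)) {
      if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
        df[[nm]] <- sprintf("%.10g", df[[nm]])
      }
    }
    df
  }
  paths <- character(0)
  per_cat <- summary$per_category
  per_cat$level <- "category"
  grand <- summary$grand
  grand$level <- "grand"
  grand$category <- NA
  both <- rbind(
    per_cat[, c("level", "feature_set", "n_pos", "category",
                "mean_dprime")],
    cbind(grand[, c("level", "feature_set", "n_pos", "category",
                    "mean_dprime")]))
  both$ci_lower <- c(rep(NA, nrow(per_cat)), summary$grand$ci_lower)
  both$ci_upper <- c(rep(NA, nrow(per_cat)), summary$grand$ci_upper)
  p_sum <- file.path(out_dir, "summary.tsv")
  utils::write.table(fmt(both), p_sum, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = "")
  paths <- c(paths, p_sum)
  if (!is.null(contrasts) && nrow(contrasts) > 0) {
    p_con <- file.path(out_dir, "contrasts.tsv")
    utils::write.table(fmt(contrasts), p_con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", na = "")
    paths <- c(paths, p_con)
  }
  p_fig <- file.path(out_dir, "figure_dprime.png")
  grDevices::png(p_fig, width = 1600, height = 900, res = 160)
  print(plot_benchmark(summary))
  grDevices::dev.off()
  paths <- c(paths, p_fig)
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(manifest, list(n_boot = summary$n_boot, level = summary$level,
                     bootstrap_seed = summary$seed)),
    p_man, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p_man)
  invisible(paths)
}
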