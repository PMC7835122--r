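make_results <- function(dprimes, n_splits = 4) {
  # dprimes: named list feature_set -> category -> vector over splits
  rows <- list()
  for (fs in names(dprimes)) {
    for (cat in names(dprimes[[fs]])) {
      v <- dprimes[[fs]][[cat]]
      for (s in seq_along(v)) {
        rows[[length(rows) + 1]] <- data.frame(
          feature_set = fs, category = cat, n_pos = 1L,
          split_index = s, hits = 1L, misses = 0L, false_alarms = 0L,
          correct_rejections = 1L, dprime = v[s],
          solver_converged = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

test_that("constant results give a degenerate bootstrap interval", {
  res <- make_results(list(f = list(a = rep(1.3, 4), b = rep(1.3, 4))))
  s <- summarize_benchmark(res, n_boot = 200, seed = 1)
  expect_equal(s$grand$mean_dprime, 1.3)
  expect_equal(s$grand$ci_lower, 1.3)
  expect_equal(s$grand$ci_upper, 1.3)
})

test_that("point estimates are independent of bootstrap size and row order", {
  res <- make_results(list(f = list(a = c(1, 2), b = c(0, 1),
                                    c = c(2, 3))))
  s1 <- summarize_benchmark(res, n_boot = 100, seed = 1)
  s2 <- summarize_benchmark(res, n_boot = 2000, seed = 1)
  expect_equal(s1$grand$mean_dprime, s2$grand$mean_dprime)

  shuffled <- res[conceptbench:::with_seed(2, sample(nrow(res))), ]
  class(shuffled) <- class(res)
  s3 <- summarize_benchmark(shuffled, n_boot = 100, seed = 1)
  expect_equal(s3$per_category, s1$per_category)
  expect_equal(s3$grand, s1$grand)
})

test_that("incomplete factorials are reported with the missing cells", {
  res <- make_results(list(f = list(a = c(1, 2), b = c(0, 1))))
  expect_error(summarize_benchmark(res[-1, ], n_boot = 10, seed = 1),
               "short cells")
})

test_that("bootstrap CIs have near-nominal coverage over categories", {
  # d' ~ N(1, 0.1) over 30 categories: the 95% CI for the cross-category
  # mean should cover 1 in roughly 95% of seeded repetitions
  n_rep <- 150
  covered <- vapply(seq_len(n_rep), function(r) {
    res <- conceptbench:::with_seed(1000 + r, {
      make_results(list(f = stats::setNames(
        lapply(1:30, function(i) rnorm(2, mean = 1, sd = 0.1)),
        sprintf("c%02d", 1:30))), n_splits = 2)
    })
    s <- summarize_benchmark(res, n_boot = 300, seed = r)
    s$grand$ci_lower <= 1 && s$grand$ci_upper >= 1
  }, logical(1))
  expect_gt(mean(covered), 0.85)
  expect_lte(mean(covered), 1)
})

test_that("self-contrast is exactly null", {
  res <- make_results(list(f = list(a = c(1, 2), b = c(0, 1))))
  ct <- contrast_feature_sets(res, "f", "f", 1, n_perm = 500, seed = 1)
  expect_equal(ct$mean_difference, 0)
  expect_equal(ct$p_value, 1)
})

test_that("contrasts are antisymmetric and match exhaustive enumeration", {
  set.seed(71)
  dp_a <- lapply(1:8, function(i) rnorm(4, 1.2, 0.3))
  dp_b <- lapply(1:8, function(i) rnorm(4, 0.9, 0.3))
  names(dp_a) <- names(dp_b) <- sprintf("c%02d", 1:8)
  res <- make_results(list(A = dp_a, B = dp_b))
  ab <- contrast_feature_sets(res, "A", "B", 1, n_perm = NULL)
  ba <- contrast_feature_sets(res, "B", "A", 1, n_perm = NULL)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(ab$p_value, ba$p_value)

  # Monte-Carlo permutation converges to the exhaustive answer
  mc <- contrast_feature_sets(res, "A", "B", 1, n_perm = 20000, seed = 2)
  expect_lt(abs(mc$p_value - ab$p_value), 0.02)
})

test_that("uniformly positive differences reach the smallest attainable p", {
  k <- 10
  dp_a <- stats::setNames(lapply(1:k, function(i) rep(2, 2)),
                          sprintf("c%02d", 1:k))
  dp_b <- stats::setNames(lapply(1:k, function(i) rep(1 + 0.01 * i, 2)),
                          sprintf("c%02d", 1:k))
  res <- make_results(list(A = dp_a, B = dp_b))
  ct <- contrast_feature_sets(res, "A", "B", 1, n_perm = NULL)
  # all-positive paired differences: only the all-plus and all-minus
  # assignments reach |T|, so p = 2 / 2^k
  expect_equal(ct$p_value, 2 / 2^k)
})

test_that("contrasts guard against mismatched inputs", {
  res <- make_results(list(A = list(a = c(1, 2)), B = list(a = c(0, 1))))
  expect_error(contrast_feature_sets(res, "A", "C", 1), "not present")
  expect_error(contrast_feature_sets(res, "A", "B", 99), "no rows")
})

test_that("reports are written with byte-stable tables", {
  res <- make_results(list(A = list(a = c(1, 2), b = c(0.5, 1)),
                           B = list(a = c(0, 1), b = c(0.2, 0.4))))
  s <- summarize_benchmark(res, n_boot = 100, seed = 3)
  ct <- contrast_feature_sets(res, "A", "B", 1, n_perm = NULL)
  d1 <- tempfile(); d2 <- tempfile()
  write_report(s, ct, d1, manifest = list(run = "test"))
  write_report(s, ct, d2, manifest = list(run = "test"))
  for (f in c("summary.tsv", "contrasts.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "figure_dprime.png")))
  expect_true(file.exists(file.path(d1, "manifest.json")))

  # no contrasts: summary-only report
  d3 <- tempfile()
  write_report(s, NULL, d3)
  expect_false(file.exists(file.path(d3, "contrasts.tsv")))
})
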