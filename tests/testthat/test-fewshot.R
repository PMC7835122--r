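test_that("job enumeration reproduces the factorial arithmetic", {
  full <- enumerate_jobs(sprintf("c%03d", 1:100),
                         c(2, 4, 8, 16, 32, 64, 128), 20)
  expect_equal(nrow(full), 14000)     # 100 categories x 7 sizes x 20
  desk <- enumerate_jobs(sprintf("c%02d", 1:10), c(2, 4, 8, 16, 32), 20)
  expect_equal(nrow(desk), 1000)
})

test_that("protocol config requires even training sizes", {
  expect_error(protocol_config(training_sizes = c(2, 3)), "even")
  expect_error(protocol_config(training_sizes = 0), "even")
})

test_that("splits are balanced, disjoint and cell-seeded", {
  fm <- gaussian_features(n_cat = 5, per_cat = 30, seed = 2)
  splits <- make_splits(fm, "cat01", n_total = 2, n_splits = 10,
                        master_seed = 9)
  for (sp in splits) {
    expect_length(sp$train_pos_ids, 1)   # n = 2: one positive, one negative
    expect_length(sp$train_neg_ids, 1)
    train <- c(sp$train_pos_ids, sp$train_neg_ids)
    test <- c(sp$test_pos_ids, sp$test_neg_ids)
    expect_length(intersect(train, test), 0)
    expect_false(anyDuplicated(c(train, test)) > 0)
    expect_true(all(fm$labels[match(sp$test_pos_ids, fm$ids)] == "cat01"))
    expect_true(all(fm$labels[match(sp$train_neg_ids, fm$ids)] != "cat01"))
    # balanced test set by default
    expect_length(sp$test_neg_ids, length(sp$test_pos_ids))
  }
  # reproducibility cell by cell
  again <- make_splits(fm, "cat01", 2, 10, master_seed = 9)
  expect_identical(splits, again)
  # a different master seed changes the draws
  other <- make_splits(fm, "cat01", 2, 10, master_seed = 10)
  expect_false(identical(splits, other))
})

test_that("split requests beyond the category size fail loudly", {
  fm <- gaussian_features(n_cat = 3, per_cat = 10, seed = 3)
  expect_error(make_splits(fm, "cat01", 20, 1, 1), "cat01")
  expect_error(make_splits(fm, "nope", 2, 1, 1), "not present")
})

test_that("the benchmark is factorially complete, paired and deterministic", {
  fsets <- list(
    setA = gaussian_features(n_cat = 4, per_cat = 16, p = 6, seed = 5,
                             effect = 1.5),
    setB = gaussian_features(n_cat = 4, per_cat = 16, p = 6, seed = 5,
                             effect = 0.3))
  # same seed for ids/labels, different effect: setB relabels values only
  fsets$setB$ids <- fsets$setA$ids
  fsets$setB$labels <- fsets$setA$labels
  proto <- protocol_config(training_sizes = c(2, 4), n_splits = 5,
                           master_seed = 17)
  res <- run_benchmark(fsets, proto, enet_config())
  expect_s3_class(res, "benchmark_result")
  expect_equal(nrow(res), 2 * 4 * 2 * 5)   # sets x categories x sizes x splits
  tab <- table(res$feature_set, res$category, res$n_pos)
  expect_true(all(tab == 5))

  # confusion counts partition the test sets
  expect_true(all(res$hits + res$misses >= 1))
  expect_true(all(res$false_alarms + res$correct_rejections ==
                    res$hits + res$misses))  # balanced test default

  # identical splits across feature sets licence paired contrasts:
  # test-set sizes agree cell by cell
  a <- res[res$feature_set == "setA", ]
  b <- res[res$feature_set == "setB", ]
  expect_identical(a$hits + a$misses, b$hits + b$misses)

  res2 <- run_benchmark(fsets, proto, enet_config())
  expect_identical(as.data.frame(res)[names(res)],
                   as.data.frame(res2)[names(res2)])

  # TSV bytes are stable
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_benchmark(res, p1)
  write_benchmark(res2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_benchmark(p1)
  expect_equal(back$dprime, res$dprime, tolerance = 1e-9)
})

test_that("feature sets over different images are rejected", {
  a <- gaussian_features(n_cat = 3, per_cat = 10, seed = 6)
  b <- gaussian_features(n_cat = 3, per_cat = 10, seed = 6)
  b$ids[1] <- "other0001"
  expect_error(
    run_benchmark(list(a = a, b = b), protocol_config(training_sizes = 2),
                  enet_config()),
    "same images")
})

test_that("class-structured features beat label-shuffled features", {
  fm <- gaussian_features(n_cat = 5, per_cat = 24, p = 6, seed = 8,
                          effect = 2)
  shuffled <- fm
  shuffled$labels <- conceptbench:::with_seed(4, sample(fm$labels))
  proto <- protocol_config(training_sizes = c(4, 8), n_splits = 8,
                           master_seed = 21)
  res_true <- run_benchmark(list(f = fm), proto, enet_config())
  res_null <- run_benchmark(list(f = shuffled), proto, enet_config())
  expect_gt(mean(res_true$dprime), mean(res_null$dprime))
})

test_that("a single-positive benchmark on label-shuffled features is null", {
  # the n = 2 cell is the clean null: with one training positive a
  # classifier cannot learn the realised composition of a permuted
  # category, so grand-mean d-prime sits at chance
  fm <- gaussian_features(n_cat = 5, per_cat = 24, p = 6, seed = 8,
                          effect = 2)
  shuffled <- fm
  shuffled$labels <- conceptbench:::with_seed(4, sample(fm$labels))
  proto <- protocol_config(training_sizes = 2, n_splits = 16,
                           master_seed = 21)
  res_null <- run_benchmark(list(f = shuffled), proto, enet_config())
  s <- summarize_benchmark(res_null, n_boot = 1000, seed = 5)
  expect_true(all(s$grand$ci_lower <= 0 & s$grand$ci_upper >= 0))
})
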