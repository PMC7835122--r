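# Shared fixtures, built once per test session and memoised.  The tiny
# world keeps unit tests fast; the reference pipeline (the package's
# documented study conditions) is built lazily by the tests that need it.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small world: 6 base / 3 novel categories, 16x16 canvas, 30 exemplars.
tiny_config <- function(seed = 11) {
  world_config(n_base_categories = 6, n_novel_categories = 3,
               exemplars_per_category = 30,
               val_exemplars_per_base_category = 6,
               image_size = 16, part_dictionary_size = 8,
               parts_per_category = 2, translation_jitter = 2,
               scale_jitter = c(0.85, 1.2), rotation_jitter = 15,
               clutter_density = 0.5, noise_sd = 0.05, seed = seed)
}

tiny_world <- function() {
  memoise_fixture("tiny_world", function() build_world(tiny_config()))
}

tiny_model <- function() {
  memoise_fixture("tiny_model", function() {
    w <- tiny_world()
    tr <- generate_dataset(w, "base-train")
    va <- generate_dataset(w, "base-val")
    hc <- hierarchy_config(concept_width = 6, input_size = 16,
                           stage_widths = c(6, 10, 16), epochs = 4,
                           batch_size = 16, seed = 3)
    list(world = w, train = tr, val = va,
         model = train_hierarchy(tr, va, hc))
  })
}

# Gaussian class-structured feature matrices for protocol/report tests
# that do not need a trained network: category means drawn N(0, effect^2),
# exemplars N(mean, 1).
gaussian_features <- function(n_cat = 5, per_cat = 30, p = 8, seed = 1,
                              effect = 1.5, tap = "synthetic") {
  conceptbench:::with_seed(seed, {
    labels <- rep(sprintf("cat%02d", seq_len(n_cat)), each = per_cat)
    mu <- matrix(rnorm(n_cat * p, sd = effect), n_cat, p)
    values <- mu[rep(seq_len(n_cat), each = per_cat), ] +
      matrix(rnorm(n_cat * per_cat * p), n_cat * per_cat, p)
    ids <- sprintf("img%04d", seq_along(labels))
    conceptbench:::new_feature_matrix(values, ids, labels, tap)
  })
}

# ---- reference study conditions (expensive; built once) -------------------

reference_config <- function(seed = 7) world_config(seed = seed)

reference_feature_sets <- function(seed = 7, taps = c(
    "Conceptual", "Generic1", "Generic2", "Generic3")) {
  w <- build_world(reference_config(seed))
  tr <- generate_dataset(w, "base-train")
  va <- generate_dataset(w, "base-val")
  no <- generate_dataset(w, "novel")
  hc <- hierarchy_config(concept_width = 30, epochs = 20, seed = seed)
  model <- train_hierarchy(tr, va, hc)
  fsets <- lapply(taps, function(tp) extract_features(model, no, tp))
  names(fsets) <- taps
  if (all(c("Generic1", "Conceptual") %in% taps)) {
    fsets[["Generic1+Conceptual"]] <-
      combine_feature_sets(fsets$Generic1, fsets$Conceptual)
  }
  list(model = model, val = va, novel = no, features = fsets)
}

reference_run <- function() {
  memoise_fixture("reference_run", function() {
    pipe <- reference_feature_sets(7)
    res <- run_benchmark(pipe$features, protocol_config(master_seed = 7),
                         enet_config())
    list(pipeline = pipe, results = res)
  })
}

# Conceptual-vs-Generic1 grand-mean gap by training size for one seed
# (used for the multi-seed expectation check).
gap_by_size <- function(seed) {
  memoise_fixture(paste0("gap_seed_", seed), function() {
    if (seed == 7) {
      res <- reference_run()$results
    } else {
      pipe <- reference_feature_sets(seed, taps = c("Conceptual",
                                                    "Generic1"))
      res <- run_benchmark(pipe$features[c("Conceptual", "Generic1")],
                           protocol_config(master_seed = seed),
                           enet_config())
    }
    g <- stats::aggregate(dprime ~ feature_set + n_pos, data = res,
                          FUN = mean)
    sizes <- sort(unique(g$n_pos))
    vapply(sizes, function(np) {
      g$dprime[g$feature_set == "Conceptual" & g$n_pos == np] -
        g$dprime[g$feature_set == "Generic1" & g$n_pos == np]
    }, numeric(1))
  })
}
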