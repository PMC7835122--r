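#' Configuration of a synthetic category world
#'
#' The world emulates the structure assumed by the few-shot transfer
#' hypothesis: a large set of mutually exclusive "base" categories learned
#' first, plus a disjoint set of "novel" categories that share visual parts
#' with the base categories (a car wheel is new, but wheels are not).
#' Exemplars of every category vary in position, scale, rotation, clutter
#' and pixel noise, mimicking the pose/clutter/lighting variation of
#' natural photographs at a desk scale.
#'
#' Defaults are the package's reference study conditions: 30 base and 10
#' novel categories, 200 exemplars per category on a 32 x 32 canvas, with
#' 25 of the 200 base exemplars held out for validation.
#'
#' @param n_base_categories,n_novel_categories category counts.
#' @param exemplars_per_category rendered exemplars per category.
#' @param val_exemplars_per_base_category base exemplars held out for
#'   validation; must be smaller than `exemplars_per_category`.
#' @param image_size square canvas edge in pixels.
#' @param part_dictionary_size number of shape stamps in the shared part
#'   dictionary.
#' @param parts_per_category parts composing each category (sampled from
#'   the shared dictionary, so base/novel part overlap is nonzero in
#'   expectation).
#' @param translation_jitter per-part positional jitter in pixels.
#' @param scale_jitter length-2 multiplicative scale range, e.g.
#'   `c(0.8, 1.25)`.
#' @param rotation_jitter per-part rotation jitter in degrees.
#' @param clutter_density expected number of distractor parts per image
#'   (Poisson), drawn from the same dictionary so negatives are genuinely
#'   confusable.
#' @param noise_sd additive Gaussian pixel noise, in [0,1] intensity units.
#' @param seed master seed; all role-specific streams derive from it.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_base_categories = 30,
                         n_novel_categories = 10,
                         exemplars_per_category = 200,
                         val_exemplars_per_base_category = 25,
                         image_size = 32,
                         part_dictionary_size = 12,
                         parts_per_category = 3,
                         translation_jitter = 3,
                         scale_jitter = c(0.8, 1.25),
                         rotation_jitter = 20,
                         clutter_density = 1,
                         noise_sd = 0.05,
                         seed = 7) {
  for (nm in c("n_base_categories", "n_novel_categories",
               "exemplars_per_category", "val_exemplars_per_base_category",
               "image_size", "part_dictionary_size", "parts_per_category")) {
    stop_if_not_count(get(nm), nm)
  }
  if (parts_per_category > part_dictionary_size) {
    stop("parts_per_category must not exceed part_dictionary_size",
         call. = FALSE)
  }
  if (val_exemplars_per_base_category >= exemplars_per_category) {
    stop("val_exemplars_per_base_category must be smaller than ",
         "exemplars_per_category", call. = FALSE)
  }
  if (noise_sd < 0 || translation_jitter < 0 || rotation_jitter < 0 ||
      clutter_density < 0) {
    stop("noise_sd, jitters and clutter_density must be non-negative",
         call. = FALSE)
  }
  stopifnot(length(scale_jitter) == 2, all(scale_jitter > 0),
            scale_jitter[1] <= scale_jitter[2])
  structure(list(
    n_base_categories = as.integer(n_base_categories),
    n_novel_categories = as.integer(n_novel_categories),
    exemplars_per_category = as.integer(exemplars_per_category),
    val_exemplars_per_base_category =
      as.integer(val_exemplars_per_base_category),
    image_size = as.integer(image_size),
    part_dictionary_size = as.integer(part_dictionary_size),
    parts_per_category = as.integer(parts_per_category),
    translation_jitter = translation_jitter,
    scale_jitter = scale_jitter,
    rotation_jitter = rotation_jitter,
    clutter_density = clutter_density,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "world_config")
}

# ---- part dictionary ------------------------------------------------------

# Procedural shape stamps on a fixed base grid.  Families cycle (blob, bar,
# ring, corner, cross, spokes) with seeded parameter jitter, so any
# dictionary size yields visually distinct, roughly balanced parts.
make_part_stamp <- function(family, grid = 15) {
  ax <- seq(-1, 1, length.out = grid)
  X <- matrix(ax, grid, grid, byrow = TRUE)
  Y <- matrix(ax, grid, grid)
  soft <- function(d, edge = 0.12) pmin(pmax((edge - d) / edge, 0), 1)
  img <- switch(family,
    blob = {
      cx <- runif(1, -0.3, 0.3); cy <- runif(1, -0.3, 0.3)
      rx <- runif(1, 0.35, 0.6); ry <- runif(1, 0.35, 0.6)
      d <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2) - 1
      soft(d, 0.35)
    },
    bar = {
      th <- runif(1, 0, pi)
      u <- X * cos(th) + Y * sin(th)
      v <- -X * sin(th) + Y * cos(th)
      hw <- runif(1, 0.12, 0.22)
      soft(pmax(abs(v) - hw, abs(u) - 0.8))
    },
    ring = {
      r <- runif(1, 0.45, 0.65); t <- runif(1, 0.1, 0.2)
      soft(abs(sqrt(X^2 + Y^2) - r) - t)
    },
    corner = {
      hw <- runif(1, 0.12, 0.2)
      arm1 <- pmax(abs(Y + 0.4) - hw, abs(X) - 0.75)
      arm2 <- pmax(abs(X + 0.4) - hw, abs(Y) - 0.75)
      pmax(soft(arm1), soft(arm2))
    },
    cross = {
      hw <- runif(1, 0.1, 0.18)
      pmax(soft(pmax(abs(Y) - hw, abs(X) - 0.8)),
           soft(pmax(abs(X) - hw, abs(Y) - 0.8)))
    },
    spokes = {
      k <- sample(3:5, 1)
      ang <- atan2(Y, X); r <- sqrt(X^2 + Y^2)
      m <- abs(sin(k * ang / 2))^0.5
      soft(pmax(r - 0.8, 0.25 - r)) * pmin(1.2 * (1 - m) + 0.2, 1) *
        (r <= 0.85)
    },
    stop("unknown stamp family: ", family))
  img[img < 0.02] <- 0
  img
}

part_families <- c("blob", "bar", "ring", "corner", "cross", "spokes")

#' Build a synthetic category world
#'
#' Generates the shared part dictionary and the base/novel category
#' specifications.  Each category samples `parts_per_category` parts without
#' replacement from the shared dictionary (with replacement across
#' categories), so part overlap between novel and base categories is
#' nonzero in expectation; base and novel labels are disjoint by
#' construction.
#'
#' @param config a [world_config()].
#' @return an object of class `category_world` with elements `parts`
#'   (list of stamp matrices), `base` and `novel` (lists of category
#'   specs with `label`, `part_ids`, `layout`), and `config`.
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(derive_seed(config$seed, "world"), {
    parts <- lapply(seq_len(config$part_dictionary_size), function(i) {
      make_part_stamp(part_families[(i - 1) %% length(part_families) + 1])
    })
    make_spec <- function(label) {
      ids <- sample.int(config$part_dictionary_size,
                        config$parts_per_category, replace = FALSE)
      layout <- data.frame(
        part_id = ids,
        x = runif(length(ids), 0.2, 0.8),
        y = runif(length(ids), 0.2, 0.8),
        scale = runif(length(ids), 0.25, 0.45)
      )
      list(label = label, part_ids = ids, layout = layout)
    }
    base <- lapply(sprintf("base%02d", seq_len(config$n_base_categories)),
                   make_spec)
    novel <- lapply(sprintf("novel%02d", seq_len(config$n_novel_categories)),
                    make_spec)
    structure(list(parts = parts, base = base, novel = novel,
                   config = config),
              class = "category_world")
  })
}

#' @export
print.category_world <- function(x, ...) {
  cat(sprintf(
    "<category_world> %d parts, %d base + %d novel categories, %dx%d px\n",
    length(x$parts), length(x$base), length(x$novel),
    x$config$image_size, x$config$image_size))
  invisible(x)
}

# ---- rendering ------------------------------------------------------------

#' Render one exemplar of a category
#'
#' Stamps each part at its canonical position perturbed by translation
#' jitter, scaled by a draw from the scale-jitter range, and rotated by a
#' uniform draw in +/- `rotation_jitter` degrees; adds Poisson-distributed
#' distractor parts from the shared dictionary; then adds Gaussian pixel
#' noise and clips to [0, 1].  Consumes the current RNG stream; with all
#' jitters, clutter and noise at zero the rendering is deterministic.
#'
#' @param spec a category spec from [build_world()].
#' @param parts the world's part dictionary.
#' @param config the [world_config()].
#' @return an `image_size` x `image_size` intensity matrix in [0, 1].
#' @export
render_exemplar <- function(spec, parts, config) {
  sz <- config$image_size
  canvas <- matrix(0, sz, sz)
  lay <- spec$layout
  for (i in seq_len(nrow(lay))) {
    cy <- lay$y[i] * (sz - 1) + 1 +
      runif(1, -config$translation_jitter, config$translation_jitter)
    cx <- lay$x[i] * (sz - 1) + 1 +
      runif(1, -config$translation_jitter, config$translation_jitter)
    sc <- lay$scale[i] * sz / nrow(parts[[lay$part_id[i]]]) *
      runif(1, config$scale_jitter[1], config$scale_jitter[2])
    th <- runif(1, -config$rotation_jitter, config$rotation_jitter) * pi / 180
    canvas <- place_stamp(canvas, parts[[lay$part_id[i]]], cy, cx, sc, th)
  }
  n_clutter <- if (config$clutter_density > 0) {
    stats::rpois(1, config$clutter_density)
  } else 0L
  if (n_clutter > 0) {
    for (j in seq_len(n_clutter)) {
      pid <- sample.int(length(parts), 1)
      cy <- runif(1, 1, sz); cx <- runif(1, 1, sz)
      sc <- runif(1, 0.25, 0.45) * sz / nrow(parts[[pid]]) *
        runif(1, config$scale_jitter[1], config$scale_jitter[2])
      th <- runif(1, 0, 2 * pi)
      canvas <- place_stamp(canvas, parts[[pid]], cy, cx, sc, th)
    }
  }
  if (config$noise_sd > 0) {
    canvas <- canvas + matrix(stats::rnorm(sz * sz, 0, config$noise_sd),
                              sz, sz)
  }
  pmin(pmax(canvas, 0), 1)
}

#' Render the canonical (jitter-free, noise-free) image of a category
#'
#' @inheritParams render_exemplar
#' @export
render_canonical <- function(spec, parts, config) {
  cfg0 <- config
  cfg0$translation_jitter <- 0
  cfg0$rotation_jitter <- 0
  cfg0$scale_jitter <- c(1, 1)
  cfg0$clutter_density <- 0
  cfg0$noise_sd <- 0
  render_exemplar(spec, parts, cfg0)
}

# ---- dataset generation ---------------------------------------------------

dataset_roles <- c("base-train", "base-val", "novel")

#' Expected dataset sizes implied by a world configuration
#'
#' Pure partition arithmetic: base-train images per base category are the
#' exemplars remaining after the validation hold-out; base-val holds the
#' hold-out; novel categories keep all exemplars.
#'
#' @param config a [world_config()].
#' @return named list with `base_train`, `base_val` and `novel` image counts.
#' @export
dataset_sizes <- function(config) {
  stopifnot(inherits(config, "world_config"))
  per_train <- config$exemplars_per_category -
    config$val_exemplars_per_base_category
  list(
    base_train = config$n_base_categories * per_train,
    base_val = config$n_base_categories *
      config$val_exemplars_per_base_category,
    novel = config$n_novel_categories * config$exemplars_per_category
  )
}

#' Generate a rendered image dataset for one role
#'
#' Roles are `base-train`, `base-val` and `novel`.  Each role renders from
#' its own sub-seed derived from the master seed, so datasets for different
#' roles are independently reproducible and no rendered image is shared
#' between base-train and base-val.
#'
#' @param world a [build_world()] result.
#' @param role one of `"base-train"`, `"base-val"`, `"novel"`.
#' @param config optional override of `world$config`.
#' @return an object of class `image_dataset`: list with `images`
#'   (size x size x n array), `ids`, `labels`, `role`, `provenance`.
#' @export
generate_dataset <- function(world, role, config = world$config) {
  stopifnot(inherits(world, "category_world"))
  if (!role %in% dataset_roles) {
    stop("unknown role '", role, "'; expected one of: ",
         paste(dataset_roles, collapse = ", "), call. = FALSE)
  }
  specs <- if (role == "novel") world$novel else world$base
  n_per <- switch(role,
    "base-train" = config$exemplars_per_category -
      config$val_exemplars_per_base_category,
    "base-val" = config$val_exemplars_per_base_category,
    "novel" = config$exemplars_per_category)
  role_seed <- derive_seed(config$seed, "dataset", role)
  sz <- config$image_size
  n_total <- length(specs) * n_per
  images <- array(0, dim = c(sz, sz, n_total))
  labels <- character(n_total)
  ids <- character(n_total)
  with_seed(role_seed, {
    k <- 0L
    for (spec in specs) {
      for (i in seq_len(n_per)) {
        k <- k + 1L
        images[, , k] <- render_exemplar(spec, world$parts, config)
        labels[k] <- spec$label
        ids[k] <- sprintf("%s/%s/%04d", role, spec$label, i)
      }
    }
  })
  structure(list(images = images, ids = ids, labels = labels, role = role,
                 provenance = list(world_seed = config$seed,
                                   role_seed = role_seed)),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> role=%s, %d images (%dx%d), %d categories\n",
              x$role, length(x$ids), dim(x$images)[1], dim(x$images)[2],
              length(unique(x$labels))))
  invisible(x)
}

#' Subset an image dataset by image index
#' @param x an `image_dataset`.
#' @param idx integer or logical index over images.
#' @export
dataset_subset <- function(x, idx) {
  structure(list(images = x$images[, , idx, drop = FALSE],
                 ids = x$ids[idx], labels = x$labels[idx],
                 role = x$role, provenance = x$provenance),
            class = "image_dataset")
}
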