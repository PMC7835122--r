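# Disk formats: datasets as one PNG per image under role/category
# directories with a manifest CSV as the source of truth; feature
# matrices as CSV with (image_id, label, f0000...); model checkpoints as
# an RDS parameter container with a JSON sidecar for the config, tap
# registry and training log.

#' Write an image dataset to disk
#'
#' One grayscale PNG per image under `dir/role/category/`, plus
#' `manifest.csv` (image path, label, role) and the world configuration
#' as `world_config.json`.
#'
#' @param dataset an `image_dataset`.
#' @param dir output directory.
#' @param config optional [world_config()] to serialise alongside.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  stopifnot(inherits(dataset, "image_dataset"))
  n <- length(dataset$ids)
  paths <- file.path(dir, paste0(dataset$ids, ".png"))
  for (d in unique(dirname(paths))) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[, , i], paths[i])
  }
  manifest <- data.frame(path = paste0(dataset$ids, ".png"),
                         label = dataset$labels, role = dataset$role,
                         stringsAsFactors = FALSE)
  mpath <- file.path(dir, paste0(gsub("/", "_", dataset$role),
                                 "_manifest.csv"))
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config),
                         file.path(dir, "world_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(mpath)
}

#' Read an image dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @param role which role's manifest to read.
#' @export
read_dataset <- function(dir, role) {
  mpath <- file.path(dir, paste0(gsub("/", "_", role), "_manifest.csv"))
  if (!file.exists(mpath)) {
    stop("no manifest for role '", role, "' in ", dir, call. = FALSE)
  }
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  imgs <- lapply(file.path(dir, manifest$path), function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  sz <- nrow(imgs[[1]])
  images <- array(unlist(imgs), dim = c(sz, sz, length(imgs)))
  structure(list(images = images,
                 ids = sub("\\.png$", "", manifest$path),
                 labels = manifest$label, role = role,
                 provenance = list(source = dir)),
            class = "image_dataset")
}

#' Write a feature matrix as CSV
#'
#' Header `image_id, label, f0000, ...`; the canonical on-disk format for
#' extracted features.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(image_id = fm$ids, label = fm$labels,
                   fm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV written by [write_features()]
#'
#' @param path CSV path.
#' @param tap tap name to record on the object.
#' @export
read_features <- function(path, tap) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  new_feature_matrix(values, df$image_id, df$label, tap)
}

#' Save / load a trained hierarchy
#'
#' The parameter container is a single RDS file; a JSON sidecar
#' (`<path>.json`) carries the configuration, tap registry and training
#' log for inspection without loading the parameters.
#'
#' @param model a `trained_hierarchy`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @export
save_hierarchy <- function(model, path) {
  stopifnot(inherits(model, "trained_hierarchy"))
  saveRDS(model, path)
  side <- list(config = unclass(model$config), labels = model$labels,
               taps = model$taps,
               log = if (!is.null(model$log)) model$log else NULL)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname save_hierarchy
#' @export
load_hierarchy <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_hierarchy"))
  model
}
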