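#' Generate a shape dataset in memory
#'
#' Renders `n_per_category` images for each requested category.  Each
#' image's seed is derived deterministically from the master seed, the
#' category name and the image index (see [derive_seed()]), so any subset of
#' the dataset is reproducible independently of generation order.
#'
#' @param categories character vector of category names (default: all 24).
#' @param n_per_category images per category (default from the registry:
#'   540).
#' @param master_seed integer master seed.
#' @param registry a [shape_registry()].
#' @param canvas_size render size in pixels.
#' @return an object of class `shape_dataset`: a list with `images` (list of
#'   `raster_image` matrices) and `manifest` (data frame with columns
#'   `category`, `index`, `seed`, `split`, `params_json`).
#' @export
generate_images <- function(categories = category_names(registry),
                            n_per_category = registry$n_per_category,
                            master_seed = 1,
                            registry = shape_registry(),
                            canvas_size = 256) {
  stopifnot(all(categories %in% category_names(registry)))
  total <- length(categories) * n_per_category
  images <- vector("list", total)
  rows <- vector("list", total)
  k <- 0
  for (cat in categories) {
    for (i in seq_len(n_per_category)) {
      k <- k + 1
      seed <- derive_seed(master_seed, cat, i)
      spec <- tryCatch(
        make_shape(cat, seed, registry),
        shapenet_generation_error = function(e) {
          stop_generation("category %s, index %d (seed %d): %s",
                          cat, i, seed, conditionMessage(e))
        }
      )
      images[[k]] <- render(spec, canvas_size)
      rows[[k]] <- data.frame(
        category = cat, index = i, seed = seed, split = NA_character_,
        params_json = jsonlite::toJSON(spec$transform, auto_unbox = TRUE,
                                       digits = 6),
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$params_json <- as.character(manifest$params_json)
  structure(list(images = images, manifest = manifest,
                 canvas_size = canvas_size, master_seed = master_seed),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf("shape_dataset: %d images, %d categories, %dx%d px\n",
              nrow(x$manifest), length(unique(x$manifest$category)),
              x$canvas_size, x$canvas_size))
  invisible(x)
}

#' Generate a shape dataset on disk
#'
#' Like [generate_images()], but writes each image as a PNG in a
#' category-per-directory layout (`<out_dir>/<category>/<index>.png`), plus
#' `manifest.csv` and the registry configuration as a YAML sidecar.
#'
#' @inheritParams generate_images
#' @param out_dir output directory (created if needed).
#' @return the manifest data frame (invisibly), with a `path` column
#'   pointing at the written files.
#' @export
generate_dataset <- function(out_dir,
                             categories = category_names(registry),
                             n_per_category = registry$n_per_category,
                             master_seed = 1,
                             registry = shape_registry(),
                             canvas_size = 256) {
  ds <- generate_images(categories, n_per_category, master_seed, registry,
                        canvas_size)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- ds$manifest
  man$path <- file.path(out_dir, man$category,
                        sprintf("%04d.png", man$index))
  for (d in unique(dirname(man$path))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  for (k in seq_len(nrow(man))) {
    png::writePNG(unclass(ds$images[[k]]) / 255, man$path[k])
  }
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write_registry(registry, file.path(out_dir, "registry.yaml"))
  invisible(man)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return a `shape_dataset` with images read back from PNG.
#' @export
load_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  images <- lapply(man$path, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    structure(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
              class = c("raster_image", "matrix", "array"))
  })
  structure(list(images = images, manifest = man,
                 canvas_size = nrow(images[[1]]), master_seed = NA),
            class = "shape_dataset")
}

#' Stratified train/validation split of learning categories
#'
#' Tags each image of the two learning categories as `"train"` or
#' `"validation"` by a per-category stratified random draw; `round(train_frac
#' * n)` images per category go to training.  Other categories' split tags
#' are left untouched.
#'
#' @param manifest a dataset manifest data frame.
#' @param categories character vector of learning category names present in
#'   the manifest.
#' @param train_frac fraction of each category used for training, in (0, 1);
#'   default 0.85.
#' @param seed integer seed for the split draw.
#' @return the manifest with an updated `split` column.
#' @export
make_splits <- function(manifest, categories, train_frac = 0.85, seed = 1) {
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly inside (0, 1)")
  }
  missing_cats <- setdiff(categories, manifest$category)
  if (length(missing_cats)) {
    stop("categories absent from manifest: ",
         paste(missing_cats, collapse = ", "))
  }
  with_seed(seed, {
    for (cat in categories) {
      idx <- which(manifest$category == cat)
      n_train <- round(train_frac * length(idx))
      if (n_train == 0 || n_train == length(idx)) {
        stop("train_frac ", train_frac, " leaves an empty partition for ", cat)
      }
      tr <- sample(idx, n_train)
      manifest$split[idx] <- "validation"
      manifest$split[tr] <- "train"
    }
  })
  manifest
}
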