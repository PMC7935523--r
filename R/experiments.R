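#' The learning/transfer task registry
#'
#' The 12 benchmark tasks in 6 groups.  Groups A and B probe local features
#' with quadrilaterals (group A learns square vs. trapezoid, group B square
#' vs. parallelogram, each with three transfer pairs); groups C and D probe
#' the presence of a hole with regular and irregularized figures; group E
#' probes connectivity (outline triangles vs. their disassembled sides); and
#' group F probes the inside/outside relationship (dot placement relative to
#' a closed figure).  Class 0 of a transfer pair plays the role of class 0
#' of the learning pair: a classifier that extracted the shared feature
#' should label transfer images by the learned rule.
#'
#' @param id optional experiment id (e.g. `"C.1"`) to return a single
#'   definition.
#' @return a named list of `experiment_def` objects (or one, if `id` is
#'   given), each with fields `id`, `group`, `learning_pair`,
#'   `transfer_pair`, and `epochs`.
#' @examples
#' experiment_registry("A.1")$learning_pair
#' @export
experiment_registry <- function(id = NULL) {
  def <- function(id, learning, transfer, epochs = 20L) {
    structure(list(id = id, group = sub("\\..*$", "", id),
                   learning_pair = learning, transfer_pair = transfer,
                   epochs = epochs),
              class = "experiment_def")
  }
  defs <- list(
    def("A.1", c("square", "trapezoid"), c("rectangle", "trapezoid")),
    def("A.2", c("square", "trapezoid"), c("parallelogram", "trapezoid")),
    def("A.3", c("square", "trapezoid"), c("rectangle", "parallelogram")),
    def("B.1", c("square", "parallelogram"), c("trapezoid", "parallelogram")),
    def("B.2", c("square", "parallelogram"), c("rectangle", "parallelogram")),
    def("B.3", c("square", "parallelogram"), c("rectangle", "trapezoid")),
    def("C.1", c("disk", "ring"), c("triangle-solid", "triangle-ring")),
    def("C.2", c("disk", "ring"), c("square-solid", "square-ring")),
    def("D.1", c("irregular-disk", "irregular-ring"),
        c("irregular-triangle-solid", "irregular-triangle-ring")),
    def("D.2", c("irregular-disk", "irregular-ring"),
        c("irregular-square", "irregular-square-ring")),
    def("E", c("isosceles-triangle-outline", "disassembled-isosceles-triangle"),
        c("irregular-triangle-outline", "disassembled-irregular-triangle")),
    def("F", c("dot-inside-circle", "dot-outside-circle"),
        c("dot-inside-square", "dot-outside-square"))
  )
  names(defs) <- vapply(defs, `[[`, "", "id")
  if (is.null(id)) return(defs)
  if (!id %in% names(defs)) stop("unknown experiment id: ", id)
  defs[[id]]
}

#' @export
print.experiment_def <- function(x, ...) {
  cat(sprintf("experiment %s: learn %s vs. %s; transfer %s vs. %s (%d epochs)\n",
              x$id, x$learning_pair[1], x$learning_pair[2],
              x$transfer_pair[1], x$transfer_pair[2], x$epochs))
  invisible(x)
}

#' Run one learning-to-transfer experiment
#'
#' Splits the learning pair 85/15 into train/validation, trains the
#' classifier one epoch at a time, and after every epoch records the
#' validation accuracy on the held-out learning images (the learning curve)
#' and the accuracy on the complete transfer pair (the transfer curve).  No
#' transfer image is ever used for training.
#'
#' @param def an `experiment_def` (or an id string).
#' @param model_factory function of one argument (`seed`) returning a fresh
#'   classifier honoring the contract of [train_one_epoch()].
#' @param dataset a `shape_dataset` containing all four categories.
#' @param epochs number of training epochs (default: the definition's, 20).
#' @param split_seed seed for the train/validation draw.
#' @param train_seed seed passed to `model_factory`.
#' @param train_frac training fraction of the learning categories.
#' @param preset input preset used to prepare features (see
#'   [input_preset()]).
#' @return an object of class `shapenet_run` with per-epoch `learning` and
#'   `transfer` accuracy vectors (percent).
#' @seealso [summary.shapenet_run()], [tfi()], [build_report()]
#' @export
run_experiment <- function(def, model_factory, dataset,
                           epochs = NULL, split_seed = 1, train_seed = 1,
                           train_frac = 0.85, preset = "reference") {
  if (is.character(def)) def <- experiment_registry(def)
  stopifnot(inherits(def, "experiment_def"),
            inherits(dataset, "shape_dataset"))
  if (is.null(epochs)) epochs <- def$epochs
  man <- dataset$manifest
  need <- c(def$learning_pair, def$transfer_pair)
  missing_cats <- setdiff(need, man$category)
  if (length(missing_cats)) {
    stop("dataset lacks categories: ", paste(missing_cats, collapse = ", "))
  }
  man <- make_splits(man, def$learning_pair, train_frac, split_seed)
  man$split[man$category %in% setdiff(def$transfer_pair, def$learning_pair)] <-
    "transfer"

  feat <- function(idx) flatten_images(dataset$images[idx], preset)
  lab <- function(idx, pair) ifelse(man$category[idx] == pair[1], 0L, 1L)

  itr <- which(man$category %in% def$learning_pair & man$split == "train")
  iva <- which(man$category %in% def$learning_pair & man$split == "validation")
  # the transfer evaluation uses every image of both transfer categories; a
  # category reused from the learning pair keeps its train/validation tag,
  # all purely-transfer images are tagged "transfer" and never trained on
  ite <- which(man$category %in% def$transfer_pair)

  xtr <- feat(itr); ytr <- lab(itr, def$learning_pair)
  xva <- feat(iva); yva <- lab(iva, def$learning_pair)
  xte <- feat(ite); yte <- lab(ite, def$transfer_pair)
  attr(xva, "labels") <- yva
  attr(xte, "labels") <- yte

  clf <- model_factory(train_seed)
  learning <- transfer <- numeric(epochs)
  for (e in seq_len(epochs)) {
    clf <- train_one_epoch(clf, xtr, ytr)
    learning[e] <- evaluate(clf, xva, yva)
    transfer[e] <- evaluate(clf, xte, yte)
  }
  structure(list(
    id = def$id, model = class(clf)[1], epochs = epochs,
    split_seed = split_seed, train_seed = train_seed,
    learning = learning, transfer = transfer,
    n_train = length(itr), n_validation = length(iva), n_transfer = length(ite)
  ), class = "shapenet_run")
}

#' @export
print.shapenet_run <- function(x, ...) {
  cat(sprintf("shapenet_run %s [%s], %d epochs\n", x$id, x$model, x$epochs))
  cat(sprintf("  learning: %.2f%% (epoch 1) -> %.2f%% (epoch %d)\n",
              x$learning[1], x$learning[x$epochs], x$epochs))
  cat(sprintf("  transfer: %.2f%% (epoch 1) -> %.2f%% (epoch %d)\n",
              x$transfer[1], x$transfer[x$epochs], x$epochs))
  invisible(x)
}

#' @export
as.data.frame.shapenet_run <- function(x, ...) {
  data.frame(epoch = seq_len(x$epochs), learning_acc = x$learning,
             transfer_acc = x$transfer)
}

#' Summarize a run with the transfer statistics
#'
#' @param object a `shapenet_run`.
#' @param ... unused.
#' @return a list with learning accuracy and Transfer Index at epochs 1 and
#'   K, plus the learning-vs-transfer regression slope and R.
#' @export
summary.shapenet_run <- function(object, ...) {
  k <- object$epochs
  reg <- transfer_regression(object$learning, object$transfer)
  out <- list(
    id = object$id, model = object$model, epochs = k,
    learning_1 = object$learning[1], learning_k = object$learning[k],
    tfi_1 = tfi(object$learning, object$transfer, 1, on_undefined = "na"),
    tfi_k = tfi(object$learning, object$transfer, k, on_undefined = "na"),
    slope = reg$slope, r = reg$r, degenerate = reg$degenerate
  )
  class(out) <- "summary.shapenet_run"
  out
}

#' @export
print.summary.shapenet_run <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "N/A" else sprintf("%.2f", v)
  cat(sprintf("experiment %s [%s]\n", x$id, x$model))
  cat(sprintf("  learning accuracy: epoch 1 = %s, epoch %d = %s\n",
              fmt(x$learning_1), x$epochs, fmt(x$learning_k)))
  cat(sprintf("  TFI: epoch 1 = %s%%, epoch %d = %s%%\n",
              fmt(x$tfi_1), x$epochs, fmt(x$tfi_k)))
  cat(sprintf("  regression: slope = %s, R = %s%s\n", fmt(x$slope), fmt(x$r),
              if (x$degenerate) " (N/A: constant learning curve)" else ""))
  invisible(x)
}

#' Plot learning and transfer curves
#'
#' @param x a `shapenet_run`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.shapenet_run <- function(x, ...) {
  graphics::matplot(seq_len(x$epochs), cbind(x$learning, x$transfer),
                    type = "b", pch = c(16, 17), lty = 1,
                    col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "accuracy (%)", ylim = c(0, 100),
                    main = sprintf("experiment %s", x$id), ...)
  graphics::abline(h = 50, lty = 3)
  graphics::legend("bottomright", c("learning", "transfer"),
                   col = c("black", "firebrick"), pch = c(16, 17), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Write / read a run log as CSV
#'
#' The CSV has columns `epoch, learning_acc, transfer_acc` plus `#`-prefixed
#' metadata header lines; the round-trip is lossless for the curves.
#' Externally produced CSVs with the three columns (no metadata) are
#' accepted, enabling metric-only use on accuracy logs from other training
#' stacks.
#'
#' @param run a `shapenet_run`.
#' @param path CSV file path.
#' @return `write_log` returns `path` invisibly; `read_log` returns a
#'   `shapenet_run`.
#' @export
write_log <- function(run, path) {
  stopifnot(inherits(run, "shapenet_run"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf("#%s=%s", c("id", "model", "split_seed", "train_seed"),
                  c(run$id, run$model, run$split_seed, run$train_seed))
  writeLines(meta, con)
  write.csv(as.data.frame(run), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  need <- c("epoch", "learning_acc", "transfer_acc")
  if (!all(need %in% names(df))) {
    stop("log must have columns: ", paste(need, collapse = ", "))
  }
  if (!identical(as.integer(df$epoch), seq_len(nrow(df)))) {
    stop("epochs must be consecutive from 1 (row ",
         which(as.integer(df$epoch) != seq_len(nrow(df)))[1], ")")
  }
  if (any(df$learning_acc < 0 | df$learning_acc > 100) ||
      any(df$transfer_acc < 0 | df$transfer_acc > 100)) {
    stop("accuracies must lie in [0, 100]")
  }
  structure(list(
    id = meta$id %||% NA_character_, model = meta$model %||% NA_character_,
    epochs = nrow(df),
    split_seed = as.integer(meta$split_seed %||% NA),
    train_seed = as.integer(meta$train_seed %||% NA),
    learning = as.numeric(df$learning_acc),
    transfer = as.numeric(df$transfer_acc),
    n_train = NA, n_validation = NA, n_transfer = NA
  ), class = "shapenet_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
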