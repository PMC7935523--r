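#' Half Area Under Curve (HAUC)
#'
#' Accumulates accuracy above the 50% chance level over training epochs:
#' `sum(accuracy[e] - 50)` for epochs `1..k` (discrete rectangle rule).
#' "Half" refers to measuring only the area above chance; the value can be
#' negative when a curve runs below 50%.  A trapezoidal rule is available as
#' a non-default alternative.
#'
#' @param curve numeric vector of per-epoch accuracies in percent (epoch 1
#'   first), or a `shapenet_run` curve.
#' @param k integrate over epochs `1..k` (default: the whole curve).
#' @param rule `"sum"` (default) or `"trapezoid"`.
#' @return HAUC in percent-epochs.
#' @examples
#' hauc(c(60, 70, 80))  # 10 + 20 + 30 = 60
#' @export
hauc <- function(curve, k = length(curve), rule = c("sum", "trapezoid")) {
  rule <- match.arg(rule)
  curve <- as_curve(curve)
  if (k < 1 || k > length(curve)) {
    stop("k must be between 1 and the curve length (", length(curve), ")")
  }
  x <- curve[seq_len(k)] - 50
  if (rule == "sum" || k == 1) sum(x) else sum((x[-1] + x[-k]) / 2)
}

as_curve <- function(curve) {
  if (inherits(curve, "shapenet_run")) {
    stop("pass run$learning or run$transfer, not the run object")
  }
  if (is.data.frame(curve)) {
    stopifnot(!is.null(curve$accuracy))
    curve <- curve$accuracy
  }
  stopifnot(is.numeric(curve), length(curve) >= 1, all(is.finite(curve)),
            all(curve >= 0 & curve <= 100))
  as.numeric(curve)
}

#' Transfer Index (TFI)
#'
#' The ratio of the transfer curve's HAUC to the learning curve's HAUC,
#' expressed in percent: `100 * hauc(transfer, k) / hauc(learning, k)`.
#' 100% is perfect transfer (achieved when both curves sit at 100%
#' accuracy); 0% means the transfer curve never left chance level; negative
#' values mean below-chance transfer.  The index is undefined when the
#' learning HAUC is not positive (learning never exceeded chance): that case
#' raises an error by default, or returns `NA` with `on_undefined = "na"`.
#'
#' @param learning,transfer per-epoch accuracy vectors (percent) sharing an
#'   epoch range.
#' @param k epoch horizon (default: full curve).
#' @param on_undefined `"error"` or `"na"`.
#' @inheritParams hauc
#' @return TFI in percent.
#' @examples
#' tfi(rep(100, 20), rep(100, 20))    # 100
#' tfi(c(80), c(65), k = 1)           # 50
#' @export
tfi <- function(learning, transfer, k = length(as_curve(learning)),
                on_undefined = c("error", "na"), rule = c("sum", "trapezoid")) {
  on_undefined <- match.arg(on_undefined)
  rule <- match.arg(rule)
  learning <- as_curve(learning)
  transfer <- as_curve(transfer)
  if (length(learning) != length(transfer)) {
    stop("learning and transfer curves must share their epoch range")
  }
  hl <- hauc(learning, k, rule)
  if (hl <= 0) {
    if (on_undefined == "na") return(NA_real_)
    stop(structure(
      class = c("shapenet_undefined_tfi", "error", "condition"),
      list(message = sprintf(
        "TFI undefined: learning HAUC = %.3f is not positive", hl),
        call = sys.call())
    ))
  }
  100 * hauc(transfer, k, rule) / hl
}

#' Learning-vs-transfer regression
#'
#' Ordinary least squares of transfer accuracy (response) on learning
#' accuracy (predictor) across epochs, summarizing how tightly the transfer
#' curve tracks the learning curve.  `r` is the signed Pearson correlation
#' coefficient (set `absolute_r = TRUE` for its magnitude).  When the
#' learning curve is (numerically) constant the regression is degenerate and
#' both statistics are reported as `NA` with the `degenerate` flag set,
#' mirroring "N/A" entries in benchmark tables.
#'
#' @inheritParams tfi
#' @param var_tol predictor-variance threshold below which the fit is
#'   declared degenerate (percent^2 units).
#' @param absolute_r report `|r|` instead of signed `r`.
#' @return a list with `slope`, `r`, and logical `degenerate`.
#' @export
transfer_regression <- function(learning, transfer, var_tol = 1e-9,
                                absolute_r = FALSE) {
  learning <- as_curve(learning)
  transfer <- as_curve(transfer)
  if (length(learning) != length(transfer)) {
    stop("curves must share their epoch range")
  }
  if (length(learning) < 3) stop("regression needs at least 3 epochs")
  if (var(learning) < var_tol) {
    return(list(slope = NA_real_, r = NA_real_, degenerate = TRUE))
  }
  fit <- lm(transfer ~ learning)
  r <- if (var(transfer) < var_tol) 0 else cor(learning, transfer)
  list(slope = unname(coef(fit)[2]), r = if (absolute_r) abs(r) else r,
       degenerate = FALSE)
}

#' Build a transfer report from run logs
#'
#' One row per run: learning accuracy at epochs 1 and K, Transfer Index at
#' epochs 1 and K, and the learning-vs-transfer regression slope and R
#' (flagged `N/A` when degenerate) — the per-experiment summary block of a
#' benchmark table.
#'
#' @param runs a list of `shapenet_run` objects (from [run_experiment()] or
#'   [read_log()]).
#' @inheritParams hauc
#' @return a data frame of class `transfer_report`.
#' @export
build_report <- function(runs, rule = c("sum", "trapezoid")) {
  rule <- match.arg(rule)
  if (inherits(runs, "shapenet_run")) runs <- list(runs)
  rows <- lapply(runs, function(run) {
    stopifnot(inherits(run, "shapenet_run"))
    k <- run$epochs
    reg <- transfer_regression(run$learning, run$transfer)
    data.frame(
      experiment = run$id, model = run$model, epochs = k,
      learning_1 = run$learning[1], learning_k = run$learning[k],
      tfi_1 = tfi(run$learning, run$transfer, 1, "na", rule),
      tfi_k = tfi(run$learning, run$transfer, k, "na", rule),
      slope = reg$slope, r = reg$r, degenerate = reg$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transfer_report", "data.frame")
  out
}

#' @export
print.transfer_report <- function(x, digits = 2, ...) {
  fmt <- function(v, flag = rep(FALSE, length(v))) {
    ifelse(is.na(v) | flag, "N/A", formatC(v, digits = digits, format = "f"))
  }
  cat("Transfer report\n")
  df <- data.frame(
    experiment = x$experiment, model = x$model,
    `learn@1` = fmt(x$learning_1), `learn@K` = fmt(x$learning_k),
    `TFI@1` = fmt(x$tfi_1), `TFI@K` = fmt(x$tfi_k),
    slope = fmt(x$slope, x$degenerate), R = fmt(x$r, x$degenerate),
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write / read a transfer report as CSV
#'
#' @param report a `transfer_report`.
#' @param path CSV file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the `transfer_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "transfer_report"))
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("transfer_report", "data.frame")
  out
}
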