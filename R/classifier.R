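# Classifier contract: an object with train_one_epoch(clf, x, y) -> clf and
# predict(clf, x) -> integer labels in {0, 1}, where x is an n x d feature
# matrix.  predict must be deterministic between training calls.

#' Train a classifier for one epoch
#'
#' Generic entry point of the classifier contract used by
#' [run_experiment()].  One call consumes the full training set once, in a
#' shuffled minibatch order derived from the classifier's seed and epoch
#' counter, and returns the updated classifier.
#'
#' @param clf a classifier object.
#' @param x numeric feature matrix, one row per image.
#' @param y integer labels in `{0, 1}`.
#' @return the updated classifier.
#' @export
train_one_epoch <- function(clf, x, y) UseMethod("train_one_epoch")

#' Classification accuracy in percent
#'
#' @param clf a classifier object.
#' @param x feature matrix.
#' @param y true labels in `{0, 1}`.
#' @return `100 * correct / total`.
#' @export
evaluate <- function(clf, x, y) {
  if (is.null(nrow(x)) || nrow(x) == 0) stop("cannot evaluate on an empty set")
  stopifnot(nrow(x) == length(y))
  100 * mean(predict(clf, x) == y)
}

#' Reference classifier: a small seeded convolutional network
#'
#' A compact CNN for desk-scale runs: three 3x3 convolution blocks (ReLU,
#' then 2x2 max pooling) followed by one ReLU dense layer and a 2-way
#' softmax, trained with minibatch stochastic gradient descent with momentum
#' (learning rate 0.01, momentum 0.9, batch size 32).  The default takes
#' 64x64 grayscale input (flattened rows of [flatten_images()]) and uses
#' convolution widths 8/16/32 with a 128-unit dense layer, small enough to
#' train on a single CPU core in seconds per epoch.  Initialization and
#' per-epoch shuffling are fully determined by `seed`, so identical seeds
#' give identical models.
#'
#' @param input_size input image side length in pixels; must be divisible
#'   by 8 (three pooling stages).
#' @param widths integer vector of three convolution channel widths.
#' @param hidden dense layer width.
#' @param lr SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param batch_size minibatch size.
#' @param seed integer seed for weight initialization and shuffling.
#' @return an object of class `reference_classifier`.
#' @export
reference_classifier <- function(input_size = 64, widths = c(8, 16, 32),
                                 hidden = 128, lr = 0.01, momentum = 0.9,
                                 batch_size = 32, seed = 1) {
  stopifnot(input_size %% 8 == 0, length(widths) == 3, all(widths > 0),
            hidden > 0, batch_size > 0)
  cin <- c(1, widths[1], widths[2])
  flat <- (input_size / 8)^2 * widths[3]
  par <- with_seed(seed, {
    p <- list()
    for (l in 1:3) {
      fan_in <- 9 * cin[l]
      p[[paste0("W", l)]] <- matrix(rnorm(widths[l] * fan_in,
                                          sd = sqrt(2 / fan_in)),
                                    widths[l], fan_in)
      p[[paste0("b", l)]] <- rep(0, widths[l])
    }
    p$W4 <- matrix(rnorm(hidden * flat, sd = sqrt(2 / flat)), hidden, flat)
    p$b4 <- rep(0, hidden)
    p$W5 <- matrix(rnorm(2 * hidden, sd = sqrt(1 / hidden)), 2, hidden)
    p$b5 <- rep(0, 2)
    p
  })
  vel <- lapply(par, function(w) w * 0)
  structure(list(
    input_size = input_size, widths = widths, hidden = hidden,
    lr = lr, momentum = momentum, batch_size = batch_size, seed = seed,
    epoch = 0L, par = par, vel = vel
  ), class = c("reference_classifier", "shapenet_classifier"))
}

# forward pass through the conv trunk; returns activations needed by
# backprop.  Activations are channel-first (C, H, W, N) so the GEMM output
# (C_out x positions) reshapes to the next layer's input without copying.
cnn_forward <- function(clf, xb) {
  p <- clf$par
  sz <- clf$input_size
  w <- clf$widths
  nb <- nrow(xb)
  x <- t(xb)
  dim(x) <- c(1, sz, sz, nb)
  a <- list(x = x, nb = nb)
  h <- sz
  cin <- 1
  for (l in 1:3) {
    a[[paste0("cols", l)]] <- .im2col3(a[[if (l == 1) "x" else paste0("p", l - 1)]],
                                       cin, h, h, nb)
    z <- p[[paste0("W", l)]] %*% a[[paste0("cols", l)]] + p[[paste0("b", l)]]
    a[[paste0("mask", l)]] <- z > 0
    zr <- z * a[[paste0("mask", l)]]
    dim(zr) <- c(w[l], h, h, nb)
    pl <- .pool2_fwd(zr, w[l], h, h, nb)
    h <- h / 2
    pool <- pl$out
    dim(pool) <- c(w[l], h, h, nb)
    a[[paste0("p", l)]] <- pool
    a[[paste0("idx", l)]] <- pl$idx
    a[[paste0("xlen", l)]] <- length(zr)
    cin <- w[l]
  }
  flat <- a$p3
  dim(flat) <- c(length(flat) / nb, nb)
  a$flat <- flat
  a$z4 <- p$W4 %*% a$flat + p$b4
  a$h4 <- pmax(a$z4, 0)
  a$logits <- p$W5 %*% a$h4 + p$b5
  a
}

#' @export
train_one_epoch.reference_classifier <- function(clf, x, y) {
  stopifnot(ncol(x) == clf$input_size^2, all(y %in% c(0, 1)))
  n <- nrow(x)
  clf$epoch <- clf$epoch + 1L
  ord <- with_seed(clf$seed + 7919L * clf$epoch, sample.int(n))
  p <- clf$par
  v <- clf$vel
  sz <- clf$input_size
  w <- clf$widths
  for (s in seq(1, n, by = clf$batch_size)) {
    b <- ord[s:min(s + clf$batch_size - 1, n)]
    nb <- length(b)
    clf$par <- p
    a <- cnn_forward(clf, x[b, , drop = FALSE])
    # softmax cross-entropy gradient
    lg <- sweep(a$logits, 2, apply(a$logits, 2, max))
    pr <- exp(lg)
    pr <- sweep(pr, 2, colSums(pr), "/")
    dlg <- pr
    dlg[cbind(y[b] + 1, seq_len(nb))] <- dlg[cbind(y[b] + 1, seq_len(nb))] - 1
    dlg <- dlg / nb
    g <- list()
    g$W5 <- tcrossprod(dlg, a$h4)
    g$b5 <- rowSums(dlg)
    dh4 <- crossprod(p$W5, dlg) * (a$z4 > 0)
    g$W4 <- tcrossprod(dh4, a$flat)
    g$b4 <- rowSums(dh4)
    dflat <- crossprod(p$W4, dh4)
    h <- sz / 8
    dnext <- dflat
    for (l in 3:1) {
      dz <- .pool2_bwd(as.numeric(dnext), a[[paste0("idx", l)]],
                       a[[paste0("xlen", l)]])
      dim(dz) <- c(w[l], a[[paste0("xlen", l)]] / w[l])
      dz <- dz * a[[paste0("mask", l)]]
      g[[paste0("W", l)]] <- tcrossprod(dz, a[[paste0("cols", l)]])
      g[[paste0("b", l)]] <- rowSums(dz)
      if (l > 1) {
        dcols <- crossprod(p[[paste0("W", l)]], dz)
        dnext <- .col2im3(dcols, w[l - 1], 2 * h, 2 * h, a$nb)
        h <- h * 2
      }
    }
    for (nm in names(p)) {
      v[[nm]] <- clf$momentum * v[[nm]] - clf$lr * g[[nm]]
      p[[nm]] <- p[[nm]] + v[[nm]]
    }
  }
  clf$par <- p
  clf$vel <- v
  clf
}

#' @export
predict.reference_classifier <- function(object, newdata, ...) {
  n <- nrow(newdata)
  out <- integer(n)
  # evaluate in chunks to bound im2col memory
  for (s in seq(1, n, by = 256)) {
    b <- s:min(s + 255, n)
    a <- cnn_forward(object, newdata[b, , drop = FALSE])
    out[b] <- as.integer(max.col(t(a$logits)) - 1L)
  }
  out
}

#' @export
print.reference_classifier <- function(x, ...) {
  cat(sprintf(
    "reference_classifier: %dx%d input, conv widths %s, %d dense units, %d epoch(s) trained\n",
    x$input_size, x$input_size, paste(x$widths, collapse = "/"),
    x$hidden, x$epoch))
  invisible(x)
}

#' Degenerate classifiers for protocol checks
#'
#' `constant_classifier` always predicts one class (accuracy 50% on balanced
#' sets); `oracle_classifier` reads the true labels from the `"labels"`
#' attribute that [run_experiment()] attaches to every evaluation matrix
#' (accuracy 100%).  Both honor the classifier contract and are used to
#' validate the experiment protocol independently of any real model.
#'
#' @param label the constant label predicted.
#' @return a classifier object.
#' @export
constant_classifier <- function(label = 0L) {
  structure(list(label = as.integer(label)),
            class = c("constant_classifier", "shapenet_classifier"))
}

#' @export
train_one_epoch.constant_classifier <- function(clf, x, y) clf

#' @export
predict.constant_classifier <- function(object, newdata, ...) {
  rep(object$label, nrow(newdata))
}

#' @rdname constant_classifier
#' @export
oracle_classifier <- function() {
  structure(list(), class = c("oracle_classifier", "shapenet_classifier"))
}

#' @export
train_one_epoch.oracle_classifier <- function(clf, x, y) clf

#' @export
predict.oracle_classifier <- function(object, newdata, ...) {
  labels <- attr(newdata, "labels")
  if (is.null(labels)) stop("oracle_classifier needs a 'labels' attribute")
  labels
}

#' Flatten images into classifier features
#'
#' Resizes each image to the preset input size and flattens the grayscale
#' channel to a feature row, mapped so ink is 1 and background is 0.
#'
#' @param images list of `raster_image` matrices or 3-channel arrays.
#' @param preset model input preset name (see [input_preset()]).
#' @return an `n x size^2` numeric matrix in `[0, 1]`.
#' @export
flatten_images <- function(images, preset = "reference") {
  sz <- input_preset(preset)[1]
  out <- matrix(0, length(images), sz * sz)
  for (i in seq_along(images)) {
    a <- to_model_input(images[[i]], preset)
    out[i, ] <- 1 - as.numeric(a[, , 1]) / 255
  }
  out
}
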