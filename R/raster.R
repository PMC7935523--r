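#' Rasterize a shape specification
#'
#' Renders a dark shape on a light background as an 8-bit grayscale matrix.
#' Coverage is computed per pixel on a supersampled subgrid (box-filter
#' antialiasing); with `antialias = FALSE` pixels are binary.  Outline styles
#' use the spec's stroke width in canvas units, with an enforced minimum
#' effective half-width of 0.7 output pixels so thin strokes stay connected
#' at small render sizes.  Rendering is deterministic for fixed inputs.
#'
#' @param spec a `shape_spec` from [make_shape()], or a bare shape object.
#' @param canvas_size output size in pixels (square).
#' @param antialias logical; 2x2 supersampling when `TRUE`.
#' @param canvas_units canvas extent in geometry units (taken from the spec
#'   when available).
#' @return an integer matrix (`canvas_size` x `canvas_size`) of intensities
#'   0-255, 0 = ink, 255 = background, with class `raster_image`.
#' @export
render <- function(spec, canvas_size = 256, antialias = NULL,
                   canvas_units = NULL) {
  if (inherits(spec, "shape_spec")) {
    shape <- spec$geometry
    if (is.null(canvas_units)) canvas_units <- spec$canvas_units
    if (is.null(antialias)) antialias <- spec$antialias
  } else {
    shape <- spec
    if (is.null(canvas_units)) canvas_units <- 256
    if (is.null(antialias)) antialias <- TRUE
  }
  ss <- if (antialias) 2L else 1L
  scale <- canvas_units / canvas_size
  cov <- shape_coverage(shape, canvas_size, scale, ss)
  # floor, not round: half-covered pixels (coverage exactly 0.5) must land
  # on the ink side of the default binarization threshold
  img <- matrix(as.integer(floor(255 * (1 - pmin(1, pmax(0, cov))))),
                canvas_size, canvas_size)
  structure(img, class = c("raster_image", class(img)))
}

shape_coverage <- function(shape, n, scale, ss) {
  min_halfw <- 0.8 * scale  # stroke survival floor, in canvas units
  switch(shape$type,
    polygon = {
      if (shape$style == "filled") {
        .cov_polygon(n, n, scale, ss, shape$vertices[, 1], shape$vertices[, 2])
      } else {
        .cov_stroke(n, n, scale, ss, shape$vertices[, 1], shape$vertices[, 2],
                    max(shape$stroke_width / 2, min_halfw), TRUE)
      }
    },
    circle = {
      filled <- shape$style == "filled"
      .cov_circle(n, n, scale, ss, shape$center[1], shape$center[2],
                  shape$radius, filled,
                  if (filled) 0 else max(shape$stroke_width / 2, min_halfw))
    },
    segment = {
      v <- rbind(shape$p1, shape$p2)
      .cov_stroke(n, n, scale, ss, v[, 1], v[, 2],
                  max(shape$stroke_width / 2, min_halfw), FALSE)
    },
    annulus = {
      pmax(shape_coverage(shape$outer, n, scale, ss) -
             shape_coverage(shape$inner, n, scale, ss), 0)
    },
    composite = {
      covs <- lapply(shape$parts, shape_coverage, n = n, scale = scale, ss = ss)
      Reduce(pmax, covs)
    },
    stop("unknown shape type: ", shape$type)
  )
}

#' Resize an image to a model's input preset
#'
#' Bilinear resizing (via \pkg{EBImage}) to the input size a named model
#' expects, with the grayscale channel replicated to three channels.
#'
#' @param img a `raster_image` matrix (0-255) or a 3-channel array.
#' @param preset model name: `"alexnet"` (227), `"vgg19"` (224),
#'   `"resnet101"` (224), `"inception-resnet-v2"` (299), or `"reference"`
#'   (64).
#' @return a `size x size x 3` numeric array of intensities 0-255.
#' @export
to_model_input <- function(img, preset = "reference") {
  sz <- input_preset(preset)[1]
  m <- if (length(dim(img)) == 3) img[, , 1] else unclass(img)
  storage.mode(m) <- "double"
  if (nrow(m) != sz || ncol(m) != sz) {
    m <- EBImage::resize(m / 255, w = sz, h = sz) * 255
    m <- pmin(255, pmax(0, m))
  }
  array(m, dim = c(sz, sz, 3))
}

#' Input-size presets of the benchmark models
#'
#' @param model model name (see [to_model_input()]).
#' @return integer vector `(height, width, channels)`.
#' @examples
#' input_preset("alexnet")  # 227 227 3
#' @export
input_preset <- function(model) {
  presets <- c(alexnet = 227L, vgg19 = 224L, resnet101 = 224L,
               `inception-resnet-v2` = 299L, reference = 64L)
  if (!model %in% names(presets)) {
    stop("unknown model preset: ", model, " (known: ",
         paste(names(presets), collapse = ", "), ")")
  }
  c(presets[[model]], presets[[model]], 3L)
}

#' Topological summary of a rendered image
#'
#' Binarizes the image (ink = intensity below `threshold`) and counts
#' foreground connected components with 8-connectivity and holes as
#' background components (4-connectivity) that do not touch the image
#' border.  The complementary 8/4 connectivity pair is the standard
#' convention that makes hole counting well-defined.
#'
#' Binarizing an antialiased edge can strand tiny speckles: an isolated
#' background pixel or a few-pixel sliver trapped where two stroke edges
#' meet at a corner, or dually a stray ink speck.  Components and holes
#' smaller than `min_area` pixels are therefore ignored.  This is safe
#' because every genuine structure is orders of magnitude larger by
#' construction (the smallest hole — a ring at minimum scale and hole ratio
#' — still covers hundreds of pixels at the native 256 px canvas), while
#' binarization artifacts never exceed a few pixels.
#'
#' @param img a `raster_image` matrix (0-255) or 3-channel array.
#' @param threshold binarization intensity threshold (default 128).
#' @param min_area minimum pixel count for a component or hole to be
#'   counted; default 2.5e-4 of the image area (16 px at the native 256 px
#'   canvas), at least 2.
#' @return a list of class `topology_summary` with `n_components` and
#'   `n_holes`.
#' @export
topology <- function(img, threshold = 128, min_area = NULL) {
  m <- if (length(dim(img)) == 3) img[, , 1] else unclass(img)
  if (is.null(min_area)) min_area <- max(2, round(2.5e-4 * length(m)))
  fg <- m < threshold
  lab_fg <- .label_components(fg, 8L)
  lab_bg <- .label_components(!fg, 4L)
  border <- unique(c(lab_bg[1, ], lab_bg[nrow(lab_bg), ],
                     lab_bg[, 1], lab_bg[, ncol(lab_bg)]))
  border <- border[border > 0]
  count_big <- function(lab, drop = integer(0)) {
    sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n"))
    if (length(drop)) sizes <- sizes[-drop]
    sum(sizes >= min_area)
  }
  n_comp <- count_big(lab_fg)
  structure(list(
    n_components = as.integer(n_comp),
    n_holes = if (n_comp == 0) 0L
              else as.integer(count_big(lab_bg, drop = unique(border)))
  ), class = "topology_summary")
}

# flip background pixels whose 4 orthogonal neighbours are all foreground
# (sub-pixel hole speckles) and foreground pixels with no 8-neighbour support
# (ink speckles); both arise only from antialiasing quantization
despeckle_mask <- function(fg) {
  n <- nrow(fg); m <- ncol(fg)
  pad <- function(fill) matrix(fill, n + 2, m + 2)
  p <- pad(FALSE); p[2:(n + 1), 2:(m + 1)] <- fg
  up <- p[1:n, 2:(m + 1)]; down <- p[3:(n + 2), 2:(m + 1)]
  left <- p[2:(n + 1), 1:m]; right <- p[2:(n + 1), 3:(m + 2)]
  fg[!fg & up & down & left & right] <- TRUE
  p[2:(n + 1), 2:(m + 1)] <- fg
  nb8 <- p[1:n, 2:(m + 1)] | p[3:(n + 2), 2:(m + 1)] |
    p[2:(n + 1), 1:m] | p[2:(n + 1), 3:(m + 2)] |
    p[1:n, 1:m] | p[1:n, 3:(m + 2)] | p[3:(n + 2), 1:m] | p[3:(n + 2), 3:(m + 2)]
  fg[fg & !nb8] <- FALSE
  fg
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("topology: %d component(s), %d hole(s)\n",
              x$n_components, x$n_holes))
  invisible(x)
}

#' Test whether a dot is enclosed by a figure
#'
#' Removes the dot from the foreground and flood-fills the background from
#' the image border: the dot is "inside" iff the background region containing
#' the dot centroid is not reachable from the border.
#'
#' @param img a rendered image containing both figure and dot.
#' @param dot_mask logical matrix marking the dot's pixels (e.g. a binarized
#'   render of the dot part alone).
#' @param threshold binarization threshold, as in [topology()].
#' @return `TRUE` if the dot lies in a region enclosed by the figure.
#' @export
containment <- function(img, dot_mask, threshold = 128) {
  m <- if (length(dim(img)) == 3) img[, , 1] else unclass(img)
  fg <- despeckle_mask(m < threshold)
  if (!any(dot_mask)) stop("dot_mask is empty")
  figure <- fg & !dot_mask
  # the dot must be separated from the figure: its mask dilated by one pixel
  # may not touch figure ink
  idx <- which(dot_mask, arr.ind = TRUE)
  cen <- round(colMeans(idx))
  if (figure[cen[1], cen[2]]) {
    stop("dot_mask overlaps the figure outline")
  }
  bg <- !figure
  lab <- .label_components(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  !(lab[cen[1], cen[2]] %in% border)
}

#' Render the dot part of a dot-figure spec as a mask
#'
#' Convenience for [containment()]: rasterizes only the `"dot"` part of a
#' composite dot-figure shape.
#'
#' @param spec a `shape_spec` of a dot category.
#' @inheritParams render
#' @return a logical matrix marking dot pixels.
#' @export
dot_mask <- function(spec, canvas_size = 256, threshold = 128) {
  stopifnot(inherits(spec, "shape_spec"),
            spec$geometry$type == "composite")
  i <- which(spec$geometry$roles == "dot")
  if (length(i) != 1) stop("spec has no unique dot part")
  img <- render(spec$geometry$parts[[i]], canvas_size,
                antialias = spec$antialias, canvas_units = spec$canvas_units)
  unclass(img) < threshold
}
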