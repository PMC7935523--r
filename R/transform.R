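#' Apply a similarity transform to a shape
#'
#' Scales about `center`, rotates about `center` (positive degrees are
#' clockwise in the raster frame, where y points down), then translates.
#' Similarity transforms preserve every category-defining predicate: side
#' equality, parallel pairs, angles, hole ratio, component count and
#' containment.  Stroke widths scale with the shape, as when a drawn image
#' is rescaled; the renderer enforces a minimum effective width so thin
#' strokes stay visible.
#'
#' @param shape a shape object.
#' @param rotation rotation in degrees.
#' @param scale positive scale factor.
#' @param translation numeric length-2 translation in canvas units.
#' @param center centre of rotation/scaling (default: canvas centre of the
#'   default registry).
#' @return the transformed shape.
#' @export
apply_transform <- function(shape, rotation = 0, scale = 1,
                            translation = c(0, 0),
                            center = c(128, 128)) {
  stopifnot(scale > 0, length(translation) == 2)
  th <- rotation * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tp <- function(p) as.numeric(Rm %*% (scale * (p - center))) + center + translation
  rec <- function(s) {
    switch(s$type,
      polygon = {
        s$vertices <- t(apply(s$vertices, 1, tp))
        s$stroke_width <- s$stroke_width * scale
        s
      },
      circle = {
        s$center <- tp(s$center)
        s$radius <- s$radius * scale
        s$stroke_width <- s$stroke_width * scale
        s
      },
      segment = {
        s$p1 <- tp(s$p1); s$p2 <- tp(s$p2)
        s$stroke_width <- s$stroke_width * scale
        s
      },
      annulus = { s$outer <- rec(s$outer); s$inner <- rec(s$inner); s },
      composite = { s$parts <- lapply(s$parts, rec); s }
    )
  }
  rec(shape)
}

#' Generate one fully specified shape instance
#'
#' Builds the category's base geometry (sampling its family parameters),
#' then applies a random similarity transform drawn from the registry
#' ranges: rotation uniform on the registry rotation range, scale uniform on
#' the scale range, and translation uniform over all positions that keep the
#' shape (including stroke) fully inside the canvas with the configured
#' margin.  All randomness is driven by `seed`, so identical
#' `(category, seed, registry)` gives bit-identical geometry.
#'
#' @param category one of the registry's category names.
#' @param seed integer seed for this instance.
#' @param registry a [shape_registry()].
#' @return an object of class `shape_spec`: the transformed geometry plus
#'   the category, seed and transform parameters used.
#' @examples
#' spec <- make_shape("ring", seed = 1)
#' spec$transform$rotation
#' @export
make_shape <- function(category, seed = 1, registry = shape_registry()) {
  cat_def <- registry$categories[[category]]
  if (is.null(cat_def)) {
    stop("unknown category: ", category, " (see category_names())")
  }
  with_seed(seed, {
    geom <- build_base_geometry(cat_def, registry)
    cen <- rep(registry$canvas_units / 2, 2)
    m <- registry$canvas_margin
    # a large shape at a large scale and unlucky rotation can overflow the
    # canvas; re-draw the whole transform until the shape fits
    for (i in seq_len(registry$retry_limit)) {
      rot <- runif(1, registry$transform$rotation[1],
                   registry$transform$rotation[2])
      sc <- runif(1, registry$transform$scale[1], registry$transform$scale[2])
      g2 <- apply_transform(geom, rot, sc, c(0, 0), cen)
      bb <- shape_bbox(g2)
      lo <- m - bb[1, ]
      hi <- registry$canvas_units - m - bb[2, ]
      if (any(hi < lo)) next
      tr <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      return(structure(list(
        category = category,
        seed = seed,
        geometry = translate_shape(g2, tr),
        transform = list(rotation = rot, scale = sc, translation = tr),
        canvas_units = registry$canvas_units,
        antialias = registry$antialias
      ), class = "shape_spec"))
    }
    stop_generation("category %s does not fit the canvas under the transform ranges",
                    category)
  })
}

build_base_geometry <- function(cat_def, registry) {
  switch(cat_def$family,
    quadrilateral = make_quadrilateral(cat_def$kind, registry, cat_def$style),
    annular = {
      if (isTRUE(cat_def$hole)) {
        make_annulus(cat_def$kind,
                     runif(1, registry$hole_ratio[1], registry$hole_ratio[2]),
                     registry)
      } else {
        make_annulus_outer(cat_def$kind, registry)
      }
    },
    irregular = {
      base <- if (isTRUE(cat_def$hole)) {
        make_annulus(cat_def$kind,
                     runif(1, registry$hole_ratio[1], registry$hole_ratio[2]),
                     registry)
      } else {
        make_annulus_outer(cat_def$kind, registry)
      }
      make_irregular(base, registry = registry)
    },
    triangle = {
      tri <- make_triangle(cat_def$kind, "outline", registry)
      if (isTRUE(cat_def$disassembled)) {
        disassemble(tri, registry = registry)
      } else {
        tri
      }
    },
    dot = {
      # smaller figure extent leaves room for outside dot placements
      fig_reg <- registry
      fig_reg$base_extent <- 0.45
      fig <- if (cat_def$figure == "circle") {
        base <- fig_reg$base_extent * registry$canvas_units
        new_circle(rep(registry$canvas_units / 2, 2),
                   base / 2 * runif(1, 0.6, 0.9), "outline",
                   registry$stroke_width)
      } else {
        make_quadrilateral("square", fig_reg, style = "outline")
      }
      place_dot(fig, cat_def$inside, registry = registry)
    },
    stop("unknown family: ", cat_def$family)
  )
}

#' Declared topological invariants of a category
#'
#' The ground truth the raster-level [topology()] and [containment()] checks
#' must reproduce for every generated image: number of connected foreground
#' components, number of holes, and (for dot figures) whether the dot is
#' enclosed.
#'
#' @inheritParams make_shape
#' @return a list with `components`, `holes`, and `enclosed_dot`
#'   (logical or `NA` when not applicable).
#' @export
expected_topology <- function(category, registry = shape_registry()) {
  cat_def <- registry$categories[[category]]
  if (is.null(cat_def)) stop("unknown category: ", category)
  if (cat_def$family == "dot") {
    # outline figure encloses one background region (a hole); the dot is a
    # second component and, when inside, sits within that hole
    return(list(components = 2L, holes = 1L, enclosed_dot = cat_def$inside))
  }
  if (cat_def$family == "triangle") {
    return(if (isTRUE(cat_def$disassembled)) {
      list(components = 3L, holes = 0L, enclosed_dot = NA)
    } else {
      list(components = 1L, holes = 1L, enclosed_dot = NA)
    })
  }
  holes <- if (isTRUE(cat_def$hole)) 1L else 0L
  list(components = 1L, holes = holes, enclosed_dot = NA)
}
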