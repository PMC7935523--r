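# Parametric constructors for every shape family.  Constructors consume the
# R random number stream; seed with set.seed() (or go through make_shape(),
# which derives and sets a per-image seed) for reproducible geometry.

#' Construct a random quadrilateral of a given family
#'
#' Families are mutually exclusive by construction: squares have four equal
#' sides and four right angles; rectangles have four right angles and an
#' aspect ratio sampled away from 1; trapezoids have exactly one pair of
#' parallel opposite sides; parallelograms have two parallel pairs and no
#' right angle.
#'
#' @param family one of `"square"`, `"rectangle"`, `"trapezoid"`,
#'   `"parallelogram"`.
#' @param registry a [shape_registry()] supplying sampling ranges.
#' @param style `"filled"` or `"outline"`.
#' @return a polygon shape centred on the canvas, base orientation
#'   (rotation/scale/translation variation is applied by [make_shape()]).
#' @export
make_quadrilateral <- function(family, registry = shape_registry(),
                               style = "filled") {
  family <- match.arg(family,
                      c("square", "rectangle", "trapezoid", "parallelogram"))
  base <- registry$base_extent * registry$canvas_units
  v <- switch(family,
    square = {
      s <- base * runif(1, 0.8, 1)
      rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
    },
    rectangle = {
      w <- base * runif(1, 0.8, 1)
      h <- w / runif(1, registry$rect_aspect[1], registry$rect_aspect[2])
      rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
    },
    trapezoid = {
      w <- base * runif(1, 0.8, 1)
      wt <- w * runif(1, registry$trapezoid_top_frac[1],
                      registry$trapezoid_top_frac[2])
      h <- w * runif(1, 0.5, 0.8)
      off <- (w - wt) / 2 + w * runif(1, -0.1, 0.1)
      # legs are parallel only if top and bottom widths are equal; the top
      # fraction range keeps them apart, so exactly one parallel pair
      rbind(c(0, h), c(w, h), c(off + wt, 0), c(off, 0))
    },
    parallelogram = {
      w <- base * runif(1, 0.8, 1)
      s <- w * runif(1, 0.5, 0.8)
      ang <- runif(1, registry$parallelogram_angle[1],
                   registry$parallelogram_angle[2]) * pi / 180
      if (runif(1) < 0.5) ang <- pi - ang  # supplementary shear direction
      sh <- c(s * cos(ang), -s * sin(ang))
      rbind(c(0, 0), c(w, 0), c(w, 0) + sh, sh)
    }
  )
  center_on_canvas(new_polygon(v, style, registry$stroke_width), registry)
}

#' Construct a random triangle
#'
#' `"isosceles"` triangles have two equal legs by construction;
#' `"irregular"` (scalene) triangles are rejection-sampled so all three side
#' lengths differ pairwise by a clear margin.  Both kinds are non-degenerate
#' (minimum interior angle at least 15 degrees).
#'
#' @param kind `"isosceles"` or `"irregular"`.
#' @param style `"filled"` or `"outline"`.
#' @inheritParams make_quadrilateral
#' @return a polygon shape centred on the canvas.
#' @export
make_triangle <- function(kind, style = "filled",
                          registry = shape_registry()) {
  kind <- match.arg(kind, c("isosceles", "irregular"))
  base <- registry$base_extent * registry$canvas_units
  margin <- 0.05 * base
  for (i in seq_len(registry$retry_limit)) {
    v <- if (kind == "isosceles") {
      b <- base * runif(1, 0.7, 0.95)
      h <- b * runif(1, 0.7, 1.0)
      rbind(c(0, h), c(b, h), c(b / 2, 0))
    } else {
      base * cbind(runif(3), runif(3))
    }
    ok <- min(interior_angles(v)) >= 15
    if (ok && kind == "irregular") {
      s <- sort(side_lengths(v))
      # distinct sides, and no degenerate small triangle (keeps the size
      # distribution comparable to the isosceles kind)
      ok <- min(diff(s)) > margin && s[1] >= 0.4 * base
    }
    if (ok) {
      return(center_on_canvas(new_polygon(v, style, registry$stroke_width),
                              registry))
    }
  }
  stop_generation("could not sample a valid %s triangle", kind)
}

#' Construct an annular (one-hole) shape
#'
#' The inner boundary is the outer boundary scaled about its centroid by
#' `hole_ratio`, so the hole has the same shape as the figure and there is
#' positive clearance everywhere.  `hole_ratio` values leaving less than a
#' stroke-safe clearance are rejected (after resampling the outer figure up
#' to the registry retry limit).
#'
#' @param kind `"circle"`, `"triangle"`, or `"square"` outer figure.
#' @param hole_ratio linear scale of the hole relative to the outer figure,
#'   in (0, 1).
#' @inheritParams make_quadrilateral
#' @return an annulus shape.
#' @export
make_annulus <- function(kind, hole_ratio, registry = shape_registry()) {
  kind <- match.arg(kind, c("circle", "triangle", "square"))
  if (!is.numeric(hole_ratio) || hole_ratio <= 0 || hole_ratio >= 1) {
    stop("hole_ratio must be in (0, 1)")
  }
  min_clear <- 2  # canvas units; keeps the ring wall safely rasterizable
  for (i in seq_len(registry$retry_limit)) {
    outer <- make_annulus_outer(kind, registry)
    cen <- shape_centroid(outer)
    inr <- inradius(outer, cen)
    if ((1 - hole_ratio) * inr >= min_clear) {
      inner <- scale_about(outer, cen, hole_ratio)
      return(new_annulus(outer, inner))
    }
  }
  stop_generation("hole_ratio %.3f leaves no stroke-safe clearance", hole_ratio)
}

make_annulus_outer <- function(kind, registry) {
  base <- registry$base_extent * registry$canvas_units
  if (kind == "circle") {
    r <- base / 2 * runif(1, 0.8, 1)
    new_circle(rep(registry$canvas_units / 2, 2), r)
  } else if (kind == "square") {
    make_quadrilateral("square", registry)
  } else {
    make_triangle("isosceles", "filled", registry)
  }
}

# distance from a reference interior point to the boundary
inradius <- function(shape, center = shape_centroid(shape)) {
  if (shape$type == "circle") return(shape$radius)
  point_boundary_distance(center, shape)
}

#' Irregularize a shape by a random radial harmonic perturbation
#'
#' The boundary is resampled densely and each boundary point's distance from
#' the centroid is scaled by `1 + amplitude * h(theta)`, where `h` is a sum
#' of `n_harmonics` random low-order harmonics normalized to unit maximum.
#' Because the perturbation is a single-valued radial field, the boundary
#' stays simple and the topology (component and hole count) is unchanged.
#' For an annulus the same field is applied to both boundaries, preserving
#' the hole ratio and clearance.  Circles are polygonized (the registry's
#' `irregular$n_vertices` vertices) before perturbation.
#'
#' @param base a polygon, circle, or annulus shape (star-shaped about its
#'   centroid).
#' @param amplitude perturbation amplitude as a fraction of local radius, in
#'   `[0, 0.3]`.
#' @param n_harmonics number of random harmonics (>= 1).
#' @inheritParams make_quadrilateral
#' @return a shape of the same kind as `base` (circles become polygons).
#' @export
make_irregular <- function(base, amplitude = NULL, n_harmonics = NULL,
                           registry = shape_registry()) {
  if (is.null(amplitude)) amplitude <- registry$irregular$amplitude
  if (is.null(n_harmonics)) n_harmonics <- registry$irregular$n_harmonics
  stopifnot(amplitude >= 0, amplitude <= 0.3, n_harmonics >= 1)
  nv <- registry$irregular$n_vertices

  if (base$type == "annulus") {
    cen <- shape_centroid(base$outer)
    ratio <- inradius(base$inner, cen) / inradius(base$outer, cen)
    outer <- perturb_radial(base$outer, amplitude, n_harmonics, nv)
    return(new_annulus(outer, scale_about(outer, cen, ratio)))
  }
  perturb_radial(base, amplitude, n_harmonics, nv)
}

perturb_radial <- function(shape, amplitude, n_harmonics, nv) {
  stopifnot(shape$type %in% c("polygon", "circle"))
  cen <- shape_centroid(shape)
  pts <- if (shape$type == "circle") {
    th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
    cbind(cen[1] + shape$radius * cos(th), cen[2] + shape$radius * sin(th))
  } else {
    resample_boundary(shape$vertices, nv)
  }
  a <- runif(n_harmonics, -1, 1)
  ph <- runif(n_harmonics, 0, 2 * pi)
  h <- function(theta) {
    out <- 0
    for (k in seq_len(n_harmonics)) out <- out + a[k] * cos(k * theta + ph[k])
    out
  }
  # normalize to unit max so `amplitude` is the true max radial deviation
  norm <- max(abs(h(seq(0, 2 * pi, length.out = 720))), 1e-9)
  theta <- atan2(pts[, 2] - cen[2], pts[, 1] - cen[1])
  fac <- 1 + amplitude * h(theta) / norm
  out <- cbind(cen[1] + fac * (pts[, 1] - cen[1]),
               cen[2] + fac * (pts[, 2] - cen[2]))
  new_polygon(out, if (shape$type == "circle") "filled" else shape$style,
              if (is.null(shape$stroke_width)) 3 else shape$stroke_width)
}

# subdivide polygon edges into ~n boundary points (original vertices kept)
resample_boundary <- function(v, n) {
  nv <- nrow(v)
  j <- c(2:nv, 1)
  lens <- side_lengths(v)
  per <- sum(lens)
  pts <- NULL
  for (i in seq_len(nv)) {
    k <- max(1L, round(n * lens[i] / per))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    pts <- rbind(pts, cbind(v[i, 1] + t * (v[j[i], 1] - v[i, 1]),
                            v[i, 2] + t * (v[j[i], 2] - v[i, 2])))
  }
  pts
}

#' Disassemble an outline triangle into three separated sides
#'
#' Each side becomes a rigidly moved copy of itself: translated outward from
#' the triangle centroid by `displacement` and rotated about its own midpoint
#' by a random angle within the registry's rotation range.  Placements are
#' rejection-sampled until all pairwise part distances reach the minimum gap
#' (twice the stroke width); total ink (sum of segment lengths) equals the
#' source perimeter because the motions are rigid.
#'
#' @param triangle a polygon shape with 3 vertices and `style = "outline"`.
#' @param displacement outward translation in canvas units; defaults to the
#'   registry fraction (0.25) of the triangle circumradius.  Values below
#'   the minimum gap cannot separate parts that share a vertex and raise a
#'   generation error.
#' @inheritParams make_quadrilateral
#' @return a composite shape with three `"segment"` parts.
#' @export
disassemble <- function(triangle, displacement = NULL,
                        registry = shape_registry()) {
  stopifnot(triangle$type == "polygon", nrow(triangle$vertices) == 3)
  if (triangle$style != "outline") {
    stop("disassemble() requires an outline triangle")
  }
  v <- triangle$vertices
  cen <- circumcenter(v)
  R <- sqrt(sum((v[1, ] - cen)^2))
  if (is.null(displacement)) {
    displacement <- registry$disassemble$displacement_frac * R
  }
  gap <- 2 * triangle$stroke_width
  if (displacement < gap) {
    stop_generation(
      "displacement %.2f below minimum gap %.2f: parts touch", displacement, gap)
  }
  rot_max <- registry$disassemble$rotation_range
  g <- polygon_centroid(v)
  j <- c(2, 3, 1)
  for (try in seq_len(registry$retry_limit)) {
    segs <- vector("list", 3)
    for (i in 1:3) {
      a <- v[i, ]; b <- v[j[i], ]
      mid <- (a + b) / 2
      dir <- mid - g
      dir <- dir / sqrt(sum(dir^2))
      newmid <- mid + displacement * dir
      th <- runif(1, -rot_max, rot_max) * pi / 180
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      segs[[i]] <- new_segment(newmid + Rm %*% (a - mid),
                               newmid + Rm %*% (b - mid),
                               triangle$stroke_width)
    }
    d12 <- segment_distance(segs[[1]]$p1, segs[[1]]$p2, segs[[2]]$p1, segs[[2]]$p2)
    d13 <- segment_distance(segs[[1]]$p1, segs[[1]]$p2, segs[[3]]$p1, segs[[3]]$p2)
    d23 <- segment_distance(segs[[2]]$p1, segs[[2]]$p2, segs[[3]]$p1, segs[[3]]$p2)
    if (min(d12, d13, d23) >= gap) {
      return(new_composite(segs, rep("segment", 3)))
    }
  }
  stop_generation("could not separate triangle sides by gap %.2f", gap)
}

circumcenter <- function(v) {
  ax <- v[1, 1]; ay <- v[1, 2]; bx <- v[2, 1]; by <- v[2, 2]
  cx <- v[3, 1]; cy <- v[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy)
}

#' Place a filled dot inside or outside a closed outline figure
#'
#' The dot centre is rejection-sampled until the point-in-figure test matches
#' `inside` and the dot boundary keeps at least the safety margin (twice the
#' stroke width) from the figure outline; outside placements are kept within
#' a bounded neighbourhood of the figure so the composite stays compact.
#'
#' @param figure a circle or polygon shape with `style = "outline"`.
#' @param inside logical: place the dot inside the enclosed region?
#' @param dot_radius dot radius in canvas units; must be smaller than the
#'   enclosed region's inradius.  Default: sampled from the registry range.
#' @inheritParams make_quadrilateral
#' @return a composite shape with parts `"figure"` and `"dot"`.
#' @export
place_dot <- function(figure, inside, dot_radius = NULL,
                      registry = shape_registry()) {
  stopifnot(figure$type %in% c("circle", "polygon"))
  if (figure$style != "outline") stop("place_dot() requires an outline figure")
  if (is.null(dot_radius)) {
    dot_radius <- runif(1, registry$dot_radius[1], registry$dot_radius[2])
  }
  cen <- shape_centroid(figure)
  inr <- inradius(figure, cen)
  if (dot_radius >= inr) stop("dot_radius must be below the figure inradius")
  margin <- 2 * figure$stroke_width
  bb <- shape_bbox(figure)
  span <- bb[2, ] - bb[1, ]
  lo <- if (inside) bb[1, ] else bb[1, ] - 0.3 * span
  hi <- if (inside) bb[2, ] else bb[2, ] + 0.3 * span
  in_figure <- function(p) {
    if (figure$type == "circle") {
      sqrt(sum((p - figure$center)^2)) < figure$radius
    } else {
      point_in_polygon(p, figure$vertices)
    }
  }
  for (i in seq_len(registry$retry_limit)) {
    p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    if (in_figure(p) != inside) next
    clear <- point_boundary_distance(p, figure) -
      figure$stroke_width / 2 - dot_radius
    if (clear >= margin) {
      return(new_composite(list(figure, new_circle(p, dot_radius)),
                           c("figure", "dot")))
    }
  }
  stop_generation("no valid dot placement (inside=%s, radius=%.1f)",
                  inside, dot_radius)
}

center_on_canvas <- function(shape, registry) {
  cen <- shape_centroid(shape)
  target <- rep(registry$canvas_units / 2, 2)
  translate_shape(shape, target - cen)
}

translate_shape <- function(shape, delta) {
  switch(shape$type,
    polygon = { shape$vertices <- sweep(shape$vertices, 2, delta, "+"); shape },
    circle = { shape$center <- shape$center + delta; shape },
    segment = { shape$p1 <- shape$p1 + delta; shape$p2 <- shape$p2 + delta; shape },
    annulus = {
      shape$outer <- translate_shape(shape$outer, delta)
      shape$inner <- translate_shape(shape$inner, delta)
      shape
    },
    composite = {
      shape$parts <- lapply(shape$parts, translate_shape, delta = delta)
      shape
    }
  )
}
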