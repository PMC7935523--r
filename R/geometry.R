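# Vector-space shape primitives.  All coordinates are continuous canvas
# units, origin top-left, x rightward, y downward (matching the raster
# frame); rotation is positive clockwise in that frame.

new_polygon <- function(vertices, style = "filled", stroke_width = 3) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3, all(is.finite(vertices)))
  style <- match.arg(style, c("filled", "outline"))
  structure(list(type = "polygon", vertices = vertices, style = style,
                 stroke_width = stroke_width),
            class = "shape")
}

new_circle <- function(center, radius, style = "filled", stroke_width = 3) {
  stopifnot(length(center) == 2, radius > 0)
  style <- match.arg(style, c("filled", "outline"))
  structure(list(type = "circle", center = as.numeric(center), radius = radius,
                 style = style, stroke_width = stroke_width),
            class = "shape")
}

new_segment <- function(p1, p2, stroke_width = 3) {
  structure(list(type = "segment", p1 = as.numeric(p1), p2 = as.numeric(p2),
                 stroke_width = stroke_width),
            class = "shape")
}

# inner must be strictly contained in outer; both rendered filled, the inner
# region subtracted (one topological hole)
new_annulus <- function(outer, inner) {
  stopifnot(inherits(outer, "shape"), inherits(inner, "shape"))
  structure(list(type = "annulus", outer = outer, inner = inner),
            class = "shape")
}

new_composite <- function(parts, roles) {
  stopifnot(length(parts) == length(roles),
            all(vapply(parts, inherits, TRUE, "shape")))
  structure(list(type = "composite", parts = parts, roles = roles),
            class = "shape")
}

polygon_area <- function(v) {
  # shoelace; positive magnitude
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

polygon_centroid <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

side_lengths <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sqrt(rowSums((v[j, ] - v)^2))
}

# interior angles in degrees at each vertex
interior_angles <- function(v) {
  n <- nrow(v)
  prev <- c(n, 1:(n - 1))
  nxt <- c(2:n, 1)
  a <- v[prev, , drop = FALSE] - v
  b <- v[nxt, , drop = FALSE] - v
  cosang <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# angle in degrees between two direction vectors, folded to [0, 90]
line_angle <- function(u, w) {
  cosang <- abs(sum(u * w)) / (sqrt(sum(u^2)) * sqrt(sum(w^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# number of parallel opposite-side pairs of a quadrilateral, within tol deg
parallel_pairs <- function(v, tol = 0.5) {
  stopifnot(nrow(v) == 4)
  e <- v[c(2:4, 1), ] - v
  sum(line_angle(e[1, ], e[3, ]) <= tol, line_angle(e[2, ], e[4, ]) <= tol)
}

point_in_polygon <- function(p, v) {
  n <- nrow(v)
  j <- c(n, 1:(n - 1))
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- v[i, 2]; yj <- v[j[i], 2]
    if ((yi > p[2]) != (yj > p[2])) {
      xcross <- (v[j[i], 1] - v[i, 1]) * (p[2] - yi) / (yj - yi) + v[i, 1]
      if (p[1] < xcross) inside <- !inside
    }
  }
  inside
}

point_segment_distance <- function(p, a, b) {
  d <- b - a
  L2 <- sum(d^2)
  t <- if (L2 > 0) max(0, min(1, sum((p - a) * d) / L2)) else 0
  sqrt(sum((a + t * d - p)^2))
}

point_boundary_distance <- function(p, shape) {
  if (shape$type == "circle") {
    return(abs(sqrt(sum((p - shape$center)^2)) - shape$radius))
  }
  v <- shape$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  min(vapply(seq_len(n), function(i)
    point_segment_distance(p, v[i, ], v[j[i], ]), 0))
}

segment_distance <- function(a1, a2, b1, b2) {
  # minimum distance between two segments; 0 if they intersect
  d1 <- cross2(a2 - a1, b1 - a1)
  d2 <- cross2(a2 - a1, b2 - a1)
  d3 <- cross2(b2 - b1, a1 - b1)
  d4 <- cross2(b2 - b1, a2 - b1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(point_segment_distance(b1, a1, a2), point_segment_distance(b2, a1, a2),
      point_segment_distance(a1, b1, b2), point_segment_distance(a2, b1, b2))
}

cross2 <- function(u, w) u[1] * w[2] - u[2] * w[1]

# axis-aligned bounding box of a shape, inflated by stroke half-widths
shape_bbox <- function(shape) {
  switch(shape$type,
    polygon = {
      pad <- if (shape$style == "outline") shape$stroke_width / 2 else 0
      rbind(apply(shape$vertices, 2, min) - pad,
            apply(shape$vertices, 2, max) + pad)
    },
    circle = {
      pad <- shape$radius +
        if (shape$style == "outline") shape$stroke_width / 2 else 0
      rbind(shape$center - pad, shape$center + pad)
    },
    segment = {
      pad <- shape$stroke_width / 2
      v <- rbind(shape$p1, shape$p2)
      rbind(apply(v, 2, min) - pad, apply(v, 2, max) + pad)
    },
    annulus = shape_bbox(shape$outer),
    composite = {
      bs <- lapply(shape$parts, shape_bbox)
      rbind(apply(do.call(rbind, lapply(bs, function(b) b[1, ])), 2, min),
            apply(do.call(rbind, lapply(bs, function(b) b[2, ])), 2, max))
    },
    stop("unknown shape type: ", shape$type)
  )
}

shape_centroid <- function(shape) {
  switch(shape$type,
    polygon = polygon_centroid(shape$vertices),
    circle = shape$center,
    segment = (shape$p1 + shape$p2) / 2,
    annulus = shape_centroid(shape$outer),
    composite = colMeans(do.call(rbind, lapply(shape$parts, shape_centroid)))
  )
}

# scale a shape about a fixed point (used for annulus holes)
scale_about <- function(shape, center, factor) {
  sc <- function(p) center + factor * (p - center)
  switch(shape$type,
    polygon = {
      s <- shape
      s$vertices <- t(apply(shape$vertices, 1, sc))
      s
    },
    circle = {
      s <- shape
      s$center <- sc(shape$center)
      s$radius <- shape$radius * factor
      s
    },
    stop("cannot scale shape of type ", shape$type)
  )
}
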