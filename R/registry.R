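#' The shape category registry
#'
#' Central configuration for shape synthesis: the 24 category names with
#' their geometric family and rendering style, all sampling ranges (side
#' lengths, aspect ratios, angles, hole ratios, irregularity), the transform
#' ranges used to vary images within a category, rasterization defaults, and
#' numerical tolerances.  Every generator in the package draws its parameters
#' from a registry so a whole dataset is reproducible from one object.
#'
#' Lengths and widths are in canvas units (one unit = one pixel at the
#' native canvas size); angles are degrees.  Rotation is positive clockwise
#' in the raster frame (origin top-left, y downward).
#'
#' @param ... named overrides of top-level registry fields, e.g.
#'   `shape_registry(canvas_units = 128, stroke_width = 2)`.
#' @return a list of class `shape_registry`.
#' @examples
#' reg <- shape_registry()
#' length(reg$categories)   # 24
#' @export
shape_registry <- function(...) {
  reg <- list(
    canvas_units = 256,
    canvas_margin = 4,
    stroke_width = 3,
    dot_radius = c(6, 12),
    antialias = TRUE,
    threshold = 128,
    n_per_category = 540,
    train_frac = 0.85,
    epochs = 20,
    # base characteristic size of a category, as a fraction of the canvas,
    # before the per-image scale transform
    base_extent = 0.62,
    hole_ratio = c(0.3, 0.6),
    rect_aspect = c(1.3, 2.5),
    trapezoid_top_frac = c(0.4, 0.72),
    parallelogram_angle = c(50, 80),
    irregular = list(amplitude = 0.15, n_harmonics = 5, n_vertices = 120),
    disassemble = list(displacement_frac = 0.25, rotation_range = 30),
    transform = list(rotation = c(0, 360), scale = c(0.5, 1)),
    tol_angle = 0.5,        # degrees
    tol_length_frac = 0.005, # fraction of canvas size
    retry_limit = 1000,
    categories = NULL
  )
  reg$categories <- category_table()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(reg))
    if (length(bad)) stop("unknown registry fields: ", paste(bad, collapse = ", "))
    reg[names(dots)] <- dots
  }
  structure(reg, class = "shape_registry")
}

# The 24 category names with family/style.  The quadrilaterals double as
# both local-feature categories (filled) and, under the "*-solid"/"*-ring"
# names, as the no-hole/one-hole categories of the topology experiments.
category_table <- function() {
  def <- function(name, family, style = "filled", ...) {
    c(list(name = name, family = family, style = style), list(...))
  }
  cats <- list(
    def("square", "quadrilateral", kind = "square"),
    def("rectangle", "quadrilateral", kind = "rectangle"),
    def("trapezoid", "quadrilateral", kind = "trapezoid"),
    def("parallelogram", "quadrilateral", kind = "parallelogram"),
    def("disk", "annular", kind = "circle", hole = FALSE),
    def("ring", "annular", kind = "circle", hole = TRUE),
    def("triangle-solid", "annular", kind = "triangle", hole = FALSE),
    def("triangle-ring", "annular", kind = "triangle", hole = TRUE),
    def("square-solid", "annular", kind = "square", hole = FALSE),
    def("square-ring", "annular", kind = "square", hole = TRUE),
    def("irregular-disk", "irregular", kind = "circle", hole = FALSE),
    def("irregular-ring", "irregular", kind = "circle", hole = TRUE),
    def("irregular-triangle-solid", "irregular", kind = "triangle", hole = FALSE),
    def("irregular-triangle-ring", "irregular", kind = "triangle", hole = TRUE),
    def("irregular-square", "irregular", kind = "square", hole = FALSE),
    def("irregular-square-ring", "irregular", kind = "square", hole = TRUE),
    def("isosceles-triangle-outline", "triangle", style = "outline",
        kind = "isosceles", disassembled = FALSE),
    def("disassembled-isosceles-triangle", "triangle", style = "outline",
        kind = "isosceles", disassembled = TRUE),
    def("irregular-triangle-outline", "triangle", style = "outline",
        kind = "irregular", disassembled = FALSE),
    def("disassembled-irregular-triangle", "triangle", style = "outline",
        kind = "irregular", disassembled = TRUE),
    def("dot-inside-circle", "dot", figure = "circle", inside = TRUE),
    def("dot-outside-circle", "dot", figure = "circle", inside = FALSE),
    def("dot-inside-square", "dot", figure = "square", inside = TRUE),
    def("dot-outside-square", "dot", figure = "square", inside = FALSE)
  )
  names(cats) <- vapply(cats, `[[`, "", "name")
  cats
}

#' @rdname shape_registry
#' @param registry a `shape_registry`.
#' @export
category_names <- function(registry = shape_registry()) {
  names(registry$categories)
}

#' Read / write a shape registry as YAML
#'
#' Round-trips the full registry (category table and all sampling ranges) so
#' a dataset's configuration can be archived next to the images.
#'
#' @param registry a `shape_registry`.
#' @param path file path.
#' @return `read_registry` returns a `shape_registry`;
#'   `write_registry` returns `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "shape_registry"))
  yaml::write_yaml(unclass(registry), path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- shape_registry()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    # yaml flattens numeric pairs to lists of scalars; restore vectors
    if (is.list(v) && length(v) && all(vapply(v, is.numeric, TRUE)) &&
        is.null(names(v))) v <- unlist(v)
    reg[[nm]] <- v
  }
  reg
}

registry_tolerances <- function(registry) {
  list(
    angle = registry$tol_angle,
    length = registry$tol_length_frac * registry$canvas_units
  )
}
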