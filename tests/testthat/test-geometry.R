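reg <- shape_registry()
tol <- 0.5   # degrees, matching the registry angular tolerance

test_that("quadrilateral families satisfy their defining invariants", {
  for (s in 1:25) {
    set.seed(s)
    sq <- make_quadrilateral("square", reg)
    v <- sq$vertices
    expect_equal(max(oracle_side_lengths(v)) - min(oracle_side_lengths(v)), 0,
                 tolerance = 1e-9)
    expect_true(all(abs(oracle_angles(v) - 90) < tol))

    set.seed(s)
    rc <- make_quadrilateral("rectangle", reg)$vertices
    expect_true(all(abs(oracle_angles(rc) - 90) < tol))
    sides <- oracle_side_lengths(rc)
    aspect <- max(sides) / min(sides)
    expect_gte(aspect, 1.3)
    expect_lte(aspect, 2.5)

    set.seed(s)
    tz <- make_quadrilateral("trapezoid", reg)$vertices
    p13 <- oracle_parallel(tz, 1, 3, tol)
    p24 <- oracle_parallel(tz, 2, 4, tol)
    expect_true(xor(p13, p24))  # exactly one parallel pair

    set.seed(s)
    pg <- make_quadrilateral("parallelogram", reg)$vertices
    expect_true(oracle_parallel(pg, 1, 3, tol) && oracle_parallel(pg, 2, 4, tol))
    expect_true(all(abs(oracle_angles(pg) - 90) > 9))  # never near-rectangle
  }
  expect_error(make_quadrilateral("pentagon", reg))
})

test_that("triangles are isosceles or scalene as requested, never degenerate", {
  for (s in 1:25) {
    set.seed(s)
    iso <- make_triangle("isosceles", "outline", reg)$vertices
    len <- sort(oracle_side_lengths(iso))
    expect_true(min(abs(c(len[2] - len[1], len[3] - len[2]))) <
                  reg$tol_length_frac * reg$canvas_units)
    expect_equal(sum(oracle_angles(iso)), 180, tolerance = 1e-6)

    set.seed(s + 100)
    irr <- make_triangle("irregular", "filled", reg)$vertices
    len <- sort(oracle_side_lengths(irr))
    expect_gt(min(diff(len)), 0.05 * reg$base_extent * reg$canvas_units)
    expect_gte(min(oracle_angles(irr)), 15)
    expect_equal(sum(oracle_angles(irr)), 180, tolerance = 1e-6)
  }
})

test_that("annuli scale the hole about the centroid by hole_ratio", {
  set.seed(0)
  ring <- make_annulus("circle", 0.5, reg)
  expect_equal(ring$inner$radius, 0.5 * ring$outer$radius)
  expect_equal(ring$inner$center, ring$outer$center)

  set.seed(5)
  sqr <- make_annulus("square", 0.4, reg)
  so <- oracle_side_lengths(sqr$outer$vertices)
  si <- oracle_side_lengths(sqr$inner$vertices)
  expect_equal(si, 0.4 * so, tolerance = 1e-9)
  co <- colMeans(sqr$outer$vertices)
  ci <- colMeans(sqr$inner$vertices)
  expect_equal(ci, co, tolerance = 1e-9)

  expect_error(make_annulus("circle", 1.2, reg))
  expect_error(make_annulus("circle", 0, reg))
  # near-unity hole ratio leaves no stroke-safe clearance anywhere
  set.seed(1)
  expect_error(make_annulus("triangle", 0.995, reg),
               class = "shapenet_generation_error")
})

test_that("radial irregularization preserves boundary at amplitude 0 and topology otherwise", {
  set.seed(3)
  base <- make_quadrilateral("square", reg)
  out0 <- make_irregular(base, amplitude = 0, n_harmonics = 5, registry = reg)
  # every resampled vertex must lie on the original boundary
  v <- base$vertices
  d <- apply(out0$vertices, 1, function(p) {
    min(vapply(1:4, function(i) {
      oracle_pt_seg(p, v[i, ], v[if (i == 4) 1 else i + 1, ])
    }, 0))
  })
  expect_lt(max(d), 1e-9)

  set.seed(9)
  ring <- make_annulus("circle", 0.45, reg)
  irr <- make_irregular(ring, amplitude = 0.15, n_harmonics = 5, registry = reg)
  tp <- topology(render(irr, canvas_units = reg$canvas_units))
  expect_identical(tp$n_components, 1L)
  expect_identical(tp$n_holes, 1L)

  set.seed(10)
  disk <- new_circle(c(128, 128), 60)
  pd <- make_irregular(disk, amplitude = 0.2, n_harmonics = 4, registry = reg)
  tp <- topology(render(pd, canvas_units = reg$canvas_units))
  expect_identical(tp$n_components, 1L)
  expect_identical(tp$n_holes, 0L)

  expect_error(make_irregular(base, amplitude = 0.5, registry = reg))
})

test_that("disassembly yields three separated rigid copies of the sides", {
  set.seed(4)
  tri <- make_triangle("isosceles", "outline", reg)
  set.seed(4)
  parts <- disassemble(tri, registry = reg)
  expect_identical(length(parts$parts), 3L)
  expect_identical(parts$roles, rep("segment", 3))
  # rigid motions preserve total ink length
  seg_len <- vapply(parts$parts, function(s) sqrt(sum((s$p2 - s$p1)^2)), 0)
  expect_equal(sum(seg_len), sum(oracle_side_lengths(tri$vertices)),
               tolerance = 1e-9)
  # pairwise separation of at least twice the stroke width
  gap <- 2 * tri$stroke_width
  for (i in 1:2) for (j in (i + 1):3) {
    a <- parts$parts[[i]]; b <- parts$parts[[j]]
    d <- min(oracle_pt_seg(a$p1, b$p1, b$p2), oracle_pt_seg(a$p2, b$p1, b$p2),
             oracle_pt_seg(b$p1, a$p1, a$p2), oracle_pt_seg(b$p2, a$p1, a$p2))
    expect_gte(d, gap)
  }
  tp <- topology(render(parts, canvas_units = reg$canvas_units))
  expect_identical(tp$n_components, 3L)
  # zero displacement cannot separate parts sharing a vertex
  expect_error(disassemble(tri, displacement = 0, registry = reg),
               class = "shapenet_generation_error")
  expect_error(disassemble(make_triangle("isosceles", "filled", reg)))
})

test_that("dot placement matches the requested containment side", {
  set.seed(6)
  fig <- make_quadrilateral("square", reg, style = "outline")
  for (inside in c(TRUE, FALSE)) {
    set.seed(7)
    comp <- place_dot(fig, inside, dot_radius = 8, registry = reg)
    dot <- comp$parts[[which(comp$roles == "dot")]]
    # independent even-odd point-in-polygon at the dot centre
    v <- fig$vertices
    crossings <- 0
    for (i in 1:4) {
      a <- v[i, ]; b <- v[if (i == 4) 1 else i + 1, ]
      if ((a[2] > dot$center[2]) != (b[2] > dot$center[2])) {
        xc <- a[1] + (dot$center[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
        if (dot$center[1] < xc) crossings <- crossings + 1
      }
    }
    expect_identical(crossings %% 2 == 1, inside)
  }
  expect_error(place_dot(fig, TRUE, dot_radius = 1e4, registry = reg))
  expect_error(place_dot(make_quadrilateral("square", reg), TRUE))
})

test_that("similarity transforms preserve category-defining predicates", {
  set.seed(12)
  sq <- make_quadrilateral("square", reg)
  r90 <- apply_transform(sq, rotation = 90, center = c(128, 128))
  expect_true(all(abs(oracle_angles(r90$vertices) - 90) < tol))
  sides <- oracle_side_lengths(r90$vertices)
  expect_lt(max(sides) - min(sides), 1e-9)

  ident <- apply_transform(sq)
  expect_equal(ident$vertices, sq$vertices, tolerance = 1e-12)

  set.seed(13)
  ring <- make_annulus("circle", 0.37, reg)
  half <- apply_transform(ring, scale = 0.5, center = c(128, 128))
  expect_equal(half$inner$radius / half$outer$radius, 0.37, tolerance = 1e-12)

  # full random transforms keep parallelism patterns, across seeds
  for (s in 1:40) {
    fam <- c("square", "rectangle", "trapezoid", "parallelogram")[s %% 4 + 1]
    spec <- make_shape(fam, seed = s)
    v <- spec$geometry$vertices
    np <- oracle_parallel(v, 1, 3, tol) + oracle_parallel(v, 2, 4, tol)
    expect_identical(np, if (fam == "trapezoid") 1L else 2L)
    if (fam %in% c("square", "rectangle")) {
      expect_true(all(abs(oracle_angles(v) - 90) < tol))
    }
  }
})

test_that("generation is deterministic in (category, seed, registry)", {
  for (cat in c("trapezoid", "irregular-ring", "disassembled-irregular-triangle",
                "dot-outside-square")) {
    s1 <- make_shape(cat, seed = 77)
    s2 <- make_shape(cat, seed = 77)
    expect_identical(s1, s2)
    s3 <- make_shape(cat, seed = 78)
    expect_false(identical(s1$geometry, s3$geometry))
  }
})

test_that("the registry round-trips through YAML", {
  reg2 <- shape_registry(canvas_units = 128, stroke_width = 2)
  path <- tempfile(fileext = ".yaml")
  write_registry(reg2, path)
  back <- read_registry(path)
  expect_identical(back$canvas_units, 128)
  expect_identical(back$stroke_width, 2)
  expect_identical(category_names(back), category_names(reg2))
  expect_equal(back$hole_ratio, reg2$hole_ratio)
  expect_error(shape_registry(not_a_field = 1))
})
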