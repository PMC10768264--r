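test_that("longest diameter is the exhaustive farthest vertex pair", {
  sq <- planar_contour(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_equal(longest_diameter(sq)$length, 2 * sqrt(2))

  shp <- make_biellipse_polygon(biellipse_params(6, 4, 3), n_vertices = 500)
  ld <- longest_diameter(shp$contour)
  expect_equal(ld$length, 10, tolerance = 1e-3)
  expect_equal(sort(c(ld$p1[1], ld$p2[1])), c(-6, 4), tolerance = 1e-3)

  set.seed(11)
  for (i in 1:20) {
    p <- random_biellipse_params()
    v <- as.matrix(make_biellipse_polygon(p, n_vertices = 128)$contour)
    expect_identical(longest_diameter(planar_contour(v))$length,
                     brute_force_diameter(v))
  }
})

test_that("chord measurements are invariant under rigid motions", {
  set.seed(21)
  shp <- make_biellipse_polygon(biellipse_params(6, 4, 3), n_vertices = 400)
  moved <- rotate_contour(shp$contour, 37, shift = c(12.3, -4.56))
  ld1 <- longest_diameter(shp$contour)
  ld2 <- longest_diameter(moved)
  expect_equal(ld1$length, ld2$length, tolerance = 1e-9)
  pd1 <- perpendicular_diameter(shp$contour, ld1)
  pd2 <- perpendicular_diameter(moved, ld2)
  expect_equal(pd1$length, pd2$length, tolerance = 1e-9)
  expect_equal(polygon_area(moved), polygon_area(shp$contour),
               tolerance = 1e-9)
  # vertex-order reversal leaves the vertex set, hence LD and area, intact
  rev_v <- planar_contour(as.matrix(shp$contour)[400:1, ])
  expect_equal(longest_diameter(rev_v)$length, ld1$length, tolerance = 1e-12)
  expect_equal(polygon_area(rev_v), polygon_area(shp$contour))
})

test_that("uniform scaling scales lengths linearly and areas quadratically", {
  shp <- make_biellipse_polygon(biellipse_params(6, 4, 3), n_vertices = 400)
  f1 <- shape_features(shp$contour)
  f2 <- shape_features(planar_contour(as.matrix(shp$contour) * 2.5))
  expect_equal(f2$LD_mm, 2.5 * f1$LD_mm, tolerance = 1e-9)
  expect_equal(f2$PD_mm, 2.5 * f1$PD_mm, tolerance = 1e-9)
  expect_equal(f2$MA_mm2, 2.5^2 * f1$MA_mm2, tolerance = 1e-9)
  expect_equal(f2$LD_PD, f1$LD_PD, tolerance = 1e-9)
  expect_equal(f2$BiA_SmA, f1$BiA_SmA, tolerance = 1e-9)
})

test_that("perpendicular diameter matches geometry and the fine-sweep oracle", {
  # bi-ellipse: the shared minor axis is the maximal perpendicular chord
  shp <- make_biellipse_polygon(biellipse_params(6, 4, 3), n_vertices = 720)
  ld <- longest_diameter(shp$contour)
  pd <- perpendicular_diameter(shp$contour, ld)
  expect_equal(pd$length, 6, tolerance = 1e-3)
  expect_equal(abs(pd$p1[2] - pd$p2[2]), 6, tolerance = 1e-3)

  # circle: every diameter is an LD and PD equals it
  circ <- make_biellipse_polygon(biellipse_params(5, 5, 5), n_vertices = 720)
  ldc <- longest_diameter(circ$contour)
  pdc <- perpendicular_diameter(circ$contour, ldc)
  expect_equal(pdc$length, ldc$length, tolerance = 2e-3)

  # rectangle with a diagonal LD, against a 10x finer sweep
  rect <- planar_contour(rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2)))
  rr <- resample_contour(rect, n = 400)
  ldr <- longest_diameter(rr)
  expect_equal(ldr$length, sqrt(20))
  pd_def <- perpendicular_diameter(rr, ldr, n_steps = 500L)
  pd_fine <- perpendicular_diameter(rr, ldr, n_steps = 5000L)
  expect_lt(abs(pd_def$length / pd_fine$length - 1), 0.01)

  set.seed(31)
  for (i in 1:10) {
    p <- random_biellipse_params()
    ct <- make_biellipse_polygon(p, n_vertices = 256)$contour
    ld_i <- longest_diameter(ct)
    d_def <- perpendicular_diameter(ct, ld_i, n_steps = 500L)$length
    d_fine <- perpendicular_diameter(ct, ld_i, n_steps = 5000L)$length
    expect_lt(abs(d_def / d_fine - 1), 0.01)
  }
})

test_that("quadrilateral angles follow the two-ray construction", {
  # rhombus: symmetric, both angles 90
  ld <- mk_chord(c(-1, 0), c(1, 0))
  pd <- mk_chord(c(0, 1), c(0, -1))
  q <- quadrilateral_angles(ld, pd)
  expect_equal(q$angle_A, 90)
  expect_equal(q$angle_B, 90)
  expect_equal(bia_sma_ratio(q$BiA, q$SmA), 1)

  # kite: closed form atan(CO/AO) + atan(OD/AO) at each vertex
  ldk <- mk_chord(c(-1, 0), c(2, 0))
  q2 <- quadrilateral_angles(ldk, pd)
  expect_equal(q2$angle_A, 90, tolerance = 1e-9)
  expect_equal(q2$angle_B, 2 * atan(1 / 2) * 180 / pi, tolerance = 1e-9)
  expect_equal(bia_sma_ratio(q2$BiA, q2$SmA), 1.6938, tolerance = 1e-4)

  # bi-ellipse closed form; the endpoint nearer O carries the larger angle
  ldb <- mk_chord(c(-6, 0), c(4, 0))
  pdb <- mk_chord(c(0, 3), c(0, -3))
  q3 <- quadrilateral_angles(ldb, pdb)
  expect_equal(q3$BiA, 2 * atan(3 / 4) * 180 / pi, tolerance = 1e-9)
  expect_equal(q3$SmA, 2 * atan(3 / 6) * 180 / pi, tolerance = 1e-9)
  expect_equal(q3$BiA / q3$SmA, 1.3879, tolerance = 1e-4)

  # invariant to which endpoint is labelled A/B or C/D
  q4 <- quadrilateral_angles(mk_chord(c(4, 0), c(-6, 0)),
                             mk_chord(c(0, -3), c(0, 3)))
  expect_equal(q4$BiA, q3$BiA)
  expect_equal(q4$SmA, q3$SmA)

  # non-crossing chords are an error
  expect_error(
    quadrilateral_angles(mk_chord(c(-1, 0), c(1, 0)),
                         mk_chord(c(2, 1), c(2, -1))),
    "do not intersect")
})

test_that("the angle-ratio helper validates its arguments", {
  expect_equal(round(bia_sma_ratio(77.03, 60.55), 4), 1.2722)
  expect_equal(bia_sma_ratio(90, 90), 1)
  expect_equal(bia_sma_ratio(90, 53.1301), 1.6938, tolerance = 1e-4)
  expect_error(bia_sma_ratio(90, 0), "positive")
  expect_error(bia_sma_ratio(50, 60), ">= SmA")
})
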