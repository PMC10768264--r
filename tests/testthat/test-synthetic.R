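test_that("bi-ellipse ground truth matches its closed forms", {
  tr <- biellipse_truth(biellipse_params(6, 4, 3))
  expect_equal(tr$LD_mm, 10)
  expect_equal(tr$PD_mm, 6)
  expect_equal(tr$SmA_deg, 2 * atan(3 / 6) * 180 / pi)
  expect_equal(tr$BiA_deg, 2 * atan(3 / 4) * 180 / pi)
  expect_equal(tr$BiA_SmA, 1.3879, tolerance = 1e-4)
  expect_equal(tr$MA_mm2, pi * 3 * 10 / 2)

  circ <- biellipse_truth(biellipse_params(5, 5, 5))
  expect_equal(circ$LD_mm, 10)
  expect_equal(circ$PD_mm, 10)
  expect_equal(circ$BiA_SmA, 1)
})

test_that("parameter invariants are enforced", {
  expect_error(biellipse_params(4, 6, 3), "a1 >= a2")
  expect_error(biellipse_params(6, 4, 5), "a2 >= c")
  expect_error(biellipse_params(6, 4, -1), "c > 0")
  expect_error(biellipse_params(6, 4, 3, noise_sd = -1), "noise_sd")
  expect_error(make_biellipse_polygon(biellipse_params(6, 4, 3),
                                      n_vertices = 32), ">= 64")
})

test_that("generated polygons match truth and respond to noise and motion", {
  shp <- make_biellipse_polygon(biellipse_params(6, 4, 3), n_vertices = 1000)
  f <- shape_features(shp$contour)
  expect_equal(f$LD_mm, shp$truth$LD_mm, tolerance = 0.01)
  expect_equal(f$PD_mm, shp$truth$PD_mm, tolerance = 0.01)
  expect_lt(abs(f$BiA_deg - shp$truth$BiA_deg), 1)
  expect_lt(abs(f$SmA_deg - shp$truth$SmA_deg), 1)

  # any rotation/translation: same truth, measured within the same tolerance
  shp2 <- make_biellipse_polygon(
    biellipse_params(6, 4, 3, rotation = 73, translation = c(11, -4)),
    n_vertices = 1000)
  f2 <- shape_features(shp2$contour)
  expect_equal(f2$LD_mm, 10, tolerance = 0.01)
  expect_lt(abs(f2$BiA_deg - shp$truth$BiA_deg), 1)

  # radial jitter perturbs the boundary but is seeded and bounded
  set.seed(99)
  shp3 <- make_biellipse_polygon(biellipse_params(6, 4, 3, noise_sd = 0.05),
                                 n_vertices = 500)
  expect_equal(polygon_area(shp3$contour), shp$truth$MA_mm2, tolerance = 0.02)
})

test_that("extruded volumes peak at the central axial slice", {
  vol <- make_biellipse_volume(biellipse_params(6, 4, 3), spacing = 0.25)
  ct <- extract_max_cross_section(vol)
  expect_equal(attr(ct, "plane"), "axial")
  expect_equal(attr(ct, "slice_index"), (dim(vol$voxels)[3] + 1L) %/% 2L)
  expect_warning(make_biellipse_volume(biellipse_params(4, 3, 1),
                                       spacing = 0.3), "coarse")
})

test_that("target inversion solves the bi-ellipse exactly", {
  p <- params_from_targets(10, 10 / 6, atan(3 / 4) / atan(3 / 6))
  expect_equal(c(p$a1, p$a2, p$c), c(6, 4, 3), tolerance = 1e-8)

  # boundary of feasibility: a circle request
  pc <- params_from_targets(10, 1, 1)
  expect_equal(c(pc$a1, pc$a2, pc$c), c(5, 5, 5))

  expect_error(params_from_targets(10, 10 / 6, 2.5), "infeasible")
  expect_error(params_from_targets(10, 1, 1.2), "infeasible")

  # forward-inverse round trip on random feasible targets
  set.seed(5)
  for (i in 1:200) {
    ld <- runif(1, 5, 28)
    ld_pd <- runif(1, 1.01, 2.2)
    cc <- ld / (2 * ld_pd)
    bmax <- atan(1) / atan(cc / (ld - cc))
    bs <- runif(1, 1, bmax)
    p_i <- params_from_targets(ld, ld_pd, bs)
    tr <- biellipse_truth(p_i)
    expect_equal(tr$LD_mm, ld, tolerance = 1e-6)
    expect_equal(tr$LD_PD, ld_pd, tolerance = 1e-6)
    expect_equal(tr$BiA_SmA, bs, tolerance = 1e-6)
  }
})

test_that("angle asymmetry grows with axis asymmetry at fixed thickness", {
  ratios <- vapply(seq(0, 1.8, by = 0.3), function(d) {
    biellipse_truth(biellipse_params(5 + d, 5 - d, 3))$BiA_SmA
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("cohort sampling is reproducible and respects its spec", {
  spec <- cohort_spec(seed = 7)
  c1 <- sample_cohort(spec, shapes = "none")
  c2 <- sample_cohort(spec, shapes = "none")
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 98)
  expect_equal(as.vector(table(c1$group)), c(39, 59))
  expect_true(all(c1$LD_mm >= 3 & c1$LD_mm <= 30))
  expect_true(all(c1$LD_PD >= 1.001 & c1$BiA_SmA >= 1.001))

  small <- sample_cohort(cohort_spec(n = c(PGL_MIA = 5L, IAC = 5L), seed = 3),
                         shapes = "none")
  expect_equal(as.vector(table(small$group)), c(5, 5))

  # an impossible target distribution fails loudly with advice
  bad <- cohort_spec(targets = list(
    PGL_MIA = list(ld = c(12, 4), ld_pd = c(1.01, 0.005),
                   bia_sma = c(1.4, 0.05)),
    IAC = list(ld = c(19, 6), ld_pd = c(1.5, 0.5), bia_sma = c(1.1, 0.08))),
    seed = 1)
  expect_error(sample_cohort(bad, shapes = "none"), "infeasible")
})

test_that("cohort group means track the truncated target distributions", {
  # oracle: truncated-normal mean by numeric integration
  tn_mean <- function(mu, sd, lo, hi) {
    z <- function(x) x * stats::dnorm(x, mu, sd)
    stats::integrate(z, lo, hi)$value /
      (stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd))
  }
  m_ld <- vapply(1:30, function(s) {
    co <- sample_cohort(cohort_spec(seed = s), shapes = "none")
    mean(co$LD_mm[co$group == "PGL_MIA"])
  }, 0)
  expected <- tn_mean(11.818, 4.742, 3, 30)
  se <- 4.742 / sqrt(39) / sqrt(30)
  expect_lt(abs(mean(m_ld) - expected), 3 * se)
})

test_that("measured features of sampled shapes match the generator truth", {
  co <- sample_cohort(cohort_spec(n = c(PGL_MIA = 8L, IAC = 8L), seed = 11),
                      n_vertices = 360)
  f <- shape_features_table(co$shape, co$lesion_id,
                            boundary_smooth_mm = 0.15)
  expect_true(all(f$flags == ""))
  rel <- function(m, t) abs(m / t - 1)
  expect_lt(median(rel(f$LD_mm, co$LD_mm)), 0.02)
  expect_lt(median(rel(f$PD_mm, co$PD_mm)), 0.02)
  expect_lt(median(rel(f$BiA_SmA, co$BiA_SmA)), 0.02)
})
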