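test_that("circularity matches closed forms for canonical shapes", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-12)
  hex <- regular_ngon(6)
  expect_equal(circularity(hex), pi * sqrt(3) / 6, tolerance = 1e-12)
  # regular n-gon closed form (pi/n)/tan(pi/n), increasing toward 1
  prev <- 0
  for (n in c(8, 16, 32, 64, 128, 256)) {
    got <- circularity(regular_ngon(n))
    expect_equal(got, (pi / n) / tan(pi / n), tolerance = 1e-9)
    expect_gt(got, prev)
    prev <- got
  }
  expect_error(circularity(cbind(c(0, 1, 2), c(0, 1, 2))), "zero area")
})

test_that("the isoperimetric bound holds on random polygons", {
  set.seed(55)
  for (i in 1:300) {
    p <- random_star_polygon(n_vertices = sample(5:40, 1),
                             irregularity = runif(1, 0, 0.9))
    expect_lte(circularity(p), 1 + 1e-6)
  }
})

test_that("circularity and g-ratio are scale invariant, thickness scales linearly", {
  f <- fiber_geometry("f", regular_ngon(64, 5), regular_ngon(64, 3))
  m1 <- measure_fiber(f)
  f10 <- fiber_geometry("f", regular_ngon(64, 50), regular_ngon(64, 30))
  m10 <- measure_fiber(f10)
  expect_equal(m10$circularity, m1$circularity, tolerance = 1e-12)
  expect_equal(m10$g_ratio, m1$g_ratio, tolerance = 1e-12)
  expect_equal(m10$myelin_thickness_um, 10 * m1$myelin_thickness_um,
               tolerance = 1e-9)
})

test_that("equivalent diameter follows the circle reduction", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(78.53982), 10, tolerance = 1e-6)
  expect_equal(equivalent_diameter(4 * 7), 2 * equivalent_diameter(7))
  expect_error(equivalent_diameter(0), "positive")
})

test_that("measure_fiber reproduces the concentric-circle closed form", {
  f <- fiber_geometry("demo", regular_ngon(256, 5), regular_ngon(256, 3))
  m <- measure_fiber(f)
  expect_equal(m$g_ratio, 0.6, tolerance = 1e-9)
  expect_equal(m$myelin_thickness_um, 2.0, tolerance = 1e-3)
  # demyelinated limit: inner = outer scaled by ~1
  f1 <- fiber_geometry("gone", regular_ngon(64, 5), regular_ngon(64, 5 - 1e-9))
  expect_warning(m1 <- measure_fiber(f1), "no measurable myelin")
  expect_equal(m1$g_ratio, 1, tolerance = 1e-6)
  expect_equal(m1$myelin_thickness_um, 0, tolerance = 1e-6)
})

test_that("radial perturbation strictly lowers circularity at fixed vertex count", {
  set.seed(12)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  base <- cbind(cos(th), sin(th))
  noisy_r <- 1 + 0.2 * sin(4 * th)
  noisy <- cbind(noisy_r * cos(th), noisy_r * sin(th))
  expect_lt(circularity(noisy), circularity(base))
})

test_that("fiber geometry validation catches containment violations", {
  expect_error(fiber_geometry("bad", regular_ngon(64, 2), regular_ngon(64, 3)),
               "exceeds")
  shifted <- regular_ngon(64, 1.5, cx = 1.5)
  expect_error(fiber_geometry("bad2", regular_ngon(64, 2), shifted),
               "not contained")
})

test_that("label-mask morphometry agrees with the polygon oracle", {
  # rasterized annulus: axon r = 50 px inside myelin to r = 60 px
  n <- 140
  ij <- expand.grid(i = 1:n, j = 1:n)
  d <- sqrt((ij$i - 70.5)^2 + (ij$j - 70.5)^2)
  mask <- matrix(ifelse(d <= 50, 2L, ifelse(d <= 60, 3L, 0L)), n, n)
  m <- measure_from_labelmask(mask, pixel_size_um = 1)
  expect_equal(nrow(m), 1)
  expect_equal(m$circularity, 1, tolerance = 0.02)
  expect_equal(m$g_ratio, 50 / 60, tolerance = 0.02)

  # paired comparison against the exact polygon pathway on synthetic fibers
  fibers <- generate_nerve_cross_section(
    nerve_synth_params(n_fibers = 6, degeneration_level = 0.3, seed = 5,
                       field_size_um = 60))
  mask2 <- rasterize_fibers(fibers, 60, pixel_size_um = 0.1)
  got <- measure_from_labelmask(mask2, 0.1)
  want <- dplyr::bind_rows(lapply(fibers, measure_fiber))
  expect_equal(nrow(got), nrow(want))
  for (col in c("circularity", "g_ratio", "myelin_thickness_um")) {
    expect_equal(got[[col]], want[[col]], tolerance = 0.03)
  }
})

test_that("label-mask edge cases: empty mask and parity violations", {
  expect_equal(nrow(measure_from_labelmask(matrix(0L, 10, 10), 1)), 0)
  bad <- matrix(0L, 30, 30); bad[10:15, 10:15] <- 2L  # axon with no myelin
  expect_warning(out <- measure_from_labelmask(bad, 1), "parity")
  expect_equal(nrow(out), 0)
})

test_that("nerve summaries aggregate the three indices", {
  fibers <- tibble::tibble(
    fiber_id = c("a", "b", "c"),
    circularity = c(0.9, 0.95, 1.0),
    g_ratio = c(0.5, 0.6, 0.7),
    myelin_thickness_um = c(1, 2, 3),
    axon_area_um2 = 1, fiber_area_um2 = 2)
  s <- summarize_nerve(fibers)
  g <- s[s$index == "g_ratio", ]
  expect_equal(g$mean, 0.6)
  expect_equal(g$sem, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_equal(g$n_fibers, 3)
  # permutation invariance
  s2 <- summarize_nerve(fibers[c(3, 1, 2), ])
  expect_equal(s, s2)
  expect_warning(summarize_nerve(fibers[1, ]), "single fiber")
})

test_that("fiber polygon CSV round-trips", {
  fibers <- generate_nerve_cross_section(
    nerve_synth_params(n_fibers = 4, seed = 2, field_size_um = 60))
  path <- tempfile(fileext = ".csv")
  write_fiber_polygons(fibers, path)
  back <- read_fiber_polygons(path)
  expect_equal(length(back), length(fibers))
  got <- dplyr::bind_rows(lapply(back, measure_fiber))
  want <- dplyr::bind_rows(lapply(fibers, measure_fiber))
  expect_equal(dplyr::arrange(got, fiber_id), dplyr::arrange(want, fiber_id),
               tolerance = 1e-9)
})
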