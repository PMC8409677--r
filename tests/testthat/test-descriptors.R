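test_that("Feret calipers agree with square and disc geometry", {
  sq <- square_mask(100)
  f <- feret_diameters(sq, 1)
  expect_equal(f[["max_feret"]], 100 * sqrt(2), tolerance = 1e-3)
  expect_equal(f[["min_feret"]], 100, tolerance = 1e-9)
  expect_equal(f[["max_feret90"]], 100 * sqrt(2), tolerance = 1e-3)

  d <- feret_diameters(disc_mask(200), 1)
  expect_true(all(abs(d / 200 - 1) < 0.01))

  expect_error(feret_diameters(matrix(0L, 5, 5), 1), "empty")
})

test_that("calipers on random convex polygons match the brute-force oracle", {
  for (k in 1:5) {
    pts <- with_seed_test(k, {
      ang <- sort(runif(12, 0, 2 * pi))
      r <- runif(12, 40, 100)
      cbind(r * cos(ang), r * sin(ang))
    })
    hull <- pts[chull(pts), ]
    got <- feret_calipers(hull, angular_step = 0.005)
    want <- oracle_calipers(hull, step_deg = 0.005)
    expect_equal(got[["max_feret"]], want[["max"]], tolerance = 1e-6)
    expect_equal(got[["min_feret"]], want[["min"]], tolerance = 1e-6)
    expect_equal(got[["max_feret90"]], want[["max90"]], tolerance = 1e-6)
  }
})

test_that("a digitized disc has near-unit shape descriptors", {
  s <- 0.2
  m <- morphology_2d(disc_mask(150), s)
  for (d in c("circularity", "shape_factor", "convexity", "roughness"))
    expect_true(m[[d]] > 0.98 && m[[d]] < 1.02, label = d)
  expect_equal(m$length, 150 * s, tolerance = 0.02)
  # width is area/length, so a disc reports (pi/4) d
  expect_equal(m$width, (pi / 4) * 150 * s, tolerance = 0.02)
  expect_equal(m$eq_diameter, 150 * s, tolerance = 0.02)
  expect_equal(m$mean_chord, (pi / 4) * 150 * s, tolerance = 0.02)
  expect_equal(m$perimeter, pi * 150 * s, tolerance = 0.01)
})

test_that("an elongated ellipse matches its analytic descriptors", {
  a <- 90; b <- 50   # px semi-axes, ratio 1.8
  for (th in c(0, 0.53, 1.1)) {
    m <- morphology_2d(ellipse_mask(a, b, theta = th), 1)
    # Ramanujan perimeter for the analytic circularity oracle
    h <- ((a - b) / (a + b))^2
    P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    circ_true <- 4 * pi * (pi * a * b) / P^2
    expect_equal(m$circularity, circ_true, tolerance = 0.02)
    expect_equal(m$elongation, 1.8, tolerance = 0.02)
  }
})

test_that("multi-component masks violate the morphology contract", {
  m <- matrix(0L, 30, 30)
  m[5:10, 5:10] <- 1L
  m[20:25, 20:25] <- 1L
  expect_error(morphology_2d(m, 1), "components")
})

test_that("equivalent volumes follow their closed forms", {
  expect_equal(volume_eq_sphere(1), pi / 6)
  expect_equal(volume_eq_sphere(2) / volume_eq_sphere(1), 8)
  expect_error(volume_eq_sphere(-1), "> 0")

  # capsule degenerates to the sphere at l = d
  expect_equal(volume_eq_cylinder(10, 10), volume_eq_sphere(10))
  expect_equal(volume_eq_cylinder(50, 20) / volume_eq_cylinder(25, 10), 8)
  expect_warning(v <- volume_eq_cylinder(5, 10), "clamping")
  expect_equal(v, volume_eq_sphere(10))

  # monotone in each argument
  expect_gt(volume_eq_cylinder(26, 16), volume_eq_cylinder(25, 16))
  expect_gt(volume_eq_cylinder(26, 17), volume_eq_cylinder(26, 16))
})

test_that("printed volume means are consistent with the mean geometry", {
  # evaluating the closed forms at the printed mean bright-field Brassica
  # geometry reproduces the printed volume means within a Jensen-gap tolerance
  expect_equal(volume_eq_sphere(23.18), 6620.79, tolerance = 0.02)
  expect_equal(volume_eq_cylinder(25.36, 16.69), 4375.56, tolerance = 0.02)
})

test_that("colour statistics satisfy their exact identities", {
  img <- flat_rgb(20, c(116, 104, 72))
  m <- matrix(1L, 20, 20)
  cs <- colour_stats(img, m)
  expect_equal(cs$mean_intensity, (116 + 104 + 72) / 3)
  expect_equal(cs$mean_brightness, cs$mean_intensity * 100 / 255)
  expect_equal(cs$intensity_variation, 0)
  expect_equal(cs$bright_variation, 0)
  expect_equal(cs$hue_variation, 0)

  # identities hold to float precision on arbitrary images
  noisy <- with_seed_test(3, array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3)))
  mask <- with_seed_test(4, matrix(rbinom(32 * 32, 1, 0.6), 32, 32))
  cs2 <- colour_stats(noisy, mask)
  expect_equal(cs2$mean_intensity,
               (cs2$mean_red + cs2$mean_green + cs2$mean_blue) / 3,
               tolerance = 1e-12)
  expect_equal(cs2$mean_brightness, cs2$mean_intensity * 100 / 255,
               tolerance = 1e-12)
  expect_equal(cs2$bright_variation, cs2$intensity_variation * 100 / 255,
               tolerance = 1e-12)
  expect_error(colour_stats(noisy, matrix(0L, 32, 32)), "empty")
})

test_that("optical density of the printed mean intensity respects the Jensen bound", {
  # a uniform region at the printed bright-field Brassica mean intensity has
  # OD -log10(97.27/255) = 0.4186, at most the printed per-pixel mean 0.43
  img <- flat_rgb(10, rep(97.27, 3))
  cs <- colour_stats(img, matrix(1L, 10, 10))
  expect_equal(cs$mean_density, -log10(97.27 / 255), tolerance = 1e-9)
  expect_lte(cs$mean_density, 0.43)
})

test_that("micrometre descriptors scale with pixel size, dimensionless ones do not", {
  mask <- ellipse_mask(70, 45, theta = 0.4)
  m1 <- morphology_2d(mask, 0.2)
  m2 <- morphology_2d(mask, 0.4)
  for (d in c("eq_diameter", "perimeter", "mean_chord", "length", "width",
              "min_feret", "max_feret90"))
    expect_equal(m2[[d]] / m1[[d]], 2, tolerance = 1e-9, label = d)
  expect_equal(m2$area / m1$area, 4, tolerance = 1e-9)
  for (d in c("circularity", "elongation", "shape_factor", "convexity",
              "roughness"))
    expect_equal(m2[[d]], m1[[d]], tolerance = 1e-9, label = d)
  expect_equal(volume_eq_sphere(2 * m1$eq_diameter) /
                 volume_eq_sphere(m1$eq_diameter), 8)
})

test_that("dimensionless descriptors are rotation-robust", {
  ref <- morphology_2d(ellipse_mask(80, 50, theta = 0), 1)
  for (th in c(0.3, 0.7, 1.2, 2.0)) {
    m <- morphology_2d(ellipse_mask(80, 50, theta = th), 1)
    for (d in c("circularity", "elongation", "shape_factor", "convexity",
                "roughness"))
      expect_lt(abs(m[[d]] / ref[[d]] - 1), 0.02, label = sprintf("%s@%g", d, th))
  }
})

test_that("extract_features assembles complete rows and recovers phantom truth", {
  # one clean psilate disc grain
  mask <- disc_mask(120)
  n <- nrow(mask)
  img <- flat_rgb(n, c(116, 104, 72))
  z <- matrix(0, n, n)
  grains <- label_grains(mask, field_id = "fx", modality = "BF")
  ft <- extract_features(img, z, grains, 0.16, taxon = "Brassica")
  expect_equal(nrow(ft), 1L)
  expect_named(ft, c(descriptor_names(), "taxon", "modality", "grain_id"))
  expect_true(all(is.finite(as.matrix(ft[descriptor_names()]))))
  expect_gt(ft$roughness, 0.98)
  expect_equal(ft$edf_roughness, 1, tolerance = 1e-9)

  # empty grain list gives an empty, fully-typed table
  empty <- extract_features(img, z, list(), 0.16)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c(descriptor_names(), "taxon", "modality", "grain_id"))

  # zero-variance Brassica phantoms: Length column sits at the generating mean
  app <- taxon_appearance("Brassica", "BF", length_sd = 0,
                          elongation_mean = 1, elongation_sd = 0,
                          exine_class = "psilate")
  lens <- vapply(1:3, function(k) {
    g <- make_grain_mask(app, 0.16, seed = k)
    gr <- label_grains(g$mask)
    morphology_2d(gr[[1]]$mask, 0.16)$length
  }, 1)
  expect_true(all(abs(lens - 25.36) < 0.4))
})
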