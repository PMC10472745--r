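# Morphometric operations against closed-form geometry and brute-force
# oracles.

test_that("vessel tortuosity: straight line, semicircle, invariances", {
  straight <- cbind(c(0, 5, 10), c(0, 5, 10))
  expect_equal(vessel_tortuosity(straight), 1.0)

  # semicircle: arc/chord = (pi*r)/(2r) = pi/2
  arc <- make_semicircle(30, n = 100L)
  expect_equal(vessel_tortuosity(arc), pi / 2, tolerance = 0.001)

  # rigid motion + uniform scaling leave the ratio unchanged
  set.seed(11)
  pl <- cbind(cumsum(runif(20)), cumsum(rnorm(20)))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(2 * pl %*% R, 2L, c(13, -4), "+")
  expect_equal(vessel_tortuosity(moved), vessel_tortuosity(pl))

  expect_error(vessel_tortuosity(rbind(c(0, 0), c(1, 1), c(0, 0))),
               "closed curve")
})

test_that("crypt shape matches analytic circle, ellipse, unit square", {
  circ <- make_circle(100, 100, 20, n = 360L)
  sh <- crypt_shape(circ, pixel_size = 1)
  expect_equal(sh[["area"]], pi * 400, tolerance = 0.001)
  expect_lt(sh[["eccentricity"]], 0.01)
  expect_equal(sh[["diameter"]], 40, tolerance = 0.001)

  ell <- make_ellipse(0, 0, 20, 10, theta = 0.9, n = 360L)
  expect_equal(crypt_shape(ell)[["eccentricity"]], sqrt(3) / 2,
               tolerance = 0.02)

  sq <- make_square(5, 5, 0.5)  # unit square
  sh2 <- crypt_shape(sq, pixel_size = 2)
  expect_equal(sh2[["area"]], 1 * 2^2)
  expect_equal(sh2[["diameter"]], 2 * sqrt(1 / pi) * 2)

  expect_error(crypt_shape(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("crypt shape is scale-equivariant in pixel size", {
  poly <- make_ellipse(40, 40, 12, 8, theta = 0.3)
  s1 <- crypt_shape(poly, pixel_size = 1)
  s2 <- crypt_shape(poly, pixel_size = 2)
  expect_equal(s2[["area"]], 4 * s1[["area"]])
  expect_equal(s2[["diameter"]], 2 * s1[["diameter"]])
  expect_equal(s2[["eccentricity"]], s1[["eccentricity"]])
})

test_that("wall thickness: annulus closed form, thin limit, square oracle", {
  outer <- make_circle(50, 50, 15, n = 720L)
  inner <- make_circle(50, 50, 10, n = 720L)
  expect_equal(wall_thickness(outer, inner), 5.0, tolerance = 0.01)

  # inner almost equal to outer: thickness tends to 0
  expect_lt(wall_thickness(outer, make_circle(50, 50, 15 * 0.999, n = 720L)),
            0.02)

  # concentric squares vs an independent ray-casting closed form
  wt <- wall_thickness(make_square(0, 0, 10), make_square(0, 0, 6),
                       n_rays = 72L)
  expect_equal(wt, square_ray_gap_oracle(10, 6, 72L), tolerance = 1e-9)

  # missing lumen gives a missing value, not zero
  expect_true(is.na(wall_thickness(crypt_annotation(outer, NULL, "c"))))
})

test_that("intercrypt distance: two circles, symmetry, brute-force oracle", {
  c1 <- make_circle(0, 0, 10, 720L)
  c2 <- make_circle(30, 0, 10, 720L)
  icd <- intercrypt_distance(list(c1, c2))
  expect_equal(icd, c(10, 10), tolerance = 0.01)

  # three collinear equidistant circles: middle ICD equals side ICD
  c3 <- make_circle(60, 0, 10, 720L)
  icd3 <- intercrypt_distance(list(c1, c2, c3))
  expect_equal(icd3[2L], icd3[1L])
  expect_equal(icd3[2L], icd3[3L])

  # fewer than two crypts: feature missing
  expect_null(intercrypt_distance(list(c1)))

  # random scenes equal the brute-force all-pairs vertex oracle
  set.seed(7)
  polys <- lapply(1:8, function(i) {
    make_ellipse(runif(1, 0, 200), runif(1, 0, 200),
                 runif(1, 5, 15), runif(1, 3, 10), runif(1, 0, pi), n = 60L)
  })
  got <- intercrypt_distance(polys, pixel_size = 1)
  want <- sapply(seq_along(polys), function(i) {
    min(sapply(seq_along(polys)[-i], function(j) {
      icd_bruteforce(polys[[i]], polys[[j]])
    }))
  })
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("FLCM: constant field, set semantics for overlapping annuli", {
  img <- matrix(7.5, 120, 120)
  crypts <- list(crypt_annotation(make_circle(40, 40, 12), crypt_id = "a"),
                 crypt_annotation(make_circle(70, 40, 12), crypt_id = "b"))
  sc <- mosaic_scene(img, crypts, pixel_size = 1, mosaic_id = "m")
  res <- flcm(sc, annulus_width = 8)
  expect_equal(unname(res$pericrypt), c(7.5, 7.5))
  expect_equal(res$elsewhere, 7.5)

  # crypts 30 px apart with 20 um annuli: annuli overlap; each crypt keeps
  # its own annulus mean and elsewhere excludes the union
  img2 <- matrix(1, 120, 120)
  res2 <- flcm(mosaic_scene(img2, crypts, pixel_size = 1), annulus_width = 20)
  expect_length(res2$pericrypt, 2L)
  expect_equal(res2$elsewhere, 1)
})

test_that("patient aggregation pools structures and respects missingness", {
  cfg1 <- scene_config(n_crypts = 3L, n_vessels = 1L, seed = 21L)
  cfg2 <- scene_config(n_crypts = 3L, n_vessels = 1L, seed = 22L)
  r1 <- measure_scene(generate_mosaic_scene(cfg1)$scene)
  r2 <- measure_scene(generate_mosaic_scene(cfg2)$scene)
  r1$patient_id <- r2$patient_id <- "P1"
  row <- aggregate_patient(list(r1, r2))
  expect_equal(nrow(row), 1L)
  expect_equal(row$max_crypt_area, max(c(r1$area, r2$area)))
  expect_equal(row$mean_vessel_tortuosity, mean(c(r1$tortuosity, r2$tortuosity)))
  expect_equal(row$mean_icd, mean(c(r1$icd, r2$icd)))

  r2$patient_id <- "P2"
  expect_error(aggregate_patient(list(r1, r2)), "mix")

  # a record with no vessels leaves the tortuosity pooled over the rest;
  # with none anywhere the aggregate is NA, not zero
  r3 <- r1
  r3$tortuosity <- numeric(0)
  r1b <- r1; r1b$tortuosity <- numeric(0)
  row2 <- aggregate_patient(list(r1b, r3))
  expect_true(is.na(row2$mean_vessel_tortuosity))
})

test_that("variant flags: Feret diameter, center ICD, mosaic-mean pooling", {
  ell <- make_ellipse(0, 0, 20, 10, theta = 0.5, n = 360L)
  sh <- crypt_shape(ell, diameter_method = "feret")
  expect_equal(sh[["diameter"]], 40, tolerance = 0.001)  # major axis

  c1 <- make_circle(0, 0, 10, 360L)
  c2 <- make_circle(30, 0, 10, 360L)
  expect_equal(intercrypt_distance(list(c1, c2), mode = "center"),
               c(30, 30), tolerance = 0.01)

  r1 <- list(patient_id = "P", timepoint = "pre", mosaic_id = "a",
             tortuosity = c(1.1, 1.3), area = c(100, 200),
             eccentricity = c(0.2, 0.4), diameter = c(10, 16),
             wall_thickness = c(5, 7), icd = c(20, 20),
             flcm_pericrypt = NULL, flcm_elsewhere = NULL)
  r2 <- r1; r2$mosaic_id <- "b"; r2$tortuosity <- 1.9
  class(r1) <- class(r2) <- "morphometric_record"
  by_struct <- aggregate_patient(list(r1, r2))
  by_mosaic <- aggregate_patient(list(r1, r2), pooling = "mosaic_means")
  expect_equal(by_struct$mean_vessel_tortuosity, mean(c(1.1, 1.3, 1.9)))
  expect_equal(by_mosaic$mean_vessel_tortuosity, mean(c(1.2, 1.9)))
})
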