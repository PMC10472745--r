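# Ex vivo dual-threshold quantification.

test_that("artifact mask discards constant pixels and keeps varying ones", {
  imgs <- list(matrix(c(0.5, 0.0, 0.2, 0.2), 2),
               matrix(c(0.5, 1.0, 0.2, 0.8), 2))
  st <- exvivo_stack(imgs, "s1")
  m <- artifact_mask(st, theta_sigma = 0.01)
  expect_true(m[1, 1])    # constant 0.5: SD 0 < 0.01, discarded
  expect_false(m[2, 1])   # alternating 0/1: SD ~0.707, kept
  expect_true(m[1, 2])
  expect_false(m[2, 2])

  expect_error(exvivo_stack(list(matrix(0.5, 2, 2))), ">= 2 images")

  # recovered mask equals generator truth when tissue SD >> theta_sigma
  out <- generate_exvivo_stack(stack_config(n_images = 15L,
                                            image_size = c(30L, 30L),
                                            artifact_fraction = 0.2, seed = 7L))
  expect_identical(artifact_mask(out$stack), out$truth$artifact)
})

test_that("threshold estimation follows the declared SD convention", {
  # all retained equal c: mu = c, sigma = 0, both thresholds c
  st <- exvivo_stack(list(matrix(c(0.4, 0.1), 1), matrix(c(0.4, 0.9), 1)), "s")
  mask <- artifact_mask(st)
  th <- estimate_thresholds(st, mask)
  # first pixel is artifact; retained values are {0.1, 0.9} -> mu 0.5
  expect_equal(th$mu_fluo, 0.5)
  expect_equal(th$sigma_fluo, sd(c(0.1, 0.9)))
  expect_equal(th$theta_con, 0.5 + 2 * sd(c(0.1, 0.9)))
  expect_equal(th$theta_rel, 0.5)

  # hand computation with {0.1, 0.3}: mu 0.2, sample SD sqrt(0.02)
  st2 <- exvivo_stack(list(matrix(0.1, 1, 1), matrix(0.3, 1, 1)), "s2")
  th2 <- estimate_thresholds(st2, matrix(FALSE, 1, 1))
  expect_equal(th2$mu_fluo, 0.2)
  expect_equal(th2$sigma_fluo, sqrt(0.02))
  expect_equal(th2$theta_con, 0.2 + 2 * sqrt(0.02))

  const <- exvivo_stack(list(matrix(0.3, 2, 2), matrix(0.3, 2, 2)), "s3")
  expect_error(estimate_thresholds(const, artifact_mask(const)),
               "no analyzable tissue")

  # law of large numbers: pooled estimates approach the generator values
  out <- generate_exvivo_stack(stack_config(n_images = 30L,
                                            image_size = c(60L, 60L),
                                            artifact_fraction = 0,
                                            blob_fraction = 0, seed = 11L))
  th3 <- estimate_thresholds(out$stack, artifact_mask(out$stack))
  expect_equal(th3$mu_fluo, 0.3, tolerance = 0.01)
  expect_equal(th3$sigma_fluo, 0.05, tolerance = 0.01)
})

test_that("image quantification is strict and handles empty selections", {
  th <- structure(list(theta_sigma = 0.01, mu_fluo = 0.5, sigma_fluo = 0.1,
                       theta_con = 0.7, theta_rel = 0.5),
                  class = "exvivo_thresholds")
  mask <- matrix(FALSE, 2, 2)

  # constant image exactly at mu: strict > selects nothing at theta_rel
  q <- quantify_image(matrix(0.5, 2, 2), th, mask)
  expect_equal(q$area_rel, 0L)
  expect_true(is.na(q$intensity_rel))

  # one bright pixel
  img <- matrix(0.5, 2, 2); img[1, 1] <- 1.0
  q2 <- quantify_image(img, th, mask)
  expect_equal(q2$area_con, 1L)
  expect_equal(q2$intensity_con, 1.0)
  expect_equal(q2$mean_intensity, mean(img))
})

test_that("specimen aggregation and intensity ordering invariants", {
  per <- data.frame(specimen_id = "s", image = 1:2,
                    area_con = c(10, 30), frac_con = c(0.1, 0.3),
                    intensity_con = c(0.8, 0.9),
                    area_rel = c(40, 60), frac_rel = c(0.4, 0.6),
                    intensity_rel = c(0.6, 0.7),
                    mean_intensity = c(0.5, 0.55))
  agg <- aggregate_specimen(per)
  expect_equal(agg$mean_frac_con, 0.2)
  expect_equal(agg$max_frac_con, 0.3)
  expect_equal(agg$mean_intensity_rel, 0.65)
  per2 <- per; per2$specimen_id <- c("a", "b")
  expect_error(aggregate_specimen(per2), "mix")

  # full pipeline on a generated stack: ordering invariants hold
  out <- generate_exvivo_stack(stack_config(n_images = 12L,
                                            image_size = c(40L, 40L),
                                            artifact_fraction = 0.05,
                                            blob_fraction = 0.08, seed = 13L))
  q <- quantify_stack(out$stack)
  expect_true(all(q$per_image$area_con <= q$per_image$area_rel))
  expect_true(all(q$per_image$intensity_con >= q$per_image$intensity_rel,
                  na.rm = TRUE))
  expect_true(all(q$per_image$intensity_rel >= q$per_image$mean_intensity,
                  na.rm = TRUE))
})

test_that("adding artifact pixels changes no readout", {
  out <- generate_exvivo_stack(stack_config(n_images = 8L,
                                            image_size = c(20L, 20L),
                                            artifact_fraction = 0,
                                            blob_fraction = 0.1, seed = 17L))
  base <- quantify_stack(out$stack)
  # append a constant column to every frame
  aug <- lapply(out$stack$images, function(m) cbind(m, 0.42))
  q2 <- quantify_stack(exvivo_stack(aug, "aug"))
  expect_equal(q2$thresholds$mu_fluo, base$thresholds$mu_fluo)
  expect_equal(q2$per_image$frac_con, base$per_image$frac_con)
  expect_equal(q2$per_image$intensity_rel, base$per_image$intensity_rel)
})

test_that("drug stacks with binding blobs exceed isotype controls", {
  # emulates the isotype-control comparison: hyperfluorescent binding
  # raises the high-threshold area in the drug-labeled specimen
  wins <- 0L
  for (s in 1:20) {
    iso <- generate_exvivo_stack(stack_config(n_images = 8L,
                                              image_size = c(32L, 32L),
                                              blob_fraction = 0, seed = 100L + s))
    drug <- generate_exvivo_stack(stack_config(n_images = 8L,
                                               image_size = c(32L, 32L),
                                               blob_fraction = 0.1,
                                               seed = 200L + s))
    qi <- quantify_stack(iso$stack)$specimen$mean_frac_con
    qd <- quantify_stack(drug$stack)$specimen$mean_frac_con
    if (qd > qi) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("raising blob intensity never decreases the high area", {
  for (s in 1:5) {
    fr <- sapply(c(0.5, 0.65, 0.8), function(bm) {
      out <- generate_exvivo_stack(stack_config(n_images = 6L,
                                                image_size = c(32L, 32L),
                                                blob_fraction = 0.1,
                                                blob_mean = bm, seed = 300L + s))
      quantify_stack(out$stack)$specimen$mean_frac_con
    })
    expect_true(all(diff(fr) >= 0))
  }
})
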