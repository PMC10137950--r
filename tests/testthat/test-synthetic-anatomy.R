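test_that("femur truth satisfies the closed-form offset of an angled neck", {
  f <- generate_femur(femur_params(noise_sd = 0, neck_shaft_angle = 135,
                                   anteversion = 0, neck_length = 50,
                                   head_radius = 24))
  expect_equal(f$truth$true_FO3D, 50 * sin(45 * pi / 180), tolerance = 1e-12)
  expect_lt(abs(point_line_distance(f$truth$head_center, f$truth$shaft_axis) -
                f$truth$true_FO3D), 1e-9)
  # zero anteversion: head centre in the plane of shaft axis and ML axis
  expect_lt(abs(f$truth$head_center[2]), 1e-12)
})

test_that("femur truth offset consistency holds across the parameter space", {
  set.seed(21)
  for (k in 1:12) {
    p <- femur_params(head_radius = runif(1, 19, 27),
                      neck_shaft_angle = runif(1, 115, 145),
                      anteversion = runif(1, -20, 45),
                      neck_length = runif(1, 40, 65),
                      noise_sd = 0, seed = k)
    tr <- generate_femur(p)$truth
    expect_lt(abs(point_line_distance(tr$head_center, tr$shaft_axis) -
                  tr$true_FO3D), 1e-9)
    expect_true(all(is.finite(unlist(tr[c("head_center", "reference_point")]))))
  }
})

test_that("generators are deterministic for a fixed seed", {
  a <- generate_femur(femur_params(noise_sd = 0.5, seed = 7))
  b <- generate_femur(femur_params(noise_sd = 0.5, seed = 7))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  pa <- generate_hemipelvis(pelvis_params(noise_sd = 0.5, seed = 7))
  pb <- generate_hemipelvis(pelvis_params(noise_sd = 0.5, seed = 7))
  expect_identical(serialize(pa, NULL), serialize(pb, NULL))
})

test_that("mirroring a right-side specimen reproduces the left-side truth", {
  r <- generate_femur(femur_params(noise_sd = 0, anteversion = 12))
  l <- generate_femur(femur_params(noise_sd = 0, anteversion = 12, side = "left"))
  expect_equal(l$truth$head_center,
               c(-r$truth$head_center[1], r$truth$head_center[2:3]),
               tolerance = 1e-12)
  mirrored <- mirror_mesh(r$mesh)
  expect_equal(mirrored$vertices, l$mesh$vertices, tolerance = 1e-9)
  expect_identical(mirrored$side, "left")
})

test_that("parameter validation errors name the offending field", {
  expect_error(femur_params(head_radius = -1), "head_radius")
  expect_error(femur_params(neck_shaft_angle = 190), "neck_shaft_angle")
  expect_error(femur_params(anteversion = 90), "anteversion")
  expect_error(femur_params(noise_sd = -0.1), "noise_sd")
  expect_error(pelvis_params(CE_angle = 95), "CE_angle")
  expect_error(pelvis_params(wall_thickness = -2), "wall_thickness")
  expect_error(pelvis_params(cup_face_inclination = 75), "cup_face")
})

test_that("hemipelvis truth realises the requested geometry", {
  # zero wall thickness: the true floor is the medial pole of the socket
  p0 <- generate_hemipelvis(pelvis_params(wall_thickness = 0, noise_sd = 0))
  expect_lt(norm3(p0$truth$true_floor_point -
                  (p0$truth$acetabular_center -
                   c(p0$truth$acetabular_radius, 0, 0))), 1e-9)
  # centre-edge angle recomputed from the emitted landmarks
  for (ce in c(22, 30, 42)) {
    p <- generate_hemipelvis(pelvis_params(CE_angle = ce, noise_sd = 0))
    d <- p$truth$lateral_acetabular_edge - p$truth$acetabular_center
    ce_back <- atan2(d[1], d[3]) * 180 / pi
    expect_lt(abs(ce_back - ce), 0.5)
  }
  # identical truth for a fixed seed
  t1 <- generate_hemipelvis(pelvis_params(seed = 5))$truth
  t2 <- generate_hemipelvis(pelvis_params(seed = 5))$truth
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
})

test_that("cohort draws match their target distributions", {
  # all-zero SDs collapse onto the means
  d0 <- cohort_distributions()
  d0$sd <- 0
  one <- generate_cohort(n = 1, distributions = d0, seed = 3, meshes = FALSE)
  ref <- d0[d0$group == one$sex, ]
  expect_equal(one$ce_angle, ref$mean[ref$parameter == "ce_angle"])
  expect_equal(one$fo3d_true, ref$mean[ref$parameter == "fo3d"])
  expect_equal(one$body_length, ref$mean[ref$parameter == "body_length"])

  # reproducibility
  c1 <- generate_cohort(n = 4, seed = 9)
  c2 <- generate_cohort(n = 4, seed = 9)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))

  # anteversion sample means track the sex-specific targets (3 sd / sqrt(n))
  co <- generate_cohort(n = 66, seed = 17, meshes = FALSE)
  expect_identical(sum(co$sex == "men"), 28L)
  for (g in c("men", "women")) {
    ref <- cohort_distributions()
    ref <- ref[ref$parameter == "femoral_anteversion" & ref$group == g, ]
    x <- co$femoral_anteversion[co$sex == g]
    expect_lt(abs(mean(x) - ref$mean), 3 * ref$sd / sqrt(length(x)))
  }
  # invariant bounds respected
  expect_true(all(co$ce_angle >= 20))
  expect_true(all(co$wall_thickness >= 1.5))
  expect_error(generate_cohort(n = 3, distributions = cohort_distributions()[0, ]),
               "empty")
})
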