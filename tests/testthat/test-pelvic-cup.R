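test_that("APP frame construction follows the landmark geometry", {
  lm <- list(ASIS_R = c(118, 0, 0), ASIS_L = c(-118, 0, 0),
             pubic_tubercle_R = c(28, 0, -98), pubic_tubercle_L = c(-28, 0, -98))
  fr <- build_app_frame(lm)
  expect_equal(fr$ap, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$ml, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$si, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))

  # generator truth landmarks reproduce the constructive frame
  p <- generate_hemipelvis(pelvis_params(noise_sd = 0))
  fr2 <- build_app_frame(p$truth$APP_landmarks)
  expect_lt(norm3(fr2$ml - c(1, 0, 0)), 1e-9)
  expect_lt(norm3(fr2$ap - c(0, 1, 0)), 1e-9)

  # swapping left/right landmarks mirrors the frame but keeps it right-handed
  swapped <- list(ASIS_R = lm$ASIS_L, ASIS_L = lm$ASIS_R,
                  pubic_tubercle_R = lm$pubic_tubercle_L,
                  pubic_tubercle_L = lm$pubic_tubercle_R)
  frs <- build_app_frame(swapped)
  expect_equal(frs$ml, c(-1, 0, 0), tolerance = 1e-12)
  expect_gt(det(cbind(frs$ml, frs$ap, frs$si)), 0)

  expect_error(build_app_frame(list(ASIS_R = c(1, 0, 0), ASIS_L = c(-1, 0, 0),
                                    pubic_tubercle_R = c(0.5, 0, 0),
                                    pubic_tubercle_L = c(-0.5, 0, 0))),
               "collinear")
})

test_that("acetabular morphometry recovers the socket, floor and rim", {
  p <- generate_hemipelvis(pelvis_params(acetabular_radius = 26,
                                         wall_thickness = 5, noise_sd = 0))
  fr <- build_app_frame(p$truth$APP_landmarks)
  a <- measure_acetabulum(p$mesh, fr, p$truth)
  expect_lt(abs(a$native_radius - 26), 0.1)
  expect_lt(norm3(a$native_center - p$truth$acetabular_center), 0.1)
  expect_lt(norm3(a$true_floor_point - p$truth$true_floor_point), 0.5)
  expect_lt(abs(a$rim_max_diameter - 52), 0.5)
  expect_gte(a$rim_max_diameter, 2 * a$native_radius - 2)
})

test_that("axial-slab rim search agrees with the all-pairs maximum", {
  p <- generate_hemipelvis(pelvis_params(noise_sd = 0, seed = 2))
  fr <- build_app_frame(p$truth$APP_landmarks)
  a <- measure_acetabulum(p$mesh, fr, p$truth)
  all_pairs <- max(stats::dist(a$rim_points))
  expect_lt(abs(a$rim_max_diameter - all_pairs), 1e-6)
})

test_that("cup sizing takes the largest size not exceeding the rim", {
  p <- generate_hemipelvis(pelvis_params(noise_sd = 0))
  fr <- build_app_frame(p$truth$APP_landmarks)
  a <- measure_acetabulum(p$mesh, fr, p$truth)
  a$rim_max_diameter <- 51.3
  cup <- place_cup(a, fr, cup_sizes = seq(44, 60, by = 2))
  expect_equal(cup$diameter, 50)
  expect_error(place_cup(a, fr, cup_sizes = c(60, 62)), "no cup size fits")
  expect_error(place_cup(a, fr, cup_sizes = numeric(0)), "empty")
})

test_that("a full-size cup in a wall-less socket lands on the native centre", {
  p <- generate_hemipelvis(pelvis_params(wall_thickness = 0, noise_sd = 0))
  fr <- build_app_frame(p$truth$APP_landmarks)
  a <- measure_acetabulum(p$mesh, fr, p$truth)
  cup <- place_cup(a, fr, cup_sizes = 2 * a$native_radius - 0.1)
  expect_lt(norm3(cup$CC - a$native_center), 0.5)
})

test_that("cup placement medialises by the wall depth and never lateralises", {
  p <- generate_hemipelvis(pelvis_params(wall_thickness = 5, noise_sd = 0))
  fr <- build_app_frame(p$truth$APP_landmarks)
  a <- measure_acetabulum(p$mesh, fr, p$truth)
  cup <- place_cup(a, fr, cup_sizes = 2 * a$native_radius - 0.1)
  shift <- sum((cup$CC - a$native_center) * fr$ml)   # lateral axis, right hip
  expect_lt(abs(shift + 5), 0.6)                     # ~5 mm towards medial

  for (w in c(0, 2, 5, 8)) {
    pw <- generate_hemipelvis(pelvis_params(wall_thickness = w, noise_sd = 0.4,
                                            seed = 40 + w))
    aw <- measure_acetabulum(pw$mesh, fr, pw$truth)
    cw <- place_cup(aw, fr)
    expect_lte(sum(cw$CC * fr$ml), sum(aw$native_center * fr$ml) + 0.2)
  }
})

test_that("cup anteversion follows the transverse acetabular ligament", {
  p <- generate_hemipelvis(pelvis_params(cup_face_anteversion = 24, noise_sd = 0))
  fr <- build_app_frame(p$truth$APP_landmarks)
  a <- measure_acetabulum(p$mesh, fr, p$truth)
  cup <- place_cup(a, fr, inclination = p$truth$face_inclination)
  expect_lt(abs(cup$anteversion - 24), 0.5)
})

test_that("cup centre recovery across noisy pelves stays within 1 mm", {
  set.seed(88)
  errs <- vapply(1:50, function(s) {
    ra <- runif(1, 23, 28)
    w <- runif(1, 2, 8)
    p <- generate_hemipelvis(pelvis_params(acetabular_radius = ra,
                                           wall_thickness = w,
                                           noise_sd = 0.5, seed = 1000 + s))
    fr <- build_app_frame(p$truth$APP_landmarks)
    a <- measure_acetabulum(p$mesh, fr, p$truth)
    cup <- place_cup(a, fr)
    sizes <- seq(38, 66, by = 2)
    d_true <- max(sizes[sizes <= 2 * ra])
    cc_true <- p$truth$true_floor_point + (d_true / 2) * c(1, 0, 0)
    norm3(cup$CC - cc_true)
  }, numeric(1))
  expect_lt(mean(errs), 1)
})
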