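make_matched <- function(anteversion = 15, noise_sd = 0, seed = 1) {
  f <- generate_femur(femur_params(anteversion = anteversion,
                                   noise_sd = noise_sd, seed = seed))
  p <- generate_hemipelvis(pelvis_params(noise_sd = noise_sd, seed = seed))
  fr <- build_app_frame(p$truth$APP_landmarks)
  fm <- measure_femur(f$mesh, f$truth$landmarks)
  acet <- measure_acetabulum(p$mesh, fr, p$truth)
  cup <- place_cup(acet, fr)
  list(f = f, p = p, frame = fr, fm = fm, acet = acet, cup = cup,
       scene = match_hip(fm, acet, fr, cup = cup))
}

test_that("matching puts the femoral head centre exactly on the HRC", {
  s <- make_matched()
  expect_lt(norm3(s$scene$FHC_world - s$scene$HRC_world), 1e-6)
  # the pose maps the measured FHC onto the HRC
  expect_lt(norm3(apply_rigid(s$scene$femur_pose, s$fm$FHC) - s$scene$HRC_world),
            1e-9)
})

test_that("matching is equivariant: a rigidly pre-transformed femur yields the
          identical matched scene", {
  s <- make_matched(anteversion = 18, noise_sd = 0.3, seed = 4)
  rot <- random_rotation(seed = 12)
  tr <- c(-30, 55, 10)
  mesh2 <- s$f$mesh
  mesh2$vertices <- sweep(mesh2$vertices %*% t(rot), 2, tr, "+")
  lm2 <- lapply(s$f$truth$landmarks, function(p) drop(rot %*% p) + tr)
  fm2 <- measure_femur(mesh2, lm2)
  scene2 <- match_hip(fm2, s$acet, s$frame, cup = s$cup)
  expect_lt(norm3(scene2$reference_point_world - s$scene$reference_point_world),
            1e-4)
  expect_lt(norm3(scene2$FHC_world - s$scene$FHC_world), 1e-9)
})

test_that("an already-reduced hip matches with a near-identity pose", {
  f <- generate_femur(femur_params(anteversion = 10, noise_sd = 0))
  p <- generate_hemipelvis(pelvis_params(noise_sd = 0))
  fr <- build_app_frame(p$truth$APP_landmarks)
  acet <- measure_acetabulum(p$mesh, fr, p$truth)
  # translate the femur so its head centre already sits on the HRC
  shift <- acet$native_center - f$truth$head_center
  mesh <- f$mesh
  mesh$vertices <- sweep(mesh$vertices, 2, shift, "+")
  lm <- lapply(f$truth$landmarks, function(q) q + shift)
  fm <- measure_femur(mesh, lm)
  scene <- match_hip(fm, acet, fr)
  rot <- scene$femur_pose$rotation
  expect_lt(max(abs(rot - diag(3))), 2e-3)          # < 0.1 degree
  expect_lt(norm3(apply_rigid(scene$femur_pose, fm$FHC) - fm$FHC), 0.01)
})

test_that("3D offsets satisfy their definitional identities", {
  s <- make_matched(anteversion = 15)
  o <- compute_offsets3d(s$scene, s$cup)
  expect_equal(o$cup_femoral_diff, o$cup_offset3d - o$fo3d, tolerance = 1e-9)
  expect_gt(o$fo3d, 0)
  # fo3d is the point-to-line distance to the matched shaft axis
  expect_lt(abs(o$fo3d - point_line_distance(s$scene$FHC_world,
                                             s$scene$shaft_axis_world)), 1e-9)
  expect_lt(abs(o$fo3d - s$fm$fo3d), 1e-9)
  # triangle inequality between the three centres
  expect_lte(abs(o$cup_offset3d - o$fo3d), o$dist_cup_head + 1e-9)
  # coincident centres degenerate cleanly
  cup0 <- s$cup
  cup0$CC <- s$scene$FHC_world
  o0 <- compute_offsets3d(s$scene, cup0)
  expect_equal(o0$cup_femoral_diff, 0, tolerance = 1e-9)
  expect_equal(o0$dist_cup_head, 0, tolerance = 1e-9)
  expect_equal(o0$angle_cup_head, 0)
})

test_that("constructed medialisation appears in the cup-femoral difference", {
  diffs <- vapply(1:8, function(s) {
    f <- generate_femur(femur_params(anteversion = 0, noise_sd = 0, seed = s))
    p <- generate_hemipelvis(pelvis_params(wall_thickness = 5, noise_sd = 0,
                                           seed = s))
    row <- measure_hip(f$mesh, p$mesh, hip_landmarks(f$truth, p$truth),
                       cup_sizes = 2 * p$truth$acetabular_radius - 0.2)
    row$cup_femoral_diff
  }, numeric(1))
  # a near-full-size cup flush to a 5 mm-deep floor medialises by ~5 mm; at
  # zero anteversion the difference equals the mediolateral medialisation
  expect_lt(abs(mean(diffs) - 5), 0.5)
})
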