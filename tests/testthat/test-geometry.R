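test_that("sphere fit recovers exact spheres and refuses degenerate input", {
  pts <- sphere_points(100, center = c(1, 2, 3), radius = 24)
  for (method in c("algebraic", "geometric")) {
    fit <- fit_sphere(pts, method = method)
    expect_lt(norm3(fit$center - c(1, 2, 3)), 1e-9)
    expect_lt(abs(fit$radius - 24), 1e-9)
  }
  expect_error(fit_sphere(pts[1:3, ]), "at least 4")
  # coplanar circle: infinitely many spheres
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  expect_error(fit_sphere(cbind(cos(th), sin(th), 0)), "coplanar")
})

test_that("noisy sphere fits recover the centre and the geometric fit never
          does worse than the algebraic one", {
  set.seed(101)
  errs <- numeric(200)
  worse <- 0
  for (k in 1:200) {
    pts <- sphere_points(500, center = c(10, -5, 30), radius = 24) +
      matrix(rnorm(1500, 0, 0.5), ncol = 3)
    fa <- fit_sphere(pts, "algebraic")
    fg <- fit_sphere(pts, "geometric")
    obj <- function(f) {
      d <- sqrt(rowSums(sweep(pts, 2, f$center)^2))
      sum((d - f$radius)^2)
    }
    if (obj(fg) > obj(fa) + 1e-12) worse <- worse + 1
    errs[k] <- norm3(fg$center - c(10, -5, 30))
  }
  expect_lt(mean(errs), 0.15)
  expect_equal(worse, 0)
})

test_that("sphere fit is equivariant under rigid motion", {
  set.seed(7)
  pts <- sphere_points(200, center = c(3, 1, -2), radius = 20) +
    matrix(rnorm(600, 0, 0.3), ncol = 3)
  fit <- fit_sphere(pts)
  rot <- random_rotation(seed = 5)
  tr <- c(12, -7, 30)
  fit2 <- fit_sphere(sweep(pts %*% t(rot), 2, tr, "+"))
  expect_lt(norm3(fit2$center - (drop(rot %*% fit$center) + tr)), 1e-7)
  expect_lt(abs(fit2$radius - fit$radius), 1e-9)
})

test_that("axis fit reproduces collinear midpoints, two-point lines, and a
          stable distal-to-proximal orientation", {
  z <- seq(0, 50, by = 5)
  mids <- cbind(0, 0, z)
  ln <- fit_axis_from_section_midpoints(mids)
  expect_lt(norm3(ln$direction - c(0, 0, 1)), 1e-12)
  expect_lt(attr(ln, "rms"), 1e-12)

  two <- rbind(c(1, 1, 0), c(4, 5, 0))
  ln2 <- fit_axis_from_section_midpoints(two)
  expect_lt(norm3(ln2$direction - c(3, 4, 0) / 5), 1e-12)
  expect_lt(point_line_distance(c(1, 1, 0), ln2), 1e-12)

  # orientation follows the distal -> proximal ordering even under noise
  set.seed(3)
  for (k in 1:20) {
    d <- hipoffset:::unit_vector(rnorm(3))
    pts <- outer(seq(0, 60, by = 6), d) + matrix(rnorm(33, 0, 0.2), ncol = 3)
    fit <- fit_axis_from_section_midpoints(pts)
    expect_gt(sum(fit$direction * d), 0)
  }
  expect_error(fit_axis_from_section_midpoints(rbind(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
})

test_that("point-line distance matches a brute-force scalar minimisation", {
  expect_equal(point_line_distance(c(1, 0, 0), line3(c(0, 0, 0), c(0, 0, 1))), 1)
  expect_lt(point_line_distance(c(0, 0, 17), line3(c(0, 0, 0), c(0, 0, 1))), 1e-12)
  set.seed(11)
  for (k in 1:25) {
    p <- rnorm(3, 0, 20)
    a <- rnorm(3, 0, 20)
    d <- hipoffset:::unit_vector(rnorm(3))
    ln <- line3(a, d)
    brute <- stats::optimize(function(t) norm3(p - (a + t * d)),
                             c(-500, 500), tol = 1e-12)$objective
    expect_lt(abs(point_line_distance(p, ln) - brute), 1e-6)
  }
})

test_that("angles are unsigned degrees in [0, 180]", {
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero")
  set.seed(2)
  for (k in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    a <- angle_between(u, v)
    expect_gte(a, 0)
    expect_lte(a, 180)
    expect_equal(a, angle_between(v, u), tolerance = 1e-12)
  }
})

test_that("coronal projection drops the AP coordinate, is idempotent in-plane
          and never expands distances", {
  fr <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(project_to_coronal(c(3, 99, -4), fr), c(ml = 3, si = -4))
  expect_equal(project_to_coronal(c(3, 0, -4), fr), c(ml = 3, si = -4))
  set.seed(4)
  for (k in 1:20) {
    p1 <- rnorm(3, 0, 50); p2 <- rnorm(3, 0, 50)
    d2 <- norm3(project_to_coronal(p1, fr) - project_to_coronal(p2, fr))
    expect_lte(d2, norm3(p1 - p2) + 1e-12)
  }
  # two points differing only in AP project identically
  expect_equal(project_to_coronal(c(1, 5, 2), fr), project_to_coronal(c(1, -9, 2), fr))
})

test_that("anatomical frames demand orthonormal right-handed axes", {
  expect_error(anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
               "orthogonal")
  expect_error(anatomical_frame(c(0, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               "right-handed")
})

test_that("rigid transforms compose points correctly", {
  rot <- random_rotation(seed = 9)
  tf <- rigid_transform(rot, c(1, 2, 3))
  p <- c(4, -5, 6)
  expect_equal(apply_rigid(tf, p), drop(rot %*% p) + c(1, 2, 3))
  expect_error(rigid_transform(matrix(2 * diag(3), 3)), "rotation")
})
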