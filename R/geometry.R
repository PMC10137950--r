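# Primitive 3D estimators shared by every measurement stage: sphere fits,
# total-least-squares axes, distances, angles, frames and projections.

`%||%` <- function(x, y) if (is.null(x)) y else x

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || any(!is.finite(x))) {
    stop("expected a finite 3-vector", call. = FALSE)
  }
  x
}

vnorm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v) {
  v <- vec3(v)
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  points <- unname(as.matrix(points))
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
  if (any(!is.finite(points))) stop("points contain non-finite coordinates", call. = FALSE)
  points
}

#' Sphere in 3D
#'
#' @param center Numeric 3-vector, millimetres.
#' @param radius Positive radius in millimetres.
#' @return An object of class `sphere3`.
#' @export
sphere3 <- function(center, radius) {
  center <- vec3(center)
  radius <- as.numeric(radius)
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0) {
    stop("radius must be a single positive number", call. = FALSE)
  }
  structure(list(center = center, radius = radius), class = "sphere3")
}

#' @export
print.sphere3 <- function(x, ...) {
  cat(sprintf("<sphere3> center (%.3f, %.3f, %.3f) mm, radius %.3f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Line in 3D (point + unit direction)
#'
#' @param point Numeric 3-vector on the line.
#' @param direction Direction vector; normalised internally.
#' @return An object of class `line3`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = vec3(point), direction = unit_vector(direction)),
            class = "line3")
}

#' @export
print.line3 <- function(x, ...) {
  cat(sprintf("<line3> through (%.3f, %.3f, %.3f) along (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Plane in 3D (point + unit normal)
#'
#' @param point Numeric 3-vector on the plane.
#' @param normal Normal vector; normalised internally.
#' @return An object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = vec3(point), normal = unit_vector(normal)),
            class = "plane3")
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a 3D point cloud. The algebraic method solves the
#' linearised sphere equation by ordinary least squares; the geometric method
#' refines that solution with Gauss-Newton iterations minimising the sum of
#' squared radial residuals `(|p_i - c| - r)^2`, which is the fit used for
#' femoral head and acetabular socket centres.
#'
#' @param points n x 3 matrix (n >= 4, non-coplanar) of coordinates in mm.
#' @param method `"geometric"` (default) or `"algebraic"`.
#' @return A [sphere3()] with attributes `rms` (root-mean-square radial
#'   residual) and `method`.
#' @export
fit_sphere <- function(points, method = c("geometric", "algebraic")) {
  method <- match.arg(method)
  pts <- as_point_matrix(points)
  if (nrow(pts) < 4L) {
    stop("sphere fit needs at least 4 points", call. = FALSE)
  }
  ctr <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(ctr, nu = 0L, nv = 0L)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("sphere fit is degenerate: points are (nearly) coplanar", call. = FALSE)
  }

  a <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  beta <- qr.solve(a, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (r2 <= 0) stop("algebraic sphere fit collapsed", call. = FALSE)
  radius <- sqrt(r2)

  if (method == "geometric") {
    par <- c(center, radius)
    d <- sqrt(rowSums(sweep(pts, 2L, par[1:3])^2))
    obj <- sum((d - par[4])^2)
    for (iter in seq_len(100L)) {
      diffs <- sweep(pts, 2L, par[1:3])
      d <- sqrt(rowSums(diffs^2))
      d[d < 1e-12] <- 1e-12
      jac <- cbind(-diffs / d, -1)
      res <- d - par[4]
      step <- tryCatch(qr.solve(jac, -res), error = function(e) rep(0, 4))
      par_new <- par + step
      d_new <- sqrt(rowSums(sweep(pts, 2L, par_new[1:3])^2))
      obj_new <- sum((d_new - par_new[4])^2)
      if (!is.finite(obj_new) || obj_new > obj) break
      converged <- (obj - obj_new) < 1e-10 * max(obj, 1e-30)
      par <- par_new
      obj <- obj_new
      if (converged) break
    }
    center <- par[1:3]
    radius <- par[4]
  }

  d <- sqrt(rowSums(sweep(pts, 2L, center)^2))
  out <- sphere3(center, radius)
  attr(out, "rms") <- sqrt(mean((d - radius)^2))
  attr(out, "method") <- method
  out
}

#' Total-least-squares axis through section midpoints
#'
#' The femoral shaft axis is the line connecting the midpoints of the shaft
#' cross-sections; with more than two sections this is realised as the first
#' principal direction through the midpoint centroid. The direction is
#' oriented from the first (distal) towards the last (proximal) midpoint.
#'
#' @param midpoints n x 3 matrix of section midpoints ordered distal to
#'   proximal (n >= 2, not all identical).
#' @return A [line3()] with attribute `rms` (RMS perpendicular residual).
#' @export
fit_axis_from_section_midpoints <- function(midpoints) {
  pts <- as_point_matrix(midpoints)
  if (nrow(pts) < 2L) stop("axis fit needs at least 2 midpoints", call. = FALSE)
  centroid <- colMeans(pts)
  ctr <- sweep(pts, 2L, centroid)
  if (max(abs(ctr)) < 1e-12) {
    stop("axis fit is degenerate: all midpoints identical", call. = FALSE)
  }
  dec <- svd(ctr, nu = 0L)
  dir <- dec$v[, 1L]
  span <- pts[nrow(pts), ] - pts[1L, ]
  if (sum(dir * span) < 0) dir <- -dir
  out <- line3(centroid, dir)
  perp <- ctr - outer(drop(ctr %*% dir), dir)
  attr(out, "rms") <- sqrt(mean(rowSums(perp^2)))
  out
}

#' Perpendicular distance from a point to a line
#'
#' @param p Numeric 3-vector.
#' @param line A [line3()].
#' @return Distance in mm.
#' @export
point_line_distance <- function(p, line) {
  stopifnot(inherits(line, "line3"))
  v <- vec3(p) - line$point
  vnorm(v - sum(v * line$direction) * line$direction)
}

#' Orthogonal projection of a point onto a line
#'
#' @inheritParams point_line_distance
#' @return The closest point on the line, a 3-vector.
#' @export
project_point_on_line <- function(p, line) {
  stopifnot(inherits(line, "line3"))
  v <- vec3(p) - line$point
  line$point + sum(v * line$direction) * line$direction
}

#' Unsigned angle between two vectors, in degrees
#'
#' @param u,v Numeric 3-vectors (non-zero).
#' @return Angle in `[0, 180]` degrees.
#' @export
angle_between <- function(u, v) {
  u <- unit_vector(u)
  v <- unit_vector(v)
  # atan2 form is numerically stable near 0 and 180 degrees
  atan2(vnorm(cross3(u, v)), sum(u * v)) * 180 / pi
}

#' Anatomical coordinate frame
#'
#' Right-handed orthonormal frame with mediolateral (ml), anteroposterior
#' (ap, anterior positive) and superoinferior (si, superior positive) axes.
#' By convention ml points towards the patient's right, so "lateral" for a
#' given hip is `ml` for a right hip and `-ml` for a left hip.
#'
#' @param origin Frame origin in world coordinates (mm).
#' @param ml,ap,si Orthonormal axis vectors.
#' @param body `"femur"` or `"pelvis"`.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, ml, ap, si, body = c("pelvis", "femur")) {
  body <- match.arg(body)
  ml <- unit_vector(ml); ap <- unit_vector(ap); si <- unit_vector(si)
  g <- abs(c(sum(ml * ap), sum(ml * si), sum(ap * si)))
  if (any(g > 1e-10)) stop("frame axes are not orthogonal", call. = FALSE)
  if (det(cbind(ml, ap, si)) < 0) {
    stop("frame axes are not right-handed", call. = FALSE)
  }
  structure(list(origin = vec3(origin), ml = ml, ap = ap, si = si, body = body),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> %s, origin (%.2f, %.2f, %.2f) mm\n",
              x$body, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Orthographic projection onto the coronal plane
#'
#' Drops the anteroposterior coordinate of a point relative to a frame: the
#' parallel-beam AP-radiograph idealisation. Returns in-plane coordinates
#' (mediolateral, superoinferior) in mm.
#'
#' @param point A 3-vector or n x 3 matrix of world coordinates.
#' @param frame An [anatomical_frame()].
#' @return A length-2 vector, or n x 2 matrix, of `(ml, si)` coordinates.
#' @export
project_to_coronal <- function(point, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  pts <- as_point_matrix(point)
  rel <- sweep(pts, 2L, frame$origin)
  out <- cbind(ml = drop(rel %*% frame$ml), si = drop(rel %*% frame$si))
  if (nrow(out) == 1L) drop(out) else out
}

# --- rigid transforms -------------------------------------------------------

#' Rigid-body transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation 3-vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      det(rotation) < 0) {
    stop("rotation must be a proper 3 x 3 rotation matrix", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = vec3(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points 3-vector or n x 3 matrix.
#' @return Transformed coordinates with the input's shape.
#' @export
apply_rigid <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  pts <- as_point_matrix(points)
  out <- pts %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (nrow(out) == 1L) drop(out) else out
}

#' Random rotation matrix (uniform on SO(3))
#'
#' Utility for pose-invariance studies; uses the QR decomposition of a
#' Gaussian matrix with sign correction.
#'
#' @param seed Optional integer seed.
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  m <- matrix(stats::rnorm(9), 3L, 3L)
  qr_dec <- qr(m)
  q <- qr.Q(qr_dec)
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_local_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  force(code)
}
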