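# Parametric proximal-femur generator. Emulates a CT-derived bone surface:
# a sphere-capped head on an angled, anteverted neck joining a tubular
# shaft, with Gaussian noise along vertex normals standing in for 1 mm
# slice-reconstruction error. Every constructive parameter is emitted as
# ground truth so measurements can be scored by parameter recovery.

check_param <- function(value, name, lower = -Inf, upper = Inf,
                        open_lower = FALSE, open_upper = FALSE) {
  if (length(value) != 1L || !is.finite(value)) {
    stop(sprintf("parameter '%s' must be a single finite number", name), call. = FALSE)
  }
  bad_low <- if (open_lower) value <= lower else value < lower
  bad_up <- if (open_upper) value >= upper else value > upper
  if (bad_low || bad_up) {
    stop(sprintf("parameter '%s' = %g outside its domain %s%g, %g%s", name, value,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  }
  invisible(value)
}

#' Femur generator parameters
#'
#' All lengths in millimetres, angles in degrees. The neck-shaft angle is the
#' angle between the neck axis and the shaft axis measured on the medial side
#' (anatomically about 125-135 degrees); anteversion rotates the neck
#' anteriorly out of the coronal plane about the shaft axis.
#'
#' @param head_radius Femoral head radius (> 0).
#' @param neck_shaft_angle Degrees in (0, 180).
#' @param anteversion Degrees in `[-45, 60]`.
#' @param neck_length Distance from the neck base on the shaft axis to the
#'   head centre (> 0).
#' @param shaft_radius,shaft_length Shaft tube dimensions (> 0).
#' @param side `"right"` or `"left"`.
#' @param noise_sd Gaussian surface noise SD along vertex normals (>= 0).
#' @param seed Integer seed controlling the noise draw.
#' @return A list of class `femur_params`.
#' @export
femur_params <- function(head_radius = 24, neck_shaft_angle = 130,
                         anteversion = 15, neck_length = 48,
                         shaft_radius = 14, shaft_length = 120,
                         side = c("right", "left"), noise_sd = 0.5, seed = 1L) {
  side <- match.arg(side)
  check_param(head_radius, "head_radius", 0, Inf, open_lower = TRUE)
  check_param(neck_shaft_angle, "neck_shaft_angle", 0, 180,
              open_lower = TRUE, open_upper = TRUE)
  check_param(anteversion, "anteversion", -45, 60)
  check_param(neck_length, "neck_length", 0, Inf, open_lower = TRUE)
  check_param(shaft_radius, "shaft_radius", 0, Inf, open_lower = TRUE)
  check_param(shaft_length, "shaft_length", 0, Inf, open_lower = TRUE)
  check_param(noise_sd, "noise_sd", 0, Inf)
  check_param(as.numeric(seed), "seed", 0, 2^31 - 1)
  structure(list(head_radius = head_radius, neck_shaft_angle = neck_shaft_angle,
                 anteversion = anteversion, neck_length = neck_length,
                 shaft_radius = shaft_radius, shaft_length = shaft_length,
                 side = side, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "femur_params")
}

ring_points <- function(center, e1, e2, radius, psi) {
  sweep(outer(cos(psi), e1 * radius) + outer(sin(psi), e2 * radius),
        2L, center, "+")
}

connect_rings <- function(ring1, ring2, flip = FALSE) {
  k <- length(ring1)
  k1 <- c(seq_len(k)[-1L], 1L)
  f <- rbind(cbind(ring1, ring1[k1], ring2[k1]),
             cbind(ring1, ring2[k1], ring2))
  if (flip) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  f
}

fan_faces <- function(center, ring, flip = FALSE) {
  k <- length(ring)
  k1 <- c(seq_len(k)[-1L], 1L)
  f <- cbind(center, ring, ring[k1])
  if (flip) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  f
}

orient_faces <- function(vertices, faces, desired) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a; w <- c3 - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  bad <- rowSums(fn * desired) < 0
  faces[bad, ] <- faces[bad, c(1L, 3L, 2L), drop = FALSE]
  faces
}

apply_surface_noise <- function(mesh, noise_sd, seed) {
  if (noise_sd <= 0) return(mesh)
  normals <- vertex_normals(mesh)
  disp <- with_local_seed(seed, stats::rnorm(nrow(mesh$vertices), 0, noise_sd))
  mesh$vertices <- mesh$vertices + normals * disp
  mesh
}

#' Generate a synthetic proximal femur with ground truth
#'
#' Builds the femur in its local anatomical frame: +x lateral (towards the
#' generated side), +y anterior, +z superior; the shaft axis is the z axis
#' with the distal end at z = 0. The true 3D femoral offset is
#' `neck_length * sin(180 - neck_shaft_angle)`, the perpendicular distance
#' from the head centre to the shaft axis.
#'
#' @param params A [femur_params()].
#' @return A list with elements `mesh` (a [bone_surface()], vertex regions
#'   tagged `head`/`neck`/`shaft`) and `truth` (constructive ground truth:
#'   head centre/radius, shaft axis, reference point, true 3D offset,
#'   anteversion, and virtual condylar/trochanteric landmarks).
#' @export
generate_femur <- function(params) {
  stopifnot(inherits(params, "femur_params"))
  p <- params
  phi <- (180 - p$neck_shaft_angle) * pi / 180   # neck angle from +z
  av <- p$anteversion * pi / 180
  d_neck <- c(-sin(phi) * cos(av), sin(phi) * sin(av), cos(phi))
  neck_base <- c(0, 0, p$shaft_length)
  head_center <- neck_base + p$neck_length * d_neck
  neck_radius <- min(0.60 * p$head_radius, 0.90 * p$shaft_radius)
  weld_offset <- sqrt(p$head_radius^2 - neck_radius^2)
  if (p$neck_length <= weld_offset) {
    stop("parameter 'neck_length' too short for the head/neck geometry", call. = FALSE)
  }

  n_around <- 36L
  psi <- 2 * pi * (seq_len(n_around) - 1L) / n_around

  # basis perpendicular to the neck axis
  e1n <- unit_vector(cross3(d_neck, c(0, 0, 1)))
  e2n <- cross3(d_neck, e1n)

  verts <- NULL
  faces <- NULL
  regions <- character()
  add_verts <- function(v, region) {
    verts <<- rbind(verts, v)
    regions <<- c(regions, rep(region, nrow(v)))
    (nrow(verts) - nrow(v) + 1L):nrow(verts)
  }

  # shaft tube
  zs <- seq(0, p$shaft_length, length.out = max(2L, ceiling(p$shaft_length / 3)))
  shaft_rings <- lapply(zs, function(z) {
    add_verts(ring_points(c(0, 0, z), c(1, 0, 0), c(0, 1, 0), p$shaft_radius, psi),
              "shaft")
  })
  for (i in seq_len(length(shaft_rings) - 1L)) {
    faces <- rbind(faces, connect_rings(shaft_rings[[i]], shaft_rings[[i + 1L]]))
  }
  bottom_c <- add_verts(matrix(c(0, 0, 0), 1L), "shaft")
  top_c <- add_verts(matrix(neck_base, 1L), "shaft")
  faces <- rbind(faces,
                 fan_faces(bottom_c, shaft_rings[[1L]], flip = TRUE),
                 fan_faces(top_c, shaft_rings[[length(shaft_rings)]]))

  # neck tube from the base towards the head weld circle
  s_end <- p$neck_length - weld_offset
  ss <- seq(0, s_end, length.out = max(2L, ceiling(s_end / 2.5)))
  neck_rings <- lapply(ss, function(s) {
    add_verts(ring_points(neck_base + s * d_neck, e1n, e2n, neck_radius, psi), "neck")
  })
  for (i in seq_len(length(neck_rings) - 1L)) {
    faces <- rbind(faces, connect_rings(neck_rings[[i]], neck_rings[[i + 1L]]))
  }

  # spherical head cap, far pole (medial apex) down to the weld circle; the
  # neck's end ring lies exactly on the weld circle and closes the cap
  theta_weld <- pi - asin(neck_radius / p$head_radius)
  thetas <- seq(0, theta_weld, length.out = 24L)
  thetas <- thetas[-c(1L, length(thetas))]
  pole <- add_verts(matrix(head_center + p$head_radius * d_neck, 1L), "head")
  head_rings <- lapply(thetas, function(th) {
    ctr <- head_center + p$head_radius * cos(th) * d_neck
    add_verts(ring_points(ctr, e1n, e2n, p$head_radius * sin(th), psi), "head")
  })
  faces <- rbind(faces, fan_faces(pole, head_rings[[1L]]))
  for (i in seq_len(length(head_rings) - 1L)) {
    faces <- rbind(faces, connect_rings(head_rings[[i]], head_rings[[i + 1L]], flip = TRUE))
  }
  faces <- rbind(faces,
                 connect_rings(head_rings[[length(head_rings)]],
                               neck_rings[[length(neck_rings)]]))

  # enforce outward orientation component-wise
  fc <- (verts[faces[, 1L], ] + verts[faces[, 2L], ] + verts[faces[, 3L], ]) / 3
  freg <- regions[faces[, 1L]]
  desired <- matrix(0, nrow(faces), 3L)
  is_head <- freg == "head"
  desired[is_head, ] <- sweep(fc[is_head, , drop = FALSE], 2L, head_center)
  is_neck <- freg == "neck"
  if (any(is_neck)) {
    rel <- sweep(fc[is_neck, , drop = FALSE], 2L, neck_base)
    ax <- drop(rel %*% d_neck)
    desired[is_neck, ] <- rel - outer(ax, d_neck)
  }
  is_shaft <- freg == "shaft"
  rel <- fc[is_shaft, , drop = FALSE]
  radial <- cbind(rel[, 1], rel[, 2], 0)
  endcap <- abs(rel[, 3]) < 1e-9 | abs(rel[, 3] - p$shaft_length) < 1e-9 |
    sqrt(rel[, 1]^2 + rel[, 2]^2) < 0.999 * p$shaft_radius
  radial[endcap, ] <- rep(c(0, 0, 1), each = sum(endcap)) *
    sign(rel[endcap, 3] - p$shaft_length / 2)
  desired[is_shaft, ] <- radial
  faces <- orient_faces(verts, faces, desired)

  mesh <- bone_surface(verts, faces, side = "right", label = "femur",
                       regions = regions)
  mesh <- apply_surface_noise(mesh, p$noise_sd, p$seed)

  truth <- list(
    head_center = head_center,
    head_radius = p$head_radius,
    shaft_axis = line3(c(0, 0, 0), c(0, 0, 1)),
    reference_point = c(0, 0, head_center[3]),
    true_FO3D = p$neck_length * sin(phi),
    anteversion = p$anteversion,
    neck_shaft_angle = p$neck_shaft_angle,
    side = p$side,
    landmarks = list(
      lesser_trochanter = c(-p$shaft_radius, -4, p$shaft_length - 18),
      condyle_medial = c(-22, -12, -280),
      condyle_lateral = c(22, -12, -280)
    )
  )
  class(truth) <- "anatomy_truth"

  stopifnot(abs(point_line_distance(truth$head_center, truth$shaft_axis) -
                truth$true_FO3D) < 1e-9)

  if (p$side == "left") {
    mesh <- mirror_mesh(mesh)
    truth <- mirror_truth(truth)
  }
  list(mesh = mesh, truth = truth)
}

mirror_truth <- function(truth) {
  mirror_any <- function(x) {
    if (inherits(x, "line3")) {
      line3(mirror_point(x$point), mirror_point(x$direction))
    } else if (is.numeric(x) && length(x) == 3L) {
      mirror_point(x)
    } else if (is.list(x)) {
      lapply(x, mirror_any)
    } else {
      x
    }
  }
  out <- lapply(truth, function(f) {
    if (is.numeric(f) && length(f) == 1L) f else mirror_any(f)
  })
  out$side <- if (truth$side == "right") "left" else "right"
  class(out) <- "anatomy_truth"
  out
}
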