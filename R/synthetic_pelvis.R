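# Parametric hemipelvis generator: a hemispherical acetabular socket carved
# into a bony shell of finite thickness, with a recessed cotyloid fossa
# whose floor is the "true floor" of the acetabulum, a superior roof whose
# lateral edge realises a prescribed centre-edge angle, and the anterior
# pelvic plane landmarks that define the pelvic coordinate frame.

#' Hemipelvis generator parameters
#'
#' Lengths in millimetres, angles in degrees. `cup_face_inclination` and
#' `cup_face_anteversion` orient the native socket opening (radiographic
#' convention: inclination tilts the face normal inferiorly from the
#' mediolateral axis in the coronal plane, anteversion tilts it anteriorly).
#' `wall_thickness` is the depth of the cotyloid fossa floor beyond the
#' articular sphere: the bone that a cup seated flush to the true floor
#' medialises into. `teardrop_offset` is the mediolateral distance from the
#' teardrop landmark to the socket centre (the radiographic acetabular
#' offset by construction).
#'
#' @param acetabular_radius Socket sphere radius (> 0).
#' @param wall_thickness Fossa depth beyond the socket sphere (>= 0).
#' @param cup_face_inclination,cup_face_anteversion Native socket face
#'   orientation, degrees.
#' @param CE_angle Target lateral centre-edge angle in `[0, 90)`; realised by
#'   root-finding on the projected roof-edge angle to 0.5 degrees.
#' @param teardrop_offset Mediolateral teardrop-to-centre distance (> 0).
#' @param side `"right"` or `"left"`.
#' @param noise_sd Gaussian surface noise SD along normals (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param fossa_half_angle Polar half-angle of the recessed fossa about the
#'   medial pole, degrees; must exceed the face-normal tilt so the medial
#'   pole of the socket lies inside the fossa.
#' @return A list of class `pelvis_params`.
#' @export
pelvis_params <- function(acetabular_radius = 26, wall_thickness = 5,
                          cup_face_inclination = 40, cup_face_anteversion = 18,
                          CE_angle = 30, teardrop_offset = 34,
                          side = c("right", "left"), noise_sd = 0.5, seed = 1L,
                          fossa_half_angle = 55) {
  side <- match.arg(side)
  check_param(acetabular_radius, "acetabular_radius", 0, Inf, open_lower = TRUE)
  check_param(wall_thickness, "wall_thickness", 0, Inf)
  check_param(CE_angle, "CE_angle", 0, 90, open_upper = TRUE)
  check_param(cup_face_inclination, "cup_face_inclination", 0, 80)
  check_param(cup_face_anteversion, "cup_face_anteversion", -30, 45)
  check_param(teardrop_offset, "teardrop_offset", 0, Inf, open_lower = TRUE)
  check_param(noise_sd, "noise_sd", 0, Inf)
  check_param(fossa_half_angle, "fossa_half_angle", 10, 80)
  check_param(as.numeric(seed), "seed", 0, 2^31 - 1)
  n <- socket_face_normal(cup_face_inclination, cup_face_anteversion)
  tilt <- angle_between(n, c(1, 0, 0))
  if (tilt > fossa_half_angle - 4) {
    stop(sprintf(paste("parameters 'cup_face_inclination'/'cup_face_anteversion':",
                       "face normal tilts %.1f deg from the mediolateral axis,",
                       "leaving the medial pole outside the fossa (half-angle %g deg)"),
                 tilt, fossa_half_angle), call. = FALSE)
  }
  structure(list(acetabular_radius = acetabular_radius,
                 wall_thickness = wall_thickness,
                 cup_face_inclination = cup_face_inclination,
                 cup_face_anteversion = cup_face_anteversion,
                 CE_angle = CE_angle, teardrop_offset = teardrop_offset,
                 side = side, noise_sd = noise_sd, seed = as.integer(seed),
                 fossa_half_angle = fossa_half_angle),
            class = "pelvis_params")
}

# Radiographic face normal in the right-side frame (+x lateral, +y anterior,
# +z superior): inclination i tilts inferiorly in the coronal plane,
# anteversion a tilts anteriorly out of it.
socket_face_normal <- function(inclination, anteversion) {
  i <- inclination * pi / 180
  a <- anteversion * pi / 180
  c(cos(a) * cos(i), sin(a), -cos(a) * sin(i))
}

#' Generate a synthetic hemipelvis with ground truth
#'
#' Builds the acetabular region of a hemipelvis in the anterior-pelvic-plane
#' frame (+x towards the patient's right, +y anterior, +z superior, origin
#' mid-ASIS; a right hip is generated and mirrored for `side = "left"`).
#' The socket is a spherical cavity whose superior roof is extended (or cut
#' back) until the projected centre-edge angle of its lateral edge matches
#' `CE_angle`; the cotyloid fossa around the medial pole is recessed by
#' `wall_thickness`, so the most medial point of the internal wall is the
#' true acetabular floor.
#'
#' @param params A [pelvis_params()].
#' @return A list with `mesh` (a [bone_surface()], regions tagged
#'   `lunate`/`fossa`/`outer`/`band`) and `truth` (socket centre and radius,
#'   true floor point, TAL endpoints, APP landmarks, teardrop, lateral
#'   acetabular edge, native face orientation).
#' @export
generate_hemipelvis <- function(params) {
  stopifnot(inherits(params, "pelvis_params"))
  p <- params
  ra <- p$acetabular_radius
  center <- c(45, -20, -85)
  n_face <- socket_face_normal(p$cup_face_inclination, p$cup_face_anteversion)
  w0 <- unit_vector(c(0, 0, 1) - sum(c(0, 0, 1) * n_face) * n_face)  # superior-most
  u0 <- cross3(n_face, w0)

  # polar direction from the socket centre at polar angle theta (from the
  # medial pole -n_face) and azimuth psi (0 = superior)
  s_dir <- function(theta, psi) {
    -cos(theta) * n_face + sin(theta) * (cos(psi) * w0 + sin(psi) * u0)
  }

  # roof extension e realising the centre-edge angle: the lateral edge is the
  # roof boundary point at the superior azimuth, CE measured in the coronal
  # projection from the socket centre
  proj_angle <- function(e) {
    d <- s_dir(pi / 2 + e, 0)
    atan2(d[1], d[3]) * 180 / pi
  }
  f <- function(e) proj_angle(e) - p$CE_angle
  lo <- -(p$cup_face_inclination - 1) * pi / 180
  hi <- 80 * pi / 180
  if (f(lo) * f(hi) > 0) {
    stop("parameter 'CE_angle' unreachable for this face orientation", call. = FALSE)
  }
  e_roof <- stats::uniroot(f, c(lo, hi), tol = 1e-4 * pi / 180)$root
  lateral_edge <- center + ra * s_dir(pi / 2 + e_roof, 0)

  theta_f <- p$fossa_half_angle * pi / 180
  bump <- function(psi) {
    psi <- atan2(sin(psi), cos(psi))  # wrap to (-pi, pi]
    ifelse(abs(psi) < pi / 2, cos(psi)^2, 0)
  }
  theta_max <- function(psi) pi / 2 + e_roof * bump(psi)

  n_psi <- 48L
  n_theta <- 18L
  psi <- 2 * pi * (seq_len(n_psi) - 1L) / n_psi
  shell <- 7  # outer cortical shell thickness, fixed construction constant
  rb <- ra + shell

  verts <- NULL
  faces <- NULL
  regions <- character()
  add_verts <- function(v, region) {
    verts <<- rbind(verts, v)
    regions <<- c(regions, rep(region, nrow(v)))
    (nrow(verts) - nrow(v) + 1L):nrow(verts)
  }
  surf_rings <- function(radius, fossa_shift, tag_inner) {
    apex <- center + radius * s_dir(0, 0)
    if (tag_inner) apex <- apex - c(fossa_shift, 0, 0)
    apex_id <- add_verts(matrix(apex, 1L),
                         if (tag_inner) "fossa" else "outer")
    rings <- lapply(seq_len(n_theta), function(j) {
      th <- theta_max(psi) * j / n_theta
      pts <- t(vapply(seq_along(psi),
                      function(k) center + radius * s_dir(th[k], psi[k]),
                      numeric(3)))
      if (tag_inner) {
        in_fossa <- th < theta_f
        pts[in_fossa, 1] <- pts[in_fossa, 1] - fossa_shift
        tags <- ifelse(in_fossa, "fossa", "lunate")
        idx <- add_verts(pts, "tmp")
        regions[idx] <<- tags
        idx
      } else {
        add_verts(pts, "outer")
      }
    })
    list(apex = apex_id, rings = rings)
  }

  inner <- surf_rings(ra, p$wall_thickness, tag_inner = TRUE)
  outer <- surf_rings(rb, 0, tag_inner = FALSE)

  faces <- rbind(faces, fan_faces(inner$apex, inner$rings[[1L]]))
  for (j in seq_len(n_theta - 1L)) {
    faces <- rbind(faces, connect_rings(inner$rings[[j]], inner$rings[[j + 1L]]))
  }
  faces <- rbind(faces, fan_faces(outer$apex, outer$rings[[1L]]))
  for (j in seq_len(n_theta - 1L)) {
    faces <- rbind(faces, connect_rings(outer$rings[[j]], outer$rings[[j + 1L]]))
  }
  band <- connect_rings(inner$rings[[n_theta]], outer$rings[[n_theta]])
  band_rows <- nrow(faces) + seq_len(nrow(band))
  faces <- rbind(faces, band)

  # outward-from-bone orientation: inner surface faces point at the centre,
  # outer surface faces point away, the rim band points out of the opening
  fc <- (verts[faces[, 1L], ] + verts[faces[, 2L], ] + verts[faces[, 3L], ]) / 3
  desired <- sweep(fc, 2L, center)            # radial, correct for outer
  inner_face <- regions[faces[, 1L]] %in% c("lunate", "fossa")
  desired[inner_face, ] <- -desired[inner_face, , drop = FALSE]
  desired[band_rows, ] <- rep(n_face, each = length(band_rows))
  faces <- orient_faces(verts, faces, desired)

  mesh <- bone_surface(verts, faces, side = "right", label = "hemipelvis",
                       regions = regions)
  mesh <- apply_surface_noise(mesh, p$noise_sd, p$seed)

  tal_mid <- center + ra * s_dir(pi / 2, pi)   # inferior rim (acetabular notch)
  tal_dir <- unit_vector(c(n_face[2], -n_face[1], 0))
  teardrop <- center + c(-p$teardrop_offset, 4, -(ra + 4))

  truth <- list(
    acetabular_center = center,
    acetabular_radius = ra,
    true_floor_point = center - c(ra + p$wall_thickness, 0, 0),
    wall_thickness = p$wall_thickness,
    rim_max_diameter = 2 * ra,
    lateral_acetabular_edge = lateral_edge,
    CE_angle = p$CE_angle,
    face_normal = n_face,
    face_inclination = p$cup_face_inclination,
    face_anteversion = p$cup_face_anteversion,
    TAL_endpoints = list(anterior = tal_mid + 9 * tal_dir,
                         posterior = tal_mid - 9 * tal_dir),
    teardrop_inferior_edge = teardrop,
    APP_landmarks = list(ASIS_R = c(118, 0, 0), ASIS_L = c(-118, 0, 0),
                         pubic_tubercle_R = c(28, 0, -98),
                         pubic_tubercle_L = c(-28, 0, -98)),
    side = p$side
  )
  class(truth) <- "anatomy_truth"

  if (p$side == "left") {
    mesh <- mirror_mesh(mesh)
    truth <- mirror_truth(truth)
    # the left ASIS/pubic landmarks swap names when mirrored
    ap <- truth$APP_landmarks
    truth$APP_landmarks <- list(ASIS_R = ap$ASIS_L, ASIS_L = ap$ASIS_R,
                                pubic_tubercle_R = ap$pubic_tubercle_L,
                                pubic_tubercle_L = ap$pubic_tubercle_R)
  }
  list(mesh = mesh, truth = truth)
}
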