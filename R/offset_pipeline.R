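# Femur-to-pelvis matching at the native hip rotation centre and the 3D
# offset quantities measured on the matched scene.

#' Match the femur to the pelvis at the native hip centre
#'
#' Rigidly repositions the measured femur so the femoral head centre
#' coincides with the native acetabular centre (the hip rotation centre),
#' with the shaft axis aligned to the pelvic superoinferior axis in a
#' neutral limb pose and the rotation about the shaft axis chosen so the
#' measured anteversion is preserved relative to the pelvic frame.
#'
#' @param femur_meas A [measure_femur()] result.
#' @param acet A [measure_acetabulum()] result.
#' @param pelvis_frame Pelvic [anatomical_frame()].
#' @param cup Optional [place_cup()] plan; its centre is carried into the
#'   scene as `CC_world`.
#' @return An object of class `matched_scene` with the femur pose (a
#'   [rigid_transform()] from femur-local to world coordinates) and the
#'   world-space femoral head centre, reference point and cup centre.
#' @export
match_hip <- function(femur_meas, acet, pelvis_frame, cup = NULL) {
  stopifnot(inherits(femur_meas, "femur_measurement"),
            inherits(acet, "acetabulum_measurement"),
            inherits(pelvis_frame, "anatomical_frame"))
  lat <- lateral_axis(pelvis_frame, acet$side)
  av <- femur_meas$anteversion
  if (is.na(av)) av <- 0
  av_r <- av * pi / 180

  hrc <- acet$native_center
  fhc_world <- hrc
  # neck direction (reference point -> FHC) in the matched pose: medial,
  # rotated anteriorly by the anteversion, perpendicular to the vertical axis
  u_med <- -cos(av_r) * lat + sin(av_r) * pelvis_frame$ap
  ref_world <- fhc_world - femur_meas$fo3d * u_med
  axis_world <- line3(ref_world, pelvis_frame$si)

  # rigid transform femur-local -> world mapping the measured triad onto the
  # target triad
  z_l <- femur_meas$shaft_axis$direction
  v_neck <- femur_meas$FHC - femur_meas$reference_point
  v_t <- v_neck - sum(v_neck * z_l) * z_l
  if (vnorm(v_t) < 1e-9) {
    v_t <- if (abs(z_l[1]) < 0.9) cross3(z_l, c(1, 0, 0)) else cross3(z_l, c(0, 1, 0))
  }
  v_t <- v_t / vnorm(v_t)
  local_basis <- cbind(v_t, cross3(z_l, v_t), z_l)
  target_basis <- cbind(u_med, cross3(pelvis_frame$si, u_med), pelvis_frame$si)
  rot <- target_basis %*% t(local_basis)
  pose <- rigid_transform(rot, hrc - drop(rot %*% femur_meas$FHC))

  structure(list(femur_pose = pose, pelvis_frame = pelvis_frame,
                 FHC_world = fhc_world, HRC_world = hrc,
                 reference_point_world = ref_world,
                 shaft_axis_world = axis_world,
                 CC_world = if (is.null(cup)) NULL else cup$CC,
                 anteversion = av, side = acet$side),
            class = "matched_scene")
}

#' @export
print.matched_scene <- function(x, ...) {
  cat(sprintf("<matched_scene> (%s) FHC at HRC (%.2f, %.2f, %.2f) mm\n",
              x$side, x$FHC_world[1], x$FHC_world[2], x$FHC_world[3]))
  invisible(x)
}

#' 3D offsets of a matched hip
#'
#' The 3D femoral offset is the distance between the reference point and the
#' femoral head centre, and the 3D cup offset the distance between the
#' reference point and the cup centre; because the reference point is the
#' orthogonal projection of the FHC onto the shaft axis, the 3D femoral
#' offset equals the point-to-line distance from the FHC to the axis. The
#' coronally projected counterparts (parallel projection along the
#' anteroposterior axis) are reported alongside, as is the cup-to-head
#' centre distance and the angle subtended at the reference point.
#'
#' @param scene A [match_hip()] scene.
#' @param cup A [place_cup()] plan (may be omitted if the scene carries
#'   `CC_world`).
#' @return A one-row [tibble::tibble()]: `fo3d`, `cup_offset3d`,
#'   `cup_femoral_diff`, `dist_cup_head`, `angle_cup_head`,
#'   `femoral_anteversion`, `fo3d_coronal`, `cup_offset3d_coronal`.
#' @export
compute_offsets3d <- function(scene, cup = NULL) {
  stopifnot(inherits(scene, "matched_scene"))
  cc <- if (!is.null(cup)) cup$CC else scene$CC_world
  if (is.null(cc)) stop("no cup plan available for the 3D cup offset", call. = FALSE)
  ref <- scene$reference_point_world
  fhc <- scene$FHC_world

  fo3d <- vnorm(fhc - ref)
  cup_offset3d <- vnorm(cc - ref)
  dist_cup_head <- vnorm(cc - fhc)
  angle_cup_head <- if (dist_cup_head < 1e-9) 0 else angle_between(fhc - ref, cc - ref)

  pr <- project_to_coronal(rbind(ref, fhc, cc), scene$pelvis_frame)
  fo3d_cor <- vnorm(pr[2, ] - pr[1, ])
  cup_cor <- vnorm(pr[3, ] - pr[1, ])

  tibble::tibble(
    fo3d = fo3d,
    cup_offset3d = cup_offset3d,
    cup_femoral_diff = cup_offset3d - fo3d,
    dist_cup_head = dist_cup_head,
    angle_cup_head = angle_cup_head,
    femoral_anteversion = scene$anteversion,
    fo3d_coronal = fo3d_cor,
    cup_offset3d_coronal = cup_cor
  )
}
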