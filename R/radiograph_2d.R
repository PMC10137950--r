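# Simulated AP-radiograph measurements on the orthographically projected
# matched scene: centre-edge angle, femoral, acetabular and global offsets.

project_landmark <- function(p, frame) {
  p <- as.numeric(p)
  if (length(p) == 2L) return(p)
  project_to_coronal(p, frame)
}

#' 2D offset measurements on the simulated AP radiograph
#'
#' The scene is projected orthographically onto the coronal plane of the
#' anterior pelvic plane frame ("vertical" is the pelvic superoinferior
#' axis). The 2D femoral offset is the perpendicular distance from the
#' projected hip rotation centre to the projected femoral shaft axis; the
#' acetabular offset is the horizontal distance from the projected HRC to
#' the vertical line through the projected inferior teardrop edge; the
#' global offset is their sum; the centre-edge angle is measured between the
#' vertical through the HRC and the line to the lateral acetabular edge.
#'
#' @param scene A [match_hip()] scene.
#' @param landmarks_2d Named list with `teardrop` and `lateral_edge`, each a
#'   world 3-vector (projected internally) or an already projected
#'   `(ml, si)` pair.
#' @return A one-row [tibble::tibble()]: `ce_angle`, `fo2d`, `ao2d`, `go2d`.
#' @export
measure_2d <- function(scene, landmarks_2d) {
  stopifnot(inherits(scene, "matched_scene"))
  if (is.null(landmarks_2d$teardrop) || is.null(landmarks_2d$lateral_edge)) {
    stop("2D measurement needs 'teardrop' and 'lateral_edge' landmarks", call. = FALSE)
  }
  frame <- scene$pelvis_frame
  s <- if (scene$side == "right") 1 else -1

  hrc <- project_to_coronal(scene$HRC_world, frame)
  ref <- project_to_coronal(scene$reference_point_world, frame)
  ax2 <- project_to_coronal(scene$reference_point_world +
                              20 * scene$shaft_axis_world$direction, frame)
  td <- project_landmark(landmarks_2d$teardrop, frame)
  edge <- project_landmark(landmarks_2d$lateral_edge, frame)

  # perpendicular distance from the projected HRC to the projected axis
  a_dir <- ax2 - ref
  a_dir <- a_dir / sqrt(sum(a_dir^2))
  rel <- hrc - ref
  fo2d <- sqrt(max(0, sum(rel^2) - sum(rel * a_dir)^2))

  ao2d <- abs(hrc[1] - td[1])
  ce <- atan2(s * (edge[1] - hrc[1]), edge[2] - hrc[2]) * 180 / pi

  tibble::tibble(ce_angle = ce, fo2d = fo2d, ao2d = ao2d, go2d = ao2d + fo2d)
}

#' Pair the 2D and 3D offsets of one specimen
#'
#' Emits the 3D-minus-2D femoral offset difference together with the
#' femoral anteversion, the quantity whose cohort-level correlation links
#' out-of-plane neck orientation to radiographic offset underestimation.
#'
#' @param offsets2d A [measure_2d()] row.
#' @param offsets3d A [compute_offsets3d()] row.
#' @return A one-row [tibble::tibble()] combining both with
#'   `fo_diff_3d_2d = fo3d - fo2d`.
#' @export
compare_2d_3d <- function(offsets2d, offsets3d) {
  dplyr::bind_cols(offsets2d, offsets3d) |>
    dplyr::mutate(fo_diff_3d_2d = .data$fo3d - .data$fo2d)
}
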