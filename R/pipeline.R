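# End-to-end measurement of one hip and of a whole cohort: femoral and
# acetabular morphometry, virtual cup implantation, matching at the native
# hip centre, 3D offsets and the simulated AP-radiograph measures.

#' Measure one hip end to end
#'
#' Runs the full pipeline on a femur/hemipelvis mesh pair: femoral
#' morphometry, APP frame construction, acetabular morphometry, virtual cup
#' implantation, femur-to-pelvis matching, 3D offsets and simulated
#' radiographic 2D offsets.
#'
#' @param femur,pelvis [bone_surface()] meshes of the same side.
#' @param landmarks Named list: `APP_landmarks` (for [build_app_frame()]),
#'   `TAL_endpoints`, `teardrop_inferior_edge`, `lateral_acetabular_edge`,
#'   and optionally `condyle_medial`/`condyle_lateral` for anteversion.
#' @param cup_sizes,inclination,flush Passed to [place_cup()].
#' @param spacing Shaft section spacing, mm.
#' @return A one-row [tibble::tibble()] combining [measure_2d()],
#'   [compute_offsets3d()], `fo_diff_3d_2d`, and the cup diameter, native
#'   socket radius and rim diameter.
#' @export
measure_hip <- function(femur, pelvis, landmarks,
                        cup_sizes = seq(38, 66, by = 2), inclination = 40,
                        flush = "mediolateral", spacing = 5) {
  if (femur$side != pelvis$side) {
    stop("femur and pelvis sides disagree", call. = FALSE)
  }
  fm <- measure_femur(femur, landmarks = landmarks, spacing = spacing)
  frame <- build_app_frame(landmarks$APP_landmarks)
  acet <- measure_acetabulum(pelvis, frame, landmarks)
  cup <- place_cup(acet, frame, cup_sizes = cup_sizes,
                   inclination = inclination, flush = flush)
  scene <- match_hip(fm, acet, frame, cup = cup)
  o3 <- compute_offsets3d(scene, cup)
  o2 <- measure_2d(scene, list(teardrop = landmarks$teardrop_inferior_edge,
                               lateral_edge = landmarks$lateral_acetabular_edge))
  compare_2d_3d(o2, o3) |>
    dplyr::mutate(cup_diameter = cup$diameter,
                  cup_anteversion = cup$anteversion,
                  native_radius = acet$native_radius,
                  rim_max_diameter = acet$rim_max_diameter,
                  measured_head_radius = fm$head_radius)
}

truth_landmarks <- function(truth) {
  pt <- truth$pelvis
  c(truth$femur$landmarks,
    list(APP_landmarks = pt$APP_landmarks,
         TAL_endpoints = pt$TAL_endpoints,
         teardrop_inferior_edge = pt$teardrop_inferior_edge,
         lateral_acetabular_edge = pt$lateral_acetabular_edge))
}

#' Measure every specimen of a synthetic cohort
#'
#' Applies [measure_hip()] to each row of a [generate_cohort()] table, using
#' the generator's landmark truth for the landmark file, and returns the
#' cohort measurement table (one row per hip) with demographics and ground
#' truth carried alongside.
#'
#' @param cohort A [generate_cohort()] tibble with mesh list-columns.
#' @param ... Passed to [measure_hip()].
#' @return A [tibble::tibble()], one row per specimen.
#' @export
measure_cohort <- function(cohort, ...) {
  stopifnot(all(c("femur", "pelvis", "truth") %in% names(cohort)))
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    res <- tryCatch(
      measure_hip(cohort$femur[[i]], cohort$pelvis[[i]],
                  truth_landmarks(cohort$truth[[i]]), ...),
      error = function(e) {
        stop(sprintf("specimen %d (measurement): %s", cohort$specimen[i],
                     conditionMessage(e)), call. = FALSE)
      })
    res
  })
  keep <- intersect(c("specimen", "sex", "side", "age", "body_length", "bmi",
                      "fo3d_true", "femoral_anteversion", "wall_thickness",
                      "teardrop_offset", "ce_angle", "acetabular_radius"),
                    names(cohort))
  meta <- cohort[, keep]
  names(meta)[names(meta) == "femoral_anteversion"] <- "anteversion_true"
  names(meta)[names(meta) == "ce_angle"] <- "ce_angle_true"
  dplyr::bind_cols(meta, dplyr::bind_rows(rows))
}
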