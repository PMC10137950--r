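# Published normative cohort summary used to calibrate the synthetic cohort
# and for the definitional offset identities.

#' Reference hip offset cohort summary
#'
#' Sex-stratified summary (mean, SD) of radiographic and 3D hip parameters
#' for a 66-hip adult cohort (28 men, 38 women) with spherical femoral heads
#' and centre-edge angle >= 20 degrees, measured on standardised AP
#' radiographs and CT-based 3D surface models. These printed values are the
#' calibration targets of [cohort_distributions()] and the inputs to the
#' definitional identities [global_offset()] and [cup_femoral_difference()].
#'
#' Parameters: demographics (`age` years, `body_length` cm, `bmi` kg/m^2),
#' radiographic 2D (`ce_angle` deg, `global_offset`, `acetabular_offset`,
#' `femoral_offset` mm) and 3D (`fo3d`, `cup_offset3d`, `cup_femoral_diff`,
#' `dist_cup_head` mm, `angle_cup_head`, `femoral_anteversion` deg).
#'
#' @return A [tibble::tibble()] with columns `parameter`, `group`
#'   (`"men"`/`"women"`), `n`, `mean`, `sd`.
#' @export
reference_offset_table <- function() {
  men <- tibble::tribble(
    ~parameter, ~mean, ~sd,
    "age", 52.5, 15.5,
    "body_length", 169.4, 5.6,
    "bmi", 23.5, 3.2,
    "ce_angle", 31.9, 5.3,
    "global_offset", 80.9, 8.8,
    "acetabular_offset", 37.7, 4.0,
    "femoral_offset", 43.2, 8.3,
    "fo3d", 42.1, 4.8,
    "cup_offset3d", 48.4, 5.1,
    "cup_femoral_diff", 6.3, 1.9,
    "dist_cup_head", 8.1, 3.0,
    "angle_cup_head", 6.2, 4.3,
    "femoral_anteversion", 13.2, 9.6
  )
  women <- tibble::tribble(
    ~parameter, ~mean, ~sd,
    "age", 58.0, 15.7,
    "body_length", 154.9, 4.0,
    "bmi", 23.6, 4.5,
    "ce_angle", 28.1, 6.8,
    "global_offset", 72.6, 5.9,
    "acetabular_offset", 34.2, 2.4,
    "femoral_offset", 38.4, 5.0,
    "fo3d", 38.4, 3.6,
    "cup_offset3d", 43.3, 3.4,
    "cup_femoral_diff", 4.9, 1.8,
    "dist_cup_head", 7.2, 2.3,
    "angle_cup_head", 7.1, 3.4,
    "femoral_anteversion", 21.2, 9.9
  )
  dplyr::bind_rows(
    dplyr::mutate(men, group = "men", n = 28L),
    dplyr::mutate(women, group = "women", n = 38L)
  ) |>
    dplyr::select("parameter", "group", "n", "mean", "sd")
}

#' Global offset from its components
#'
#' The global offset is by definition the sum of the acetabular offset (the
#' horizontal distance from the hip rotation centre to the vertical teardrop
#' reference line) and the femoral offset (the perpendicular distance from
#' the HRC to the femoral shaft axis).
#'
#' @param acetabular_offset,femoral_offset Offsets in mm (vectorised).
#' @return `acetabular_offset + femoral_offset`, mm.
#' @export
global_offset <- function(acetabular_offset, femoral_offset) {
  acetabular_offset + femoral_offset
}

#' Cup-femoral offset difference (hip centre medialisation)
#'
#' @param cup_offset,femoral_offset 3D offsets in mm (vectorised).
#' @return `cup_offset - femoral_offset`, mm: how far the reconstructed hip
#'   centre is medialised relative to the native femoral offset.
#' @export
cup_femoral_difference <- function(cup_offset, femoral_offset) {
  cup_offset - femoral_offset
}

#' Pooled mean across groups
#'
#' @param means Group means.
#' @param ns Group sizes.
#' @return The size-weighted pooled mean.
#' @export
pooled_mean <- function(means, ns) {
  sum(means * ns) / sum(ns)
}
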