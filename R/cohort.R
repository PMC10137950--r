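# Synthetic study cohort: per-specimen anatomical parameters drawn from
# truncated normal distributions calibrated to the reference cohort summary,
# realised as paired femur/hemipelvis meshes with ground truth.

rtrunc_norm1 <- function(mean, sd, lower, upper, max_retries = 100L) {
  if (sd < 0) stop("distribution sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate distribution mean outside its bounds", call. = FALSE)
    }
    return(mean)
  }
  for (i in seq_len(max_retries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated normal sampling exhausted its retries", call. = FALSE)
}

#' Default cohort parameter distributions
#'
#' Per-parameter mean/SD (truncated normal bounds included) for the
#' synthetic cohort. Demographics, centre-edge angle, femoral anteversion
#' and the target 3D femoral offset are taken per sex from
#' [reference_offset_table()]; purely constructive parameters (head radius,
#' neck-shaft angle, shaft dimensions, acetabular cartilage allowance,
#' medial wall thickness, socket face orientation, teardrop margin) use
#' field-typical values for an adult hip.
#'
#' @return A [tibble::tibble()] with columns `parameter`, `group`, `mean`,
#'   `sd`, `lower`, `upper`.
#' @export
cohort_distributions <- function() {
  ref <- reference_offset_table()
  ref_par <- function(par, group) {
    row <- ref[ref$parameter == par & ref$group == group, ]
    c(mean = row$mean, sd = row$sd)
  }
  rows <- list()
  add <- function(parameter, group, mean, sd, lower, upper) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      parameter = parameter, group = group, mean = mean, sd = sd,
      lower = lower, upper = upper)
  }
  for (g in c("men", "women")) {
    for (par in c("age", "body_length", "bmi")) {
      v <- ref_par(par, g)
      add(par, g, v["mean"], v["sd"],
          if (par == "age") 20 else -Inf, Inf)
    }
    v <- ref_par("ce_angle", g)
    add("ce_angle", g, v["mean"], v["sd"], 20, 48)   # dysplastic hips excluded
    v <- ref_par("femoral_anteversion", g)
    add("femoral_anteversion", g, v["mean"], v["sd"], -20, 50)
    v <- ref_par("fo3d", g)
    add("fo3d", g, v["mean"], v["sd"], 28, 58)
  }
  add("head_radius", "men", 24, 1.2, 19, 28)
  add("head_radius", "women", 21.5, 1.1, 17, 26)
  for (g in c("men", "women")) {
    add("neck_shaft_angle", g, 128, 5, 112, 145)
    add("shaft_radius", g, 14, 1, 11, 17)
    add("shaft_length", g, 120, 6, 100, 140)
    add("cartilage", g, 2.5, 0.3, 1.5, 3.5)
    add("wall_thickness", g, 5, 1.5, 1.5, 9)
    add("cup_face_inclination", g, 40, 4, 30, 50)
    add("cup_face_anteversion", g, 18, 5, 5, 32)
    add("teardrop_margin", g, 3, 0.8, 1, 5.5)
  }
  dplyr::bind_rows(rows)
}

draw_specimen_params <- function(sex, dists, seed) {
  d <- dists[dists$group == sex, ]
  if (!nrow(d)) stop("empty distribution table for group ", sex, call. = FALSE)
  get <- function(par) {
    row <- d[d$parameter == par, ]
    if (!nrow(row)) stop("distribution table lacks parameter ", par, call. = FALSE)
    row
  }
  with_local_seed(seed, {
    draw <- function(par) {
      row <- get(par)
      rtrunc_norm1(row$mean, row$sd, row$lower, row$upper)
    }
    body_length <- draw("body_length")
    blr <- get("body_length")
    z_bl <- if (blr$sd > 0) (body_length - blr$mean) / blr$sd else 0
    # femoral offset partially tracks stature (r ~ 0.4)
    fr <- get("fo3d")
    fo <- rtrunc_norm1(fr$mean + fr$sd * 0.4 * z_bl, fr$sd * sqrt(1 - 0.4^2),
                       fr$lower, fr$upper)
    incl <- NA_real_
    acet_av <- NA_real_
    for (i in seq_len(100L)) {   # joint truncation: medial pole inside fossa
      incl <- draw("cup_face_inclination")
      acet_av <- draw("cup_face_anteversion")
      tilt <- angle_between(socket_face_normal(incl, acet_av), c(1, 0, 0))
      if (tilt <= 50) break
      if (i == 100L) stop("socket orientation sampling exhausted retries", call. = FALSE)
    }
    list(
      age = draw("age"), body_length = body_length, bmi = draw("bmi"),
      ce_angle = draw("ce_angle"),
      femoral_anteversion = draw("femoral_anteversion"),
      fo3d_true = fo,
      head_radius = draw("head_radius"),
      neck_shaft_angle = draw("neck_shaft_angle"),
      shaft_radius = draw("shaft_radius"),
      shaft_length = draw("shaft_length"),
      cartilage = draw("cartilage"),
      wall_thickness = draw("wall_thickness"),
      cup_face_inclination = incl,
      cup_face_anteversion = acet_av,
      teardrop_margin = draw("teardrop_margin")
    )
  })
}

#' Generate a synthetic study cohort
#'
#' Draws `n` specimens (men/women in the 28:38 proportion of the reference
#' cohort) from the parameter distributions and realises each as a paired
#' synthetic femur and hemipelvis with ground truth. All randomness is
#' derived deterministically from `seed`.
#'
#' @param n Number of specimens (>= 1).
#' @param distributions Distribution table as from [cohort_distributions()].
#' @param seed Integer master seed.
#' @param noise_sd Surface noise SD in mm applied to both meshes.
#' @param side Anatomical side for all specimens.
#' @param meshes Generate meshes (set `FALSE` for a parameters-only table).
#' @return A [tibble::tibble()] with one row per specimen: identifiers,
#'   demographics, all anatomical parameters (including the derived
#'   `neck_length`, `acetabular_radius` and `teardrop_offset`), and
#'   list-columns `femur`, `pelvis` ([bone_surface()]) and `truth`.
#' @export
generate_cohort <- function(n = 66, distributions = cohort_distributions(),
                            seed = 1L, noise_sd = 0.5, side = "right",
                            meshes = TRUE) {
  if (length(n) != 1L || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!nrow(distributions)) stop("empty distribution table", call. = FALSE)
  n <- as.integer(n)
  n_men <- round(n * 28 / 66)
  sexes <- rep(c("men", "women"), c(n_men, n - n_men))
  seeds <- with_local_seed(seed, matrix(sample.int(2^31 - 2L, 3L * n), ncol = 3L))

  specs <- purrr::map(seq_len(n), function(i) {
    p <- draw_specimen_params(sexes[i], distributions, seeds[i, 1L])
    p$neck_length <- p$fo3d_true / sin((180 - p$neck_shaft_angle) * pi / 180)
    p$acetabular_radius <- p$head_radius + p$cartilage
    p$teardrop_offset <- p$acetabular_radius + p$wall_thickness + p$teardrop_margin
    p
  })

  tbl <- tibble::tibble(
    specimen = seq_len(n),
    sex = sexes,
    side = side,
    femur_seed = seeds[, 2L],
    pelvis_seed = seeds[, 3L]
  )
  tbl <- dplyr::bind_cols(tbl, dplyr::bind_rows(purrr::map(specs, tibble::as_tibble)))
  tbl$noise_sd <- noise_sd

  if (meshes) {
    built <- purrr::map(seq_len(n), function(i) {
      p <- specs[[i]]
      fem <- generate_femur(femur_params(
        head_radius = p$head_radius, neck_shaft_angle = p$neck_shaft_angle,
        anteversion = p$femoral_anteversion, neck_length = p$neck_length,
        shaft_radius = p$shaft_radius, shaft_length = p$shaft_length,
        side = side, noise_sd = noise_sd, seed = seeds[i, 2L]))
      pel <- generate_hemipelvis(pelvis_params(
        acetabular_radius = p$acetabular_radius,
        wall_thickness = p$wall_thickness,
        cup_face_inclination = p$cup_face_inclination,
        cup_face_anteversion = p$cup_face_anteversion,
        CE_angle = p$ce_angle, teardrop_offset = p$teardrop_offset,
        side = side, noise_sd = noise_sd, seed = seeds[i, 3L]))
      list(femur = fem$mesh, pelvis = pel$mesh,
           truth = list(femur = fem$truth, pelvis = pel$truth))
    })
    tbl$femur <- purrr::map(built, "femur")
    tbl$pelvis <- purrr::map(built, "pelvis")
    tbl$truth <- purrr::map(built, "truth")
  }
  tbl
}
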