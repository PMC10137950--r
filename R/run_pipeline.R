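# File-level driver: landmark JSON input/output, run configuration, and the
# end-to-end cohort run with serialised outputs.

#' Read / write an anatomical landmark file
#'
#' Landmark files are JSON: a named object whose values are 3-vectors (mm)
#' or nested objects of 3-vectors (e.g. `APP_landmarks`, `TAL_endpoints`).
#'
#' @param path JSON file path.
#' @return A named list of numeric 3-vectors / nested lists.
#' @export
read_landmarks <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE) |>
    rapply(as.numeric, classes = c("numeric", "integer"), how = "replace")
}

#' @rdname read_landmarks
#' @param landmarks Named list of 3-vectors / nested lists.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' @param n Cohort size.
#' @param seed Master seed; recorded in every output.
#' @param out_dir Output directory (created if missing).
#' @param noise_sd Surface noise SD, mm.
#' @param cup_sizes Available cup diameters, mm.
#' @param inclination Cup inclination, degrees.
#' @param flush Cup seating direction (see [place_cup()]).
#' @param side Anatomical side.
#' @param write_meshes Also serialise every mesh as binary STL.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n = 20, seed = 1L, out_dir = tempfile("hipoffset_run_"),
                       noise_sd = 0.5, cup_sizes = seq(38, 66, by = 2),
                       inclination = 40, flush = "mediolateral",
                       side = "right", write_meshes = FALSE) {
  structure(list(n = as.integer(n), seed = as.integer(seed), out_dir = out_dir,
                 noise_sd = noise_sd, cup_sizes = cup_sizes,
                 inclination = inclination, flush = flush, side = side,
                 write_meshes = write_meshes),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic cohort, measures every hip, computes the cohort
#' statistics, and serialises the measurement table (`cohort.csv`), the
#' statistics report (`stats.json`) and the configuration with its seed
#' (`config.json`) into the output directory. The run is deterministic for
#' a fixed seed: repeated runs produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `cohort` (measurement tibble), `stats`
#'   (a [cohort_stats()] object) and `files` (paths written).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("hipoffset run: n = %d, seed = %d", config$n, config$seed))

  cohort <- generate_cohort(n = config$n, seed = config$seed,
                            noise_sd = config$noise_sd, side = config$side)
  measured <- measure_cohort(cohort, cup_sizes = config$cup_sizes,
                             inclination = config$inclination,
                             flush = config$flush)
  stats_rep <- cohort_stats(measured)

  files <- character()
  cohort_csv <- file.path(config$out_dir, "cohort.csv")
  utils::write.csv(as.data.frame(measured), cohort_csv, row.names = FALSE)
  files <- c(files, cohort_csv)

  stats_json <- file.path(config$out_dir, "stats.json")
  jsonlite::write_json(list(seed = config$seed,
                            summary = stats_rep$summary,
                            t_tests = stats_rep$ttests,
                            offset_comparison = stats_rep$offset_comparison,
                            correlations = stats_rep$correlations),
                       stats_json, digits = 10, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, stats_json)

  config_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), config_json, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, config_json)

  if (isTRUE(config$write_meshes)) {
    for (i in seq_len(nrow(cohort))) {
      fp <- file.path(config$out_dir, sprintf("specimen%03d_femur.stl", i))
      pp <- file.path(config$out_dir, sprintf("specimen%03d_pelvis.stl", i))
      write_stl(cohort$femur[[i]], fp)
      write_stl(cohort$pelvis[[i]], pp)
      lj <- file.path(config$out_dir, sprintf("specimen%03d_landmarks.json", i))
      write_landmarks(truth_landmarks(cohort$truth[[i]]), lj)
      files <- c(files, fp, pp, lj)
    }
  }
  message(sprintf("hipoffset run: wrote %d files to %s", length(files),
                  config$out_dir))
  invisible(list(cohort = measured, stats = stats_rep, files = files))
}
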