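# Femoral morphometry: isolate the spherical head region, fit the femoral
# head centre (FHC), slice the shaft into cross-sections to recover the
# proximal femoral bone axis, and derive the reference point, the 3D
# femoral offset and femoral anteversion.

#' Isolate the femoral head surface by iterative sphere-region growing
#'
#' Starting from a seed neighbourhood, alternately fits a sphere to the
#' current region and re-selects the mesh vertices whose radial residual is
#' below twice the median residual of the region (with a 0.25 mm floor so a
#' noise-free cap is not rejected), for at most 10 rounds.
#'
#' @param mesh A [bone_surface()].
#' @param seed_point Approximate point on the head. Defaults to the mesh
#'   vertex farthest from the provisional shaft axis, which on a proximal
#'   femur lies on the head.
#' @param seed_radius Radius (mm) of the initial seed neighbourhood.
#' @return Integer vector of retained vertex indices, with the final
#'   [sphere3()] fit as attribute `sphere`.
#' @export
extract_head_surface <- function(mesh, seed_point = NULL, seed_radius = 20) {
  v <- mesh$vertices
  if (is.null(seed_point)) {
    axis <- provisional_shaft_axis(mesh)
    rel <- sweep(v, 2L, axis$point)
    perp <- rel - outer(drop(rel %*% axis$direction), axis$direction)
    seed_point <- v[which.max(rowSums(perp^2)), ]
  }
  d_seed <- sqrt(rowSums(sweep(v, 2L, vec3(seed_point))^2))
  keep <- which(d_seed < seed_radius)
  if (length(keep) < 10L) {
    stop("head extraction failed: seed region too small", call. = FALSE)
  }
  fit <- NULL
  for (round in seq_len(10L)) {
    fit <- tryCatch(fit_sphere(v[keep, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      stop("head extraction failed: sphere fit degenerate", call. = FALSE)
    }
    res <- abs(sqrt(rowSums(sweep(v, 2L, fit$center)^2)) - fit$radius)
    thr <- max(2 * stats::median(res[keep]), 0.25)
    keep_new <- which(res < thr)
    if (length(keep_new) < 50L) {
      stop("head extraction failed: selection collapsed below 50 vertices",
           call. = FALSE)
    }
    if (length(keep_new) == length(keep) && all(keep_new == keep)) {
      keep <- keep_new
      break
    }
    keep <- keep_new
  }
  fit <- fit_sphere(v[keep, , drop = FALSE])
  # reject fits that are not a genuinely spherical region: the retained
  # cloud must be three-dimensional at the scale of the fitted radius, and
  # disjoint halves of the region must agree on the sphere centre
  pts <- v[keep, , drop = FALSE]
  ctr <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(ctr, nu = 0L)
  if (!is.finite(fit$radius) || fit$radius > 80 || fit$radius < 5 ||
      sv$d[3] / sqrt(nrow(pts)) < 0.05 * fit$radius) {
    stop("head extraction failed: no spherical region found", call. = FALSE)
  }
  for (j in 1:3) {   # split along each principal direction
    tj <- drop(ctr %*% sv$v[, j])
    halves <- lapply(list(tj <= stats::median(tj), tj > stats::median(tj)),
                     function(sel) {
                       tryCatch(fit_sphere(pts[sel, , drop = FALSE]),
                                error = function(e) NULL)
                     })
    if (any(vapply(halves, is.null, logical(1))) ||
        vnorm(halves[[1L]]$center - halves[[2L]]$center) > 0.2 * fit$radius) {
      stop("head extraction failed: region is not spherical", call. = FALSE)
    }
  }
  structure(keep, sphere = fit)
}

# Provisional shaft axis by trimmed principal-component iteration: refit the
# dominant direction on the 60% of vertices nearest the current axis, which
# converges onto the tubular shaft (the head and neck are trimmed away as
# off-axis outliers). Oriented distal -> proximal: the trimmed-away
# head/neck cluster marks the proximal end.
provisional_shaft_axis <- function(mesh) {
  v <- mesh$vertices
  centroid <- colMeans(v)
  dir <- svd(sweep(v, 2L, centroid), nu = 0L)$v[, 1L]
  keep <- rep(TRUE, nrow(v))
  for (round in 1:10) {
    rel <- sweep(v, 2L, centroid)
    t_all <- drop(rel %*% dir)
    perp2 <- rowSums(rel^2) - t_all^2
    keep <- perp2 <= stats::quantile(perp2, 0.6)
    sub <- v[keep, , drop = FALSE]
    new_centroid <- colMeans(sub)
    new_dir <- svd(sweep(sub, 2L, new_centroid), nu = 0L)$v[, 1L]
    if (sum(new_dir * dir) < 0) new_dir <- -new_dir
    moved <- angle_between(new_dir, dir)
    centroid <- new_centroid
    dir <- new_dir
    if (moved < 0.01) break
  }
  t_all <- drop(sweep(v, 2L, centroid) %*% dir)
  if (any(!keep) && mean(t_all[!keep]) < 0) dir <- -dir
  line3(centroid, dir)
}

#' Shaft cross-section midpoints
#'
#' Slices the distal shaft with planes perpendicular to a provisional axis
#' (principal direction of the distal 60% of the mesh) at the given spacing;
#' each midpoint is the area centroid of the closed cross-section contour.
#' Midpoints are returned ordered distal to proximal.
#'
#' @param mesh A [bone_surface()].
#' @param spacing Plane spacing in mm (> 0).
#' @return k x 3 matrix of midpoints with the provisional axis as attribute
#'   `axis`.
#' @export
compute_shaft_sections <- function(mesh, spacing = 5) {
  check_param(spacing, "spacing", 0, Inf, open_lower = TRUE)
  axis <- provisional_shaft_axis(mesh)
  t_all <- drop(sweep(mesh$vertices, 2L, axis$point) %*% axis$direction)
  lo <- min(t_all)
  len <- max(t_all) - lo
  offsets <- seq(lo + 0.06 * len, lo + 0.52 * len, by = spacing)
  mids <- lapply(offsets, function(ti) {
    pts <- mesh_plane_section(mesh, axis$point + ti * axis$direction,
                              axis$direction)
    if (is.null(pts)) return(NULL)
    section_area_centroid(pts, axis$direction)
  })
  mids <- do.call(rbind, mids[!vapply(mids, is.null, logical(1))])
  if (is.null(mids) || nrow(mids) < 2L) {
    stop("shaft sectioning failed: fewer than 2 usable sections", call. = FALSE)
  }
  structure(mids, axis = axis)
}

#' Femoral measurement
#'
#' Full femoral morphometry: femoral head centre by geometric sphere fit to
#' the extracted head region, shaft axis by total least squares through the
#' section midpoints, reference point as the orthogonal projection of the
#' FHC onto the shaft axis (so the 3D femoral offset is exactly the
#' point-to-line distance and the offset segment is perpendicular to the
#' axis), and femoral anteversion as the transverse-plane angle between the
#' neck axis and the posterior condylar axis.
#'
#' @param mesh A [bone_surface()] of a proximal femur.
#' @param landmarks Optional named list with `condyle_medial` and
#'   `condyle_lateral` 3-vectors; without them anteversion is `NA` and the
#'   reference used is reported as such.
#' @param spacing Shaft section spacing in mm.
#' @return An object of class `femur_measurement`: `FHC`, `head_radius`,
#'   `shaft_axis`, `reference_point`, `fo3d`, `anteversion`,
#'   `anteversion_reference`, `side`.
#' @export
measure_femur <- function(mesh, landmarks = NULL, spacing = 5) {
  stopifnot(inherits(mesh, "bone_surface"))
  mids <- compute_shaft_sections(mesh, spacing = spacing)
  shaft_axis <- fit_axis_from_section_midpoints(mids)
  head_idx <- extract_head_surface(mesh)
  head_fit <- attr(head_idx, "sphere")
  fhc <- head_fit$center
  reference_point <- project_point_on_line(fhc, shaft_axis)
  fo3d <- point_line_distance(fhc, shaft_axis)

  anteversion <- NA_real_
  av_ref <- NA_character_
  if (!is.null(landmarks) &&
      all(c("condyle_medial", "condyle_lateral") %in% names(landmarks))) {
    ml_ref <- vec3(landmarks$condyle_lateral) - vec3(landmarks$condyle_medial)
    z <- shaft_axis$direction
    m_lat <- ml_ref - sum(ml_ref * z) * z
    if (vnorm(m_lat) > 1e-9) {
      m_lat <- m_lat / vnorm(m_lat)
      s <- if (mesh$side == "right") 1 else -1
      a_ant <- s * cross3(z, m_lat)
      v_neck <- fhc - reference_point
      v_t <- v_neck - sum(v_neck * z) * z
      anteversion <- atan2(sum(v_t * a_ant), sum(v_t * -m_lat)) * 180 / pi
      av_ref <- "posterior_condylar_axis"
    }
  }

  structure(list(FHC = fhc, head_radius = head_fit$radius,
                 shaft_axis = shaft_axis, reference_point = reference_point,
                 fo3d = fo3d, anteversion = anteversion,
                 anteversion_reference = av_ref, side = mesh$side,
                 n_head_vertices = length(head_idx),
                 head_fit_rms = attr(head_fit, "rms")),
            class = "femur_measurement")
}

#' @export
print.femur_measurement <- function(x, ...) {
  cat(sprintf(paste0("<femur_measurement> (%s)\n",
                     "  FHC (%.2f, %.2f, %.2f) mm, head radius %.2f mm\n",
                     "  3D femoral offset %.2f mm, anteversion %s\n"),
              x$side, x$FHC[1], x$FHC[2], x$FHC[3], x$head_radius, x$fo3d,
              if (is.na(x$anteversion)) "NA" else sprintf("%.1f deg", x$anteversion)))
  invisible(x)
}
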