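# Pelvic side of the pipeline: the anterior-pelvic-plane frame, acetabular
# morphometry (socket sphere, rim, true floor, transverse acetabular
# ligament direction) and virtual cup implantation flush to the true floor.

#' Build the anterior pelvic plane frame
#'
#' The APP passes through both anterior superior iliac spines and the
#' midpoint of the pubic tubercles. The mediolateral axis runs from the left
#' to the right ASIS (towards the patient's right), the anteroposterior axis
#' is the plane normal (anterior positive), and the superoinferior axis
#' completes the right-handed frame. Origin at mid-ASIS.
#'
#' @param landmarks Named list with `ASIS_R`, `ASIS_L`, `pubic_tubercle_R`,
#'   `pubic_tubercle_L` 3-vectors (mm).
#' @return An [anatomical_frame()] with `body = "pelvis"`.
#' @export
build_app_frame <- function(landmarks) {
  need <- c("ASIS_R", "ASIS_L", "pubic_tubercle_R", "pubic_tubercle_L")
  if (!all(need %in% names(landmarks))) {
    stop("APP frame needs landmarks: ", paste(need, collapse = ", "), call. = FALSE)
  }
  asis_r <- vec3(landmarks$ASIS_R)
  asis_l <- vec3(landmarks$ASIS_L)
  mid_asis <- (asis_r + asis_l) / 2
  mid_pt <- (vec3(landmarks$pubic_tubercle_R) + vec3(landmarks$pubic_tubercle_L)) / 2
  ml <- asis_r - asis_l
  w <- mid_pt - mid_asis
  if (vnorm(ml) < 1e-9 || vnorm(cross3(ml, w)) < 1e-9 * vnorm(ml) * max(vnorm(w), 1e-9)) {
    stop("APP landmarks are degenerate (collinear)", call. = FALSE)
  }
  ml <- unit_vector(ml)
  ap <- unit_vector(cross3(ml, w))
  si <- cross3(ml, ap)
  anatomical_frame(mid_asis, ml, ap, si, body = "pelvis")
}

lateral_axis <- function(frame, side) {
  if (side == "right") frame$ml else -frame$ml
}

#' Acetabular morphometry
#'
#' Recovers the native socket sphere (hip rotation centre and radius) by an
#' iterative residual-filtered sphere fit restricted to the internal wall
#' (vertices whose outward normal faces the cavity centre); detects the
#' recessed cotyloid fossa as off-sphere internal-wall points and fits its
#' sphere to locate the true acetabular floor; extracts the acetabular rim
#' as the per-azimuth extremal socket points and measures the maximum rim
#' diameter within the best 1 mm axial slab.
#'
#' @param mesh A hemipelvis [bone_surface()].
#' @param frame Pelvic [anatomical_frame()] from [build_app_frame()].
#' @param landmarks Named list with `TAL_endpoints` (list of two 3-vectors);
#'   optional `teardrop_inferior_edge`, `lateral_acetabular_edge` passed
#'   through for downstream 2D measurements.
#' @return An object of class `acetabulum_measurement`.
#' @export
measure_acetabulum <- function(mesh, frame, landmarks) {
  stopifnot(inherits(mesh, "bone_surface"), inherits(frame, "anatomical_frame"))
  v <- mesh$vertices
  normals <- vertex_normals(mesh)

  # initial fit on everything; inner and outer shells are nearly concentric,
  # so the centre lands close to the socket centre and the inner shell is
  # the cluster nearer than the fitted radius
  fit <- fit_sphere(v, method = "algebraic")
  d <- sqrt(rowSums(sweep(v, 2L, fit$center)^2))
  keep <- which(d < fit$radius)
  if (length(keep) < 50L) stop("acetabulum extraction failed", call. = FALSE)
  fit <- fit_sphere(v[keep, , drop = FALSE])
  # internal wall: vertices whose outward normal faces the cavity centre
  to_center <- sweep(-v, 2L, fit$center, "+")
  inner_wall <- which(rowSums(to_center * normals) > 0)
  # residual-filtered convergence onto the better-populated internal shell:
  # the internal wall holds two exact spheres of the same radius, the
  # articular (lunate) surface and the recessed cotyloid fossa, offset
  # medially by the wall depth
  refine <- function(fit, pool, rounds = 8L) {
    keep <- pool
    for (round in seq_len(rounds)) {
      res <- sqrt(rowSums(sweep(v, 2L, fit$center)^2)) - fit$radius
      thr <- max(2 * stats::quantile(abs(res[pool]), 0.25), 0.3)
      keep_new <- pool[abs(res[pool]) < thr]
      if (length(keep_new) < 50L) return(NULL)
      stable <- length(keep_new) == length(keep) && all(keep_new == keep)
      keep <- keep_new
      fit <- fit_sphere(v[keep, , drop = FALSE])
      if (stable) break
    }
    list(fit = fit, keep = keep, thr = thr)
  }
  lat <- lateral_axis(frame, mesh$side)

  # split the internal wall about the socket opening axis: the cotyloid
  # fossa is the central cap (small polar angle from the deep pole), the
  # articular lunate surface the peripheral zone; the two are coincident
  # spheres of the same radius offset medially by the wall depth, so the
  # angular split, iterated with the improving centre, separates them
  center <- fit$center
  pool_angles <- function(center) {
    rel <- sweep(v[inner_wall, , drop = FALSE], 2L, center)
    deep <- unit_vector(colMeans(rel))          # towards the socket apex
    acos(pmin(1, pmax(-1, drop(rel %*% deep) / sqrt(rowSums(rel^2))))) * 180 / pi
  }
  s1 <- NULL
  for (round in 1:3) {
    ang <- pool_angles(center)
    lunate_pool <- inner_wall[ang > 62]
    if (length(lunate_pool) < 50L) {
      stop("acetabulum extraction failed: lunate selection collapsed", call. = FALSE)
    }
    s1 <- refine(fit_sphere(v[lunate_pool, , drop = FALSE]), lunate_pool,
                 rounds = 4L)
    if (is.null(s1)) {
      stop("acetabulum extraction failed: lunate selection collapsed", call. = FALSE)
    }
    if (vnorm(s1$fit$center - center) < 1e-6) break
    center <- s1$fit$center
  }
  keep <- s1$keep
  center <- s1$fit$center
  radius <- s1$fit$radius

  # fossa shell: central-cap points clearly off the articular sphere
  ang <- pool_angles(center)
  res1 <- sqrt(rowSums(sweep(v, 2L, center)^2)) - radius
  fossa_pool <- inner_wall[ang < 48 & res1[inner_wall] > max(s1$thr, 0.8)]
  s2 <- NULL
  if (length(fossa_pool) >= 40L) {
    f2 <- tryCatch(fit_sphere(v[fossa_pool, , drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(f2)) s2 <- refine(f2, fossa_pool, rounds = 3L)
    if (!is.null(s2) &&
        (s2$fit$radius < 0.5 * radius || s2$fit$radius > 1.6 * radius)) {
      s2 <- NULL
    }
  }
  if (!is.null(s2)) {
    true_floor <- s2$fit$center - s2$fit$radius * lat
  } else {
    true_floor <- center - radius * lat
  }
  wall_depth <- sum((center - radius * lat - true_floor) * lat)

  # rim: per-azimuth extremal polar angle of the lunate points about the
  # estimated opening axis
  lun <- v[keep, , drop = FALSE]
  open_axis <- -unit_vector(colMeans(lun) - center)   # points medially
  rel <- sweep(lun, 2L, center)
  polar <- acos(pmin(1, pmax(-1, drop(rel %*% -open_axis) /
                               sqrt(rowSums(rel^2)))))
  e1 <- unit_vector(cross3(open_axis, frame$si))
  e2 <- cross3(open_axis, e1)
  azim <- atan2(drop(rel %*% e2), drop(rel %*% e1))
  bins <- cut(azim, breaks = seq(-pi, pi, length.out = 49L), include.lowest = TRUE)
  rim_rows <- vapply(split(seq_len(nrow(lun)), bins), function(ii) {
    if (!length(ii)) return(NA_integer_)
    ii[which.max(polar[ii])]
  }, integer(1))
  rim_pts <- lun[rim_rows[!is.na(rim_rows)], , drop = FALSE]
  if (nrow(rim_pts) < 8L) {
    stop("acetabular rim not found", call. = FALSE)
  }
  rim <- rim_max_diameter(rim_pts, frame)

  tal_dir <- NULL
  if (!is.null(landmarks$TAL_endpoints)) {
    ep <- landmarks$TAL_endpoints
    tal_dir <- unit_vector(vec3(ep[[1L]]) - vec3(ep[[2L]]))
  }

  structure(list(native_center = center, native_radius = radius,
                 rim_max_diameter = rim$diameter, rim_pair = rim$pair,
                 rim_points = rim_pts, true_floor_point = true_floor,
                 wall_depth = wall_depth, TAL_direction = tal_dir,
                 side = mesh$side, fit_rms = attr(fit, "rms"),
                 n_lunate_vertices = length(keep)),
            class = "acetabulum_measurement")
}

#' @export
print.acetabulum_measurement <- function(x, ...) {
  cat(sprintf(paste0("<acetabulum_measurement> (%s)\n",
                     "  HRC (%.2f, %.2f, %.2f) mm, radius %.2f mm\n",
                     "  rim max diameter %.2f mm, medial wall depth %.2f mm\n"),
              x$side, x$native_center[1], x$native_center[2], x$native_center[3],
              x$native_radius, x$rim_max_diameter, x$wall_depth))
  invisible(x)
}

# Maximum pairwise distance among rim points within the 1 mm axial slab
# that maximises it, slid over the superoinferior range.
rim_max_diameter <- function(rim_pts, frame, slab = 1) {
  z <- drop(sweep(rim_pts, 2L, frame$origin) %*% frame$si)
  z0s <- seq(min(z), max(z), by = slab / 2)
  best <- list(diameter = -Inf, pair = NULL)
  for (z0 in z0s) {
    ii <- which(abs(z - z0) <= slab / 2)
    if (length(ii) < 2L) next
    sub <- rim_pts[ii, , drop = FALSE]
    dd <- as.matrix(stats::dist(sub))
    k <- arrayInd(which.max(dd), dim(dd))
    if (dd[k] > best$diameter) {
      best <- list(diameter = dd[k], pair = sub[as.vector(k), , drop = FALSE])
    }
  }
  if (!is.finite(best$diameter)) stop("acetabular rim not found", call. = FALSE)
  best
}

#' Virtual cup implantation
#'
#' Selects the largest available cup diameter not exceeding the maximum rim
#' diameter, seats the cup flush to the true acetabular floor, and orients
#' the face with a fixed radiographic inclination and an anteversion chosen
#' so the face's transverse trace is parallel to the transverse acetabular
#' ligament. "Flush to the true floor" is realised as contact along the
#' mediolateral axis by default (`flush = "mediolateral"`, so the cup centre
#' sits `diameter/2` lateral to the floor); `flush = "face_normal"` instead
#' places polar contact along the cup face normal.
#'
#' @param acet An [measure_acetabulum()] result.
#' @param frame Pelvic [anatomical_frame()].
#' @param cup_sizes Available cup diameters in mm.
#' @param inclination Radiographic cup inclination in degrees (default 40).
#' @param flush `"mediolateral"` or `"face_normal"`.
#' @return An object of class `cup_plan`: `CC`, `diameter`, `face_normal`,
#'   `inclination`, `anteversion`.
#' @export
place_cup <- function(acet, frame, cup_sizes = seq(38, 66, by = 2),
                      inclination = 40, flush = c("mediolateral", "face_normal")) {
  flush <- match.arg(flush)
  stopifnot(inherits(acet, "acetabulum_measurement"))
  if (!length(cup_sizes)) stop("cup size list is empty", call. = FALSE)
  fitting <- cup_sizes[cup_sizes <= acet$rim_max_diameter]
  if (!length(fitting)) {
    stop(sprintf("no cup size fits: rim max diameter %.1f mm below smallest size %g mm",
                 acet$rim_max_diameter, min(cup_sizes)), call. = FALSE)
  }
  diameter <- max(fitting)
  lat <- lateral_axis(frame, acet$side)

  anteversion <- 0
  if (!is.null(acet$TAL_direction)) {
    t_lat <- sum(acet$TAL_direction * lat)
    t_ant <- sum(acet$TAL_direction * frame$ap)
    if (t_ant > 0) {
      t_lat <- -t_lat
      t_ant <- -t_ant
    }
    anteversion <- atan(t_lat / (-t_ant) * cos(inclination * pi / 180)) * 180 / pi
  }
  n_local <- socket_face_normal(inclination, anteversion)
  face_normal <- n_local[1] * lat + n_local[2] * frame$ap + n_local[3] * frame$si

  dir <- if (flush == "mediolateral") lat else face_normal
  cc <- acet$true_floor_point + (diameter / 2) * dir

  structure(list(CC = cc, diameter = diameter, face_normal = face_normal,
                 inclination = inclination, anteversion = anteversion,
                 flush = flush, side = acet$side),
            class = "cup_plan")
}

#' @export
print.cup_plan <- function(x, ...) {
  cat(sprintf(paste0("<cup_plan> %g mm cup (%s)\n",
                     "  CC (%.2f, %.2f, %.2f) mm, inclination %.1f deg,",
                     " anteversion %.1f deg\n"),
              x$diameter, x$side, x$CC[1], x$CC[2], x$CC[3],
              x$inclination, x$anteversion))
  invisible(x)
}
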