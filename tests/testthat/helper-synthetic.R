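# Shared fixtures, all built in code at test time.

norm3 <- function(v) sqrt(sum(v^2))

# plain open cylinder mesh along +z (no head): degenerate femur fixture
make_tube_mesh <- function(radius = 14, length = 100, step = 3, n_around = 36) {
  psi <- 2 * pi * (seq_len(n_around) - 1) / n_around
  zs <- seq(0, length, by = step)
  verts <- do.call(rbind, lapply(zs, function(z) {
    cbind(radius * cos(psi), radius * sin(psi), z)
  }))
  faces <- NULL
  for (i in seq_len(length(zs) - 1)) {
    r1 <- ((i - 1) * n_around + 1):(i * n_around)
    r2 <- (i * n_around + 1):((i + 1) * n_around)
    k1 <- c(2:n_around, 1)
    faces <- rbind(faces, cbind(r1, r1[k1], r2[k1]), cbind(r1, r2[k1], r2))
  }
  bone_surface(verts, faces, side = "right", label = "femur")
}

# landmark list for measure_hip() assembled from generator truth
hip_landmarks <- function(femur_truth, pelvis_truth) {
  c(femur_truth$landmarks,
    list(APP_landmarks = pelvis_truth$APP_landmarks,
         TAL_endpoints = pelvis_truth$TAL_endpoints,
         teardrop_inferior_edge = pelvis_truth$teardrop_inferior_edge,
         lateral_acetabular_edge = pelvis_truth$lateral_acetabular_edge))
}

# one noise-free hip with a chosen femoral anteversion, measured end to end
measure_ideal_hip <- function(anteversion, seed = 1, noise_sd = 0, ...) {
  f <- generate_femur(femur_params(anteversion = anteversion,
                                   noise_sd = noise_sd, seed = seed))
  p <- generate_hemipelvis(pelvis_params(noise_sd = noise_sd, seed = seed))
  measure_hip(f$mesh, p$mesh, hip_landmarks(f$truth, p$truth), ...)
}

# exact points on a sphere (deterministic quasi-uniform spiral)
sphere_points <- function(n, center = c(0, 0, 0), radius = 1) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  sweep(radius * cbind(r * cos(phi), r * sin(phi), z), 2, center, "+")
}
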