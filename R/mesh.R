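# Triangulated bone surface container plus the small amount of mesh
# machinery the measurement stages need: vertex normals, plane sections,
# boundary loops, mirroring, and STL/PLY input/output.

#' Triangulated bone surface
#'
#' The pipeline's raw input: a triangle mesh in millimetres with an
#' anatomical side tag. Faces are 1-based vertex index triples wound so that
#' face normals point out of the bone.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of vertex indices.
#' @param side `"left"` or `"right"`.
#' @param label `"femur"` or `"hemipelvis"`.
#' @param regions Optional character vector of length n tagging each vertex
#'   with the anatomical region it was constructed from (synthetic meshes).
#' @return An object of class `bone_surface`.
#' @export
bone_surface <- function(vertices, faces, side = c("right", "left"),
                         label = c("femur", "hemipelvis"), regions = NULL) {
  side <- match.arg(side)
  label <- match.arg(label)
  vertices <- as_point_matrix(vertices)
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix", call. = FALSE)
  if (nrow(vertices) < 4L) stop("a bone surface needs at least 4 vertices", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range", call. = FALSE)
  }
  areas <- face_areas(vertices, faces)
  if (any(areas <= 1e-12)) stop("mesh contains degenerate (zero-area) faces", call. = FALSE)
  if (!is.null(regions) && length(regions) != nrow(vertices)) {
    stop("regions must tag every vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, side = side,
                 label = label, regions = regions),
            class = "bone_surface")
}

#' @export
print.bone_surface <- function(x, ...) {
  cat(sprintf("<bone_surface> %s (%s): %d vertices, %d faces\n",
              x$label, x$side, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- c3 - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Area-weighted outward vertex normals
#'
#' @param mesh A [bone_surface()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])  # length = 2 * area
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    acc <- rowsum(fn, f[, k])
    idx <- as.integer(rownames(acc))
    n[idx, ] <- n[idx, ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-12] <- 1
  n / len
}

#' Mirror a bone surface across the sagittal plane
#'
#' Negates the first (mediolateral) coordinate, rewinds faces to keep
#' outward normals, and flips the side tag. Region tags are preserved.
#'
#' @param mesh A [bone_surface()].
#' @return The mirrored `bone_surface`.
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  bone_surface(v, f, side = if (mesh$side == "right") "left" else "right",
               label = mesh$label, regions = mesh$regions)
}

mirror_point <- function(p) {
  p <- vec3(p)
  c(-p[1], p[2], p[3])
}

# --- plane sections ---------------------------------------------------------

# Intersect the mesh with the plane {x : (x - p0) . n = 0}. Returns the
# intersection points of crossing edges (each crossing edge contributes one
# point; shared edges are deduplicated), or NULL when the plane misses.
mesh_plane_section <- function(mesh, p0, n) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- drop(sweep(v, 2L, p0) %*% n)
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  s1 <- s[edges[, 1L]]
  s2 <- s[edges[, 2L]]
  cross_idx <- which((s1 > 0 & s2 < 0) | (s1 < 0 & s2 > 0))
  on_plane <- which(s1 == 0)
  pts <- NULL
  if (length(cross_idx)) {
    t <- s1[cross_idx] / (s1[cross_idx] - s2[cross_idx])
    a <- v[edges[cross_idx, 1L], , drop = FALSE]
    b <- v[edges[cross_idx, 2L], , drop = FALSE]
    pts <- a + (b - a) * t
  }
  if (length(on_plane)) {
    pts <- rbind(pts, v[unique(edges[on_plane, 1L]), , drop = FALSE])
  }
  if (is.null(pts) || nrow(pts) < 3L) return(NULL)
  pts
}

# Area centroid of the closed cross-section contour cut by a plane.
# Section points are projected into the plane, ordered by angle about their
# mean (shaft sections are convex), and the polygon centroid is taken.
section_area_centroid <- function(points, n) {
  n <- unit_vector(n)
  e1 <- unit_vector(if (abs(n[1]) < 0.9) cross3(n, c(1, 0, 0)) else cross3(n, c(0, 1, 0)))
  e2 <- cross3(n, e1)
  base <- colMeans(points)
  rel <- sweep(points, 2L, base)
  xy <- cbind(drop(rel %*% e1), drop(rel %*% e2))
  ord <- order(atan2(xy[, 2], xy[, 1]))
  xy <- xy[ord, , drop = FALSE]
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  area <- sum(cr) / 2
  if (abs(area) < 1e-9) {  # degenerate sliver: fall back to vertex mean
    cx <- mean(x); cy <- mean(y)
  } else {
    cx <- sum((x + xn) * cr) / (6 * area)
    cy <- sum((y + yn) * cr) / (6 * area)
  }
  base + cx * e1 + cy * e2
}

# --- STL / PLY input and output --------------------------------------------

#' Write a bone surface as STL
#'
#' @param mesh A [bone_surface()].
#' @param path Output file path.
#' @param binary Write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  u <- b - a; w <- c3 - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(fn^2)); len[len < 1e-12] <- 1
  fn <- fn / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "hipoffset binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    tri <- t(cbind(fn, a, b, c3))  # 12 floats per facet, column-per-facet
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[, i]), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    lines <- c("solid hipoffset",
               unlist(lapply(seq_len(nrow(f)), function(i) {
                 c(sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
                   sprintf("    vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
                   sprintf("    vertex %.9g %.9g %.9g", c3[i, 1], c3[i, 2], c3[i, 3]),
                   "  endloop",
                   "endfacet")
               })),
               "endsolid hipoffset")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file as a bone surface
#'
#' Detects binary versus ASCII, merges duplicated vertices (STL stores each
#' facet independently) and returns a [bone_surface()].
#'
#' @param path STL file path.
#' @param side,label Anatomical tags for the result.
#' @return A [bone_surface()].
#' @export
read_stl <- function(path, side = "right", label = "femur") {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  size <- file.info(path)$size
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    size == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    raw_rest <- readBin(con, "raw", size - 84)
    close(con)
    tri <- matrix(NA_real_, ntri, 9L)
    for (i in seq_len(ntri)) {
      off <- (i - 1L) * 50L
      vals <- readBin(raw_rest[(off + 1):(off + 48)], "numeric", 12L,
                      size = 4L, endian = "little")
      tri[i, ] <- vals[4:12]
    }
  } else {
    close(con)
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4])))
    if (nrow(nums) %% 3L != 0L) stop("malformed ASCII STL", call. = FALSE)
    m <- nrow(nums) / 3L
    tri <- cbind(nums[seq(1L, by = 3L, length.out = m), , drop = FALSE],
                 nums[seq(2L, by = 3L, length.out = m), , drop = FALSE],
                 nums[seq(3L, by = 3L, length.out = m), , drop = FALSE])
  }
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  m <- nrow(tri)
  order_idx <- as.vector(t(matrix(seq_len(3 * m), ncol = 3L)))
  pts <- pts[order_idx, , drop = FALSE]  # v1,v2,v3 per facet consecutive
  key <- apply(round(pts, 6L), 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  bone_surface(verts, faces, side = side, label = label)
}

#' Write a bone surface as ASCII PLY
#'
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY file as a bone surface
#'
#' @inheritParams read_stl
#' @return A [bone_surface()].
#' @export
read_ply <- function(path, side = "right", label = "femur") {
  txt <- readLines(path, warn = FALSE)
  endh <- which(txt == "end_header")[1L]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", txt, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "", grep("^element face", txt, value = TRUE)[1L]))
  vl <- txt[(endh + 1):(endh + nv)]
  fl <- txt[(endh + nv + 1):(endh + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  bone_surface(verts, faces, side = side, label = label)
}
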