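# Triangle-mesh container and geometry utilities.
#
# All coordinates are millimetres. A TriMesh is a plain list with a class
# attribute, in the style of structures used by mesh-based analysis packages:
#   vertices    n x 3 numeric matrix
#   faces       m x 3 integer matrix (1-based vertex indices)
#   label       body/tissue name
#   compartment per-face factor-like character in {"medial","lateral","none"}

#' Construct a triangle mesh
#'
#' Builds a validated `TriMesh`. Faces whose area is exactly zero (degenerate
#' slivers produced by welding) are dropped, so the invariant "no zero-area
#' faces" holds after construction.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label body or tissue name.
#' @param compartment per-face tag, one of `"medial"`, `"lateral"`, `"none"`;
#'   recycled to the number of faces.
#' @return A `TriMesh` object.
#' @export
trimesh <- function(vertices, faces, label = "mesh", compartment = "none") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) knee_stop("vertices must be n x 3", "knee_mesh_error")
  if (nrow(faces) > 0L && ncol(faces) != 3L)
    knee_stop("faces must be m x 3", "knee_mesh_error")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    knee_stop("face indices out of range", "knee_mesh_error")
  compartment <- rep_len(as.character(compartment), max(nrow(faces), 1L))[seq_len(nrow(faces))]
  m <- structure(list(vertices = vertices, faces = faces,
                      label = label, compartment = compartment),
                 class = "TriMesh")
  a <- face_areas(m)
  if (any(a == 0)) {
    keep <- a > 0
    m$faces <- m$faces[keep, , drop = FALSE]
    m$compartment <- m$compartment[keep]
  }
  m
}

#' @export
print.TriMesh <- function(x, ...) {
  cat(sprintf("TriMesh '%s': %d vertices, %d faces (%d medial, %d lateral)\n",
              x$label, nrow(x$vertices), nrow(x$faces),
              sum(x$compartment == "medial"), sum(x$compartment == "lateral")))
  invisible(x)
}

#' Per-face areas of a triangle mesh
#' @param mesh a `TriMesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(numeric(0))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

#' Area-weighted vertex normals
#' @param mesh a `TriMesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2A * unit normal
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    n[, 1] <- n[, 1] + tabulate_weighted(idx, fn[, 1], nrow(v))
    n[, 2] <- n[, 2] + tabulate_weighted(idx, fn[, 2], nrow(v))
    n[, 3] <- n[, 3] + tabulate_weighted(idx, fn[, 3], nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.xmin)
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Tributary (one-third incident) vertex areas
#' @param mesh a `TriMesh`.
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  a <- face_areas(mesh) / 3
  out <- numeric(nrow(mesh$vertices))
  for (k in 1:3) out <- out + tabulate_weighted(mesh$faces[, k], a, nrow(mesh$vertices))
  out
}

#' Total surface area
#' @param mesh a `TriMesh`.
#' @return total area (mm^2).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a closed, outward-oriented `TriMesh`.
#' @return volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Weld coincident vertices
#'
#' Merges vertices closer than `tol` (default 1e-6 mm, well below scanner
#' precision) and reindexes faces.
#'
#' @param mesh a `TriMesh`.
#' @param tol welding tolerance (mm).
#' @return a `TriMesh` with deduplicated vertices.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  key <- apply(round(mesh$vertices / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  # map into the compacted index space
  newidx <- cumsum(first)
  remap <- newidx[match(key[first], key)][map]
  trimesh(mesh$vertices[first, , drop = FALSE],
          matrix(remap[mesh$faces], ncol = 3),
          label = mesh$label, compartment = mesh$compartment)
}

#' Apply an affine transform to a mesh
#'
#' @param mesh a `TriMesh`.
#' @param A invertible 3 x 3 linear map.
#' @param t length-3 translation (mm).
#' @return transformed `TriMesh`; enclosed volume scales by `abs(det(A))`.
#' @export
affine_scale <- function(mesh, A = diag(3), t = c(0, 0, 0)) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(3, 3)) || abs(det(A)) < 1e-12)
    knee_stop("linear map must be an invertible 3x3 matrix", "knee_transform_error")
  out <- mesh
  out$vertices <- sweep(mesh$vertices %*% t(A), 2, -as.numeric(t))
  out
}

# ---- STL I/O ---------------------------------------------------------------

#' Read an STL file (binary or ASCII)
#'
#' Vertices are welded at 1e-6 mm; zero-area facets are dropped.
#'
#' @param path file path.
#' @param label label for the returned mesh (defaults to the solid name or
#'   file stem).
#' @return a `TriMesh`.
#' @export
read_stl <- function(path, label = NULL) {
  if (!file.exists(path) || file.info(path)$size == 0)
    knee_stop(sprintf("STL format error at byte 0: empty or missing file '%s'", path),
              "knee_format_error")
  head_raw <- readBin(path, "raw", n = min(512, file.info(path)$size))
  txt <- iconv(rawToChar(head_raw[head_raw != as.raw(0)]), "latin1", "ASCII",
               sub = "")
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  nt <- nrow(tri) / 3L
  mesh <- trimesh(tri, matrix(seq_len(3L * nt), ncol = 3, byrow = TRUE),
                  label = label %||% sub("\\.[^.]*$", "", basename(path)))
  weld_vertices(mesh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 84)
    knee_stop(sprintf("STL format error at byte %d: truncated binary header", sz),
              "knee_format_error")
  invisible(readBin(con, "raw", n = 80))
  nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(nt)
  if (nt < 0 || sz < expected)
    knee_stop(sprintf("STL format error at byte %d: expected %d facets (%d bytes)",
                      sz, nt, expected), "knee_format_error")
  if (nt < 1)
    knee_stop("STL format error at byte 80: no facets", "knee_format_error")
  rec <- readBin(con, "raw", n = 50 * nt)
  dim(rec) <- c(50, nt)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12L * nt, size = 4,
                  endian = "little")
  vals <- matrix(vals, ncol = 12, byrow = TRUE)  # normal + 3 vertices
  tri <- matrix(0, 3L * nt, 3)
  tri[seq(1, 3 * nt, by = 3), ] <- vals[, 4:6, drop = FALSE]
  tri[seq(2, 3 * nt, by = 3), ] <- vals[, 7:9, drop = FALSE]
  tri[seq(3, 3 * nt, by = 3), ] <- vals[, 10:12, drop = FALSE]
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    knee_stop(sprintf("STL format error at byte %d: vertex count %d not divisible by 3",
                      file.info(path)$size, length(vl)), "knee_format_error")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  tri <- do.call(rbind, nums)
  if (anyNA(tri))
    knee_stop("STL format error: unparsable vertex line", "knee_format_error")
  tri
}

#' Write an STL file
#'
#' @param mesh a `TriMesh`.
#' @param path output path.
#' @param ascii write ASCII STL instead of binary.
#' @return invisibly, `path`.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    cat(sprintf("solid %s\n", mesh$label), file = con)
    for (i in seq_len(nrow(f))) {
      cat(sprintf("facet normal %.9e %.9e %.9e\n outer loop\n", fn[i, 1], fn[i, 2], fn[i, 3]),
          file = con)
      for (k in 1:3)
        cat(sprintf("  vertex %.9e %.9e %.9e\n", v[f[i, k], 1], v[f[i, k], 2], v[f[i, k], 3]),
            file = con)
      cat(" endloop\nendfacet\n", file = con)
    }
    cat(sprintf("endsolid %s\n", mesh$label), file = con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("kneefdk", mesh$label)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(fn[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

# ---- RBF morphing ----------------------------------------------------------

#' Landmark set
#' @param names character vector of unique landmark names.
#' @param positions n x 3 matrix (mm).
#' @return a `LandmarkSet`.
#' @export
landmark_set <- function(names, positions) {
  positions <- as.matrix(positions)
  if (anyDuplicated(names)) knee_stop("landmark names must be unique", "knee_pairing_error")
  if (length(names) != nrow(positions))
    knee_stop("names/positions length mismatch", "knee_pairing_error")
  structure(list(names = as.character(names), positions = positions),
            class = "LandmarkSet")
}

#' Read/write landmark sets as delimited text (name, x, y, z in mm)
#' @param path file path.
#' @return a `LandmarkSet`.
#' @export
read_landmarks <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  landmark_set(d$name, as.matrix(d[, c("x", "y", "z")]))
}

#' @rdname read_landmarks
#' @param lm a `LandmarkSet`.
#' @export
write_landmarks <- function(lm, path) {
  d <- data.frame(name = lm$names, x = lm$positions[, 1],
                  y = lm$positions[, 2], z = lm$positions[, 3])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Triharmonic kernel |r|^3: the 3-D analogue of the thin-plate spline. With
# the first-order polynomial term the interpolant reproduces affine maps
# exactly, which is what bone-morphing workflows rely on.
rbf_fit <- function(src, dst) {
  n <- nrow(src)
  if (n < 4) knee_stop("need at least 4 landmark pairs", "knee_conditioning_error")
  P <- cbind(1, src)
  if (qr(P)$rank < 4)
    knee_stop("landmarks are coplanar or collinear: RBF system ill-conditioned",
              "knee_conditioning_error")
  D <- as.matrix(dist(src))
  if (any(D[upper.tri(D)] < 1e-9))
    knee_stop("duplicate landmarks: RBF system ill-conditioned", "knee_conditioning_error")
  K <- D^3
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  co <- tryCatch(solve(M, rhs), error = function(e)
    knee_stop("RBF system singular", "knee_conditioning_error"))
  list(src = src, w = co[1:n, , drop = FALSE], a = co[(n + 1):(n + 4), , drop = FALSE])
}

rbf_eval <- function(fit, pts) {
  # ||pts_i - src_j||^3 cross-distance
  d2 <- outer(rowSums(pts^2), rep(1, nrow(fit$src))) +
    outer(rep(1, nrow(pts)), rowSums(fit$src^2)) - 2 * pts %*% t(fit$src)
  K <- pmax(d2, 0)^1.5
  K %*% fit$w + cbind(1, pts) %*% fit$a
}

#' Nonlinear landmark-driven mesh morphing
#'
#' Triharmonic (r^3) radial-basis interpolation with a first-order polynomial
#' term. Source landmarks are mapped exactly onto their targets; landmark
#' configurations related by an affine map are reproduced exactly at every
#' mesh vertex.
#'
#' @param mesh a `TriMesh` to deform.
#' @param source,target `LandmarkSet`s with identical name sets (>= 4
#'   non-coplanar pairs).
#' @return the morphed `TriMesh`.
#' @export
rbf_morph <- function(mesh, source, target) {
  if (!setequal(source$names, target$names))
    knee_stop("source/target landmark names do not match", "knee_pairing_error")
  ord <- match(source$names, target$names)
  fit <- rbf_fit(source$positions, target$positions[ord, , drop = FALSE])
  out <- mesh
  out$vertices <- rbf_eval(fit, mesh$vertices)
  out
}

#' Project mesh vertices onto a target surface
#'
#' Moves each vertex to its closest point on the target triangulation (the
#' final surface-snap step of bone morphing). Idempotent.
#'
#' @param mesh a `TriMesh`.
#' @param target a `TriMesh` covering the projection footprint.
#' @return the projected `TriMesh`.
#' @export
project_to_surface <- function(mesh, target) {
  if (nrow(target$faces) == 0)
    knee_stop("projection target has no faces", "knee_mesh_error")
  out <- mesh
  out$vertices <- cpp_closest_points(mesh$vertices, target$vertices, target$faces)
  out
}

# ---- length-mass-fat scaling ----------------------------------------------

#' Length-mass-fat scale factors
#'
#' Scaling convention for segments treated as fat-free-mass cylinders:
#' longitudinal factor is the segment length ratio; the radial factor
#' preserves fat-free mass density, and the strength factor scales maximum
#' isometric muscle force with fat-free mass per unit length.
#'
#' @param subject,generic lists with elements `mass` (kg), `length` (m),
#'   `fat` (fat fraction in `[0, 1)`).
#' @return a `ScaleFactors` list: `longitudinal`, `radial`, `strength`.
#' @export
length_mass_fat_factors <- function(subject, generic) {
  chk <- function(p) {
    if (p$mass <= 0 || p$length <= 0 || p$fat < 0 || p$fat >= 1)
      knee_stop("mass/length must be positive and fat fraction in [0,1)",
                "knee_domain_error")
  }
  chk(subject); chk(generic)
  kl <- subject$length / generic$length
  km <- (subject$mass * (1 - subject$fat)) / (generic$mass * (1 - generic$fat))
  out <- list(longitudinal = kl, radial = sqrt(km / kl), strength = km / kl)
  class(out) <- "ScaleFactors"
  out
}
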