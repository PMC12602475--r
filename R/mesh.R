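#' Triangle surface mesh
#'
#' Vertices (mm) in a named body frame plus triangle connectivity.  Face
#' normals, face areas, outward vertex normals (area-weighted) and vertex
#' tributary areas (one third of the summed incident triangle areas) are
#' precomputed; degenerate triangles (area <= 1e-9 mm^2) are rejected.
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices, wound so
#'   that face normals point outward.
#' @param frame name of the body frame the coordinates live in
#'   (e.g. \code{"femur"}, \code{"tibia"}, \code{"ground"}).
#' @param open logical; \code{TRUE} marks an intentionally open patch
#'   (e.g. a cartilage facet), suppressing the non-watertight warning in
#'   \code{\link{penetration_query}}.
#' @return an object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, frame = "ground", open = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("surface_mesh: vertices and faces must have 3 columns", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("surface_mesh: non-finite vertex coordinates", call. = FALSE)
  nv <- nrow(vertices)
  if (min(faces) < 1L || max(faces) > nv)
    stop("surface_mesh: face indices out of range", call. = FALSE)

  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  cc <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  a2 <- sqrt(rowSums(cr^2))
  face_area <- a2 / 2
  if (any(face_area <= 1e-9))
    stop("surface_mesh: degenerate triangle(s) with area <= 1e-9 mm^2",
         call. = FALSE)
  face_normal <- cr / a2

  # area-weighted outward vertex normals and tributary areas
  vn <- matrix(0, nv, 3L)
  varea <- numeric(nv)
  w <- cr           # un-normalised face normal carries the area weight
  for (k in 1:3) {
    idx <- faces[, k]
    for (j in 1:3)
      vn[, j] <- vn[, j] + unname(tapply_add(w[, j], idx, nv))
    varea <- varea + unname(tapply_add(face_area / 3, idx, nv))
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm < 1e-12] <- 1
  vn <- vn / nrm

  # watertight iff every edge is shared by exactly two triangles
  ekey <- c(edge_key(faces[, 1L], faces[, 2L], nv),
            edge_key(faces[, 2L], faces[, 3L], nv),
            edge_key(faces[, 3L], faces[, 1L], nv))
  watertight <- all(tabulate(match(ekey, unique(ekey))) == 2L)

  structure(list(vertices = vertices, faces = faces, frame = frame,
                 face_normal = face_normal, face_area = face_area,
                 vertex_normal = vn, vertex_area = varea,
                 watertight = watertight, open = isTRUE(open),
                 cache = new.env(parent = emptyenv())),
            class = "surface_mesh")
}

# lazily built uniform-grid accelerator, in the mesh's own coordinates
mesh_grid <- function(mesh) {
  if (is.null(mesh$cache$grid))
    mesh$cache$grid <- cpp_grid_build(mesh$vertices, mesh$faces,
                                      mesh$vertex_normal)
  mesh$cache$grid
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

edge_key <- function(i, j, nv) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.numeric(lo) * (nv + 1) + hi
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, frame '%s'%s\n",
              nrow(x$vertices), nrow(x$faces), x$frame,
              if (x$watertight) ", watertight" else ""))
  invisible(x)
}

#' Rigidly transform a mesh
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector (mm).
#' @param frame frame name of the result.
#' @return transformed \code{surface_mesh}.
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0),
                           frame = "ground") {
  V <- mesh$vertices %*% t(R)
  V <- sweep(V, 2L, -as.numeric(t))
  out <- mesh
  out$vertices <- V
  out$face_normal <- mesh$face_normal %*% t(R)
  out$vertex_normal <- mesh$vertex_normal %*% t(R)
  out$frame <- frame
  out$cache <- new.env(parent = emptyenv())  # grid is coordinate-bound
  out
}

# place a body-frame mesh into the ground frame given the body's rigid state
mesh_to_ground <- function(mesh, state) {
  f <- as_rigid_state(state)$frame
  transform_mesh(mesh, frame_matrix(f), f$origin, frame = "ground")
}

#' Read a surface mesh from OBJ, ASCII STL or ASCII PLY
#'
#' Units are taken to be mm.  Only triangular faces are supported (OBJ/PLY
#' quads are fan-triangulated).
#'
#' @param path file path; format chosen by extension (.obj, .stl, .ply).
#' @param frame,open passed to \code{\link{surface_mesh}}.
#' @return a \code{\link{surface_mesh}}.
#' @export
read_mesh <- function(path, frame = "ground", open = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path, frame, open),
         stl = read_stl_ascii(path, frame, open),
         ply = read_ply_ascii(path, frame, open),
         stop("read_mesh: unsupported mesh format '.", ext, "'",
              call. = FALSE))
}

#' Write a surface mesh to OBJ, ASCII STL or ASCII PLY
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @param path output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = write_obj(mesh, path),
         stl = write_stl_ascii(mesh, path),
         ply = write_ply_ascii(mesh, path),
         stop("write_mesh: unsupported mesh format '.", ext, "'",
              call. = FALSE))
  invisible(path)
}

read_obj <- function(path, frame, open) {
  ln <- readLines(path, warn = FALSE)
  vln <- grep("^v\\s", ln, value = TRUE)
  fln <- grep("^f\\s", ln, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vln)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  tris <- list()
  for (l in fln) {
    toks <- strsplit(trimws(sub("^f", "", l)), "\\s+")[[1L]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1L))
    for (k in seq_len(length(idx) - 2L))
      tris[[length(tris) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
  }
  surface_mesh(V, do.call(rbind, tris), frame, open)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# kneesim surface mesh (mm)", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
}

read_stl_ascii <- function(path, frame, open) {
  ln <- readLines(path, warn = FALSE)
  vln <- grep("^\\s*vertex\\s", ln, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("vertex", "", vln)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  if (nrow(V) %% 3L != 0L)
    stop("read_mesh: malformed ASCII STL", call. = FALSE)
  # merge duplicated vertices so connectivity (and watertightness) survives
  key <- apply(round(V, 9), 1L, paste, collapse = ",")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  Vu <- V[uid, , drop = FALSE]
  Fm <- matrix(map, ncol = 3L, byrow = TRUE)
  surface_mesh(Vu, Fm, frame, open)
}

write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid kneesim", con)
  V <- mesh$vertices
  Fm <- mesh$faces
  N <- mesh$face_normal
  for (t in seq_len(nrow(Fm))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       N[t, 1L], N[t, 2L], N[t, 3L]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      v <- V[Fm[t, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1L], v[2L], v[3L]),
                 con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid kneesim", con)
}

read_ply_ascii <- function(path, frame, open) {
  ln <- readLines(path, warn = FALSE)
  if (!grepl("^ply", ln[1L]))
    stop("read_mesh: not a PLY file", call. = FALSE)
  if (!any(grepl("format ascii", ln)))
    stop("read_mesh: only ASCII PLY is supported", call. = FALSE)
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", ln, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", ln, value = TRUE)[1L]))
  hdr_end <- grep("^end_header", ln)[1L]
  vlines <- ln[(hdr_end + 1L):(hdr_end + nv)]
  flines <- ln[(hdr_end + nv + 1L):(hdr_end + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  tris <- list()
  for (l in flines) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1L]])
    n <- x[1L]
    idx <- x[2:(n + 1L)] + 1L       # PLY indices are 0-based
    for (k in seq_len(n - 2L))
      tris[[length(tris) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
  }
  surface_mesh(V, do.call(rbind, tris), frame, open)
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment kneesim surface mesh (mm)",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                     mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}
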