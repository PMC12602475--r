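#' Cartilage-on-cartilage penetration query
#'
#' Tests every vertex of the tibial cartilage against the femoral cartilage
#' surface, both placed in the ground frame by their bodies' rigid states.
#' A vertex lying on the inner (non-outward) side of the femoral surface is
#' in contact; its penetration depth \code{delta} is the distance to the
#' nearest point of the femoral surface, the contact normal is the outward
#' femoral face normal there, and the tributary area is one third of the
#' vertex's incident triangle area.  For an open (non-watertight) femoral
#' patch the inside test is the signed distance along the nearest-point
#' normal; a warning is emitted unless the mesh is flagged \code{open}.
#'
#' @param femoral_cartilage,tibial_cartilage \code{\link{surface_mesh}}es in
#'   their body frames (or already in ground if the matching state is an
#'   identity pose).
#' @param femur_state,tibia_state \code{\link{rigid_state}}s of the two
#'   bodies in the ground frame.
#' @param max_dist search cutoff (mm): vertices farther than this from the
#'   femoral surface are reported as out of contact without an exact
#'   distance.
#' @param inside_only if \code{TRUE} (default), vertices outside the
#'   femoral mesh's bounding box are skipped outright -- they cannot
#'   penetrate; set \code{FALSE} when the signed gap of separated surfaces
#'   is wanted in \code{min_gap}.
#' @param subset optional integer vector of tibial vertex indices to
#'   restrict the query to (the equilibrium solver's active set).
#' @param near_margin if positive, the indices of vertices whose signed
#'   distance is below this margin are returned in the
#'   \code{near_vertices} attribute (penetrating or nearly so).
#' @return a \code{contact_set}: data frame with one row per penetrating
#'   tibial vertex and columns \code{vertex}, \code{x,y,z} (contact location,
#'   ground, mm), \code{nx,ny,nz} (outward femoral normal), \code{delta}
#'   (mm, >= 0), \code{delta_rate} (mm/s, closing positive) and \code{area}
#'   (mm^2).  The attribute \code{min_gap} carries the smallest signed
#'   vertex-to-surface distance seen (negative inside), when resolved
#'   within \code{max_dist}.
#' @export
penetration_query <- function(femoral_cartilage, tibial_cartilage,
                              femur_state = NULL, tibia_state = NULL,
                              max_dist = 6, inside_only = TRUE,
                              subset = NULL, near_margin = 0) {
  fm <- femoral_cartilage
  tm <- tibial_cartilage
  # a near-margin query must see vertices just outside the bounding box:
  # they may enter contact within the margin
  if (near_margin > 0) inside_only <- FALSE
  if (!fm$watertight && !fm$open)
    warning("femoral cartilage is not watertight; inside test falls back ",
            "to the signed distance along the nearest-point normal",
            call. = FALSE)

  # work in the femoral mesh's own coordinates so its grid can be reused
  P <- tm$vertices
  if (!is.null(subset)) P <- P[subset, , drop = FALSE]
  RT <- diag(3); oT <- c(0, 0, 0)
  RF <- diag(3); oF <- c(0, 0, 0)
  if (!is.null(tibia_state)) {
    fr <- as_rigid_state(tibia_state)$frame
    RT <- frame_matrix(fr); oT <- fr$origin
    P <- P %*% t(RT)
    P <- sweep(P, 2L, -oT)              # tibial vertices in ground
  }
  if (!is.null(femur_state)) {
    fr <- as_rigid_state(femur_state)$frame
    RF <- frame_matrix(fr); oF <- fr$origin
    P <- sweep(P, 2L, oF) %*% RF        # ground -> femoral body frame
  }

  res <- cpp_grid_query(mesh_grid(fm), P, max_dist, inside_only)
  valid <- res[, 6L] == 1
  sdist <- res[, 1L]
  # projections onto an open-patch rim (boundary edge/vertex) do not
  # define a penetration: the surface simply ends there
  interior <- valid & res[, 10L] == 0
  pen <- which(interior & sdist < 0)
  near <- if (near_margin > 0) which(interior & sdist < near_margin)
          else integer(0)
  vid <- if (is.null(subset)) pen else subset[pen]

  loc <- res[pen, 2:4, drop = FALSE]
  # outward femoral normal, Phong-interpolated from vertex normals at the
  # nearest point so it (and the signed distance measured along it)
  # varies continuously across facet boundaries
  nrm <- res[pen, 7:9, drop = FALSE]
  if (!is.null(femur_state)) {          # femoral body frame -> ground
    loc <- sweep(loc %*% t(RF), 2L, -oF)
    nrm <- nrm %*% t(RF)
  }

  # relative closing rate along the contact normal (zero in quasi-static use)
  rate <- numeric(length(pen))
  if (length(pen)) {
    vT <- if (is.null(tibia_state)) c(0, 0, 0) else as_rigid_state(tibia_state)$v
    wT <- if (is.null(tibia_state)) c(0, 0, 0) else as_rigid_state(tibia_state)$w
    vF <- if (is.null(femur_state)) c(0, 0, 0) else as_rigid_state(femur_state)$v
    wF <- if (is.null(femur_state)) c(0, 0, 0) else as_rigid_state(femur_state)$w
    if (any(c(vT, wT, vF, wF) != 0)) {
      for (k in seq_along(pen)) {
        pg <- as.numeric(RT %*% tm$vertices[vid[k], ]) + oT
        vel_t <- vT + vcross(wT, pg - oT)
        vel_f <- vF + vcross(wF, loc[k, ] - oF)
        # penetration grows when the tibial vertex moves against the
        # outward femoral normal
        rate[k] <- -sum((vel_t - vel_f) * nrm[k, ])
      }
    }
  }

  out <- data.frame(
    vertex = vid,
    x = loc[, 1L], y = loc[, 2L], z = loc[, 3L],
    nx = nrm[, 1L], ny = nrm[, 2L], nz = nrm[, 3L],
    delta = -sdist[pen],
    delta_rate = rate,
    area = tm$vertex_area[vid]
  )
  class(out) <- c("contact_set", class(out))
  attr(out, "min_gap") <- if (any(valid)) min(sdist[valid]) else NA_real_
  attr(out, "near_vertices") <-
    if (is.null(subset)) near else subset[near]
  out
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> %d contact point(s)", nrow(x)))
  if (nrow(x))
    cat(sprintf(", max delta %.4f mm, area %.1f mm^2",
                max(x$delta), sum(x$area)))
  cat("\n")
  invisible(x)
}

#' Analytic sphere-on-plane contact oracle
#'
#' Closed-form deepest penetration of a sphere of radius \code{radius}
#' whose centre sits \code{center_height} above an infinite plane with
#' upward normal \code{(0,0,1)}: \code{delta = max(0, radius -
#' center_height)}.
#'
#' @param radius sphere radius (mm), > 0.
#' @param center_height height of the sphere centre above the plane (mm).
#' @return list with \code{delta} (mm) and \code{normal}.
#' @export
sphere_plane_oracle <- function(radius, center_height) {
  stopifnot(radius > 0)
  list(delta = max(0, radius - center_height), normal = c(0, 0, 1))
}

#' Meshed sphere (UV parameterisation)
#'
#' @param radius radius (mm).
#' @param center centre (mm).
#' @param n_theta,n_phi latitude/longitude resolution.
#' @param frame frame name.
#' @return a watertight \code{\link{surface_mesh}} with outward normals.
#' @export
mesh_uv_sphere <- function(radius = 1, center = c(0, 0, 0), n_theta = 32,
                           n_phi = 64, frame = "ground") {
  th <- seq(0, pi, length.out = n_theta + 1L)[2:n_theta]   # exclude poles
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  g <- expand.grid(th = th, ph = ph)
  V <- cbind(radius * sin(g$th) * cos(g$ph),
             radius * sin(g$th) * sin(g$ph),
             radius * cos(g$th))
  V <- rbind(c(0, 0, radius), c(0, 0, -radius), V)
  idx <- function(i, j) 2L + i + ((j - 1L) %% n_phi) * (n_theta - 1L)
  tris <- list()
  for (j in seq_len(n_phi)) {
    # pole caps
    tris[[length(tris) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(2L, idx(n_theta - 1L, j + 1L),
                                   idx(n_theta - 1L, j))
    for (i in seq_len(n_theta - 2L)) {
      tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j),
                                     idx(i + 1L, j + 1L))
      tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L),
                                     idx(i, j + 1L))
    }
  }
  V <- sweep(V, 2L, -as.numeric(center))
  surface_mesh(V, do.call(rbind, tris), frame)
}

#' Meshed rectangular plane patch
#'
#' A regular triangulated grid on z = 0 with upward (+z) normals.
#'
#' @param half_extent half side length (mm).
#' @param n grid resolution per side.
#' @param frame frame name.
#' @return an open \code{\link{surface_mesh}}.
#' @export
mesh_plane_grid <- function(half_extent = 2, n = 40, frame = "ground") {
  s <- seq(-half_extent, half_extent, length.out = n + 1L)
  g <- expand.grid(x = s, y = s)
  V <- cbind(g$x, g$y, 0)
  idx <- function(i, j) i + (j - 1L) * (n + 1L)
  tris <- vector("list", 2L * n * n)
  k <- 0L
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      k <- k + 1L
      tris[[k]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
      k <- k + 1L
      tris[[k]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
  }
  surface_mesh(V, do.call(rbind, tris), frame, open = TRUE)
}
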