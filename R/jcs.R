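#' Anatomical landmark set
#'
#' Bundles the ten named anatomical points (mm) from which the femoral and
#' tibial body frames are constructed: femoral lateral/medial epicondyles
#' (\code{Lepi}, \code{Mepi}), most posterior points of the lateral/medial
#' condyles (\code{Lppc}, \code{Mppc}), hip-ball centre (\code{Chip}) and
#' femoral origin (\code{Ofem}); tibial medial/lateral condyle centres
#' (\code{Mctc}, \code{Lctc}), ankle centre (\code{Cank}) and tibial origin
#' (\code{Otib}).
#'
#' @param points named list of ten numeric 3-vectors (mm).
#' @param side \code{"right"} or \code{"left"}; controls the sign convention
#'   of the X axes (lateral for a right limb, medial for a left limb).
#' @return an object of class \code{landmark_set}.
#' @export
landmark_set <- function(points, side = c("right", "left")) {
  side <- match.arg(side)
  required <- c("Lepi", "Mepi", "Mppc", "Lppc", "Chip", "Ofem",
                "Mctc", "Lctc", "Cank", "Otib")
  missing <- setdiff(required, names(points))
  if (length(missing))
    stop("landmark_set: missing points: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pts <- lapply(points[required], v3)
  bad <- names(pts)[!vapply(pts, function(p) all(is.finite(p)), logical(1L))]
  if (length(bad))
    stop("landmark_set: non-finite coordinates for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  distinct <- function(a, b, what) {
    if (vnorm(pts[[a]] - pts[[b]]) < 1e-9)
      stop("landmark_set: ", a, " and ", b, " coincide (", what, ")",
           call. = FALSE)
  }
  distinct("Chip", "Ofem", "femoral long axis")
  distinct("Mppc", "Lppc", "femoral posterior condylar axis")
  distinct("Otib", "Cank", "tibial mechanical axis")
  distinct("Mctc", "Lctc", "tibial transverse axis")
  structure(list(points = pts, side = side), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> side:", x$side, "-", length(x$points), "points\n")
  invisible(x)
}

#' Orthonormal body frame
#'
#' An origin plus a right-handed orthonormal triad, all expressed in some
#' enclosing coordinate system (mm).
#'
#' @param origin numeric 3-vector (mm).
#' @param X,Y,Z unit 3-vectors; must be pairwise orthogonal and right-handed.
#' @param side limb side the frame belongs to; for a left limb the clinical
#'   sign conventions of adduction and internal rotation are inverted in
#'   \code{\link{decompose_joint}} so that mirrored knees report identical
#'   angles.
#' @return an object of class \code{body_frame}.
#' @export
body_frame <- function(origin, X, Y, Z, side = c("right", "left")) {
  side <- match.arg(side)
  origin <- v3(origin); X <- v3(X); Y <- v3(Y); Z <- v3(Z)
  f <- structure(list(origin = origin, X = X, Y = Y, Z = Z, side = side),
                 class = "body_frame")
  validate_body_frame(f)
  f
}

validate_body_frame <- function(f, tol = 1e-9) {
  for (a in c("X", "Y", "Z"))
    if (abs(vnorm(f[[a]]) - 1) > tol)
      stop("body_frame: axis ", a, " is not unit length", call. = FALSE)
  if (abs(sum(f$X * f$Y)) > tol || abs(sum(f$Y * f$Z)) > tol ||
      abs(sum(f$Z * f$X)) > tol)
    stop("body_frame: axes are not orthogonal", call. = FALSE)
  if (abs(sum(vcross(f$X, f$Y) * f$Z) - 1) > tol)
    stop("body_frame: triad is not right-handed", call. = FALSE)
  invisible(f)
}

#' @export
print.body_frame <- function(x, ...) {
  cat("<body_frame> origin:", sprintf("%.3f", x$origin), "mm\n")
  m <- rbind(X = x$X, Y = x$Y, Z = x$Z)
  print(round(m, 6))
  invisible(x)
}

# 3x3 rotation matrix with the frame axes as columns.
frame_matrix <- function(f) cbind(f$X, f$Y, f$Z, deparse.level = 0L)

frame_from_matrix <- function(origin, R, side = "right") {
  body_frame(origin, R[, 1L], R[, 2L], R[, 3L], side = side)
}

#' Rigid state of a body
#'
#' A \code{\link{body_frame}} placed in the ground coordinate system plus
#' optional linear (mm/s) and angular (rad/s) velocities; both default to
#' zero, which is the quasi-static case.
#'
#' @param frame a \code{body_frame} expressed in ground coordinates.
#' @param v,w linear (mm/s) and angular (rad/s) velocity 3-vectors.
#' @return an object of class \code{rigid_state}.
#' @export
rigid_state <- function(frame, v = c(0, 0, 0), w = c(0, 0, 0)) {
  validate_body_frame(frame)
  structure(list(frame = frame, v = v3(v), w = v3(w)),
            class = "rigid_state")
}

as_rigid_state <- function(x) {
  if (inherits(x, "rigid_state")) return(x)
  if (inherits(x, "body_frame")) return(rigid_state(x))
  stop("expected a rigid_state or body_frame", call. = FALSE)
}

# Shared triad construction: Z along `long`, side-adjusted transverse
# direction `trans` (medial -> lateral), Y = unit(Z x trans), X = Y x Z.
# The side flag flips the transverse direction so that X points laterally
# for a right limb and medially for a left limb while the triad stays
# right-handed with Y anterior and Z proximal.
build_frame_zd <- function(origin, long, trans, side) {
  Z <- vunit(long)
  d <- vunit(trans)
  if (side == "left") d <- -d
  zc <- vcross(Z, d)
  if (vnorm(zc) < 1e-9)
    stop("degenerate landmark geometry: longitudinal and transverse ",
         "directions are collinear; frame is not constructible",
         call. = FALSE)
  Y <- vunit(zc)
  X <- vunit(vcross(Y, Z))
  body_frame(origin, X, Y, Z, side = side)
}

#' Construct the femoral anatomical frame
#'
#' Origin at \code{Ofem}; Z along \code{Ofem -> Chip} (proximal); Y is the
#' normalised cross product of Z with the posterior-condyle direction
#' \code{Mppc -> Lppc} (anterior); X completes the right-handed triad and
#' points laterally for a right limb, medially for a left limb.
#'
#' @param landmarks a \code{\link{landmark_set}}.
#' @return a \code{\link{body_frame}}.
#' @export
build_femoral_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points
  build_frame_zd(p$Ofem, p$Chip - p$Ofem, p$Lppc - p$Mppc, landmarks$side)
}

#' Construct the tibial anatomical frame
#'
#' Origin at \code{Otib}; Z along the tibial mechanical axis
#' \code{Cank -> Otib}; Y from the cross product of Z with the condyle-centre
#' direction \code{Mctc -> Lctc}; X completes the triad with the same side
#' convention as \code{\link{build_femoral_frame}}.
#'
#' @inheritParams build_femoral_frame
#' @return a \code{\link{body_frame}}.
#' @export
build_tibial_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points
  build_frame_zd(p$Otib, p$Otib - p$Cank, p$Lctc - p$Mctc, landmarks$side)
}

#' Joint coordinates of the tibiofemoral articulation
#'
#' The clinical joint coordinate system: flexion--extension \code{alpha}
#' about the femoral X axis, tibial internal--external rotation \code{gamma}
#' about the tibial Z axis, and abduction--adduction \code{pi/2 - beta} about
#' the floating axis \code{e2} perpendicular to both.  The origin-to-origin
#' vector \code{H} is resolved both as joint translations \code{S1,S2,S3}
#' (components in the generally non-orthogonal joint basis) and clinical
#' translations \code{q1,q2,q3} (orthogonal projections onto the joint axes).
#' \code{S2} always equals \code{q2}; \code{S1 = q1} and \code{S3 = q3} only
#' at zero adduction.
#'
#' @param alpha flexion(+)/extension(-) angle.
#' @param adduction abduction--adduction angle (\code{pi/2 - beta}).
#' @param gamma tibial internal--external rotation.
#' @param S1,S2,S3 joint translations (mm) along \code{e1,e2,e3}.
#' @param degrees if \code{TRUE} the three angles are given in degrees.
#' @return an object of class \code{joint_coordinates}.  Fields \code{H},
#'   \code{q1..q3} and the axes \code{e1,e2,e3} are filled in by
#'   \code{\link{decompose_joint}}/\code{\link{compose_joint}}.
#' @export
joint_coordinates <- function(alpha = 0, adduction = 0, gamma = 0,
                              S1 = 0, S2 = 0, S3 = 0, degrees = FALSE) {
  if (degrees) {
    alpha <- deg2rad(alpha); adduction <- deg2rad(adduction)
    gamma <- deg2rad(gamma)
  }
  beta <- pi / 2 - adduction
  if (beta <= 0 || beta >= pi)
    stop("joint_coordinates: beta must lie strictly in (0, pi)", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 adduction = adduction,
                 S1 = S1, S2 = S2, S3 = S3,
                 q1 = NA_real_, q2 = NA_real_, q3 = NA_real_,
                 H = rep(NA_real_, 3L),
                 e1 = NULL, e2 = NULL, e3 = NULL),
            class = "joint_coordinates")
}

#' @export
print.joint_coordinates <- function(x, ...) {
  cat(sprintf(
    "<joint_coordinates> flexion %.3f deg, adduction %.3f deg, int-ext %.3f deg\n",
    rad2deg(x$alpha), rad2deg(x$adduction), rad2deg(x$gamma)))
  cat(sprintf("  S = (%.3f, %.3f, %.3f) mm", x$S1, x$S2, x$S3))
  if (!is.na(x$q1))
    cat(sprintf(";  q = (%.3f, %.3f, %.3f) mm", x$q1, x$q2, x$q3))
  cat("\n")
  invisible(x)
}

#' Decompose a relative femur/tibia pose into joint coordinates
#'
#' The two embedded joint axes are the femoral X (\code{e1}) and tibial Z
#' (\code{e3}); the floating axis is \code{e2 = unit(e3 x e1)}.  The relative
#' orientation is factored as a rotation by \code{-alpha} about the femoral
#' X, then \code{adduction} about the floating axis, then \code{gamma} about
#' the tibial Z (flexion positive when the tibia swings posteriorly under
#' the femur).  Joint translations solve \code{H = S1 e1 + S2 e2 + S3 e3} in
#' the non-orthogonal joint basis; clinical translations are the orthogonal
#' projections \code{q_i = H . e_i}.
#'
#' @param femur,tibia \code{\link{rigid_state}}s (or bare
#'   \code{\link{body_frame}}s) in the ground coordinate system.
#' @return a \code{\link{joint_coordinates}} with all fields filled.
#' @export
decompose_joint <- function(femur, tibia) {
  fF <- as_rigid_state(femur)$frame
  fT <- as_rigid_state(tibia)$frame
  RF <- frame_matrix(fF)
  RT <- frame_matrix(fT)
  Rrel <- crossprod(RF, RT)             # tibial axes in femoral coordinates

  s_ad <- Rrel[1L, 3L]                  # sin(adduction)
  if (abs(abs(s_ad) - 1) < 1e-12 ||
      (Rrel[2L, 3L]^2 + Rrel[3L, 3L]^2) < 1e-24)
    stop("decompose_joint: femoral X parallel to tibial Z ",
         "(beta = 0 or pi); joint coordinates are gimbal-degenerate",
         call. = FALSE)
  adduction <- asin(max(-1, min(1, s_ad)))
  alpha <- atan2(Rrel[2L, 3L], Rrel[3L, 3L])
  gamma <- atan2(-Rrel[1L, 2L], Rrel[1L, 1L])
  if (identical(fF$side %||% "right", "left")) {
    # left limb: clinical adduction / internal rotation have opposite sign
    adduction <- -adduction
    gamma <- -gamma
  }

  e1 <- fF$X
  e3 <- fT$Z
  e2 <- vunit(vcross(e3, e1))
  H <- fT$origin - fF$origin
  E <- cbind(e1, e2, e3, deparse.level = 0L)
  S <- solve(E, H)
  q <- as.numeric(crossprod(E, H))

  jc <- joint_coordinates(alpha, adduction, gamma, S[1L], S[2L], S[3L])
  jc$H <- H
  jc$q1 <- q[1L]; jc$q2 <- q[2L]; jc$q3 <- q[3L]
  jc$e1 <- e1; jc$e2 <- e2; jc$e3 <- e3
  jc
}

#' Place the tibia from joint coordinates
#'
#' Inverse of \code{\link{decompose_joint}}: given the femoral pose and a
#' full set of joint coordinates, returns the tibial rigid state such that
#' decomposing the pair reproduces the coordinates.
#'
#' @param jc a \code{\link{joint_coordinates}} (angles in radians,
#'   translations in mm).
#' @param femur femoral \code{\link{rigid_state}} (or \code{body_frame}).
#' @return tibial \code{\link{rigid_state}}.
#' @export
compose_joint <- function(jc, femur) {
  stopifnot(inherits(jc, "joint_coordinates"))
  if (jc$beta <= 0 || jc$beta >= pi)
    stop("compose_joint: degenerate beta", call. = FALSE)
  fF <- as_rigid_state(femur)$frame
  RF <- frame_matrix(fF)
  sgn <- if (identical(fF$side %||% "right", "left")) -1 else 1
  Rrel <- rot_x(-jc$alpha) %*% rot_y(sgn * jc$adduction) %*%
    rot_z(sgn * jc$gamma)
  RT <- RF %*% Rrel
  e1 <- fF$X
  e3 <- RT[, 3L]
  e2 <- vunit(vcross(e3, e1))
  origin <- fF$origin + jc$S1 * e1 + jc$S2 * e2 + jc$S3 * e3
  rigid_state(frame_from_matrix(origin, RT, side = fF$side %||% "right"))
}
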