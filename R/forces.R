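#' Contact-law parameters
#'
#' Penalty contact between cartilage surfaces: static part
#' \code{k * delta^p}, plus a damping part \code{delta_rate * C *
#' h(delta, delta_c)} active only in dynamic-relaxation mode, where
#' \code{h} is a unity-gain smooth step over the transition interval
#' \code{delta_c}.
#'
#' @param k contact stiffness (N/mm^p per unit reference area), default 500.
#' @param p force-deformation exponent, default 1.5.
#' @param delta_c step transition interval (mm), default 0.01.
#' @param C damping coefficient (kg/s), default 5.
#' @param aggregation \code{"area"} distributes the law over the contact
#'   patch (per penetrating vertex, weighted by tributary area in mm^2);
#'   \code{"deepest"} applies a single resultant at the deepest
#'   penetration point, per compartment.
#' @return an object of class \code{contact_params}.
#' @export
contact_params <- function(k = 500, p = 1.5, delta_c = 0.01, C = 5,
                           aggregation = c("area", "deepest")) {
  stopifnot(k > 0, p >= 1, delta_c > 0, C >= 0)
  structure(list(k = k, p = p, delta_c = delta_c, C = C,
                 aggregation = match.arg(aggregation)),
            class = "contact_params")
}

#' Unity-gain smooth step
#'
#' Cubic Hermite step \code{3x^2 - 2x^3} with \code{x = delta/delta_c},
#' clamped to 0 below zero and 1 above \code{delta_c}; C1 at both ends.
#'
#' @param delta penetration depth (mm); vectorised.
#' @param delta_c transition interval (mm), > 0.
#' @return value in [0, 1].
#' @export
smooth_step <- function(delta, delta_c) {
  stopifnot(delta_c > 0)
  x <- pmin(pmax(delta / delta_c, 0), 1)
  3 * x^2 - 2 * x^3
}

#' Scalar contact force law
#'
#' Zero for separation; \code{k delta^p + delta_rate * C * h(delta,
#' delta_c)} for penetration (closing rate positive), clamped below at
#' zero so contact never pulls.
#'
#' @param delta penetration depth (mm); vectorised.
#' @param delta_rate closing rate (mm/s); positive when the penetration
#'   deepens.
#' @param params a \code{\link{contact_params}}.
#' @return normal force (N), >= 0.
#' @export
contact_force <- function(delta, delta_rate = 0, params = contact_params()) {
  f <- ifelse(delta < 0, 0,
              params$k * pmax(delta, 0)^params$p +
                delta_rate * params$C * smooth_step(delta, params$delta_c))
  pmax(f, 0)
}

# contact potential energy density: integral of k*delta^p over delta
contact_energy_density <- function(delta, params) {
  params$k * pmax(delta, 0)^(params$p + 1) / (params$p + 1)
}

#' Generalized force on the tibia
#'
#' Sums the 15 ligament tensions along their lines of action and the
#' cartilage contact forces along their outward femoral normals into a net
#' force (N) and torque (N mm) about the tibial origin, in the ground
#' frame.  The wrench on the femur is the equal-and-opposite wrench
#' transported to the femoral origin.
#'
#' @param model a \code{\link{knee_model}} with initialised ligaments.
#' @param femur,tibia \code{\link{rigid_state}}s in the ground frame.
#' @param max_dist contact query cutoff (mm).
#' @return list with \code{force}, \code{torque} (about the tibial origin),
#'   \code{femur_force}, \code{femur_torque} (about the femoral origin),
#'   \code{ligaments} (list of \code{\link{ligament_state}}s),
#'   \code{contacts} (a \code{contact_set}) and \code{contact_total}
#'   (total contact force magnitude, N).
#' @export
assemble_wrench <- function(model, femur, tibia, max_dist = 2,
                            contact_subset = NULL, near_margin = 0) {
  fF <- as_rigid_state(femur)$frame
  fT <- as_rigid_state(tibia)$frame
  oT <- fT$origin
  oF <- fF$origin

  force <- c(0, 0, 0)
  torque <- c(0, 0, 0)

  lig_states <- lapply(model$ligaments, function(spec) {
    ligament_state(spec, femur, tibia)
  })
  for (st in lig_states) {
    if (st$tension > 0) {
      f <- st$tension * st$direction          # pulls tibia toward femur
      force <- force + f
      torque <- torque + vcross(st$tibial_pt - oT, f)
    }
  }

  contacts <- penetration_query(model$femur_cartilage, model$tibia_cartilage,
                                femur, tibia, max_dist = max_dist,
                                subset = contact_subset,
                                near_margin = near_margin)
  contact_total <- 0
  if (nrow(contacts)) {
    fc <- contact_point_forces(contacts, model$contact)
    contact_total <- sum(fc)
    n <- cbind(contacts$nx, contacts$ny, contacts$nz)
    fvec <- n * fc
    force <- force + colSums(fvec)
    arm <- cbind(contacts$x - oT[1L], contacts$y - oT[2L],
                 contacts$z - oT[3L])
    torque <- torque + colSums(cbind(
      arm[, 2L] * fvec[, 3L] - arm[, 3L] * fvec[, 2L],
      arm[, 3L] * fvec[, 1L] - arm[, 1L] * fvec[, 3L],
      arm[, 1L] * fvec[, 2L] - arm[, 2L] * fvec[, 1L]))
  }

  # equal and opposite, transported to the femoral origin
  femur_force <- -force
  femur_torque <- -torque - vcross(oT - oF, force)

  list(force = force, torque = torque,
       femur_force = femur_force, femur_torque = femur_torque,
       ligaments = lig_states, contacts = contacts,
       contact_total = contact_total)
}

# per-contact-point scalar forces under the chosen aggregation mode
contact_point_forces <- function(contacts, params) {
  if (!nrow(contacts)) return(numeric(0))
  if (params$aggregation == "deepest") {
    fc <- numeric(nrow(contacts))
    i <- which.max(contacts$delta)
    fc[i] <- contact_force(contacts$delta[i], contacts$delta_rate[i], params)
    fc
  } else {
    contact_force(contacts$delta, contacts$delta_rate, params) *
      contacts$area
  }
}

# total potential energy (N*mm) of ligaments + contact at a given pose
total_energy <- function(model, femur, tibia, max_dist = 2,
                         contact_subset = NULL) {
  e <- 0
  for (spec in model$ligaments) {
    st_len <- ligament_length(spec, femur, tibia)
    e <- e + ligament_energy(spec, st_len)
  }
  contacts <- penetration_query(model$femur_cartilage, model$tibia_cartilage,
                                femur, tibia, max_dist = max_dist,
                                subset = contact_subset)
  if (nrow(contacts)) {
    if (model$contact$aggregation == "deepest") {
      e <- e + contact_energy_density(max(contacts$delta), model$contact)
    } else {
      e <- e + sum(contact_energy_density(contacts$delta, model$contact) *
                     contacts$area)
    }
  }
  e
}

ligament_length <- function(spec, femur, tibia) {
  fF <- as_rigid_state(femur)$frame
  fT <- as_rigid_state(tibia)$frame
  pf <- fF$origin + as.numeric(frame_matrix(fF) %*% spec$femoral_mm)
  pt <- fT$origin + as.numeric(frame_matrix(fT) %*% spec$tibial_mm)
  vnorm(pf - pt)
}
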