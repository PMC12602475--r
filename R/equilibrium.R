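#' Equilibrium solver settings
#'
#' @param tol residual tolerance on every component of the generalized
#'   force (N for translations, N mm for rotations), default 1e-3.
#' @param max_iter maximum Newton iterations per solve.
#' @param step_deg continuation step for flexion sweeps (degrees).
#' @param warm_start reuse the previous solution as the starting guess.
#' @param mode \code{"quasi-static"} (velocities and contact damping zero)
#'   or \code{"dynamic-relaxation"} (damped settling; the contact damping
#'   term is active).
#' @param contact_margin signed-distance margin (mm) for the solver's
#'   active contact set.
#' @param preload_N axial compressive preload (N) used only during
#'   contact-only solves (full-extension initialisation), where contact
#'   alone would leave the joint unloaded.
#' @param centering_force,centering_torque centering stiffnesses (N/mm,
#'   N mm/rad) that regularise, toward the neutral coordinates, the
#'   motions that frictionless contact alone cannot stabilise in
#'   contact-only solves (internal rotation, adduction and the two
#'   in-plane translations).
#' @return an object of class \code{equilibrium_settings}.
#' @export
equilibrium_settings <- function(tol = 1e-3, max_iter = 80, step_deg = 0.5,
                                 warm_start = TRUE,
                                 mode = c("quasi-static",
                                          "dynamic-relaxation"),
                                 contact_margin = 0.8,
                                 preload_N = 30, centering_force = 1,
                                 centering_torque = 500) {
  stopifnot(tol > 0, step_deg > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = max_iter, step_deg = step_deg,
                 warm_start = isTRUE(warm_start), mode = match.arg(mode),
                 contact_margin = contact_margin,
                 preload_N = preload_N,
                 centering_force = centering_force,
                 centering_torque = centering_torque),
            class = "equilibrium_settings")
}

# pose map: free coordinates u = (gamma, adduction, S1, S2, S3) at fixed
# flexion alpha -> tibial rigid state
free_coords_pose <- function(u, alpha, femur) {
  jc <- joint_coordinates(alpha = alpha, adduction = u[2L], gamma = u[1L],
                          S1 = u[3L], S2 = u[4L], S3 = u[5L])
  compose_joint(jc, femur)
}

free_coords_from_pose <- function(femur, tibia) {
  jc <- decompose_joint(femur, tibia)
  list(u = c(jc$gamma, jc$adduction, jc$S1, jc$S2, jc$S3),
       alpha = jc$alpha)
}

# numerical Jacobian of the pose map: columns are (d origin / d u_j) and
# (d rotation-vector / d u_j); cheap (no mesh work involved)
pose_jacobian <- function(u, alpha, femur, h = 1e-6) {
  Jo <- matrix(0, 3L, 5L)
  Jw <- matrix(0, 3L, 5L)
  for (j in 1:5) {
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    tp <- free_coords_pose(up, alpha, femur)$frame
    tm <- free_coords_pose(um, alpha, femur)$frame
    Jo[, j] <- (tp$origin - tm$origin) / (2 * h)
    W <- frame_matrix(tp) %*% t(frame_matrix(tm))
    Jw[, j] <- c(W[3L, 2L] - W[2L, 3L],
                 W[1L, 3L] - W[3L, 1L],
                 W[2L, 1L] - W[1L, 2L]) / (4 * h)
  }
  list(Jo = Jo, Jw = Jw)
}

# vectorised ligament parameter table (cached on the model's ligaments)
ligament_table_matrices <- function(model) {
  lig <- model$ligaments
  list(PF = do.call(rbind, lapply(lig, `[[`, "femoral_mm")),
       PT = do.call(rbind, lapply(lig, `[[`, "tibial_mm")),
       K_Q = vapply(lig, `[[`, numeric(1L), "K_Q"),
       K_L = vapply(lig, `[[`, numeric(1L), "K_L"),
       L0 = vapply(lig, `[[`, numeric(1L), "L0"),
       eps1 = vapply(lig, `[[`, numeric(1L), "epsilon1"),
       names = names(lig))
}

# generalized force and potential energy at u, restricted to an active
# contact subset (NULL = full query); contact-only solves add the axial
# preload and centering terms and drop the ligaments.  A single contact
# query feeds both the wrench and the energy.
eval_generalized <- function(u, alpha, femur, model, settings,
                             subset = NULL, contact_only = FALSE,
                             near_margin = 0, udot = NULL) {
  tibia <- free_coords_pose(u, alpha, femur)
  fF <- as_rigid_state(femur)$frame
  fT <- tibia$frame
  oT <- fT$origin
  J <- pose_jacobian(u, alpha, femur)
  if (!is.null(udot)) {
    # coordinate rates -> rigid-body velocities: the damping part of the
    # contact law sees the closing rate at each contact point
    tibia$v <- as.numeric(J$Jo %*% udot)
    tibia$w <- as.numeric(J$Jw %*% udot)
  }

  force <- c(0, 0, 0)
  torque <- c(0, 0, 0)
  E <- 0
  tensions <- NULL

  if (!contact_only) {
    lt <- model$cache$lig %||% ligament_table_matrices(model)
    if (is.null(model$cache$lig) && !is.null(model$cache))
      model$cache$lig <- lt
    pf <- sweep(lt$PF %*% t(frame_matrix(fF)), 2L, -fF$origin)
    pt <- sweep(lt$PT %*% t(frame_matrix(fT)), 2L, -oT)
    dvec <- pf - pt
    L <- sqrt(rowSums(dvec^2))
    eps <- (L - lt$L0) / lt$L0
    eps_t <- 2 * lt$eps1
    f <- numeric(15L)
    toe <- eps >= 0 & eps <= eps_t
    lin <- eps > eps_t
    f[toe] <- lt$K_Q[toe] * (L[toe] - lt$L0[toe])^2
    f[lin] <- lt$K_L[lin] * (L[lin] - lt$L0[lin] * (1 + lt$eps1[lin]))
    f <- pmax(f, 0)
    tensions <- setNames(f, lt$names)
    # strain energy
    e_el <- numeric(15L)
    e_el[toe] <- lt$K_Q[toe] * (L[toe] - lt$L0[toe])^3 / 3
    if (any(lin)) {
      Lt <- lt$L0[lin] * (1 + eps_t[lin])
      aa <- lt$L0[lin] * (1 + lt$eps1[lin])
      e_el[lin] <- lt$K_Q[lin] * (Lt - lt$L0[lin])^3 / 3 +
        lt$K_L[lin] / 2 * ((L[lin] - aa)^2 - (Lt - aa)^2)
    }
    E <- E + sum(e_el)
    taut <- f > 0
    if (any(taut)) {
      dirs <- dvec[taut, , drop = FALSE] / L[taut]
      fv <- dirs * f[taut]
      force <- force + colSums(fv)
      arm <- pt[taut, , drop = FALSE] -
        matrix(oT, sum(taut), 3L, byrow = TRUE)
      torque <- torque + colSums(cbind(
        arm[, 2L] * fv[, 3L] - arm[, 3L] * fv[, 2L],
        arm[, 3L] * fv[, 1L] - arm[, 1L] * fv[, 3L],
        arm[, 1L] * fv[, 2L] - arm[, 2L] * fv[, 1L]))
    }
  }

  contacts <- penetration_query(model$femur_cartilage,
                                model$tibia_cartilage, femur, tibia,
                                max_dist = 1.5, subset = subset,
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
    if (model$contact$aggregation == "deepest") {
      E <- E + contact_energy_density(max(contacts$delta), model$contact)
    } else {
      E <- E + sum(contact_energy_density(contacts$delta, model$contact) *
                     contacts$area)
    }
  }

  Q <- as.numeric(crossprod(J$Jo, force) + crossprod(J$Jw, torque))

  if (contact_only) {
    zF <- fF$Z
    # compressive preload along the femoral long axis
    Q <- Q + settings$preload_N * as.numeric(crossprod(J$Jo, zF))
    E <- E - settings$preload_N * sum(oT * zF)
    # centering of the coordinates contact cannot stabilise
    kr <- settings$centering_torque
    kt <- settings$centering_force
    Q <- Q - c(kr * u[1L], kr * u[2L], kt * u[3L], kt * u[4L], 0)
    E <- E + 0.5 * (kr * (u[1L]^2 + u[2L]^2) + kt * (u[3L]^2 + u[4L]^2))
  }

  wr <- list(force = force, torque = torque, contacts = contacts,
             contact_total = contact_total, tensions = tensions)
  list(Q = Q, E = E, wrench = wr, tibia = tibia)
}

#' Relax the tibia to static equilibrium at fixed flexion
#'
#' Solves for the five free joint coordinates -- internal rotation,
#' adduction and the three joint translations -- with flexion held at
#' the prescribed value, by a two-phase damped Newton iteration: global
#' descent on the total potential energy (ligament strain energy plus
#' penalty contact energy, with a monotone energy trace), then a
#' monotone polish of the force balance itself, because the smoothed
#' contact force field is the energy gradient only to first order.
#' Convergence requires every generalized-force component to fall below
#' \code{settings$tol}, evaluated on the full (non-cached) contact set.
#'
#' @param model an initialised \code{\link{knee_model}} (contact-only mode
#'   excepted).
#' @param femur femoral \code{\link{rigid_state}} (held fixed).
#' @param tibia starting tibial \code{\link{rigid_state}} (guess).
#' @param alpha prescribed flexion (rad); default: the flexion of the
#'   starting pose.
#' @param settings an \code{\link{equilibrium_settings}}.
#' @param contact_only drop the ligaments and add the axial preload and
#'   centering terms (full-extension initialisation mode).
#' @param H0 optional 5x5 Hessian from a neighbouring solve, used as the
#'   starting curvature model (warm-started continuation).
#' @return list with \code{tibia} (equilibrium state), \code{u} (free
#'   coordinates), \code{converged}, \code{iterations}, \code{residual}
#'   (max abs generalized force at the solution), \code{residuals}
#'   (per-coordinate), \code{energy}, \code{energy_trace} and
#'   \code{wrench} (final full wrench).
#' @export
relax_to_equilibrium <- function(model, femur, tibia, alpha = NULL,
                                 settings = equilibrium_settings(),
                                 contact_only = FALSE, H0 = NULL) {
  fc0 <- free_coords_from_pose(femur, tibia)
  if (is.null(alpha)) alpha <- fc0$alpha
  u <- fc0$u

  active <- NULL
  refresh <- function(u) {
    ev <- eval_generalized(u, alpha, femur, model, settings,
                           subset = NULL, contact_only = contact_only,
                           near_margin = settings$contact_margin)
    active <<- attr(ev$wrench$contacts, "near_vertices")
    ev
  }

  # `ev` always holds a full-query evaluation at the current u; the
  # active subset is rebuilt from it after every accepted step, so the
  # cheap subset evaluations used for the Hessian and the line search
  # agree with it exactly at u (a single trust-region step cannot move a
  # vertex across the contact margin)
  # Two phases.  Phase 1 descends the total potential energy globally.
  # Because the contact normal field is smoothed, the analytic wrench is
  # the gradient of the energy only to first order, so the energy
  # minimiser and the force-balance root are distinct points a small
  # distance apart; chasing both simultaneously can cycle.  Phase 2
  # therefore switches to a damped Newton iteration on the force balance
  # alone, accepting only strict reductions of the residual (monotone,
  # hence cycle-free).
  ev <- refresh(u)

  if (settings$mode == "dynamic-relaxation") {
    # damped pseudo-dynamic settle: explicit integration of the
    # generalized dynamics with unit-scale inertias and the contact
    # damping term active, used to precondition stiff or distant starts
    # before the static iteration takes over
    v <- rep(0, 5L)
    dt <- 1e-3                        # s
    minv <- 1 / c(4e4, 4e4, 4, 4, 4)  # kg mm^2 (rot), kg (trans)
    for (k in seq_len(150L)) {
      ev_d <- eval_generalized(u, alpha, femur, model, settings,
                               subset = active,
                               contact_only = contact_only, udot = v)
      v <- (v + dt * 1000 * ev_d$Q * minv) * 0.85
      du <- dt * v
      dmove <- sum(abs(du[3:5])) + (abs(du[1L]) + abs(du[2L])) * 45
      if (dmove > 0.4) du <- du * (0.4 / dmove)
      u <- u + du
      if (k %% 25L == 0L) ev <- refresh(u)
      if (max(abs(ev_d$Q)) < 20) break
    }
    ev <- refresh(u)
  }

  energy_trace <- ev$E
  H_last <- H0
  iter <- 0L
  converged <- FALSE
  phase2 <- FALSE
  q_switch <- 50           # residual (N, N*mm) at which phase 2 begins
  p2_stalls <- 0L          # limited bounces back to descent on a stall
  e_steps_pending <- 0L    # forced descent steps after such a bounce

  cap <- function(d) {
    # trust region: bound the worst-case cartilage-vertex displacement
    # (translations plus rotation times the plateau lever arm) so one
    # step stays strictly inside the active-set margin
    dmove <- sum(abs(d[3:5])) + (abs(d[1L]) + abs(d[2L])) * 45
    if (dmove > 0.6) d * (0.6 / dmove) else d
  }

  while (iter < settings$max_iter) {
    if (max(abs(ev$Q)) < settings$tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    if (!phase2 && e_steps_pending == 0L && max(abs(ev$Q)) < q_switch)
      phase2 <- TRUE

    # the local stiffness changes with the active contact set, so the
    # Jacobian of the generalized force is re-differenced every
    # iteration, with a step that shrinks with the residual so the
    # local (not facet-averaged) stiffness drives the terminal steps
    Hraw <- matrix(0, 5L, 5L)
    hsc <- min(1, max(max(abs(ev$Q)) / 100, 1e-3))
    hstep <- c(2e-5, 2e-5, 1e-3, 1e-3, 2e-4) * hsc
    for (j in 1:5) {
      up <- u; up[j] <- up[j] + hstep[j]
      evp <- eval_generalized(up, alpha, femur, model, settings,
                              subset = active,
                              contact_only = contact_only)
      Hraw[, j] <- -(evp$Q - ev$Q) / hstep[j]
    }
    # descent direction from the symmetrised positive-definite part;
    # root-finding direction from the raw (generally asymmetric) Jacobian
    Hsym <- (Hraw + t(Hraw)) / 2
    eg <- eigen(Hsym, symmetric = TRUE)
    floor_ev <- max(abs(eg$values)) * 1e-8 + 1e-6
    Hpd <- eg$vectors %*% (t(eg$vectors) * pmax(abs(eg$values), floor_ev))
    H_last <- Hpd
    d_raw <- tryCatch(solve(Hraw, ev$Q), error = function(e) NULL)
    d_pd <- tryCatch(solve(Hpd, ev$Q), error = function(e) ev$Q * 1e-4)

    accept_E <- function(u_try, ev_try) ev_try$E < ev$E - 1e-12
    accept_Q <- function(u_try, ev_try)
      max(abs(ev_try$Q)) < max(abs(ev$Q)) * (1 - 1e-6)
    acceptor <- if (phase2) accept_Q else accept_E
    try_direction <- function(d) {
      s <- 1
      for (ls in 1:10) {
        u_try <- u + s * d
        if (abs(u_try[2L]) < 1.4) {         # keep beta off the gimbal
          ev_try <- eval_generalized(u_try, alpha, femur, model, settings,
                                     subset = active,
                                     contact_only = contact_only)
          if (acceptor(u_try, ev_try))
            return(list(u = u_try, ev = ev_try))
        }
        s <- s / 2
      }
      NULL
    }

    dirs <- if (phase2) list(d_raw, d_pd) else list(d_pd, d_raw)
    step <- NULL
    for (d in dirs) {
      if (!is.null(d)) step <- try_direction(cap(d))
      if (!is.null(step)) break
    }
    if (is.null(step) && !phase2) {
      # short gradient step as a last resort in the descent phase
      d_grad <- ev$Q
      gmove <- sum(abs(d_grad[3:5])) +
        (abs(d_grad[1L]) + abs(d_grad[2L])) * 45
      if (gmove > 0) step <- try_direction(d_grad * (0.05 / gmove))
    }
    if (is.null(step)) {
      if (!phase2) {
        phase2 <- TRUE                      # descent exhausted: polish
        next
      }
      # the residual norm has a local minimum away from a root (the
      # smoothed contact field also admits spurious energy minima with
      # unbalanced forces): take the capped Newton step unconditionally
      # a limited number of times to leave the trap (nonmonotone escape)
      if (p2_stalls < 3L) {
        p2_stalls <- p2_stalls + 1L
        d_esc <- if (!is.null(d_raw)) d_raw else d_pd
        u <- u + cap(d_esc)
        ev <- refresh(u)
        next
      }
      break                                 # stalled
    }
    u <- step$u
    ev <- refresh(u)
    if (!phase2) {
      energy_trace <- c(energy_trace, ev$E)
      if (e_steps_pending > 0L) e_steps_pending <- e_steps_pending - 1L
    }
  }

  list(tibia = ev$tibia, u = u, converged = converged,
       iterations = iter, residual = max(abs(ev$Q)), residuals = ev$Q,
       energy = ev$E, energy_trace = energy_trace, wrench = ev$wrench,
       alpha = alpha, H = H_last)
}

#' Bring the knee to full extension and measure ligament lengths
#'
#' Continuation from the starting flexion to zero flexion solving a
#' contact-only equilibrium at each step (ligaments inactive -- their
#' slack lengths are not yet known).  Because contact alone leaves the
#' joint unloaded, a small axial compressive preload plus very weak
#' centering terms close the problem (see
#' \code{\link{equilibrium_settings}}).  At the full-extension pose the
#' insertion-to-insertion length \code{Le} of every element is measured.
#'
#' @param model a \code{\link{knee_model}} (slack lengths may be unset).
#' @param start optional list with \code{femur}/\code{tibia} rigid states;
#'   default \code{model$initial}.
#' @param settings an \code{\link{equilibrium_settings}}.
#' @return list with \code{femur}, \code{tibia} (the full-extension
#'   poses), \code{Le} (named lengths, mm), \code{alpha_reached} (rad, 0
#'   unless continuation failed early) and \code{converged}.
#' @export
estimate_full_extension <- function(model, start = NULL,
                                    settings = equilibrium_settings()) {
  start <- start %||% model$initial
  if (is.null(start))
    stop("estimate_full_extension: no starting pose available",
         call. = FALSE)
  alpha0 <- decompose_joint(start$femur, start$tibia)$alpha
  step <- deg2rad(settings$step_deg)
  alphas <- rev(seq(0, alpha0, by = step))
  if (length(alphas) == 0L || alphas[1L] != alpha0)
    alphas <- c(alpha0, alphas)

  tibia <- start$tibia
  last_ok <- NULL
  for (a in alphas) {
    femur <- hinged_femur_state(a, model$side)
    sol <- relax_to_equilibrium(model, femur, tibia, alpha = a,
                                settings = settings, contact_only = TRUE)
    if (!sol$converged) {
      if (!is.null(last_ok)) {
        warning(sprintf(
          "estimate_full_extension: stopped at %.2f deg (non-convergence)",
          rad2deg(last_ok$alpha)), call. = FALSE)
        break
      }
      stop("estimate_full_extension: no converged step", call. = FALSE)
    }
    tibia <- sol$tibia
    last_ok <- sol
  }

  femur <- hinged_femur_state(last_ok$alpha, model$side)
  Le <- vapply(model$ligaments, ligament_length, numeric(1L),
               femur = femur, tibia = last_ok$tibia)
  list(femur = femur, tibia = last_ok$tibia, Le = Le,
       alpha_reached = last_ok$alpha,
       converged = abs(last_ok$alpha) < 1e-12)
}

#' Initialise ligament slack lengths from full-extension lengths
#'
#' Sets each element's slack length \code{L0 = e * Le} and its transition
#' strain \code{epsilon1 = K_L / (4 K_Q L0)}.
#'
#' @param model a \code{\link{knee_model}}.
#' @param Le named numeric vector of full-extension lengths (mm), e.g.
#'   from \code{\link{estimate_full_extension}}.
#' @return the model with initialised ligaments.
#' @export
initialize_slack_lengths <- function(model, Le) {
  missing <- setdiff(ligament_names(), names(Le))
  if (length(missing))
    stop("initialize_slack_lengths: missing elements: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(Le)) || any(Le <= 0))
    stop("initialize_slack_lengths: Le must be positive and finite",
         call. = FALSE)
  for (nm in ligament_names()) {
    spec <- model$ligaments[[nm]]
    spec$L0 <- slack_length(spec$e, Le[[nm]])
    spec$epsilon1 <- transition_strain(spec$K_Q, spec$K_L, spec$L0)
    model$ligaments[[nm]] <- spec
  }
  # the cached parameter table is bound to the ligament set
  model$cache <- new.env(parent = emptyenv())
  model
}
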