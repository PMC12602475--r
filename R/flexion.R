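# initial-guess pose for a direct (cold) solve at flexion alpha: tibia
# under the hinged femur tracking the condylar contact point, with the
# coarse coupled-motion trends of passive flexion (slight internal
# rotation peaking mid-flexion, growing adduction, small medial shift)
# so the solve starts inside the physiological equilibrium basin
cold_start_pose <- function(model, alpha) {
  sc <- model$meta$scale %||% 1
  ad <- rad2deg(alpha)
  zc <- (20 * cos(alpha) - condyle_radius(ad, 24, 19) + 3) * sc
  jc <- joint_coordinates(
    alpha = alpha,
    adduction = deg2rad(-2.2 * (ad / 112)^1.7),
    gamma = deg2rad(-5 * sin(pi * min(ad, 100) / 100)),
    S1 = -1.5 * sc * sin(pi * ad / 112),
    S2 = -20 * sc * sin(alpha),
    S3 = zc + 0.3
  )
  compose_joint(jc, hinged_femur_state(alpha, model$side))
}

#' Passive-flexion sweep (hinged femur, moving tibia)
#'
#' Drives the femur about its flexion axis through the prescribed flexion
#' profiles (the examiner's hand of a passive-flexion examination) and
#' solves the remaining five joint coordinates to static equilibrium at
#' every sample, warm-starting each solve from its predecessor.  Emits
#' joint and clinical coordinates, per-ligament tensions and the total
#' contact force at each sample.
#'
#' @param model an initialised \code{\link{knee_model}} (slack lengths
#'   set; see \code{\link{initialize_slack_lengths}}).
#' @param cycles list of flexion profiles (numeric vectors, degrees);
#'   default \code{model$profiles}.
#' @param settings an \code{\link{equilibrium_settings}}.
#' @param start optional starting tibial \code{\link{rigid_state}} (with
#'   its femoral counterpart implied by the model's reference flexion);
#'   default \code{model$initial$tibia}.
#' @param quiet suppress progress messages.
#' @return a \code{trajectory_set}: data frame with one row per sample and
#'   columns \code{cycle}, \code{sample}, \code{flexion_deg},
#'   \code{adduction_deg}, \code{internal_rotation_deg},
#'   \code{S1_mm..S3_mm}, \code{q1_mm..q3_mm}, \code{lig_<name>_N} for the
#'   15 elements, \code{contact_total_N}, \code{residual} and
#'   \code{converged}.  Non-converged samples are flagged, kept, and
#'   counted in the \code{n_flagged} attribute.
#' @export
run_passive_flexion <- function(model, cycles = NULL,
                                settings = equilibrium_settings(),
                                start = NULL, quiet = TRUE) {
  if (any(vapply(model$ligaments, function(l) is.na(l$L0), logical(1L))))
    stop("run_passive_flexion: ligament slack lengths are not initialised",
         call. = FALSE)
  cycles <- cycles %||% model$profiles
  if (is.null(cycles) || !length(cycles))
    stop("run_passive_flexion: no flexion profiles", call. = FALSE)

  lig_nm <- ligament_names()
  rows <- vector("list", sum(lengths(cycles)))
  k <- 0L
  n_flagged <- 0L

  # walk from the reference pose to the first commanded sample
  tibia <- (start %||% model$initial$tibia)
  stopifnot(!is.null(tibia))
  alpha_here <- decompose_joint(
    hinged_femur_state(deg2rad(model$meta$ref_flexion_deg %||% 0),
                       model$side), tibia)$alpha
  H <- NULL
  walk_to <- function(target, tibia, H) {
    step <- deg2rad(settings$step_deg)
    path <- seq(alpha_here, target,
                by = if (target >= alpha_here) step else -step)
    path <- c(path[-1L], if (!length(path) ||
                             path[length(path)] != target) target)
    for (a in path) {
      femur <- hinged_femur_state(a, model$side)
      sol <- relax_to_equilibrium(model, femur, tibia, alpha = a,
                                  settings = settings, H0 = H)
      tibia <- sol$tibia
      H <- sol$H
    }
    list(tibia = tibia, H = H)
  }

  for (cy in seq_along(cycles)) {
    prof <- cycles[[cy]]
    w <- walk_to(deg2rad(prof[1L]), tibia, H)
    tibia <- w$tibia; H <- w$H
    alpha_here <- deg2rad(prof[1L])

    for (i in seq_along(prof)) {
      a <- deg2rad(prof[i])
      femur <- hinged_femur_state(a, model$side)
      sol <- relax_to_equilibrium(model, femur, tibia, alpha = a,
                                  settings = settings,
                                  H0 = if (settings$warm_start) H else NULL)
      if (!sol$converged) {
        # halve the continuation step down to step/8 before flagging
        sub <- subdivide_solve(model, tibia, alpha_here, a, settings, H)
        sol <- sub$sol
        H <- sub$H
      }
      if (sol$converged) {
        tibia <- sol$tibia
        H <- sol$H
      } else {
        n_flagged <- n_flagged + 1L
        if (!quiet)
          message(sprintf("cycle %d sample %d (%.2f deg): not converged",
                          cy, i, prof[i]))
      }
      alpha_here <- a

      jc <- decompose_joint(femur, sol$tibia)
      tens <- sol$wrench$tensions
      if (is.null(tens)) tens <- setNames(rep(NA_real_, 15L), lig_nm)
      k <- k + 1L
      rows[[k]] <- c(cycle = cy, sample = i,
                     flexion_deg = rad2deg(jc$alpha),
                     adduction_deg = rad2deg(jc$adduction),
                     internal_rotation_deg = rad2deg(jc$gamma),
                     S1_mm = jc$S1, S2_mm = jc$S2, S3_mm = jc$S3,
                     q1_mm = jc$q1, q2_mm = jc$q2, q3_mm = jc$q3,
                     setNames(as.numeric(tens[lig_nm]),
                              paste0("lig_", lig_nm, "_N")),
                     contact_total_N = sol$wrench$contact_total,
                     residual = sol$residual,
                     converged = as.numeric(sol$converged))
    }
    if (!quiet) message(sprintf("cycle %d done (%d samples)", cy,
                                length(prof)))
  }

  out <- as.data.frame(do.call(rbind, rows[seq_len(k)]))
  class(out) <- c("trajectory_set", class(out))
  attr(out, "n_flagged") <- n_flagged
  attr(out, "settings") <- settings
  out
}

subdivide_solve <- function(model, tibia, a_from, a_to, settings, H) {
  for (div in c(2L, 4L, 8L)) {
    path <- seq(a_from, a_to, length.out = div + 1L)[-1L]
    tb <- tibia
    Hc <- H
    ok <- TRUE
    for (a in path) {
      femur <- hinged_femur_state(a, model$side)
      sol <- relax_to_equilibrium(model, femur, tb, alpha = a,
                                  settings = settings, H0 = Hc)
      if (!sol$converged) {
        ok <- FALSE
        break
      }
      tb <- sol$tibia
      Hc <- sol$H
    }
    if (ok) return(list(sol = sol, H = Hc))
  }
  list(sol = sol, H = H)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d samples, %d cycle(s), flexion %.1f-%.1f deg",
              nrow(x), length(unique(x$cycle)), min(x$flexion_deg),
              max(x$flexion_deg)))
  nf <- attr(x, "n_flagged") %||% 0L
  if (nf > 0L) cat(sprintf(", %d flagged", nf)) else cat(", all converged")
  cat("\n")
  invisible(x)
}

#' Write / read a trajectory CSV
#'
#' Fixed dialect: comma separated, \code{.} decimal, UTF-8, one header
#' line.  Leading comment lines starting with \code{#} carry provenance
#' (seed, config hash) and are skipped on read.
#'
#' @param trajectory a \code{trajectory_set} (or plain data frame with the
#'   same columns).
#' @param path file path.
#' @param header_lines optional character vector written as \code{#}
#'   comments before the header.
#' @return \code{path} (write) / a \code{trajectory_set} (read).
#' @export
write_trajectory_csv <- function(trajectory, path, header_lines = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.csv(as.data.frame(trajectory), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  out <- utils::read.csv(path, comment.char = "#")
  class(out) <- c("trajectory_set", class(out))
  out
}
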