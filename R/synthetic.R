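# Parametric synthetic knee.  The generator stands in for image
# segmentation: it emits a geometrically plausible right knee with the
# qualitative features the contact model needs -- femoral condyles whose
# sagittal radius shrinks posteriorly, a concave medial / flat lateral
# tibial plateau, cartilage patches offset from bone, ten landmarks,
# thirty ligament insertion points and four seeded passive-flexion cycles.
# No claim of anatomical fidelity beyond those features is made.

synthetic_presets <- function() {
  list(
    default = list(scale = 1.0),
    compact = list(scale = 0.9)
  )
}

# sagittal condyle radius: large anteriorly/distally, small posteriorly
condyle_radius <- function(phi_deg, rho_ant, rho_post,
                           phi_t = 45, width = 12) {
  rho_post + (rho_ant - rho_post) / (1 + exp((phi_deg - phi_t) / width))
}

# one femoral condyle as a swept arc patch in the femoral frame:
# p(phi, psi) = a0 + rho(phi) cos(psi) dir(phi) + w sin(psi) X,
# dir(phi) = -sin(phi) Y - cos(phi) Z  (phi = 0 distal, 90 posterior)
condyle_patch <- function(x_c, z_c, rho_ant, rho_post, half_width,
                          n_phi = 54, n_psi = 22,
                          phi_range = c(-50, 150), psi_half = 80,
                          scale = 1) {
  phi <- seq(phi_range[1L], phi_range[2L], length.out = n_phi + 1L)
  psi <- seq(-psi_half, psi_half, length.out = n_psi + 1L)
  g <- expand.grid(phi = phi, psi = psi)
  rho <- condyle_radius(g$phi, rho_ant, rho_post)
  pr <- deg2rad(g$phi)
  ps <- deg2rad(g$psi)
  V <- cbind(x_c + half_width * sin(ps),
             -rho * cos(ps) * sin(pr),
             z_c - rho * cos(ps) * cos(pr))
  V <- V * scale
  np <- n_phi + 1L
  idx <- function(i, j) i + (j - 1L) * np
  tris <- vector("list", 2L * n_phi * n_psi)
  k <- 0L
  for (j in seq_len(n_psi)) {
    for (i in seq_len(n_phi)) {
      k <- k + 1L
      tris[[k]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
      k <- k + 1L
      tris[[k]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
  }
  m <- surface_mesh(V, do.call(rbind, tris), frame = "femur", open = TRUE)
  orient_away_from(m, c(x_c, 0, z_c) * scale)
}

# flip triangle winding if face normals point toward an interior point
orient_away_from <- function(mesh, interior) {
  ctr <- (mesh$vertices[mesh$faces[, 1L], ] +
            mesh$vertices[mesh$faces[, 2L], ] +
            mesh$vertices[mesh$faces[, 3L], ]) / 3
  outward <- sweep(ctr, 2L, interior)
  s <- rowSums(outward * mesh$face_normal)
  if (mean(s > 0) < 0.5)
    surface_mesh(mesh$vertices, mesh$faces[, c(1L, 3L, 2L)],
                 frame = mesh$frame, open = mesh$open)
  else mesh
}

# tibial plateau compartment as a height field: concave spherical dish
# (finite dish_R), or near-flat with an optional gentle sagittal trough
# (dish_R = Inf, sag_R finite: the "flat-to-saddle" lateral facet);
# up-facing normals
plateau_patch <- function(x_c, half, n = 36, z0 = -3, dish_R = Inf,
                          sag_R = Inf, scale = 1) {
  s <- seq(-half, half, length.out = n + 1L)
  g <- expand.grid(x = s, y = s)
  r2 <- g$x^2 + g$y^2
  z <- if (is.finite(dish_R)) z0 + r2 / (2 * dish_R)
       else if (is.finite(sag_R)) z0 + g$y^2 / (2 * sag_R)
       else rep(z0, nrow(g))
  V <- cbind(x_c + g$x, g$y, z) * scale
  np <- n + 1L
  idx <- function(i, j) i + (j - 1L) * np
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
  surface_mesh(V, do.call(rbind, tris), frame = "tibia", open = TRUE)
}

#' Hinged femoral state
#'
#' The femoral rigid state of the passive-flexion rig: the femur rotated
#' by \code{alpha} about its X (flexion) axis through the femoral origin,
#' which is fixed to the ground.
#'
#' @param alpha flexion angle (rad).
#' @param side limb side (\code{"right"}/\code{"left"}).
#' @return a \code{\link{rigid_state}}.
#' @export
hinged_femur_state <- function(alpha, side = "right") {
  rigid_state(frame_from_matrix(c(0, 0, 0), rot_x(alpha), side = side))
}

# default ligament table: insertions (right knee, body frames, mm),
# linear / quadratic stiffnesses and expansion constants.  Values are
# literature-typical for bundle-level straight-line elements (reference
# strains at full extension of a few percent; linear stiffnesses of tens
# of N/mm); they are editable configuration, not measured constants.
synthetic_ligament_table <- function(scale = 1) {
  # femoral points sit near the condylar centre line (x, 0, ~20), the
  # near-isometric locus under passive flexion; the small (y, z) offsets
  # from it set each element's engagement pattern (posterior/below ->
  # taut in extension, anterior/below -> recruited with flexion)
  L <- list(
    #        femoral (mm)        tibial (mm)          K_Q  K_L    e
    aACL = list(c(  9,  -4, 21), c(  2,  12,  -4),    30,  65, 0.985),
    pACL = list(c(  9,  -7, 19), c( -3,   8,  -4),    28,  60, 0.940),
    aPCL = list(c( -8,   3, 18), c(  1, -13,  -9),    35,  80, 1.005),
    pPCL = list(c( -8,   4, 16), c( -2, -15, -11),    30,  70, 1.035),
    dMCLa = list(c(-38,   3, 19), c(-30,   6,  -8),   12,  25, 1.005),
    dMCLp = list(c(-38,  -4, 19), c(-30,  -4,  -8),   12,  25, 0.975),
    oMCLa = list(c(-36,  -6, 20), c(-28,  -2, -12),   10,  20, 0.995),
    oMCLp = list(c(-36,  -8, 18), c(-26, -10, -12),   10,  20, 0.970),
    sMCL = list(c(-40,  -1, 19), c(-16,   3, -50),     8,  70, 0.985),
    ALL  = list(c( 38,   3, 17), c( 26,  14, -18),    10,  20, 0.995),
    LCL  = list(c( 40,  -1, 19), c( 34,  -8, -30),    15,  55, 0.980),
    OPL  = list(c( 18, -10, 16), c(-16, -16, -10),     8,  15, 0.970),
    APL  = list(c(-14, -10, 16), c( 26, -12, -14),     7,  12, 0.970),
    mCAP = list(c(-24, -12, 17), c(-22, -14,  -8),    10,  25, 0.980),
    lCAP = list(c( 24, -12, 17), c( 24, -12,  -8),    10,  25, 0.980)
  )
  lapply(names(L), function(nm) {
    x <- L[[nm]]
    ligament_spec(nm, x[[1L]] * scale, x[[2L]] * scale,
                  K_Q = x[[3L]], K_L = x[[4L]], e = x[[5L]])
  })
}

synthetic_landmarks <- function(scale = 1) {
  landmark_set(lapply(list(
    Lepi = c(42, 0, 6), Mepi = c(-42, 0, 6),
    Mppc = c(-22, -20, 20), Lppc = c(22, -20, 20),
    Chip = c(0, 0, 420), Ofem = c(0, 0, 0),
    Mctc = c(-22, 0, -3), Lctc = c(22, 0, -3),
    Cank = c(0, 0, -360), Otib = c(0, 0, 0)
  ), function(p) p * scale), side = "right")
}

# four passive-flexion cycles: ~7 deg -> ~112 deg -> ~7 deg at `step`
# degrees, with smooth seeded cycle-to-cycle perturbations (endpoint-safe)
synthetic_flexion_profiles <- function(n_cycles = 4, alpha_min = 7.5,
                                       alpha_max = 111.5, step = 0.5) {
  lapply(seq_len(n_cycles), function(cy) {
    peak <- alpha_max - abs(rnorm(1L, 0, 0.4))
    lo <- alpha_min + abs(rnorm(1L, 0, 0.2))
    up <- seq(lo, peak, by = step)
    down <- rev(up)[-1L]
    base <- c(up, down)
    t <- seq(0, 1, length.out = length(base))
    wob <- numeric(length(base))
    for (j in 1:3)
      wob <- wob + rnorm(1L, 0, 0.12) * sin(j * pi * t + runif(1L, 0, pi))
    prof <- base + wob * sin(pi * t)    # vanish at the cycle endpoints
    pmin(pmax(prof, 7.01), 111.99)
  })
}

#' Generate a synthetic knee model
#'
#' Builds a deterministic parametric right-knee \code{\link{knee_model}}:
#' two femoral condyle patches whose sagittal radius decreases posteriorly,
#' a concave medial and flat lateral tibial plateau, cartilage offset from
#' coarser bone surfaces, ten landmarks, fifteen ligament elements with
#' plausible insertion sites, and four seeded passive-flexion cycles
#' spanning roughly 7 to 112 degrees.  The tibia of the returned reference
#' pose is settled vertically under the hinged femur until the deepest
#' cartilage penetration reaches a small target, so the surfaces start in
#' light contact.
#'
#' @param preset \code{"default"} or \code{"compact"} (90\% scale).
#' @param seed integer seed driving the cycle-to-cycle flexion
#'   perturbations; the same (preset, seed) pair reproduces the model
#'   exactly.
#' @param ref_flexion_deg flexion angle of the reference (imaging) pose.
#' @return a \code{\link{knee_model}} with \code{initial} poses and
#'   \code{profiles} filled in; ligament slack lengths are left
#'   uninitialised (see \code{\link{initialize_slack_lengths}}).
#' @export
generate_synthetic_knee <- function(preset = "default", seed = 1L,
                                    ref_flexion_deg = 15) {
  presets <- synthetic_presets()
  if (!preset %in% names(presets))
    stop("generate_synthetic_knee: unknown preset '", preset, "'",
         call. = FALSE)
  sc <- presets[[preset]]$scale

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # cartilage: lateral condyle at +x, medial at -x (right knee);
  # matched distal reach so both compartments share load near extension
  lat_cart <- condyle_patch(22, 20, 24, 19, 11, scale = sc)
  med_cart <- condyle_patch(-22, 21, 25, 20, 11, scale = sc)
  femur_cartilage <- mesh_merge(lat_cart, med_cart)

  lat_bone <- condyle_patch(22, 20, 22.8, 17.8, 10.5, n_phi = 22,
                            n_psi = 10, scale = sc)
  med_bone <- condyle_patch(-22, 21, 23.8, 18.8, 10.5, n_phi = 22,
                            n_psi = 10, scale = sc)
  femur_bone <- mesh_merge(lat_bone, med_bone)

  tib_med <- plateau_patch(-22, 15, n = 36, z0 = -3, dish_R = 30,
                           scale = sc)
  tib_lat <- plateau_patch(22, 15, n = 36, z0 = -3, sag_R = 120,
                           scale = sc)
  tibia_cartilage <- mesh_merge(tib_med, tib_lat)

  tib_bone <- mesh_merge(
    plateau_patch(-22, 15, n = 14, z0 = -4.2, dish_R = 30, scale = sc),
    plateau_patch(22, 15, n = 14, z0 = -4.2, sag_R = 120, scale = sc))

  landmarks <- synthetic_landmarks(sc)
  ligaments <- synthetic_ligament_table(sc)
  profiles <- synthetic_flexion_profiles()

  model <- knee_model(femur_bone, femur_cartilage, tib_bone,
                      tibia_cartilage, landmarks, ligaments,
                      contact = contact_params(), side = "right",
                      profiles = profiles,
                      meta = list(preset = preset, seed = as.integer(seed),
                                  scale = sc))

  alpha0 <- deg2rad(ref_flexion_deg)
  model$initial <- settle_reference_pose(model, alpha0)
  model$meta$ref_flexion_deg <- ref_flexion_deg
  model
}

# vertical settle: lower/raise the tibia under the hinged femur until the
# deepest cartilage penetration hits `target_pen` (mm); deterministic
settle_reference_pose <- function(model, alpha, target_pen = 0.15) {
  femur <- hinged_femur_state(alpha, model$side)
  sc <- model$meta$scale %||% 1
  guess_y <- -20 * sc * sin(alpha)
  deepest <- function(oz) {
    tib <- rigid_state(frame_from_matrix(c(0, guess_y, oz), diag(3),
                                         side = model$side))
    cs <- penetration_query(model$femur_cartilage, model$tibia_cartilage,
                            femur, tib, max_dist = 3)
    if (nrow(cs)) max(cs$delta) else 0
  }
  # bracket: high enough to penetrate, low enough to separate
  zc <- (20 * cos(alpha) - condyle_radius(rad2deg(alpha), 24, 19) + 3) * sc
  lo <- zc - 4
  hi <- zc + 4
  if (deepest(hi) < target_pen)
    stop("settle_reference_pose: could not bracket contact", call. = FALSE)
  for (i in 1:48) {
    mid <- (lo + hi) / 2
    if (deepest(mid) < target_pen) lo <- mid else hi <- mid
  }
  oz <- (lo + hi) / 2
  tibia <- rigid_state(frame_from_matrix(c(0, guess_y, oz), diag(3),
                                         side = model$side))
  list(femur = femur, tibia = tibia)
}
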