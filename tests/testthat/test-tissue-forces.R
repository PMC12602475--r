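test_that("strain, slack length and transition strain follow their
          definitions", {
  expect_equal(strain(100, 100), 0)
  expect_equal(strain(103, 100), 0.03)
  expect_equal(strain(95, 100), -0.05)
  expect_error(strain(100, 0), "positive")

  expect_equal(slack_length(1, 40), 40)
  expect_equal(slack_length(0.95, 40), 38)
  expect_equal(slack_length(1.05, 40), 42)
  expect_error(slack_length(-1, 40), "positive")

  expect_equal(transition_strain(10, 2, 10), 0.005)
  # doubling K_Q halves the transition strain
  expect_equal(transition_strain(20, 2, 10),
               transition_strain(10, 2, 10) / 2)

  # independent check: solve the value/slope continuity conditions
  # numerically on a grid of eps1 candidates
  K_Q <- 10; K_L <- 2; L0 <- 10
  mismatch <- function(e1) {
    Lt <- L0 * (1 + 2 * e1)
    val <- K_Q * (Lt - L0)^2 - K_L * (Lt - L0 * (1 + e1))
    slo <- 2 * K_Q * (Lt - L0) - K_L
    abs(val) + abs(slo)
  }
  grid <- seq(1e-4, 0.05, by = 1e-6)
  e1_star <- grid[which.min(vapply(grid, mismatch, numeric(1L)))]
  expect_equal(transition_strain(K_Q, K_L, L0), e1_star,
               tolerance = 1e-3)
})

test_that("the ligament force law is slack below zero strain, C1 at the
          transition and asymptotically linear", {
  m <- acceptance_model()
  for (spec in m$ligaments) {
    expect_equal(ligament_tension(spec, spec$L0), 0)
    expect_equal(ligament_tension(spec, spec$L0 * 0.95), 0)

    # finite-difference value and slope discontinuities at strain
    # 2*eps1, Richardson-extrapolated so the regular variation of F
    # does not masquerade as a jump
    Lt <- spec$L0 * (1 + 2 * spec$epsilon1)
    h1 <- 1e-5 * spec$L0
    h2 <- h1 / 2
    gap <- function(h) ligament_tension(spec, Lt + h) -
      ligament_tension(spec, Lt - h)
    expect_lt(abs(2 * gap(h2) - gap(h1)), 1e-6 * spec$K_L)
    one_sided <- function(h, sgn) sgn * (ligament_tension(spec, Lt + sgn * h) -
                                           ligament_tension(spec, Lt)) / h
    s_lo <- 2 * one_sided(h2, -1) - one_sided(h1, -1)
    s_hi <- 2 * one_sided(h2, 1) - one_sided(h1, 1)
    expect_lt(abs(s_hi - s_lo), 1e-6 * spec$K_L)

    # asymptotic slope equals K_L
    L1 <- spec$L0 * 1.2
    s_asym <- (ligament_tension(spec, L1 + 1e-5) -
                 ligament_tension(spec, L1)) / 1e-5
    expect_equal(s_asym, spec$K_L, tolerance = 1e-6)

    # monotone nondecreasing
    Ls <- seq(0.9, 1.3, by = 1e-3) * spec$L0
    expect_true(all(diff(ligament_tension(spec, Ls)) >= -1e-12))
  }
})

test_that("the strict-literal transition variant is discontinuous where
          the default is smooth", {
  spec <- ligament_spec("aACL", c(0, 0, 0), c(0, 0, 30),
                        K_Q = 30, K_L = 60, e = 1)
  spec$L0 <- 30
  spec$epsilon1 <- transition_strain(30, 60, 30)
  Lt1 <- spec$L0 * (1 + spec$epsilon1)
  h <- 1e-9
  jump <- abs(ligament_tension(spec, Lt1 + h, strict_literal = TRUE) -
                ligament_tension(spec, Lt1 - h, strict_literal = TRUE))
  expect_gt(jump, 0.01)
})

test_that("the smooth step and the scalar contact law match their closed
          forms", {
  expect_equal(smooth_step(0, 0.01), 0)
  expect_equal(smooth_step(0.01, 0.01), 1)
  expect_equal(smooth_step(0.005, 0.01), 0.5)
  expect_equal(smooth_step(-1, 0.01), 0)

  p <- contact_params()
  expect_equal(contact_force(-0.5, 0, p), 0)
  expect_equal(contact_force(0.01, 0, p), 500 * 0.01^1.5)
  expect_equal(contact_force(0.01, 0, p), 0.5)
  # contact never pulls, however fast the gap opens
  expect_equal(contact_force(0.005, -1e6, p), 0)
  # closing rate adds force through the damping term
  expect_gt(contact_force(0.02, 10, p), contact_force(0.02, 0, p))
})

test_that("the assembled wrench obeys superposition and Newton's third
          law", {
  m <- acceptance_model()
  femur <- m$initial$femur
  tibia <- m$initial$tibia

  wr <- assemble_wrench(m, femur, tibia)
  # third law: femoral wrench is the opposite, transported to Ofem
  expect_equal(wr$femur_force, -wr$force, tolerance = 1e-12)
  oF <- femur$frame$origin
  oT <- tibia$frame$origin
  expect_equal(wr$femur_torque,
               -wr$torque - kneesim:::vcross(oT - oF, wr$force),
               tolerance = 1e-9)

  # superposition: total = contact-only + sum of single-element wrenches
  slacken <- function(model, keep) {
    for (nm in ligament_names())
      if (!nm %in% keep) model$ligaments[[nm]]$L0 <- 1e6
    model$cache <- new.env(parent = emptyenv())
    model
  }
  wr_contact <- assemble_wrench(slacken(m, character(0)), femur, tibia)
  force_sum <- wr_contact$force
  torque_sum <- wr_contact$torque
  for (nm in ligament_names()) {
    w1 <- assemble_wrench(slacken(m, nm), femur, tibia)
    force_sum <- force_sum + (w1$force - wr_contact$force)
    torque_sum <- torque_sum + (w1$torque - wr_contact$torque)
  }
  expect_equal(force_sum, wr$force, tolerance = 1e-9)
  expect_equal(torque_sum, wr$torque, tolerance = 1e-9)

  # single taut element: torque equals insertion-arm x force by hand
  tens <- vapply(wr$ligaments, `[[`, numeric(1L), "tension")
  nm_taut <- names(which.max(tens))
  st <- wr$ligaments[[nm_taut]]
  expect_gt(st$tension, 0)
  f_hand <- st$tension * st$direction
  t_hand <- kneesim:::vcross(st$tibial_pt - oT, f_hand)
  w_single <- assemble_wrench(slacken(m, nm_taut), femur, tibia)
  expect_equal(w_single$force - wr_contact$force, f_hand,
               tolerance = 1e-9)
  expect_equal(w_single$torque - wr_contact$torque, t_hand,
               tolerance = 1e-9)
})

test_that("a model with slack ligaments and separated surfaces has a zero
          wrench", {
  m <- acceptance_model()
  for (nm in ligament_names()) m$ligaments[[nm]]$L0 <- 1e6
  m$cache <- new.env(parent = emptyenv())
  # lift the tibia clear of contact
  fr <- m$initial$tibia$frame
  tibia <- rigid_state(body_frame(fr$origin - c(0, 0, 10), fr$X, fr$Y,
                                  fr$Z, fr$side))
  wr <- assemble_wrench(m, m$initial$femur, tibia)
  expect_equal(wr$force, c(0, 0, 0))
  expect_equal(wr$torque, c(0, 0, 0))
  expect_equal(wr$contact_total, 0)
})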