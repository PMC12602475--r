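test_that("full-extension continuation reaches zero flexion with both
          condyles loaded and measures ligament lengths there", {
  fe <- acceptance_full_extension()
  expect_true(fe$converged)
  expect_equal(fe$alpha_reached, 0)
  cs <- penetration_query(generate_synthetic_knee("default", 1)$femur_cartilage,
                          generate_synthetic_knee("default", 1)$tibia_cartilage,
                          fe$femur, fe$tibia)
  expect_gt(sum(cs$x < 0), 0)
  expect_gt(sum(cs$x > 0), 0)
  expect_setequal(names(fe$Le), ligament_names())
  expect_true(all(fe$Le > 10 & fe$Le < 120))

  # starting already at full extension, Le equals the measured lengths
  m <- generate_synthetic_knee("default", 1)
  fe0 <- estimate_full_extension(
    m, start = list(femur = fe$femur, tibia = fe$tibia))
  direct <- vapply(m$ligaments, kneesim:::ligament_length, numeric(1L),
                   femur = fe$femur, tibia = fe0$tibia)
  expect_equal(fe0$Le, direct, tolerance = 1e-9)
})

test_that("full-extension lengths are insensitive to the continuation
          step size", {
  m <- generate_synthetic_knee("default", 1)
  fe1 <- acceptance_full_extension()
  fe2 <- estimate_full_extension(
    m, settings = equilibrium_settings(step_deg = 0.25))
  expect_true(fe2$converged)
  expect_lt(max(abs(fe1$Le - fe2$Le)), 0.1)
})

test_that("slack-length initialisation applies L0 = e * Le locally", {
  m <- generate_synthetic_knee("default", 1)
  Le <- setNames(rep(40, 15L), ligament_names())
  m1 <- initialize_slack_lengths(m, Le)
  for (nm in ligament_names())
    expect_equal(m1$ligaments[[nm]]$L0, m1$ligaments[[nm]]$e * 40)

  # e = 1 for all elements gives L0 = Le exactly
  m2 <- m
  for (nm in ligament_names()) m2$ligaments[[nm]]$e <- 1
  m2 <- initialize_slack_lengths(m2, Le)
  expect_true(all(vapply(m2$ligaments, `[[`, numeric(1L), "L0") == 40))

  # modifying one expansion constant rescales only that element
  m3 <- m
  m3$ligaments[["LCL"]]$e <- m3$ligaments[["LCL"]]$e * 1.01
  m3 <- initialize_slack_lengths(m3, Le)
  for (nm in ligament_names()) {
    if (nm == "LCL") expect_false(m3$ligaments[[nm]]$L0 ==
                                    m1$ligaments[[nm]]$L0)
    else expect_equal(m3$ligaments[[nm]]$L0, m1$ligaments[[nm]]$L0)
  }
  expect_error(initialize_slack_lengths(m, Le[-1L]), "missing")
})

test_that("a converged equilibrium is a fixed point of the solver and its
          energy trace is monotone", {
  m <- acceptance_model()
  a <- deg2rad(30)
  femur <- kneesim:::hinged_femur_state(a, m$side)
  sol <- relax_to_equilibrium(m, femur, kneesim:::cold_start_pose(m, a),
                              alpha = a)
  expect_true(sol$converged)
  expect_lt(sol$residual, 1e-3)
  expect_true(all(diff(sol$energy_trace) <= 1e-9))

  again <- relax_to_equilibrium(m, femur, sol$tibia, alpha = a)
  expect_true(again$converged)
  expect_lte(again$iterations, 1L)
  expect_lt(max(abs(again$u - sol$u)), 1e-9)
})

test_that("dynamic relaxation settles to the same equilibrium as the
          quasi-static solve", {
  m <- acceptance_model()
  a <- deg2rad(40)
  femur <- hinged_femur_state(a, m$side)
  qs <- relax_to_equilibrium(m, femur, kneesim:::cold_start_pose(m, a),
                             alpha = a)
  dyn <- relax_to_equilibrium(
    m, femur, kneesim:::cold_start_pose(m, a), alpha = a,
    settings = equilibrium_settings(mode = "dynamic-relaxation"))
  expect_true(qs$converged)
  expect_true(dyn$converged)
  expect_lt(dyn$residual, 1e-3)
  expect_lt(max(abs(dyn$u - qs$u)), 1e-5)
})

test_that("a constant flexion profile yields constant dependent motions", {
  m <- acceptance_model()
  tr <- run_passive_flexion(m, cycles = list(rep(20, 6)))
  expect_equal(attr(tr, "n_flagged"), 0L)
  for (cn in c("adduction_deg", "internal_rotation_deg", "S1_mm",
               "S2_mm", "S3_mm"))
    expect_lt(diff(range(tr[[cn]])), 1e-6)
})

test_that("the sweep is deterministic and round-trips through the
          trajectory CSV", {
  m <- acceptance_model()
  cyc <- list(seq(10, 40, by = 5))
  t1 <- run_passive_flexion(m, cycles = cyc)
  t2 <- run_passive_flexion(m, cycles = cyc)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(t1, f, header_lines = c("seed: 1", "config: cafe"))
  back <- read_trajectory_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(t1), tolerance = 1e-12,
               ignore_attr = TRUE)
  hdr <- readLines(f, n = 2L)
  expect_match(hdr[1L], "^# seed")
  unlink(f)
})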