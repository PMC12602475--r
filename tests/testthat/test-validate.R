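# small synthetic trajectory builder: v(alpha) per motion, optional noise
make_traj <- function(alphas, cycles = 1L, fun = function(a) 0.1 * a,
                      noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_len(cycles), function(cy) {
    v <- fun(alphas) + rnorm(length(alphas), 0, noise)
    data.frame(cycle = cy, sample = seq_along(alphas),
               flexion_deg = alphas,
               adduction_deg = v, internal_rotation_deg = v,
               S1_mm = v, S2_mm = v, S3_mm = v)
  }))
}

test_that("resampling onto the flexion grid is exact for data already on
          the grid and for linear curves", {
  grid <- seq(10, 90, by = 1)
  tr <- make_traj(grid)
  cv <- parametrize_by_flexion(tr, grid, motions = "S2_mm")
  expect_equal(as.numeric(cv$S2_mm[, 1L]), 0.1 * grid, tolerance = 1e-12)

  # irregular sampling of a linear curve still recovers 0.1 * grid
  set.seed(3)
  al <- sort(runif(300, 5, 100))
  tr2 <- make_traj(al)
  cv2 <- parametrize_by_flexion(tr2, grid, motions = "S2_mm")
  expect_equal(as.numeric(cv2$S2_mm[, 1L]), 0.1 * grid, tolerance = 1e-9)

  expect_error(parametrize_by_flexion(tr, seq(0, 200, 1)), "range")
})

test_that("an injected spike is flagged and excluded by the outlier
          screen", {
  grid <- seq(10, 90, by = 1)
  al <- seq(5, 100, by = 0.5)
  tr <- make_traj(al, noise = 0.02, seed = 4)
  i <- which.min(abs(al - 50))
  tr$S2_mm[i] <- tr$S2_mm[i] + 50
  cv <- parametrize_by_flexion(tr, grid, motions = "S2_mm")
  expect_gte(attr(cv, "n_outliers"), 1L)
  expect_lt(max(abs(cv$S2_mm[, 1L] - 0.1 * grid)), 0.5)
})

test_that("cycle averages and variances behave as expected", {
  grid <- seq(10, 90, by = 1)
  tr <- make_traj(grid, cycles = 3L)
  cv <- parametrize_by_flexion(tr, grid, motions = "S2_mm")
  av <- average_cycles(cv, "S2_mm")
  expect_equal(max(av$variance), 0, tolerance = 1e-20)

  # two traces v and -v average to zero
  m <- cbind(0.1 * grid, -0.1 * grid)
  av2 <- average_cycles(m)
  expect_equal(max(abs(av2$mean)), 0, tolerance = 1e-12)

  # with seeded noise sigma the mean pointwise variance approaches
  # sigma^2 (within 30% at 200 grid points, 4 cycles)
  grid200 <- seq(10, 90, length.out = 200)
  tr4 <- make_traj(grid200, cycles = 4L, noise = 0.5, seed = 11)
  cv4 <- parametrize_by_flexion(tr4, grid200, motions = "S2_mm",
                                mad_threshold = 1e6)
  av4 <- average_cycles(cv4, "S2_mm")
  expect_lt(abs(mean(av4$variance) - 0.25), 0.3 * 0.25)
})

test_that("ordinary least squares recovers exact and noisy affine
          relations", {
  x <- seq(0, 10, by = 0.05)

  r1 <- linear_regress(x, x)
  expect_equal(r1$b1, 1, tolerance = 1e-12)
  expect_equal(r1$b0, 0, tolerance = 1e-12)
  expect_equal(r1$RMSE, 0, tolerance = 1e-12)
  expect_equal(r1$adj_r_squared, 1, tolerance = 1e-12)

  r2 <- linear_regress(2 * x + 3, x)
  expect_equal(r2$b1, 2, tolerance = 1e-12)
  expect_equal(r2$b0, 3, tolerance = 1e-12)
  expect_equal(r2$RMSE, 0, tolerance = 1e-10)

  # Pearson r^2 equals the unadjusted R^2 of the simple regression
  set.seed(5)
  xr <- rnorm(100)
  yr <- 0.7 * xr + rnorm(100, 0, 0.4)
  r3 <- linear_regress(yr, xr)
  expect_equal(r3$pearson_r^2, r3$r_squared, tolerance = 1e-12)

  # noisy identity: slope within 3 standard errors of 1, and the
  # reported standard error agrees with a bootstrap estimate
  set.seed(6)
  xn <- seq(0, 10, length.out = 200)
  yn <- xn + rnorm(200, 0, 0.5)
  r4 <- linear_regress(yn, xn)
  expect_lt(abs(r4$b1 - 1), 3 * r4$b1_se)
  boots <- replicate(400, {
    i <- sample.int(200, replace = TRUE)
    unname(coef(lm(yn[i] ~ xn[i]))[2L])
  })
  expect_lt(abs(sd(boots) - r4$b1_se), 0.2 * r4$b1_se)

  expect_error(linear_regress(1:2, 1:2), "fewer than 3")
  expect_error(linear_regress(1:5, rep(1, 5)), "zero variance")
})

test_that("a trajectory compared against itself reproduces the identity
          pattern for every motion and range", {
  tr <- make_traj(c(seq(7, 111, by = 1), seq(111, 7, by = -1)),
                  cycles = 2L,
                  fun = function(a) sin(a / 20) * 5, noise = 0.01,
                  seed = 9)
  tab <- compare_nk_cm(tr, tr)
  expect_equal(nrow(tab), 10L)
  expect_true(all(abs(tab$slope - 1) < 1e-9))
  expect_true(all(abs(tab$intercept) < 1e-9))
  expect_true(all(tab$RMSE < 1e-9))
  expect_true(all(abs(tab$adj_r_squared - 1) < 1e-9))
  # range truncation bookkeeping: the narrower range uses fewer points
  n90 <- tab$n[tab$lo == 7 & tab$hi == 90][1L]
  n112 <- tab$n[tab$lo == 7 & tab$hi == 112][1L]
  expect_lt(n90, n112)
})

test_that("independent white-noise traces are uncorrelated: R^2 near zero
          and p typically above 0.05", {
  set.seed(21)
  n <- 150
  reps <- 400
  r2 <- p <- numeric(reps)
  for (i in seq_len(reps)) {
    y <- rnorm(n)
    x <- rnorm(n)
    r <- linear_regress(y, x)
    r2[i] <- r$r_squared
    p[i] <- r$p_value
  }
  expect_lt(mean(r2), 0.05)
  # under the null, p is uniform: its median sits near 0.5
  expect_gt(median(p), 0.3)
  expect_gt(mean(p > 0.05), 0.85)
})

test_that("the comparison is invariant to cycle order and uniform
          resampling of the input", {
  base <- make_traj(c(seq(7, 111, by = 0.8), seq(111, 7, by = -0.8)),
                    cycles = 3L,
                    fun = function(a) 0.02 * a^1.3, noise = 0.05,
                    seed = 33)
  sim <- make_traj(c(seq(7, 111, by = 1.1), seq(111, 7, by = -1.1)),
                   fun = function(a) 0.02 * a^1.3)
  t1 <- compare_nk_cm(base, sim)

  # swap cycle order
  swapped <- base
  swapped$cycle <- c(3, 1, 2)[swapped$cycle]
  swapped <- swapped[order(swapped$cycle, swapped$sample), ]
  t2 <- compare_nk_cm(swapped, sim)
  expect_equal(t1$slope, t2$slope, tolerance = 1e-9)
  expect_equal(t1$RMSE, t2$RMSE, tolerance = 1e-9)

  # duplicate every sample (uniform time reparameterisation)
  dense <- base[rep(seq_len(nrow(base)), each = 2L), ]
  t3 <- compare_nk_cm(dense, sim)
  expect_equal(t1$slope, t3$slope, tolerance = 1e-6)
})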