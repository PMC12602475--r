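test_that("femoral frame matches the hand-derived cross products", {
  lm <- landmark_set(list(
    Lepi = c(40, 0, 5), Mepi = c(-40, 0, 5),
    Mppc = c(-30, -20, 5), Lppc = c(30, -20, 5),
    Chip = c(0, 0, 400), Ofem = c(0, 0, 0),
    Mctc = c(-25, 0, -3), Lctc = c(25, 0, -3),
    Cank = c(0, 0, -380), Otib = c(0, 0, 0)
  ), side = "right")
  fr <- build_femoral_frame(lm)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$Z, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$Y, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$X, c(1, 0, 0), tolerance = 1e-12)

  ft <- build_tibial_frame(lm)
  expect_equal(ft$origin, c(0, 0, 0))
  expect_equal(ft$Z, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(ft$Y, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(ft$X, c(1, 0, 0), tolerance = 1e-12)
})

test_that("frames are equivariant under rigid rotation of the landmarks", {
  set.seed(11)
  lm <- canonical_landmarks()
  f0 <- build_femoral_frame(lm)
  t0 <- build_tibial_frame(lm)
  for (i in 1:100) {
    R <- random_rotation()
    shift <- stats::rnorm(3, sd = 50)
    lmr <- rotate_landmarks(lm, R, shift)
    fr <- build_femoral_frame(lmr)
    tr <- build_tibial_frame(lmr)
    for (ax in c("X", "Y", "Z")) {
      expect_equal(fr[[ax]], as.numeric(R %*% f0[[ax]]), tolerance = 1e-9)
      expect_equal(tr[[ax]], as.numeric(R %*% t0[[ax]]), tolerance = 1e-9)
    }
    expect_equal(fr$origin, as.numeric(R %*% f0$origin) + shift,
                 tolerance = 1e-9)
  }
})

test_that("degenerate landmark geometry is rejected", {
  lm <- canonical_landmarks()
  pts <- lapply(lm$points, identity)
  pts$Chip <- pts$Ofem
  expect_error(landmark_set(pts, "right"), "Chip and Ofem")

  pts <- lapply(lm$points, identity)
  pts$Mctc <- pts$Lctc
  expect_error(landmark_set(pts, "right"), "Mctc and Lctc")

  # collinear long/transverse directions -> non-constructible frame
  pts <- lapply(lm$points, identity)
  pts$Mppc <- c(0, 0, -50)
  pts$Lppc <- c(0, 0, 50)
  lm2 <- landmark_set(pts, "right")
  expect_error(build_femoral_frame(lm2), "not constructible")
})

test_that("every constructed frame is orthonormal and right-handed", {
  set.seed(7)
  lm <- canonical_landmarks()
  for (i in 1:50) {
    lmr <- rotate_landmarks(lm, random_rotation(), stats::rnorm(3, sd = 20))
    for (fr in list(build_femoral_frame(lmr), build_tibial_frame(lmr))) {
      M <- kneesim:::frame_matrix(fr)
      expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
      expect_equal(det(M), 1, tolerance = 1e-9)
    }
  }
})

test_that("coincident frames decompose to the zero joint coordinates", {
  lm <- canonical_landmarks()
  fr <- rigid_state(build_femoral_frame(lm))
  jc <- decompose_joint(fr, fr)
  expect_equal(jc$alpha, 0, tolerance = 1e-12)
  expect_equal(jc$gamma, 0, tolerance = 1e-12)
  expect_equal(jc$adduction, 0, tolerance = 1e-12)
  expect_equal(jc$H, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(c(jc$S1, jc$S2, jc$S3), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(c(jc$q1, jc$q2, jc$q3), c(0, 0, 0), tolerance = 1e-12)
})

test_that("compose/decompose round-trips 1000 random coordinate tuples", {
  set.seed(42)
  lm <- canonical_landmarks()
  femur <- rigid_state(build_femoral_frame(lm))
  worst <- 0
  for (i in 1:1000) {
    jc0 <- joint_coordinates(
      alpha = stats::runif(1, -pi / 2, 2),
      adduction = stats::runif(1, -0.4, 0.4),
      gamma = stats::runif(1, -1, 1),
      S1 = stats::runif(1, -20, 20),
      S2 = stats::runif(1, -20, 20),
      S3 = stats::runif(1, -60, 20)
    )
    tibia <- compose_joint(jc0, femur)
    jc1 <- decompose_joint(femur, tibia)
    err <- max(abs(jc1$alpha - jc0$alpha), abs(jc1$gamma - jc0$gamma),
               abs(jc1$adduction - jc0$adduction),
               abs(jc1$S1 - jc0$S1), abs(jc1$S2 - jc0$S2),
               abs(jc1$S3 - jc0$S3))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-9)
})

test_that("S2 always equals q2; S1=q1 and S3=q3 exactly at zero adduction", {
  set.seed(99)
  lm <- canonical_landmarks()
  femur <- rigid_state(build_femoral_frame(lm))
  for (i in 1:200) {
    ad <- if (i %% 2 == 0) 0 else stats::runif(1, -0.4, 0.4)
    jc0 <- joint_coordinates(stats::runif(1, -1, 2), ad,
                             stats::runif(1, -1, 1),
                             stats::rnorm(1, sd = 10),
                             stats::rnorm(1, sd = 10),
                             stats::rnorm(1, sd = 10))
    jc <- decompose_joint(femur, compose_joint(jc0, femur))
    expect_equal(jc$S2, jc$q2, tolerance = 1e-9)
    expect_equal(jc$H, jc$S1 * jc$e1 + jc$S2 * jc$e2 + jc$S3 * jc$e3,
                 tolerance = 1e-9)
    if (ad == 0) {
      expect_equal(jc$S1, jc$q1, tolerance = 1e-9)
      expect_equal(jc$S3, jc$q3, tolerance = 1e-9)
    } else {
      # with non-trivial adduction the joint and clinical translations differ
      expect_false(isTRUE(all.equal(jc$S1, jc$q1, tolerance = 1e-9)) &&
                   isTRUE(all.equal(jc$S3, jc$q3, tolerance = 1e-9)))
    }
  }
})

test_that("a pure drawer displacement moves the origin along the floating axis", {
  lm <- canonical_landmarks()
  femur <- rigid_state(build_femoral_frame(lm))
  jc <- joint_coordinates(S2 = 10)
  tibia <- compose_joint(jc, femur)
  jcd <- decompose_joint(femur, tibia)
  expect_equal(tibia$frame$origin, femur$frame$origin + 10 * jcd$e2,
               tolerance = 1e-9)
  expect_equal(jcd$S2, 10, tolerance = 1e-9)
  expect_equal(jcd$q2, 10, tolerance = 1e-9)
})

test_that("angles are invariant under mirroring a right knee to a left knee", {
  set.seed(5)
  lmr <- canonical_landmarks("right")
  lml <- canonical_landmarks("left")   # mirrored through the sagittal plane
  fr <- rigid_state(build_femoral_frame(lmr))
  fl <- rigid_state(build_femoral_frame(lml))
  M <- diag(c(-1, 1, 1))               # sagittal mirror
  for (i in 1:25) {
    jc0 <- joint_coordinates(stats::runif(1, 0, 2), stats::runif(1, -0.3, 0.3),
                             stats::runif(1, -0.8, 0.8),
                             stats::rnorm(1, 2), stats::rnorm(1, 2),
                             stats::rnorm(1, 2))
    tr <- compose_joint(jc0, fr)
    # mirror the right-knee tibial pose into the left knee
    RT <- kneesim:::frame_matrix(tr$frame)
    RTl <- M %*% RT %*% diag(c(-1, 1, 1))
    tl <- rigid_state(kneesim:::frame_from_matrix(
      as.numeric(M %*% tr$frame$origin), RTl))
    jcl <- decompose_joint(fl, tl)
    expect_equal(jcl$alpha, jc0$alpha, tolerance = 1e-9)
    expect_equal(jcl$adduction, jc0$adduction, tolerance = 1e-9)
    expect_equal(jcl$gamma, jc0$gamma, tolerance = 1e-9)
  }
})

test_that("parallel femoral X and tibial Z is reported as gimbal-degenerate", {
  lm <- canonical_landmarks()
  femur <- rigid_state(build_femoral_frame(lm))
  R <- kneesim:::rot_y(pi / 2)   # tibial Z onto femoral X
  RT <- kneesim:::frame_matrix(femur$frame) %*% R
  tibia <- rigid_state(kneesim:::frame_from_matrix(c(0, 0, 0), RT))
  expect_error(decompose_joint(femur, tibia), "gimbal")
})
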