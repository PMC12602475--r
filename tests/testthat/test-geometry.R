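test_that("mesh construction validates geometry and computes areas", {
  sph <- mesh_uv_sphere(2, n_theta = 16, n_phi = 32)
  expect_true(sph$watertight)
  expect_equal(sum(sph$face_area), 4 * pi * 2^2, tolerance = 0.02)
  expect_equal(sum(sph$vertex_area), sum(sph$face_area), tolerance = 1e-9)
  nl <- sqrt(rowSums(sph$vertex_normal^2))
  expect_lt(max(abs(nl - 1)), 1e-9)
  # outward normals point away from the centre
  dots <- rowSums(sph$vertex_normal * sph$vertices)
  expect_gt(min(dots), 0)

  expect_error(surface_mesh(matrix(0, 3, 3), rbind(c(1, 2, 3))),
               "degenerate")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 4))), "out of range")
})

test_that("mesh files round-trip through OBJ, ASCII STL and ASCII PLY", {
  sph <- mesh_uv_sphere(1.5, center = c(1, 2, 3), n_theta = 8, n_phi = 12)
  for (ext in c("obj", "stl", "ply")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mesh(sph, f)
    back <- read_mesh(f)
    expect_equal(nrow(back$faces), nrow(sph$faces))
    if (ext == "stl") {
      # vertex merge may renumber; compare sorted coordinates
      expect_equal(dim(back$vertices), dim(sph$vertices))
      expect_equal(sort(back$vertices[, 1L]), sort(sph$vertices[, 1L]),
                   tolerance = 1e-6)
    } else {
      expect_equal(back$vertices, sph$vertices, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
    expect_equal(sum(back$face_area), sum(sph$face_area),
                 tolerance = 1e-5)
    unlink(f)
  }
  expect_error(read_mesh("x.xyz"), "unsupported")
})

test_that("separated surfaces yield an empty contact set", {
  sph <- mesh_uv_sphere(1, c(0, 0, 2), n_theta = 24, n_phi = 48)
  pl <- mesh_plane_grid(2, 30)
  cs <- penetration_query(sph, pl, inside_only = FALSE)
  expect_equal(nrow(cs), 0L)
  expect_gt(attr(cs, "min_gap"), 0)
})

test_that("sphere-on-plane penetration matches the analytic oracle", {
  orc <- sphere_plane_oracle(1, 0.9)
  expect_equal(orc$delta, 0.1)
  expect_equal(sphere_plane_oracle(20, 19.9)$delta, 0.1)
  expect_equal(sphere_plane_oracle(20, 25)$delta, 0)

  sph <- mesh_uv_sphere(1, c(0, 0, 0.9), n_theta = 70, n_phi = 140)
  pl <- mesh_plane_grid(2, 80)
  cs <- penetration_query(sph, pl)
  expect_gt(nrow(cs), 10)
  expect_equal(max(cs$delta), 0.1, tolerance = 1e-2)
  expect_lt(abs(max(cs$delta) - 0.1), 1e-3)
  # normals near the deepest point align with the plane normal
  i <- which.max(cs$delta)
  expect_lt(acos(min(1, abs(cs$nz[i]))), deg2rad(1))
})

test_that("deepest-penetration error decreases monotonically under mesh
          refinement", {
  pl <- mesh_plane_grid(2, 80)
  errs <- vapply(c(20, 40, 80), function(n) {
    sph <- mesh_uv_sphere(1, c(0, 0, 0.9), n_theta = n, n_phi = 2 * n)
    cs <- penetration_query(sph, pl)
    abs(max(cs$delta) - 0.1)
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
})

test_that("penetration depth is invariant to a common rigid motion and
          continuous in pose", {
  m <- generate_synthetic_knee("default", 1)
  fs <- m$initial$femur
  ts <- m$initial$tibia
  cs0 <- penetration_query(m$femur_cartilage, m$tibia_cartilage, fs, ts)
  expect_gt(nrow(cs0), 0)

  # translate both bodies together
  shift <- c(3.5, -2.25, 7)
  fs2 <- rigid_state(body_frame(fs$frame$origin + shift, fs$frame$X,
                                fs$frame$Y, fs$frame$Z, fs$frame$side))
  ts2 <- rigid_state(body_frame(ts$frame$origin + shift, ts$frame$X,
                                ts$frame$Y, ts$frame$Z, ts$frame$side))
  cs1 <- penetration_query(m$femur_cartilage, m$tibia_cartilage, fs2, ts2)
  expect_equal(cs1$vertex, cs0$vertex)
  expect_equal(cs1$delta, cs0$delta, tolerance = 1e-9)

  # continuity: a small vertical move changes every delta by <= 2*move
  for (dz in c(1e-4, 5e-5)) {
    ts3 <- rigid_state(body_frame(ts$frame$origin + c(0, 0, dz),
                                  ts$frame$X, ts$frame$Y, ts$frame$Z,
                                  ts$frame$side))
    cs2 <- penetration_query(m$femur_cartilage, m$tibia_cartilage, fs, ts3)
    common <- intersect(cs0$vertex, cs2$vertex)
    d0 <- cs0$delta[match(common, cs0$vertex)]
    d2 <- cs2$delta[match(common, cs2$vertex)]
    expect_lt(max(abs(d2 - d0)), 2 * dz)
  }
})

test_that("the synthetic knee generator is deterministic and anatomically
          structured", {
  m1 <- generate_synthetic_knee("default", 7)
  m2 <- generate_synthetic_knee("default", 7)
  expect_identical(m1$femur_cartilage$vertices, m2$femur_cartilage$vertices)
  expect_identical(m1$profiles, m2$profiles)
  m3 <- generate_synthetic_knee("default", 8)
  expect_false(identical(m1$profiles, m3$profiles))
  expect_identical(m1$femur_cartilage$vertices, m3$femur_cartilage$vertices)

  expect_error(generate_synthetic_knee("no-such-preset", 1), "preset")

  # all 15 elements present with both insertions
  expect_setequal(names(m1$ligaments), ligament_names())
  for (l in m1$ligaments) {
    expect_length(l$femoral_mm, 3L)
    expect_length(l$tibial_mm, 3L)
  }

  # at the reference pose each condyle carries at least one contact point
  cs <- penetration_query(m1$femur_cartilage, m1$tibia_cartilage,
                          m1$initial$femur, m1$initial$tibia)
  expect_gt(sum(cs$x < 0), 0)   # medial compartment
  expect_gt(sum(cs$x > 0), 0)   # lateral compartment

  # four cycles spanning roughly 7 to 112 degrees
  expect_length(m1$profiles, 4L)
  for (p in m1$profiles) {
    expect_gt(min(p), 7)
    expect_lt(max(p), 112)
    expect_gt(max(p), 108)
  }

  # femoral sagittal radius decreases posteriorly
  r_ant <- condyle_radius(0, 24, 19)
  r_post <- condyle_radius(110, 24, 19)
  expect_gt(r_ant, r_post)

  # medial plateau concave (centre below rim), lateral near-flat
  tc <- m1$tibia_cartilage$vertices
  med <- tc[tc[, 1L] < 0, ]
  ctr <- med[order(abs(med[, 1L] + 22) + abs(med[, 2L])), ][1L, 3L]
  rim <- max(med[, 3L])
  expect_gt(rim - ctr, 2)
  lat <- tc[tc[, 1L] > 0, ]
  expect_lt(diff(range(lat[, 3L])), 1.5)
})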