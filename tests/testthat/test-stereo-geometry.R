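test_that("projection follows the pinhole model and rejects points behind the camera", {
  cam <- camera_model(c(1, 1), c(0, 0), diag(3), c(0, 0, 0))
  expect_equal(project(cam, c(0, 0, 1)), c(0, 0))
  cam2 <- camera_model(c(100, 100), c(50, 50), diag(3), c(0, 0, 0))
  expect_equal(project(cam2, c(1, 2, 2)), c(100, 150))
  expect_error(project(cam, c(0, 0, -1)), "behind camera")
  expect_error(camera_model(c(-1, 1), c(0, 0), diag(3), c(0, 0, 0)),
               "positive")
  expect_error(camera_model(c(1, 1), c(0, 0), matrix(1, 3, 3), c(0, 0, 0)),
               "orthonormal")
})

test_that("fundamental matrix of a pure-translation rig is the canonical rectified form", {
  cam1 <- camera_model(c(1, 1), c(0, 0), diag(3), c(0, 0, 0))
  cam2 <- camera_model(c(1, 1), c(0, 0), diag(3), c(100, 0, 0))
  rig <- stereo_rig(cam1, cam2)
  Fc <- matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  Fc <- Fc / sqrt(sum(Fc^2))
  expect_true(min(norm(rig$F - Fc, "F"), norm(rig$F + Fc, "F")) < 1e-12)
})

test_that("identical cameras give a degenerate-rig error", {
  cam <- camera_model(c(1000, 1000), c(320, 240), diag(3), c(0, 0, -1000))
  expect_error(stereo_rig(cam, cam), "degenerate")
})

test_that("epipolar identity holds for random rigs and points", {
  withr::with_seed(42, {
    for (k in 1:10) {
      rig <- random_rig()
      P <- cbind(stats::runif(100, -100, 100), stats::runif(100, -100, 100),
                 stats::runif(100, -50, 50))
      x1 <- project(rig$cam1, P)
      x2 <- project(rig$cam2, P)
      res <- abs(rowSums(cbind(x2, 1) * (cbind(x1, 1) %*% t(rig$F))))
      expect_lt(max(res), 1e-9)
      # epipole null spaces
      expect_lt(max(abs(rig$F %*% rig$e)), 1e-8)
      expect_lt(max(abs(t(rig$F) %*% rig$e_prime)), 1e-8)
    }
  })
})

test_that("normalized 8-point estimation recovers F from noise-free correspondences", {
  withr::with_seed(7, {
    rig <- random_rig()
    P <- cbind(stats::runif(20, -100, 100), stats::runif(20, -100, 100),
               stats::runif(20, -50, 50))
    x1 <- project(rig$cam1, P)
    x2 <- project(rig$cam2, P)
    Fh <- estimate_fundamental(x1, x2)
    expect_lt(min(norm(Fh - rig$F, "F"), norm(Fh + rig$F, "F")), 1e-6)
    expect_error(estimate_fundamental(x1[1:7, ], x2[1:7, ]), "at least 8")
    # all points on one image line: degenerate
    t <- seq(0, 1, length.out = 10)
    l1 <- cbind(10 + 100 * t, 20 + 50 * t)
    l2 <- cbind(30 + 80 * t, 10 + 60 * t)
    expect_error(estimate_fundamental(l1, l2), "degenerate")
  })
})

test_that("midpoint of skew rays matches the closed-form construction", {
  out <- triangulate_rays(c(0, 0, 0), c(0, 0, 1), c(100, 1, 0), c(-1, 0, 0))
  expect_equal(out$error_mm, 1.0)
  expect_equal(out$point3d, c(0, 0.5, 0))
  expect_error(
    triangulate_rays(c(0, 0, 0), c(0, 0, 1), c(5, 5, 0), c(0, 0, 1)),
    "parallel")
})

test_that("triangulation error equals the closed-form skew-line distance", {
  withr::with_seed(11, {
    for (k in 1:1000) {
      o1 <- stats::rnorm(3, sd = 100); d1 <- stats::rnorm(3)
      o2 <- stats::rnorm(3, sd = 100); d2 <- stats::rnorm(3)
      cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
              d1[3] * d2[1] - d1[1] * d2[3],
              d1[1] * d2[2] - d1[2] * d2[1])
      ncr <- sqrt(sum(cr^2))
      if (ncr / sqrt(sum(d1^2) * sum(d2^2)) < 1e-6) next
      closed <- abs(sum((o2 - o1) * cr)) / ncr
      got <- triangulate_rays(o1, d1, o2, d2)$error_mm
      expect_equal(got, closed, tolerance = 1e-12)
    }
  })
})

test_that("triangulate after project is the identity on 3D points", {
  cam1 <- look_at_camera(c(-200, 0, -1000), focal = c(1000, 1000))
  cam2 <- look_at_camera(c(200, 0, -1000), focal = c(1000, 1000))
  rig <- stereo_rig(cam1, cam2)
  out <- triangulate_midpoint(rig, project(rig$cam1, c(10, 20, 500)),
                              project(rig$cam2, c(10, 20, 500)))
  expect_lt(max(abs(out$point3d - c(10, 20, 500))), 1e-9)
  expect_lt(out$error_mm, 1e-9)
  expect_equal(out$point3d, colMeans(out$ray_points))

  withr::with_seed(5, {
    for (k in 1:10) {
      rig <- random_rig()
      P <- cbind(stats::runif(100, -100, 100), stats::runif(100, -100, 100),
                 stats::runif(100, -50, 50))
      tr <- triangulate_points(rig, project(rig$cam1, P), project(rig$cam2, P))
      expect_lt(max(abs(as.matrix(tr[, c("x", "y", "z")]) - P)), 1e-9)
      expect_lt(max(tr$error_mm), 1e-9)
    }
  })
})

test_that("triangulation error grows in expectation with pixel noise", {
  sc <- make_scene(scene_params(), seed = 2)
  means <- vapply(c(0, 0.25, 0.5, 1.0), function(s) {
    ps <- planted_correspondence_set(sc, pixel_noise_sigma = s, seed = 3,
                                     n_points = 500)
    mean(triangulate_points(sc$rig, ps$pts1, ps$pts2)$error_mm)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
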