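# Epipolar rectification: epipole-to-infinity mapping and disparity
# minimization.

verging_setup <- local({
  sc <- make_scene(scene_params(), seed = 4)
  ps <- planted_correspondence_set(sc, 0, 0, seed = 4, n_points = 50)
  list(rig = sc$rig, pts1 = ps$pts1, pts2 = ps$pts2)
})

test_that("an already-rectified pair is left with unchanged y-disparity", {
  Fc <- matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  withr::with_seed(1, {
    pts1 <- cbind(stats::runif(30, 50, 600), stats::runif(30, 50, 430))
    pts2 <- cbind(pts1[, 1] + stats::runif(30, -30, 30), pts1[, 2])
  })
  rp <- compute_rectification(Fc, pts1, pts2, c(640, 480))
  q1 <- apply_homography(rp$H, pts1)
  q2 <- apply_homography(rp$H_prime, pts2)
  expect_lt(mean(abs(q1[, 2] - q2[, 2])), 1e-6)
})

test_that("a verging rig rectifies to sub-0.1-px y-disparity with the epipole at infinity", {
  s <- verging_setup
  rp <- compute_rectification(s$rig$F, s$pts1, s$pts2, c(640, 480))
  q1 <- apply_homography(rp$H, s$pts1)
  q2 <- apply_homography(rp$H_prime, s$pts2)
  expect_lt(mean(abs(q1[, 2] - q2[, 2])), 0.1)
  einf <- rp$H_prime %*% s$rig$e_prime
  expect_lt(abs(einf[3]) / sqrt(sum(einf[1:2]^2)), 1e-8)
  expect_true(all(is.finite(rp$H)) && abs(det(rp$H)) > 1e-12)
  expect_true(all(is.finite(rp$H_prime)) && abs(det(rp$H_prime)) > 1e-12)
})

test_that("rectification does not increase the mean y-disparity of ground truth", {
  s <- verging_setup
  pre <- mean(abs(s$pts1[, 2] - s$pts2[, 2]))
  rp <- compute_rectification(s$rig$F, s$pts1, s$pts2, c(640, 480))
  expect_lte(rp$mean_y_disparity, pre + 1e-9)
})

test_that("degenerate inputs are rejected", {
  # epipole at the image centre: two cameras looking at each other-ish
  cam1 <- look_at_camera(c(0, 0, -1000))
  cam2 <- look_at_camera(c(0, 0, -2000))
  rig <- stereo_rig(cam1, cam2)
  withr::with_seed(2, {
    pts <- cbind(stats::runif(20, 100, 500), stats::runif(20, 100, 380))
  })
  expect_error(compute_rectification(rig$F, pts, pts, c(640, 480)),
               "epipole|unbounded|distorted")
  expect_error(compute_rectification(diag(3), pts, pts, c(640, 480)),
               "rank")
})

test_that("warp_image inverts apply_homography on pixel positions", {
  withr::with_seed(3, {
    img <- matrix(stats::runif(60 * 80), 60, 80)
  })
  H <- matrix(c(1, 0, 0, 0, 1, 0, 5, 3, 1), 3, 3)  # translation by (5, 3)
  w <- warp_image(img, H, c(90, 70))
  # pixel (x, y) of the source appears at (x+5, y+3)
  expect_equal(w[10 + 3 + 1, 20 + 5 + 1], img[10 + 1, 20 + 1], tolerance = 1e-12)
})

test_that("rectify_stereo synthesizes correspondences and rectifies the default rig", {
  sc <- make_scene(scene_params(), seed = 6)
  rp <- rectify_stereo(sc$rig, c(640, 480))
  ps <- planted_correspondence_set(sc, 0, 0, seed = 6, n_points = 40)
  q1 <- apply_homography(rp$H, ps$pts1)
  q2 <- apply_homography(rp$H_prime, ps$pts2)
  expect_lt(mean(abs(q1[, 2] - q2[, 2])), 0.1)
})
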