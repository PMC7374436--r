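# Synthetic stereo scenes: determinism, geometry, noise and illumination.

default_scene <- local({
  sc <- make_scene(scene_params(), seed = 1)
  list(scene = sc, views = render_views(sc))
})

test_that("scenes and renders are deterministic under the seed", {
  sc2 <- make_scene(scene_params(), seed = 1)
  expect_equal(default_scene$scene$landmarks, sc2$landmarks)
  rv2 <- render_views(sc2)
  expect_identical(default_scene$views$img1, rv2$img1)
  expect_identical(default_scene$views$img2, rv2$img2)
  sc3 <- make_scene(scene_params(), seed = 2)
  expect_false(identical(default_scene$scene$landmarks$u, sc3$landmarks$u))
  expect_false(identical(render_views(sc3)$img1, rv2$img1))
})

test_that("the requested landmarks exist, lie on the surface and are visible", {
  sc <- default_scene$scene
  expect_equal(nrow(sc$landmarks), 20)
  h <- stereospine:::scene_height(sc, sc$landmarks$u, sc$landmarks$v)
  expect_lt(max(abs(sc$landmarks$Z + h)), 1e-6)
  w <- sc$params$image_size[1]; hh <- sc$params$image_size[2]
  expect_true(all(sc$landmarks$x1 >= 0 & sc$landmarks$x1 <= w - 1 &
                    sc$landmarks$y1 >= 0 & sc$landmarks$y1 <= hh - 1))
  expect_true(all(sc$landmarks$x2 >= 0 & sc$landmarks$x2 <= w - 1 &
                    sc$landmarks$y2 >= 0 & sc$landmarks$y2 <= hh - 1))
})

test_that("extreme vergence is rejected as infeasible", {
  expect_error(make_scene(scene_params(vergence_deg = 180)), "infeasible")
})

test_that("ground-truth projections triangulate back to the landmarks exactly", {
  sc <- default_scene$scene
  gt <- default_scene$views$gt
  tr <- triangulate_points(sc$rig, cbind(gt$x1, gt$y1), cbind(gt$x2, gt$y2))
  expect_lt(max(tr$error_mm), 1e-9)
  expect_lt(max(abs(as.matrix(tr[, c("x", "y", "z")]) -
                      as.matrix(gt[, c("X", "Y", "Z")]))), 1e-9)
})

test_that("pixel noise has the configured standard deviation", {
  clean <- default_scene$views
  noisy <- render_views(make_scene(scene_params(noise_sigma = 2), seed = 1))
  d <- (noisy$img1 - clean$img1)[60:420, 60:580] * 255
  expect_lt(abs(stats::sd(d) - 2) / 2, 0.1)
})

test_that("the illumination scalar scales image intensity linearly", {
  dark <- render_views(make_scene(scene_params(illumination = 0.1), seed = 1))
  ratio <- mean(dark$img1) / mean(default_scene$views$img1)
  expect_lt(abs(ratio - 0.1), 0.01)
})

test_that("planted correspondence sets honour their outlier contract", {
  sc <- default_scene$scene
  ps0 <- planted_correspondence_set(sc, 0, 0, seed = 2, n_points = 100)
  expect_true(all(ps0$labels == "inlier"))
  ps <- planted_correspondence_set(sc, 0, 0.2, seed = 2, n_points = 100)
  expect_equal(sum(ps$labels == "outlier"), 20)
  # same seed reproduces the set exactly
  ps2 <- planted_correspondence_set(sc, 0, 0.2, seed = 2, n_points = 100)
  expect_identical(ps, ps2)
  expect_error(planted_correspondence_set(sc, 0, 1.0), "outlier_fraction")
})

test_that("dimmer scenes never raise the median matched-inlier count", {
  lo <- integer(0); hi <- integer(0)
  for (s in 1:5) {
    bright <- render_views(make_scene(scene_params(noise_sigma = 1), seed = s))
    dim <- render_views(make_scene(scene_params(noise_sigma = 1,
                                                illumination = 0.1), seed = s))
    rig <- make_scene(scene_params(), seed = s)$rig
    rb <- process_frame_pair(bright$img1, bright$img2, rig,
                             run_config(detector = "fast"))
    rd <- suppressWarnings(
      process_frame_pair(dim$img1, dim$img2, rig,
                         run_config(detector = "fast")))
    hi <- c(hi, rb$inlier_count); lo <- c(lo, rd$inlier_count)
  }
  expect_lte(stats::median(lo), stats::median(hi))
})
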