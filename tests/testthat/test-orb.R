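# Oriented FAST + rotated binary descriptors.

orb_fixture <- local({
  img <- make_wedge_image(seed = 5)
  res <- orb_detect_describe(img)
  list(img = img, res = res)
})

test_that("the intensity-centroid orientation points along the mass offset", {
  # a bright lobe displaced along +x from a corner point: theta near 0
  img <- matrix(0.2, 81, 81)
  gg <- expand.grid(dy = -16:16, dx = -16:16)
  u <- gg$dx; v <- gg$dy
  inside <- u > 0.5 & u < 14.5 & abs(v) < u * tan(25 * pi / 180)
  img[cbind(40 + gg$dy, 40 + gg$dx)] <- 0.2 + 0.6 * inside
  res <- orb_detect_describe(img, detector_config(orb = list(n_levels = 1)))
  apex <- which.min((res$keypoints$x - 39)^2 + (res$keypoints$y - 40)^2)
  th <- res$keypoints$orientation[apex]
  expect_lt(min(th, 2 * pi - th), 0.05)
})

test_that("descriptors are 256-bit with zero self-distance and full complement distance", {
  D <- orb_fixture$res$descriptors
  expect_equal(ncol(D), 256)
  expect_true(all(D %in% c(0L, 1L)))
  expect_equal(sum(xor(D[1, ], D[1, ])), 0)
  expect_equal(sum(xor(D[1, ], 1 - D[1, ])), 256)
  expect_equal(attr(D, "kind"), "binary256")
})

test_that("the binary test pattern is deterministic", {
  p1 <- stereospine:::orb_test_pattern()
  p2 <- stereospine:::orb_test_pattern()
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(256L, 4L))
  expect_true(all(abs(p1) <= 13))
})

test_that("keypoint orientations rotate with the image", {
  # aggregate over seeds; orientation shifts by the rotation angle within
  # 5 degrees for at least 90% of geometrically corresponding keypoints
  th <- 45 * pi / 180
  shifts <- c()
  for (sd in 1:5) {
    img <- make_wedge_image(seed = sd)
    H <- rotation_homography(th, 220)
    rot <- warp_image(img, H, c(220, 220), fill = 0.3)
    r1 <- if (sd == 5) orb_fixture$res else orb_detect_describe(img)
    r2 <- orb_detect_describe(rot)
    k1 <- r1$keypoints[r1$keypoints$level == 0, ]
    k2 <- r2$keypoints[r2$keypoints$level == 0, ]
    p2 <- apply_homography(solve(H), cbind(k2$x, k2$y))
    for (i in seq_len(nrow(k2))) {
      d <- sqrt((k1$x - p2[i, 1])^2 + (k1$y - p2[i, 2])^2)
      j <- which.min(d)
      if (d[j] < 2) {
        dd <- (k2$orientation[i] - k1$orientation[j] - th) %% (2 * pi)
        shifts <- c(shifts, min(dd, 2 * pi - dd))
      }
    }
  }
  expect_gt(length(shifts), 50)
  expect_gte(mean(shifts < 5 * pi / 180), 0.9)
})

test_that("keypoint positions at the base level shift under integer translation", {
  img <- orb_fixture$img
  cfg <- detector_config(orb = list(n_levels = 1))
  a <- orb_detect_describe(img[1:200, 1:200], cfg)$keypoints
  b <- orb_detect_describe(img[6:205, 9:208], cfg)$keypoints
  lo <- 60; hi <- 140
  inA <- a[a$x >= lo & a$x <= hi & a$y >= lo & a$y <= hi, ]
  inB <- b[b$x + 8 >= lo & b$x + 8 <= hi & b$y + 5 >= lo & b$y + 5 <= hi, ]
  expect_gt(nrow(inA), 0)
  expect_setequal(paste(inA$x, inA$y), paste(inB$x + 8, inB$y + 5))
})

test_that("an undersized image degrades to fewer pyramid levels with a warning", {
  img <- make_wedge_image(seed = 1, size = 150, n = 3)
  expect_warning(res <- orb_detect_describe(img), "levels")
  expect_true(nrow(res$keypoints) >= 0)
})
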