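# Hessian-determinant blob detection, orientation and 64-d descriptors.

test_that("integral image reproduces brute-force box sums", {
  expect_equal(integral_image(matrix(1, 3, 3))[4, 4], 9)
  expect_equal(integral_image(matrix(7, 1, 1))[2, 2], 7)
  expect_error(integral_image(matrix(numeric(0), 0, 0)), "empty")
  withr::with_seed(13, {
    img <- matrix(stats::runif(40 * 30), 40, 30)
    S <- integral_image(img)
    for (k in 1:200) {
      r <- sort(sample(40, 2)); c <- sort(sample(30, 2))
      expect_equal(box_sum(S, r[1], c[1], r[2], c[2]),
                   sum(img[r[1]:r[2], c[1]:c[2]]), tolerance = 1e-9)
    }
  })
})

test_that("the determinant approximation follows its defining identity", {
  expect_equal(hessian_det_combine(2, 3, 1), 3 * 2 - (0.9 * 1)^2)
  hd <- hessian_det(matrix(0.5, 64, 64), 9)
  expect_lt(max(abs(hd$det_map)), 1e-9)
  expect_equal(hd$det_map,
               hessian_det_combine(hd$Lxx, hd$Lyy, hd$Lxy))
  expect_error(hessian_det(matrix(0.5, 8, 8), 9), "larger")
  expect_error(hessian_det(matrix(0.5, 64, 64), 10), "multiple of 3")
})

test_that("blob detections sit at the dense response argmax in position and scale", {
  sizes_all <- sort(unique(c(vapply(1:3, function(o)
    stereospine:::surf_filter_size(o, 1:6), numeric(6)))))
  sizes_all <- sizes_all[sizes_all <= 75]
  cfg <- detector_config(surf = list(feature_threshold = 50))
  picked <- c()
  for (s in c(2.5, 4, 6)) {
    img <- blob_image(s)
    ctr <- (nrow(img) - 1) / 2 + 1
    dense <- vapply(sizes_all, function(L) hessian_det(img, L)$det_map[ctr, ctr],
                    numeric(1))
    best_L <- sizes_all[which.max(dense)]
    kp <- surf_detect(img, cfg)
    kp <- kp[which.max(kp$response), ]
    expect_lt(sqrt((kp$x - (ctr - 1))^2 + (kp$y - (ctr - 1))^2), 2)
    expect_equal(kp$scale, 1.2 * best_L / 9, tolerance = 1e-9)
    picked <- c(picked, kp$scale)
  }
  # selected scale grows with blob size
  expect_true(all(diff(picked) > 0))
})

test_that("flat images yield no keypoints and thresholds are respected", {
  expect_equal(nrow(surf_detect(matrix(0.5, 64, 64))), 0)
  img <- blob_image(3, amp = 0.7)
  kp <- surf_detect(img)  # default threshold 600
  if (nrow(kp) > 0) expect_true(all(kp$response >= 600))
})

test_that("keypoint positions shift exactly under integer translation", {
  withr::with_seed(17, {
    big <- stereospine:::box_smooth(matrix(stats::runif(140 * 140), 140, 140), 2)
  })
  cfg <- detector_config(surf = list(feature_threshold = 5, n_octaves = 2))
  a <- surf_detect(big[1:120, 1:120], cfg)
  b <- surf_detect(big[6:125, 9:128], cfg)   # (dy, dx) = (5, 8)
  lo <- 40; hi <- 80
  inA <- a[a$x >= lo & a$x <= hi & a$y >= lo & a$y <= hi, ]
  inB <- b[b$x + 8 >= lo & b$x + 8 <= hi & b$y + 5 >= lo & b$y + 5 <= hi, ]
  expect_gt(nrow(inA), 0)
  expect_setequal(paste(inA$x, inA$y, inA$scale),
                  paste(inB$x + 8, inB$y + 5, inB$scale))
})

test_that("orientation follows image structure", {
  ramp <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64, 64,
                 byrow = FALSE)
  o <- surf_orient(ramp, 31, 31, 2)
  expect_lt(min(abs(o - 0), abs(o - pi), abs(o - 2 * pi)), 0.05)
  expect_equal(surf_orient(matrix(0.5, 64, 64), 31, 31, 2), 0)
  expect_true(is.na(surf_orient(matrix(0.5, 64, 64), 2, 2, 2)))
  # asymmetric two-lobe patch: a well-defined dominant direction
  g <- expand.grid(y = 0:63, x = 0:63)
  base <- matrix(0.3 + 0.5 * exp(-((g$x - 31)^2 + (g$y - 31)^2) / 18) +
                   0.4 * exp(-((g$x - 39)^2 + (g$y - 31)^2) / 12), 64, 64)
  o1 <- surf_orient(base, 31, 31, 2)
  rot <- t(base)[, ncol(base):1]  # exact 90-degree rotation
  o2 <- surf_orient(rot, 31, 31, 2)
  dd <- (o2 - o1) %% (2 * pi)
  expect_lt(min(abs(dd - pi / 2), abs(dd - 3 * pi / 2)), 0.1)
})

test_that("descriptors are 64-d unit vectors with perfect self-correlation", {
  withr::with_seed(23, {
    base <- stereospine:::box_smooth(matrix(stats::runif(80 * 80), 80, 80), 2)
  })
  o <- surf_orient(base, 40, 40, 2)
  d <- surf_describe(base, 40, 40, 2, o)
  expect_length(d, 64)
  expect_equal(sum(d^2), 1, tolerance = 1e-12)
  expect_equal(ncc(d, d), 1.0)
  expect_null(surf_describe(base, 2, 2, 2, 0))
})

test_that("descriptors of a rotated patch beat the random-patch null", {
  withr::with_seed(29, {
    size <- 161
    img <- stereospine:::box_smooth(matrix(stats::runif(size * size),
                                           size, size), 3)
    ctr <- (size - 1) / 2
    o1 <- surf_orient(img, ctr, ctr, 3)
    d1 <- surf_describe(img, ctr, ctr, 3, o1)
    rot <- warp_image(img, rotation_homography(30 * pi / 180, size),
                      c(size, size), fill = 0.5)
    o2 <- surf_orient(rot, ctr, ctr, 3)
    d2 <- surf_describe(rot, ctr, ctr, 3, o2)
    score <- ncc(d1, d2)
    null_scores <- vapply(1:200, function(k) {
      rimg <- stereospine:::box_smooth(matrix(stats::runif(101 * 101),
                                              101, 101), 3)
      ro <- surf_orient(rimg, 50, 50, 3)
      ncc(d1, surf_describe(rimg, 50, 50, 3, ro))
    }, numeric(1))
    expect_gt(score, stats::quantile(null_scores, 0.95))
  })
})
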