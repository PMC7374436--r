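test_that("CLAHE preserves flatness and the intensity range", {
  flat <- matrix(0.4, 64, 64)
  out <- clahe(flat)
  expect_equal(length(unique(as.vector(out))), 1)
  withr::with_seed(1, img <- matrix(stats::runif(128 * 128), 128, 128))
  out <- clahe(img)
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_equal(dim(out), dim(img))
})

test_that("CLAHE clips every tile histogram at the configured limit", {
  withr::with_seed(2, img <- matrix(stats::runif(128 * 128), 128, 128))
  out <- clahe(img, clip_limit = 0.03, tile_grid = c(8, 8),
               return_tiles = TRUE)
  th <- attr(out, "tile_histograms")
  # recompute tile histograms from the input and audit the clip bound
  limit <- ceiling(0.03 * 16 * 16)
  expect_true(all(th <= limit))
  q <- round(img * 255)
  for (i in c(1, 4, 8)) for (j in c(1, 5, 8)) {
    tile <- q[((i - 1) * 16 + 1):(i * 16), ((j - 1) * 16 + 1):(j * 16)]
    h <- tabulate(tile + 1, nbins = 256)
    expect_equal(th[(i - 1) * 8 + j, ], pmin(h, limit))
  }
})

test_that("CLAHE rejects invalid parameters", {
  img <- matrix(0.5, 16, 16)
  expect_error(clahe(img, clip_limit = 0), "clip_limit")
  expect_error(clahe(img, clip_limit = 1.5), "clip_limit")
  expect_error(clahe(img, tile_grid = c(32, 32)), "tile")
})

test_that("Otsu's threshold equals the exhaustive between-class-variance maximizer", {
  withr::with_seed(3, {
    for (k in 1:100) {
      img <- matrix(stats::runif(24 * 24), 24, 24)
      expect_identical(otsu_threshold(img), as.integer(otsu_oracle(img)))
    }
  })
  bimodal <- matrix(c(rep(50, 512), rep(200, 512)) / 255, 32, 32)
  lev <- otsu_threshold(bimodal)
  expect_true(lev > 50 && lev < 200)
  expect_error(otsu_threshold(matrix(0.5, 8, 8)), "degenerate")
})

test_that("segment_spine grows exactly the bright connected component", {
  img <- matrix(30 / 255, 128, 128)
  img[40:79, 50:89] <- 220 / 255
  pp <- segment_spine(img)
  expect_equal(sum(pp$mask), 40 * 40)
  expect_equal(unname(pp$roi), c(49, 39, 40, 40))
  expect_true(all(pp$mask[40:79, 50:89] == 1))
  # multiplying by the mask zeroes exactly the background
  expect_true(all(pp$enhanced[pp$mask == 0] == 0))
  # idempotence: re-segmenting the masked image returns the same mask
  pp2 <- segment_spine(pp$enhanced)
  expect_equal(pp2$mask, pp$mask)
  expect_error(segment_spine(matrix(0, 32, 32)), "degenerate|empty")
})

test_that("segmentation separates the two blobs by seed", {
  img <- matrix(20 / 255, 100, 100)
  img[10:29, 10:29] <- 0.8
  img[60:89, 60:89] <- 0.8
  pp <- segment_spine(img)          # largest component wins by default
  expect_equal(sum(pp$mask), 30 * 30)
  pp2 <- segment_spine(img, seed = c(15, 15))
  expect_equal(sum(pp2$mask), 20 * 20)
  expect_error(segment_spine(img, seed = c(50, 50)), "seed")
})

test_that("keypoints back-project by the ROI offset and re-crop to identity", {
  img <- matrix(30 / 255, 128, 128)
  img[51:100, 101:120] <- 0.9
  pp <- segment_spine(img)
  kp <- tibble::tibble(x = c(0, 10), y = c(0, 30), scale = 2,
                       orientation = 0, response = 1)
  out <- crop_and_backproject(pp, kp)
  expect_equal(out$x, kp$x + pp$offset[[1]])
  expect_equal(out$y, kp$y + pp$offset[[2]])
  # identity when the ROI is the full frame
  full <- structure(list(roi = c(x = 0, y = 0, width = 128, height = 128),
                         offset = c(x = 0, y = 0)),
                    class = "preprocess_result")
  expect_equal(crop_and_backproject(full, kp)$x, kp$x)
  # round trip: subtracting the offset restores the ROI-local coordinates
  back <- out
  back$x <- back$x - pp$offset[[1]]; back$y <- back$y - pp$offset[[2]]
  expect_equal(back, kp)
  expect_error(crop_and_backproject(pp, tibble::tibble(x = -1, y = 0)),
               "outside")
})
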