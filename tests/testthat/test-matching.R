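test_that("normalized cross-correlation obeys its algebraic identities", {
  withr::with_seed(31, v <- stats::rnorm(64))
  expect_equal(ncc(v, v), 1.0)
  expect_equal(ncc(v, -v), -1.0)
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)  # zero-mean orthogonal
  expect_equal(ncc(a, b), 0.0)
  expect_error(ncc(rep(1, 8), v[1:8]), "zero-variance")
  expect_error(ncc(v, v[1:10]), "equal length")
})

test_that("a planted row permutation is recovered by mutual-best matching", {
  withr::with_seed(37, {
    D1 <- matrix(stats::rnorm(200 * 64), 200)
    attr(D1, "kind") <- "real64"
    perm <- sample(200)
    D2 <- D1[perm, ]
    attr(D2, "kind") <- "real64"
    m <- match_descriptors(D1, D2)
    expect_gte(mean(m$idx1 == perm[m$idx2]), 0.99)
    # symmetry: swapping the sets transposes the pairs
    m2 <- match_descriptors(D2, D1)
    expect_setequal(paste(m$idx1, m$idx2), paste(m2$idx2, m2$idx1))
  })
})

test_that("matching is one-to-one, kind-checked and sorted by similarity", {
  withr::with_seed(41, {
    D1 <- matrix(stats::rnorm(50 * 64), 50); attr(D1, "kind") <- "real64"
    D2 <- matrix(stats::rnorm(60 * 64), 60); attr(D2, "kind") <- "real64"
  })
  m <- match_descriptors(D1, D2)
  expect_equal(anyDuplicated(m$idx1), 0)
  expect_equal(anyDuplicated(m$idx2), 0)
  expect_true(all(diff(m$score) <= 1e-12))
  B <- matrix(0L, 5, 256); attr(B, "kind") <- "binary256"
  expect_error(match_descriptors(D1, B), "kinds differ")
  empty <- matrix(numeric(), 0, 64); attr(empty, "kind") <- "real64"
  expect_equal(nrow(match_descriptors(D1, empty)), 0)
})

test_that("equal-score candidates resolve to the lower second-view index", {
  D1 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0), 2, 4, byrow = TRUE)
  attr(D1, "kind") <- "real64"
  D2 <- rbind(D1[2, ], D1[1, ], D1[1, ])  # rows 2 and 3 tie for D1 row 1
  attr(D2, "kind") <- "real64"
  m <- match_descriptors(D1, D2)
  expect_equal(m$idx2[m$idx1 == 1], 2L)
})

test_that("binary descriptors match by Hamming distance", {
  withr::with_seed(43, {
    D1 <- matrix(as.integer(stats::runif(40 * 256) > 0.5), 40)
    attr(D1, "kind") <- "binary256"
    perm <- sample(40)
    D2 <- D1[perm, ]
    attr(D2, "kind") <- "binary256"
  })
  m <- match_descriptors(D1, D2)
  expect_equal(attr(m, "metric"), "hamming")
  expect_true(all(m$score == 0))
  expect_true(all(m$idx1 == perm[m$idx2]))
  # strict-fidelity mode treats the bits as floats under NCC
  m2 <- match_descriptors(D1, D2, metric = "ncc-all")
  expect_equal(attr(m2, "metric"), "ncc")
  expect_true(all(m2$idx1 == perm[m2$idx2]))
})

test_that("the epipolar filter flags planted gross outliers and keeps true matches", {
  sc <- make_scene(scene_params(), seed = 10)
  ps <- planted_correspondence_set(sc, pixel_noise_sigma = 0,
                                   outlier_fraction = 0.2, seed = 11,
                                   n_points = 100)
  kp1 <- tibble::tibble(x = ps$pts1[, 1], y = ps$pts1[, 2])
  kp2 <- tibble::tibble(x = ps$pts2[, 1], y = ps$pts2[, 2])
  m <- tibble::tibble(idx1 = 1:100, idx2 = 1:100, score = 1)
  # rectified frame: warp coordinates with the rig's rectification
  rp <- rectify_stereo(sc$rig, c(640, 480))
  q1 <- apply_homography(rp$H, ps$pts1)
  q2 <- apply_homography(rp$H_prime, ps$pts2)
  out <- epipolar_filter(m, tibble::tibble(x = q1[, 1], y = q1[, 2]),
                         tibble::tibble(x = q2[, 1], y = q2[, 2]),
                         "rectified", tol_px = 1)
  expect_equal(sum(ps$labels == "outlier"), 20)
  expect_true(all(!out$inlier[ps$labels == "outlier"]))
  expect_gte(mean(out$inlier[ps$labels == "inlier"]), 0.99)
  # general mode with F agrees on the unrectified coordinates
  outg <- epipolar_filter(m, kp1, kp2, "general", tol_px = 1, F = sc$rig$F)
  expect_true(all(!outg$inlier[ps$labels == "outlier"]))
  expect_gte(mean(outg$inlier[ps$labels == "inlier"]), 0.99)
  expect_error(epipolar_filter(m, kp1, kp2, "general", tol_px = 1), "F")
  # pure flagging: scores and pairs unchanged
  expect_equal(out$score, m$score)
  expect_equal(out$idx1, m$idx1)
  # a single planted 50 px outlier is flagged
  one <- epipolar_filter(tibble::tibble(idx1 = 1L, idx2 = 1L, score = 1),
                         tibble::tibble(x = 10, y = 10),
                         tibble::tibble(x = 12, y = 60), "rectified", 1)
  expect_false(one$inlier)
  # empty match set passes through
  emp <- epipolar_filter(tibble::tibble(idx1 = integer(), idx2 = integer(),
                                        score = numeric()),
                         kp1, kp2, "rectified", 1)
  expect_equal(nrow(emp), 0)
})
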