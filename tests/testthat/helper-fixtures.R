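# Shared fixtures and independent oracles for the test suite.

# Brute-force FAST segment-test oracle: for every interior pixel, check all
# 16 cyclic arc starts directly (no vectorization shared with the
# implementation).
fast_oracle <- function(img, T = 0.2, n = 12, pretest = TRUE) {
  off <- cbind(dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1),
               dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3))
  nr <- nrow(img); nc <- ncol(img)
  out <- NULL
  for (r in 4:(nr - 3)) {
    for (c in 4:(nc - 3)) {
      p <- img[r, c]
      circ <- img[cbind(r + off[, "dy"], c + off[, "dx"])]
      b <- circ > p + T
      d <- circ < p - T
      if (pretest && n >= 12) {
        comp <- c(1, 5, 9, 13)
        if (sum(b[comp]) < 3 && sum(d[comp]) < 3) next
      }
      arc <- function(f) {
        f2 <- c(f, f)
        any(vapply(1:16, function(s) all(f2[s:(s + n - 1)]), logical(1)))
      }
      if (arc(b) || arc(d)) out <- rbind(out, c(c - 1, r - 1))
    }
  }
  out
}

# Exhaustive Otsu oracle: direct between-class-variance search over all
# 255 candidate split levels (background < L, foreground >= L).
otsu_oracle <- function(img) {
  q <- pmin(pmax(round(img * 255), 0), 255)
  best <- -1; bl <- NA
  for (L in 1:255) {
    a <- q[q < L]; b <- q[q >= L]
    if (length(a) == 0 || length(b) == 0) next
    v <- as.numeric(length(a)) * length(b) * (mean(a) - mean(b))^2
    if (v > best + 1e-9) { best <- v; bl <- L }
  }
  bl
}

# Look-at camera: world->camera rotation pointing the optical axis at a
# target point.
look_at_camera <- function(center, target = c(0, 0, 0), focal = c(1000, 1000),
                           pp = c(319.5, 239.5)) {
  z <- target - center; z <- z / sqrt(sum(z^2))
  up <- c(0, 1, 0)
  x <- c(up[2] * z[3] - up[3] * z[2],
         up[3] * z[1] - up[1] * z[3],
         up[1] * z[2] - up[2] * z[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  camera_model(focal, pp, rbind(x, y, z), center)
}

# Random verging rig with both cameras aimed at the origin.
random_rig <- function() {
  a1 <- stats::runif(1, -0.3, -0.05)
  a2 <- stats::runif(1, 0.05, 0.3)
  d <- stats::runif(1, 800, 1200)
  c1 <- c(d * sin(a1), stats::runif(1, -100, 100), -d * cos(a1))
  c2 <- c(d * sin(a2), stats::runif(1, -100, 100), -d * cos(a2))
  f <- stats::runif(1, 800, 1200)
  stereo_rig(look_at_camera(c1, focal = c(f, f)),
             look_at_camera(c2, focal = c(f, f)))
}

# Isotropic Gaussian blob on a flat background.
blob_image <- function(sigma, size = 121, amp = 0.6, bg = 0.2) {
  g <- expand.grid(y = 0:(size - 1), x = 0:(size - 1))
  ctr <- (size - 1) / 2
  matrix(bg + amp * exp(-((g$x - ctr)^2 + (g$y - ctr)^2) / (2 * sigma^2)),
         size, size)
}

# Anti-aliased wedge features: sharp apex corners with a long intensity-
# centroid lever arm, for orientation equivariance tests.
make_wedge_image <- function(seed = 5, size = 220, n = 8) {
  withr::with_seed(seed, {
    im <- matrix(0.3, size, size)
    pts <- matrix(numeric(0), 0, 2); tries <- 0
    while (nrow(pts) < n && tries < 4000) {
      tries <- tries + 1
      c0 <- c(sample(60:(size - 60), 1), sample(60:(size - 60), 1))
      if (nrow(pts) == 0 ||
          min((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2) > 40^2)
        pts <- rbind(pts, c0)
    }
    gg <- expand.grid(dy = -16:16, dx = -16:16)
    sub <- expand.grid(sy = c(-1, 0, 1) / 3, sx = c(-1, 0, 1) / 3)
    for (i in seq_len(nrow(pts))) {
      a <- stats::runif(1, 0, 2 * pi)
      cov <- 0
      for (k in 1:9) {
        dx <- gg$dx + sub$sx[k]; dy <- gg$dy + sub$sy[k]
        u <- dx * cos(a) + dy * sin(a)
        v <- -dx * sin(a) + dy * cos(a)
        cov <- cov + (u > 0.5 & u < 14.5 & abs(v) < u * tan(25 * pi / 180))
      }
      im[cbind(pts[i, 2] + gg$dy, pts[i, 1] + gg$dx)] <-
        im[cbind(pts[i, 2] + gg$dy, pts[i, 1] + gg$dx)] + 0.5 * cov / 9
    }
    im
  })
}

# Rotation homography about the image centre (0-based pixel frame).
rotation_homography <- function(theta, size) {
  ctr <- (size - 1) / 2
  Tc <- matrix(c(1, 0, 0, 0, 1, 0, -ctr, -ctr, 1), 3, 3)
  Rz <- matrix(c(cos(theta), sin(theta), 0,
                 -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  solve(Tc) %*% Rz %*% Tc
}

# Minimal frame-pair result with given per-feature errors, for statistics
# tests.
fake_result <- function(errors, detector = "fast",
                        times = c(preprocess = 0.1, detect = 0.1,
                                  match = 0.1, triangulate = 0.1)) {
  structure(
    list(detector = detector,
         matches = tibble::tibble(idx1 = seq_along(errors),
                                  idx2 = seq_along(errors),
                                  score = rep(1, length(errors)),
                                  inlier = rep(TRUE, length(errors))),
         triangulations = tibble::tibble(x = errors, y = errors, z = errors,
                                         error_mm = errors),
         inlier_count = length(errors), n_keypoints = c(10, 10),
         stage_times = times, rectification = NULL),
    class = "frame_pair_result")
}

# Pairwise best Jaccard of region pixel sets from one MSER run to another.
best_jaccards <- function(ra, rb) {
  key <- function(px) paste(px[, 1], px[, 2])
  vapply(seq_len(nrow(ra)), function(i) {
    a <- key(ra$pixels[[i]])
    max(vapply(seq_len(nrow(rb)), function(j) {
      b <- key(rb$pixels[[j]])
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1)))
  }, numeric(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
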