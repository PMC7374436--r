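# Oriented FAST + rotated binary-test descriptors (ORB-style).

# Bilinear image resize to (new_nr, new_nc).
resample_bilinear <- function(img, new_nr, new_nc) {
  sr <- nrow(img) / new_nr; sc <- ncol(img) / new_nc
  gy <- ((seq_len(new_nr) - 0.5) * sr) - 0.5
  gx <- ((seq_len(new_nc) - 0.5) * sc) - 0.5
  gy <- pmin(pmax(gy, 0), nrow(img) - 1)
  gx <- pmin(pmax(gx, 0), ncol(img) - 1)
  sx <- rep(gx, each = new_nr)
  sy <- rep(gy, times = new_nc)
  matrix(bilinear_sample(img, sx, sy), new_nr, new_nc)
}

# 5x5 box smoothing via the integral image (border windows clipped).
box_smooth <- function(img, half = 2) {
  S <- integral_image(img)
  nr <- nrow(img); nc <- ncol(img)
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r0 <- pmax(R - half, 1); r1 <- pmin(R + half, nr)
  c0 <- pmax(C - half, 1); c1 <- pmin(C + half, nc)
  s <- box_sum(S, as.vector(r0), as.vector(c0), as.vector(r1), as.vector(c1))
  matrix(s / ((as.vector(r1) - as.vector(r0) + 1) *
                (as.vector(c1) - as.vector(c0) + 1)), nr, nc)
}

# Fixed pseudo-random binary test pattern: 256 point pairs inside a 31x31
# patch, roughly Gaussian-distributed, generated by a small LCG so the
# pattern is deterministic and independent of R's RNG state.
orb_test_pattern <- function(n_bits = 256, half = 13) {
  state <- 12345
  nxt <- function() {
    # LCG modulo 2^32 (exact in doubles); returns in [0, 1)
    state <<- (69069 * state + 1) %% 2^32
    state / 2^32
  }
  draw <- function() {
    # sum of three uniforms ~ bell-shaped on [-1.5, 1.5]
    v <- (nxt() + nxt() + nxt()) - 1.5
    max(-half, min(half, round(v * half / 1.2)))
  }
  m <- matrix(0L, n_bits, 4)
  for (i in seq_len(n_bits)) m[i, ] <- c(draw(), draw(), draw(), draw())
  colnames(m) <- c("xa", "ya", "xb", "yb")
  m
}

.orb_cache <- new.env(parent = emptyenv())

orb_pattern_cached <- function() {
  if (is.null(.orb_cache$pattern)) .orb_cache$pattern <- orb_test_pattern()
  .orb_cache$pattern
}

# intensity-centroid orientation offsets (radius-15 disc)
orb_moment_grid <- function(radius = 15) {
  g <- expand.grid(ox = -radius:radius, oy = -radius:radius)
  g[g$ox^2 + g$oy^2 <= radius^2, ]
}

#' Detect and describe oriented binary features (ORB)
#'
#' Runs FAST corner detection on every level of a `scale_factor` image
#' pyramid, assigns each keypoint the intensity-centroid orientation
#' `theta = atan2(m01, m10)` of its surrounding patch, and extracts a
#' 256-bit descriptor of binary intensity comparisons on a 5x5 box-smoothed
#' patch, with the fixed test pattern rotated by `theta`. Keypoint
#' coordinates are mapped back to level-0 pixels.
#'
#' @param img Gray image in `[0, 1]`.
#' @param config A [detector_config()] (the `orb` and `fast` entries are
#'   used; FAST runs with the ORB contrast threshold).
#' @return A list with `keypoints` (tibble: `x`, `y` level-0 pixels,
#'   `scale` = pyramid scale of the detection level, `orientation`,
#'   `response`, `level`) and `descriptors` (n x 256 0/1 matrix, attribute
#'   `kind = "binary256"`).
#' @export
orb_detect_describe <- function(img, config = detector_config()) {
  cf <- config$orb
  fast_cf <- config
  fast_cf$fast$min_contrast <- cf$fast_contrast
  pat <- orb_pattern_cached()
  mg <- orb_moment_grid()
  margin <- 21  # moments radius 15; rotated tests reach ceil(13*sqrt(2)) + 2

  n_levels <- cf$n_levels
  min_dim <- min(dim(img))
  max_feasible <- floor(log(min_dim / (2 * margin + 7)) / log(cf$scale_factor)) + 1
  if (max_feasible < n_levels) {
    warning("image too small for ", n_levels, " pyramid levels; using ",
            max_feasible)
    n_levels <- max(1, max_feasible)
  }

  kps <- list(); descs <- list()
  for (lev in seq_len(n_levels) - 1) {
    sc <- cf$scale_factor^lev
    nr <- round(nrow(img) / sc); nc <- round(ncol(img) / sc)
    limg <- if (lev == 0) img else resample_bilinear(img, nr, nc)
    kp <- fast_detect(limg, fast_cf)
    if (nrow(kp) == 0) next
    ok <- kp$x >= margin & kp$x <= nc - 1 - margin &
      kp$y >= margin & kp$y <= nr - 1 - margin
    kp <- kp[ok, , drop = FALSE]
    if (nrow(kp) == 0) next
    sm <- box_smooth(limg)
    n <- nrow(kp)
    theta <- numeric(n)
    D <- matrix(0L, n, cf$descriptor_bits)
    for (i in seq_len(n)) {
      r <- kp$y[i] + 1; c <- kp$x[i] + 1
      vals <- limg[cbind(r + mg$oy, c + mg$ox)]
      m10 <- sum(mg$ox * vals); m01 <- sum(mg$oy * vals)
      th <- atan2(m01, m10) %% (2 * pi)
      theta[i] <- th
      co <- cos(th); si <- sin(th)
      rax <- round(co * pat[, "xa"] - si * pat[, "ya"])
      ray <- round(si * pat[, "xa"] + co * pat[, "ya"])
      rbx <- round(co * pat[, "xb"] - si * pat[, "yb"])
      rby <- round(si * pat[, "xb"] + co * pat[, "yb"])
      va <- sm[cbind(r + ray, c + rax)]
      vb <- sm[cbind(r + rby, c + rbx)]
      D[i, ] <- as.integer(va < vb)
    }
    kps[[length(kps) + 1]] <- tibble::tibble(
      x = kp$x * sc, y = kp$y * sc, scale = sc,
      orientation = theta, response = kp$response, level = lev)
    descs[[length(descs) + 1]] <- D
  }
  if (length(kps) == 0) {
    D <- matrix(integer(), 0, cf$descriptor_bits)
    attr(D, "kind") <- "binary256"
    return(list(keypoints = tibble::tibble(
      x = numeric(), y = numeric(), scale = numeric(),
      orientation = numeric(), response = numeric(), level = integer()),
      descriptors = D))
  }
  D <- do.call(rbind, descs)
  attr(D, "kind") <- "binary256"
  list(keypoints = dplyr::bind_rows(kps), descriptors = D)
}
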