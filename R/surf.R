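# Hessian-determinant blob detector with box-filter second derivatives
# (SURF-style), Haar-wavelet orientation and 64-d descriptors.

# Box filter side length for 1-based octave o, scale index k:
# L = 6 * 2^(o-1) * k + 3, giving the ladder 9,15,...,39 / 15,27,...,75 / ...
surf_filter_size <- function(octave, k) {
  6L * 2L^(octave - 1L) * k + 3L
}

#' Combine second-derivative responses into the approximated Hessian
#' determinant
#'
#' `det = Lxx * Lyy - (0.9 * Lxy)^2`; the constant 0.9 compensates the box
#' filter approximation of the Gaussian second derivatives.
#'
#' @param Lxx,Lyy,Lxy Second-derivative responses (scalars or arrays).
#' @return The determinant approximation, elementwise.
#' @export
hessian_det_combine <- function(Lxx, Lyy, Lxy) {
  Lxx * Lyy - (0.9 * Lxy)^2
}

#' Approximated Hessian determinant response map
#'
#' Evaluates box-filter approximations of the second Gaussian derivatives
#' `Lxx`, `Lyy`, `Lxy` at every pixel for one filter size, normalized by the
#' filter area, and combines them with [hessian_det_combine()]. Pixels
#' closer than half the filter size to the border are zero.
#'
#' @param img Gray image in `[0, 1]` (internally scaled to 0-255).
#' @param size Filter side length: an odd multiple of 3 (9, 15, 21, ...).
#' @return A list of class `scale_space_response` with `Lxx`, `Lyy`, `Lxy`,
#'   `det_map`, `size` and the equivalent Gaussian `sigma = 1.2 * size / 9`.
#' @export
hessian_det <- function(img, size) {
  nr <- nrow(img); nc <- ncol(img)
  if (size %% 3 != 0 || size %% 2 == 0) stop("size must be an odd multiple of 3")
  if (size > min(nr, nc)) stop("filter larger than the image")
  l <- size %/% 3
  half <- (size - 1) %/% 2
  S <- integral_image(img * 255)
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  hb <- (l - 1) %/% 2  # half-height of the middle Dyy band

  bs <- function(r0, c0, r1, c1) {
    matrix(box_sum(S, as.vector(r0), as.vector(c0),
                   as.vector(r1), as.vector(c1)), nr, nc)
  }
  mid_yy <- bs(R - hb, C - (l - 1), R + hb, C + (l - 1))
  top_yy <- bs(R - hb - l, C - (l - 1), R - hb - 1, C + (l - 1))
  bot_yy <- bs(R + hb + 1, C - (l - 1), R + hb + l, C + (l - 1))
  Lyy <- (top_yy + bot_yy - 2 * mid_yy) / size^2
  mid_xx <- bs(R - (l - 1), C - hb, R + (l - 1), C + hb)
  lef_xx <- bs(R - (l - 1), C - hb - l, R + (l - 1), C - hb - 1)
  rig_xx <- bs(R - (l - 1), C + hb + 1, R + (l - 1), C + hb + l)
  Lxx <- (lef_xx + rig_xx - 2 * mid_xx) / size^2
  tl <- bs(R - l, C - l, R - 1, C - 1)
  tr <- bs(R - l, C + 1, R - 1, C + l)
  bl <- bs(R + 1, C - l, R + l, C - 1)
  br <- bs(R + 1, C + 1, R + l, C + l)
  Lxy <- (tl + br - tr - bl) / size^2

  valid <- R > half & R <= nr - half & C > half & C <= nc - half
  Lxx[!valid] <- 0; Lyy[!valid] <- 0; Lxy[!valid] <- 0
  structure(
    list(Lxx = Lxx, Lyy = Lyy, Lxy = Lxy,
         det_map = hessian_det_combine(Lxx, Lyy, Lxy),
         size = size, sigma = 1.2 * size / 9),
    class = "scale_space_response"
  )
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Max over the 8 (exclude_center) or 9 neighbours of every pixel.
neighbor_max <- function(m, exclude_center = TRUE) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (exclude_center && dr == 0 && dc == 0) next
    out <- pmax(out, shift_mat(m, dr, dc))
  }
  out
}

#' Detect blob keypoints by scale-space Hessian-determinant maxima
#'
#' Builds response maps per octave/scale, applies 3x3x3 non-maximum
#' suppression within each octave's scale stack, and emits keypoints with
#' response at or above the feature threshold.
#'
#' @param img Gray image in `[0, 1]`.
#' @param config A [detector_config()] (the `surf` entry is used).
#' @return A tibble with `x`, `y` (0-based pixels), `scale` (equivalent
#'   Gaussian sigma), `orientation` (filled later, `NA`), `response`.
#' @export
surf_detect <- function(img, config = detector_config()) {
  cf <- config$surf
  res <- list()
  for (o in seq_len(cf$n_octaves)) {
    sizes <- surf_filter_size(o, seq_len(cf$n_scales))
    if (sizes[3] > min(dim(img))) break
    maps <- lapply(sizes, function(L) {
      if (L > min(dim(img))) NULL else hessian_det(img, L)$det_map
    })
    for (k in 2:(cf$n_scales - 1)) {
      if (is.null(maps[[k + 1]])) break
      m <- maps[[k]]
      cand <- m >= cf$feature_threshold &
        m > neighbor_max(m, TRUE) &
        m > neighbor_max(maps[[k - 1]], FALSE) &
        m > neighbor_max(maps[[k + 1]], FALSE)
      idx <- which(cand, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        res[[length(res) + 1]] <- tibble::tibble(
          x = idx[, 2] - 1, y = idx[, 1] - 1,
          scale = 1.2 * sizes[k] / 9,
          response = m[idx], octave = o)
      }
    }
  }
  if (length(res) == 0)
    return(tibble::tibble(x = numeric(), y = numeric(), scale = numeric(),
                          orientation = numeric(), response = numeric()))
  kp <- dplyr::arrange(dplyr::bind_rows(res), .data$y, .data$x, .data$scale)
  kp <- dplyr::distinct(kp, .data$x, .data$y, .data$scale, .keep_all = TRUE)
  tibble::tibble(x = kp$x, y = kp$y, scale = kp$scale,
                 orientation = NA_real_, response = kp$response)
}

# Haar wavelet responses at 1-based centres (r, c) with half-width hw
# (filter side 2*hw), from a summed-area table.
haar_responses <- function(S, r, c, hw) {
  dx <- box_sum(S, r - hw, c, r + hw - 1, c + hw - 1) -
    box_sum(S, r - hw, c - hw, r + hw - 1, c - 1)
  dy <- box_sum(S, r, c - hw, r + hw - 1, c + hw - 1) -
    box_sum(S, r - hw, c - hw, r - 1, c + hw - 1)
  list(dx = dx, dy = dy)
}

surf_orient_impl <- function(S, nr, nc, x, y, scale) {
  s <- max(1, round(scale))
  hw <- max(1, round(2 * scale))
  g <- expand.grid(i = -6:6, j = -6:6)
  g <- g[g$i^2 + g$j^2 <= 36, ]
  px <- round(x + g$i * s); py <- round(y + g$j * s)
  r <- py + 1; c <- px + 1
  if (any(r - hw < 1 | r + hw - 1 > nr | c - hw < 1 | c + hw - 1 > nc))
    return(NA_real_)  # border-skip: orientation window exceeds the image
  h <- haar_responses(S, r, c, hw)
  w <- exp(-(g$i^2 + g$j^2) / (2 * 2.5^2))
  dx <- h$dx * w; dy <- h$dy * w
  ang <- atan2(dy, dx) %% (2 * pi)
  best <- c(0, 0); best_mag <- -1
  for (a0 in seq(0, 2 * pi - 1e-9, by = pi / 36)) {
    d <- (ang - a0) %% (2 * pi)
    sel <- d < pi / 3
    sx <- sum(dx[sel]); sy <- sum(dy[sel])
    mag <- sx^2 + sy^2
    if (mag > best_mag) { best_mag <- mag; best <- c(sx, sy) }
  }
  if (best_mag < 1e-12) return(0)
  atan2(best[2], best[1]) %% (2 * pi)
}

#' Dominant orientation of a keypoint
#'
#' Gaussian-weighted Haar wavelet responses are collected on a circular grid
#' of radius 6 scales around the keypoint; a pi/3 sliding sector sums the
#' response vectors and the direction of the longest summed vector is
#' returned. A flat neighbourhood yields orientation 0.
#'
#' @param img Gray image in `[0, 1]`.
#' @param x,y 0-based keypoint position.
#' @param scale Keypoint scale (Gaussian sigma, pixels).
#' @return Orientation in radians in `[0, 2*pi)`, or `NA` if the window
#'   leaves the image (border skip).
#' @export
surf_orient <- function(img, x, y, scale) {
  surf_orient_impl(integral_image(img), nrow(img), ncol(img), x, y, scale)
}

surf_describe_impl <- function(S, nr, nc, x, y, scale, orientation) {
  s <- scale
  hw <- max(1, round(s))
  g <- expand.grid(u = seq(-9.5, 9.5, by = 1), v = seq(-9.5, 9.5, by = 1))
  co <- cos(orientation); si <- sin(orientation)
  px <- x + (co * g$u - si * g$v) * s
  py <- y + (si * g$u + co * g$v) * s
  r <- round(py) + 1; c <- round(px) + 1
  if (any(r - hw < 1 | r + hw - 1 > nr | c - hw < 1 | c + hw - 1 > nc))
    return(NULL)  # descriptor window out of bounds: keypoint dropped
  h <- haar_responses(S, r, c, hw)
  # rotate responses into the keypoint frame
  dxr <- co * h$dx + si * h$dy
  dyr <- -si * h$dx + co * h$dy
  w <- exp(-(g$u^2 + g$v^2) / (2 * 3.3^2))
  dxr <- dxr * w; dyr <- dyr * w
  iu <- pmin(floor((g$u + 10) / 5), 3)
  iv <- pmin(floor((g$v + 10) / 5), 3)
  sub <- iv * 4 + iu + 1  # 16 subregions
  f <- function(v) as.numeric(rowsum(v, sub, reorder = TRUE))
  d <- as.numeric(rbind(f(dxr), f(abs(dxr)), f(dyr), f(abs(dyr))))
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) return(rep(0, 64))
  d / nrm
}

#' 64-dimensional keypoint descriptor
#'
#' An oriented, scale-proportional 20x20-sample window is split into a 4x4
#' grid of subregions; each subregion contributes the Gaussian-weighted sums
#' `(sum dx, sum |dx|, sum dy, sum |dy|)` of rotated Haar wavelet responses,
#' giving 64 values normalized to unit length.
#'
#' @inheritParams surf_orient
#' @param orientation Keypoint orientation in radians.
#' @return A unit-norm numeric vector of length 64, or `NULL` when the
#'   window leaves the image (keypoint dropped).
#' @export
surf_describe <- function(img, x, y, scale, orientation = 0) {
  surf_describe_impl(integral_image(img), nrow(img), ncol(img),
                     x, y, scale, orientation)
}

#' Assign orientations and descriptors to a set of keypoints
#'
#' Batch wrapper around [surf_orient()] and [surf_describe()]: keypoints
#' whose orientation or descriptor window leaves the image are dropped.
#'
#' @param img Gray image in `[0, 1]`.
#' @param keypoints Tibble with `x`, `y`, `scale` columns.
#' @return A list with `keypoints` (the retained rows, orientations filled)
#'   and `descriptors` (n x 64 matrix of class attribute `kind = "real64"`).
#' @export
describe_keypoints <- function(img, keypoints) {
  S <- integral_image(img)
  nr <- nrow(img); nc <- ncol(img)
  n <- nrow(keypoints)
  desc <- vector("list", n)
  ori <- rep(NA_real_, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    o <- surf_orient_impl(S, nr, nc, keypoints$x[i], keypoints$y[i],
                          keypoints$scale[i])
    if (is.na(o)) next
    d <- surf_describe_impl(S, nr, nc, keypoints$x[i], keypoints$y[i],
                            keypoints$scale[i], o)
    if (is.null(d)) next
    ori[i] <- o
    desc[[i]] <- d
    keep[i] <- TRUE
  }
  kp <- keypoints[keep, , drop = FALSE]
  kp$orientation <- ori[keep]
  D <- if (any(keep)) do.call(rbind, desc[keep]) else
    matrix(numeric(), 0, 64)
  attr(D, "kind") <- "real64"
  list(keypoints = kp, descriptors = D)
}
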