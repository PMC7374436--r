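#' Back-project a pixel to a world-frame viewing ray
#'
#' @param camera A [camera_model()].
#' @param x Pixel coordinates (0-based), length-2 vector or n x 2 matrix.
#' @return A list with `origin` (camera centre) and `direction` (unit
#'   3-vector, or n x 3 matrix of unit rows).
#' @export
backproject_ray <- function(camera, x) {
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1, 2) else as.matrix(x)
  d_cam <- cbind((xm[, 1] - camera$principal_point[1]) / camera$focal[1],
                 (xm[, 2] - camera$principal_point[2]) / camera$focal[2],
                 1)
  d <- d_cam %*% camera$rotation  # = t(R) %*% d_cam, per row
  d <- d / sqrt(rowSums(d^2))
  list(origin = camera$center, direction = if (single) as.numeric(d) else d)
}

#' Midpoint triangulation of two viewing rays
#'
#' Finds the closest points of the two (skew) lines
#' `o1 + s d1` and `o2 + t d2`. The reconstructed point is the midpoint of
#' the connecting segment and the triangulation error is the segment length:
#' the minimum distance between the rays.
#'
#' @param o1,d1 Origin and direction of the first ray (3-vectors, mm).
#' @param o2,d2 Origin and direction of the second ray.
#' @return A list with `point3d`, `error_mm` and `ray_points` (2 x 3 matrix of
#'   the two closest points).
#' @examples
#' triangulate_rays(c(0, 0, 0), c(0, 0, 1), c(100, 1, 0), c(-1, 0, 0))
#' @export
triangulate_rays <- function(o1, d1, o2, d2) {
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  if (sqrt(sum(cr^2)) < 1e-8)
    stop("parallel rays: no unique midpoint")
  b <- o2 - o1
  a12 <- sum(d1 * d2)
  denom <- 1 - a12^2  # |d1|=|d2|=1
  s <- (sum(b * d1) - a12 * sum(b * d2)) / denom
  t <- (a12 * sum(b * d1) - sum(b * d2)) / denom
  p1 <- o1 + s * d1
  p2 <- o2 + t * d2
  list(point3d = (p1 + p2) / 2,
       error_mm = sqrt(sum((p1 - p2)^2)),
       ray_points = rbind(p1, p2))
}

#' Midpoint triangulation of a pixel correspondence
#'
#' Back-projects the matched pixels `x1`, `x2` through the calibrated rig and
#' intersects the two rays by the midpoint method. The triangulation error is
#' the length in mm of the shortest segment connecting the rays.
#'
#' @param rig A [stereo_rig()].
#' @param x1,x2 Matched 0-based pixels in view 1 and view 2 (length-2).
#' @return An object of class `triangulation`: a list with `point3d` (mm),
#'   `error_mm`, `ray_points` and `image_points`.
#' @export
triangulate_midpoint <- function(rig, x1, x2) {
  r1 <- backproject_ray(rig$cam1, x1)
  r2 <- backproject_ray(rig$cam2, x2)
  out <- triangulate_rays(r1$origin, r1$direction, r2$origin, r2$direction)
  out$image_points <- rbind(x1 = as.numeric(x1), x2 = as.numeric(x2))
  class(out) <- "triangulation"
  out
}

#' @export
print.triangulation <- function(x, ...) {
  cat("<triangulation> X = (", paste(signif(x$point3d, 6), collapse = ", "),
      ") mm, error ", signif(x$error_mm, 4), " mm\n", sep = "")
  invisible(x)
}

#' Vectorized midpoint triangulation
#'
#' Triangulates many pixel correspondences at once.
#'
#' @param rig A [stereo_rig()].
#' @param X1,X2 n x 2 matrices of matched 0-based pixels.
#' @return A tibble with columns `x`, `y`, `z` (mm) and `error_mm`.
#' @export
triangulate_points <- function(rig, X1, X2) {
  X1 <- matrix(as.numeric(as.matrix(X1)), ncol = 2)
  X2 <- matrix(as.numeric(as.matrix(X2)), ncol = 2)
  stopifnot(nrow(X1) == nrow(X2))
  if (nrow(X1) == 0)
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          error_mm = numeric()))
  D1 <- backproject_ray(rig$cam1, X1)$direction
  D2 <- backproject_ray(rig$cam2, X2)$direction
  b <- rig$cam2$center - rig$cam1$center
  a12 <- rowSums(D1 * D2)
  denom <- 1 - a12^2
  bd1 <- D1 %*% b
  bd2 <- D2 %*% b
  s <- (bd1 - a12 * bd2) / denom
  t <- (a12 * bd1 - bd2) / denom
  P1 <- sweep(D1 * as.numeric(s), 2, rig$cam1$center, "+")
  P2 <- sweep(D2 * as.numeric(t), 2, rig$cam2$center, "+")
  mid <- (P1 + P2) / 2
  tibble::tibble(x = mid[, 1], y = mid[, 2], z = mid[, 3],
                 error_mm = sqrt(rowSums((P1 - P2)^2)))
}
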