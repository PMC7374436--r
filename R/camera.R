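#' Metric pinhole camera model
#'
#' Constructs a calibrated pinhole camera. The camera maps a world point
#' `X` (mm) to pixel coordinates via `x = f * (R (X - C))_xy / (R (X - C))_z + pp`.
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' x increasing rightwards (columns) and y downwards (rows).
#'
#' @param focal Focal lengths `c(fx, fy)` in pixels (both > 0).
#' @param principal_point Principal point `c(cx, cy)` in pixels.
#' @param rotation 3x3 orthonormal world-to-camera rotation matrix.
#' @param center Camera centre, 3-vector in world millimetres.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(c(1000, 1000), c(320, 240), diag(3), c(0, 0, 0))
#' project(cam, c(0, 0, 1000))
#' @export
camera_model <- function(focal, principal_point, rotation, center) {
  focal <- as.numeric(focal)
  principal_point <- as.numeric(principal_point)
  rotation <- matrix(as.numeric(rotation), 3, 3)
  center <- as.numeric(center)
  stopifnot(length(focal) == 2, length(principal_point) == 2,
            length(center) == 3)
  if (any(focal <= 0)) stop("focal components must be positive")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal (R'R = I)")
  structure(
    list(focal = focal, principal_point = principal_point,
         rotation = rotation, center = center),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model> f = (", paste(signif(x$focal, 6), collapse = ", "),
      ") px, pp = (", paste(signif(x$principal_point, 6), collapse = ", "),
      ") px, C = (", paste(signif(x$center, 6), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

# 3x3 intrinsic matrix
camera_K <- function(cam) {
  matrix(c(cam$focal[1], 0, 0,
           0, cam$focal[2], 0,
           cam$principal_point[1], cam$principal_point[2], 1), 3, 3)
}

#' Project world points into a camera
#'
#' Perspective projection of 3D world points (mm) to 0-based pixel
#' coordinates. Points must have positive depth in the camera frame.
#'
#' @param camera A [camera_model()].
#' @param X A 3-vector or an n x 3 matrix of world points in mm.
#' @return A length-2 numeric vector, or an n x 2 matrix for matrix input.
#' @export
project <- function(camera, X) {
  single <- is.null(dim(X))
  Xm <- if (single) matrix(X, 1, 3) else as.matrix(X)
  stopifnot(ncol(Xm) == 3)
  Xc <- sweep(Xm, 2, camera$center) %*% t(camera$rotation)
  if (any(Xc[, 3] <= 0))
    stop("point behind camera: non-positive depth in the camera frame")
  px <- cbind(camera$focal[1] * Xc[, 1] / Xc[, 3] + camera$principal_point[1],
              camera$focal[2] * Xc[, 2] / Xc[, 3] + camera$principal_point[2])
  if (single) as.numeric(px) else px
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Fix the projective scale of F: unit Frobenius norm, largest element positive.
normalize_fundamental <- function(F) {
  F <- F / sqrt(sum(F^2))
  if (F[which.max(abs(F))] < 0) F <- -F
  F
}

#' Fundamental matrix of a calibrated stereo rig
#'
#' Computes the rank-2 fundamental matrix `F` such that corresponding pixels
#' satisfy `t(x2) %*% F %*% x1 = 0` (homogeneous 0-based pixels). The scale is
#' fixed to unit Frobenius norm with positive largest element so that the
#' matrix is a deterministic function of the rig.
#'
#' @param rig A [stereo_rig()], or a list with elements `cam1`, `cam2`.
#' @return A 3x3 matrix.
#' @export
fundamental_from_cameras <- function(rig) {
  cam1 <- rig$cam1; cam2 <- rig$cam2
  b <- cam1$center - cam2$center
  if (sqrt(sum(b^2)) < 1e-9)
    stop("degenerate rig: camera centers coincide")
  K1 <- camera_K(cam1); K2 <- camera_K(cam2)
  R_rel <- cam2$rotation %*% t(cam1$rotation)
  t_rel <- cam2$rotation %*% b
  F <- t(solve(K2)) %*% skew3(t_rel) %*% R_rel %*% solve(K1)
  normalize_fundamental(F)
}

#' Calibrated two-camera rig
#'
#' Bundles two [camera_model()]s with their fundamental matrix and epipoles.
#' The epipole `e` is the image of camera 2's centre in view 1 (right null
#' vector of `F`), and `e_prime` the image of camera 1's centre in view 2
#' (left null vector).
#'
#' @param cam1,cam2 [camera_model()] objects with distinct centres.
#' @return An object of class `stereo_rig` with elements `cam1`, `cam2`, `F`,
#'   `e`, `e_prime`.
#' @export
stereo_rig <- function(cam1, cam2) {
  stopifnot(inherits(cam1, "camera_model"), inherits(cam2, "camera_model"))
  F <- fundamental_from_cameras(list(cam1 = cam1, cam2 = cam2))
  ep <- epipoles_from_F(F)
  structure(
    list(cam1 = cam1, cam2 = cam2, F = F, e = ep$e, e_prime = ep$e_prime),
    class = "stereo_rig"
  )
}

#' @export
print.stereo_rig <- function(x, ...) {
  base <- sqrt(sum((x$cam1$center - x$cam2$center)^2))
  cat("<stereo_rig> baseline", signif(base, 6), "mm\n")
  invisible(x)
}

# Unit-norm homogeneous epipoles from a fundamental matrix.
epipoles_from_F <- function(F) {
  s <- svd(F)
  e <- s$v[, 3]       # F e = 0
  e_prime <- s$u[, 3] # t(F) e' = 0
  list(e = e / sqrt(sum(e^2)), e_prime = e_prime / sqrt(sum(e_prime^2)))
}

#' Estimate a fundamental matrix from point correspondences
#'
#' Normalized 8-point estimate with rank-2 enforcement. Both point sets are
#' translated to zero centroid and scaled to RMS distance `sqrt(2)` before the
#' linear solve; the smallest singular value of the estimate is zeroed to
#' enforce rank 2. The returned matrix satisfies `t(x2) %*% F %*% x1 ~ 0` and
#' is scale-normalized as in [fundamental_from_cameras()].
#'
#' @param pts1,pts2 n x 2 matrices of corresponding 0-based pixels (n >= 8).
#' @return A 3x3 rank-2 matrix.
#' @export
estimate_fundamental <- function(pts1, pts2) {
  pts1 <- as.matrix(pts1); pts2 <- as.matrix(pts2)
  n <- nrow(pts1)
  if (n < 8 || nrow(pts2) != n)
    stop("at least 8 correspondences are required")

  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    ms <- mean(d)
    if (ms < 1e-12) stop("degenerate configuration: coincident points")
    s <- sqrt(2) / ms
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
    list(p = sweep(sweep(p, 2, ctr), 2, c(s, s), "*"), T = T)
  }
  n1 <- norm_pts(pts1); n2 <- norm_pts(pts2)
  x1 <- n1$p[, 1]; y1 <- n1$p[, 2]; x2 <- n2$p[, 1]; y2 <- n2$p[, 2]
  A <- cbind(x2 * x1, x2 * y1, x2, y2 * x1, y2 * y1, y2, x1, y1, 1)
  s <- svd(A, nu = 0, nv = 9)
  d <- s$d
  if (length(d) < 8 || d[8] < 1e-9 * d[1])
    stop("degenerate point configuration for fundamental-matrix estimation")
  Fn <- matrix(s$v[, 9], 3, 3, byrow = TRUE)
  sf <- svd(Fn)
  Fn <- sf$u %*% diag(c(sf$d[1:2], 0)) %*% t(sf$v)
  F <- t(n2$T) %*% Fn %*% n1$T
  normalize_fundamental(F)
}
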