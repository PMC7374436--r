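#' Projective epipolar rectification (epipole-to-infinity method)
#'
#' Computes a pair of homographies `H` (view 1) and `H_prime` (view 2) that
#' map both epipoles to the point at infinity on the x-axis so that
#' corresponding points share the same row. `H_prime` is built from a
#' translation of the image centre to the origin, a rotation placing the
#' epipole on the positive x-axis and the map `G = diag(1,1,1); G[3,1] = -1/f`
#' sending it to infinity. The matching `H` is `A %*% H_prime %*% M`, where
#' `M` is a homography compatible with `F` (`F = [e']_x M`) and the affine
#' row `A` is chosen by least squares to minimize the sum of squared
#' distances between the transformed correspondences (the horizontal
#' disparity criterion).
#'
#' After construction both homographies receive a common vertical offset and
#' per-view horizontal offsets so the warped images have non-negative pixel
#' coordinates; this translation does not change y-disparities.
#'
#' @param F 3x3 rank-2 fundamental matrix (`t(x2) F x1 = 0`).
#' @param pts1,pts2 n x 2 matrices of corresponding 0-based pixels used for
#'   the disparity-minimizing least squares (n >= 2).
#' @param size1,size2 Image sizes `c(width, height)` in pixels.
#' @return An object of class `rectifying_pair`: list with `H`, `H_prime`,
#'   `size1`, `size2` (rectified sizes, width x height), `residual_disparity`
#'   (the minimized sum-of-squared-distances criterion over the input
#'   correspondences) and `mean_y_disparity` (mean absolute post-warp
#'   y-disparity, pixels).
#' @export
compute_rectification <- function(F, pts1, pts2, size1, size2 = size1) {
  pts1 <- as.matrix(pts1); pts2 <- as.matrix(pts2)
  stopifnot(nrow(pts1) == nrow(pts2), nrow(pts1) >= 2)
  sv <- svd(F)
  if (sv$d[3] > 1e-6 * sv$d[1])
    stop("F must have rank 2 (rank-3 matrix supplied)")
  ep <- epipoles_from_F(F)

  check_inside <- function(e, size, which_view) {
    # epipole strictly inside the image interior makes the warp unbounded
    if (abs(e[3]) < 1e-12) return(invisible(NULL))
    p <- e[1:2] / e[3]
    if (p[1] > -0.5 && p[1] < size[1] - 0.5 &&
        p[2] > -0.5 && p[2] < size[2] - 0.5)
      stop("epipole lies inside image ", which_view,
           ": projective rectification is unbounded")
    invisible(NULL)
  }
  check_inside(ep$e, size1, 1)
  check_inside(ep$e_prime, size2, 2)

  # H_prime: centre, rotate epipole onto +x, send to infinity
  ctr2 <- c((size2[1] - 1) / 2, (size2[2] - 1) / 2)
  Tc <- matrix(c(1, 0, 0, 0, 1, 0, -ctr2[1], -ctr2[2], 1), 3, 3)
  et <- as.numeric(Tc %*% ep$e_prime)
  hyp <- sqrt(et[1]^2 + et[2]^2)
  at_inf <- abs(et[3]) <= 1e-12 * hyp
  if (at_inf) {
    ex <- et[1]; ey <- et[2]
  } else {
    ex <- et[1] / et[3]; ey <- et[2] / et[3]
  }
  th <- -atan2(ey, ex)
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  G <- diag(3)
  if (!at_inf) {
    f <- sqrt(ex^2 + ey^2)
    G[3, 1] <- -1 / f
  }
  H2 <- G %*% Rz %*% Tc

  # matching homography for view 1: F = [e']_x M
  M <- skew3(ep$e_prime) %*% F + ep$e_prime %*% t(c(1, 1, 1))
  H0 <- H2 %*% M

  p1 <- apply_homography(H0, pts1)
  p2 <- apply_homography(H2, pts2)
  # affine x-row minimizing the horizontal disparity criterion
  Amat <- cbind(p1[, 1], p1[, 2], 1)
  coefs <- qr.coef(qr(Amat), p2[, 1])
  A <- matrix(c(coefs[1], 0, 0, coefs[2], 1, 0, coefs[3], 0, 1), 3, 3)
  H1 <- A %*% H0

  # common vertical offset, per-view horizontal offsets
  corners <- function(size) {
    cbind(c(0, size[1] - 1, 0, size[1] - 1),
          c(0, 0, size[2] - 1, size[2] - 1))
  }
  cw1 <- apply_homography(H1, corners(size1))
  cw2 <- apply_homography(H2, corners(size2))
  ty <- -min(cw1[, 2], cw2[, 2])
  tx1 <- -min(cw1[, 1]); tx2 <- -min(cw2[, 1])
  H1 <- matrix(c(1, 0, 0, 0, 1, 0, tx1, ty, 1), 3, 3) %*% H1
  H2 <- matrix(c(1, 0, 0, 0, 1, 0, tx2, ty, 1), 3, 3) %*% H2
  out_h <- ceiling(max(cw1[, 2], cw2[, 2]) + ty) + 1
  out_w1 <- ceiling(max(cw1[, 1]) + tx1) + 1
  out_w2 <- ceiling(max(cw2[, 1]) + tx2) + 1
  lim <- 4 * max(size1, size2)
  if (max(out_h, out_w1, out_w2) > lim)
    stop("rectifying warp too distorted (epipole too close to the image)")

  q1 <- apply_homography(H1, pts1)
  q2 <- apply_homography(H2, pts2)
  structure(
    list(H = H1, H_prime = H2,
         size1 = c(out_w1, out_h), size2 = c(out_w2, out_h),
         residual_disparity = sum((q1 - q2)^2),
         mean_y_disparity = mean(abs(q1[, 2] - q2[, 2]))),
    class = "rectifying_pair"
  )
}

#' @export
print.rectifying_pair <- function(x, ...) {
  cat("<rectifying_pair> rectified sizes ",
      paste(x$size1, collapse = "x"), " / ",
      paste(x$size2, collapse = "x"),
      ", mean |y-disparity| ", signif(x$mean_y_disparity, 4), " px\n",
      sep = "")
  invisible(x)
}

#' Apply a homography to 2D points
#'
#' @param H 3x3 homography.
#' @param pts Length-2 vector or n x 2 matrix of 0-based pixels.
#' @return Transformed points, same shape as the input.
#' @export
apply_homography <- function(H, pts) {
  single <- is.null(dim(pts))
  p <- if (single) matrix(pts, 1, 2) else as.matrix(pts)
  q <- cbind(p, 1) %*% t(H)
  out <- q[, 1:2, drop = FALSE] / q[, 3]
  if (single) as.numeric(out) else out
}

# Bilinear sampling of img (matrix, [row, col]) at 0-based pixel positions.
# Out-of-range samples return `fill`.
bilinear_sample <- function(img, sx, sy, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- rep(fill, length(sx))
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1 &
    is.finite(sx) & is.finite(sy)
  # clamp the +1 neighbour at the last row/column
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  if (any(ok)) {
    g <- function(yy, xx) img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v <- (1 - fx[ok]) * (1 - fy[ok]) * g(y0, x0) +
      fx[ok] * (1 - fy[ok]) * g(y0, x1) +
      (1 - fx[ok]) * fy[ok] * g(y1, x0) +
      fx[ok] * fy[ok] * g(y1, x1)
    val[ok] <- v
  }
  val
}

#' Warp an image with a homography
#'
#' Inverse-maps every output pixel through `solve(H)` and samples the source
#' image bilinearly; pixels mapping outside the source are filled with
#' `fill`.
#'
#' @param img Gray-scale image matrix (values in `[0, 1]`).
#' @param H 3x3 homography taking source pixels to output pixels (0-based).
#' @param out_size Output size `c(width, height)`.
#' @param fill Fill value for unmapped pixels.
#' @return A `height x width` matrix.
#' @export
warp_image <- function(img, H, out_size, fill = 0) {
  w <- out_size[1]; h <- out_size[2]
  Hi <- solve(H)
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  q <- cbind(gx, gy, 1) %*% t(Hi)
  sx <- q[, 1] / q[, 3]
  sy <- q[, 2] / q[, 3]
  matrix(bilinear_sample(img, sx, sy, fill = fill), nrow = h, ncol = w)
}

#' Rectify a calibrated rig
#'
#' Synthesizes noise-free correspondences by projecting a 3D point grid
#' centred on the convergence point of the two optical axes, then calls
#' [compute_rectification()] on the rig's fundamental matrix.
#'
#' @param rig A [stereo_rig()].
#' @param size1,size2 Image sizes `c(width, height)`.
#' @param working_distance Fallback viewing distance in mm when the optical
#'   axes are parallel.
#' @return A `rectifying_pair`.
#' @export
rectify_stereo <- function(rig, size1, size2 = size1,
                           working_distance = 1000) {
  d1 <- rig$cam1$rotation[3, ]
  d2 <- rig$cam2$rotation[3, ]
  look <- tryCatch(
    triangulate_rays(rig$cam1$center, d1, rig$cam2$center, d2)$point3d,
    error = function(e) rig$cam1$center + working_distance * d1
  )
  D <- sqrt(sum((look - rig$cam1$center)^2))
  ax1 <- rig$cam1$rotation[1, ]  # world direction of camera-1 x axis
  ax2 <- rig$cam1$rotation[2, ]
  ext <- 0.25 * D
  g <- as.matrix(expand.grid(u = seq(-1, 1, length.out = 5),
                             v = seq(-1, 1, length.out = 5),
                             w = c(-0.15, 0, 0.15)))
  pts3 <- sweep(g[, "u", drop = FALSE] %*% t(ax1) * ext +
                  g[, "v", drop = FALSE] %*% t(ax2) * ext +
                  g[, "w", drop = FALSE] %*% t(d1) * D,
                2, look, "+")
  keep_visible <- function(cam, size, P) {
    Xc <- sweep(P, 2, cam$center) %*% t(cam$rotation)
    ok <- Xc[, 3] > 0
    px <- matrix(NA_real_, nrow(P), 2)
    px[ok, ] <- cbind(
      cam$focal[1] * Xc[ok, 1] / Xc[ok, 3] + cam$principal_point[1],
      cam$focal[2] * Xc[ok, 2] / Xc[ok, 3] + cam$principal_point[2])
    ok & px[, 1] >= 0 & px[, 1] <= size[1] - 1 &
      px[, 2] >= 0 & px[, 2] <= size[2] - 1
  }
  ok <- keep_visible(rig$cam1, size1, pts3) & keep_visible(rig$cam2, size2, pts3)
  if (sum(ok) < 8)
    stop("could not place a correspondence grid visible in both views")
  p1 <- project(rig$cam1, pts3[ok, , drop = FALSE])
  p2 <- project(rig$cam2, pts3[ok, , drop = FALSE])
  compute_rectification(rig$F, p1, p2, size1, size2)
}
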