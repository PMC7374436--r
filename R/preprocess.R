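#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-based histogram equalization toward a uniform target distribution,
#' with each tile histogram clipped at `clip_limit` times the tile pixel
#' count (excess redistributed uniformly over all bins) and per-pixel
#' bilinear blending between the four surrounding tile mappings. Input and
#' output are gray images in `[0, 1]`; histograms use 256 bins (8-bit
#' resolution).
#'
#' @param img Gray-scale image matrix, values in `[0, 1]`.
#' @param clip_limit Contrast limit as a fraction of tile pixels, in
#'   `(0, 1]`. Default 0.03.
#' @param tile_grid `c(rows, cols)` of the tile grid. Default `c(8, 8)`.
#' @param return_tiles If `TRUE`, attach the per-tile clipped
#'   (pre-redistribution) histograms as attribute `"tile_histograms"` — a
#'   `(rows*cols) x 256` matrix in tile raster order — for auditing the
#'   clip limit.
#' @return The enhanced image, same shape and range as the input.
#' @export
clahe <- function(img, clip_limit = 0.03, tile_grid = c(8, 8),
                  return_tiles = FALSE) {
  if (length(img) == 0) stop("empty image")
  if (clip_limit <= 0 || clip_limit > 1)
    stop("clip_limit must lie in (0, 1]")
  tr <- tile_grid[1]; tc <- tile_grid[2]
  nr <- nrow(img); nc <- ncol(img)
  if (tr > nr || tc > nc)
    stop("tile grid finer than the image (tiles smaller than one pixel)")
  th <- ceiling(nr / tr); tw <- ceiling(nc / tc)
  # pad by edge replication to an exact tile multiple
  pr <- tr * th; pc <- tc * tw
  pad <- img[c(seq_len(nr), rep(nr, pr - nr)), c(seq_len(nc), rep(nc, pc - nc)),
             drop = FALSE]
  q <- pmin(pmax(round(pad * 255), 0), 255)

  npix <- th * tw
  clip_n <- ceiling(clip_limit * npix)
  nt <- tr * tc
  lut <- matrix(0, nt, 256)
  clipped_hists <- if (return_tiles) matrix(0L, nt, 256) else NULL
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- q[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw)]
      h <- tabulate(tile + 1, nbins = 256)
      hc <- pmin(h, clip_n)
      excess <- npix - sum(hc)
      id <- (i - 1) * tc + j
      if (return_tiles) clipped_hists[id, ] <- as.integer(hc)
      h2 <- hc + excess / 256
      lut[id, ] <- cumsum(h2) / npix
    }
  }

  # bilinear blending between the four surrounding tile mappings
  fi <- ((seq_len(pr) - 0.5) / th) - 0.5   # fractional tile-row position
  fj <- ((seq_len(pc) - 0.5) / tw) - 0.5
  i0 <- pmin(pmax(floor(fi), 0), tr - 1); i1 <- pmin(i0 + 1, tr - 1)
  j0 <- pmin(pmax(floor(fj), 0), tc - 1); j1 <- pmin(j0 + 1, tc - 1)
  wi <- pmin(pmax(fi - floor(fi), 0), 1)
  wi[fi < 0] <- 0; wi[fi > tr - 1] <- 1
  wj <- pmin(pmax(fj - floor(fj), 0), 1)
  wj[fj < 0] <- 0; wj[fj > tc - 1] <- 1

  bin1 <- q + 1
  Wi <- matrix(wi, pr, pc); Wj <- matrix(wj, pr, pc, byrow = TRUE)
  tid <- function(ti, tj) {
    matrix(ti, pr, pc) * tc + matrix(tj, pr, pc, byrow = TRUE) + 1
  }
  g <- function(ids) matrix(lut[cbind(as.vector(ids), as.vector(bin1))], pr, pc)
  out <- (1 - Wi) * (1 - Wj) * g(tid(i0, j0)) +
    (1 - Wi) * Wj * g(tid(i0, j1)) +
    Wi * (1 - Wj) * g(tid(i1, j0)) +
    Wi * Wj * g(tid(i1, j1))
  out <- out[seq_len(nr), seq_len(nc), drop = FALSE]
  out <- pmin(pmax(out, 0), 1)
  if (return_tiles) attr(out, "tile_histograms") <- clipped_hists
  out
}

#' Otsu's threshold
#'
#' Returns the 8-bit intensity level maximizing the between-class variance
#' of the image histogram, splitting pixels into a background class
#' (`value < level`) and a foreground class (`value >= level`). Ties are
#' broken toward the lowest level.
#'
#' @param img Gray-scale image matrix in `[0, 1]`.
#' @return Integer level in `1..255` on the 8-bit scale; foreground pixels
#'   are those with `round(img * 255) >= level`.
#' @export
otsu_threshold <- function(img) {
  q <- pmin(pmax(round(img * 255), 0), 255)
  h <- as.numeric(tabulate(q + 1, nbins = 256))
  if (sum(h > 0) < 2)
    stop("degenerate histogram: image has fewer than 2 distinct intensities")
  n <- sum(h)
  cs <- cumsum(h)
  cm <- cumsum(h * (0:255))
  mt <- cm[256]
  w0 <- cs[1:255]     # pixels with value < L, for L = 1..255
  m0 <- cm[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- w0 * w1 * (m0 / w0 - (mt - m0) / w1)^2
  bcv[!valid] <- -Inf
  as.integer(which.max(bcv))
}

#' Segment the spine region
#'
#' Otsu-thresholds the (enhanced) image, grows the foreground region from a
#' seed by 8-connected flood fill, and multiplies the image by the resulting
#' binary mask. The region of interest is the mask's bounding box, replacing
#' a manual crop in an unattended pipeline.
#'
#' @param img Gray-scale image in `[0, 1]`, typically a [clahe()] output.
#' @param seed Optional `c(x, y)` 0-based seed pixel; defaults to a pixel of
#'   the largest foreground connected component nearest its centroid.
#' @return An object of class `preprocess_result`: list with `enhanced` (the
#'   masked image), `mask` (0/1 matrix), `roi` (`c(x, y, width, height)`,
#'   0-based full-frame pixels), `offset` (`c(x, y)`), and `threshold` (the
#'   Otsu level).
#' @export
segment_spine <- function(img, seed = NULL) {
  lev <- otsu_threshold(img)
  q <- pmin(pmax(round(img * 255), 0), 255)
  fg <- q >= lev
  if (!any(fg)) stop("empty mask: no foreground above the Otsu threshold")
  lab <- label_components_cpp(fg)
  if (is.null(seed)) {
    big <- which.max(lab$sizes)
    idx <- which(lab$labels == big, arr.ind = TRUE)
    ctr <- colMeans(idx)
    near <- which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    seed_rc <- idx[near, ]
  } else {
    seed_rc <- c(seed[2] + 1, seed[1] + 1)
    if (seed_rc[1] < 1 || seed_rc[1] > nrow(img) ||
        seed_rc[2] < 1 || seed_rc[2] > ncol(img) ||
        !fg[seed_rc[1], seed_rc[2]])
      stop("seed pixel is not inside the thresholded foreground")
  }
  grown <- lab$labels == lab$labels[seed_rc[1], seed_rc[2]]
  mask <- matrix(0, nrow(img), ncol(img))
  mask[grown] <- 1
  idx <- which(grown, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  structure(
    list(enhanced = img * mask, mask = mask,
         roi = c(x = c0 - 1, y = r0 - 1, width = c1 - c0 + 1,
                 height = r1 - r0 + 1),
         offset = c(x = c0 - 1, y = r0 - 1),
         threshold = lev),
    class = "preprocess_result"
  )
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result> Otsu level ", x$threshold, ", roi [x=", x$roi[1],
      ", y=", x$roi[2], ", ", x$roi[3], "x", x$roi[4], "]\n", sep = "")
  invisible(x)
}

#' Crop the image to the segmented region of interest
#'
#' @param result A [segment_spine()] result.
#' @return The masked image cropped to the ROI bounding box.
#' @export
crop_to_roi <- function(result) {
  r <- result$roi
  result$enhanced[(r[2] + 1):(r[2] + r[4]), (r[1] + 1):(r[1] + r[3]),
                  drop = FALSE]
}

#' Back-project ROI-local keypoints to full-frame coordinates
#'
#' Shifts keypoint coordinates detected inside the cropped ROI back to the
#' full image frame; scale, orientation and response are unchanged.
#'
#' @param result A [segment_spine()] result.
#' @param keypoints Tibble/data frame with 0-based `x`, `y` columns local to
#'   the ROI.
#' @return The keypoints with `x`, `y` shifted by the ROI offset.
#' @export
crop_and_backproject <- function(result, keypoints) {
  kp <- tibble::as_tibble(keypoints)
  if (nrow(kp) == 0) return(kp)
  r <- result$roi
  if (any(kp$x < 0 | kp$y < 0 | kp$x > r[3] - 1 | kp$y > r[4] - 1))
    stop("keypoint outside the region of interest")
  kp$x <- kp$x + result$offset[[1]]
  kp$y <- kp$y + result$offset[[2]]
  kp
}

# Binary erosion of a 0/1 mask with a (2r+1) square structuring element.
erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  m <- mask > 0
  for (k in seq_len(radius)) {
    nr <- nrow(m); nc <- ncol(m)
    p <- matrix(FALSE, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    m <- p[2:(nr + 1), 2:(nc + 1)] &
      p[1:nr, 2:(nc + 1)] & p[3:(nr + 2), 2:(nc + 1)] &
      p[2:(nr + 1), 1:nc] & p[2:(nr + 1), 3:(nc + 2)] &
      p[1:nr, 1:nc] & p[1:nr, 3:(nc + 2)] &
      p[3:(nr + 2), 1:nc] & p[3:(nr + 2), 3:(nc + 2)]
  }
  m * 1
}
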