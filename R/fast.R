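# FAST segment-test corner detection on the 16-pixel Bresenham circle of
# radius 3.

# circle offsets (dx, dy), clockwise from 12 o'clock
fast_circle_offsets <- function() {
  cbind(dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1),
        dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3))
}

#' FAST segment-test corner detection
#'
#' A pixel `p` is a corner when at least `arc_length` contiguous pixels on
#' the 16-pixel Bresenham circle of radius 3 are all brighter than
#' `I(p) + T` or all darker than `I(p) - T`, with
#' `T = min_contrast * intensity range` (range 1 for `[0, 1]` images). For
#' `arc_length >= 12` the high-speed pretest on the four compass pixels
#' (reject unless at least 3 pass) is applied first; it is a necessary
#' condition of the full test at that arc length. Corners are scored by the
#' summed contrast margin over the circle, non-maximum suppressed in a 3x3
#' neighbourhood (raster-order tie-break), and gated at
#' `min_quality * max score`.
#'
#' @param img Gray image in `[0, 1]`, at least 7x7.
#' @param config A [detector_config()] (the `fast` entry is used).
#' @param nms Apply non-maximum suppression and the quality gate; set
#'   `FALSE` to obtain the raw segment-test positives.
#' @return A tibble with `x`, `y` (0-based), `scale` (fixed nominal scale 2),
#'   `orientation` (0) and `response` (corner score).
#' @export
fast_detect <- function(img, config = detector_config(), nms = TRUE) {
  cf <- config$fast
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 7 || nc < 7) stop("image must be at least 7x7")
  T <- cf$min_contrast  # intensity range is 1 for [0,1] images
  off <- fast_circle_offsets()
  inr <- 4:(nr - 3); inc <- 4:(nc - 3)
  ctr <- img[inr, inc]
  hi <- ctr + T; lo <- ctr - T
  bright <- vector("list", 16)
  dark <- vector("list", 16)
  for (i in 1:16) {
    sh <- img[inr + off[i, "dy"], inc + off[i, "dx"]]
    bright[[i]] <- sh > hi
    dark[[i]] <- sh < lo
  }
  pretest <- NULL
  if (cf$arc_length >= 12) {
    compass <- c(1, 5, 9, 13)
    nb <- Reduce(`+`, bright[compass])
    nd <- Reduce(`+`, dark[compass])
    pretest <- nb >= 3 | nd >= 3
  }
  n <- cf$arc_length
  arc_any <- function(flags) {
    found <- matrix(FALSE, nrow(ctr), ncol(ctr))
    for (s in 1:16) {
      run <- flags[[s]]
      for (k in 1:(n - 1)) {
        run <- run & flags[[(s + k - 1) %% 16 + 1]]
        if (!any(run)) break
      }
      found <- found | run
    }
    found
  }
  corner <- arc_any(bright) | arc_any(dark)
  if (!is.null(pretest)) corner <- corner & pretest

  # summed contrast margin over the circle
  score_b <- 0; score_d <- 0
  for (i in 1:16) {
    sh <- img[inr + off[i, "dy"], inc + off[i, "dx"]]
    score_b <- score_b + pmax(sh - hi, 0)
    score_d <- score_d + pmax(lo - sh, 0)
  }
  score <- pmax(score_b, score_d)
  score[!corner] <- -Inf

  if (nms && any(corner)) {
    # keep a pixel over an equal-scoring neighbour earlier in raster order
    earlier <- pmax(shift_mat(score, 1, 1), shift_mat(score, 1, 0),
                    shift_mat(score, 1, -1), shift_mat(score, 0, 1))
    later <- pmax(shift_mat(score, -1, -1), shift_mat(score, -1, 0),
                  shift_mat(score, -1, 1), shift_mat(score, 0, -1))
    keep <- corner & score > earlier & score >= later
    smax <- max(score[keep], -Inf)
    keep <- keep & score >= cf$min_quality * smax
    corner <- keep
  }
  idx <- which(corner, arr.ind = TRUE)
  out <- tibble::tibble(
    x = as.numeric(inc[1] - 1 + idx[, 2] - 1),
    y = as.numeric(inr[1] - 1 + idx[, 1] - 1),
    scale = 2, orientation = 0,
    response = score[idx])
  dplyr::arrange(out, .data$y, .data$x)
}
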