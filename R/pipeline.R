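# End-to-end frame-pair processing and run-level evaluation statistics.

#' Detect and describe features with a chosen detector
#'
#' Uniform dispatcher over the four detectors. MSER regions and FAST
#' corners carry no native descriptor; they are described by the real-valued
#' 64-d descriptor evaluated at the region's ellipse centre (at a scale
#' proportional to the equivalent circular radius) or at the corner at a
#' fixed nominal scale, so all detectors share one matching path.
#'
#' @param img Gray image in `[0, 1]`.
#' @param detector `"surf"`, `"mser"`, `"fast"` or `"orb"`.
#' @param config A [detector_config()].
#' @return A list with `keypoints` (tibble) and `descriptors` (matrix with
#'   `kind` attribute).
#' @export
detect_features <- function(img, detector = c("surf", "mser", "fast", "orb"),
                            config = detector_config()) {
  detector <- match.arg(detector)
  if (detector == "orb") return(orb_detect_describe(img, config))
  kp <- switch(detector,
    surf = surf_detect(img, config),
    fast = fast_detect(img, config),
    mser = {
      reg <- mser_detect(img, config)
      tibble::tibble(x = reg$x, y = reg$y,
                     scale = pmax(1.5, reg$scale / 3),
                     orientation = NA_real_, response = reg$response)
    })
  describe_keypoints(img, kp)
}

# Iterative intensity-weighted centroid refinement in the original image.
# The border-ring mean is subtracted as local background and a smooth
# radial taper centred on the running subpixel estimate removes the
# asymmetric truncation of a hard window edge. Returns the input position
# when the window leaves the image or has no signal above its border level.
refine_centroid <- function(img, pt, radius = 6, iters = 4) {
  nr <- nrow(img); nc <- ncol(img)
  est <- pt
  for (it in seq_len(iters)) {
    cx <- round(est[1]); cy <- round(est[2])
    if (cx - radius < 0 || cy - radius < 0 ||
        cx + radius > nc - 1 || cy + radius > nr - 1) return(est)
    xs <- (cx - radius):(cx + radius)
    ys <- (cy - radius):(cy + radius)
    patch <- img[ys + 1, xs + 1]
    ring <- c(patch[1, ], patch[nrow(patch), ],
              patch[, 1], patch[, ncol(patch)])
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    gy <- matrix(ys, length(ys), length(xs))
    d2 <- ((gx - est[1])^2 + (gy - est[2])^2) / radius^2
    taper <- pmax(1 - d2, 0)^2
    # squared weights: same centroid for a symmetric peak, but the rim
    # clamp discontinuity is suppressed quadratically
    w <- pmax(patch - mean(ring), 0)^2 * taper
    tw <- sum(w)
    if (tw < 1e-9) return(est)
    est <- c(sum(w * gx) / tw, sum(w * gy) / tw)
  }
  est
}

#' Process one stereo frame pair through the full pipeline
#'
#' Rectifies both views with the calibrated rig, enhances and segments the
#' spine region (CLAHE, Otsu, region growing), detects and describes
#' features inside the segmented crop, matches descriptors across views,
#' flags epipolar outliers, optionally refines matched inlier positions to
#' sub-pixel precision in the original images, and triangulates every
#' inlier by the midpoint method. Per-stage wall-clock times are recorded.
#'
#' @param img1,img2 Gray images in `[0, 1]` from camera 1 and camera 2.
#' @param rig A calibrated [stereo_rig()] (required for metric output).
#' @param config A [run_config()].
#' @param detector Detector name; defaults to `config$detector`.
#' @return An object of class `frame_pair_result`: list with `detector`,
#'   `matches` (tibble with scores, y-disparities and inlier flags),
#'   `triangulations` (tibble with the 3D points in mm, `error_mm`, and the
#'   original-frame pixel coordinates), `inlier_count`, `n_keypoints`
#'   (per view), `stage_times` (seconds: preprocess, detect, match,
#'   triangulate) and the `rectification` used.
#' @export
process_frame_pair <- function(img1, img2, rig, config = run_config(),
                               detector = config$detector) {
  detector <- match.arg(detector, c("surf", "mser", "fast", "orb"))
  stopifnot(is.matrix(img1), is.matrix(img2))
  if (is.null(rig$F)) rig <- stereo_rig(rig$cam1, rig$cam2)
  times <- c(preprocess = 0, detect = 0, match = 0, triangulate = 0)
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  rect <- rectify_stereo(rig, c(ncol(img1), nrow(img1)),
                         c(ncol(img2), nrow(img2)))
  R1 <- warp_image(img1, rect$H, rect$size1)
  R2 <- warp_image(img2, rect$H_prime, rect$size2)
  prep_one <- function(R) {
    enh <- if (config$enhance)
      clahe(R, config$clahe_clip, config$clahe_tiles) else R
    segment_spine(enh)
  }
  pp1 <- prep_one(R1)
  pp2 <- prep_one(R2)
  times["preprocess"] <- tic() - t0

  t0 <- tic()
  mask_filter <- function(pp, kp) {
    em <- erode_mask(pp$mask, config$mask_margin)
    em[cbind(pmin(pmax(round(kp$y), 0), nrow(em) - 1) + 1,
             pmin(pmax(round(kp$x), 0), ncol(em) - 1) + 1)] > 0
  }
  det_one <- function(pp) {
    if (detector == "orb") {
      # ORB computes its own descriptors; run it on the full masked frame
      fd <- orb_detect_describe(pp$enhanced, config$detectors)
      keep <- if (nrow(fd$keypoints)) mask_filter(pp, fd$keypoints) else
        logical(0)
      return(list(
        keypoints = fd$keypoints[keep, , drop = FALSE],
        descriptors = structure(fd$descriptors[keep, , drop = FALSE],
                                kind = attr(fd$descriptors, "kind"))))
    }
    # detect inside the segmented crop, then describe on the full frame so
    # descriptor windows are not clipped by the crop border
    crop <- crop_to_roi(pp)
    kp <- switch(detector,
      surf = surf_detect(crop, config$detectors),
      fast = fast_detect(crop, config$detectors),
      mser = {
        reg <- mser_detect(crop, config$detectors)
        tibble::tibble(x = reg$x, y = reg$y,
                       scale = pmax(1.5, reg$scale / 3),
                       orientation = NA_real_, response = reg$response)
      })
    if (nrow(kp) == 0)
      return(list(keypoints = kp,
                  descriptors = structure(matrix(numeric(), 0, 64),
                                          kind = "real64")))
    kp <- crop_and_backproject(pp, kp)
    kp <- kp[mask_filter(pp, kp), , drop = FALSE]
    describe_keypoints(pp$enhanced, kp)
  }
  f1 <- det_one(pp1)
  f2 <- det_one(pp2)
  times["detect"] <- tic() - t0

  t0 <- tic()
  metric <- if (config$metric == "ncc-all") "ncc-all" else "auto"
  matches <- match_descriptors(f1$descriptors, f2$descriptors, metric)
  matches <- epipolar_filter(matches, f1$keypoints, f2$keypoints,
                             "rectified", config$epipolar_tol)
  times["match"] <- tic() - t0

  t0 <- tic()
  inl <- matches[matches$inlier, , drop = FALSE]
  if (nrow(inl) == 0) {
    warning("no matched inliers for this frame pair")
    tri <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          error_mm = numeric(), x1 = numeric(),
                          y1 = numeric(), x2 = numeric(), y2 = numeric())
  } else {
    r1 <- cbind(f1$keypoints$x[inl$idx1], f1$keypoints$y[inl$idx1])
    r2 <- cbind(f2$keypoints$x[inl$idx2], f2$keypoints$y[inl$idx2])
    o1 <- apply_homography(solve(rect$H), r1)
    o2 <- apply_homography(solve(rect$H_prime), r2)
    if (config$refine == "centroid") {
      for (i in seq_len(nrow(o1))) {
        o1[i, ] <- refine_centroid(img1, o1[i, ])
        o2[i, ] <- refine_centroid(img2, o2[i, ])
      }
    }
    tri <- triangulate_points(rig, o1, o2)
    tri$x1 <- o1[, 1]; tri$y1 <- o1[, 2]
    tri$x2 <- o2[, 1]; tri$y2 <- o2[, 2]
  }
  times["triangulate"] <- tic() - t0

  structure(
    list(detector = detector, matches = matches, triangulations = tri,
         inlier_count = sum(matches$inlier),
         n_keypoints = c(nrow(f1$keypoints), nrow(f2$keypoints)),
         stage_times = times, rectification = rect),
    class = "frame_pair_result"
  )
}

#' @export
print.frame_pair_result <- function(x, ...) {
  cat("<frame_pair_result> detector ", x$detector, ": ",
      x$n_keypoints[1], "/", x$n_keypoints[2], " keypoints, ",
      nrow(x$matches), " matches, ", x$inlier_count, " inliers",
      if (nrow(x$triangulations) > 0)
        paste0(", mean error ",
               signif(mean(x$triangulations$error_mm), 4), " mm"),
      "\n", sep = "")
  invisible(x)
}

# type-7 quantiles, the documented convention for medians and IQRs
iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Summarize triangulation errors and inlier counts over a run
#'
#' Per-group statistics in the style of a per-patient evaluation: the group
#' mean and standard deviation are computed over per-frame mean errors (a
#' group with a single frame reports `NA` standard deviation); the median
#' and interquartile range are pooled over all per-feature errors
#' (type-7 quantiles); inlier counts are summarized by max/min/mean/median/
#' IQR across frame pairs. Frames without inliers are retained in the
#' inlier statistics but contribute no error values.
#'
#' @param results A list of [process_frame_pair()] results.
#' @param groups Optional group label per result (e.g. patient); defaults
#'   to a single group `"all"`.
#' @return An object of class `run_summary`: list with tibbles
#'   `error_summary`, `inlier_summary`, `frames` and `errors`.
#' @export
summarize_runs <- function(results, groups = NULL) {
  if (inherits(results, "frame_pair_result")) results <- list(results)
  if (length(results) == 0) stop("at least one frame-pair result is required")
  groups <- groups %||% rep("all", length(results))
  groups <- rep_len(as.character(groups), length(results))
  frames <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tibble::tibble(
      frame = i, group = groups[i], detector = r$detector,
      inliers = r$inlier_count,
      mean_error = if (nrow(r$triangulations) > 0)
        mean(r$triangulations$error_mm) else NA_real_)
  }))
  errors <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    tr <- results[[i]]$triangulations
    if (nrow(tr) == 0) return(NULL)
    tibble::tibble(frame = i, group = groups[i],
                   detector = results[[i]]$detector,
                   error_mm = tr$error_mm)
  }))
  err_sum <- frames |>
    dplyr::filter(!is.na(.data$mean_error)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      sd_error = stats::sd(.data$mean_error),  # NA for single-frame groups
      mean_error = mean(.data$mean_error),
      .groups = "drop")
  pooled <- if (nrow(errors) > 0) {
    errors |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(median_error = stats::median(.data$error_mm),
                       iqr_error = iqr7(.data$error_mm), .groups = "drop")
  } else {
    tibble::tibble(group = character(), median_error = numeric(),
                   iqr_error = numeric())
  }
  err_sum <- dplyr::left_join(err_sum, pooled, by = "group") |>
    dplyr::relocate("mean_error", .before = "sd_error")
  inl_sum <- frames |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      max_inliers = max(.data$inliers), min_inliers = min(.data$inliers),
      mean_inliers = mean(.data$inliers),
      median_inliers = stats::median(.data$inliers),
      iqr_inliers = iqr7(.data$inliers), .groups = "drop")
  structure(list(error_summary = err_sum, inlier_summary = inl_sum,
                 frames = frames, errors = errors),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary> ", nrow(x$frames), " frame pairs, ",
      nrow(x$errors), " triangulated features\n", sep = "")
  print(x$error_summary)
  print(x$inlier_summary)
  invisible(x)
}

#' Empirical CDF of triangulation errors with a distribution-free band
#'
#' Computes the empirical cumulative distribution of the error values and a
#' pointwise confidence band from the Dvoretzky-Kiefer-Wolfowitz
#' inequality: the half-width is `sqrt(log(2 / alpha) / (2 n))` at
#' confidence `1 - alpha`.
#'
#' @param errors Numeric vector of triangulation errors (mm), n >= 1.
#' @param confidence Band confidence level (default 0.95).
#' @return An object of class `error_cdf`: list with `points` (tibble
#'   `error_mm`, `cdf`, `lower`, `upper`), `n`, `half_width`, `confidence`
#'   and `cdf_at(q)`, the fraction of errors at or below `q`.
#' @export
error_cdf <- function(errors, confidence = 0.95) {
  errors <- as.numeric(errors)
  stopifnot(length(errors) >= 1, confidence > 0, confidence < 1)
  n <- length(errors)
  xs <- sort(errors)
  cdf <- seq_len(n) / n
  eps <- sqrt(log(2 / (1 - confidence)) / (2 * n))
  structure(
    list(points = tibble::tibble(error_mm = xs, cdf = cdf,
                                 lower = pmax(cdf - eps, 0),
                                 upper = pmin(cdf + eps, 1)),
         n = n, half_width = eps, confidence = confidence,
         cdf_at = function(q) mean(errors <= q)),
    class = "error_cdf"
  )
}

#' @export
print.error_cdf <- function(x, ...) {
  cat("<error_cdf> n = ", x$n, ", ", 100 * x$confidence,
      "% DKW half-width ", signif(x$half_width, 4), "\n", sep = "")
  invisible(x)
}

#' Per-stage timing report
#'
#' Mean and sample standard deviation of per-stage execution times across
#' frame pairs, per detector, with a frames-per-second figure derived as
#' the reciprocal mean detection time.
#'
#' @param results A list of [process_frame_pair()] results.
#' @return A tibble with `detector`, `stage`, `mean_s`, `sd_s`, `n`, `fps`
#'   (detect stage only).
#' @export
timing_report <- function(results) {
  if (inherits(results, "frame_pair_result")) results <- list(results)
  rows <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(detector = r$detector,
                   stage = names(r$stage_times),
                   seconds = as.numeric(r$stage_times))
  }))
  rows |>
    dplyr::group_by(.data$detector, .data$stage) |>
    dplyr::summarise(
      mean_s = mean(.data$seconds),
      sd_s = stats::sd(.data$seconds),  # NA when only one frame
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(fps = ifelse(.data$stage == "detect" & .data$mean_s > 0,
                               1 / .data$mean_s, NA_real_))
}
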