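#' Default detector configuration
#'
#' Parameter set for the four feature detectors, following the values used
#' for spinal feature detection: SURF-style Hessian blobs (feature threshold
#' 600, 4 octaves, 6 scales per octave), MSER (threshold step 0.3% of the
#' intensity range, region area 100-800 px^2, maximum area variation 0.3),
#' FAST (minimum corner quality 0.1 of the strongest corner, minimum
#' contrast 0.2 of the intensity range, segment arc of 12 on a 16-pixel
#' circle), and ORB (pyramid scale factor 1.2, 8 levels, 256-bit
#' descriptors).
#'
#' @param ... Named overrides, e.g.
#'   `detector_config(fast = list(min_contrast = 0.1))`. Unknown names or
#'   fields are an error.
#' @return A nested list of class `detector_config`.
#' @export
detector_config <- function(...) {
  cfg <- list(
    surf = list(feature_threshold = 600, n_octaves = 4, n_scales = 6),
    mser = list(threshold_step = 0.3, area_range = c(100, 800),
                max_area_variation = 0.3, min_diversity = 0.2),
    fast = list(min_quality = 0.1, min_contrast = 0.2,
                arc_length = 12, circle_size = 16),
    orb = list(scale_factor = 1.2, n_levels = 8, descriptor_bits = 256,
               patch_size = 31, fast_contrast = 0.08)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown detector: ", nm)
    for (f in names(dots[[nm]])) {
      if (!f %in% names(cfg[[nm]]))
        stop("unknown ", nm, " parameter: ", f)
      cfg[[nm]][[f]] <- dots[[nm]][[f]]
    }
  }
  stopifnot(cfg$surf$feature_threshold > 0,
            cfg$mser$threshold_step > 0,
            cfg$mser$area_range[1] < cfg$mser$area_range[2],
            cfg$fast$min_contrast > 0,
            cfg$fast$arc_length <= cfg$fast$circle_size,
            cfg$orb$scale_factor > 1)
  structure(cfg, class = "detector_config")
}

#' Default pipeline run configuration
#'
#' @param detector One of `"surf"`, `"mser"`, `"fast"`, `"orb"`.
#' @param detectors A [detector_config()].
#' @param clahe_clip,clahe_tiles CLAHE contrast limit and tile grid.
#' @param epipolar_tol Epipolar inlier tolerance in rectified pixels.
#' @param metric `"auto"` (NCC for real descriptors, Hamming for binary) or
#'   `"ncc-all"` (NCC on binary descriptors treated as floats).
#' @param refine Subpixel refinement of matched inliers before
#'   triangulation: `"centroid"` (intensity-weighted centroid in the
#'   original images) or `"none"`.
#' @param mask_margin Pixels eroded off the segmentation mask border before
#'   keypoints are accepted (border detections are unreliable).
#' @param enhance Apply CLAHE before segmentation/detection.
#' @param seed Integer seed controlling any stochastic component.
#' @return A list of class `run_config`.
#' @export
run_config <- function(detector = "surf", detectors = detector_config(),
                       clahe_clip = 0.03, clahe_tiles = c(8, 8),
                       epipolar_tol = 1.0, metric = c("auto", "ncc-all"),
                       refine = c("centroid", "none"),
                       mask_margin = 8, enhance = TRUE, seed = 1L) {
  detector <- match.arg(detector, c("surf", "mser", "fast", "orb"))
  structure(
    list(detector = detector, detectors = detectors,
         clahe_clip = clahe_clip, clahe_tiles = clahe_tiles,
         epipolar_tol = epipolar_tol, metric = match.arg(metric),
         refine = match.arg(refine), mask_margin = mask_margin,
         enhance = enhance, seed = as.integer(seed)),
    class = "run_config"
  )
}
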