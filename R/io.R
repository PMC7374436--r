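# File I/O: gray images, calibration configs, manifests, result exports.

#' Read a gray-scale image (PNG or TIFF)
#'
#' 8- or 16-bit images are returned as matrices in `[0, 1]`. Color inputs
#' are converted to luminance (0.299 R + 0.587 G + 0.114 B) with a warning,
#' or rejected in strict mode.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param strict Reject color images instead of converting.
#' @return A numeric matrix in `[0, 1]`.
#' @export
read_gray <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 2) img <- img[, , 1]  # gray + alpha
    else {
      if (strict) stop("color image rejected in strict gray-scale mode: ",
                       path)
      warning("color image converted to luminance: ", path)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
  }
  matrix(as.numeric(img), dim(img)[1], dim(img)[2])
}

#' Write a gray-scale image as PNG
#'
#' @param img Matrix in `[0, 1]`.
#' @param path Output path.
#' @export
write_gray <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a stereo calibration config (JSON or YAML)
#'
#' Per camera: `fx, fy, cx, cy`, the world-to-camera rotation `R` as 9
#' row-major floats and the centre `C` in mm.
#'
#' @param rig A [stereo_rig()].
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @export
write_calibration <- function(rig, path) {
  enc <- function(cam) {
    list(fx = cam$focal[1], fy = cam$focal[2],
         cx = cam$principal_point[1], cy = cam$principal_point[2],
         R = as.numeric(t(cam$rotation)),  # row-major
         C = as.numeric(cam$center))
  }
  obj <- list(cam1 = enc(rig$cam1), cam2 = enc(rig$cam2))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path, precision = 17)
  } else stop("unsupported calibration format: .", ext)
  invisible(path)
}

#' Read a stereo calibration config (JSON or YAML)
#'
#' @param path Calibration file written by [write_calibration()] (or the
#'   same schema produced elsewhere).
#' @return A [stereo_rig()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported calibration format: .", ext)
  dec <- function(cm) {
    camera_model(c(cm$fx, cm$fy), c(cm$cx, cm$cy),
                 matrix(as.numeric(unlist(cm$R)), 3, 3, byrow = TRUE),
                 as.numeric(unlist(cm$C)))
  }
  stereo_rig(dec(obj$cam1), dec(obj$cam2))
}

#' Load stereo frame pairs from a manifest
#'
#' The manifest (CSV, or a data frame) has columns `frame_id`,
#' `path_view1`, `path_view2` and optionally `group`. Images are read in
#' manifest order; unreadable rows raise an error naming the row.
#'
#' @param manifest Path to a CSV file or a data frame.
#' @param strict Passed to [read_gray()].
#' @return A tibble with `frame_id`, `group` and list-columns `img1`,
#'   `img2`.
#' @export
load_images <- function(manifest, strict = FALSE) {
  mf <- if (is.character(manifest)) {
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else as.data.frame(manifest)
  need <- c("frame_id", "path_view1", "path_view2")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(mf$group)) mf$group <- "all"
  img1 <- vector("list", nrow(mf)); img2 <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    img1[[i]] <- tryCatch(read_gray(mf$path_view1[i], strict),
      error = function(e) stop("manifest row ", mf$frame_id[i], " (view 1): ",
                               conditionMessage(e), call. = FALSE))
    img2[[i]] <- tryCatch(read_gray(mf$path_view2[i], strict),
      error = function(e) stop("manifest row ", mf$frame_id[i], " (view 2): ",
                               conditionMessage(e), call. = FALSE))
  }
  tibble::tibble(frame_id = mf$frame_id, group = mf$group,
                 img1 = img1, img2 = img2)
}

#' Export a match set as CSV
#'
#' Columns: `idx1, x1_px, y1_px, idx2, x2_px, y2_px, score, y_disparity_px,
#' inlier` (units in the header).
#'
#' @param matches An [epipolar_filter()] result.
#' @param kps1,kps2 The keypoint tibbles the indices refer to.
#' @param path Output CSV path.
#' @export
write_matches_csv <- function(matches, kps1, kps2, path) {
  df <- data.frame(
    idx1 = matches$idx1,
    x1_px = signif(kps1$x[matches$idx1], 6),
    y1_px = signif(kps1$y[matches$idx1], 6),
    idx2 = matches$idx2,
    x2_px = signif(kps2$x[matches$idx2], 6),
    y2_px = signif(kps2$y[matches$idx2], 6),
    score = signif(matches$score, 6),
    y_disparity_px = signif(matches$y_disparity %||% NA_real_, 6),
    inlier = matches$inlier %||% NA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export keypoints as CSV
#'
#' Columns: `x_px, y_px, scale_px, orientation_rad, response`.
#'
#' @param keypoints Keypoint tibble.
#' @param path Output CSV path.
#' @export
write_keypoints_csv <- function(keypoints, path) {
  df <- data.frame(
    x_px = signif(keypoints$x, 6), y_px = signif(keypoints$y, 6),
    scale_px = signif(keypoints$scale, 6),
    orientation_rad = signif(keypoints$orientation, 6),
    response = signif(keypoints$response, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline over a manifest and write its artifacts
#'
#' Processes every frame pair with [process_frame_pair()], writes one
#' per-frame triangulation CSV per pair, a run summary JSON and a CDF
#' points CSV into `out_dir`, and returns the results invisibly.
#'
#' @param frames A [load_images()] tibble.
#' @param rig A [stereo_rig()].
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `results`, `summary` and `cdf`.
#' @export
run_pipeline <- function(frames, rig, config = run_config(),
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- vector("list", nrow(frames))
  for (i in seq_len(nrow(frames))) {
    results[[i]] <- process_frame_pair(frames$img1[[i]], frames$img2[[i]],
                                       rig, config)
    tr <- results[[i]]$triangulations
    df <- data.frame(x_mm = signif(tr$x, 6), y_mm = signif(tr$y, 6),
                     z_mm = signif(tr$z, 6),
                     error_mm = signif(tr$error_mm, 6),
                     x1_px = signif(tr$x1, 6), y1_px = signif(tr$y1, 6),
                     x2_px = signif(tr$x2, 6), y2_px = signif(tr$y2, 6))
    utils::write.csv(df, file.path(out_dir,
                                   paste0("frame_", frames$frame_id[i],
                                          "_", config$detector, ".csv")),
                     row.names = FALSE)
  }
  summ <- summarize_runs(results, frames$group)
  out <- list(
    detector = config$detector,
    error_summary = summ$error_summary,
    inlier_summary = summ$inlier_summary,
    timing = timing_report(results))
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cdf <- NULL
  if (nrow(summ$errors) > 0) {
    cdf <- error_cdf(summ$errors$error_mm)
    utils::write.csv(
      data.frame(error_mm = signif(cdf$points$error_mm, 6),
                 cdf = signif(cdf$points$cdf, 6),
                 lower = signif(cdf$points$lower, 6),
                 upper = signif(cdf$points$upper, 6)),
      file.path(out_dir, "error_cdf.csv"), row.names = FALSE)
  }
  invisible(list(results = results, summary = summ, cdf = cdf))
}

#' Write a synthetic scene to disk as a pipeline-ready dataset
#'
#' Renders `n_frames` stereo pairs (same geometry, fresh noise per frame),
#' and writes the PNG images, a calibration JSON, a ground-truth landmark
#' CSV (`X_mm ... y2_px`) and a manifest CSV consumable by [load_images()].
#'
#' @param scene A [make_scene()] result.
#' @param out_dir Output directory.
#' @param n_frames Number of frame pairs to render.
#' @return The manifest path, invisibly.
#' @export
write_scene_dataset <- function(scene, out_dir, n_frames = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    sc <- scene
    sc$seed <- scene$seed + (i - 1L) * 1000L
    rv <- render_views(sc)
    p1 <- file.path(out_dir, sprintf("frame%03d_view1.png", i))
    p2 <- file.path(out_dir, sprintf("frame%03d_view2.png", i))
    write_gray(rv$img1, p1)
    write_gray(rv$img2, p2)
    rows[[i]] <- data.frame(frame_id = sprintf("%03d", i),
                            path_view1 = p1, path_view2 = p2,
                            group = "synthetic")
  }
  write_calibration(scene$rig, file.path(out_dir, "calibration.json"))
  gt <- scene$landmarks
  utils::write.csv(
    data.frame(X_mm = gt$X, Y_mm = gt$Y, Z_mm = gt$Z,
               x1_px = gt$x1, y1_px = gt$y1, x2_px = gt$x2, y2_px = gt$y2),
    file.path(out_dir, "landmarks.csv"), row.names = FALSE)
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  invisible(mf)
}
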