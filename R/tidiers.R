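# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a run summary into its per-group error table
#'
#' @param x A [summarize_runs()] result.
#' @param ... Unused.
#' @return The `error_summary` tibble joined with the inlier statistics.
#' @export
tidy.run_summary <- function(x, ...) {
  dplyr::left_join(x$error_summary, x$inlier_summary, by = "group")
}

#' One-row overview of a run summary
#'
#' @param x A [summarize_runs()] result.
#' @param ... Unused.
#' @return A one-row tibble with pooled error statistics and totals.
#' @export
glance.run_summary <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$frames),
    n_features = nrow(x$errors),
    mean_error = if (nrow(x$errors)) mean(x$errors$error_mm) else NA_real_,
    median_error = if (nrow(x$errors)) stats::median(x$errors$error_mm)
      else NA_real_,
    mean_inliers = mean(x$frames$inliers))
}

#' Tidy a frame-pair result into its triangulation table
#'
#' @param x A [process_frame_pair()] result.
#' @param ... Unused.
#' @return The triangulations tibble with a `detector` column.
#' @export
tidy.frame_pair_result <- function(x, ...) {
  det <- x$detector
  dplyr::mutate(x$triangulations, detector = det, .before = 1)
}

#' One-row overview of a frame-pair result
#'
#' @param x A [process_frame_pair()] result.
#' @param ... Unused.
#' @return A one-row tibble with counts, mean error and stage times.
#' @export
glance.frame_pair_result <- function(x, ...) {
  tibble::tibble(
    detector = x$detector,
    n_keypoints1 = x$n_keypoints[1], n_keypoints2 = x$n_keypoints[2],
    n_matches = nrow(x$matches), inliers = x$inlier_count,
    mean_error_mm = if (nrow(x$triangulations)) mean(x$triangulations$error_mm)
      else NA_real_,
    t_preprocess_s = x$stage_times[["preprocess"]],
    t_detect_s = x$stage_times[["detect"]],
    t_match_s = x$stage_times[["match"]],
    t_triangulate_s = x$stage_times[["triangulate"]])
}

#' Plot an error CDF with its confidence band
#'
#' Step plot of the empirical CDF with the DKW band as a ribbon.
#'
#' @param object An [error_cdf()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_cdf <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$error_mm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_step(ggplot2::aes(y = .data$cdf)) +
    ggplot2::labs(x = "triangulation error (mm)",
                  y = "cumulative fraction",
                  title = sprintf("Empirical CDF with %g%% DKW band",
                                  100 * object$confidence)) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Boxplot of triangulation errors by group
#'
#' @param object A [summarize_runs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.run_summary <- function(object, ...) {
  if (nrow(object$errors) == 0) stop("no triangulated errors to plot")
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = .data$group, y = .data$error_mm)) +
    ggplot2::geom_boxplot(outlier.shape = 3) +
    ggplot2::labs(x = NULL, y = "triangulation error (mm)")
}
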