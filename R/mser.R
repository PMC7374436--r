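# Maximally stable extremal regions: R surface over the C++ component tree.

# Moments-based bounding ellipse of a pixel set (0-based coords in, list out).
region_ellipse <- function(px) {
  x <- px[, 2] - 1; y <- px[, 1] - 1
  ctr <- c(mean(x), mean(y))
  cxx <- mean((x - ctr[1])^2); cyy <- mean((y - ctr[2])^2)
  cxy <- mean((x - ctr[1]) * (y - ctr[2]))
  C <- matrix(c(cxx, cxy, cxy, cyy), 2, 2)
  ev <- eigen(C, symmetric = TRUE)
  axes <- 2 * sqrt(pmax(ev$values, 0))
  list(center = ctr, axes = axes,
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi)
}

#' Detect maximally stable extremal regions (MSER)
#'
#' Sweeps the intensity thresholds of an 8-bit quantized image, tracks
#' connected extremal regions across the sweep, and emits regions where the
#' relative area change over `delta` gray levels is a local minimum along
#' the region's growth history and does not exceed the configured maximum
#' area variation. Both polarities (dark and bright extremal regions) are
#' detected; region areas are filtered to the configured range. Each region
#' is summarized by its bounding ellipse and carries its full pixel set.
#'
#' The threshold step parameter is a percentage of the full intensity range
#' per stability step (`delta = max(1, round(step/100 * 255))` gray levels).
#'
#' @param img Gray image in `[0, 1]`.
#' @param config A [detector_config()] (the `mser` entry is used).
#' @return A tibble with one row per region: `x`, `y` (ellipse centre,
#'   0-based), `scale` (`sqrt(area / pi)`, the equivalent circular radius),
#'   `orientation` (ellipse angle), `response` (negative stability, so that
#'   more stable regions score higher), `area`, `stability`, `level`,
#'   `polarity` (`"dark"` or `"bright"`), `axis_major`, `axis_minor`, and a
#'   `pixels` list-column of m x 2 matrices of 1-based (row, col) pixels.
#' @export
mser_detect <- function(img, config = detector_config()) {
  cf <- config$mser
  q <- matrix(as.integer(pmin(pmax(round(img * 255), 0), 255)),
              nrow(img), ncol(img))
  delta <- max(1L, as.integer(round(cf$threshold_step / 100 * 255)))
  one_polarity <- function(qq, polarity) {
    cand <- mser_tree_cpp(qq, delta, cf$max_area_variation,
                          as.integer(cf$area_range[1]),
                          as.integer(cf$area_range[2]),
                          cf$min_diversity)
    if (nrow(cand) == 0) return(NULL)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      px <- flood_le_cpp(qq, cand$seed_row[i], cand$seed_col[i],
                         cand$level[i])
      ell <- region_ellipse(px)
      tibble::tibble(
        x = ell$center[1], y = ell$center[2],
        scale = sqrt(nrow(px) / pi),
        orientation = ell$angle,
        response = -cand$stability[i],
        area = nrow(px), stability = cand$stability[i],
        level = if (polarity == "dark") cand$level[i] else 255L - cand$level[i],
        polarity = polarity,
        axis_major = max(ell$axes), axis_minor = min(ell$axes),
        pixels = list(px))
    })
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(one_polarity(q, "dark"),
                          one_polarity(255L - q, "bright"))
  if (is.null(out) || nrow(out) == 0)
    return(tibble::tibble(
      x = numeric(), y = numeric(), scale = numeric(),
      orientation = numeric(), response = numeric(), area = integer(),
      stability = numeric(), level = integer(), polarity = character(),
      axis_major = numeric(), axis_minor = numeric(), pixels = list()))
  dplyr::arrange(out, .data$y, .data$x)
}
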