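#' Normalized cross-correlation of two vectors
#'
#' Zero-mean, unit-norm inner product; the score lies in `[-1, 1]`.
#'
#' @param a,b Numeric vectors of equal length with non-zero variance.
#' @return The correlation score.
#' @export
ncc <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-15 || nb < 1e-15)
    stop("undefined correlation: zero-variance vector")
  sum(a * b) / (na * nb)
}

# Row-standardize a descriptor matrix for NCC scoring; zero-variance rows
# become NaN rows (they can never be a best match).
standardize_rows <- function(D) {
  D <- D - rowMeans(D)
  n <- sqrt(rowSums(D^2))
  D / n
}

#' Match descriptors between two views
#'
#' Greedy mutual-best one-to-one matching. Real-valued descriptors are
#' scored by normalized cross-correlation (higher is better); binary
#' descriptors by Hamming distance (lower is better) unless
#' `metric = "ncc-all"`, which treats the bits as floats and uses NCC
#' throughout. A pair `(i, j)` is kept when `j` is the best candidate for
#' `i` and `i` the best for `j`; score ties resolve to the lower index.
#' Pairs are sorted by decreasing similarity.
#'
#' @param D1,D2 Descriptor matrices with attribute `kind` (`"real64"` or
#'   `"binary256"`); kinds must agree.
#' @param metric `"auto"` or `"ncc-all"`.
#' @return A `match_set`: tibble with `idx1`, `idx2`, `score` and attribute
#'   `metric` (`"ncc"` or `"hamming"`).
#' @export
match_descriptors <- function(D1, D2, metric = c("auto", "ncc-all")) {
  metric <- match.arg(metric)
  k1 <- attr(D1, "kind") %||% "real64"
  k2 <- attr(D2, "kind") %||% "real64"
  if (!identical(k1, k2))
    stop("descriptor kinds differ: ", k1, " vs ", k2)
  empty <- tibble::tibble(idx1 = integer(), idx2 = integer(),
                          score = numeric())
  if (nrow(D1) == 0 || nrow(D2) == 0) {
    attr(empty, "metric") <- if (k1 == "binary256" && metric == "auto")
      "hamming" else "ncc"
    class(empty) <- c("match_set", class(empty))
    return(empty)
  }
  use_hamming <- k1 == "binary256" && metric == "auto"
  if (use_hamming) {
    A <- matrix(as.numeric(D1), nrow(D1))
    B <- matrix(as.numeric(D2), nrow(D2))
    S <- A %*% t(1 - B) + (1 - A) %*% t(B)  # pairwise Hamming distances
    best2 <- apply(S, 1, which.min)
    best1 <- apply(S, 2, which.min)
  } else {
    S <- standardize_rows(matrix(as.numeric(D1), nrow(D1))) %*%
      t(standardize_rows(matrix(as.numeric(D2), nrow(D2))))
    S[!is.finite(S)] <- -Inf
    best2 <- apply(S, 1, which.max)
    best1 <- apply(S, 2, which.max)
  }
  i <- seq_len(nrow(D1))
  mutual <- best1[best2[i]] == i
  out <- tibble::tibble(idx1 = i[mutual],
                        idx2 = as.integer(best2[i[mutual]]),
                        score = S[cbind(i[mutual], best2[i[mutual]])])
  out <- if (use_hamming) dplyr::arrange(out, .data$score, .data$idx1)
  else dplyr::arrange(out, dplyr::desc(.data$score), .data$idx1)
  attr(out, "metric") <- if (use_hamming) "hamming" else "ncc"
  class(out) <- c("match_set", class(out))
  out
}

#' Flag epipolar-constraint outliers in a match set
#'
#' In `rectified` mode a pair is an inlier when its absolute y-disparity is
#' at most `tol_px`; in `general` mode when the larger of the two
#' point-to-epipolar-line distances (using `F`) is at most `tol_px`.
#' Filtering is a pure flagging operation: no pair is re-matched or removed
#' and scores are unchanged.
#'
#' @param matches A [match_descriptors()] result.
#' @param kps1,kps2 Keypoint tibbles with `x`, `y` columns indexed by
#'   `idx1` / `idx2`.
#' @param mode `"rectified"` or `"general"`.
#' @param tol_px Tolerance in pixels.
#' @param F Fundamental matrix, required in general mode.
#' @return The match set with `y_disparity` and `inlier` columns added.
#' @export
epipolar_filter <- function(matches, kps1, kps2,
                            mode = c("rectified", "general"),
                            tol_px = 1.0, F = NULL) {
  mode <- match.arg(mode)
  m <- matches
  if (nrow(m) == 0) {
    m$y_disparity <- numeric(0)
    m$inlier <- logical(0)
    return(m)
  }
  p1 <- cbind(kps1$x[m$idx1], kps1$y[m$idx1])
  p2 <- cbind(kps2$x[m$idx2], kps2$y[m$idx2])
  m$y_disparity <- p2[, 2] - p1[, 2]
  if (mode == "rectified") {
    m$inlier <- abs(m$y_disparity) <= tol_px
  } else {
    if (is.null(F)) stop("general mode requires the fundamental matrix F")
    x1 <- cbind(p1, 1); x2 <- cbind(p2, 1)
    l2 <- x1 %*% t(F)            # epipolar lines in view 2
    l1 <- x2 %*% F               # epipolar lines in view 1
    d2 <- abs(rowSums(l2 * x2)) / sqrt(l2[, 1]^2 + l2[, 2]^2)
    d1 <- abs(rowSums(l1 * x1)) / sqrt(l1[, 1]^2 + l1[, 2]^2)
    m$inlier <- pmax(d1, d2) <= tol_px
  }
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x
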