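#' Integral image (summed-area table)
#'
#' Returns a `(nrow+1) x (ncol+1)` table `S` with a zero first row and
#' column, such that any axis-aligned box sum of the image is four lookups
#' (see [box_sum()]).
#'
#' @param img Image matrix.
#' @return The summed-area table.
#' @export
integral_image <- function(img) {
  if (length(img) == 0) stop("empty image")
  s <- matrix(apply(img, 2, cumsum), nrow(img), ncol(img))
  s <- matrix(t(apply(s, 1, cumsum)), nrow(img), ncol(img))
  S <- matrix(0, nrow(img) + 1, ncol(img) + 1)
  S[-1, -1] <- s
  S
}

#' Box sums from a summed-area table
#'
#' Sum of the image over the inclusive 1-based pixel rectangle
#' `[r0, r1] x [c0, c1]`; all four arguments may be vectors. Rectangles are
#' clipped to the image.
#'
#' @param S A table from [integral_image()].
#' @param r0,c0,r1,c1 Rectangle bounds (1-based rows/columns, inclusive).
#' @return Numeric vector of box sums.
#' @export
box_sum <- function(S, r0, c0, r1, c1) {
  nr <- nrow(S) - 1; nc <- ncol(S) - 1
  empty <- r1 < pmax(r0, 1) | c1 < pmax(c0, 1) | r0 > nr | c0 > nc
  r0 <- pmin(pmax(r0, 1), nr); c0 <- pmin(pmax(c0, 1), nc)
  r1 <- pmin(pmax(r1, 1), nr); c1 <- pmin(pmax(c1, 1), nc)
  v <- S[cbind(r1 + 1, c1 + 1)] - S[cbind(r0, c1 + 1)] -
    S[cbind(r1 + 1, c0)] + S[cbind(r0, c0)]
  v[empty] <- 0
  v
}
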