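#' Land-cover class codes
#'
#' Integer codes used in categorical land-cover rasters.
#'
#' @return Named integer vector: forest = 1, agropastoral = 2, water = 3,
#'   nonveg = 4.
#' @export
landcoverCodes <- function() {
  c(forest = 1L, agropastoral = 2L, water = 3L, nonveg = 4L)
}

#' Conservation-status weights
#'
#' Priority weights by threat category used in the zonation stage:
#' Data Deficient = 1, Vulnerable = 2, Endangered = 3,
#' Critically Endangered = 4.
#'
#' @return Named numeric vector.
#' @export
statusWeights <- function() c(DD = 1, VU = 2, EN = 3, CR = 4)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Moving-window class fraction
#'
#' Fraction (in percent) of TRUE cells of a mask within a square window
#' centered on each cell. Edge cells use the truncated window (no padding).
#'
#' @param mask boolean [GridRaster-class].
#' @param windowCells odd window side length, in cells.
#' @return A [GridRaster-class] in \[0, 100\].
#' @export
windowFraction <- function(mask, windowCells = 5) {
  stopifnot(windowCells >= 1, windowCells %% 2 == 1)
  m <- maskMatrix(mask)
  k <- matrix(1, windowCells, windowCells)
  num <- EBImage::filter2(m, k, boundary = 0)
  den <- EBImage::filter2(matrix(1, nrow(m), ncol(m)), k, boundary = 0)
  # filter2 works in Fourier space; clamp its rounding error out
  likeRaster(mask, clamp(100 * as.matrix(num) / as.matrix(den), 0, 100))
}

# 8-neighbourhood binary dilation (one-cell buffer)
dilate1 <- function(m) {
  as.matrix(EBImage::filter2(m, matrix(1, 3, 3), boundary = 0)) > 1e-9
}

# Bresenham-style raster line between two (row, col) cells
rasterLine <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  cbind(row = round(seq(r0, r1, length.out = n)),
        col = round(seq(c0, c1, length.out = n)))
}
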