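## First-pass segmentation: a fast, locally adaptive threshold that flags
## candidate culture pixels so they can be cut out of the lighting map.
## Over-calling agar as culture is harmless here (those pixels are simply
## interpolated over); missing culture pixels is what must be avoided,
## since the later gradient correction would flatten their signal away.

## Shift a matrix by (dy, dx) with edge replication.
shiftPad <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- clamp(seq_len(h) - dy, 1L, h)
  ci <- clamp(seq_len(w) - dx, 1L, w)
  m[ri, ci, drop = FALSE]
}

#' Sobel gradient-magnitude map
#'
#' Convolves a greyscale raster with the standard 3x3 Sobel kernels and
#' returns \code{sqrt(Gx^2 + Gy^2)} per pixel. Borders are handled by edge
#' replication, so a flat image yields an identically zero map.
#'
#' @param grey a greyscale \linkS4class{PlateImage} or numeric matrix,
#'   at least 3 x 3.
#' @return A nonnegative numeric matrix of gradient magnitudes, same
#'   dimensions as the input.
#' @export
sobelGradient <- function(grey) {
  m <- if (is(grey, "PlateImage")) {
    stopifnot(channels(grey) == "grey")
    grey@pixels
  } else as.matrix(grey)
  if (nrow(m) < 3L || ncol(m) < 3L)
    stop("sobelGradient: image must be at least 3 x 3", call. = FALSE)
  ## Gx = [-1 0 1; -2 0 2; -1 0 1], x increasing with column index
  gx <- (shiftPad(m, -1, 1) + 2 * shiftPad(m, 0, 1) + shiftPad(m, 1, 1)) -
        (shiftPad(m, -1, -1) + 2 * shiftPad(m, 0, -1) + shiftPad(m, 1, -1))
  gy <- (shiftPad(m, 1, -1) + 2 * shiftPad(m, 1, 0) + shiftPad(m, 1, 1)) -
        (shiftPad(m, -1, -1) + 2 * shiftPad(m, -1, 0) + shiftPad(m, -1, 1))
  sqrt(gx^2 + gy^2)
}

#' Mask of the steepest intensity gradients within a tile
#'
#' Estimates the gradient value below which \code{1 - keepFraction} of the
#' tile's pixels lie (nearest-rank percentile) and marks the pixels strictly
#' above that cutoff, i.e. the top 5\% of gradients at the default. Ties at
#' the cutoff resolve towards background, so an all-equal tile yields an
#' empty mask.
#'
#' @param gm gradient-magnitude matrix from \code{\link{sobelGradient}}.
#' @param tile one tile (a one-row data.frame or list with \code{x},
#'   \code{y}, \code{width}, \code{height}), clamped to the map.
#' @param keepFraction fraction of highest-gradient pixels to retain
#'   (default 0.05).
#' @return A logical matrix covering the clamped tile (TRUE = high gradient),
#'   with attributes \code{rows}/\code{cols} giving its 1-based position in
#'   the full map.
#' @export
gradientMask <- function(gm, tile, keepFraction = 0.05) {
  stopifnot(keepFraction > 0, keepFraction <= 1)
  rows <- tileRows(tile, nrow(gm)); cols <- tileCols(tile, ncol(gm))
  if (!length(rows) || !length(cols))
    stop("gradientMask: tile does not intersect the image", call. = FALSE)
  sub <- gm[rows, cols, drop = FALSE]
  cutoff <- nearestRank(as.vector(sub), 1 - keepFraction)
  out <- sub > cutoff
  attr(out, "rows") <- rows
  attr(out, "cols") <- cols
  out
}

#' First-pass local intensity threshold for one tile
#'
#' From the tile pixels flagged by the gradient mask, finds the intensity
#' below which the darkest \code{darkFraction} of masked pixels lie
#' (nearest-rank percentile) and re-thresholds the whole tile of the
#' original greyscale image at that cutoff: every tile pixel strictly above
#' it is classed as culture, so whole colonies (not just their high-gradient
#' edges) survive. Tiles with no masked pixels, and tiles whose cutoff falls
#' below the median intensity of the unmasked (background) pixels — meaning
#' the high-gradient pixels are plain background noise with no signal to
#' keep — return an all-background mask flagged with attribute
#' \code{flat = TRUE}.
#'
#' @param grey greyscale \linkS4class{PlateImage} or matrix.
#' @param tile one tile (as for \code{\link{gradientMask}}).
#' @param mask the tile's gradient mask from \code{\link{gradientMask}}.
#' @param darkFraction fraction of masked pixels allocated to background
#'   (default 0.33).
#' @return A logical matrix covering the clamped tile (TRUE = culture), with
#'   \code{rows}/\code{cols} position attributes and attribute \code{flat}.
#' @export
localThreshold <- function(grey, tile, mask, darkFraction = 0.33) {
  stopifnot(darkFraction > 0, darkFraction < 1)
  m <- if (is(grey, "PlateImage")) grey@pixels else as.matrix(grey)
  rows <- attr(mask, "rows"); cols <- attr(mask, "cols")
  if (is.null(rows)) { rows <- tileRows(tile, nrow(m)); cols <- tileCols(tile, ncol(m)) }
  sub <- m[rows, cols, drop = FALSE]
  flat <- !any(mask)
  if (!flat) {
    cutoff <- nearestRank(sub[mask], darkFraction)
    if (!all(mask)) flat <- cutoff < stats::median(sub[!mask])
  }
  if (flat) {
    out <- matrix(FALSE, nrow(sub), ncol(sub))
  } else {
    out <- sub > cutoff
  }
  attr(out, "rows") <- rows
  attr(out, "cols") <- cols
  attr(out, "flat") <- flat
  out
}

#' Whole-plate first-pass segmentation
#'
#' Runs the Sobel / top-gradient / darkest-fraction pipeline over every tile
#' and assembles plate-wide masks. Thresholding is per tile, which adapts
#' the sensitivity to the signal present in each grid position.
#'
#' @param grey greyscale \linkS4class{PlateImage} or matrix.
#' @param tiles tile data.frame from \code{\link{initTiles}}.
#' @param keepFraction top-gradient fraction retained per tile (default 0.05).
#' @param darkFraction masked-pixel fraction allocated to background
#'   (default 0.33).
#' @return A list with logical matrices \code{culture} (first-pass culture
#'   pixels) and \code{gradient} (top-gradient pixels, used later as the
#'   granularity map), plus \code{flatTiles}, the number of tiles with no
#'   gradient contrast.
#' @export
firstPass <- function(grey, tiles, keepFraction = 0.05, darkFraction = 0.33) {
  m <- if (is(grey, "PlateImage")) grey@pixels else as.matrix(grey)
  gm <- sobelGradient(m)
  culture <- matrix(FALSE, nrow(m), ncol(m))
  gradient <- matrix(FALSE, nrow(m), ncol(m))
  flat <- 0L
  for (i in seq_len(nrow(tiles))) {
    tile <- tiles[i, ]
    gmask <- gradientMask(gm, tile, keepFraction)
    cmask <- localThreshold(m, tile, gmask, darkFraction)
    rows <- attr(gmask, "rows"); cols <- attr(gmask, "cols")
    gradient[rows, cols] <- gradient[rows, cols] | gmask
    culture[rows, cols] <- culture[rows, cols] | cmask
    if (isTRUE(attr(cmask, "flat"))) flat <- flat + 1L
  }
  list(culture = culture, gradient = gradient, flatTiles = flat)
}
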