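## Pseudo-empty plate reconstruction: the lighting map is built from the
## plate itself, so no dummy-plate photograph is needed and reflective halos
## around cultures are partially removed along with the cultures.

## Pad a matrix by r rows/columns on every side, extrapolating linearly
## from the border (reflection through the edge value). Exact for linear
## ramps, so plate-scale lighting gradients survive smoothing undistorted
## right up to the image border; constant images stay constant.
padLinear <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(seq.int(r + 1L, 2L), seq_len(h), seq.int(h - 1L, h - r))
  out <- m[ri, , drop = FALSE]
  top <- seq_len(r); bot <- seq.int(r + h + 1L, r + h + r)
  out[top, ] <- 2 * rep(m[1L, ], each = r) - out[top, ]
  out[bot, ] <- 2 * rep(m[h, ], each = r) - out[bot, ]
  ci <- c(seq.int(r + 1L, 2L), seq_len(w), seq.int(w - 1L, w - r))
  out <- out[, ci, drop = FALSE]
  lef <- seq_len(r); rig <- seq.int(r + w + 1L, r + w + r)
  out[, lef] <- 2 * out[, rep(r + 1L, r)] - out[, lef]
  out[, rig] <- 2 * out[, rep(r + w, r)] - out[, rig]
  out
}

#' Gaussian smoothing of a greyscale raster
#'
#' Separable Gaussian blur (kernel truncated at 3 sigma). Borders are padded
#' by linear extrapolation from the edge, so flat fields are exactly
#' invariant and smooth lighting ramps are preserved undistorted up to the
#' border. Used to average out background texture before interpolating over
#' culture pixels.
#'
#' @param grey greyscale \linkS4class{PlateImage} or numeric matrix.
#' @param sigma Gaussian standard deviation in pixels, > 0. The pipeline
#'   default is a quarter of the tile width: strong enough to suppress pixel
#'   noise at colony scale while leaving plate-scale gradients intact.
#' @return A numeric matrix of the same dimensions.
#' @export
smoothPlate <- function(grey, sigma) {
  stopifnot(sigma > 0)
  m <- if (is(grey, "PlateImage")) grey@pixels else as.matrix(grey)
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  if (radius >= min(dim(m))) radius <- min(dim(m)) - 1L
  w <- stats::dnorm(seq.int(-radius, radius), sd = sigma)
  w <- w / sum(w)
  p <- padLinear(m, radius)
  pass <- function(x, vertical) {
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_along(w)) {
      off <- j - radius - 1L
      out <- out + w[j] * (if (vertical) shiftPad(x, off, 0L)
                           else shiftPad(x, 0L, off))
    }
    out
  }
  sm <- pass(pass(p, TRUE), FALSE)
  sm[radius + seq_len(nrow(m)), radius + seq_len(ncol(m)), drop = FALSE]
}

#' Background edge value beside a gap in a scan line
#'
#' Searches away from a gap (a run of cut-out culture pixels) along a scan
#' line for up to \code{searchDist} pixels and returns the darkest intensity
#' found. Taking the minimum skips over the bright reflective halos that
#' often ring a culture, so gaps are filled with true agar intensity. The
#' search is truncated at the image border; if no pixel exists on the
#' requested side, \code{NA} is returned and the caller falls back to the
#' opposite edge value.
#'
#' @param line numeric vector: one image row or column of the smoothed raster.
#' @param gapStart,gapEnd 1-based first and last indices of the gap run.
#' @param side \code{"before"} (lower indices) or \code{"after"}.
#' @param searchDist maximum number of pixels to search, >= 1. The pipeline
#'   uses half a tile dimension, roughly a typical culture radius.
#' @return The minimum intensity in the search window, or NA if empty.
#' @export
findEdgeValue <- function(line, gapStart, gapEnd,
                          side = c("before", "after"), searchDist) {
  side <- match.arg(side)
  stopifnot(searchDist >= 1)
  idx <- if (side == "before") {
    seq.int(max(1L, gapStart - searchDist), gapStart - 1L)
  } else {
    seq.int(gapEnd + 1L, min(length(line), gapEnd + searchDist))
  }
  if (gapStart == 1L && side == "before") return(NA_real_)
  if (gapEnd == length(line) && side == "after") return(NA_real_)
  min(line[idx])
}

#' Fill culture gaps along one scan axis
#'
#' Replaces every maximal run of culture pixels along the scan axis with a
#' linear ramp between the two background edge values found by
#' \code{\link{findEdgeValue}}. Observed (non-culture) pixels pass through
#' unchanged. Runs touching the border take both edge values from the single
#' available side (a constant fill); scan lines that are entirely culture
#' fall back to the plate-wide median of observed pixels.
#'
#' @param grey smoothed greyscale matrix (or \linkS4class{PlateImage}).
#' @param culture logical matrix of first-pass culture pixels.
#' @param axis \code{"horizontal"} (scan along rows) or \code{"vertical"}.
#' @param searchDist edge-value search distance in pixels.
#' @return A numeric matrix with gaps filled.
#' @export
fillGaps <- function(grey, culture, axis = c("horizontal", "vertical"),
                     searchDist) {
  axis <- match.arg(axis)
  m <- if (is(grey, "PlateImage")) grey@pixels else as.matrix(grey)
  stopifnot(identical(dim(m), dim(culture)))
  if (!any(culture)) return(m)
  searchDist <- max(1L, as.integer(round(searchDist)))
  plateMedian <- if (all(culture)) stats::median(m) else stats::median(m[!culture])
  if (axis == "vertical") {
    return(t(fillGaps(t(m), t(culture), "horizontal", searchDist)))
  }
  out <- m
  for (i in seq_len(nrow(m))) {
    maskLine <- culture[i, ]
    if (!any(maskLine)) next
    line <- m[i, ]
    runs <- rle(maskLine)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      a <- starts[k]; b <- ends[k]
      vL <- findEdgeValue(line, a, b, "before", searchDist)
      vR <- findEdgeValue(line, a, b, "after", searchDist)
      if (is.na(vL) && is.na(vR)) { vL <- vR <- plateMedian }
      else if (is.na(vL)) vL <- vR
      else if (is.na(vR)) vR <- vL
      g <- b - a + 1L
      out[i, a:b] <- vL + (vR - vL) * seq_len(g) / (g + 1)
    }
  }
  out
}

#' Build the pseudo-empty plate
#'
#' Reconstructs the plate as it would appear with no cultures: the greyscale
#' image is strongly smoothed, first-pass culture pixels are cut out and
#' filled by horizontal-scan interpolation (edge-value search distance half
#' a tile width); the same is done on a fresh smoothed copy with vertical
#' scanning (search distance half a tile height); and the two directional
#' fills are merged by taking the pixel-wise minimum. The minimum merge
#' guards against islands of bright pixels inside irregular cultures biasing
#' one directional fill upwards.
#'
#' @param grey greyscale \linkS4class{PlateImage} or matrix (the original,
#'   un-smoothed image).
#' @param culture logical matrix of first-pass culture pixels.
#' @param spec the plate's \linkS4class{GridSpec} (sets the search distances
#'   and the default smoothing scale).
#' @param sigma smoothing standard deviation; default \code{xDim/4}.
#' @return A \linkS4class{PseudoEmptyPlate}.
#' @export
buildPseudoEmpty <- function(grey, culture, spec, sigma = NULL) {
  m <- if (is(grey, "PlateImage")) grey@pixels else as.matrix(grey)
  stopifnot(identical(dim(m), dim(culture)))
  d <- tileDims(spec)
  if (is.null(sigma)) sigma <- d[["xDim"]] / 4
  sm <- smoothPlate(m, sigma)
  hFill <- fillGaps(sm, culture, "horizontal", d[["xDim"]] / 2)
  vFill <- fillGaps(sm, culture, "vertical", d[["yDim"]] / 2)
  pe <- pmin(hFill, vFill)
  new("PseudoEmptyPlate", pixels = clamp(pe, 0, 255), interpolated = culture)
}
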