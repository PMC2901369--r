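#' @import methods
NULL

#' PlateImage: a plate photograph raster
#'
#' Holds an 8-bit-scale pixel raster on \code{[0, 255]}, either greyscale
#' (a matrix) or RGB (a height x width x 3 array). Matrices are indexed
#' \code{[y, x]} with y the row from the top and x the column from the left,
#' both 0-based in the tile coordinate system exposed to users.
#'
#' @slot pixels numeric matrix (grey) or 3-d array (rgb), values in [0, 255].
#' @slot channels \code{"grey"} or \code{"rgb"}.
#' @export
setClass("PlateImage",
  representation(pixels = "array", channels = "character"))

setValidity("PlateImage", function(object) {
  p <- object@pixels
  ch <- object@channels
  if (!length(ch) == 1L || !ch %in% c("grey", "rgb"))
    return("channels must be 'grey' or 'rgb'")
  nd <- length(dim(p))
  if (ch == "grey" && nd != 2L) return("grey image must be a 2-d matrix")
  if (ch == "rgb" && !(nd == 3L && dim(p)[3] == 3L))
    return("rgb image must be a h x w x 3 array")
  if (any(dim(p)[1:2] < 1L)) return("width and height must be >= 1")
  if (anyNA(p)) return("pixels must not contain NA")
  if (min(p) < 0 || max(p) > 255) return("intensities must lie in [0, 255]")
  TRUE
})

#' Construct a PlateImage from a pixel array
#'
#' @param pixels numeric matrix (greyscale) or height x width x 3 array (RGB),
#'   intensities on \code{[0, 255]}.
#' @return A \linkS4class{PlateImage}.
#' @export
PlateImage <- function(pixels) {
  pixels <- as.array(pixels)
  ch <- if (length(dim(pixels)) == 3L) "rgb" else "grey"
  new("PlateImage", pixels = pixels, channels = ch)
}

#' @describeIn PlateImage-class pixel raster accessor
#' @param object,x a \code{PlateImage}
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname PlateImage-class
#' @export
setMethod("pixels", "PlateImage", function(object) object@pixels)

#' @describeIn PlateImage-class channel tag (\code{"grey"} or \code{"rgb"})
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' @rdname PlateImage-class
#' @export
setMethod("channels", "PlateImage", function(object) object@channels)

#' @rdname PlateImage-class
#' @export
setMethod("dim", "PlateImage", function(x) dim(x@pixels)[1:2])

#' @describeIn PlateImage-class image width in pixels
#' @export
setGeneric("imageWidth", function(object) standardGeneric("imageWidth"))

#' @rdname PlateImage-class
#' @export
setMethod("imageWidth", "PlateImage", function(object) dim(object@pixels)[2])

#' @describeIn PlateImage-class image height in pixels
#' @export
setGeneric("imageHeight", function(object) standardGeneric("imageHeight"))

#' @rdname PlateImage-class
#' @export
setMethod("imageHeight", "PlateImage", function(object) dim(object@pixels)[1])

setMethod("show", "PlateImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PlateImage (%s): %d x %d px, intensity range [%.1f, %.1f]\n",
              object@channels, d[2], d[1],
              min(object@pixels), max(object@pixels)))
})

#' GridSpec: culture-grid calibration for a plate image
#'
#' Records the array layout (rows x columns) and the user's estimates of the
#' centres of the top-left and bottom-right cultures, from which the tile
#' lattice is derived. Tile dimensions may be supplied explicitly (required
#' when a count is 1) or left \code{NA} to be derived from the corner-centre
#' spacing.
#'
#' @slot nRows,nCols grid dimensions (e.g. 16 x 24 for 384 format).
#' @slot xTL,yTL pixel coordinates of the centre of the top-left culture.
#' @slot xBR,yBR pixel coordinates of the centre of the bottom-right culture.
#' @slot xDim,yDim tile dimensions in pixels, or NA to derive.
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer",
                 xTL = "numeric", yTL = "numeric",
                 xBR = "numeric", yBR = "numeric",
                 xDim = "numeric", yDim = "numeric"))

setValidity("GridSpec", function(object) {
  if (object@nRows < 1L || object@nCols < 1L)
    return("nRows and nCols must be >= 1")
  if (object@xTL > object@xBR || object@yTL > object@yBR)
    return("top-left centre must not lie beyond bottom-right centre")
  if (object@nCols > 1L && object@xTL == object@xBR)
    return("xTL == xBR is only permitted when nCols == 1")
  if (object@nRows > 1L && object@yTL == object@yBR)
    return("yTL == yBR is only permitted when nRows == 1")
  if (!is.na(object@xDim) && object@xDim <= 0) return("xDim must be > 0")
  if (!is.na(object@yDim) && object@yDim <= 0) return("yDim must be > 0")
  if (object@nCols == 1L && is.na(object@xDim))
    return("xDim must be supplied when nCols == 1")
  if (object@nRows == 1L && is.na(object@yDim))
    return("yDim must be supplied when nRows == 1")
  TRUE
})

#' Construct a GridSpec
#'
#' @param nRows,nCols number of culture rows and columns on the grid.
#' @param xTL,yTL centre of the top-left culture (pixels).
#' @param xBR,yBR centre of the bottom-right culture (pixels).
#' @param xDim,yDim tile width/height in pixels; \code{NA} (default) derives
#'   them from the corner-centre spacing when the corresponding count
#'   exceeds 1.
#' @return A \linkS4class{GridSpec}.
#' @examples
#' gridSpec(4, 4, 100, 50, 340, 290)
#' @export
gridSpec <- function(nRows, nCols, xTL, yTL, xBR, yBR,
                     xDim = NA_real_, yDim = NA_real_) {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      xTL = as.numeric(xTL), yTL = as.numeric(yTL),
      xBR = as.numeric(xBR), yBR = as.numeric(yBR),
      xDim = as.numeric(xDim), yDim = as.numeric(yDim))
}

#' @describeIn GridSpec-class number of grid rows
#' @param object a \code{GridSpec}
#' @export
setGeneric("nRows", function(object) standardGeneric("nRows"))

#' @rdname GridSpec-class
#' @export
setMethod("nRows", "GridSpec", function(object) object@nRows)

#' @describeIn GridSpec-class number of grid columns
#' @export
setGeneric("nCols", function(object) standardGeneric("nCols"))

#' @rdname GridSpec-class
#' @export
setMethod("nCols", "GridSpec", function(object) object@nCols)

setMethod("show", "GridSpec", function(object) {
  d <- tileDims(object)
  cat(sprintf(
    "GridSpec: %d x %d grid, TL centre (%.1f, %.1f), BR centre (%.1f, %.1f), tile %.1f x %.1f px\n",
    object@nRows, object@nCols, object@xTL, object@yTL,
    object@xBR, object@yBR, d[["xDim"]], d[["yDim"]]))
})

#' PseudoEmptyPlate: reconstructed culture-free plate
#'
#' The best estimate of how the agar plate would photograph with no cultures:
#' the strongly smoothed greyscale image with first-pass culture pixels cut
#' out and replaced by directional linear interpolation from nearby dark edge
#' values. Serves as the lighting map for gradient correction.
#'
#' @slot pixels greyscale raster, same dimensions as the source image.
#' @slot interpolated logical matrix; TRUE where the value was interpolated
#'   (i.e. inside a first-pass culture region).
#' @export
setClass("PseudoEmptyPlate",
  representation(pixels = "matrix", interpolated = "matrix"))

setValidity("PseudoEmptyPlate", function(object) {
  if (!identical(dim(object@pixels), dim(object@interpolated)))
    return("pixels and interpolated must have identical dimensions")
  if (!is.logical(object@interpolated)) return("interpolated must be logical")
  if (min(object@pixels) < 0 || max(object@pixels) > 255)
    return("intensities must lie in [0, 255]")
  TRUE
})

#' @rdname PseudoEmptyPlate-class
#' @param object a \code{PseudoEmptyPlate}
#' @export
setMethod("pixels", "PseudoEmptyPlate", function(object) object@pixels)

#' @describeIn PseudoEmptyPlate-class logical matrix of interpolated pixels
#' @export
setGeneric("interpolated", function(object) standardGeneric("interpolated"))

#' @rdname PseudoEmptyPlate-class
#' @export
setMethod("interpolated", "PseudoEmptyPlate",
          function(object) object@interpolated)

setMethod("show", "PseudoEmptyPlate", function(object) {
  cat(sprintf("PseudoEmptyPlate: %d x %d px, %.1f%% interpolated\n",
              ncol(object@pixels), nrow(object@pixels),
              100 * mean(object@interpolated)))
})

#' CorrectionMap: per-pixel lighting-correction ratios
#'
#' The ratio map that regresses every pixel of the pseudo-empty plate back
#' towards the median agar intensity: ratio = iMed / pseudo-empty intensity,
#' floored and clipped to guard against degenerate pixels. Applying it to
#' the original image removes the lighting gradient.
#'
#' @slot ratios positive real matrix, same dimensions as the image.
#' @slot iMed median background intensity of the plate.
#' @slot nClipped number of ratios clipped to the allowed range.
#' @export
setClass("CorrectionMap",
  representation(ratios = "matrix", iMed = "numeric", nClipped = "integer"))

setValidity("CorrectionMap", function(object) {
  if (any(!is.finite(object@ratios))) return("ratios must be finite")
  if (min(object@ratios) <= 0) return("ratios must be > 0")
  if (object@iMed <= 0) return("iMed must be > 0")
  TRUE
})

#' @describeIn CorrectionMap-class ratio raster accessor
#' @param object a \code{CorrectionMap}
#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))

#' @rdname CorrectionMap-class
#' @export
setMethod("ratios", "CorrectionMap", function(object) object@ratios)

#' @describeIn CorrectionMap-class median background intensity
#' @export
setGeneric("medianIntensity", function(object) standardGeneric("medianIntensity"))

#' @rdname CorrectionMap-class
#' @export
setMethod("medianIntensity", "CorrectionMap", function(object) object@iMed)

setMethod("show", "CorrectionMap", function(object) {
  cat(sprintf(
    "CorrectionMap: %d x %d px, iMed = %.2f, ratio range [%.3f, %.3f], %d clipped\n",
    ncol(object@ratios), nrow(object@ratios), object@iMed,
    min(object@ratios), max(object@ratios), object@nClipped))
})

#' IntensityHistogram: binned pixel intensities for mixture fitting
#'
#' Integer-binned counts over intensity bins 0..255, built from the pixels
#' inside the grid bounding box of a corrected greyscale image. The saturated
#' bins 0 and 255 are excluded from the mixture fit (their original counts
#' are retained for reporting).
#'
#' @slot counts integer vector of length 256 (bins 0..255).
#' @slot nTotal total pixel count in the bounding box.
#' @export
setClass("IntensityHistogram",
  representation(counts = "integer", nTotal = "integer"))

setValidity("IntensityHistogram", function(object) {
  if (length(object@counts) != 256L) return("counts must have length 256")
  if (any(object@counts < 0L)) return("counts must be nonnegative")
  if (sum(object@counts) != object@nTotal)
    return("counts must sum to nTotal")
  TRUE
})

#' @describeIn IntensityHistogram-class bin counts (length 256, bins 0..255)
#' @param object an \code{IntensityHistogram}
#' @export
setGeneric("histCounts", function(object) standardGeneric("histCounts"))

#' @rdname IntensityHistogram-class
#' @export
setMethod("histCounts", "IntensityHistogram", function(object) object@counts)

setMethod("show", "IntensityHistogram", function(object) {
  occ <- which(object@counts > 0L) - 1L
  cat(sprintf("IntensityHistogram: %d pixels, occupied bins %d..%d\n",
              object@nTotal, min(occ), max(occ)))
})

#' MixtureFit: two-component Gaussian intensity model
#'
#' Maximum-likelihood fit of the unnormalised two-Gaussian model
#' \deqn{g(x) = \theta e^{-(x-\mu_1)^2/2\sigma_1^2} + e^{-(x-\mu_2)^2/2\sigma_2^2}}
#' to a plate intensity histogram, where \eqn{\theta} is the ratio of the
#' two peak heights. \code{mu1 < mu2} by convention (the ordering is
#' positional; agar is usually, but not necessarily, component 1). The
#' segmentation threshold \code{xThresh} is the highest-intensity
#' intersection of the two component curves.
#'
#' @slot mu1,mu2 component means (intensities), mu1 < mu2.
#' @slot sigma1,sigma2 component standard deviations, > 0.
#' @slot theta peak-height ratio of component 1 to component 2, > 0.
#' @slot loglik maximised log-likelihood.
#' @slot llSingle maximised log-likelihood of a single-Gaussian fit to the
#'   same histogram; the gap to \code{loglik} measures how much evidence the
#'   histogram carries for a second (culture) population.
#' @slot xThresh segmentation threshold intensity in [0, 255].
#' @export
setClass("MixtureFit",
  representation(mu1 = "numeric", mu2 = "numeric",
                 sigma1 = "numeric", sigma2 = "numeric",
                 theta = "numeric", loglik = "numeric",
                 llSingle = "numeric", xThresh = "numeric"))

setValidity("MixtureFit", function(object) {
  if (object@mu1 > object@mu2) return("mu1 must be <= mu2")
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    return("sigmas must be > 0")
  if (object@theta <= 0) return("theta must be > 0")
  if (!is.na(object@xThresh) &&
      (object@xThresh < 0 || object@xThresh > 255))
    return("xThresh must lie in [0, 255]")
  TRUE
})

#' Construct a MixtureFit from explicit parameters
#'
#' Mainly useful for evaluating \code{\link{mixtureDensity}} and
#' \code{\link{solveThreshold}} at chosen parameter values.
#'
#' @param mu1,mu2 component means; reordered so that mu1 < mu2.
#' @param sigma1,sigma2 component standard deviations.
#' @param theta peak-height ratio (component 1 peak / component 2 peak).
#' @param loglik optional log-likelihood.
#' @param llSingle optional single-Gaussian log-likelihood.
#' @param xThresh optional threshold; NA if not yet solved.
#' @return A \linkS4class{MixtureFit}.
#' @export
mixtureFit <- function(mu1, mu2, sigma1, sigma2, theta,
                       loglik = NA_real_, llSingle = NA_real_,
                       xThresh = NA_real_) {
  if (mu1 > mu2) {  # enforce positional ordering, swapping the component roles
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    tmp <- sigma1; sigma1 <- sigma2; sigma2 <- tmp
    theta <- 1 / theta
  }
  new("MixtureFit", mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
      theta = theta, loglik = loglik, llSingle = llSingle,
      xThresh = xThresh)
}

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(
    "MixtureFit: mu = (%.2f, %.2f), sigma = (%.2f, %.2f), theta = %.3g\n",
    object@mu1, object@mu2, object@sigma1, object@sigma2, object@theta))
  cat(sprintf("  loglik = %.2f, threshold = %.3f\n",
              object@loglik, object@xThresh))
})

#' @describeIn MixtureFit-class segmentation threshold intensity
#' @param object a \code{MixtureFit}
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))

#' @rdname MixtureFit-class
#' @export
setMethod("threshold", "MixtureFit", function(object) object@xThresh)

#' LogisticFit: logistic growth model fit for one culture
#'
#' Parameters of the logistic population model
#' \deqn{G(t) = \frac{K G_0 e^{rt}}{K + G_0 (e^{rt} - 1)}}
#' fitted to a (time, density) timecourse: \code{g0} the inoculum density
#' G(0), \code{k} the carrying capacity K and \code{r} the growth rate
#' (per day).
#'
#' @slot g0 inoculum density, > 0.
#' @slot k carrying capacity, >= g0.
#' @slot r growth rate per day, >= 0.
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical optimiser status.
#' @slot noGrowth TRUE when the series carried no growth signal.
#' @export
setClass("LogisticFit",
  representation(g0 = "numeric", k = "numeric", r = "numeric",
                 rss = "numeric", converged = "logical",
                 noGrowth = "logical"))

setValidity("LogisticFit", function(object) {
  if (object@g0 <= 0 || object@k <= 0) return("g0 and k must be > 0")
  if (object@r < 0) return("r must be >= 0")
  if (object@g0 > object@k * (1 + 1e-8)) return("g0 must not exceed k")
  TRUE
})

#' Construct a LogisticFit from explicit parameters
#'
#' @param g0 inoculum density G(0).
#' @param k carrying capacity K.
#' @param r growth rate per day.
#' @param rss residual sum of squares (NA if not from a fit).
#' @param converged optimiser convergence flag.
#' @param noGrowth no-growth-signal flag.
#' @return A \linkS4class{LogisticFit}.
#' @export
logisticFit <- function(g0, k, r, rss = NA_real_, converged = TRUE,
                        noGrowth = FALSE) {
  new("LogisticFit", g0 = unname(g0), k = unname(k), r = unname(r),
      rss = unname(rss), converged = converged, noGrowth = noGrowth)
}

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf(
    "LogisticFit: G0 = %.4g, K = %.4g, r = %.4g /day (rss %.4g, %s%s)\n",
    object@g0, object@k, object@r, object@rss,
    if (object@converged) "converged" else "NOT converged",
    if (object@noGrowth) ", no growth" else ""))
})

#' @describeIn LogisticFit-class named parameter vector (g0, k, r)
#' @param object a \code{LogisticFit}
#' @export
setGeneric("growthParams", function(object) standardGeneric("growthParams"))

#' @rdname LogisticFit-class
#' @export
setMethod("growthParams", "LogisticFit", function(object)
  c(g0 = object@g0, k = object@k, r = object@r))
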