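## Lighting-gradient correction: regress every pixel towards the median
## background intensity using the pseudo-empty plate as the lighting map.

#' Median background intensity of the plate
#'
#' Cuts the user-estimated area containing the growing spots (the grid
#' bounding box) out of the pseudo-empty plate and returns its median pixel
#' intensity, the regression target for lighting correction.
#'
#' @param pe a \linkS4class{PseudoEmptyPlate}.
#' @param spec the plate's \linkS4class{GridSpec}.
#' @return Median background intensity (scalar).
#' @export
medianBackground <- function(pe, spec) {
  stopifnot(is(pe, "PseudoEmptyPlate"))
  box <- gridBBox(spec, dim(pe@pixels))
  stats::median(pe@pixels[box$rows, box$cols])
}

#' Build the lighting-correction ratio map
#'
#' For each pixel computes the ratio \code{iMed / I_PE}, where \code{I_PE}
#' is the pseudo-empty intensity and \code{iMed} the median background
#' intensity: multiplying the original image by this map regresses the
#' background towards \code{iMed}, flattening the lighting gradient.
#' Pseudo-empty intensities are floored at 1 intensity unit and the ratios
#' clipped to \code{[0.2, 5]} so that near-black degenerate pixels cannot
#' produce unbounded corrections; the number of clipped pixels is recorded.
#'
#' @param pe a \linkS4class{PseudoEmptyPlate}.
#' @param iMed median background intensity, > 0 (from
#'   \code{\link{medianBackground}}).
#' @param clipRange allowed ratio range (default \code{c(0.2, 5)}).
#' @return A \linkS4class{CorrectionMap}.
#' @export
buildCorrection <- function(pe, iMed, clipRange = c(0.2, 5)) {
  stopifnot(is(pe, "PseudoEmptyPlate"), iMed > 0)
  raw <- iMed / pmax(pe@pixels, 1)
  ratios <- clamp(raw, clipRange[1], clipRange[2])
  new("CorrectionMap", ratios = ratios, iMed = iMed,
      nClipped = sum(raw < clipRange[1] | raw > clipRange[2]))
}

#' Apply lighting correction to an image
#'
#' Scales each pixel to \code{ratio * intensity}, capping at 255. For RGB
#' images the greyscale-derived ratio is applied identically to all three
#' channels so colour measurements remain comparable across the plate. The
#' correction is monotone per pixel: it never reorders two pixels sharing a
#' ratio. The count of saturated (capped) pixels is attached as attribute
#' \code{nSaturated} — a quality warning, since the method assumes
#' non-saturated source images.
#'
#' @param img a \linkS4class{PlateImage} (grey or RGB).
#' @param map a \linkS4class{CorrectionMap} of matching dimensions.
#' @return A corrected \linkS4class{PlateImage} of the same channel type.
#' @export
applyCorrection <- function(img, map) {
  stopifnot(is(img, "PlateImage"), is(map, "CorrectionMap"))
  p <- img@pixels
  if (!identical(dim(p)[1:2], dim(map@ratios)))
    stop("image and correction map dimensions differ", call. = FALSE)
  r <- if (img@channels == "rgb") array(rep(map@ratios, 3L), dim = dim(p))
       else map@ratios
  scaled <- r * p
  out <- PlateImage(pmin(scaled, 255))
  attr(out@pixels, "nSaturated") <- sum(scaled > 255)
  out
}
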