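## Seeded synthetic plate-image generator. Emulates the phenomenology the
## pipeline must cope with — smooth multiplicative lighting gradients, agar
## noise, colonies from faint irregular spots to dense opaque discs,
## reflective halos and plate-wall glare — with exact ground truth, so every
## upstream contract can be tested against known answers.

#' Default colony layout for a synthetic plate
#'
#' One row per grid position (row-major) describing the colony rendered
#' there. Colonies are brighter than agar, with peak contrast proportional
#' to \code{density} (a dense opaque culture at density 1, a near-invisible
#' dilute spot near 0).
#'
#' @param spec a \linkS4class{GridSpec}.
#' @param present logical, recycled over positions.
#' @param density density parameter in [0, 1], recycled.
#' @param radius nominal colony radius in pixels, recycled; default 30\% of
#'   the smaller tile dimension.
#' @param morphology \code{"disc"} (smooth opaque disc, pinned-style) or
#'   \code{"spot"} (union of jittered sub-spots, the irregular morphology of
#'   dilute spotted cultures), recycled.
#' @return A data.frame with columns row, col, present, density, radius,
#'   morphology.
#' @export
colonyLayout <- function(spec, present = TRUE, density = 0.5, radius = NULL,
                         morphology = "disc") {
  d <- tileDims(spec)
  if (is.null(radius)) radius <- 0.3 * min(d)
  ij <- expand.grid(col = seq_len(spec@nCols) - 1L,
                    row = seq_len(spec@nRows) - 1L)
  n <- nrow(ij)
  data.frame(row = ij$row, col = ij$col,
             present = rep_len(present, n),
             density = rep_len(density, n),
             radius = rep_len(radius, n),
             morphology = rep_len(morphology, n),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic plate image
#'
#' Bundles everything \code{\link{generatePlate}} needs. Identical
#' specifications always render bit-identical images (the seed drives all
#' randomness).
#'
#' @param spec a \linkS4class{GridSpec} (also written alongside generated
#'   plates so the pipeline can consume them directly).
#' @param agarLevel base agar intensity (default 120 of 255, a typical
#'   mid-grey agar under diffuse light).
#' @param gradient multiplicative lighting field: \code{list(type = "none")},
#'   \code{list(type = "linear", direction = "x"|"y"|"diag", minFactor,
#'   maxFactor)} or \code{list(type = "radial", minFactor)} (brightest at the
#'   image centre, dimming to \code{minFactor} at the corners). Factors must
#'   lie in [0.5, 1.5].
#' @param colonies data.frame from \code{\link{colonyLayout}}.
#' @param contrast peak intensity added by a density-1 colony (default 90).
#' @param haloAmplitude peak intensity of the reflective ring around each
#'   colony (default 0 = no halos).
#' @param glareWalls add bright glare bands along the image borders.
#' @param noiseSigma Gaussian pixel-noise standard deviation (default 2).
#' @param colonyTint per-channel multipliers for the colony signal, giving
#'   cultures a cream cast against neutral agar.
#' @param seed RNG seed.
#' @return A list of class \code{"synthPlateSpec"}.
#' @export
synthPlateSpec <- function(spec, agarLevel = 120,
                           gradient = list(type = "none"),
                           colonies = colonyLayout(spec),
                           contrast = 90, haloAmplitude = 0,
                           glareWalls = FALSE, noiseSigma = 2,
                           colonyTint = c(1, 0.97, 0.85), seed = 1L) {
  stopifnot(is(spec, "GridSpec"))
  if (gradient$type != "none") {
    f <- c(gradient$minFactor,
           if (!is.null(gradient$maxFactor)) gradient$maxFactor else 1)
    if (any(f < 0.5 | f > 1.5))
      stop("gradient factors must lie in [0.5, 1.5]", call. = FALSE)
  }
  structure(list(spec = spec, agarLevel = agarLevel, gradient = gradient,
                 colonies = colonies, contrast = contrast,
                 haloAmplitude = haloAmplitude, glareWalls = glareWalls,
                 noiseSigma = noiseSigma, colonyTint = colonyTint,
                 seed = as.integer(seed)),
            class = "synthPlateSpec")
}

## Multiplicative lighting field for an h x w image.
gradientField <- function(gradient, h, w) {
  if (gradient$type == "none") return(matrix(1, h, w))
  if (gradient$type == "linear") {
    ux <- if (w > 1) (seq_len(w) - 1) / (w - 1) else 0.5
    uy <- if (h > 1) (seq_len(h) - 1) / (h - 1) else 0.5
    u <- switch(gradient$direction,
                x = matrix(ux, h, w, byrow = TRUE),
                y = matrix(uy, h, w),
                diag = (matrix(ux, h, w, byrow = TRUE) + matrix(uy, h, w)) / 2,
                stop("unknown gradient direction"))
    gradient$minFactor + (gradient$maxFactor - gradient$minFactor) * u
  } else if (gradient$type == "radial") {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    dy <- matrix(seq_len(h) - cy, h, w)
    dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
    d <- sqrt(dx^2 + dy^2)
    1 - (1 - gradient$minFactor) * d / max(d)
  } else stop("unknown gradient type: ", gradient$type)
}

## Render one colony's unit profile (values in [0,1]) into the h x w frame.
## Returns list(profile, mask): mask is the ground-truth footprint.
colonyProfile <- function(cx, cy, radius, morphology, h, w) {
  e <- 1.5   # edge roll-off half-width in pixels
  ext <- ceiling(radius + 4 * e)
  rows <- seq.int(max(1, floor(cy - ext)), min(h, ceiling(cy + ext)))
  cols <- seq.int(max(1, floor(cx - ext)), min(w, ceiling(cx + ext)))
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  rr <- sqrt(dx^2 + dy^2)
  if (morphology == "disc") {
    p <- ifelse(rr <= radius - e, 1,
                ifelse(rr >= radius + e, 0,
                       0.5 * (1 + cos(pi * (rr - radius + e) / (2 * e)))))
    mask <- rr <= radius
  } else {  # irregular spotted culture: union of jittered Gaussian sub-spots
    nsub <- sample(5:30, 1)
    sx <- stats::runif(nsub, -0.7, 0.7) * radius
    sy <- stats::runif(nsub, -0.7, 0.7) * radius
    ss <- stats::runif(nsub, radius / 6, radius / 3)
    amp <- stats::runif(nsub, 0.5, 1)
    p <- matrix(0, length(rows), length(cols))
    for (i in seq_len(nsub))
      p <- p + amp[i] * exp(-((dx - sx[i])^2 + (dy - sy[i])^2) / (2 * ss[i]^2))
    p <- pmin(p, 1)
    mask <- p >= 0.2
  }
  list(rows = rows, cols = cols, profile = p, mask = mask)
}

#' Render a synthetic plate image with ground truth
#'
#' Builds the image as
#' \code{(agar + colony signal + halos + glare) * gradient + noise},
#' clipped to [0, 255], and returns it together with a ground-truth sidecar:
#' a disjoint per-position label raster, per-position true areas and true
#' integrated densities (the rendered colony signal summed over the
#' footprint, before gradient and noise), and the true background field
#' (agar times gradient).
#'
#' @param s a \code{\link{synthPlateSpec}}.
#' @return A list with elements \code{image} (RGB
#'   \linkS4class{PlateImage}), \code{grey} (the pre-tint greyscale signal
#'   as rendered), \code{truth} (list: \code{labels} integer matrix,
#'   \code{positions} data.frame with trueArea/trueDensity, \code{background}
#'   matrix, \code{field} matrix) and \code{spec} (the
#'   \linkS4class{GridSpec}).
#' @export
generatePlate <- function(s) {
  stopifnot(inherits(s, "synthPlateSpec"))
  spec <- s$spec
  d <- tileDims(spec)
  if (any(s$colonies$radius > min(d)))
    stop("colony radius exceeds a tile dimension: colonies would overlap ",
         "tile boundaries beyond half a tile", call. = FALSE)
  w <- as.integer(roundHalfAway(spec@xTL + spec@xBR))
  h <- as.integer(roundHalfAway(spec@yTL + spec@yBR))
  withSeed(s$seed, {
    add <- matrix(0, h, w)
    labels <- matrix(0L, h, w)
    cols <- s$colonies
    cols$cx <- spec@xTL + cols$col * d[["xDim"]]
    cols$cy <- spec@yTL + cols$row * d[["yDim"]]
    cols$trueArea <- 0L
    cols$trueDensity <- 0
    for (i in seq_len(nrow(cols))) {
      if (!cols$present[i] || cols$density[i] <= 0) next
      pr <- colonyProfile(cols$cx[i], cols$cy[i], cols$radius[i],
                          cols$morphology[i], h, w)
      amp <- cols$density[i] * s$contrast
      add[pr$rows, pr$cols] <- add[pr$rows, pr$cols] + amp * pr$profile
      lab <- labels[pr$rows, pr$cols]
      claim <- pr$mask & lab == 0L
      lab[claim] <- i
      labels[pr$rows, pr$cols] <- lab
      cols$trueArea[i] <- sum(claim)
      cols$trueDensity[i] <- sum(amp * pr$profile[claim])
    }
    halo <- matrix(0, h, w)
    if (s$haloAmplitude > 0) {
      for (i in seq_len(nrow(cols))) {
        if (!cols$present[i] || cols$density[i] <= 0) next
        R <- cols$radius[i]
        ext <- ceiling(2.2 * R)
        rows <- seq.int(max(1, floor(cols$cy[i] - ext)),
                        min(h, ceiling(cols$cy[i] + ext)))
        cc <- seq.int(max(1, floor(cols$cx[i] - ext)),
                      min(w, ceiling(cols$cx[i] + ext)))
        dy <- matrix(rows - cols$cy[i], length(rows), length(cc))
        dx <- matrix(cc - cols$cx[i], length(rows), length(cc), byrow = TRUE)
        rr <- sqrt(dx^2 + dy^2)
        ring <- s$haloAmplitude * exp(-((rr - 1.4 * R) / (0.25 * R))^2)
        ring[rr <= R] <- 0
        halo[rows, cc] <- pmax(halo[rows, cc], ring)
      }
    }
    glare <- matrix(0, h, w)
    if (isTRUE(s$glareWalls)) {
      edist <- pmin(matrix(seq_len(h) - 1, h, w), matrix(h - seq_len(h), h, w),
                    matrix(seq_len(w) - 1, h, w, byrow = TRUE),
                    matrix(w - seq_len(w), h, w, byrow = TRUE))
      glare <- 60 * exp(-edist / 4)
    }
    field <- gradientField(s$gradient, h, w)
    noise <- matrix(stats::rnorm(h * w, 0, s$noiseSigma), h, w)
    base <- s$agarLevel + halo + glare
    grey <- clamp((base + add) * field + noise, 0, 255)
    rgb <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3)
      rgb[, , ch] <- clamp((base + add * s$colonyTint[ch]) * field + noise,
                           0, 255)
    list(image = PlateImage(rgb),
         grey = grey,
         truth = list(labels = labels, positions = cols,
                      background = s$agarLevel * field, field = field),
         spec = spec)
  })
}

#' Render a synthetic growth timecourse as a series of plates
#'
#' For each requested time, the density of each colony is set to
#' \eqn{G(t)/K} from its logistic growth parameters and a plate is rendered.
#' Disc colonies keep a fixed footprint with contrast tracking density, so
#' integrated colony signal is proportional to \eqn{G(t)}; spotted colonies
#' additionally grow their footprint with density. Each frame uses a
#' deterministic seed derived from the base seed.
#'
#' @param s a \code{\link{synthPlateSpec}} (its \code{colonies$density} is
#'   overridden per frame; \code{radius} gives the full-growth footprint).
#' @param fits a single \linkS4class{LogisticFit} (recycled) or a list, one
#'   per grid position in row-major order.
#' @param times observation times in days, increasing.
#' @return A list with \code{times} and \code{plates} (one
#'   \code{\link{generatePlate}} result per time).
#' @export
generateTimecourse <- function(s, fits, times) {
  stopifnot(inherits(s, "synthPlateSpec"), all(diff(times) > 0))
  n <- nrow(s$colonies)
  if (is(fits, "LogisticFit")) fits <- rep(list(fits), n)
  stopifnot(length(fits) == n)
  plates <- lapply(seq_along(times), function(ti) {
    si <- s
    dens <- vapply(seq_len(n), function(i)
      logisticDensity(times[ti], fits[[i]]) / fits[[i]]@k, numeric(1))
    dens[!si$colonies$present] <- 0
    si$colonies$density <- dens
    spot <- si$colonies$morphology == "spot"
    si$colonies$radius[spot] <-
      pmax(s$colonies$radius[spot] * sqrt(pmax(dens[spot], 0)), 2)
    si$seed <- s$seed + ti
    generatePlate(si)
  })
  list(times = times, plates = plates)
}
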