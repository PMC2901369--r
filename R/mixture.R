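## Plate-wide final segmentation. A two-component Gaussian mixture is fitted
## to the corrected image's intensity histogram by maximum likelihood and the
## plate is thresholded at the highest-intensity intersection of the two
## component curves — the intensity at which a pixel is equally likely to be
## culture or agar. Constraining the model to exactly two components forces
## every pixel into one of the two classes.

FIT_BINS <- 2:255   # histogram bins 1..254; saturated bins 0/255 are trimmed

#' Intensity histogram of the corrected plate
#'
#' Bins the corrected greyscale intensities inside the grid bounding box
#' into integer bins 0..255 (values rounded half away from zero). Bins 0 and
#' 255 are excluded from the mixture fit as saturation artefacts; their raw
#' counts remain available in the returned object.
#'
#' @param img corrected greyscale \linkS4class{PlateImage} or matrix.
#' @param spec the plate's \linkS4class{GridSpec}.
#' @return An \linkS4class{IntensityHistogram}.
#' @export
buildHistogram <- function(img, spec) {
  m <- if (is(img, "PlateImage")) img@pixels else as.matrix(img)
  box <- gridBBox(spec, dim(m))
  v <- clamp(roundHalfAway(m[box$rows, box$cols]), 0, 255)
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  new("IntensityHistogram", counts = as.integer(counts),
      nTotal = sum(counts))
}

#' Two-Gaussian mixture density (peak-height parameterisation)
#'
#' Evaluates \eqn{g(x) = \theta e^{-(x-\mu_1)^2/(2\sigma_1^2)} +
#' e^{-(x-\mu_2)^2/(2\sigma_2^2)}}: an unnormalised sum of two Gaussian
#' curves whose peak heights are in the ratio \eqn{\theta : 1}. For
#' likelihood use the curve is normalised over the fit bins 1..254.
#'
#' @param x intensity (vectorised).
#' @param fit a \linkS4class{MixtureFit}.
#' @param normalise if TRUE, divide by the sum of \code{g} over the fit bins
#'   so the result is a probability mass over bins (default FALSE).
#' @return Density value(s) at \code{x}.
#' @export
mixtureDensity <- function(x, fit, normalise = FALSE) {
  g <- fit@theta * exp(-(x - fit@mu1)^2 / (2 * fit@sigma1^2)) +
       exp(-(x - fit@mu2)^2 / (2 * fit@sigma2^2))
  if (normalise) {
    b <- FIT_BINS - 1
    z <- sum(fit@theta * exp(-(b - fit@mu1)^2 / (2 * fit@sigma1^2)) +
             exp(-(b - fit@mu2)^2 / (2 * fit@sigma2^2)))
    g <- g / z
  }
  g
}

## Negative log-likelihood of the histogram under the normalised mixture.
## par = (mu1, mu2, sigma1, sigma2, log(theta)).
mixNLL <- function(par, bins, counts) {
  mu <- par[1:2]; sg <- par[3:4]; th <- exp(par[5])
  g <- th * exp(-(bins - mu[1])^2 / (2 * sg[1]^2)) +
       exp(-(bins - mu[2])^2 / (2 * sg[2]^2))
  z <- sum(g)
  if (!is.finite(z) || z <= 0) return(1e12)
  occ <- counts > 0
  nll <- -sum(counts[occ] * (log(g[occ]) - log(z)))
  if (!is.finite(nll)) 1e12 else nll
}

## Maximised log-likelihood of a single Gaussian on the fit bins: the null
## model against which the second (culture) component is judged.
singleGaussLL <- function(bins, counts) {
  nllS <- function(p) {
    g <- exp(-(bins - p[1])^2 / (2 * p[2]^2))
    z <- sum(g)
    occ <- counts > 0
    v <- -sum(counts[occ] * (log(g[occ]) - log(z)))
    if (!is.finite(v)) 1e12 else v
  }
  mu <- sum(bins * counts) / sum(counts)
  sg <- sqrt(sum(counts * (bins - mu)^2) / sum(counts))
  -stats::optim(c(mu, max(sg, 0.6)), nllS, method = "L-BFGS-B",
                lower = c(1, 0.5), upper = c(254, 128))$value
}

## Method-of-moments style start: split the histogram at its weighted
## median and take per-side means/sds; theta from the implied peak heights.
momStart <- function(bins, counts) {
  cdf <- cumsum(counts) / sum(counts)
  split <- bins[which(cdf >= 0.5)[1]]
  lo <- bins <= split; hi <- !lo
  if (!any(hi)) { hi <- bins > split - 1; lo <- !hi }
  wmean <- function(b, c) sum(b * c) / max(sum(c), 1)
  wsd <- function(b, c, m) {
    s <- sqrt(sum(c * (b - m)^2) / max(sum(c), 1))
    max(s, 0.75)
  }
  m1 <- wmean(bins[lo], counts[lo]); s1 <- wsd(bins[lo], counts[lo], m1)
  m2 <- wmean(bins[hi], counts[hi]); s2 <- wsd(bins[hi], counts[hi], m2)
  if (m2 <= m1) m2 <- m1 + 1
  w1 <- sum(counts[lo]); w2 <- max(sum(counts[hi]), 1)
  th <- (w1 / s1) / (w2 / s2)   # peak height ~ weight / sigma
  c(m1, m2, s1, s2, log(clamp(th, 1e-4, 1e4)))
}

#' Fit the two-Gaussian mixture to an intensity histogram
#'
#' Maximises the log-likelihood \eqn{\sum_x PI[x] \log \hat g(x)} over
#' \eqn{(\mu_1, \sigma_1, \mu_2, \sigma_2, \theta)}, where \eqn{\hat g} is
#' the mixture normalised over the fit bins. Optimisation is a seeded
#' multi-start bounded search: a moments-based start plus random starts
#' drawn inside the bounds, each polished with L-BFGS-B, keeping the best.
#' Bounds: \eqn{\mu \in [1, 254]}, \eqn{\sigma \in [0.5, 128]},
#' \eqn{\theta \in [10^{-4}, 10^4]}. Components are ordered so that
#' \code{mu1 < mu2} afterwards. The same seed always returns an identical
#' fit. The segmentation threshold is solved and stored in the result.
#'
#' @param hist an \linkS4class{IntensityHistogram}.
#' @param seed RNG seed for the multi-start search (default 1).
#' @param nStarts number of random starts in addition to the moments start.
#' @return A \linkS4class{MixtureFit} with \code{xThresh} filled in.
#' @export
fitMixture <- function(hist, seed = 1L, nStarts = 24L) {
  stopifnot(is(hist, "IntensityHistogram"))
  counts <- hist@counts[FIT_BINS]
  bins <- FIT_BINS - 1
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied bins; ",
         "segmentation requires intensity contrast", call. = FALSE)
  lower <- c(1, 1, 0.5, 0.5, log(1e-4))
  upper <- c(254, 254, 128, 128, log(1e4))
  polish <- function(par) {
    stats::optim(clamp(par, lower, upper), mixNLL, method = "L-BFGS-B",
                 lower = lower, upper = upper, bins = bins, counts = counts,
                 control = list(maxit = 300))
  }
  occ <- bins[counts > 0]
  starts <- withSeed(seed, {
    lapply(seq_len(nStarts), function(i) {
      m <- sort(stats::runif(2, min(occ), max(occ)))
      c(m, stats::runif(2, 0.75, diff(range(occ)) / 2 + 1),
        stats::runif(1, log(0.01), log(100)))
    })
  })
  starts <- c(list(momStart(bins, counts)), starts)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(polish(s), error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("mixture fit failed from every start", call. = FALSE)
  p <- best$par
  fit <- mixtureFit(mu1 = p[1], mu2 = p[2], sigma1 = p[3], sigma2 = p[4],
                    theta = exp(p[5]), loglik = -best$value,
                    llSingle = singleGaussLL(bins, counts))
  fit@xThresh <- solveThreshold(fit)
  fit
}

#' Solve for the segmentation threshold intensity
#'
#' Finds where the two fitted component curves intersect, i.e. solves
#' \eqn{\theta e^{-(x-\mu_1)^2/(2\sigma_1^2)} = e^{-(x-\mu_2)^2/(2\sigma_2^2)}},
#' a quadratic in \eqn{x} (linear when the variances are equal). Among the
#' real roots, the highest-intensity intersection lying between the two
#' means is returned if one exists, otherwise the highest real root; when no
#' real root exists (nested near-identical components) the midpoint
#' \eqn{(\mu_1+\mu_2)/2} is returned with a warning. The result is the
#' intensity at which a pixel is equally probable under either component.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @return Threshold intensity, clamped to [0, 255].
#' @export
solveThreshold <- function(fit) {
  stopifnot(is(fit, "MixtureFit"))
  m1 <- fit@mu1; m2 <- fit@mu2
  s1 <- fit@sigma1; s2 <- fit@sigma2
  lt <- log(fit@theta)
  ## theta*exp(-(x-m1)^2/2s1^2) = exp(-(x-m2)^2/2s2^2)
  ## => a x^2 + b x + c = 0
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + lt
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  x <- if (!length(roots)) {
    warning("mixture components do not intersect; using midpoint threshold")
    (m1 + m2) / 2
  } else {
    inside <- roots[roots >= m1 & roots <= m2]
    if (length(inside)) max(inside) else max(roots)
  }
  clamp(x, 0, 255)
}

#' Segment the corrected plate with a fitted mixture
#'
#' Classifies every pixel as culture when its intensity exceeds the fitted
#' threshold. This is plate-wide and gradient-independent: after lighting
#' correction a single global threshold applies everywhere. On a blank plate
#' both components end up modelling the single agar population; such
#' degenerate fits are recognised by a likelihood-ratio comparison against
#' the single-Gaussian null: when the second component improves the
#' log-likelihood by less than \code{minEvidence} the histogram carries no
#' usable culture signal. An all-background mask is then returned with
#' attribute \code{noGrowth = TRUE} so callers can log "no growth detected".
#'
#' @param img corrected greyscale \linkS4class{PlateImage} or matrix.
#' @param fit a \linkS4class{MixtureFit} with \code{xThresh} set.
#' @param minEvidence log-likelihood gain below which the two-component fit
#'   is treated as a single population (default 50; blank plates typically
#'   gain under 10, a plate of barely visible cultures gains thousands).
#' @return Logical matrix (TRUE = culture) with attribute \code{noGrowth}.
#' @export
segmentPlate <- function(img, fit, minEvidence = 50) {
  m <- if (is(img, "PlateImage")) img@pixels else as.matrix(img)
  stopifnot(is(fit, "MixtureFit"))
  noGrowth <- is.finite(fit@llSingle) &&
    (fit@loglik - fit@llSingle) < minEvidence
  mask <- if (noGrowth) matrix(FALSE, nrow(m), ncol(m))
          else m > fit@xThresh
  attr(mask, "noGrowth") <- noGrowth
  mask
}
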