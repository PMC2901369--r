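test_that("histograms bin the grid bounding box with saturated bins trimmed", {
  spec <- gridSpec(2, 2, 20, 20, 60, 60)   # bbox 80 x 80
  h <- buildHistogram(matrix(100, 100, 100), spec)
  expect_equal(histCounts(h)[101], 6400L)
  expect_equal(sum(histCounts(h)), 6400L)

  two <- matrix(rep(c(60, 180), each = 3200), 80, 80)
  spec2 <- gridSpec(2, 2, 20, 20, 60, 60)   # bounding box = whole image
  h2 <- buildHistogram(two, spec2)
  expect_equal(histCounts(h2)[61], 3200L)
  expect_equal(histCounts(h2)[181], 3200L)

  # saturated pixels are counted but excluded from the fit bins
  sat <- matrix(c(rep(0, 100), rep(255, 50), rep(128, 6250)), 80, 80)
  h3 <- buildHistogram(sat, spec2)
  expect_equal(histCounts(h3)[1], 100L)
  expect_equal(histCounts(h3)[256], 50L)
  expect_equal(sum(histCounts(h3)), 6400L)
  expect_equal(sum(histCounts(h3)[2:255]), 6400L - 150L)
})

test_that("mixture density follows the peak-height parameterisation", {
  f <- mixtureFit(60, 200, 12, 18, 2)
  # direct formula oracle at arbitrary points
  g <- function(x) 2 * exp(-(x - 60)^2 / (2 * 144)) +
    exp(-(x - 200)^2 / (2 * 324))
  xs <- c(0, 47.3, 60, 128, 199.9, 255)
  expect_equal(mixtureDensity(xs, f), g(xs), tolerance = 1e-12)
  # peak-height readings for well-separated components
  expect_equal(mixtureDensity(60, f), 2, tolerance = 1e-6)
  expect_equal(mixtureDensity(200, f), 1, tolerance = 1e-6)
  # normalised version sums to one over the fit bins
  expect_equal(sum(mixtureDensity(1:254, f, normalise = TRUE)), 1,
               tolerance = 1e-12)
})

test_that("maximum-likelihood fit recovers known mixture parameters", {
  h <- sampledHistogram(80, 170, 8, 15, 0.8, n = 1e6, seed = 42)
  fit <- fitMixture(h, seed = 1)
  expect_lt(abs(fit@mu1 - 80), 1.0)
  expect_lt(abs(fit@mu2 - 170), 1.0)
  expect_lt(abs(fit@sigma1 - 8) / 8, 0.10)
  expect_lt(abs(fit@sigma2 - 15) / 15, 0.10)
  # theta consistent with the sampling ratio via peak heights:
  # theta = (w1 / sigma1) / (w2 / sigma2)
  expect_lt(abs(fit@theta - (0.8 / 8) / (0.2 / 15)) / 7.5, 0.10)

  # symmetric case: components mirror about 128
  hs <- sampledHistogram(64, 192, 10, 10, 0.5, n = 4e5, seed = 7)
  fs <- fitMixture(hs, seed = 2)
  expect_lt(abs((fs@mu1 + fs@mu2) / 2 - 128), 0.5)
  expect_lt(abs(fs@sigma1 - fs@sigma2), 1)

  # reproducibility: identical seed, identical fit
  expect_identical(fitMixture(h, seed = 9), fitMixture(h, seed = 9))

  # the fit never scores below the moments initialisation
  counts <- histCounts(h)[2:255]
  momLL <- -agarQuant:::mixNLL(agarQuant:::momStart(1:254, counts),
                               1:254, counts)
  expect_gte(fit@loglik, momLL)

  expect_error(fitMixture(buildHistogram(matrix(100, 50, 50),
                                         gridSpec(1, 1, 25, 25, 25, 25,
                                                  xDim = 40, yDim = 40))),
               "degenerate")
})

test_that("threshold solves the component-intersection quadratic", {
  # equal sigma, equal peaks: exact midpoint
  expect_equal(solveThreshold(mixtureFit(64, 192, 10, 10, 1)), 128)

  # general case: closed form agrees with a dense numerical scan
  f <- mixtureFit(50, 150, 10, 20, 1)
  xt <- solveThreshold(f)
  xs <- seq(50, 150, by = 1e-4)
  d1 <- f@theta * exp(-(xs - f@mu1)^2 / (2 * f@sigma1^2))
  d2 <- exp(-(xs - f@mu2)^2 / (2 * f@sigma2^2))
  expect_lt(abs(xt - xs[which.min(abs(d1 - d2))]), 1e-3)

  # equal-sigma, theta = 4: shift from midpoint is s^2 log(4) / (mu2 - mu1)
  s <- 12
  f4 <- mixtureFit(80, 180, s, s, 4)
  expect_equal(solveThreshold(f4), 130 + s^2 * log(4) / 100,
               tolerance = 1e-9)

  # component densities are equal at the threshold
  for (f in list(mixtureFit(50, 150, 10, 20, 1),
                 mixtureFit(90, 140, 5, 9, 30),
                 mixtureFit(30, 220, 18, 7, 0.2))) {
    xt <- solveThreshold(f)
    d1 <- f@theta * exp(-(xt - f@mu1)^2 / (2 * f@sigma1^2))
    d2 <- exp(-(xt - f@mu2)^2 / (2 * f@sigma2^2))
    expect_lt(abs(d1 - d2) / d2, 1e-6)
  }

  # nested identical components: midpoint fallback with a warning
  expect_warning(xm <- solveThreshold(mixtureFit(100, 100, 10, 10, 1)),
                 "midpoint")
  expect_equal(xm, 100)
})

test_that("fitted threshold is shift-equivariant", {
  h0 <- sampledHistogram(90, 160, 6, 10, 0.85, n = 2e5, seed = 3)
  h1 <- sampledHistogram(100, 170, 6, 10, 0.85, n = 2e5, seed = 3)
  t0 <- threshold(fitMixture(h0, seed = 4))
  t1 <- threshold(fitMixture(h1, seed = 4))
  expect_equal(t1 - t0, 10, tolerance = 0.5)
})

test_that("pixels at the threshold are equally probable under each component", {
  f <- fitMixture(sampledHistogram(100, 150, 8, 12, 0.9, n = 2e5, seed = 5),
                  seed = 6)
  xt <- threshold(f)
  # simulate pixels from the fitted mixture; near the threshold the two
  # components must contribute equally (posterior one half each)
  w1 <- f@theta * f@sigma1 / (f@theta * f@sigma1 + f@sigma2)
  n <- 4e5
  sim <- agarQuant:::withSeed(8, {
    n1 <- round(n * w1)
    list(c1 = stats::rnorm(n1, f@mu1, f@sigma1),
         c2 = stats::rnorm(n - n1, f@mu2, f@sigma2))
  })
  near1 <- sum(abs(sim$c1 - xt) < 1)
  near2 <- sum(abs(sim$c2 - xt) < 1)
  expect_lt(abs(near1 - near2) / sqrt(near1 + near2), 4)  # within MC error
})

test_that("segmentation finds faint colonies and flags blank plates", {
  spec <- stdGrid()
  # colony mean ~6 units above agar, noise sd 2: barely visible
  pl <- generatePlate(synthPlateSpec(spec,
          colonies = colonyLayout(spec, density = 6 / 90, radius = 10),
          noiseSigma = 2, seed = 17))
  grey <- toGreyscale(pl$image)
  fit <- fitMixture(buildHistogram(grey, spec), seed = 1)
  mask <- segmentPlate(grey, fit)
  for (i in seq_len(nrow(pl$truth$positions))) {
    foot <- pl$truth$labels == i
    expect_gte(sum(mask & foot) / sum(foot), 0.5)
  }

  blank <- generatePlate(synthPlateSpec(spec,
             colonies = colonyLayout(spec, present = FALSE),
             noiseSigma = 2, seed = 18))
  bgrey <- toGreyscale(blank$image)
  # nested components on a blank plate may not intersect (midpoint warning)
  bfit <- suppressWarnings(fitMixture(buildHistogram(bgrey, spec), seed = 1))
  bmask <- segmentPlate(bgrey, bfit)
  expect_true(attr(bmask, "noGrowth"))
  expect_false(any(bmask))
})
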