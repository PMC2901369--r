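# Shared fixture builders. Every fixture is generated in code under a fixed
# seed; the synthetic-plate generator provides ground truth for end-to-end
# checks.

# standard 4 x 6 grid on a 280 x 200 px plate, 40 px tiles
stdGrid <- function() gridSpec(4, 6, 40, 40, 240, 160)

# small 3 x 4 grid on a 200 x 160 px plate
smallGrid <- function() gridSpec(3, 4, 40, 40, 160, 120)

gradLinX <- function(lo = 0.8, hi = 1.2)
  list(type = "linear", direction = "x", minFactor = lo, maxFactor = hi)

gradDiag <- function(lo = 0.8, hi = 1.2)
  list(type = "linear", direction = "diag", minFactor = lo, maxFactor = hi)

# faint-spot study fixture: dilute spotted cultures (20% peak contrast)
# under a diagonal +/-20% lighting gradient — the regime where uncorrected
# segmentation loses dim-corner colonies
faintSpotPlate <- function(seed = 13)
  generatePlate(synthPlateSpec(stdGrid(), gradient = gradDiag(),
                               colonies = colonyLayout(stdGrid(),
                                                       density = 0.2,
                                                       radius = 10),
                               noiseSigma = 2, seed = seed))

# histogram sampled from a known two-Gaussian pixel population
sampledHistogram <- function(mu1, mu2, sigma1, sigma2, w1, n = 2e5,
                             seed = 1) {
  x <- agarQuant:::withSeed(seed, {
    n1 <- round(n * w1)
    c(stats::rnorm(n1, mu1, sigma1), stats::rnorm(n - n1, mu2, sigma2))
  })
  x <- pmin(pmax(round(x), 0), 255)
  counts <- tabulate(as.integer(x) + 1L, nbins = 256L)
  new("IntensityHistogram", counts = as.integer(counts),
      nTotal = sum(counts))
}

# binary mask of a 5 x 5 colony grid (18 x 18 colonies, pitch 20) uniformly
# translated by (dx, dy): emulates a misaligned plate photograph
translatedGridMask <- function(dx, dy, n = 160L) {
  m <- matrix(FALSE, n, n)
  for (gi in 0:4) for (gj in 0:4) {
    x0 <- 31L + gj * 20L + dx
    y0 <- 31L + gi * 20L + dy
    m[(y0 + 1):(y0 + 18), (x0 + 1):(x0 + 18)] <- TRUE
  }
  m
}

# centre tile of the translated-grid fixture
centreTile <- function() list(row = 2L, col = 2L, x = 70L, y = 70L,
                              width = 20L, height = 20L)
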