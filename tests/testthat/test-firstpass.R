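# independent 3x3 Sobel oracle for interior pixels (no border handling)
sobelOracle <- function(m) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # [dy, dx], x = col
  ky <- t(kx)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1)) {
    win <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    out[i, j] <- sqrt(sum(win * kx)^2 + sum(win * ky)^2)
  }
  out
}

rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

test_that("Sobel gradient matches direct convolution and its symmetries", {
  expect_true(all(sobelGradient(matrix(7, 5, 5)) == 0))

  # vertical step of height h: pixels flanking the step see magnitude 4h
  h <- 9
  step <- cbind(matrix(0, 6, 3), matrix(h, 6, 3))
  gm <- sobelGradient(step)
  expect_equal(gm[3, 3], 4 * h)
  expect_equal(gm[3, 4], 4 * h)
  expect_equal(gm[3, 2], 0)

  set.seed(11)
  m <- matrix(runif(110, 0, 255), 10, 11)
  gm <- sobelGradient(m)
  oracle <- sobelOracle(m)
  interior <- !is.na(oracle)
  expect_equal(gm[interior], oracle[interior], tolerance = 1e-12)

  # 90-degree rotation equivariance
  expect_equal(sobelGradient(rot90(m)), rot90(sobelGradient(m)),
               tolerance = 1e-12)

  expect_error(sobelGradient(matrix(0, 2, 5)), "3 x 3")
})

test_that("gradient mask keeps exactly the top keepFraction by nearest rank", {
  tile <- list(x = 0L, y = 0L, width = 10L, height = 10L)
  set.seed(5)
  gm <- matrix(sample(1:100), 10, 10)   # 100 distinct values
  mask <- gradientMask(gm, tile, 0.05)
  expect_equal(sum(mask), 5L)
  expect_setequal(gm[mask], 96:100)

  expect_equal(sum(gradientMask(matrix(3, 10, 10), tile)), 0L)

  # keepFraction = 1 retains everything except the minimum-tied set
  gm2 <- matrix(c(rep(1, 4), sample(2:97)), 10, 10)
  maskAll <- gradientMask(gm2, tile, 1)
  expect_equal(sum(maskAll), 96L)
  expect_true(all(gm2[!maskAll] == 1))
})

test_that("gradient mask retention is bounded for arbitrary tiles", {
  set.seed(23)
  for (rep in 1:10) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    gm <- matrix(sample(0:40, n1 * n2, replace = TRUE), n1, n2)
    keep <- runif(1, 0.02, 0.5)
    tile <- list(x = 0L, y = 0L, width = n2, height = n1)
    expect_lte(sum(gradientMask(gm, tile, keep)), ceiling(keep * n1 * n2))
  }
})

test_that("local threshold allocates the darkest masked fraction to background", {
  # 99 masked pixels with distinct intensities: cutoff = 33rd darkest.
  # As in real tiles the masked (high-gradient) pixels are the bright ones.
  set.seed(7)
  m <- matrix(sample(0:120, 121), 11, 11)
  tile <- list(x = 0L, y = 0L, width = 11L, height = 11L)
  mask <- m >= sort(as.vector(m))[23]   # the 99 brightest pixels
  attr(mask, "rows") <- 1:11; attr(mask, "cols") <- 1:11
  out <- localThreshold(m, tile, mask, 0.33)
  cutoff <- sort(m[mask])[ceiling(0.33 * 99)]
  expect_equal(sum(mask & !out), 33L)   # darkest 33 masked -> background
  expect_equal(unclass(out)[, ], m > cutoff, ignore_attr = TRUE)

  # uniform tile: no contrast, everything is background
  flatTile <- matrix(50, 8, 8)
  gmask <- gradientMask(sobelGradient(flatTile),
                        list(x = 0L, y = 0L, width = 8L, height = 8L))
  res <- localThreshold(flatTile, list(x = 0L, y = 0L, width = 8L, height = 8L),
                        gmask)
  expect_false(any(res))
  expect_true(attr(res, "flat"))
})

test_that("first pass recovers whole colonies, not just their edges", {
  # bright 9x9 colony (180) on dark agar (100) with a sharp edge
  set.seed(9)
  m <- matrix(100 + rnorm(900, 0, 1), 30, 30)
  m[11:19, 11:19] <- 180 + rnorm(81, 0, 1)
  tiles <- data.frame(row = 0L, col = 0L, x = 0L, y = 0L,
                      width = 30L, height = 30L)
  fp <- firstPass(m, tiles)
  expect_true(all(fp$culture[12:18, 12:18]))   # interior, not only edges
  expect_equal(fp$flatTiles, 0L)
})

test_that("first-pass culture recall exceeds 0.90 at contrast >= 10", {
  spec <- smallGrid()
  for (seed in c(9, 19)) {
    pl <- generatePlate(synthPlateSpec(spec,
            colonies = colonyLayout(spec, density = 10 / 90, radius = 10),
            noiseSigma = 2, seed = seed))
    fp <- firstPass(toGreyscale(pl$image), initTiles(spec))
    truth <- pl$truth$labels > 0
    expect_gt(sum(fp$culture & truth) / sum(truth), 0.90)
  }
})

test_that("empty noisy tiles retain almost nothing in the first pass", {
  spec <- smallGrid()
  pl <- generatePlate(synthPlateSpec(spec,
          colonies = colonyLayout(spec, present = FALSE),
          noiseSigma = 2, seed = 31))
  tiles <- initTiles(spec)
  fp <- firstPass(toGreyscale(pl$image), tiles)
  for (i in seq_len(nrow(tiles))) {
    rows <- agarQuant:::tileRows(tiles[i, ], nrow(fp$culture))
    cols <- agarQuant:::tileCols(tiles[i, ], ncol(fp$culture))
    expect_lt(mean(fp$culture[rows, cols]), 2 * 0.05)
  }
})
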