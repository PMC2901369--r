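# independent exhaustive-search oracle: box-minus-interior perimeter count,
# lexicographic (score, distance, dy, dx) selection
refineOracle <- function(tile, mask, search = 10L) {
  H <- nrow(mask); W <- ncol(mask)
  peri <- function(x, y, w, h) {
    box <- matrix(FALSE, H, W)
    rows <- intersect(seq.int(y + 1L, y + h), seq_len(H))
    cols <- intersect(seq.int(x + 1L, x + w), seq_len(W))
    box[rows, cols] <- TRUE
    inner <- matrix(FALSE, H, W)
    irows <- intersect(seq.int(y + 2L, y + h - 1L), seq_len(H))
    icols <- intersect(seq.int(x + 2L, x + w - 1L), seq_len(W))
    inner[irows, icols] <- TRUE
    sum(mask & box & !inner)
  }
  offs <- seq.int(-search, search - 1L)
  cand <- expand.grid(dx = offs, dy = offs)
  cand$score <- mapply(function(dx, dy)
    peri(tile$x + dx, tile$y + dy, tile$width, tile$height),
    cand$dx, cand$dy)
  best <- cand[order(cand$score, cand$dx^2 + cand$dy^2, cand$dy, cand$dx)[1], ]
  c(dx = best$dx, dy = best$dy)
}

test_that("tile refinement recovers whole-grid translations exactly", {
  for (off in list(c(0, 0), c(5, -3), c(-9, 2), c(9, 9), c(-9, -9))) {
    mask <- translatedGridMask(off[1], off[2])
    tile <- centreTile()
    ref <- refineTile(tile, mask)
    expect_equal(c(ref$x - tile$x, ref$y - tile$y), off)
  }

  # colony fully interior: stays put by the closest-offset tie-break
  m <- matrix(FALSE, 60, 60)
  m[26:34, 26:34] <- TRUE
  t0 <- list(x = 20L, y = 20L, width = 20L, height = 20L)
  r0 <- refineTile(t0, m)
  expect_equal(c(r0$x, r0$y), c(20L, 20L))

  # all-background: every offset ties at 0, (0, 0) wins
  rb <- refineTile(t0, matrix(FALSE, 60, 60))
  expect_equal(c(rb$x, rb$y), c(20L, 20L))
})

test_that("tile refinement matches an independent exhaustive search", {
  set.seed(33)
  for (rep in 1:6) {
    mask <- matrix(runif(80 * 80) < 0.2, 80, 80)
    tile <- list(x = sample(15:40, 1), y = sample(15:40, 1),
                 width = 18L, height = 22L)
    ref <- refineTile(tile, mask)
    oracle <- refineOracle(tile, mask)
    expect_equal(c(ref$x - tile$x, ref$y - tile$y), unname(oracle))
  }
})

test_that("tile measurements compute area, IOD and colour exactly", {
  corrected <- matrix(100, 40, 40)
  corrected[11:20, 11:20] <- 200
  mask <- corrected > 150
  grad <- matrix(FALSE, 40, 40)
  tile <- list(row = 0L, col = 0L, x = 5L, y = 5L, width = 25L, height = 25L)
  rec <- measureTile(tile, mask, corrected, NULL, grad, 100)
  expect_equal(rec$area, 100L)
  expect_equal(rec$iod, 100 * (200 - 100))
  expect_equal(rec$tile_iod, 10000)
  expect_equal(rec$granularity, 0L)

  # empty tile: zero area, NA colour
  t2 <- list(row = 0L, col = 1L, x = 0L, y = 25L, width = 10L, height = 10L)
  rec2 <- measureTile(t2, mask, corrected, NULL, grad, 100)
  expect_equal(rec2$area, 0L)
  expect_equal(rec2$iod, 0)
  expect_true(is.na(rec2$r_culture))

  # uniform culture colour is returned exactly
  rgb <- array(0, dim = c(40, 40, 3))
  rgb[, , 1] <- 30; rgb[, , 2] <- 200; rgb[, , 3] <- 40
  rec3 <- measureTile(tile, mask, corrected, PlateImage(rgb), grad, 100)
  expect_equal(c(rec3$r_culture, rec3$g_culture, rec3$b_culture),
               c(30, 200, 40))
  expect_equal(c(rec3$r_agar, rec3$g_agar, rec3$b_agar), c(30, 200, 40))

  # negative tile-total intensities clamp at zero
  dark <- matrix(50, 40, 40)
  rec4 <- measureTile(tile, mask, dark, NULL, grad, 100)
  expect_equal(rec4$tile_iod, 0)
})

test_that("plate quantification is row-major with accurate areas", {
  spec <- smallGrid()
  pl <- generatePlate(synthPlateSpec(spec,
          colonies = colonyLayout(spec, density = 0.6, radius = 10),
          noiseSigma = 2, seed = 3))
  res <- runImage(pl, pipelineConfig(spec, seed = 3))
  m <- res$measures
  expect_equal(nrow(m), 12L)
  expect_equal(m$row, rep(0:2, each = 4))
  expect_equal(m$col, rep(0:3, 3))
  expect_lt(abs(sum(m$area) - sum(pl$truth$positions$trueArea)) /
            sum(pl$truth$positions$trueArea), 0.10)
  # area equals the mask restricted to the refined tile (exact recount)
  fitMask <- NULL
  grey <- toGreyscale(pl$image)
  # recount one tile from scratch using the reported geometry
  i <- 6
  tile <- m[i, c("x", "y", "width", "height")]
  # reconstruct the mask exactly as the pipeline did
  fp <- firstPass(grey, initTiles(spec))
  pe <- buildPseudoEmpty(grey, fp$culture, spec)
  iMed <- medianBackground(pe, spec)
  corr <- applyCorrection(grey, buildCorrection(pe, iMed))
  fit <- fitMixture(buildHistogram(corr, spec), seed = 3)
  mask <- segmentPlate(corr, fit)
  rows <- agarQuant:::tileRows(tile, nrow(mask))
  cols <- agarQuant:::tileCols(tile, ncol(mask))
  expect_equal(m$area[i], sum(mask[rows, cols]))
  # edge flagging marks first/last grid rows and columns
  expect_equal(m$edge_flag, m$row %in% c(0, 2) | m$col %in% c(0, 3))
})

test_that("dense opaque discs are sized within five percent", {
  spec <- smallGrid()
  pl <- generatePlate(synthPlateSpec(spec,
          colonies = colonyLayout(spec, density = 1, radius = 14),
          noiseSigma = 2, seed = 21))
  m <- runImage(pl, pipelineConfig(spec, colour = FALSE, seed = 3))$measures
  relerr <- abs(m$area - pl$truth$positions$trueArea) /
    pl$truth$positions$trueArea
  expect_lt(max(relerr), 0.05)
})

test_that("IOD increases strictly with colony density at fixed footprint", {
  spec <- gridSpec(2, 2, 40, 40, 100, 100)
  dens <- seq(0.2, 0.9, length.out = 8)
  iods <- vapply(dens, function(d) {
    pl <- generatePlate(synthPlateSpec(spec,
            colonies = colonyLayout(spec, density = d, radius = 12),
            noiseSigma = 2, seed = 40))
    sum(runImage(pl, pipelineConfig(spec, colour = FALSE, seed = 3))$measures$iod)
  }, numeric(1))
  expect_equal(cor(iods, dens, method = "spearman"), 1)
})

test_that("measure tables are written tab-delimited with an image id", {
  spec <- smallGrid()
  pl <- generatePlate(synthPlateSpec(spec,
          colonies = colonyLayout(spec, density = 0.5), seed = 2))
  m <- runImage(pl, pipelineConfig(spec, seed = 1))$measures
  path <- withr::local_tempfile(fileext = ".dat")
  writeMeasures(m, path, imageId = "img7.png")
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 12L)
  expect_equal(unique(back$image_id), "img7.png")
  expect_named(back, c("image_id", "row", "col", "x", "y", "width", "height",
                       "area", "iod", "tile_iod", "granularity",
                       "r_culture", "g_culture", "b_culture",
                       "r_agar", "g_agar", "b_agar", "edge_flag"))
})
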