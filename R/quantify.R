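## Tile refinement and per-culture measurement. Tile positions are improved
## by brute-force search on the final segmentation mask, then every grid
## position is summarised: area, integrated optical density, tile IOD,
## granularity and mean culture/agar colour.

## Count mask-true pixels on the 1-pixel perimeter of a tile placed at
## (x, y), clamping to the image; out-of-image perimeter cells count 0.
perimeterCount <- function(mask, x, y, w, h) {
  H <- nrow(mask); W <- ncol(mask)
  rows <- seq.int(max(y + 1L, 1L), min(y + h, H))
  cols <- seq.int(max(x + 1L, 1L), min(x + w, W))
  if (!length(rows) || !length(cols) || rows[1] > rows[length(rows)] ||
      cols[1] > cols[length(cols)]) return(0L)
  top <- y + 1L; bot <- y + h; lef <- x + 1L; rig <- x + w
  n <- 0L
  if (top >= 1L && top <= H) n <- n + sum(mask[top, cols])
  if (bot >= 1L && bot <= H && bot != top) n <- n + sum(mask[bot, cols])
  innerRows <- rows[rows != top & rows != bot]
  if (length(innerRows)) {
    if (lef >= 1L && lef <= W) n <- n + sum(mask[innerRows, lef])
    if (rig >= 1L && rig <= W && rig != lef) n <- n + sum(mask[innerRows, rig])
  }
  n
}

#' Refine a tile location on the segmentation mask
#'
#' Brute-force search over a square lattice of offsets (the 20 x 20 window
#' \code{[-search, search-1]^2} at the default) for the placement that
#' minimises the number of culture pixels lying on the tile's 1-pixel
#' perimeter — a well-centred tile contains its culture without cutting
#' through it. Ties are broken by the smallest Euclidean offset, then
#' row-major offset order, so an already-optimal tile stays put. Tile
#' dimensions are never changed.
#'
#' @param tile one tile (one-row data.frame or list with \code{x}, \code{y},
#'   \code{width}, \code{height}).
#' @param mask logical segmentation mask (TRUE = culture).
#' @param search half-width of the search window in pixels (default 10).
#' @return The tile with updated \code{x}, \code{y}.
#' @export
refineTile <- function(tile, mask, search = 10L) {
  search <- as.integer(search)
  offs <- seq.int(-search, search - 1L)
  grid <- expand.grid(dx = offs, dy = offs)   # dx varies fastest: row-major in (dy, dx)
  score <- mapply(function(dx, dy)
    perimeterCount(mask, tile$x + dx, tile$y + dy, tile$width, tile$height),
    grid$dx, grid$dy)
  dist2 <- grid$dx^2 + grid$dy^2
  best <- order(score, dist2, grid$dy, grid$dx)[1]
  tile$x <- tile$x + grid$dx[best]
  tile$y <- tile$y + grid$dy[best]
  tile
}

#' Measure one culture tile
#'
#' Computes, over the (refined) tile: \code{area}, the culture pixel count;
#' \code{iod}, the sum of background-subtracted corrected intensities over
#' culture pixels (each contribution floored at 0); \code{tileIOD}, the
#' background-subtracted sum over all tile pixels (floored at 0), an
#' alternative density measure that also captures sub-threshold signal;
#' \code{granularity}, the count of tile pixels on the high-gradient map (a
#' texture/morphology measure); and the mean RGB triplets of culture and
#' agar pixels from the original image. Colour means are \code{NA} when the
#' corresponding pixel set is empty.
#'
#' @param tile one tile (refined), as for \code{\link{refineTile}}.
#' @param mask logical segmentation mask (TRUE = culture).
#' @param corrected corrected greyscale matrix or \linkS4class{PlateImage}.
#' @param original original RGB \linkS4class{PlateImage} (or NULL to skip
#'   colour measures).
#' @param gradMask logical high-gradient mask from \code{\link{firstPass}}.
#' @param iMed median background intensity.
#' @return A one-row data.frame of measurements.
#' @export
measureTile <- function(tile, mask, corrected, original, gradMask, iMed) {
  cm <- if (is(corrected, "PlateImage")) corrected@pixels else as.matrix(corrected)
  rows <- tileRows(tile, nrow(cm)); cols <- tileCols(tile, ncol(cm))
  sub <- cm[rows, cols, drop = FALSE]
  msub <- mask[rows, cols, drop = FALSE]
  gsub <- gradMask[rows, cols, drop = FALSE]
  area <- sum(msub)
  iod <- sum(pmax(sub[msub] - iMed, 0))
  tileIOD <- max(sum(sub - iMed), 0)
  gran <- sum(gsub)
  cultureRGB <- agarRGB <- rep(NA_real_, 3L)
  if (!is.null(original)) {
    op <- if (is(original, "PlateImage")) original@pixels else original
    if (length(dim(op)) == 3L) {
      for (ch in 1:3) {
        osub <- op[rows, cols, ch, drop = TRUE]
        if (area > 0) cultureRGB[ch] <- mean(osub[msub])
        if (any(!msub)) agarRGB[ch] <- mean(osub[!msub])
      }
    }
  }
  data.frame(row = tile$row, col = tile$col,
             x = tile$x, y = tile$y,
             width = tile$width, height = tile$height,
             area = area, iod = iod, tile_iod = tileIOD,
             granularity = gran,
             r_culture = cultureRGB[1], g_culture = cultureRGB[2],
             b_culture = cultureRGB[3],
             r_agar = agarRGB[1], g_agar = agarRGB[2], b_agar = agarRGB[3])
}

#' Quantify every culture on the plate
#'
#' For each grid position (row-major order): refine the tile location on the
#' segmentation mask, then measure it with \code{\link{measureTile}}. Edge
#' tiles (first/last grid row or column) are measured normally but flagged,
#' since edge cultures enjoy a nutrient advantage and should be
#' non-experimental on dense formats.
#'
#' @param tiles tile data.frame from \code{\link{initTiles}}.
#' @param mask logical segmentation mask.
#' @param corrected corrected greyscale matrix or \linkS4class{PlateImage}.
#' @param original original RGB \linkS4class{PlateImage} or NULL.
#' @param gradMask logical high-gradient mask.
#' @param iMed median background intensity.
#' @param search refinement search half-width (default 10).
#' @return A data.frame, one row per grid position in row-major order, with
#'   the \code{\link{measureTile}} columns plus \code{edge_flag}.
#' @export
quantifyPlate <- function(tiles, mask, corrected, original, gradMask, iMed,
                          search = 10L) {
  nr <- max(tiles$row); nc <- max(tiles$col)
  out <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    tile <- refineTile(tiles[i, ], mask, search = search)
    rec <- measureTile(tile, mask, corrected, original, gradMask, iMed)
    rec$edge_flag <- tile$row == 0L | tile$row == nr |
                     tile$col == 0L | tile$col == nc
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$row, res$col), , drop = FALSE]
}

#' Write a culture-measures table
#'
#' Tab-delimited text with a header row, one row per culture, prefixed with
#' an \code{image_id} column for downstream joins across timepoints.
#' Undefined colour means are written as \code{NA}.
#'
#' @param measures data.frame from \code{\link{quantifyPlate}}.
#' @param path output file path.
#' @param imageId identifier recorded in the \code{image_id} column.
#' @return \code{path}, invisibly.
#' @export
writeMeasures <- function(measures, path, imageId = "plate") {
  out <- cbind(image_id = imageId, measures)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
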