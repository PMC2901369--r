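#' Load a plate photograph
#'
#' Reads an 8-bit RGB image (JPEG, PNG or TIFF, chosen by file extension)
#' into a \linkS4class{PlateImage} on the \code{[0, 255]} intensity scale.
#' Greyscale files are promoted to RGB by channel replication; an alpha
#' channel, if present, is dropped.
#'
#' @param path path to an image file.
#' @return An RGB \linkS4class{PlateImage}.
#' @seealso \code{\link{writePlateImage}}, \code{\link{toGreyscale}}
#' @export
loadImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- tryCatch(switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for: ", path, call. = FALSE)),
    error = function(e)
      stop("failed to read image file ", path, ": ", conditionMessage(e),
           call. = FALSE))
  if (is.list(a)) a <- a[[1]]            # multi-page TIFF: first page
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  PlateImage(a * 255)
}

#' Write a PlateImage to a PNG file
#'
#' Intensities are rounded to the nearest 8-bit level on output.
#'
#' @param img a \linkS4class{PlateImage}.
#' @param path output path (PNG).
#' @return \code{path}, invisibly.
#' @export
writePlateImage <- function(img, path) {
  stopifnot(is(img, "PlateImage"))
  png::writePNG(clamp(img@pixels, 0, 255) / 255, target = path)
  invisible(path)
}

#' Convert an RGB plate image to greyscale
#'
#' Uses the ITU-R BT.601 luma weights: grey = 0.299 R + 0.587 G + 0.114 B.
#' Already-grey images are returned unchanged.
#'
#' @param img a \linkS4class{PlateImage}.
#' @return A greyscale \linkS4class{PlateImage}.
#' @export
toGreyscale <- function(img) {
  stopifnot(is(img, "PlateImage"))
  if (img@channels == "grey") return(img)
  p <- img@pixels
  g <- 0.299 * p[, , 1, drop = TRUE] + 0.587 * p[, , 2, drop = TRUE] +
    0.114 * p[, , 3, drop = TRUE]
  dim(g) <- dim(p)[1:2]
  PlateImage(g)
}

## Effective tile dimensions: derived from the corner-centre spacing when a
## count exceeds 1, otherwise the user-supplied dimension.
tileDims <- function(spec) {
  xd <- if (spec@nCols > 1L) (spec@xBR - spec@xTL) / (spec@nCols - 1L)
        else spec@xDim
  yd <- if (spec@nRows > 1L) (spec@yBR - spec@yTL) / (spec@nRows - 1L)
        else spec@yDim
  if (is.na(xd) || xd <= 0 || is.na(yd) || yd <= 0)
    stop("grid calibration implies non-positive tile dimensions", call. = FALSE)
  c(xDim = xd, yDim = yd)
}

#' Initialise the tile lattice from a grid calibration
#'
#' Derives the tile dimensions from the corner-centre spacing
#' (\code{xDim = (xBR - xTL)/(nCols - 1)}, analogously for rows; the
#' user-supplied dimension is used when a count is 1), places the top-left
#' tile at \code{(xTL - xDim/2, yTL - yDim/2)} and steps \code{xDim}
#' horizontally and \code{yDim} vertically across the grid. Tile corner
#' coordinates are rounded (half away from zero) to integer pixels once, at
#' construction; integer widths/heights are shared by all tiles.
#'
#' @param spec a \linkS4class{GridSpec}.
#' @return A data.frame with one row per tile in row-major order and columns
#'   \code{row}, \code{col} (0-based grid indices), \code{x}, \code{y}
#'   (0-based top-left corner) and \code{width}, \code{height} (pixels).
#' @examples
#' tiles <- initTiles(gridSpec(4, 4, 100, 50, 340, 290))
#' tiles[c(1, 16), ]
#' @export
initTiles <- function(spec) {
  stopifnot(is(spec, "GridSpec"))
  d <- tileDims(spec)
  xd <- d[["xDim"]]; yd <- d[["yDim"]]
  xStart <- spec@xTL - xd / 2
  yStart <- spec@yTL - yd / 2
  ij <- expand.grid(col = seq_len(spec@nCols) - 1L,
                    row = seq_len(spec@nRows) - 1L)
  data.frame(
    row = ij$row, col = ij$col,
    x = as.integer(roundHalfAway(xStart + ij$col * xd)),
    y = as.integer(roundHalfAway(yStart + ij$row * yd)),
    width = as.integer(roundHalfAway(xd)),
    height = as.integer(roundHalfAway(yd)))
}

## Grid bounding box (the user-estimated area containing growing spots):
## the extent of the tile lattice, clamped to the image. Returns 1-based
## row/col index vectors into the pixel matrix.
gridBBox <- function(spec, dims) {
  d <- tileDims(spec)
  x0 <- roundHalfAway(spec@xTL - d[["xDim"]] / 2)
  y0 <- roundHalfAway(spec@yTL - d[["yDim"]] / 2)
  x1 <- roundHalfAway(x0 + spec@nCols * d[["xDim"]])
  y1 <- roundHalfAway(y0 + spec@nRows * d[["yDim"]])
  rows <- seq.int(max(y0 + 1, 1), min(y1, dims[1]))
  cols <- seq.int(max(x0 + 1, 1), min(x1, dims[2]))
  if (!length(rows) || !length(cols) || rows[1] > rows[length(rows)])
    stop("grid bounding box does not intersect the image", call. = FALSE)
  list(rows = rows, cols = cols)
}

#' Read grid calibration from a plain-text config file
#'
#' The config replaces interactive calibration: \code{key = value} lines
#' with keys \code{nrows}, \code{ncols}, \code{xtl}, \code{ytl}, \code{xbr},
#' \code{ybr} and optional \code{xdim}, \code{ydim}. A file may contain one
#' default block for a whole image batch, plus optional per-image blocks
#' introduced by a \code{[image-file-name]} section header that override the
#' default for that image. Blank lines and lines starting with \code{#} are
#' ignored.
#'
#' @param path path to the config file.
#' @param image optional image file name selecting a per-image block.
#' @return A \linkS4class{GridSpec}.
#' @export
readGridConfig <- function(path, image = NULL) {
  if (!file.exists(path))
    stop("cannot read grid config: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- "default"
  blocks <- list(default = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (is.null(blocks[[section]])) blocks[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- tolower(trimws(kv[1]))
      blocks[[section]][[key]] <- as.numeric(trimws(paste(kv[-1], collapse = "=")))
    }
  }
  cfg <- blocks$default
  if (!is.null(image) && !is.null(blocks[[basename(image)]]))
    cfg <- utils::modifyList(cfg, blocks[[basename(image)]])
  need <- c("nrows", "ncols", "xtl", "ytl", "xbr", "ybr")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("grid config ", path, " is missing keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  gridSpec(cfg$nrows, cfg$ncols, cfg$xtl, cfg$ytl, cfg$xbr, cfg$ybr,
           xDim = if (is.null(cfg$xdim)) NA_real_ else cfg$xdim,
           yDim = if (is.null(cfg$ydim)) NA_real_ else cfg$ydim)
}
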