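## Batch orchestration: the full analysis chain per image, over directories
## of images, with stage toggles for speed (lighting correction and colour
## measures can each be disabled) and deterministic, seed-controlled output.

#' Pipeline configuration
#'
#' @param grid a \linkS4class{GridSpec}, or the path to a plain-text grid
#'   config file (see \code{\link{readGridConfig}}; per-image blocks are
#'   honoured).
#' @param lighting apply lighting-gradient correction (default TRUE).
#' @param colour compute culture/agar colour means (default TRUE).
#' @param diagnostics write intermediate images (pseudo-empty plate,
#'   corrected image, segmentation mask) as PNGs next to the output tables.
#' @param keepFraction top-gradient fraction for the first pass (default 0.05).
#' @param darkFraction darkest masked fraction allocated to background
#'   (default 0.33).
#' @param smoothSigma pseudo-empty smoothing sigma; NULL = tile width / 4.
#' @param search tile-refinement search half-width in pixels (default 10,
#'   i.e. a 20 x 20 search window).
#' @param seed RNG seed for the mixture fit (default 1).
#' @param outDir directory for output tables; NULL returns tables only.
#' @return A list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(grid, lighting = TRUE, colour = TRUE,
                           diagnostics = FALSE, keepFraction = 0.05,
                           darkFraction = 0.33, smoothSigma = NULL,
                           search = 10L, seed = 1L, outDir = NULL) {
  stopifnot(keepFraction > 0, keepFraction < 1,
            darkFraction > 0, darkFraction < 1)
  structure(list(grid = grid, lighting = lighting, colour = colour,
                 diagnostics = diagnostics, keepFraction = keepFraction,
                 darkFraction = darkFraction, smoothSigma = smoothSigma,
                 search = as.integer(search), seed = as.integer(seed),
                 outDir = outDir),
            class = "pipelineConfig")
}

resolveGrid <- function(cfg, imageId) {
  if (is(cfg$grid, "GridSpec")) cfg$grid
  else readGridConfig(cfg$grid, image = imageId)
}

#' Run the full analysis chain on one plate image
#'
#' Stage order: load, greyscale conversion, first-pass local thresholding,
#' pseudo-empty plate construction, lighting correction (skipped when
#' disabled, in which case the original greyscale image is used downstream),
#' intensity histogram and mixture fit, plate-wide segmentation, tile
#' refinement, and measurement. A plate whose intensity histogram carries no
#' resolvable second component is reported as "no growth detected" with
#' all-zero areas rather than an error.
#'
#' @param input an image file path, an RGB \linkS4class{PlateImage}, or the
#'   result of \code{\link{generatePlate}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param imageId identifier for output naming; defaults to the file name or
#'   \code{"plate"}.
#' @return Invisibly, a list: \code{measures} (the per-culture table),
#'   \code{details} (iMed, mixture fit, noGrowth flag, flat-tile count,
#'   saturated-pixel count) and \code{path} (the written table, if any).
#' @export
runImage <- function(input, cfg, imageId = NULL) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  if (is.character(input)) {
    if (is.null(imageId)) imageId <- basename(input)
    img <- loadImage(input)
  } else if (is(input, "PlateImage")) {
    img <- input
  } else if (is.list(input) && !is.null(input$image)) {
    img <- input$image
    if (is(cfg$grid, "character") || is.null(cfg$grid)) cfg$grid <- input$spec
  } else stop("unsupported input type", call. = FALSE)
  if (is.null(imageId)) imageId <- "plate"
  spec <- resolveGrid(cfg, imageId)
  grey <- toGreyscale(img)
  tiles <- initTiles(spec)
  fp <- firstPass(grey, tiles, cfg$keepFraction, cfg$darkFraction)
  saturated <- 0L
  if (cfg$lighting) {
    pe <- buildPseudoEmpty(grey, fp$culture, spec, sigma = cfg$smoothSigma)
    iMed <- medianBackground(pe, spec)
    cmap <- buildCorrection(pe, iMed)
    corrected <- applyCorrection(grey, cmap)
    saturated <- attr(corrected@pixels, "nSaturated")
  } else {
    pe <- NULL
    box <- gridBBox(spec, dim(grey))
    iMed <- stats::median(grey@pixels[box$rows, box$cols])
    corrected <- grey
  }
  hist <- buildHistogram(corrected, spec)
  fit <- tryCatch(fitMixture(hist, seed = cfg$seed), error = function(e) NULL)
  if (is.null(fit)) {
    mask <- matrix(FALSE, nrow(grey@pixels), ncol(grey@pixels))
    noGrowth <- TRUE
  } else {
    mask <- segmentPlate(corrected, fit)
    noGrowth <- isTRUE(attr(mask, "noGrowth"))
  }
  if (noGrowth)
    message("no growth detected on ", imageId)
  measures <- quantifyPlate(tiles, mask, corrected,
                            if (cfg$colour) img else NULL,
                            fp$gradient, iMed, search = cfg$search)
  path <- NULL
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    stem <- sub("\\.[A-Za-z]+$", "", imageId)
    path <- file.path(cfg$outDir, paste0(stem, ".dat"))
    writeMeasures(measures, path, imageId = imageId)
    if (isTRUE(cfg$diagnostics)) {
      if (!is.null(pe))
        writePlateImage(PlateImage(pe@pixels),
                        file.path(cfg$outDir, paste0(stem, "_pseudoempty.png")))
      writePlateImage(corrected,
                      file.path(cfg$outDir, paste0(stem, "_corrected.png")))
      png::writePNG(mask * 1,
                    file.path(cfg$outDir, paste0(stem, "_mask.png")))
    }
  }
  invisible(list(measures = measures,
                 details = list(iMed = iMed, fit = fit, noGrowth = noGrowth,
                                flatTiles = fp$flatTiles,
                                saturated = saturated),
                 path = path))
}

#' Run the pipeline over a batch of images
#'
#' Images are processed in lexicographic filename order. A failure on one
#' image is logged and skipped; the batch continues — the high-throughput
#' contract is that one corrupt photograph never aborts an overnight run.
#'
#' @param cfg a \code{\link{pipelineConfig}} (typically with \code{outDir}
#'   set and \code{grid} pointing at a batch config file).
#' @param images character vector of image paths, or a single glob pattern
#'   (e.g. \code{"plates/*.jpg"}).
#' @return A list: \code{processed}, \code{failed} (counts), \code{outputs}
#'   (written table paths) and \code{errors} (named failure messages).
#' @export
runBatch <- function(cfg, images) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  if (length(images) == 1L && grepl("[*?]", images))
    images <- Sys.glob(images)
  if (!length(images))
    stop("no input images matched", call. = FALSE)
  images <- sort(images)
  outputs <- character(0)
  errors <- character(0)
  for (p in images) {
    res <- tryCatch(runImage(p, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      warning("failed on ", basename(p), ": ", conditionMessage(res),
              call. = FALSE)
      errors[basename(p)] <- conditionMessage(res)
    } else {
      outputs <- c(outputs, res$path %||% character(0))
    }
  }
  summary <- list(processed = length(images) - length(errors),
                  failed = length(errors),
                  outputs = outputs, errors = errors)
  message(summary$processed, " processed, ", summary$failed, " failed")
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a
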