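## Logistic growth-curve summary of per-culture density timecourses.
## Lighting-corrected IOD captured at several times after inoculation is
## summarised by the three-parameter logistic population model, whose
## growth rate r is often a more informative phenotype than final density.

#' Logistic growth curve
#'
#' Closed-form solution of the logistic population model,
#' \deqn{G(t) = \frac{K G_0 e^{rt}}{K + G_0 (e^{rt} - 1)},}
#' with \eqn{G_0} the inoculum density, \eqn{K} the carrying capacity (the
#' maximum achievable cell density for the culture) and \eqn{r} the growth
#' rate per day. \eqn{G(0) = G_0} exactly and \eqn{G \to K} as
#' \eqn{t \to \infty} for \eqn{r > 0}.
#'
#' @param t time in days (vectorised).
#' @param fit a \linkS4class{LogisticFit}, or NULL to use \code{g0, k, r}.
#' @param g0,k,r explicit parameters (used when \code{fit} is NULL).
#' @return Density at \code{t}.
#' @export
logisticDensity <- function(t, fit = NULL, g0, k, r) {
  if (!is.null(fit)) {
    stopifnot(is(fit, "LogisticFit"))
    g0 <- fit@g0; k <- fit@k; r <- fit@r
  }
  ert <- exp(r * t)
  ## algebraically K*G0*ert / (K + G0*(ert-1)); rearranged to stay finite
  ## for large rt
  k * g0 / (k * exp(-r * t) + g0 * (1 - exp(-r * t)))
}

logisticRSS <- function(par, t, d, logScale = FALSE, eps = 1e-9) {
  pred <- logisticDensity(t, g0 = par[1], k = par[2], r = par[3])
  if (logScale) sum((log(pred + eps) - log(d + eps))^2)
  else sum((pred - d)^2)
}

#' Fit the logistic growth model to a density timecourse
#'
#' Least-squares fit of \eqn{(G_0, K, r)} to (time, density) observations,
#' by default on the linear density scale (set \code{logScale = TRUE} for
#' log-scale residuals, which weight early low-density observations more
#' heavily). Starting values: \eqn{K} from the maximum density, \eqn{G_0}
#' from the first positive density and \eqn{r} from the log-slope across the
#' series; the fit uses Levenberg-Marquardt with positivity bounds, with a
#' seeded multi-start bounded \code{optim} fallback if that fails. A series
#' with no growth signal (all densities zero) returns a flagged no-growth
#' fit rather than an error.
#'
#' @param times observation times in days, strictly increasing, length >= 4.
#' @param densities nonnegative densities (IOD or area units), same length.
#' @param logScale fit on log-density scale (default FALSE).
#' @param seed RNG seed for the fallback multi-start (default 1).
#' @return A \linkS4class{LogisticFit}.
#' @export
fitLogistic <- function(times, densities, logScale = FALSE, seed = 1L) {
  stopifnot(length(times) == length(densities))
  if (length(times) < 4L)
    stop("need at least 4 observations to fit 3 parameters", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(densities < 0))
    stop("densities must be nonnegative", call. = FALSE)
  eps <- 1e-6
  if (all(densities == 0))
    return(logisticFit(g0 = eps, k = eps, r = 0, rss = 0,
                       converged = TRUE, noGrowth = TRUE))
  ## near-constant series: r ~ 0 boundary, K ~ G0 ~ mean
  mu <- mean(densities)
  if (stats::sd(densities) < 1e-9 * max(mu, 1)) {
    rss <- sum((densities - mu)^2)
    return(logisticFit(g0 = mu, k = mu, r = 0, rss = rss, converged = TRUE))
  }
  k0 <- max(densities)
  pos <- which(densities > 0)
  g00 <- max(min(densities[pos][1], k0), k0 * 1e-6)
  iLast <- pos[length(pos)]
  r0 <- (log(densities[iLast] + eps) - log(g00 + eps)) /
        max(times[iLast] - times[pos[1]], eps)
  r0 <- clamp(r0, 0.01, 50)
  lower <- c(k0 * 1e-9, k0 * 1e-6, 0)
  upper <- c(k0 * 2, k0 * 10, 1e3)
  fit <- tryCatch({
    df <- data.frame(t = times, d = densities)
    form <- if (logScale)
      log(d + 1e-9) ~ log(k * g0 / (k * exp(-r * t) + g0 * (1 - exp(-r * t))) + 1e-9)
    else
      d ~ k * g0 / (k * exp(-r * t) + g0 * (1 - exp(-r * t)))
    nls <- minpack.lm::nlsLM(
      form, data = df, start = list(g0 = g00, k = k0, r = r0),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    p <- stats::coef(nls)
    list(par = p, converged = nls$convInfo$isConv)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    ## bounded multi-start on the requested objective
    starts <- withSeed(seed, c(
      list(c(g00, k0, r0)),
      lapply(1:8, function(i)
        c(g00 * stats::runif(1, 0.1, 10), k0 * stats::runif(1, 0.5, 2),
          r0 * stats::runif(1, 0.25, 4)))))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::optim(clamp(s, lower, upper), logisticRSS, method = "L-BFGS-B",
                     lower = lower, upper = upper, t = times, d = densities,
                     logScale = logScale,
                     control = list(maxit = 1000, factr = 10)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best))
      stop("logistic fit failed to converge from every start", call. = FALSE)
    fit <- list(par = best$par, converged = best$convergence == 0)
  }
  p <- fit$par
  g0 <- min(p[1], p[2])   # enforce g0 <= k at the flat-series boundary
  rss <- logisticRSS(c(g0, p[2], p[3]), times, densities)
  logisticFit(g0 = g0, k = p[2], r = max(p[3], 0), rss = rss,
              converged = isTRUE(fit$converged))
}

#' Fit growth curves across a set of plate-measure tables
#'
#' Joins per-timepoint culture-measure tables (the output of
#' \code{\link{quantifyPlate}} / \code{\link{writeMeasures}}) on
#' \code{(row, col)} and fits the logistic model to each culture's density
#' timecourse.
#'
#' @param tables list of measure data.frames, one per timepoint.
#' @param times observation times in days, one per table.
#' @param densityColumn which measure to use as density (default
#'   \code{"iod"}; \code{"area"} and \code{"tile_iod"} also make sense).
#' @param logScale passed to \code{\link{fitLogistic}}.
#' @return A data.frame with columns row, col, g0, k, r, rss, converged.
#' @export
fitGrowthCurves <- function(tables, times, densityColumn = "iod",
                            logScale = FALSE) {
  stopifnot(length(tables) == length(times))
  ord <- order(times)
  tables <- tables[ord]; times <- times[ord]
  key <- unique(do.call(rbind, lapply(tables, function(d) d[c("row", "col")])))
  key <- key[order(key$row, key$col), , drop = FALSE]
  res <- lapply(seq_len(nrow(key)), function(i) {
    dens <- vapply(tables, function(d) {
      v <- d[[densityColumn]][d$row == key$row[i] & d$col == key$col[i]]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    ok <- !is.na(dens)
    fit <- fitLogistic(times[ok], dens[ok], logScale = logScale)
    data.frame(row = key$row[i], col = key$col[i],
               g0 = fit@g0, k = fit@k, r = fit@r, rss = fit@rss,
               converged = fit@converged)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read measure tables and fit growth curves
#'
#' File-level wrapper for \code{\link{fitGrowthCurves}}: reads tab-delimited
#' measure tables and parses the observation time (in days) from each file
#' name with a regular expression whose first capture group is the numeric
#' time.
#'
#' @param paths measure-table file paths.
#' @param timeRegex regex with one capture group extracting the time from
#'   the file name, e.g. \code{"t([0-9.]+)d"} for \code{plate_t1.5d.dat}.
#' @param ... passed to \code{\link{fitGrowthCurves}}.
#' @return As \code{\link{fitGrowthCurves}}.
#' @export
growthFromTables <- function(paths, timeRegex = "t([0-9.]+)", ...) {
  m <- regmatches(basename(paths), regexec(timeRegex, basename(paths)))
  times <- vapply(m, function(g) {
    if (length(g) < 2L) NA_real_ else as.numeric(g[2])
  }, numeric(1))
  if (anyNA(times))
    stop("could not parse a time from: ",
         paste(basename(paths)[is.na(times)], collapse = ", "), call. = FALSE)
  tables <- lapply(paths, utils::read.delim)
  fitGrowthCurves(tables, times, ...)
}
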