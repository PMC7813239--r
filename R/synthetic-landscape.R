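# Synthetic landscapes with known ground truth.
#
# The generator emulates the statistical structure of the real inputs the
# pipeline is designed for: a spatially autocorrelated digital elevation
# model (fine grid, emulating a 250 m DEM), a categorical vegetation mosaic
# including excluded classes such as water and cleared land (fine grid), and
# coarse climate fields correlated with elevation (lapse-rate cooling,
# orographic rainfall) plus smooth latitudinal gradients and autocorrelated
# noise. A virtual species is then defined by a known suitability surface
# and sampled with the artefacts real occurrence downloads carry (exact
# duplicates, coarse-accuracy records).

#' Landscape generator configuration
#'
#' @param shape coarse grid (rows, cols); the fine grid is
#'   \code{shape * fineFactor}.
#' @param fineFactor fine subcells per coarse cell edge (4 emulates 250 m
#'   cells inside ~1 km cells).
#' @param elevationScale maximum elevation (m).
#' @param smoothLengths named autocorrelation lengths, in cells of the grid
#'   each field lives on: \code{elevation}, \code{vegetation} (fine grid),
#'   \code{climate} (coarse grid).
#' @param lapseRate cooling per metre of elevation (degrees C / m).
#' @param tminBase sea-level minimum temperature of the coldest month (C)
#'   at the northern (top) edge.
#' @param tminRowGradient change in tmin per coarse row going south (C).
#' @param tminNoiseSd sd of the autocorrelated tmin noise (C).
#' @param precipBase base annual precipitation (mm).
#' @param precipOrographic precipitation gain per metre of elevation
#'   (mm / m).
#' @param precipRowGradient precipitation change per coarse row (mm).
#' @param precipNoiseSd sd of the autocorrelated precipitation noise (mm).
#' @param vegClasses named integer codes for the vegetation mosaic.
#' @param vegProps mixing proportions of the classes, same order; must sum
#'   to 1.
#' @param excludedCodes codes omitted from cover denominators (water,
#'   cleared land).
#' @param seed mandatory integer seed.
#' @return A validated list of class \code{LandscapeConfig}.
#' @export
landscapeConfig <- function(shape = c(120, 120), fineFactor = 4,
                            elevationScale = 2400,
                            smoothLengths = c(elevation = 6, vegetation = 10,
                                              climate = 8),
                            lapseRate = 0.0065, tminBase = 12,
                            tminRowGradient = -0.01, tminNoiseSd = 0.4,
                            precipBase = 250, precipOrographic = 0.15,
                            precipRowGradient = 4, precipNoiseSd = 60,
                            vegClasses = c(woodland = 1, grassland = 2,
                                           shrubland = 3, water = 90,
                                           cleared = 99),
                            vegProps = c(0.35, 0.25, 0.2, 0.08, 0.12),
                            excludedCodes = c(90, 99), seed) {
  if (missing(seed)) stop("seed is mandatory in landscapeConfig()")
  if (length(shape) != 2L || any(shape < 2)) stop("shape must be two values >= 2")
  if (fineFactor < 1) stop("fineFactor must be >= 1")
  if (abs(sum(vegProps) - 1) > 1e-8) stop("vegProps must sum to 1")
  if (length(vegProps) != length(vegClasses))
    stop("vegProps and vegClasses must have equal length")
  structure(list(shape = as.integer(shape), fineFactor = as.integer(fineFactor),
                 elevationScale = elevationScale,
                 smoothLengths = smoothLengths, lapseRate = lapseRate,
                 tminBase = tminBase, tminRowGradient = tminRowGradient,
                 tminNoiseSd = tminNoiseSd, precipBase = precipBase,
                 precipOrographic = precipOrographic,
                 precipRowGradient = precipRowGradient,
                 precipNoiseSd = precipNoiseSd, vegClasses = vegClasses,
                 vegProps = vegProps, excludedCodes = excludedCodes,
                 seed = as.integer(seed)),
            class = "LandscapeConfig")
}

# Isotropic Gaussian smoothing by circular FFT convolution; sigma in cells.
# sigma <= 0 returns the input (identity kernel).
smoothField <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(di^2, dj^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

rescale01 <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Generate a synthetic landscape
#'
#' Produces a fine stack (elevation in metres, vegetation class codes) and a
#' coarse stack (tmin_july in degrees C, precip_ann in mm) that are fully
#' reproducible from the configured seed. Elevation is smoothed white noise
#' rescaled to [0, elevationScale]; tmin decreases with elevation at the
#' lapse rate and with a latitudinal row gradient; precipitation increases
#' orographically with elevation; vegetation is a thresholded smoothed field
#' producing contiguous class mosaics at the configured proportions.
#'
#' @param config a \code{\link{landscapeConfig}}.
#' @return List with elements \code{fine} and \code{coarse}
#'   (\linkS4class{RasterLayerStack}s on the two grids; layer names
#'   \code{elevation}, \code{vegetation} and \code{tmin_july},
#'   \code{precip_ann}) and \code{config}.
#' @export
generateLandscape <- function(config) {
  stopifnot(inherits(config, "LandscapeConfig"))
  withSeed(config$seed, {
    nrc <- config$shape[1]; ncc <- config$shape[2]
    f <- config$fineFactor
    nrf <- nrc * f; ncf <- ncc * f
    cellFine <- 1; cellCoarse <- f   # map units: one fine cell = 1 unit
    originFine <- c(0, nrf * cellFine)

    elev <- smoothField(matrix(stats::rnorm(nrf * ncf), nrf, ncf),
                        config$smoothLengths[["elevation"]])
    elev <- rescale01(elev) * config$elevationScale
    elevGrid <- rasterGrid(elev, cellFine, originFine, crs = "synthetic-equal-area")

    vfield <- smoothField(matrix(stats::rnorm(nrf * ncf), nrf, ncf),
                          config$smoothLengths[["vegetation"]])
    br <- stats::quantile(vfield, cumsum(config$vegProps)[-length(config$vegProps)])
    codes <- config$vegClasses[findInterval(vfield, br) + 1L]
    vegGrid <- rasterGrid(matrix(as.numeric(codes), nrf, ncf), cellFine,
                          originFine, crs = "synthetic-equal-area")

    elevCoarse <- blockAggregate(elevGrid, f, mean)
    rowIdx <- matrix(rep(seq_len(nrc), ncc), nrc, ncc)
    tminNoise <- smoothField(matrix(stats::rnorm(nrc * ncc), nrc, ncc),
                             config$smoothLengths[["climate"]])
    tminNoise <- tminNoise / max(stats::sd(tminNoise), 1e-12) * config$tminNoiseSd
    tmin <- config$tminBase - config$lapseRate * elevCoarse@values +
      config$tminRowGradient * rowIdx + tminNoise
    precipNoise <- smoothField(matrix(stats::rnorm(nrc * ncc), nrc, ncc),
                               config$smoothLengths[["climate"]])
    precipNoise <- precipNoise / max(stats::sd(precipNoise), 1e-12) *
      config$precipNoiseSd
    precip <- config$precipBase + config$precipOrographic * elevCoarse@values +
      config$precipRowGradient * rowIdx + precipNoise

    list(fine = layerStack(elevation = elevGrid, vegetation = vegGrid),
         coarse = layerStack(
           tmin_july = rasterGrid(tmin, cellCoarse, originFine,
                                  crs = "synthetic-equal-area"),
           precip_ann = rasterGrid(precip, cellCoarse, originFine,
                                   crs = "synthetic-equal-area")),
         config = config)
  })
}

#' Ground-truth response parameters of the virtual species
#'
#' The virtual species responds to terrain roughness with a saturating ramp
#' (positive up to the saturation point \code{roughSat}, flat beyond it), to
#' precipitation and minimum temperature with unimodal (inverted-U)
#' quadratics, and linearly to woodland fraction — the response shapes the
#' downstream model is expected to recover.
#'
#' @param roughSat roughness saturation point r* (m).
#' @param precipOpt,precipLow,precipHigh precipitation optimum and the
#'   low/high cuts where the quadratic crosses zero (mm).
#' @param tminOpt,tminWidth temperature optimum (C) and half-width.
#' @param coefRough,coefPrecip,coefTmin,coefWood,intercept linear-predictor
#'   coefficients.
#' @return List of class \code{TruthParams}.
#' @export
truthParams <- function(roughSat = 220, precipOpt = 800, precipLow = 500,
                        precipHigh = 1100, tminOpt = 5, tminWidth = 5,
                        coefRough = 12, coefPrecip = 2.5, coefTmin = 1.5,
                        coefWood = 0.75, intercept = -11) {
  if (roughSat <= 0) stop("roughSat must be positive")
  if (!(precipLow < precipOpt && precipOpt < precipHigh))
    stop("need precipLow < precipOpt < precipHigh")
  structure(list(roughSat = roughSat, precipOpt = precipOpt,
                 precipLow = precipLow, precipHigh = precipHigh,
                 tminOpt = tminOpt, tminWidth = tminWidth,
                 coefRough = coefRough, coefPrecip = coefPrecip,
                 coefTmin = coefTmin, coefWood = coefWood,
                 intercept = intercept),
            class = "TruthParams")
}

#' True suitability surface of the virtual species
#'
#' logistic(intercept + cR * min(rough, r*)/r* + cP * quad(precip) +
#' cT * quad(tmin) + cW * woodland), where quad(x) = max(1 - ((x -
#' opt)/hw)^2, -1) equals 1 at the optimum, 0 at the cuts, and bottoms out
#' at -1 beyond them (conditions past the tolerated band are simply
#' unsuitable, not unboundedly so). Bounding every term keeps the relative
#' influence of the predictors set by their coefficients, so the default
#' parameters define a species driven primarily by terrain roughness.
#'
#' @param stack coarse \linkS4class{RasterLayerStack} with layers
#'   \code{roughness}, \code{tmin_july}, \code{precip_ann}, \code{woodland}.
#' @param params a \code{\link{truthParams}}.
#' @return Probability \linkS4class{RasterGrid} with values in (0, 1).
#' @export
trueSuitability <- function(stack, params) {
  stopifnot(inherits(params, "TruthParams"))
  need <- c("roughness", "tmin_july", "precip_ann", "woodland")
  miss <- setdiff(need, layerNames(stack))
  if (length(miss)) stop("missing layer(s): ", paste(miss, collapse = ", "))
  rough <- getLayer(stack, "roughness")@values
  tmin <- getLayer(stack, "tmin_july")@values
  precip <- getLayer(stack, "precip_ann")@values
  wood <- getLayer(stack, "woodland")@values
  hw <- (params$precipHigh - params$precipLow) / 2
  quad <- function(x, opt, width) pmax(1 - ((x - opt) / width)^2, -1)
  lin <- params$intercept +
    params$coefRough * pmin(rough, params$roughSat) / params$roughSat +
    params$coefPrecip * quad(precip, params$precipOpt, hw) +
    params$coefTmin * quad(tmin, params$tminOpt, params$tminWidth) +
    params$coefWood * wood
  g <- getLayer(stack, "roughness")
  rasterGrid(stats::plogis(lin), g@cellSize, g@origin, g@crs)
}

#' Sample virtual-species occurrences
#'
#' Draws \code{n} cells with replacement with probability proportional to
#' suitability, places records at cell centers, then injects the artefacts
#' of real occurrence downloads: a fraction \code{dupRate} of records is
#' appended again as exact coordinate duplicates, and a fraction
#' \code{coarseAccuracyRate} is assigned a coordinate uncertainty above
#' 1000 m (so the standard accuracy filter removes it); all other records
#' get uncertainties below 1000 m.
#'
#' @param suitability \linkS4class{RasterGrid} of sampling weights.
#' @param n number of primary records.
#' @param dupRate fraction in [0, 1) duplicated exactly.
#' @param coarseAccuracyRate fraction in [0, 1) given coarse accuracy.
#' @param seed integer seed.
#' @param jitter if TRUE, records are jittered uniformly within their cell
#'   instead of placed at its center.
#' @return An \linkS4class{OccurrenceSet}.
#' @export
sampleOccurrences <- function(suitability, n, dupRate = 0.1,
                              coarseAccuracyRate = 0.1, seed,
                              jitter = FALSE) {
  stopifnot(n >= 1, dupRate >= 0, dupRate < 1,
            coarseAccuracyRate >= 0, coarseAccuracyRate < 1)
  if (missing(seed)) stop("seed is mandatory")
  w <- as.vector(suitability@values)
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("suitability is all zero or nodata")
  withSeed(seed, {
    d <- dim(suitability)
    cells <- sample.int(length(w), n, replace = TRUE, prob = w)
    row <- (cells - 1L) %% d[1] + 1L
    col <- (cells - 1L) %/% d[1] + 1L
    cs <- suitability@cellSize
    x <- suitability@origin[1] + (col - 0.5) * cs
    y <- suitability@origin[2] - (row - 0.5) * cs
    if (jitter) {
      x <- x + stats::runif(n, -0.5, 0.5) * cs
      y <- y + stats::runif(n, -0.5, 0.5) * cs
    }
    unc <- stats::runif(n, 30, 900)
    nCoarse <- floor(coarseAccuracyRate * n)
    if (nCoarse > 0) {
      coarseIdx <- sample.int(n, nCoarse)
      unc[coarseIdx] <- stats::runif(nCoarse, 1500, 10000)
    }
    nDup <- floor(dupRate * n)
    if (nDup > 0) {
      dupIdx <- sample.int(n, nDup, replace = TRUE)
      x <- c(x, x[dupIdx]); y <- c(y, y[dupIdx])
      unc <- c(unc, unc[dupIdx])
    }
    occurrenceSet(x, y, unc, source = rep("virtual", length(x)))
  })
}
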