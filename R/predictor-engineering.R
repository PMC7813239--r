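# Terrain and vegetation predictors derived from raw grids.

#' Predictor configuration
#'
#' @param northWindow angular interval (degrees, clockwise from north)
#'   counted as "north-facing"; the default is the symmetric quadrant
#'   [315, 45). Wrapping across 0 is handled.
#' @param woodlandCodes,grasslandCodes,excludedCodes vegetation category
#'   code sets; must be pairwise disjoint. Excluded codes leave cover
#'   denominators entirely.
#' @param factor aggregation factor from the fine to the coarse grid.
#' @param gradientMethod "central" (default) or "horn" finite differences
#'   for aspect.
#' @return List of class \code{PredictorConfig}.
#' @export
predictorConfig <- function(northWindow = c(315, 45), woodlandCodes = 1,
                            grasslandCodes = c(2, 3), excludedCodes = c(90, 99),
                            factor = 4, gradientMethod = c("central", "horn")) {
  gradientMethod <- match.arg(gradientMethod)
  sets <- list(woodlandCodes, grasslandCodes, excludedCodes)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("vegetation code sets must be pairwise disjoint")
  if (length(northWindow) != 2L) stop("northWindow must be (from, to) degrees")
  structure(list(northWindow = northWindow %% 360,
                 woodlandCodes = woodlandCodes,
                 grasslandCodes = grasslandCodes,
                 excludedCodes = excludedCodes, factor = as.integer(factor),
                 gradientMethod = gradientMethod),
            class = "PredictorConfig")
}

# shift a matrix by (di, dj), padding with NA
.shiftMat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
  okr <- ri >= 1 & ri <= nr; okc <- cj >= 1 & cj <= nc
  out[okr, okc] <- m[ri[okr], cj[okc]]
  out
}

#' Terrain roughness
#'
#' Roughness of each cell is the difference between the maximum and minimum
#' elevation over the cell and its surrounding eight neighbours. At edges
#' and next to nodata the neighbourhood is truncated to the cells present;
#' fewer than two valid cells yield nodata.
#'
#' @param elevation elevation \linkS4class{RasterGrid} (m).
#' @return Roughness \linkS4class{RasterGrid} (m).
#' @export
terrainRoughness <- function(elevation) {
  v <- elevation@values
  if (nrow(v) < 2 || ncol(v) < 2) stop("elevation grid smaller than 2x2")
  mx <- mn <- matrix(NA_real_, nrow(v), ncol(v))
  cnt <- matrix(0L, nrow(v), ncol(v))
  for (di in -1:1) for (dj in -1:1) {
    s <- .shiftMat(v, di, dj)
    ok <- !is.na(s)
    mx <- ifelse(ok & (is.na(mx) | s > mx), s, mx)
    mn <- ifelse(ok & (is.na(mn) | s < mn), s, mn)
    cnt <- cnt + ok
  }
  out <- mx - mn
  out[cnt < 2] <- NA_real_
  rasterGrid(out, elevation@cellSize, elevation@origin, elevation@crs)
}

# Downslope aspect in degrees clockwise from north for every cell of an
# elevation matrix; NA where flat or gradient undefined. Central differences
# in the interior, one-sided at edges.
.aspectDegrees <- function(v, cellSize, method = "central") {
  nr <- nrow(v); nc <- ncol(v)
  right <- .shiftMat(v, 0, 1); left <- .shiftMat(v, 0, -1)
  up <- .shiftMat(v, -1, 0); down <- .shiftMat(v, 1, 0)
  if (method == "horn") {
    ur <- .shiftMat(v, -1, 1); ul <- .shiftMat(v, -1, -1)
    dr <- .shiftMat(v, 1, 1); dl <- .shiftMat(v, 1, -1)
    dzdx <- ((ur + 2 * right + dr) - (ul + 2 * left + dl)) / (8 * cellSize)
    dzdy <- ((ul + 2 * up + ur) - (dl + 2 * down + dr)) / (8 * cellSize)
  } else {
    # central differences; one-sided at boundaries
    dzdx <- (right - left) / (2 * cellSize)
    dzdx[, 1] <- (right - v)[, 1] / cellSize
    dzdx[, nc] <- (v - left)[, nc] / cellSize
    # y increases northwards = decreasing row index
    dzdy <- (up - down) / (2 * cellSize)
    dzdy[1, ] <- (v - down)[1, ] / cellSize
    dzdy[nr, ] <- (up - v)[nr, ] / cellSize
  }
  flat <- is.na(dzdx) | is.na(dzdy) | (dzdx == 0 & dzdy == 0)
  # downslope direction is -gradient; angle clockwise from north
  a <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  a[flat] <- NA_real_
  a
}

.inWindow <- function(a, win) {
  if (win[1] <= win[2]) a >= win[1] & a < win[2]
  else a >= win[1] | a < win[2]
}

#' Percentage of north-facing fine cells per coarse cell
#'
#' Computes the downslope aspect of every fine cell from finite differences
#' of the fine elevation grid, then aggregates: each coarse cell is 100
#' times the number of fine cells whose aspect falls in the configured
#' north window divided by the number of non-flat fine cells in the block.
#' Flat cells (zero gradient) have no aspect and are excluded from both
#' numerator and denominator; an all-flat block is nodata.
#'
#' @param fineElevation fine elevation \linkS4class{RasterGrid}.
#' @param config a \code{\link{predictorConfig}}.
#' @return Coarse \linkS4class{RasterGrid} of percentages in [0, 100].
#' @export
aspectNorthFraction <- function(fineElevation, config = predictorConfig()) {
  a <- .aspectDegrees(fineElevation@values, fineElevation@cellSize,
                      config$gradientMethod)
  north <- matrix(as.numeric(.inWindow(a, config$northWindow)),
                  nrow(a), ncol(a))
  valid <- matrix(as.numeric(!is.na(a)), nrow(a), ncol(a))
  north[valid == 0] <- 0
  gs <- fineElevation@cellSize; og <- fineElevation@origin
  nsum <- blockAggregate(rasterGrid(north, gs, og, fineElevation@crs),
                         config$factor, sum)
  vsum <- blockAggregate(rasterGrid(valid, gs, og, fineElevation@crs),
                         config$factor, sum)
  frac <- 100 * nsum@values / vsum@values
  frac[!is.finite(frac)] <- NA_real_
  rasterGrid(frac, nsum@cellSize, nsum@origin, nsum@crs)
}

#' Woodland and grassland cover fractions
#'
#' Two \code{\link{aggregateFraction}} layers from a fine categorical
#' vegetation grid: the fraction of woodland/forest codes and the fraction
#' of grassland/shrubland codes per coarse cell, with the excluded codes
#' (water, cleared land, unknown) omitted from both denominators.
#'
#' @param fineCodes fine \linkS4class{RasterGrid} of category codes.
#' @param config a \code{\link{predictorConfig}}.
#' @return List with elements \code{woodland} and \code{grassland}.
#' @export
vegetationFractions <- function(fineCodes, config = predictorConfig()) {
  list(woodland = aggregateFraction(fineCodes, config$woodlandCodes,
                                    config$excludedCodes, config$factor),
       grassland = aggregateFraction(fineCodes, config$grasslandCodes,
                                     config$excludedCodes, config$factor))
}

#' Spearman rank correlation matrix of predictors at points
#'
#' Pairwise Spearman rank coefficients over the predictor values extracted
#' at a set of points (typically presences plus background), the standard
#' collinearity screen before model fitting. Ties get average ranks. A
#' predictor constant over the points yields NA (undefined), not 0.
#'
#' @param stack predictor \linkS4class{RasterLayerStack}.
#' @param px,py point coordinates.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(stack, px, py) {
  vals <- extractAt(stack, px, py)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3) stop("need >= 3 points with complete predictor values")
  m <- suppressWarnings(stats::cor(vals, method = "spearman",
                                   use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}
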