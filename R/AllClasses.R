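#' @import methods
NULL

#' Single-band raster grid
#'
#' A regular, square-celled, single-band raster on an equal-area grid.
#' Nodata cells are stored as \code{NA} in \code{values}; the nodata mask is
#' derived, so arithmetic on grids propagates missingness automatically.
#' Coordinates follow the usual raster convention: \code{origin} is the
#' (x, y) of the upper-left \emph{corner}, row indices increase southwards
#' (decreasing y), column indices increase eastwards, and cell values refer
#' to cell centers.
#'
#' @slot values numeric matrix of cell values (\code{NA} = nodata).
#' @slot cellSize positive scalar; cells are square by construction.
#' @slot origin numeric length-2, (x0, y0) of the upper-left corner.
#' @slot crs opaque CRS tag (character); the package never reprojects.
#' @aliases RasterGrid
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character"),
  prototype(cellSize = 1, origin = c(0, 0), crs = ""))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite (x0, y0) pair")
  if (length(object@crs) != 1L)
    msg <- c(msg, "crs must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix (NA = nodata).
#' @param cellSize cell edge length (same in x and y).
#' @param origin (x0, y0) of the upper-left corner. The default places the
#'   lower-left corner of the grid at (0, 0).
#' @param crs coordinate reference tag carried through I/O untouched.
#' @return A \linkS4class{RasterGrid}.
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4), cellSize = 100)
#' dim(g)
#' @export
rasterGrid <- function(values, cellSize = 1,
                       origin = c(0, nrow(values) * cellSize), crs = "") {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), nrow = 1)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), crs = as.character(crs))
}

#' @describeIn rasterGrid grid dimensions (rows, cols)
#' @param x a RasterGrid
#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid %d x %d, cell %g, origin (%g, %g)%s\n",
              nrow(v), ncol(v), object@cellSize,
              object@origin[1], object@origin[2],
              if (nzchar(object@crs)) paste0(", crs '", object@crs, "'") else ""))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  all cells nodata\n")
})

#' Stack of aligned raster layers
#'
#' An ordered, named collection of \linkS4class{RasterGrid} layers sharing
#' shape, cell size, origin and CRS exactly. The combined nodata mask of a
#' stack is the union of the layers' masks.
#'
#' @slot layers named list of RasterGrid objects.
#' @aliases RasterLayerStack
#' @exportClass RasterLayerStack
setClass("RasterLayerStack", representation(layers = "list"))

setValidity("RasterLayerStack", function(object) {
  ls <- object@layers
  if (!length(ls)) return("stack must contain at least one layer")
  if (is.null(names(ls)) || any(!nzchar(names(ls))) || anyDuplicated(names(ls)))
    return("layers must have unique non-empty names")
  if (!all(vapply(ls, is, logical(1), "RasterGrid")))
    return("all layers must be RasterGrid objects")
  g0 <- ls[[1]]
  for (g in ls[-1]) {
    if (!identical(dim(g@values), dim(g0@values)) ||
        g@cellSize != g0@cellSize || !identical(g@origin, g0@origin) ||
        !identical(g@crs, g0@crs))
      return("all layers must share geometry (shape, cellSize, origin, crs)")
  }
  TRUE
})

#' Construct a RasterLayerStack
#' @param ... named RasterGrid layers, or a single named list of them.
#' @return A \linkS4class{RasterLayerStack}.
#' @export
layerStack <- function(...) {
  ls <- list(...)
  if (length(ls) == 1L && is.list(ls[[1]]) && !is(ls[[1]], "RasterGrid"))
    ls <- ls[[1]]
  new("RasterLayerStack", layers = ls)
}

setMethod("show", "RasterLayerStack", function(object) {
  g <- object@layers[[1]]
  cat(sprintf("RasterLayerStack: %d layers, %d x %d cells (cell %g)\n",
              length(object@layers), nrow(g@values), ncol(g@values),
              g@cellSize))
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
})

#' @describeIn layerStack number of layers
#' @param x a RasterLayerStack
#' @export
setMethod("length", "RasterLayerStack", function(x) length(x@layers))

#' Occurrence records
#'
#' Point occurrence records with coordinate uncertainty (metres), a source
#' tag and a logical flag column standing in for manual record vetting
#' (flagged records are dropped by \code{\link{filterOccurrences}}).
#'
#' @slot records data.frame with columns x, y, uncertainty_m, source, flagged.
#' @aliases OccurrenceSet
#' @exportClass OccurrenceSet
setClass("OccurrenceSet", representation(records = "data.frame"))

setValidity("OccurrenceSet", function(object) {
  r <- object@records
  need <- c("x", "y", "uncertainty_m", "source", "flagged")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (any(!is.finite(r$x)) || any(!is.finite(r$y)))
      return("coordinates must be finite")
    if (any(!is.finite(r$uncertainty_m)) || any(r$uncertainty_m <= 0))
      return("uncertainty_m must be positive")
    if (!is.logical(r$flagged)) return("flagged must be logical")
  }
  TRUE
})

#' Construct an OccurrenceSet
#' @param x,y coordinates (same CRS as the rasters).
#' @param uncertainty_m positive coordinate uncertainty in metres.
#' @param source provider tag.
#' @param flagged logical; TRUE marks records vetted out upstream.
#' @return An \linkS4class{OccurrenceSet}.
#' @export
occurrenceSet <- function(x, y, uncertainty_m = rep(30, length(x)),
                          source = rep("unknown", length(x)),
                          flagged = rep(FALSE, length(x))) {
  new("OccurrenceSet", records = data.frame(
    x = as.numeric(x), y = as.numeric(y),
    uncertainty_m = as.numeric(uncertainty_m),
    source = as.character(source), flagged = as.logical(flagged),
    stringsAsFactors = FALSE))
}

#' @describeIn occurrenceSet number of records
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@records))

setMethod("show", "OccurrenceSet", function(object) {
  r <- object@records
  cat(sprintf("OccurrenceSet: %d records (%d flagged, %d with uncertainty > 1 km)\n",
              nrow(r), sum(r$flagged), sum(r$uncertainty_m > 1000)))
})

#' Spatial region mask
#'
#' A region of the landscape given either as a rectangle, a polygon
#' (point-in-polygon semantics) or a boolean grid. Used for background
#' sampling extents and for the hold-out region.
#'
#' @slot type one of "rect", "polygon", "grid".
#' @slot rect numeric (xmin, xmax, ymin, ymax) for type "rect".
#' @slot poly two-column coordinate matrix for type "polygon".
#' @slot grid list holding a RasterGrid whose non-zero, non-NA cells are
#'   inside the mask, for type "grid".
#' @aliases RegionMask
#' @exportClass RegionMask
setClass("RegionMask",
  representation(type = "character", rect = "numeric",
                 poly = "matrix", grid = "list"))

setValidity("RegionMask", function(object) {
  switch(object@type,
    rect = if (length(object@rect) != 4L || object@rect[1] >= object@rect[2] ||
               object@rect[3] >= object@rect[4])
             "rect must be (xmin, xmax, ymin, ymax) with non-empty interior"
           else TRUE,
    polygon = if (nrow(object@poly) < 3L) "polygon needs >= 3 vertices" else TRUE,
    grid = {
      g <- object@grid[[1]]
      v <- g@values
      if (!any(v != 0 & !is.na(v))) "grid mask has empty interior" else TRUE
    },
    "type must be rect, polygon or grid")
})

#' Region mask constructors
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds (map units).
#' @return A \linkS4class{RegionMask}.
#' @export
rectMask <- function(xmin, xmax, ymin, ymax)
  new("RegionMask", type = "rect", rect = c(xmin, xmax, ymin, ymax),
      poly = matrix(numeric(), 0, 2), grid = list())

#' @rdname rectMask
#' @param coords two-column matrix of polygon vertices (closed implicitly).
#' @export
polygonMask <- function(coords) {
  coords <- as.matrix(coords)
  new("RegionMask", type = "polygon", rect = numeric(4), poly = coords,
      grid = list())
}

#' @rdname rectMask
#' @param grid RasterGrid; cells with non-zero, non-NA values are inside.
#' @export
gridMask <- function(grid) {
  stopifnot(is(grid, "RasterGrid"))
  new("RegionMask", type = "grid", rect = numeric(4),
      poly = matrix(numeric(), 0, 2), grid = list(grid))
}

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask of type", object@type, "\n")
})

#' Hinge feature set
#'
#' The hinge basis expansion used by the maximum-entropy model. Each feature
#' is defined by a variable, a direction and a knot t: forward hinges map x
#' to max(0, x - t) / (vmax - t), reverse hinges to max(0, t - x) /
#' (t - vmin), both rescaled to [0, 1] using the variable range observed in
#' the fitting data (values outside the range are clamped).
#'
#' @slot table data.frame with columns variable, direction ("forward" or
#'   "reverse"), knot, vmin, vmax.
#' @aliases FeatureSet
#' @exportClass FeatureSet
setClass("FeatureSet", representation(table = "data.frame"))

setValidity("FeatureSet", function(object) {
  t <- object@table
  need <- c("variable", "direction", "knot", "vmin", "vmax")
  if (!all(need %in% names(t)))
    return(paste("feature table needs columns", paste(need, collapse = ", ")))
  if (nrow(t)) {
    if (!all(t$direction %in% c("forward", "reverse")))
      return("direction must be forward or reverse")
    if (any(t$knot <= t$vmin & t$direction == "forward") ||
        any(t$knot >= t$vmax & t$direction == "forward"))
      return("forward knots must lie strictly inside (vmin, vmax)")
    if (any(t$knot <= t$vmin & t$direction == "reverse") ||
        any(t$knot >= t$vmax & t$direction == "reverse"))
      return("reverse knots must lie strictly inside (vmin, vmax)")
  }
  TRUE
})

setMethod("show", "FeatureSet", function(object) {
  t <- object@table
  cat(sprintf("FeatureSet: %d hinge features over %d variables\n",
              nrow(t), length(unique(t$variable))))
})

#' @describeIn buildFeatures number of features
#' @param x a FeatureSet
#' @export
setMethod("length", "FeatureSet", function(x) nrow(x@table))

#' Fitted maximum-entropy model
#'
#' A Gibbs distribution over background cells, q(x) = exp(eta(x)) / Z with
#' eta = sum_j lambda_j f_j(x), fitted by L1-penalized maximum likelihood.
#' The logistic output is p = tau * exp(H) * q / (1 - tau + tau * exp(H) * q)
#' where H is the entropy of q over the training background and tau the
#' assumed prevalence.
#'
#' @slot features the \linkS4class{FeatureSet}.
#' @slot coefficients numeric vector lambda, one per feature.
#' @slot logZ log-normalizer over the training background.
#' @slot entropy entropy H of the raw training distribution.
#' @slot tau prevalence used by the logistic transform.
#' @slot presenceMeans named numeric, raw predictor means over the training
#'   presences (reference values for response curves and limiting factors).
#' @slot objective value of the penalized objective at the solution.
#' @aliases MaxentModel
#' @exportClass MaxentModel
setClass("MaxentModel",
  representation(features = "FeatureSet", coefficients = "numeric",
                 logZ = "numeric", entropy = "numeric", tau = "numeric",
                 presenceMeans = "numeric", objective = "numeric"))

setValidity("MaxentModel", function(object) {
  if (length(object@coefficients) != nrow(object@features@table))
    return("one coefficient per feature required")
  if (object@entropy < -1e-9) return("entropy must be non-negative")
  if (object@tau <= 0 || object@tau >= 1) return("tau must lie in (0, 1)")
  TRUE
})

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat(sprintf("MaxentModel: %d/%d active hinge features, tau = %g\n",
              nz, length(object@coefficients), object@tau))
  cat(sprintf("  logZ = %.6g, entropy = %.6g, objective = %.6g\n",
              object@logZ, object@entropy, object@objective))
})

#' AUC-weighted model ensemble
#'
#' @slot members list of \linkS4class{MaxentModel}.
#' @slot weights non-negative weights summing to one.
#' @slot aucs held-out AUC of each member.
#' @aliases MaxentEnsemble
#' @exportClass MaxentEnsemble
setClass("MaxentEnsemble",
  representation(members = "list", weights = "numeric", aucs = "numeric"))

setValidity("MaxentEnsemble", function(object) {
  if (!length(object@members)) return("ensemble needs at least one member")
  if (length(object@weights) != length(object@members) ||
      length(object@aucs) != length(object@members))
    return("weights and aucs must match members in length")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
    return("weights must be non-negative and sum to 1")
  TRUE
})

setMethod("show", "MaxentEnsemble", function(object) {
  cat(sprintf("MaxentEnsemble: %d members\n", length(object@members)))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
  cat("  AUCs:   ", paste(sprintf("%.3f", object@aucs), collapse = " "), "\n")
})

#' @describeIn buildEnsemble number of ensemble members
#' @export
setMethod("length", "MaxentEnsemble", function(x) length(x@members))

#' Null-group test result
#'
#' Result of comparing the suitability of a group of hold-out sites against
#' the distribution of the same statistic over random groups of background
#' cells.
#'
#' @slot observed named numeric, observed statistic(s) at the hold-out sites.
#' @slot nullStats matrix (B x statistics) of null group statistics.
#' @slot pValue named numeric, add-one permutation p per statistic.
#' @slot exceedance named numeric, count of null groups >= observed.
#' @slot nullMean mean of the null group means.
#' @slot nullCI normal-approximation 95 percent CI of that mean.
#' @slot percentiles empirical 2.5/97.5 percentiles of the null group means.
#' @slot groupSize group size g.
#' @slot B number of null groups.
#' @aliases NullTestResult
#' @exportClass NullTestResult
setClass("NullTestResult",
  representation(observed = "numeric", nullStats = "matrix",
                 pValue = "numeric", exceedance = "numeric",
                 nullMean = "numeric", nullCI = "numeric",
                 percentiles = "numeric", groupSize = "numeric",
                 B = "numeric"))

setValidity("NullTestResult", function(object) {
  if (any(object@pValue <= 0) || any(object@pValue > 1))
    return("p-values must lie in (0, 1]")
  if (length(object@nullCI) != 2L || object@nullCI[1] > object@nullCI[2])
    return("CI bounds must be ordered")
  TRUE
})

setMethod("show", "NullTestResult", function(object) {
  cat(sprintf("NullTestResult: %d null groups of size %d\n",
              object@B, object@groupSize))
  for (s in names(object@observed))
    cat(sprintf("  %-6s observed %.4g, p = %.4g\n", s, object@observed[s],
                object@pValue[s]))
  cat(sprintf("  null mean of group means %.4g (95%% CI %.4g-%.4g)\n",
              object@nullMean, object@nullCI[1], object@nullCI[2]))
})
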