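#' Accessors for raster and model objects
#'
#' Accessor generics: slot access stays behind these functions.
#'
#' @param x the object.
#' @param name layer name (for \code{getLayer}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)
#' @rdname accessors
#' @export
setMethod("cellSize", "RasterLayerStack",
          function(x) x@layers[[1]]@cellSize)

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setMethod("gridOrigin", "RasterGrid", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("crsTag", function(x) standardGeneric("crsTag"))
#' @rdname accessors
#' @export
setMethod("crsTag", "RasterGrid", function(x) x@crs)

#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname accessors
#' @export
setMethod("nodataMask", "RasterGrid", function(x) is.na(x@values))
#' @rdname accessors
#' @export
setMethod("nodataMask", "RasterLayerStack", function(x) {
  m <- is.na(x@layers[[1]]@values)
  for (g in x@layers[-1]) m <- m | is.na(g@values)
  m
})

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setMethod("layerNames", "RasterLayerStack", function(x) names(x@layers))

#' @rdname accessors
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' @rdname accessors
#' @export
setMethod("getLayer", "RasterLayerStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer named '", name, "' (have: ",
         paste(names(x@layers), collapse = ", "), ")")
  x@layers[[name]]
})

#' @rdname accessors
#' @export
setGeneric("occurrenceRecords",
           function(x) standardGeneric("occurrenceRecords"))
#' @rdname accessors
#' @export
setMethod("occurrenceRecords", "OccurrenceSet", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setMethod("featureTable", "FeatureSet", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("featureTable", "MaxentModel", function(x) x@features@table)

#' @rdname accessors
#' @export
setGeneric("modelCoefficients",
           function(x) standardGeneric("modelCoefficients"))
#' @rdname accessors
#' @export
setMethod("modelCoefficients", "MaxentModel", function(x) x@coefficients)

#' @rdname accessors
#' @export
setGeneric("ensembleWeights", function(x) standardGeneric("ensembleWeights"))
#' @rdname accessors
#' @export
setMethod("ensembleWeights", "MaxentEnsemble", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))
#' @rdname accessors
#' @export
setMethod("ensembleMembers", "MaxentEnsemble", function(x) x@members)
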