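# Model interpretation: gridded prediction, response curves, limiting
# factors.

# data.frame of layer values for every cell (column-major order), plus the
# union nodata mask
.stackTable <- function(stack) {
  vals <- as.data.frame(lapply(stack@layers, function(g) as.vector(g@values)))
  list(values = vals, ok = stats::complete.cases(vals))
}

#' Predict a suitability map
#'
#' Logistic prediction of a fitted model over every cell of a predictor
#' stack.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param stack predictor \linkS4class{RasterLayerStack} containing all
#'   model variables.
#' @return Suitability \linkS4class{RasterGrid} in (0, 1), nodata where any
#'   predictor is nodata.
#' @export
predictGrid <- function(model, stack) {
  vars <- unique(model@features@table$variable)
  miss <- setdiff(vars, layerNames(stack))
  if (length(miss)) stop("stack lacks model layer(s): ",
                         paste(miss, collapse = ", "))
  st <- .stackTable(stack)
  out <- rep(NA_real_, nrow(st$values))
  if (any(st$ok))
    out[st$ok] <- predictLogistic(model, st$values[st$ok, , drop = FALSE])
  g <- stack@layers[[1]]
  rasterGrid(matrix(out, nrow(g@values)), g@cellSize, g@origin, g@crs)
}

#' Response curve of one predictor
#'
#' Sweeps a single predictor over its observed (fitting) range in
#' \code{nSteps} steps while holding every other predictor at its presence
#' mean, and evaluates the logistic prediction at each step — the standard
#' marginal response curve.
#'
#' @param model a \linkS4class{MaxentModel} or \linkS4class{MaxentEnsemble}
#'   (ensemble curves are the weighted mean of member curves, each swept
#'   over the union range).
#' @param variable predictor name.
#' @param nSteps number of evaluation points (default 100).
#' @return data.frame with columns x and p.
#' @export
responseCurve <- function(model, variable, nSteps = 100) {
  if (is(model, "MaxentEnsemble")) {
    ranges <- vapply(model@members, function(m) {
      t <- m@features@table
      t <- t[t$variable == variable, ]
      if (!nrow(t)) c(NA_real_, NA_real_) else c(t$vmin[1], t$vmax[1])
    }, numeric(2))
    if (all(is.na(ranges[1, ]))) stop("unknown variable: ", variable)
    xs <- seq(min(ranges[1, ], na.rm = TRUE), max(ranges[2, ], na.rm = TRUE),
              length.out = nSteps)
    p <- rep(0, nSteps)
    for (i in seq_along(model@members)) {
      ci <- .responseCurveAt(model@members[[i]], variable, xs)
      p <- p + model@weights[i] * ci
    }
    return(data.frame(x = xs, p = p))
  }
  t <- model@features@table
  t <- t[t$variable == variable, ]
  if (!nrow(t)) {
    if (!variable %in% names(model@presenceMeans))
      stop("unknown variable: ", variable)
    # variable present in the data but reduced to zero features: flat curve
    pm <- model@presenceMeans[[variable]]
    xs <- seq(pm - 1, pm + 1, length.out = nSteps)
  } else {
    xs <- seq(t$vmin[1], t$vmax[1], length.out = nSteps)
  }
  data.frame(x = xs, p = .responseCurveAt(model, variable, xs))
}

.responseCurveAt <- function(model, variable, xs) {
  ref <- as.data.frame(as.list(model@presenceMeans))[rep(1, length(xs)),
                                                     , drop = FALSE]
  names(ref) <- names(model@presenceMeans)
  if (!variable %in% names(ref)) stop("unknown variable: ", variable)
  ref[[variable]] <- xs
  predictLogistic(model, ref)
}

#' Limiting-factor map
#'
#' For every cell, each predictor in turn is replaced by its presence mean
#' and the logistic prediction recomputed; the limiting factor is the
#' predictor whose replacement raises the prediction the most (the variable
#' holding suitability down locally). Ties, and cells where no replacement
#' helps, resolve to the first variable in canonical layer order with the
#' largest (least negative) change.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param stack predictor \linkS4class{RasterLayerStack}.
#' @param variables canonical variable order; defaults to the stack's layer
#'   order restricted to model variables.
#' @return List: \code{grid} (RasterGrid of 1-based variable indices) and
#'   \code{variables} (the index legend).
#' @export
limitingFactor <- function(model, stack, variables = NULL) {
  if (is.null(variables))
    variables <- intersect(layerNames(stack),
                           union(unique(model@features@table$variable),
                                 names(model@presenceMeans)))
  miss <- setdiff(variables, layerNames(stack))
  if (length(miss)) stop("stack lacks layer(s): ", paste(miss, collapse = ", "))
  st <- .stackTable(stack)
  ok <- st$ok
  vals <- st$values[ok, , drop = FALSE]
  base <- predictLogistic(model, vals)
  delta <- matrix(-Inf, nrow(vals), length(variables))
  for (i in seq_along(variables)) {
    v <- variables[i]
    mod <- vals
    mod[[v]] <- model@presenceMeans[[v]]
    delta[, i] <- predictLogistic(model, mod) - base
  }
  best <- max.col(delta, ties.method = "first")
  out <- rep(NA_real_, length(ok))
  out[ok] <- best
  g <- stack@layers[[1]]
  list(grid = rasterGrid(matrix(out, nrow(g@values)), g@cellSize, g@origin,
                         g@crs),
       variables = variables)
}
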