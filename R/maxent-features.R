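# Hinge feature expansion for the maximum-entropy model.

#' Maxent configuration
#'
#' @param betaMultiplier global L1 regularization multiplier beta (default
#'   2.5, favouring smooth, transferable responses).
#' @param prevalence assumed prevalence tau in (0, 1) used by the logistic
#'   output transform (default 0.3 for hard-to-detect species).
#' @param knotsPerVariable hinge knots per variable, placed at evenly
#'   spaced quantiles of the pooled presence + background values.
#' @param convergenceTol relative objective-change convergence tolerance.
#' @param maxIterations maximum coordinate-descent sweeps.
#' @param lambdaMax bound on coefficient magnitude; a numerical safeguard
#'   that keeps the optimum finite when presences are completely separable
#'   from the background (interior solutions are unaffected).
#' @return List of class \code{MaxentConfig}.
#' @export
maxentConfig <- function(betaMultiplier = 2.5, prevalence = 0.3,
                         knotsPerVariable = 30, convergenceTol = 1e-7,
                         maxIterations = 1000, lambdaMax = 30) {
  stopifnot(betaMultiplier > 0, prevalence > 0, prevalence < 1,
            knotsPerVariable >= 1, convergenceTol > 0, maxIterations >= 1,
            lambdaMax > 0)
  structure(list(betaMultiplier = betaMultiplier, prevalence = prevalence,
                 knotsPerVariable = as.integer(knotsPerVariable),
                 convergenceTol = convergenceTol,
                 maxIterations = as.integer(maxIterations),
                 lambdaMax = lambdaMax),
            class = "MaxentConfig")
}

#' Build hinge features
#'
#' For each variable, places \code{knotsPerVariable} knots at evenly spaced
#' quantiles of the pooled presence and background values and creates one
#' forward and one reverse hinge per knot. Duplicate knots (tied quantiles)
#' are collapsed and degenerate knots at the variable extremes dropped; a
#' constant variable therefore contributes no features.
#'
#' @param presenceValues data.frame of raw predictor values at presences.
#' @param backgroundValues data.frame with the same columns at background
#'   points.
#' @param config a \code{\link{maxentConfig}}.
#' @return A \linkS4class{FeatureSet}.
#' @export
buildFeatures <- function(presenceValues, backgroundValues,
                          config = maxentConfig()) {
  if (!nrow(presenceValues) || !nrow(backgroundValues))
    stop("presence and background tables must be non-empty")
  stopifnot(identical(sort(names(presenceValues)),
                      sort(names(backgroundValues))))
  rows <- list()
  for (v in names(presenceValues)) {
    x <- c(presenceValues[[v]], backgroundValues[[v]])
    x <- x[is.finite(x)]
    vmin <- min(x); vmax <- max(x)
    if (vmax <= vmin) next                      # constant variable
    probs <- seq(0, 1, length.out = config$knotsPerVariable + 2L)
    probs <- probs[-c(1L, length(probs))]
    knots <- unique(as.numeric(stats::quantile(x, probs, type = 7)))
    knots <- knots[knots > vmin & knots < vmax]
    if (!length(knots)) next
    rows[[v]] <- data.frame(
      variable = v,
      direction = rep(c("forward", "reverse"), each = length(knots)),
      knot = c(knots, knots), vmin = vmin, vmax = vmax,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(variable = character(), direction = character(),
                         knot = numeric(), vmin = numeric(), vmax = numeric())
  rownames(tab) <- NULL
  new("FeatureSet", table = tab)
}

#' Evaluate hinge features
#'
#' Maps raw predictor values to the [0, 1] feature space: forward hinges
#' are max(0, x - t) / (vmax - t), reverse hinges max(0, t - x) /
#' (t - vmin), clamped to [0, 1] outside the fitted range.
#'
#' @param features a \linkS4class{FeatureSet}.
#' @param values data.frame of raw predictor values.
#' @return Numeric matrix, one column per feature.
#' @export
featureValues <- function(features, values) {
  t <- features@table
  out <- matrix(0, nrow(values), nrow(t))
  if (!nrow(t)) return(out)
  for (j in seq_len(nrow(t))) {
    x <- values[[t$variable[j]]]
    if (is.null(x)) stop("values table lacks variable '", t$variable[j], "'")
    f <- if (t$direction[j] == "forward")
      (x - t$knot[j]) / (t$vmax[j] - t$knot[j])
    else
      (t$knot[j] - x) / (t$knot[j] - t$vmin[j])
    out[, j] <- pmin(1, pmax(0, f))
  }
  colnames(out) <- paste0(t$variable, "_", substr(t$direction, 1, 1), "_",
                          signif(t$knot, 8))
  out
}
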