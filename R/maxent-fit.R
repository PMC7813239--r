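# Penalized maximum-entropy fitting and prediction.

#' Fit a maximum-entropy model
#'
#' Fits the L1-penalized presence-background maximum-entropy model over the
#' hinge features by cyclic coordinate descent with soft-thresholding
#' (compiled). The per-feature penalty is r_j = beta * sqrt(s2_j / m),
#' where s2_j is the feature variance over the presences and m the number
#' of presences. The fit is deterministic given its inputs.
#'
#' @param presenceValues data.frame of raw predictor values at presences
#'   (m >= 2 rows).
#' @param backgroundValues data.frame of raw predictor values at background
#'   points.
#' @param config a \code{\link{maxentConfig}}.
#' @param features optional pre-built \linkS4class{FeatureSet}; built from
#'   the data when omitted.
#' @return A \linkS4class{MaxentModel}.
#' @export
fitMaxent <- function(presenceValues, backgroundValues,
                      config = maxentConfig(), features = NULL) {
  if (nrow(presenceValues) < 2) stop("need at least 2 presence records")
  if (!nrow(backgroundValues)) stop("background table is empty")
  if (!all(stats::complete.cases(presenceValues)) ||
      !all(stats::complete.cases(backgroundValues)))
    stop("predictor tables contain missing values; drop incomplete rows ",
         "before fitting")
  if (is.null(features))
    features <- buildFeatures(presenceValues, backgroundValues, config)
  Fp <- featureValues(features, presenceValues)
  Fb <- featureValues(features, backgroundValues)
  m <- nrow(Fp); N <- nrow(Fb)
  J <- ncol(Fp)

  if (J == 0) {
    lambda <- numeric(0)
    logZ <- log(N)
    entropy <- log(N)
    obj <- 0
  } else {
    fpmean <- colMeans(Fp)
    s2 <- apply(Fp, 2, stats::var)
    s2[!is.finite(s2)] <- 0
    reg <- config$betaMultiplier * sqrt(pmax(s2, 1e-6) / m)
    fit <- .maxentCCD(Fb, fpmean, reg, config$convergenceTol,
                      config$maxIterations, config$lambdaMax)
    if (!fit$converged)
      stop(sprintf(
        "maxent fit did not converge in %d sweeps (last objective %.8g)",
        config$maxIterations, fit$objective))
    lambda <- fit$lambda
    etab <- as.vector(Fb %*% lambda)
    mm <- max(etab)
    logZ <- mm + log(sum(exp(etab - mm)))
    q <- exp(etab - logZ)
    entropy <- -sum(q * (etab - logZ))
    obj <- fit$objective
  }

  new("MaxentModel", features = features, coefficients = as.numeric(lambda),
      logZ = logZ, entropy = max(entropy, 0), tau = config$prevalence,
      presenceMeans = colMeans(as.matrix(presenceValues)),
      objective = obj)
}

#' Raw (Gibbs) prediction
#'
#' q(x) = exp(eta(x)) / Z. With \code{renormalize = FALSE} the training
#' normalizer Z is used, so predictions over the training background sum to
#' one; with \code{renormalize = TRUE} the values are renormalized to sum
#' to one over the supplied points.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param values data.frame of raw predictor values.
#' @param renormalize see above.
#' @return Numeric vector of raw probabilities.
#' @export
predictRaw <- function(model, values, renormalize = FALSE) {
  if (length(model@coefficients) == 0) {
    # zero-feature model: uniform over the training background
    out <- rep(exp(-model@logZ), nrow(values))
    if (renormalize) out <- rep(1 / nrow(values), nrow(values))
    return(out)
  }
  Fm <- featureValues(model@features, values)
  eta <- as.vector(Fm %*% model@coefficients)
  if (renormalize) {
    m <- max(eta)
    e <- exp(eta - m)
    e / sum(e)
  } else {
    exp(eta - model@logZ)
  }
}

#' Logistic prediction
#'
#' p(x) = tau * exp(H) * q(x) / (1 - tau + tau * exp(H) * q(x)), where H is
#' the entropy of the raw distribution over the training background and tau
#' the configured prevalence. A site with average suitability (exp(H) q =
#' 1) scores exactly tau; the transform is strictly increasing in q.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param values data.frame of raw predictor values.
#' @return Numeric vector in (0, 1).
#' @export
predictLogistic <- function(model, values) {
  q <- predictRaw(model, values, renormalize = FALSE)
  eq <- exp(model@entropy) * q
  model@tau * eq / (1 - model@tau + model@tau * eq)
}

#' Serialize / load a fitted model
#'
#' JSON round-trip of the full model state (features, knots, coefficients,
#' normalizer, entropy, prevalence, presence means) at full double
#' precision, for bit-exact reload.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param path output path.
#' @return \code{readModelJSON}: the restored \linkS4class{MaxentModel}.
#' @export
writeModelJSON <- function(model, path) {
  obj <- list(features = model@features@table,
              coefficients = model@coefficients, logZ = model@logZ,
              entropy = model@entropy, tau = model@tau,
              presenceMeans = as.list(model@presenceMeans),
              objective = model@objective)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(obj$features, stringsAsFactors = FALSE)
  if (!nrow(tab))
    tab <- data.frame(variable = character(), direction = character(),
                      knot = numeric(), vmin = numeric(), vmax = numeric())
  pm <- unlist(obj$presenceMeans)
  new("MaxentModel", features = new("FeatureSet", table = tab),
      coefficients = as.numeric(obj$coefficients), logZ = obj$logZ,
      entropy = obj$entropy, tau = obj$tau,
      presenceMeans = pm, objective = obj$objective)
}
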