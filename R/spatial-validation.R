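# Spatial null-group validation of hold-out sites.

#' Null-group test configuration
#'
#' @param groupSize null group size g (default 9, the size of a
#'   geographically disjunct hold-out population).
#' @param nGroups number of null groups B (default 10000).
#' @param statistics group statistics to compute ("mean", "median" or
#'   both).
#' @param seed integer seed.
#' @return List of class \code{NullTestConfig}.
#' @export
nullTestConfig <- function(groupSize = 9, nGroups = 10000,
                           statistics = c("mean", "median"), seed = 1) {
  stopifnot(groupSize >= 1, nGroups >= 100,
            all(statistics %in% c("mean", "median")))
  structure(list(groupSize = as.integer(groupSize),
                 nGroups = as.integer(nGroups),
                 statistics = statistics, seed = as.integer(seed)),
            class = "NullTestConfig")
}

#' Null-group test of hold-out suitability
#'
#' Compares the suitability of a group of hold-out sites against the
#' distribution of the same statistic over B random groups of g distinct
#' cells drawn uniformly from the masked extent — the probability of
#' obtaining the hold-out's suitability by chance. The p-value uses the
#' add-one permutation form p = (1 + #\{null >= observed\}) / (B + 1), so it
#' can never be exactly zero from finite resampling.
#'
#' @param suitability suitability \linkS4class{RasterGrid}.
#' @param mask \linkS4class{RegionMask} restricting the null cells (NULL =
#'   all non-nodata cells).
#' @param holdout data.frame with columns x, y (hold-out site coordinates).
#' @param config a \code{\link{nullTestConfig}}. If the hold-out size
#'   differs from the configured g, g is set to the hold-out size with a
#'   warning.
#' @return A \linkS4class{NullTestResult}.
#' @export
nullGroupTest <- function(suitability, mask, holdout,
                          config = nullTestConfig()) {
  obsVals <- extractAt(suitability, holdout$x, holdout$y)
  if (anyNA(obsVals)) {
    bad <- which(is.na(obsVals))
    stop("hold-out point(s) off-grid or on nodata: ",
         paste(sprintf("(%g, %g)", holdout$x[bad], holdout$y[bad]),
               collapse = ", "))
  }
  g <- config$groupSize
  if (length(obsVals) != g) {
    warning("hold-out size ", length(obsVals), " != configured group size ",
            g, "; using hold-out size")
    g <- length(obsVals)
  }
  elig <- eligibleCells(mask, suitability)
  if (length(elig) < g)
    stop("fewer than ", g, " unmasked cells available for null groups")
  vals <- suitability@values[elig]
  B <- config$nGroups
  stats <- config$statistics
  observed <- vapply(stats, function(s) match.fun(s)(obsVals), numeric(1))
  names(observed) <- stats

  nullStats <- withSeed(config$seed, {
    out <- matrix(NA_real_, B, length(stats), dimnames = list(NULL, stats))
    for (b in seq_len(B)) {
      grp <- vals[sample.int(length(vals), g)]   # without replacement
      for (s in stats) out[b, s] <- match.fun(s)(grp)
    }
    out
  })

  pv <- ex <- numeric(length(stats)); names(pv) <- names(ex) <- stats
  for (s in stats) {
    ex[s] <- sum(nullStats[, s] >= observed[s])
    pv[s] <- (1 + ex[s]) / (B + 1)
  }
  gm <- nullStats[, if ("mean" %in% stats) "mean" else stats[1]]
  ci <- mean(gm) + c(-1, 1) * 1.96 * stats::sd(gm) / sqrt(B)
  new("NullTestResult", observed = observed, nullStats = nullStats,
      pValue = pv, exceedance = ex, nullMean = mean(gm), nullCI = ci,
      percentiles = unname(stats::quantile(gm, c(0.025, 0.975))),
      groupSize = g, B = B)
}

#' Summarize a null-group test
#'
#' Human-readable and JSON-serializable record of observed versus null:
#' observed statistic(s) and range, null mean of group means with its 95
#' percent CI and empirical percentiles, p-value(s), and a verdict line
#' ("observed inconsistent with chance" when p < 0.05 for the first
#' statistic, else "consistent with chance").
#'
#' @param result a \linkS4class{NullTestResult}.
#' @param path optional path; when given, the record is written as JSON.
#' @return The record, invisibly when written to file.
#' @export
summarizeValidation <- function(result, path = NULL) {
  s1 <- names(result@observed)[1]
  rec <- list(
    observed = as.list(result@observed),
    groupSize = result@groupSize,
    nGroups = result@B,
    nullMeanOfGroupMeans = result@nullMean,
    nullCI95 = result@nullCI,
    nullPercentiles = result@percentiles,
    pValue = as.list(result@pValue),
    exceedance = as.list(result@exceedance),
    verdict = if (result@pValue[s1] < 0.05)
      "observed inconsistent with chance"
    else "consistent with chance")
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(rec))
  }
  rec
}
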