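# Model evaluation (AUC, TSS), repeated k-fold cross-validation,
# AUC-weighted ensembling and permutation variable importance.

#' Evaluation configuration
#'
#' @param k number of cross-validation folds (default 10).
#' @param repeats number of independent k-fold repeats (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param importancePermutations permutations per variable for permutation
#'   importance (default 10).
#' @return List of class \code{EvalConfig}.
#' @export
evalConfig <- function(k = 10, repeats = 10, seed = 1,
                       importancePermutations = 10) {
  stopifnot(k >= 2, repeats >= 1, importancePermutations >= 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 importancePermutations = as.integer(importancePermutations)),
            class = "EvalConfig")
}

#' Area under the ROC curve
#'
#' Rank-based Mann-Whitney estimate: the probability that a random presence
#' scores above a random background point, with ties counted half.
#'
#' @param presenceScores,backgroundScores numeric score vectors.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores); nb <- length(backgroundScores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  r <- rank(c(presenceScores, backgroundScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' True skill statistic
#'
#' TSS = sensitivity + specificity - 1, maximized over candidate thresholds
#' (all unique score values), treating background points as absences. A
#' point is predicted present when its score >= threshold. Ties in TSS
#' resolve to the smallest threshold.
#'
#' @param presenceScores,backgroundScores numeric score vectors.
#' @return List with \code{tss} and \code{threshold}.
#' @export
tssScore <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores); nb <- length(backgroundScores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  thr <- sort(unique(c(presenceScores, backgroundScores)))
  sp <- sort(presenceScores); sb <- sort(backgroundScores)
  # count of scores >= t via findInterval on the sorted vectors
  sens <- (np - findInterval(thr, sp, left.open = TRUE)) / np
  spec <- findInterval(thr, sb, left.open = TRUE) / nb
  tss <- sens + spec - 1
  best <- which.max(tss)            # first index = smallest threshold on ties
  list(tss = tss[best], threshold = thr[best])
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, presences and background points are independently
#' partitioned into k folds (seeded). For each fold a model is fitted on
#' the other k - 1 folds of both sets (features rebuilt from the training
#' folds) and scored on the held-out presences versus held-out background.
#'
#' @param presenceValues,backgroundValues data.frames of raw predictor
#'   values.
#' @param maxentConfig a \code{\link{maxentConfig}}.
#' @param evalConfig an \code{\link{evalConfig}}.
#' @return List: \code{results} (data.frame repeat, fold, auc, tss,
#'   threshold) and \code{models} (list of k * repeats MaxentModels, in
#'   results order).
#' @export
crossValidate <- function(presenceValues, backgroundValues,
                          maxentConfig = maxentConfig(),
                          evalConfig = evalConfig()) {
  k <- evalConfig$k
  if (nrow(presenceValues) < k)
    stop("fewer presences (", nrow(presenceValues), ") than folds (", k, ")")
  results <- list(); models <- list()
  for (r in seq_len(evalConfig$repeats)) {
    folds <- withSeed(stageSeed(evalConfig$seed, paste0("cv-repeat-", r)), {
      list(p = sample(rep_len(seq_len(k), nrow(presenceValues))),
           b = sample(rep_len(seq_len(k), nrow(backgroundValues))))
    })
    for (f in seq_len(k)) {
      trainP <- presenceValues[folds$p != f, , drop = FALSE]
      trainB <- backgroundValues[folds$b != f, , drop = FALSE]
      testP <- presenceValues[folds$p == f, , drop = FALSE]
      testB <- backgroundValues[folds$b == f, , drop = FALSE]
      model <- fitMaxent(trainP, trainB, maxentConfig)
      ps <- predictLogistic(model, testP)
      bs <- predictLogistic(model, testB)
      ts <- tssScore(ps, bs)
      results[[length(results) + 1L]] <- data.frame(
        repeat_id = r, fold = f, auc = aucScore(ps, bs), tss = ts$tss,
        threshold = ts$threshold)
      models[[length(models) + 1L]] <- model
    }
  }
  list(results = do.call(rbind, results), models = models)
}

#' Build an AUC-weighted ensemble
#'
#' Selects the best fold-model of each repeat by held-out AUC ("all of the
#' best models derived from each k-fold sampling") and weights members by
#' skill above chance, (AUC - 0.5) clamped at zero and normalized to sum
#' one. If no member beats chance, uniform weights are used with a warning.
#'
#' @param models list of fitted models, in \code{results} row order.
#' @param results the cross-validation results data.frame.
#' @return A \linkS4class{MaxentEnsemble} with one member per repeat.
#' @export
buildEnsemble <- function(models, results) {
  if (!length(models)) stop("empty model list")
  if (nrow(results) != length(models))
    stop("results must cover all models (one row per model)")
  sel <- integer(); aucs <- numeric()
  for (r in unique(results$repeat_id)) {
    idx <- which(results$repeat_id == r)
    best <- idx[which.max(results$auc[idx])]
    sel <- c(sel, best); aucs <- c(aucs, results$auc[best])
  }
  w <- pmax(aucs - 0.5, 0)
  if (sum(w) == 0) {
    warning("no member exceeds AUC 0.5; using uniform weights")
    w <- rep(1, length(sel))
  }
  new("MaxentEnsemble", members = models[sel], weights = w / sum(w),
      aucs = aucs)
}

#' Ensemble prediction
#'
#' Weighted mean of the members' logistic predictions — a convex
#' combination, bounded by the member extremes per point.
#'
#' @param ensemble a \linkS4class{MaxentEnsemble}.
#' @param newdata a data.frame of predictor values or a
#'   \linkS4class{RasterLayerStack}.
#' @return Numeric vector (data.frame input) or suitability
#'   \linkS4class{RasterGrid} (stack input).
#' @export
ensemblePredict <- function(ensemble, newdata) {
  if (is(newdata, "RasterLayerStack")) {
    st <- .stackTable(newdata)
    out <- rep(NA_real_, nrow(st$values))
    if (any(st$ok))
      out[st$ok] <- ensemblePredict(ensemble,
                                    st$values[st$ok, , drop = FALSE])
    g <- newdata@layers[[1]]
    return(rasterGrid(matrix(out, nrow(g@values)), g@cellSize, g@origin,
                      g@crs))
  }
  p <- rep(0, nrow(newdata))
  for (i in seq_along(ensemble@members))
    p <- p + ensemble@weights[i] *
      predictLogistic(ensemble@members[[i]], newdata)
  p
}

#' Permutation variable importance
#'
#' AUC drop when one variable's values are permuted across the evaluation
#' points (presences and background jointly), averaged over several seeded
#' permutations, clamped at zero and normalized to sum one. Variables with
#' no active feature in any ensemble member score exactly zero.
#'
#' @param ensemble a \linkS4class{MaxentEnsemble}.
#' @param presenceValues,backgroundValues evaluation point tables.
#' @param evalConfig an \code{\link{evalConfig}} (permutation count and
#'   seed).
#' @return data.frame (variable, meanDrop, importance, rank), sorted by
#'   rank.
#' @export
variableImportance <- function(ensemble, presenceValues, backgroundValues,
                               evalConfig = evalConfig()) {
  vars <- names(presenceValues)
  np <- nrow(presenceValues)
  active <- unique(unlist(lapply(ensemble@members, function(m) {
    t <- m@features@table
    unique(t$variable[m@coefficients != 0])
  })))
  all <- rbind(presenceValues, backgroundValues)
  base <- {
    s <- ensemblePredict(ensemble, all)
    aucScore(s[seq_len(np)], s[-seq_len(np)])
  }
  drops <- numeric(length(vars)); names(drops) <- vars
  for (v in vars) {
    if (!v %in% active) { drops[v] <- 0; next }
    ds <- withSeed(stageSeed(evalConfig$seed, paste0("perm-", v)), {
      vapply(seq_len(evalConfig$importancePermutations), function(i) {
        perm <- all
        perm[[v]] <- sample(perm[[v]])
        s <- ensemblePredict(ensemble, perm)
        base - aucScore(s[seq_len(np)], s[-seq_len(np)])
      }, numeric(1))
    })
    drops[v] <- mean(ds)
  }
  imp <- pmax(drops, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  else warning("all permutation drops are zero; importance undefined")
  out <- data.frame(variable = vars, meanDrop = as.numeric(drops),
                    importance = as.numeric(imp))
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
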