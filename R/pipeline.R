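# Config-driven orchestration: simulate -> prepare -> evaluate -> predict ->
# limiting -> validate, with per-stage seeds derived from the master seed
# and a machine-readable run manifest. Stages communicate only through
# files in the output directory, so any stage can be rerun from persisted
# inputs.

.CANONICAL_PREDICTORS <- c("roughness", "aspect_north", "woodland",
                           "grassland", "tmin_july", "precip_ann")

#' Pipeline run configuration
#'
#' Collects every tunable of the workflow in one auditable place. All
#' stochastic stages derive their seeds deterministically from
#' \code{masterSeed} plus the stage name, so adding or removing optional
#' stages never shifts downstream randomness.
#'
#' @param outdir output directory (created if missing).
#' @param masterSeed integer master seed.
#' @param landscape a \code{\link{landscapeConfig}}; default uses the
#'   standard 120 x 120 landscape with a seed derived from the master seed.
#' @param truth a \code{\link{truthParams}} for the virtual species.
#' @param predictor a \code{\link{predictorConfig}}.
#' @param maxent a \code{\link{maxentConfig}}.
#' @param eval an \code{\link{evalConfig}} (its seed is rederived from the
#'   master seed).
#' @param nullTest a \code{\link{nullTestConfig}} (seed rederived).
#' @param backgrounds named list of background designs, each
#'   \code{list(mask =, n =)}. A mask of NULL means the full extent; the
#'   character sentinel \code{"occurrence-bbox"} means the bounding box of
#'   the filtered training occurrences expanded by 10 percent (a stand-in
#'   for a natural-range extent).
#' @param holdoutRegion \linkS4class{RegionMask} for hold-out validation
#'   sites, the sentinel \code{"southwest"} (lower-left 20 percent of the
#'   extent), or NULL to skip the validation stage.
#' @param nOccurrences primary virtual occurrences drawn (default 1400).
#' @param dupRate,coarseAccuracyRate occurrence-artefact rates passed to
#'   \code{\link{sampleOccurrences}}.
#' @return List of class \code{RunConfig}.
#' @export
runConfig <- function(outdir, masterSeed = 1, landscape = NULL,
                      truth = truthParams(),
                      predictor = predictorConfig(),
                      maxent = maxentConfig(), eval = evalConfig(),
                      nullTest = nullTestConfig(),
                      backgrounds = list(
                        restricted = list(mask = "occurrence-bbox", n = 10000),
                        full = list(mask = NULL, n = 30000)),
                      holdoutRegion = "southwest", nOccurrences = 1400,
                      dupRate = 0.1, coarseAccuracyRate = 0.1) {
  if (is.null(landscape))
    landscape <- landscapeConfig(seed = stageSeed(masterSeed, "landscape"))
  stopifnot(inherits(landscape, "LandscapeConfig"),
            inherits(truth, "TruthParams"),
            inherits(predictor, "PredictorConfig"),
            inherits(maxent, "MaxentConfig"),
            inherits(eval, "EvalConfig"),
            inherits(nullTest, "NullTestConfig"))
  if (!length(backgrounds) || is.null(names(backgrounds)))
    stop("backgrounds must be a named list of designs")
  structure(list(outdir = outdir, masterSeed = as.integer(masterSeed),
                 landscape = landscape, truth = truth, predictor = predictor,
                 maxent = maxent, eval = eval, nullTest = nullTest,
                 backgrounds = backgrounds, holdoutRegion = holdoutRegion,
                 nOccurrences = as.integer(nOccurrences), dupRate = dupRate,
                 coarseAccuracyRate = coarseAccuracyRate),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Maps a structured YAML tree onto \code{\link{runConfig}}: top-level keys
#' \code{outdir}, \code{masterSeed}, \code{nOccurrences}, \code{dupRate},
#' \code{coarseAccuracyRate}, plus optional sub-trees \code{landscape},
#' \code{truth}, \code{predictor}, \code{maxent}, \code{eval},
#' \code{nullTest} (arguments of the respective constructors) and
#' \code{backgrounds} (name -> \{mask: full|occurrence-bbox|[xmin, xmax,
#' ymin, ymax], n\}). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @param outdir optional override of the configured output directory.
#' @param masterSeed optional override of the configured master seed
#'   (applied before any stage seed is derived).
#' @return A \code{RunConfig}.
#' @export
readRunConfig <- function(path, outdir = NULL, masterSeed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(masterSeed)) y$masterSeed <- as.integer(masterSeed)
  known <- c("outdir", "masterSeed", "landscape", "truth", "predictor",
             "maxent", "eval", "nullTest", "backgrounds", "holdoutRegion",
             "nOccurrences", "dupRate", "coarseAccuracyRate")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- list()
  args$outdir <- if (!is.null(outdir)) outdir else y$outdir
  if (is.null(args$outdir)) stop("config must set outdir")
  for (k in c("masterSeed", "nOccurrences", "dupRate", "coarseAccuracyRate",
              "holdoutRegion"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  ctors <- list(landscape = landscapeConfig, truth = truthParams,
                predictor = predictorConfig, maxent = maxentConfig,
                eval = evalConfig, nullTest = nullTestConfig)
  for (k in names(ctors)) if (!is.null(y[[k]])) {
    a <- y[[k]]
    if (k == "landscape" && is.null(a$seed))
      a$seed <- stageSeed(if (is.null(y$masterSeed)) 1 else y$masterSeed,
                          "landscape")
    args[[k]] <- do.call(ctors[[k]], a)
  }
  if (!is.null(y$backgrounds)) {
    args$backgrounds <- lapply(y$backgrounds, function(b) {
      mask <- b$mask
      if (is.character(mask) && mask == "full") mask <- NULL
      if (is.numeric(mask) && length(mask) == 4)
        mask <- rectMask(mask[1], mask[2], mask[3], mask[4])
      list(mask = mask, n = b$n)
    })
  }
  if (is.numeric(args$holdoutRegion) && length(args$holdoutRegion) == 4)
    args$holdoutRegion <- rectMask(args$holdoutRegion[1],
                                   args$holdoutRegion[2],
                                   args$holdoutRegion[3],
                                   args$holdoutRegion[4])
  do.call(runConfig, args)
}

.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.resolveHoldout <- function(config, template) {
  hr <- config$holdoutRegion
  if (is.null(hr)) return(NULL)
  if (is.character(hr) && hr == "southwest") {
    d <- dim(template); cs <- template@cellSize; og <- template@origin
    return(rectMask(og[1], og[1] + 0.2 * d[2] * cs,
                    og[2] - d[1] * cs, og[2] - 0.8 * d[1] * cs))
  }
  hr
}

.maskToJSON <- function(mask) {
  if (is.null(mask)) return(list(type = "full"))
  if (mask@type == "rect") return(list(type = "rect", rect = mask@rect))
  if (mask@type == "polygon") return(list(type = "polygon",
                                          poly = unname(as.matrix(mask@poly))))
  list(type = "grid")
}

.maskFromJSON <- function(j) {
  if (j$type == "full") return(NULL)
  if (j$type == "rect") {
    r <- unlist(j$rect)
    return(rectMask(r[1], r[2], r[3], r[4]))
  }
  if (j$type == "polygon")
    return(polygonMask(matrix(unlist(j$poly), ncol = 2, byrow = TRUE)))
  stop("grid masks are not persisted in the manifest")
}

.stageSimulate <- function(config) {
  .logStage("simulate", "generating landscape and virtual occurrences")
  out <- file.path(config$outdir, "raw")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  land <- generateLandscape(config$landscape)
  writeGrid(getLayer(land$fine, "elevation"), file.path(out, "elevation.tif"))
  writeGrid(getLayer(land$fine, "vegetation"), file.path(out, "vegetation.tif"))
  writeGrid(getLayer(land$coarse, "tmin_july"), file.path(out, "tmin_july.tif"))
  writeGrid(getLayer(land$coarse, "precip_ann"),
            file.path(out, "precip_ann.tif"))

  # ground truth needs the derived roughness and woodland layers
  f <- config$landscape$fineFactor
  rough <- blockAggregate(terrainRoughness(getLayer(land$fine, "elevation")),
                          f, mean)
  wood <- aggregateFraction(getLayer(land$fine, "vegetation"),
                            config$predictor$woodlandCodes,
                            config$predictor$excludedCodes, f)
  truthStack <- layerStack(roughness = rough,
                           tmin_july = getLayer(land$coarse, "tmin_july"),
                           precip_ann = getLayer(land$coarse, "precip_ann"),
                           woodland = wood)
  suit <- trueSuitability(truthStack, config$truth)
  writeGrid(suit, file.path(out, "true_suitability.tif"))
  occ <- sampleOccurrences(suit, config$nOccurrences, config$dupRate,
                           config$coarseAccuracyRate,
                           seed = stageSeed(config$masterSeed, "occurrences"))
  writeOccurrences(occ, file.path(out, "occurrences.csv"))
  invisible(out)
}

.stagePrepare <- function(config) {
  .logStage("prepare", "deriving predictors, filtering occurrences, ",
            "sampling backgrounds")
  raw <- file.path(config$outdir, "raw")
  pdir <- file.path(config$outdir, "predictors")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  elev <- readGrid(file.path(raw, "elevation.tif"))
  veg <- readGrid(file.path(raw, "vegetation.tif"))
  tmin <- readGrid(file.path(raw, "tmin_july.tif"))
  precip <- readGrid(file.path(raw, "precip_ann.tif"))
  pc <- config$predictor
  rough <- blockAggregate(terrainRoughness(elev), pc$factor, mean)
  aspect <- aspectNorthFraction(elev, pc)
  vf <- vegetationFractions(veg, pc)
  layers <- list(roughness = rough, aspect_north = aspect,
                 woodland = vf$woodland, grassland = vf$grassland,
                 tmin_july = tmin, precip_ann = precip)
  for (nm in .CANONICAL_PREDICTORS)
    writeGrid(layers[[nm]], file.path(pdir, paste0(nm, ".tif")))
  jsonlite::write_json(list(layers = .CANONICAL_PREDICTORS,
                            factor = pc$factor),
                       file.path(pdir, "manifest.json"), auto_unbox = TRUE)

  occ <- readOccurrences(file.path(raw, "occurrences.csv"))
  filt <- filterOccurrences(occ)
  hr <- .resolveHoldout(config, rough)
  if (!is.null(hr)) {
    sp <- suppressWarnings(splitHoldout(filt, hr))
  } else {
    sp <- list(train = filt,
               holdout = new("OccurrenceSet",
                             records = filt@records[0, , drop = FALSE]))
  }
  writeOccurrences(sp$train, file.path(config$outdir, "occ_train.csv"))
  writeOccurrences(sp$holdout, file.path(config$outdir, "occ_holdout.csv"))

  # resolve background design masks against the training occurrences
  tr <- sp$train@records
  meta <- list()
  for (nm in names(config$backgrounds)) {
    d <- config$backgrounds[[nm]]
    mask <- d$mask
    if (is.character(mask) && mask == "occurrence-bbox") {
      padx <- 0.1 * diff(range(tr$x)); pady <- 0.1 * diff(range(tr$y))
      mask <- rectMask(min(tr$x) - padx, max(tr$x) + padx,
                       min(tr$y) - pady, max(tr$y) + pady)
    }
    bg <- sampleBackground(mask, rough, d$n,
                           seed = stageSeed(config$masterSeed,
                                            paste0("background-", nm)))
    utils::write.csv(bg, file.path(config$outdir,
                                   paste0("background_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    meta[[nm]] <- list(mask = .maskToJSON(mask), n = d$n)
  }
  jsonlite::write_json(list(designs = meta,
                            holdoutRegion = .maskToJSON(hr)),
                       file.path(config$outdir, "designs.json"),
                       auto_unbox = TRUE, digits = NA)

  stack <- layerStack(layers)
  bg1 <- utils::read.csv(file.path(config$outdir,
                                   paste0("background_",
                                          names(config$backgrounds)[1],
                                          ".csv")))
  src <- spearmanMatrix(stack, c(tr$x, bg1$x), c(tr$y, bg1$y))
  utils::write.csv(as.data.frame(src),
                   file.path(config$outdir, "spearman.csv"),
                   row.names = TRUE, quote = FALSE)
  invisible(pdir)
}

.loadPredictorStack <- function(outdir) {
  pdir <- file.path(outdir, "predictors")
  man <- jsonlite::read_json(file.path(pdir, "manifest.json"),
                             simplifyVector = TRUE)
  layers <- lapply(man$layers, function(nm)
    readGrid(file.path(pdir, paste0(nm, ".tif"))))
  names(layers) <- man$layers
  layerStack(layers)
}

.designNames <- function(config) names(config$backgrounds)

.stageEvaluate <- function(config) {
  stack <- .loadPredictorStack(config$outdir)
  train <- readOccurrences(file.path(config$outdir, "occ_train.csv"))@records
  pv <- extractAt(stack, train$x, train$y)
  keep <- stats::complete.cases(pv)
  pv <- pv[keep, , drop = FALSE]
  for (nm in .designNames(config)) {
    .logStage("evaluate", "cross-validating design '", nm, "'")
    bg <- utils::read.csv(file.path(config$outdir,
                                    paste0("background_", nm, ".csv")))
    bv <- extractAt(stack, bg$x, bg$y)
    bv <- bv[stats::complete.cases(bv), , drop = FALSE]
    ec <- config$eval
    ec$seed <- stageSeed(config$masterSeed, paste0("cv-", nm))
    cv <- crossValidate(pv, bv, config$maxent, ec)
    utils::write.csv(cv$results,
                     file.path(config$outdir,
                               paste0("metrics_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    ens <- buildEnsemble(cv$models, cv$results)
    mdir <- file.path(config$outdir, "models", nm)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(ens@members))
      writeModelJSON(ens@members[[i]],
                     file.path(mdir, sprintf("member_%02d.json", i)))
    jsonlite::write_json(
      list(members = sprintf("member_%02d.json", seq_along(ens@members)),
           weights = ens@weights, aucs = ens@aucs),
      file.path(mdir, "ensemble.json"), digits = I(17))
    imp <- variableImportance(ens, pv, bv, ec)
    utils::write.csv(imp, file.path(config$outdir,
                                    paste0("importance_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    curves <- do.call(rbind, lapply(layerNames(stack), function(v) {
      rc <- responseCurve(ens, v)
      data.frame(variable = v, x = rc$x, p = rc$p)
    }))
    utils::write.csv(curves, file.path(config$outdir,
                                       paste0("response_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

.loadEnsemble <- function(outdir, design) {
  mdir <- file.path(outdir, "models", design)
  man <- jsonlite::read_json(file.path(mdir, "ensemble.json"),
                             simplifyVector = TRUE)
  members <- lapply(man$members, function(f) readModelJSON(file.path(mdir, f)))
  new("MaxentEnsemble", members = members, weights = man$weights,
      aucs = man$aucs)
}

.stagePredict <- function(config) {
  stack <- .loadPredictorStack(config$outdir)
  designs <- .designNames(config)
  maps <- list()
  for (nm in designs) {
    .logStage("predict", "mapping design '", nm, "'")
    ens <- .loadEnsemble(config$outdir, nm)
    maps[[nm]] <- ensemblePredict(ens, stack)
    writeGrid(maps[[nm]], file.path(config$outdir,
                                    paste0("suitability_", nm, ".tif")))
  }
  if (length(designs) >= 2) {
    diffMap <- gridDifference(maps[[designs[1]]], maps[[designs[2]]])
    writeGrid(diffMap, file.path(config$outdir, "difference.tif"))
  }
  invisible(NULL)
}

.stageLimiting <- function(config) {
  nm <- .designNames(config)[1]
  .logStage("limiting", "single-model limiting-factor map (design '",
            nm, "')")
  stack <- .loadPredictorStack(config$outdir)
  train <- readOccurrences(file.path(config$outdir, "occ_train.csv"))@records
  bg <- utils::read.csv(file.path(config$outdir,
                                  paste0("background_", nm, ".csv")))
  pv <- extractAt(stack, train$x, train$y)
  pv <- pv[stats::complete.cases(pv), , drop = FALSE]
  bv <- extractAt(stack, bg$x, bg$y)
  bv <- bv[stats::complete.cases(bv), , drop = FALSE]
  model <- fitMaxent(pv, bv, config$maxent)
  lf <- limitingFactor(model, stack, .CANONICAL_PREDICTORS)
  writeGrid(lf$grid, file.path(config$outdir,
                               paste0("limiting_", nm, ".tif")))
  jsonlite::write_json(list(variables = lf$variables),
                       file.path(config$outdir, "limiting_legend.json"),
                       auto_unbox = FALSE)
  invisible(NULL)
}

.stageValidate <- function(config) {
  holdout <- readOccurrences(file.path(config$outdir,
                                       "occ_holdout.csv"))@records
  if (!nrow(holdout)) {
    .logStage("validate", "no hold-out records; stage skipped")
    return(list(skipped = TRUE, reason = "no hold-out records"))
  }
  designs <- jsonlite::read_json(file.path(config$outdir, "designs.json"),
                                 simplifyVector = FALSE)
  for (nm in .designNames(config)) {
    .logStage("validate", "null-group test, design '", nm, "'")
    suit <- readGrid(file.path(config$outdir,
                               paste0("suitability_", nm, ".tif")))
    mask <- .maskFromJSON(designs$designs[[nm]]$mask)
    nc <- config$nullTest
    nc$seed <- stageSeed(config$masterSeed, paste0("null-", nm))
    res <- suppressWarnings(nullGroupTest(suit, mask, holdout, nc))
    summarizeValidation(res, file.path(config$outdir,
                                       paste0("validation_", nm, ".json")))
  }
  list(skipped = FALSE)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order (simulate, prepare, evaluate,
#' predict, limiting, validate) for every configured background design and
#' writes a run manifest recording the configuration, derived stage seeds
#' and an md5 digest of every output file. Given the same master seed, two
#' runs produce byte-identical outputs. A missing hold-out region skips
#' the validation stage with an explicit manifest entry rather than an
#' error.
#'
#' @param config a \code{\link{runConfig}} (or path to a YAML file accepted
#'   by \code{\link{readRunConfig}}).
#' @param stages character vector of stages, or "all".
#' @return Invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  allStages <- c("simulate", "prepare", "evaluate", "predict", "limiting",
                 "validate")
  if (identical(stages, "all")) stages <- allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  validation <- NULL
  for (st in stages) {
    res <- tryCatch(switch(st,
      simulate = .stageSimulate(config),
      prepare = .stagePrepare(config),
      evaluate = .stageEvaluate(config),
      predict = .stagePredict(config),
      limiting = .stageLimiting(config),
      validate = .stageValidate(config)),
      error = function(e) stop("stage '", st, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    if (st == "validate") validation <- res
  }

  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  digests <- as.list(tools::md5sum(files))
  names(digests) <- sub(paste0("^", config$outdir, "/?"), "",
                        names(digests))
  manifest <- list(
    package = "maxentSDM",
    version = as.character(utils::packageVersion("maxentSDM")),
    masterSeed = config$masterSeed,
    stages = stages,
    stageSeeds = stats::setNames(
      lapply(c("landscape", "occurrences",
               paste0("background-", .designNames(config)),
               paste0("cv-", .designNames(config)),
               paste0("null-", .designNames(config))),
             function(s) stageSeed(config$masterSeed, s)),
      c("landscape", "occurrences",
        paste0("background-", .designNames(config)),
        paste0("cv-", .designNames(config)),
        paste0("null-", .designNames(config)))),
    config = list(
      landscape = unclass(config$landscape),
      truth = unclass(config$truth),
      predictor = unclass(config$predictor),
      maxent = unclass(config$maxent),
      eval = unclass(config$eval)[c("k", "repeats",
                                    "importancePermutations")],
      nullTest = unclass(config$nullTest)[c("groupSize", "nGroups",
                                            "statistics")],
      nOccurrences = config$nOccurrences,
      dupRate = config$dupRate,
      coarseAccuracyRate = config$coarseAccuracyRate,
      backgroundDesigns = lapply(config$backgrounds, function(b)
        list(n = b$n,
             mask = if (is.character(b$mask)) b$mask
                    else if (is.null(b$mask)) "full" else "explicit"))),
    validation = if (is.null(validation)) NULL else validation,
    outputs = digests)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a summary report from a completed run
#'
#' Renders, from stored outputs only, the standard figures of the analysis:
#' permutation-importance bars and per-predictor response curves, the
#' suitability map per design, the single between-design difference map
#' and the limiting-factor map, plus the validation table. Rerunning is
#' idempotent. Missing outputs are listed rather than silently skipped.
#'
#' @param outdir directory of a completed \code{\link{runPipeline}} run.
#' @return Invisibly, a list with the report path, the figures written and
#'   any missing outputs.
#' @export
makeReport <- function(outdir) {
  man <- file.path(outdir, "manifest.json")
  if (!file.exists(man)) stop("no manifest.json in ", outdir)
  manifest <- jsonlite::read_json(man, simplifyVector = TRUE)
  figdir <- file.path(outdir, "report")
  dir.create(figdir, showWarnings = FALSE)
  missing <- character(); figures <- character(); lines <- character()
  designs <- names(manifest$config$backgroundDesigns)
  lines <- c(lines, "# Run report", "",
             sprintf("Master seed: %d", manifest$masterSeed), "")

  plotTo <- function(file, expr) {
    grDevices::png(file.path(figdir, file), width = 900, height = 700)
    on.exit(grDevices::dev.off())
    force(expr)
    figures <<- c(figures, file)
  }

  for (nm in designs) {
    impFile <- file.path(outdir, paste0("importance_", nm, ".csv"))
    if (file.exists(impFile)) {
      imp <- utils::read.csv(impFile)
      plotTo(paste0("importance_", nm, ".png"), {
        graphics::barplot(imp$importance, names.arg = imp$variable,
                          las = 2, main = paste("Permutation importance -",
                                                nm),
                          ylab = "normalized AUC drop")
      })
      lines <- c(lines, sprintf("## Design %s", nm), "",
                 "Importance ranking: ",
                 paste(imp$variable, collapse = " > "), "")
    } else missing <- c(missing, impFile)

    rcFile <- file.path(outdir, paste0("response_", nm, ".csv"))
    if (file.exists(rcFile)) {
      rc <- utils::read.csv(rcFile)
      vars <- unique(rc$variable)
      plotTo(paste0("response_", nm, ".png"), {
        graphics::par(mfrow = c(2, 3))
        for (v in vars) {
          d <- rc[rc$variable == v, ]
          graphics::plot(d$x, d$p, type = "l", main = v, xlab = v,
                         ylab = "suitability", ylim = c(0, 1))
        }
      })
      lines <- c(lines, sprintf("Response curves (%d predictors): %s",
                                length(vars), paste(vars, collapse = ", ")),
                 "")
    } else missing <- c(missing, rcFile)

    suitFile <- file.path(outdir, paste0("suitability_", nm, ".tif"))
    if (file.exists(suitFile)) {
      g <- readGrid(suitFile)
      plotTo(paste0("suitability_", nm, ".png"), {
        graphics::image(t(g@values)[, nrow(g@values):1],
                        main = paste("Suitability -", nm), useRaster = TRUE)
      })
    } else missing <- c(missing, suitFile)

    valFile <- file.path(outdir, paste0("validation_", nm, ".json"))
    if (file.exists(valFile)) {
      v <- jsonlite::read_json(valFile, simplifyVector = TRUE)
      lines <- c(lines, sprintf(
        "Validation (%s): observed mean %.4g, null mean %.4g (CI %.4g-%.4g), p = %.4g -> %s",
        nm, v$observed$mean, v$nullMeanOfGroupMeans, v$nullCI95[1],
        v$nullCI95[2], v$pValue$mean, v$verdict), "")
    }
  }

  diffFile <- file.path(outdir, "difference.tif")
  if (file.exists(diffFile)) {
    g <- readGrid(diffFile)
    plotTo("difference.png", {
      graphics::image(t(g@values)[, nrow(g@values):1],
                      main = "Between-design suitability difference",
                      useRaster = TRUE)
    })
    lines <- c(lines, "One between-design difference map: difference.png", "")
  } else if (length(designs) >= 2) missing <- c(missing, diffFile)

  limFile <- file.path(outdir, paste0("limiting_", designs[1], ".tif"))
  if (file.exists(limFile)) {
    g <- readGrid(limFile)
    plotTo("limiting.png", {
      graphics::image(t(g@values)[, nrow(g@values):1],
                      main = "Limiting factor", useRaster = TRUE)
    })
  }

  if (length(missing))
    lines <- c(lines, "## Missing outputs", "", paste("-", missing), "")
  lines <- c(lines, "## Figures", "", paste("-", figures))
  writeLines(lines, file.path(figdir, "report.md"))
  invisible(list(report = file.path(figdir, "report.md"),
                 figures = figures, missing = missing))
}
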