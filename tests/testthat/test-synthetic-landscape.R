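test_that("landscape generation is bit-identical under a fixed seed", {
  cfg <- landscapeConfig(shape = c(20, 20), seed = 99)
  a <- generateLandscape(cfg)
  b <- generateLandscape(cfg)
  for (nm in c("elevation", "vegetation"))
    expect_identical(gridValues(getLayer(a$fine, nm)),
                     gridValues(getLayer(b$fine, nm)))
  for (nm in c("tmin_july", "precip_ann"))
    expect_identical(gridValues(getLayer(a$coarse, nm)),
                     gridValues(getLayer(b$coarse, nm)))
})

test_that("smoothing length controls spatial autocorrelation of elevation", {
  cfg0 <- landscapeConfig(shape = c(30, 30),
                          smoothLengths = c(elevation = 0, vegetation = 5,
                                            climate = 5), seed = 7)
  cfg6 <- landscapeConfig(shape = c(30, 30),
                          smoothLengths = c(elevation = 6, vegetation = 5,
                                            climate = 5), seed = 7)
  lag1 <- function(m) stats::cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  e0 <- gridValues(getLayer(generateLandscape(cfg0)$fine, "elevation"))
  e6 <- gridValues(getLayer(generateLandscape(cfg6)$fine, "elevation"))
  expect_lt(abs(lag1(e0)), 0.06)   # unsmoothed field behaves as white noise
  expect_gt(lag1(e6), 0.5)
})

test_that("with zero lapse rate and zero noise, tmin depends on row only", {
  cfg <- landscapeConfig(shape = c(15, 12), lapseRate = 0, tminNoiseSd = 0,
                         seed = 3)
  tmin <- gridValues(getLayer(generateLandscape(cfg)$coarse, "tmin_july"))
  expect_equal(apply(tmin, 1, function(r) diff(range(r))), rep(0, 15),
               tolerance = 1e-9)
  expect_equal(tmin[, 1], cfg$tminBase + cfg$tminRowGradient * 1:15)
})

test_that("vegetation mosaic hits configured class proportions", {
  cfg <- landscapeConfig(shape = c(50, 50), seed = 21)
  veg <- gridValues(getLayer(generateLandscape(cfg)$fine, "vegetation"))
  props <- as.numeric(table(veg)[as.character(cfg$vegClasses)]) / length(veg)
  expect_equal(props, cfg$vegProps, tolerance = 0.01)
})

test_that("true suitability follows its closed form", {
  mk <- function(r, t, p, w)
    layerStack(roughness = rasterGrid(matrix(r, 1, 1), 1),
               tmin_july = rasterGrid(matrix(t, 1, 1), 1),
               precip_ann = rasterGrid(matrix(p, 1, 1), 1),
               woodland = rasterGrid(matrix(w, 1, 1), 1))
  tp0 <- truthParams(coefRough = 0, coefPrecip = 0, coefTmin = 0,
                     coefWood = 0, intercept = -2)
  expect_equal(gridValues(trueSuitability(mk(100, 5, 800, 0.5), tp0))[1, 1],
               plogis(-2))

  # monotone below saturation, flat beyond
  tp <- truthParams()
  at <- function(r) gridValues(trueSuitability(mk(r, 5, 800, 0.5), tp))[1, 1]
  expect_gt(at(tp$roughSat), at(0))
  expect_gt(at(150), at(50))
  expect_equal(at(tp$roughSat), at(tp$roughSat + 200))

  # closed-form check at the precipitation optimum vs the low cut
  hw <- (tp$precipHigh - tp$precipLow) / 2
  linAt <- function(p) tp$intercept +
    tp$coefRough * min(100, tp$roughSat) / tp$roughSat +
    tp$coefPrecip * max(1 - ((p - tp$precipOpt) / hw)^2, -1) +
    tp$coefTmin * 1 + tp$coefWood * 0.5
  pAt <- function(p) gridValues(trueSuitability(mk(100, 5, p, 0.5), tp))[1, 1]
  expect_equal(pAt(tp$precipOpt), plogis(linAt(tp$precipOpt)))
  expect_equal(pAt(tp$precipLow), plogis(linAt(tp$precipLow)))
  expect_gt(pAt(tp$precipOpt), pAt(tp$precipLow))

  expect_error(trueSuitability(layerStack(roughness = rasterGrid(matrix(1))),
                               tp), "missing layer")
})

test_that("occurrence sampling concentrates on suitable cells", {
  one <- matrix(0, 5, 5); one[3, 4] <- 1
  occ <- sampleOccurrences(rasterGrid(one, 1), 50, 0, 0, seed = 1)
  r <- occurrenceRecords(occ)
  expect_equal(nrow(r), 50)
  expect_true(all(r$x == 3.5 & r$y == 2.5))

  expect_error(sampleOccurrences(rasterGrid(matrix(0, 2, 2), 1), 5, 0, 0,
                                 seed = 1), "all zero")
})

test_that("occurrence sampling frequencies match suitability weights", {
  two <- rasterGrid(matrix(c(0.8, 0.2), 1, 2), 1)
  r <- occurrenceRecords(sampleOccurrences(two, 10000, 0, 0, seed = 8))
  prop1 <- mean(r$x < 1)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(prop1 - 0.8), 3 * se)

  # chi-square goodness of fit on a multi-cell surface
  set.seed(5)
  w <- matrix(runif(25, 0.1, 1), 5, 5)
  occ <- occurrenceRecords(sampleOccurrences(rasterGrid(w, 1), 20000, 0, 0,
                                             seed = 13))
  idx <- pointToCell(rasterGrid(w, 1), occ$x, occ$y)
  counts <- tabulate(idx$cell, nbins = 25)
  gof <- suppressWarnings(chisq.test(counts, p = as.vector(w) / sum(w)))
  expect_gt(gof$p.value, 0.01)
})

test_that("duplicate and coarse-accuracy artefacts are injected as
           configured", {
  w <- rasterGrid(matrix(runif(100, 0.2, 1), 10, 10), 1)
  occ <- occurrenceRecords(sampleOccurrences(w, 200, 0.2, 0.25, seed = 4))
  expect_equal(nrow(occ), 240)                  # 200 + floor(0.2 * 200)
  expect_equal(sum(occ$uncertainty_m > 1000), sum(occ$uncertainty_m > 1500))
  # with artefact rates zero every record is unique and fine-accuracy
  clean <- occurrenceRecords(sampleOccurrences(w, 300, 0, 0, seed = 4))
  expect_equal(nrow(clean), 300)
  expect_true(all(clean$uncertainty_m <= 1000))
})
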