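test_that("hinge feature construction handles constants, knot placement and
           deduplication", {
  p <- data.frame(a = runif(20), b = 1, c = rep(c(1, 2, 3, 4, 5), 4))
  b <- data.frame(a = runif(50), b = 1, c = rep(c(1, 2, 3, 4, 5), 10))
  fs <- buildFeatures(p, b, maxentConfig(knotsPerVariable = 30))
  tab <- featureTable(fs)
  expect_false("b" %in% tab$variable)        # constant -> zero features
  # 30 knots on 5 distinct values collapse to at most 10 hinges
  expect_lte(sum(tab$variable == "c"), 10)
  expect_true(all(tab$knot > tab$vmin & tab$knot < tab$vmax))
})

test_that("hinge features map to [0,1] with the stated endpoint values", {
  p <- data.frame(a = c(0, 10)); b <- data.frame(a = seq(0, 10, 1))
  fs <- buildFeatures(p, b, maxentConfig(knotsPerVariable = 3))
  tab <- featureTable(fs)
  Fm <- featureValues(fs, data.frame(a = c(tab$knot[1], 10, 0, -5, 50)))
  fwd <- which(tab$direction == "forward")[1]
  expect_equal(unname(Fm[1, fwd]), 0)        # at the knot
  expect_equal(unname(Fm[2, fwd]), 1)        # at the max
  expect_true(all(Fm >= 0 & Fm <= 1))        # clamped outside the range
})

test_that("fitted coefficients match an independent dense grid search", {
  set.seed(42)
  p <- data.frame(v = runif(20, 0.5, 1))
  b <- data.frame(v = runif(100, 0, 1))
  cfg <- maxentConfig(knotsPerVariable = 1, convergenceTol = 1e-12)
  fs <- buildFeatures(p, b, cfg)
  fit <- fitMaxent(p, b, cfg, features = fs)
  Fp <- featureValues(fs, p); Fb <- featureValues(fs, b)
  reg <- 2.5 * sqrt(pmax(pmax(apply(Fp, 2, var), 0), 1e-6) / nrow(Fp))
  oracle <- oracleGridSearch(Fp, Fb, reg)
  expect_equal(modelCoefficients(fit), oracle$lambda, tolerance = 1e-3)
  expect_lte(fit@objective, oracle$objective + 1e-6)
})

test_that("zero-feature and dominated-penalty fits reduce to the null
           model", {
  p <- data.frame(v = rep(2, 6)); b <- data.frame(v = rep(2, 40))
  fit <- fitMaxent(p, b)
  expect_length(modelCoefficients(fit), 0)
  expect_equal(predictRaw(fit, b), rep(1 / 40, 40))
  expect_equal(fit@entropy, log(40))
  expect_equal(predictLogistic(fit, data.frame(v = c(1, 5))), c(0.3, 0.3))

  set.seed(1)
  p2 <- data.frame(v = runif(15, 0.4, 1)); b2 <- data.frame(v = runif(80))
  huge <- fitMaxent(p2, b2, maxentConfig(betaMultiplier = 1e6,
                                         knotsPerVariable = 6))
  expect_true(all(modelCoefficients(huge) == 0))
})

test_that("the fit never does worse than the zero model and its optimum is
           monotone in beta", {
  set.seed(7)
  p <- data.frame(v = runif(25, 0.3, 1), w = rnorm(25, 1))
  b <- data.frame(v = runif(120), w = rnorm(120))
  objs <- vapply(c(0.5, 1, 2.5, 5, 20), function(beta) {
    fitMaxent(p, b, maxentConfig(betaMultiplier = beta,
                                 knotsPerVariable = 4))@objective
  }, numeric(1))
  expect_lte(objs[3], 0)                     # zero vector gives objective 0
  expect_true(all(diff(objs) >= -1e-9))      # larger beta, larger minimum
})

test_that("raw predictions normalize over the training background", {
  set.seed(12)
  p <- data.frame(v = runif(30, 0.5, 1), w = runif(30))
  b <- data.frame(v = runif(300), w = runif(300))
  fit <- fitMaxent(p, b)
  expect_lt(abs(sum(predictRaw(fit, b)) - 1), 1e-10)
  expect_equal(sum(predictRaw(fit, p, renormalize = TRUE)), 1)
})

test_that("raw prediction equals direct Gibbs arithmetic on a toy model", {
  fs <- new("FeatureSet", table = data.frame(
    variable = "v", direction = "forward", knot = 0, vmin = -1, vmax = 2))
  # lambda = 0.5, background features f = (0, 0.5, 1)
  bg <- data.frame(v = c(0, 1, 2))
  model <- new("MaxentModel", features = fs, coefficients = 0.5,
               logZ = log(sum(exp(0.5 * c(0, 0.5, 1)))),
               entropy = 1, tau = 0.3,
               presenceMeans = c(v = 1), objective = 0)
  expected <- exp(0.5 * c(0, 0.5, 1)) / sum(exp(0.5 * c(0, 0.5, 1)))
  expect_equal(predictRaw(model, bg), expected)
})

test_that("the logistic transform follows its closed form", {
  # hand-built model where exp(H) * q = 2 at the probed point:
  # q = exp(eta - logZ); choose eta = 0, logZ = log(5), H = log(10)
  fs <- new("FeatureSet", table = data.frame(
    variable = "v", direction = "forward", knot = 0.5, vmin = 0, vmax = 1))
  model <- new("MaxentModel", features = fs, coefficients = 0,
               logZ = log(5), entropy = log(10), tau = 0.3,
               presenceMeans = c(v = 0.5), objective = 0)
  p <- predictLogistic(model, data.frame(v = 0.2))
  expect_equal(p, 0.3 * 2 / (1 - 0.3 + 0.3 * 2))   # = 0.6 / 1.3
  model@tau <- 0.5
  expect_equal(predictLogistic(model, data.frame(v = 0.2)),
               0.5 * 2 / (0.5 + 0.5 * 2))
})

test_that("predictions are invariant to positive rescaling of a raw
           predictor", {
  set.seed(9)
  p <- data.frame(v = runif(25, 0.4, 1)); b <- data.frame(v = runif(150))
  f1 <- fitMaxent(p, b, maxentConfig(knotsPerVariable = 8))
  f2 <- fitMaxent(p * 1000, b * 1000, maxentConfig(knotsPerVariable = 8))
  probe <- data.frame(v = seq(0.05, 0.95, 0.1))
  expect_equal(predictLogistic(f1, probe),
               predictLogistic(f2, probe * 1000), tolerance = 1e-8)
})

test_that("model JSON serialization round-trips predictions exactly", {
  set.seed(4)
  p <- data.frame(v = runif(20, 0.3, 1), w = runif(20))
  b <- data.frame(v = runif(100), w = runif(100))
  fit <- fitMaxent(p, b, maxentConfig(knotsPerVariable = 5))
  tf <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(fit, tf)
  back <- readModelJSON(tf)
  expect_identical(modelCoefficients(back), modelCoefficients(fit))
  expect_identical(predictLogistic(back, b), predictLogistic(fit, b))
})

test_that("response curves are flat for inactive variables and monotone for
           a single positive hinge", {
  set.seed(15)
  p <- data.frame(v = runif(25, 0.6, 1), noise = runif(25))
  b <- data.frame(v = runif(200), noise = runif(200))
  fit <- fitMaxent(p, b, maxentConfig(knotsPerVariable = 4))
  co <- modelCoefficients(fit); tab <- featureTable(fit)
  rcV <- responseCurve(fit, "v")
  if (all(co[tab$variable == "noise"] == 0)) {
    rcN <- responseCurve(fit, "noise")
    expect_lt(diff(range(rcN$p)), 1e-12)
  }
  expect_gt(max(rcV$p), min(rcV$p))
  expect_error(responseCurve(fit, "zz"), "unknown variable")

  # single forward hinge with positive coefficient -> non-decreasing curve
  fs <- new("FeatureSet", table = data.frame(
    variable = "v", direction = "forward", knot = 0.4, vmin = 0, vmax = 1))
  mono <- new("MaxentModel", features = fs, coefficients = 2, logZ = 0,
              entropy = 1, tau = 0.3, presenceMeans = c(v = 0.5),
              objective = 0)
  rc <- responseCurve(mono, "v")
  expect_true(all(diff(rc$p) >= 0))
})

test_that("limiting factor matches exhaustive replacement on a toy grid", {
  set.seed(33)
  p <- data.frame(a = runif(30, 0.6, 1), b = runif(30, 0, 0.4))
  bg <- data.frame(a = runif(200), b = runif(200))
  fit <- fitMaxent(p, bg, maxentConfig(knotsPerVariable = 4))
  stack <- layerStack(a = rasterGrid(matrix(c(0.1, 0.9, 0.5, 0.2), 2, 2), 1),
                      b = rasterGrid(matrix(c(0.9, 0.1, 0.5, 0.8), 2, 2), 1))
  lf <- limitingFactor(fit, stack, c("a", "b"))
  for (cell in 1:4) {
    vals <- data.frame(a = gridValues(getLayer(stack, "a"))[cell],
                       b = gridValues(getLayer(stack, "b"))[cell])
    base <- predictLogistic(fit, vals)
    deltas <- vapply(c("a", "b"), function(v) {
      mod <- vals; mod[[v]] <- fit@presenceMeans[[v]]
      predictLogistic(fit, mod) - base
    }, numeric(1))
    expect_equal(gridValues(lf$grid)[cell], unname(which.max(deltas)))
  }
})

test_that("ties in limiting factor resolve to canonical layer order", {
  fs <- new("FeatureSet", table = data.frame(
    variable = c("a", "b"), direction = "forward", knot = c(0.5, 0.5),
    vmin = 0, vmax = 1))
  model <- new("MaxentModel", features = fs, coefficients = c(1, 1),
               logZ = 0, entropy = 1, tau = 0.3,
               presenceMeans = c(a = 0.25, b = 0.25), objective = 0)
  stack <- layerStack(a = rasterGrid(matrix(0.25), 1),
                      b = rasterGrid(matrix(0.25), 1))
  lf <- limitingFactor(model, stack, c("a", "b"))
  expect_equal(gridValues(lf$grid)[1, 1], 1)   # all changes zero -> first
})
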