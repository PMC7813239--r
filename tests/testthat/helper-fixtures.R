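# Shared fixtures and independent oracles.

# Small landscape with derived predictor stack, truth surface and extracted
# presence/background tables. Everything downstream of the generator uses
# the package API; the oracles in individual tests stay independent.
makeStudy <- function(seed, shape = c(60, 60), nOcc = 400, nBg = 2000,
                      dupRate = 0.1, coarseRate = 0.1) {
  land <- generateLandscape(landscapeConfig(
    shape = shape, seed = stageSeed(seed, "landscape")))
  pc <- predictorConfig()
  elev <- getLayer(land$fine, "elevation")
  rough <- blockAggregate(terrainRoughness(elev), pc$factor, mean)
  vf <- vegetationFractions(getLayer(land$fine, "vegetation"), pc)
  stack <- layerStack(
    roughness = rough,
    aspect_north = aspectNorthFraction(elev, pc),
    woodland = vf$woodland, grassland = vf$grassland,
    tmin_july = getLayer(land$coarse, "tmin_july"),
    precip_ann = getLayer(land$coarse, "precip_ann"))
  truthStack <- layerStack(roughness = rough,
                           tmin_july = getLayer(land$coarse, "tmin_july"),
                           precip_ann = getLayer(land$coarse, "precip_ann"),
                           woodland = vf$woodland)
  suit <- trueSuitability(truthStack, truthParams())
  occ <- filterOccurrences(sampleOccurrences(
    suit, nOcc, dupRate, coarseRate, seed = stageSeed(seed, "occ")))
  bg <- sampleBackground(NULL, rough, nBg, seed = stageSeed(seed, "bg"))
  pv <- extractAt(stack, occurrenceRecords(occ)$x, occurrenceRecords(occ)$y)
  pv <- pv[stats::complete.cases(pv), , drop = FALSE]
  bv <- extractAt(stack, bg$x, bg$y)
  bv <- bv[stats::complete.cases(bv), , drop = FALSE]
  list(land = land, stack = stack, suit = suit, occ = occ, bg = bg,
       pv = pv, bv = bv)
}

# Independent oracle for the penalized maxent objective: iteratively
# refined dense grid search, no reuse of the package solver.
oracleObjective <- function(lambda, Fp, Fb, reg) {
  etab <- Fb %*% lambda
  -mean(Fp %*% lambda) + log(sum(exp(etab))) - log(nrow(Fb)) +
    sum(reg * abs(lambda))
}

oracleGridSearch <- function(Fp, Fb, reg, lo = -15, hi = 15) {
  J <- ncol(Fp)
  center <- rep(0, J); half <- (hi - lo) / 2
  for (round in 1:6) {
    axes <- lapply(seq_len(J), function(j)
      seq(center[j] - half, center[j] + half, length.out = 41))
    grid <- as.matrix(do.call(expand.grid, axes))
    vals <- apply(grid, 1, oracleObjective, Fp = Fp, Fb = Fb, reg = reg)
    center <- grid[which.min(vals), ]
    half <- half / 10
  }
  list(lambda = as.numeric(center), objective = min(vals))
}

# Brute-force pairwise AUC
bruteAUC <- function(p, b) {
  s <- 0
  for (x in p) s <- s + sum(x > b) + 0.5 * sum(x == b)
  s / (length(p) * length(b))
}

# Brute-force TSS by scanning every unique score as threshold
bruteTSS <- function(p, b) {
  thr <- sort(unique(c(p, b)))
  best <- -Inf; bestT <- NA
  for (t in thr) {
    v <- mean(p >= t) + mean(b < t) - 1
    if (v > best) { best <- v; bestT <- t }
  }
  list(tss = best, threshold = bestT)
}

# Brute-force downslope aspect (degrees clockwise from north) of one
# interior cell via central differences, written independently of the
# package implementation.
bruteAspect <- function(m, i, j, cell = 1) {
  dzdx <- (m[i, j + 1] - m[i, j - 1]) / (2 * cell)
  dzdy <- (m[i - 1, j] - m[i + 1, j]) / (2 * cell)
  if (dzdx == 0 && dzdy == 0) return(NA_real_)
  (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
}

# Minimal two-band uncompressed TIFF, used to test band-count rejection
writeTwoBandTiff <- function(path, w = 2, h = 2) {
  u16 <- function(x) writeBin(as.integer(x), raw(), 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), 4, endian = "little")
  px <- as.raw(seq_len(w * h * 2))           # 8-bit, 2 samples per pixel
  entry <- function(tag, type, count, value) {
    val <- if (type == 3) c(u16(value), raw(2)) else u32(value)
    c(u16(tag), u16(type), u32(count), val)
  }
  entries <- list(entry(256, 4, 1, w), entry(257, 4, 1, h),
                  entry(259, 3, 1, 1), entry(262, 3, 1, 1),
                  entry(273, 4, 1, 8), entry(277, 3, 1, 2),
                  entry(278, 4, 1, h), entry(279, 4, 1, length(px)),
                  entry(284, 3, 1, 1))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con); writeBin(u16(42), con)
  writeBin(u32(8 + length(px)), con)
  writeBin(px, con)
  writeBin(u16(length(entries)), con)
  for (e in entries) writeBin(e, con)
  writeBin(u32(0), con)
  invisible(path)
}
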