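test_that("GeoTIFF write/read round-trips values, mask and geometry", {
  v <- matrix(rnorm(35), 5, 7)
  v[2, 3] <- NA; v[5, 1] <- NA
  g <- rasterGrid(v, cellSize = 250, origin = c(1000, 2250),
                  crs = "EPSG:3577")
  tf <- withr::local_tempfile(fileext = ".tif")
  writeGrid(g, tf)
  g2 <- readGrid(tf)
  expect_identical(gridValues(g2), gridValues(g))
  expect_identical(nodataMask(g2), nodataMask(g))
  expect_equal(cellSize(g2), 250)
  expect_equal(gridOrigin(g2), c(1000, 2250))
  expect_equal(crsTag(g2), "EPSG:3577")
})

test_that("all-nodata and constant grids survive the file round trip", {
  allNA <- rasterGrid(matrix(NA_real_, 3, 3))
  tf <- withr::local_tempfile(fileext = ".tif")
  writeGrid(allNA, tf)
  expect_true(all(nodataMask(readGrid(tf))))

  const <- rasterGrid(matrix(4.25, 4, 4), cellSize = 10)
  writeGrid(const, tf)
  vals <- gridValues(readGrid(tf))
  expect_identical(range(vals), c(4.25, 4.25))
})

test_that("reader rejects missing files and multi-band rasters", {
  expect_error(readGrid("no/such/file.tif"), "not found")
  tf <- withr::local_tempfile(fileext = ".tif")
  writeTwoBandTiff(tf)
  expect_error(readGrid(tf), "2 bands")
})

test_that("block aggregation handles short edge blocks and nodata", {
  v <- matrix(1:25, 5, 5)
  g <- rasterGrid(v, cellSize = 1)
  agg <- blockAggregate(g, 2, mean)
  expect_equal(dim(agg), c(3, 3))
  expect_equal(gridValues(agg)[1, 1], mean(v[1:2, 1:2]))
  # bottom-right edge block is a single cell
  expect_equal(gridValues(agg)[3, 3], v[5, 5])

  v[1, 1] <- NA
  aggNA <- blockAggregate(rasterGrid(v, 1), 2, mean)
  expect_equal(gridValues(aggNA)[1, 1], mean(v[1:2, 1:2], na.rm = TRUE))
})

test_that("aggregateFraction follows the excluded-class denominator rule", {
  # 4x4 blocks: all include -> 1; half include half other -> 0.5;
  # half include half excluded -> 1 (excluded cells leave the denominator)
  b1 <- matrix(1, 4, 4)
  b2 <- matrix(c(rep(1, 8), rep(2, 8)), 4, 4)
  b3 <- matrix(c(rep(1, 8), rep(9, 8)), 4, 4)
  fine <- rasterGrid(cbind(rbind(b1, b2), rbind(b3, b1)), 1)
  out <- aggregateFraction(fine, includeCodes = 1, excludeCodes = 9,
                           factor = 4)
  expect_equal(gridValues(out)[1, 1], 1)
  expect_equal(gridValues(out)[2, 1], 0.5)
  expect_equal(gridValues(out)[1, 2], 1)
  expect_error(aggregateFraction(fine, 1, c(1, 9), 4), "overlap")
})

test_that("include-fractions over a category partition sum to one", {
  set.seed(31)
  fine <- rasterGrid(matrix(sample(1:3, 64, replace = TRUE), 8, 8), 1)
  tot <- Reduce(`+`, lapply(1:3, function(code)
    gridValues(aggregateFraction(fine, code, integer(), 4))))
  expect_equal(tot, matrix(1, 2, 2))
})

test_that("grid difference is cellwise with mask union, and rejects
           geometry mismatch", {
  a <- rasterGrid(matrix(runif(12), 3, 4), 1)
  expect_true(all(gridValues(gridDifference(a, a)) == 0))

  b <- rasterGrid(gridValues(a) + 0.3, 1)
  expect_equal(gridValues(gridDifference(b, a)),
               matrix(0.3, 3, 4), tolerance = 1e-12)

  va <- gridValues(a); va[1, 1] <- NA
  d <- gridDifference(rasterGrid(va, 1), a)
  expect_true(is.na(gridValues(d)[1, 1]))

  expect_error(gridDifference(a, rasterGrid(matrix(0, 4, 3), 1)),
               "geometries differ")
})

test_that("point/cell lookup follows the upper-left origin convention", {
  g <- rasterGrid(matrix(1:12, 3, 4), cellSize = 10, origin = c(0, 30))
  cc <- cellCenters(g, rows = 1, cols = 1)
  expect_equal(c(cc$x, cc$y), c(5, 25))
  idx <- pointToCell(g, c(5, 35, -1), c(25, 5, 5))
  expect_equal(idx$row[1:2], c(1, 3))
  expect_equal(idx$col[1:2], c(1, 4))
  expect_true(is.na(idx$row[3]))
  # extraction at centers reproduces the matrix
  all <- cellCenters(g)
  expect_equal(extractAt(g, all$x, all$y),
               gridValues(g)[cbind(all$row, all$col)])
})

test_that("region masks agree across rectangle, polygon and grid forms", {
  g <- rasterGrid(matrix(0, 10, 10), 1)
  rm <- rectMask(2, 5, 3, 6)
  pm <- polygonMask(cbind(c(2, 5, 5, 2), c(3, 3, 6, 6)))
  mv <- matrix(0, 10, 10)
  cc <- cellCenters(g)
  inside <- cc$x >= 2 & cc$x <= 5 & cc$y >= 3 & cc$y <= 6
  mv[cbind(cc$row, cc$col)] <- as.numeric(inside)
  gm <- gridMask(rasterGrid(mv, 1))
  px <- runif(200, 0, 10); py <- runif(200, 0, 10)
  expect_equal(maskContains(rm, px, py), maskContains(gm, px, py))
  # polygon boundary semantics may differ at edges; compare interiors
  strict <- px > 2.01 & px < 4.99 & py > 3.01 & py < 5.99
  expect_equal(maskContains(pm, px, py)[strict],
               maskContains(rm, px, py)[strict])
})

test_that("stage seeds are deterministic, distinct and 31-bit", {
  s1 <- stageSeed(42, "landscape")
  expect_identical(s1, stageSeed(42, "landscape"))
  expect_false(s1 == stageSeed(42, "occurrences"))
  expect_false(s1 == stageSeed(43, "landscape"))
  seeds <- vapply(1:100, function(i) stageSeed(i, "x"), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("stack validity enforces shared geometry and named layers", {
  a <- rasterGrid(matrix(0, 3, 3), 1)
  expect_error(layerStack(a = a, b = rasterGrid(matrix(0, 4, 3), 1)),
               "share geometry")
  expect_error(layerStack(list(a, a)), "names")
  st <- layerStack(a = a, b = rasterGrid(matrix(c(NA, rep(1, 8)), 3, 3), 1))
  expect_equal(layerNames(st), c("a", "b"))
  expect_true(nodataMask(st)[1, 1])
  expect_error(getLayer(st, "zz"), "no layer")
})
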