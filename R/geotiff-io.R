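# Minimal single-band GeoTIFF I/O.
#
# Uncompressed, single-strip-per-file little-endian TIFF with 64-bit float
# samples plus the GeoTIFF georeferencing tags (ModelPixelScale,
# ModelTiepoint, GeoKeyDirectory/GeoAsciiParams for the CRS citation) and
# the GDAL_NODATA ASCII tag. The reader also accepts big-endian files,
# multiple strips and 8/16/32-bit integer or 32-bit float samples so that
# externally produced rasters can be consumed; it rejects multi-band files
# and non-square cells.

.TIFF_NODATA <- -3.4028234663852886e+38

.tiffTypeSize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L,
                   `12` = 8L)

.readTag <- function(con, endian) {
  tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  type <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  count <- readBin(con, "integer", 1, 4, endian = endian)
  raw4 <- readBin(con, "raw", 4)
  list(tag = tag, type = type, count = count, raw = raw4)
}

.tagValues <- function(entry, con, endian) {
  size <- .tiffTypeSize[as.character(entry$type)]
  if (is.na(size)) return(NULL)
  nbytes <- size * entry$count
  if (nbytes <= 4) {
    raw <- entry$raw[seq_len(nbytes)]
  } else {
    off <- readBin(entry$raw, "integer", 1, 4, endian = endian)
    seek(con, off)
    raw <- readBin(con, "raw", nbytes)
  }
  switch(as.character(entry$type),
    `1` = as.numeric(readBin(raw, "integer", entry$count, 1, signed = FALSE)),
    `2` = rawToChar(raw[raw != as.raw(0)]),
    `3` = as.numeric(readBin(raw, "integer", entry$count, 2, signed = FALSE,
                             endian = endian)),
    `4` = as.numeric(readBin(raw, "integer", entry$count, 4, endian = endian)),
    `11` = readBin(raw, "double", entry$count, 4, endian = endian),
    `12` = readBin(raw, "double", entry$count, 8, endian = endian))
}

#' Read a single-band GeoTIFF
#'
#' Reads an uncompressed single-band georeferenced TIFF into a
#' \linkS4class{RasterGrid}. Cells equal to the file's declared nodata value
#' (GDAL_NODATA tag) and NaN cells become nodata. Files with more than one
#' sample per pixel, compressed data or non-square pixels are rejected.
#'
#' @param path path to the file.
#' @return A \linkS4class{RasterGrid}.
#' @seealso \code{\link{writeGrid}}
#' @export
readGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path)
  fortytwo <- readBin(con, "integer", 1, 2, endian = endian)
  if (fortytwo != 42L) stop("not a TIFF file (bad magic): ", path)
  ifdOff <- readBin(con, "integer", 1, 4, endian = endian)
  seek(con, ifdOff)
  n <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) entries[[i]] <- .readTag(con, endian)
  tags <- vapply(entries, `[[`, numeric(1), "tag")
  getv <- function(tag) {
    k <- which(tags == tag)
    if (!length(k)) return(NULL)
    .tagValues(entries[[k[1]]], con, endian)
  }

  spp <- getv(277); spp <- if (is.null(spp)) 1 else spp
  if (spp != 1)
    stop("expected a single-band raster, file has ", spp, " bands")
  comp <- getv(259); if (!is.null(comp) && comp != 1)
    stop("compressed TIFF not supported (compression code ", comp, ")")
  width <- getv(256); height <- getv(257)
  bits <- getv(258); if (is.null(bits)) bits <- 1
  fmt <- getv(339); if (is.null(fmt)) fmt <- 1
  offs <- getv(273); counts <- getv(279)
  rps <- getv(278); if (is.null(rps)) rps <- height
  if (is.null(width) || is.null(height) || is.null(offs))
    stop("malformed TIFF: missing required tags")

  vals <- numeric(0)
  for (s in seq_along(offs)) {
    seek(con, offs[s])
    npix <- counts[s] / (bits / 8)
    v <- if (fmt == 3 && bits == 64)
      readBin(con, "double", npix, 8, endian = endian)
    else if (fmt == 3 && bits == 32)
      readBin(con, "double", npix, 4, endian = endian)
    else if (bits == 8)
      as.numeric(readBin(con, "integer", npix, 1, signed = (fmt == 2)))
    else if (bits == 16)
      as.numeric(readBin(con, "integer", npix, 2, signed = (fmt == 2),
                         endian = endian))
    else if (bits == 32)
      as.numeric(readBin(con, "integer", npix, 4, endian = endian))
    else stop("unsupported sample layout: ", bits, "-bit format ", fmt)
    vals <- c(vals, v)
  }
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)

  nodata <- getv(42113)
  if (!is.null(nodata)) {
    nd <- suppressWarnings(as.numeric(nodata))
    if (is.finite(nd)) m[m == nd] <- NA_real_
  }
  m[is.nan(m)] <- NA_real_

  scale <- getv(33550); tie <- getv(33922)
  cellSize <- 1; origin <- c(0, height)
  if (!is.null(scale)) {
    if (abs(scale[1] - scale[2]) > 1e-9 * max(scale[1], scale[2]))
      stop(sprintf("non-square cells (%g x %g) not supported",
                   scale[1], scale[2]))
    cellSize <- scale[1]
  }
  if (!is.null(tie)) {
    # tiepoint maps raster point (I, J) to model (X, Y)
    origin <- c(tie[4] - tie[1] * cellSize, tie[5] + tie[2] * cellSize)
  }
  crs <- getv(34737)
  crs <- if (is.null(crs)) "" else sub("\\|$", "", crs)
  rasterGrid(m, cellSize = cellSize, origin = origin, crs = crs)
}

.u16 <- function(x) writeBin(as.integer(x), raw(), 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), 4, endian = "little")
.f64 <- function(x) writeBin(as.numeric(x), raw(), 8, endian = "little")

#' Write a grid as single-band GeoTIFF
#'
#' Writes an uncompressed little-endian GeoTIFF with 64-bit float samples
#' (values round-trip bit-exactly), ModelPixelScale/ModelTiepoint
#' georeferencing, the CRS tag as a GeoTIFF citation, and the nodata value
#' declared in the GDAL_NODATA tag. Nodata cells are stored as the sentinel
#' value.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param path output path; the parent directory must exist.
#' @param nodata sentinel value written for nodata cells.
#' @return Invisibly, \code{path}.
#' @export
writeGrid <- function(grid, path, nodata = .TIFF_NODATA) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  v <- t(grid@values)                      # row-major pixel order
  v[is.na(v)] <- nodata
  h <- nrow(grid@values); w <- ncol(grid@values)
  dataBytes <- .f64(as.vector(v))
  dataOff <- 8L

  crs <- if (nzchar(grid@crs)) paste0(grid@crs, "|") else "unknown|"
  crsRaw <- c(charToRaw(crs), as.raw(0))
  if (length(crsRaw) %% 2) crsRaw <- c(crsRaw, as.raw(0))
  ndStr <- sprintf("%.17g", nodata)
  ndRaw <- c(charToRaw(ndStr), as.raw(0))
  if (length(ndRaw) %% 2) ndRaw <- c(ndRaw, as.raw(0))

  # external value blocks placed after the pixel data
  extOff <- dataOff + length(dataBytes)
  scaleRaw <- .f64(c(grid@cellSize, grid@cellSize, 0))
  tieRaw <- .f64(c(0, 0, 0, grid@origin[1], grid@origin[2], 0))
  # GeoKeys: ModelType=Projected(1), RasterType=PixelIsArea(1),
  # GTCitation -> GeoAsciiParams
  geoKeys <- c(1, 1, 0, 3,
               1024, 0, 1, 1,
               1025, 0, 1, 1,
               1026, 34737, nchar(crs), 0)
  geoRaw <- .u16(geoKeys)

  blocks <- list(scale = scaleRaw, tie = tieRaw, geo = geoRaw,
                 crs = crsRaw, nd = ndRaw)
  offs <- list(); cur <- extOff
  for (nm in names(blocks)) { offs[[nm]] <- cur; cur <- cur + length(blocks[[nm]]) }
  ifdOff <- cur

  entry <- function(tag, type, count, value, isOffset = FALSE) {
    val <- if (isOffset) .u32(value)
           else if (type == 3) { r <- .u16(value); c(r, raw(4 - length(r))) }
           else .u32(value)
    c(.u16(tag), .u16(type), .u32(count), val)
  }
  entries <- list(
    entry(256, 4, 1, w),
    entry(257, 4, 1, h),
    entry(258, 3, 1, 64),
    entry(259, 3, 1, 1),
    entry(262, 3, 1, 1),
    entry(273, 4, 1, dataOff),
    entry(277, 3, 1, 1),
    entry(278, 4, 1, h),
    entry(279, 4, 1, length(dataBytes)),
    entry(284, 3, 1, 1),
    entry(339, 3, 1, 3),
    entry(33550, 12, 3, offs$scale, TRUE),
    entry(33922, 12, 6, offs$tie, TRUE),
    entry(34735, 3, length(geoKeys), offs$geo, TRUE),
    entry(34737, 2, length(crsRaw), offs$crs, TRUE),
    entry(42113, 2, length(ndRaw), offs$nd, TRUE))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.u16(42), con)
  writeBin(.u32(ifdOff), con)
  writeBin(dataBytes, con)
  for (b in blocks) writeBin(b, con)
  writeBin(.u16(length(entries)), con)
  for (e in entries) writeBin(e, con)
  writeBin(.u32(0), con)                   # no further IFD
  invisible(path)
}

#' Read/write occurrence CSV
#'
#' CSV interchange with header \code{x,y,uncertainty_m,source,flagged}.
#'
#' @param path file path.
#' @return \code{readOccurrences}: an \linkS4class{OccurrenceSet}.
#' @export
readOccurrences <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "uncertainty_m", "source", "flagged")
  if (!all(need %in% names(r)))
    stop("occurrence CSV must have columns ", paste(need, collapse = ", "))
  occurrenceSet(r$x, r$y, r$uncertainty_m, r$source, as.logical(r$flagged))
}

#' @rdname readOccurrences
#' @param occ an \linkS4class{OccurrenceSet}.
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(occ@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
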