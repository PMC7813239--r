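#' Cell-center coordinates
#'
#' Coordinates of cell centers under the package convention: origin is the
#' upper-left corner, x increases with column index, y decreases with row
#' index.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param rows,cols cell indices (1-based); defaults cover the whole grid.
#' @return data.frame with columns row, col, x, y.
#' @export
cellCenters <- function(grid, rows = NULL, cols = NULL) {
  d <- dim(grid)
  if (is.null(rows)) {
    idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
    rows <- idx$row; cols <- idx$col
  }
  data.frame(row = rows, col = cols,
             x = grid@origin[1] + (cols - 0.5) * grid@cellSize,
             y = grid@origin[2] - (rows - 0.5) * grid@cellSize)
}

#' Map points to cell indices
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param x,y point coordinates.
#' @return data.frame with row, col (NA for points off the grid) and the
#'   linear cell index (column-major, as R matrices are stored).
#' @export
pointToCell <- function(grid, x, y) {
  d <- dim(grid)
  col <- floor((x - grid@origin[1]) / grid@cellSize) + 1L
  row <- floor((grid@origin[2] - y) / grid@cellSize) + 1L
  off <- row < 1L | row > d[1] | col < 1L | col > d[2]
  row[off] <- NA_integer_; col[off] <- NA_integer_
  data.frame(row = row, col = col, cell = (col - 1L) * d[1] + row)
}

#' Extract layer values at points
#'
#' @param x a \linkS4class{RasterGrid} or \linkS4class{RasterLayerStack}.
#' @param px,py point coordinates.
#' @return For a grid, a numeric vector; for a stack, a data.frame with one
#'   column per layer (NA where a point is off-grid or on nodata).
#' @export
extractAt <- function(x, px, py) {
  if (is(x, "RasterGrid")) {
    idx <- pointToCell(x, px, py)
    out <- rep(NA_real_, length(px))
    ok <- !is.na(idx$cell)
    out[ok] <- x@values[idx$cell[ok]]
    return(out)
  }
  stopifnot(is(x, "RasterLayerStack"))
  as.data.frame(lapply(x@layers, extractAt, px = px, py = py))
}

#' Block aggregation of a fine grid
#'
#' Aggregates factor-by-factor blocks of a fine grid to one coarse cell with
#' a summary function (NA cells ignored). Edge blocks shorter than the
#' factor are aggregated over the cells present rather than dropped, so the
#' extent never shrinks.
#'
#' @param grid fine \linkS4class{RasterGrid}.
#' @param factor integer block edge (>= 1).
#' @param fun summary function over a numeric vector (default mean).
#' @return Coarse \linkS4class{RasterGrid}, cell size multiplied by factor.
#' @export
blockAggregate <- function(grid, factor, fun = mean) {
  stopifnot(factor >= 1)
  factor <- as.integer(factor)
  v <- grid@values
  nrc <- ceiling(nrow(v) / factor); ncc <- ceiling(ncol(v) / factor)
  out <- matrix(NA_real_, nrc, ncc)
  for (i in seq_len(nrc)) {
    ri <- ((i - 1L) * factor + 1L):min(i * factor, nrow(v))
    for (j in seq_len(ncc)) {
      cj <- ((j - 1L) * factor + 1L):min(j * factor, ncol(v))
      b <- v[ri, cj]
      b <- b[!is.na(b)]
      if (length(b)) out[i, j] <- fun(b)
    }
  }
  rasterGrid(out, cellSize = grid@cellSize * factor, origin = grid@origin,
             crs = grid@crs)
}

#' Fraction of included category codes per block
#'
#' Aggregates a fine categorical grid to a coarse fraction grid: each coarse
#' cell is the count of cells carrying a code in \code{includeCodes} divided
#' by the count of cells whose code is \emph{not} in \code{excludeCodes}.
#' Excluded codes (water, cleared land, unknown classes) leave the
#' denominator entirely, following the convention that they are omitted from
#' cover calculations. Blocks with zero valid cells become nodata.
#'
#' @param fine fine \linkS4class{RasterGrid} of integer category codes.
#' @param includeCodes codes counted in the numerator.
#' @param excludeCodes codes omitted from the denominator; must be disjoint
#'   from \code{includeCodes}.
#' @param factor integer block edge.
#' @return Coarse \linkS4class{RasterGrid} with values in [0, 1].
#' @export
aggregateFraction <- function(fine, includeCodes, excludeCodes = integer(),
                              factor) {
  if (length(intersect(includeCodes, excludeCodes)))
    stop("includeCodes and excludeCodes overlap: ",
         paste(intersect(includeCodes, excludeCodes), collapse = ", "))
  v <- fine@values
  num <- matrix(as.numeric(!is.na(v) & v %in% includeCodes), nrow(v))
  den <- matrix(as.numeric(!is.na(v) & !(v %in% excludeCodes)), nrow(v))
  gn <- blockAggregate(rasterGrid(num, fine@cellSize, fine@origin, fine@crs),
                       factor, sum)
  gd <- blockAggregate(rasterGrid(den, fine@cellSize, fine@origin, fine@crs),
                       factor, sum)
  frac <- gn@values / gd@values
  frac[!is.finite(frac)] <- NA_real_
  rasterGrid(frac, cellSize = gn@cellSize, origin = gn@origin, crs = gn@crs)
}

#' Cellwise difference of two aligned grids
#'
#' @param a,b \linkS4class{RasterGrid} objects with identical geometry.
#' @return \code{a - b}; nodata wherever either input is nodata.
#' @export
gridDifference <- function(a, b) {
  if (!identical(dim(a@values), dim(b@values)) ||
      a@cellSize != b@cellSize || !identical(a@origin, b@origin))
    stop("grid geometries differ: ",
         sprintf("%dx%d cell %g origin (%g,%g) vs %dx%d cell %g origin (%g,%g)",
                 nrow(a@values), ncol(a@values), a@cellSize,
                 a@origin[1], a@origin[2],
                 nrow(b@values), ncol(b@values), b@cellSize,
                 b@origin[1], b@origin[2]))
  rasterGrid(a@values - b@values, cellSize = a@cellSize, origin = a@origin,
             crs = a@crs)
}

#' Test points against a region mask
#'
#' @param mask a \linkS4class{RegionMask}.
#' @param x,y point coordinates.
#' @return logical vector, TRUE where the point lies inside the mask
#'   (boundary points count as inside).
#' @export
maskContains <- function(mask, x, y) {
  switch(mask@type,
    rect = x >= mask@rect[1] & x <= mask@rect[2] &
           y >= mask@rect[3] & y <= mask@rect[4],
    polygon = sp::point.in.polygon(x, y, mask@poly[, 1], mask@poly[, 2]) > 0,
    grid = {
      g <- mask@grid[[1]]
      v <- extractAt(g, x, y)
      !is.na(v) & v != 0
    })
}

#' Eligible template cells inside a mask
#'
#' Linear indices of non-nodata template cells whose centers fall inside the
#' mask.
#'
#' @param mask a \linkS4class{RegionMask} (or NULL for the whole template).
#' @param template a \linkS4class{RasterGrid}.
#' @return integer vector of linear (column-major) cell indices.
#' @export
eligibleCells <- function(mask, template) {
  cc <- cellCenters(template)
  ok <- !is.na(template@values[cbind(cc$row, cc$col)])
  if (!is.null(mask)) ok <- ok & maskContains(mask, cc$x, cc$y)
  # cellCenters enumerates (row, col) pairs; convert to linear column-major
  lin <- (cc$col - 1L) * dim(template)[1] + cc$row
  sort(lin[ok])
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic 31-bit hash of the master seed and a stage name, so that
#' adding or reordering optional pipeline stages cannot shift the randomness
#' of later ones.
#'
#' @param masterSeed integer master seed.
#' @param stage stage name.
#' @return integer in [1, 2^31 - 2].
#' @export
stageSeed <- function(masterSeed, stage) {
  p <- 2147483647
  s <- as.numeric(masterSeed) %% p
  for (c in utf8ToInt(as.character(stage))) s <- (s * 31 + c) %% p
  as.integer(max(1, s))
}
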