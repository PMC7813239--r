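# Occurrence filtering, hold-out splitting and background sampling.

#' Filter occurrence records
#'
#' Applies the standard record-quality rules: flagged records are dropped,
#' records with coordinate uncertainty above \code{maxUncertainty} metres
#' are dropped, and exact coordinate duplicates are collapsed to a single
#' entry per (x, y) pairing. Output order is deterministic (sorted by y,
#' then x). Optionally thins to one record per cell of a template grid.
#'
#' @param occ an \linkS4class{OccurrenceSet}.
#' @param maxUncertainty retain records with uncertainty_m <= this (default
#'   1000 m).
#' @param thinToCell optional \linkS4class{RasterGrid}; if given, at most
#'   one record is kept per grid cell (a stricter variant of the duplicate
#'   rule, off by default).
#' @return Filtered \linkS4class{OccurrenceSet}; the operation is
#'   idempotent.
#' @export
filterOccurrences <- function(occ, maxUncertainty = 1000, thinToCell = NULL) {
  r <- occ@records
  r <- r[!r$flagged & r$uncertainty_m <= maxUncertainty, , drop = FALSE]
  r <- r[!duplicated(r[, c("x", "y")]), , drop = FALSE]
  if (!is.null(thinToCell)) {
    idx <- pointToCell(thinToCell, r$x, r$y)
    keep <- !duplicated(idx$cell) & !is.na(idx$cell)
    r <- r[keep, , drop = FALSE]
  }
  r <- r[order(r$y, r$x), , drop = FALSE]
  if (!nrow(r))
    stop("no records survive filtering; inspect uncertainties and flags")
  rownames(r) <- NULL
  new("OccurrenceSet", records = r)
}

#' Split hold-out records by region
#'
#' Partitions an occurrence set into the records inside a validation region
#' (hold-out, excluded from model fitting) and the rest (training). Mirrors
#' the design of holding out a geographically disjunct population to
#' validate model predictions externally.
#'
#' @param occ an \linkS4class{OccurrenceSet}.
#' @param region a \linkS4class{RegionMask}.
#' @return List with \code{train} and \code{holdout} OccurrenceSets; a
#'   partition of the input.
#' @export
splitHoldout <- function(occ, region) {
  r <- occ@records
  inside <- maskContains(region, r$x, r$y)
  if (!any(inside)) warning("hold-out region contains no records")
  list(train = new("OccurrenceSet", records = {
         t <- r[!inside, , drop = FALSE]; rownames(t) <- NULL; t
       }),
       holdout = new("OccurrenceSet", records = {
         h <- r[inside, , drop = FALSE]; rownames(h) <- NULL; h
       }))
}

#' Sample background points
#'
#' Draws \code{n} background points at the centers of non-nodata template
#' cells inside a region mask, uniformly with replacement across cells (so
#' requested counts may exceed the number of distinct eligible cells, as on
#' small extents). Background points stand in for absences and define the
#' environmental prevalence the presences are contrasted against.
#'
#' @param mask a \linkS4class{RegionMask}, or NULL for the whole template.
#' @param template a \linkS4class{RasterGrid} defining cells and nodata.
#' @param n number of points.
#' @param seed integer seed.
#' @param replace sample cells with replacement (default TRUE).
#' @return data.frame with columns x, y, cell.
#' @export
sampleBackground <- function(mask, template, n, seed, replace = TRUE) {
  stopifnot(n >= 1)
  if (missing(seed)) stop("seed is mandatory")
  elig <- eligibleCells(mask, template)
  if (!length(elig)) stop("mask contains no eligible template cells")
  if (!replace && n > length(elig))
    stop("n exceeds eligible cells and replace = FALSE")
  withSeed(seed, {
    cells <- elig[sample.int(length(elig), n, replace = replace)]
    d <- dim(template)
    row <- (cells - 1L) %% d[1] + 1L
    col <- (cells - 1L) %/% d[1] + 1L
    data.frame(x = template@origin[1] + (col - 0.5) * template@cellSize,
               y = template@origin[2] - (row - 0.5) * template@cellSize,
               cell = cells)
  })
}
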