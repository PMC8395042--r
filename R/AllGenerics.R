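#' Raster cells of a grid
#' @param x an [LULCGrid-class].
#' @return integer matrix of codes (0 = nodata).
#' @export
setGeneric("lulcCells", function(x) standardGeneric("lulcCells"))

#' @rdname lulcCells
#' @export
setMethod("lulcCells", "LULCGrid", function(x) x@cells)

#' Cell side length in meters
#' @param x an [LULCGrid-class], [LULCSeries-class] or
#'   [TransitionMatrix-class].
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname cellSize
#' @export
setMethod("cellSize", "LULCGrid", function(x) x@cellSize)

#' @rdname cellSize
#' @export
setMethod("cellSize", "LULCSeries", function(x) x@grids[[1]]@cellSize)

#' @rdname cellSize
#' @export
setMethod("cellSize", "TransitionMatrix", function(x) x@cellSize)

#' Date label(s)
#' @param x an [LULCGrid-class] or [LULCSeries-class].
#' @export
setGeneric("dateLabels", function(x) standardGeneric("dateLabels"))

#' @rdname dateLabels
#' @export
setMethod("dateLabels", "LULCGrid", function(x) x@dateLabel)

#' @rdname dateLabels
#' @export
setMethod("dateLabels", "LULCSeries",
          function(x) vapply(x@grids, slot, "", "dateLabel"))

#' Grids of a series
#' @param x an [LULCSeries-class].
#' @return list of [LULCGrid-class] objects.
#' @export
setGeneric("seriesGrids", function(x) standardGeneric("seriesGrids"))

#' @rdname seriesGrids
#' @export
setMethod("seriesGrids", "LULCSeries", function(x) x@grids)

#' Number of dates in a series
#' @param x an [LULCSeries-class].
#' @export
setGeneric("nDates", function(x) standardGeneric("nDates"))

#' @rdname nDates
#' @export
setMethod("nDates", "LULCSeries", function(x) length(x@grids))

#' Transition areas as a plain matrix
#' @param x a [TransitionMatrix-class].
#' @return numeric 10 x 10 matrix (km^2) with class-name dimnames.
#' @export
setGeneric("transitionAreas", function(x) standardGeneric("transitionAreas"))

#' @rdname transitionAreas
#' @export
setMethod("transitionAreas", "TransitionMatrix", function(x) {
  a <- x@areas
  dimnames(a) <- list(lulcClasses()$name, lulcClasses()$name)
  a
})

#' Density table as a data.frame
#' @param x a [CarbonDensityTable-class].
#' @export
setGeneric("densityTable", function(x) standardGeneric("densityTable"))

#' @rdname densityTable
#' @export
setMethod("densityTable", "CarbonDensityTable", function(x) x@densities)
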