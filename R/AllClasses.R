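#' @import methods
NULL

## nodata sentinel used in all integer rasters
NODATA <- 0L

#' Land-use/land-cover class scheme
#'
#' The ten-class coastal scheme used throughout the package: codes 1--10,
#' their names, and the four first-class groups (natural wetland,
#' artificial wetland, other land, waters).
#'
#' @return A data.frame with columns `code`, `name`, `group`.
#' @examples
#' lulcClasses()
#' @export
lulcClasses <- function() {
  data.frame(
    code = 1:10,
    name = c("Offshore waters", "Tidal flat", "Coastal marsh", "Grassland",
             "River and lake", "Aquaculture fish pond", "Paddy field",
             "Reservoir", "Construction land", "Rainfed cropland"),
    group = c("waters", "natural wetland", "natural wetland", "other land",
              "natural wetland", "artificial wetland", "artificial wetland",
              "artificial wetland", "other land", "other land"),
    stringsAsFactors = FALSE
  )
}

#' LULCGrid: a dated categorical land-cover raster
#'
#' A single-band integer raster of land-cover codes 1--10 with nodata
#' sentinel 0, a square cell size in meters, a date label, and the
#' upper-left corner coordinates. Row 1 is the northernmost row.
#'
#' @slot cells integer matrix of codes (0 = nodata).
#' @slot cellSize numeric(1), cell side length in meters.
#' @slot dateLabel character(1) date label, e.g. "1990".
#' @slot origin numeric(2), (x, y) of the upper-left corner.
#' @export
setClass("LULCGrid",
  representation(cells = "matrix", cellSize = "numeric",
                 dateLabel = "character", origin = "numeric"),
  prototype(cellSize = 30, dateLabel = "t0", origin = c(0, 0)))

setValidity("LULCGrid", function(object) {
  msg <- character()
  if (!is.integer(object@cells))
    msg <- c(msg, "cells must be an integer matrix")
  else {
    bad <- which(!(object@cells %in% c(NODATA, 1:10)))
    if (length(bad)) {
      i <- bad[1]
      msg <- c(msg, sprintf(
        "invalid code %d at cell [%d, %d] (codes must be 1..10 or nodata 0)",
        object@cells[i], row(object@cells)[i], col(object@cells)[i]))
    }
  }
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be numeric(2)")
  if (length(object@dateLabel) != 1)
    msg <- c(msg, "dateLabel must be character(1)")
  if (length(msg)) msg else TRUE
})

#' Construct an LULCGrid
#'
#' @param cells integer matrix of land-cover codes (0 = nodata).
#' @param cellSize cell side length in meters.
#' @param dateLabel date label.
#' @param origin numeric(2) upper-left corner (x, y).
#' @return An [LULCGrid-class] object.
#' @examples
#' g <- LULCGrid(matrix(c(1L, 2L, 3L, 4L), 2), cellSize = 100)
#' @export
LULCGrid <- function(cells, cellSize = 30, dateLabel = "t0",
                     origin = c(0, 0)) {
  storage.mode(cells) <- "integer"
  new("LULCGrid", cells = cells, cellSize = as.numeric(cellSize),
      dateLabel = as.character(dateLabel), origin = as.numeric(origin))
}

#' LULCSeries: a time-ordered series of congruent LULC grids
#'
#' All grids share shape, cell size, origin and nodata mask; at least two
#' dates are required.
#'
#' @slot grids list of [LULCGrid-class] objects in date order.
#' @export
setClass("LULCSeries", representation(grids = "list"))

setValidity("LULCSeries", function(object) {
  g <- object@grids
  if (length(g) < 2) return("a series needs at least 2 dates")
  if (!all(vapply(g, is, logical(1), "LULCGrid")))
    return("grids must all be LULCGrid objects")
  ref <- g[[1]]
  for (i in seq_along(g)[-1]) {
    if (!identical(dim(g[[i]]@cells), dim(ref@cells)))
      return(sprintf("grid %d shape differs from grid 1", i))
    if (g[[i]]@cellSize != ref@cellSize)
      return(sprintf("grid %d cellSize differs from grid 1", i))
    if (!identical(g[[i]]@origin, ref@origin))
      return(sprintf("grid %d origin differs from grid 1", i))
    if (!identical(g[[i]]@cells == NODATA, ref@cells == NODATA))
      return(sprintf("grid %d nodata mask differs from grid 1", i))
  }
  TRUE
})

#' Construct an LULCSeries
#'
#' @param ... [LULCGrid-class] objects, or a single list of them.
#' @return An [LULCSeries-class] object.
#' @export
LULCSeries <- function(...) {
  grids <- list(...)
  if (length(grids) == 1 && is.list(grids[[1]]) && !is(grids[[1]], "LULCGrid"))
    grids <- grids[[1]]
  new("LULCSeries", grids = grids)
}

#' TransitionMatrix: period land-cover change areas
#'
#' A 10 x 10 matrix of areas (km^2) changing from the row code at the
#' start date to the column code at the end date; the diagonal holds
#' unchanged area. Backed by exact integer cell counts; rounding to the
#' 0.01 km^2 of published tables happens only at serialization.
#'
#' @slot areas numeric 10 x 10 matrix, km^2.
#' @slot period character(2), (start, end) date labels.
#' @slot cellSize numeric(1), meters (NA when unknown, e.g. read from CSV).
#' @export
setClass("TransitionMatrix",
  representation(areas = "matrix", period = "character",
                 cellSize = "numeric"),
  prototype(period = c(NA_character_, NA_character_), cellSize = NA_real_))

setValidity("TransitionMatrix", function(object) {
  a <- object@areas
  if (!is.numeric(a) || !identical(dim(a), c(10L, 10L)))
    return("areas must be a numeric 10 x 10 matrix")
  if (any(!is.finite(a)) || any(a < 0))
    return("areas must be finite and non-negative")
  if (length(object@period) != 2)
    return("period must be character(2)")
  TRUE
})

#' CarbonDensityTable: per-class carbon pool densities
#'
#' Above-ground, below-ground, soil and dead-matter carbon densities plus
#' the total, all in Mg/ha, for each of the ten land-cover classes.
#'
#' @slot densities data.frame with columns code, name, c_above, c_below,
#'   c_soil, c_dead, c_total.
#' @export
setClass("CarbonDensityTable", representation(densities = "data.frame"))

setValidity("CarbonDensityTable", function(object) {
  d <- object@densities
  need <- c("code", "name", "c_above", "c_below", "c_soil", "c_dead",
            "c_total")
  if (!all(need %in% names(d)))
    return(paste("densities must have columns", paste(need, collapse = ", ")))
  num <- c("c_above", "c_below", "c_soil", "c_dead", "c_total")
  if (any(vapply(d[num], function(x) any(!is.finite(x) | x < 0), logical(1))))
    return("densities must be finite and non-negative")
  if (anyDuplicated(d$code)) return("duplicate codes in density table")
  TRUE
})

#' CoastScenario: parameters of the synthetic coastal simulator
#'
#' Defines a seeded accretion--succession--reclamation simulation on a
#' land-sea gradient. Per-interval probabilities cover the six driving
#' processes; reclamation picks target classes from a distribution over
#' codes 6--10 and acts only within `reclamationReach` columns of the
#' initial land edge.
#'
#' @slot shape integer(2), (rows, cols).
#' @slot cellSize numeric(1), meters.
#' @slot nDates integer(1) >= 2.
#' @slot rates named numeric: accretion, succession, regressive_succession,
#'   erosion, reclamation, restoration; each in \[0, 1\].
#' @slot reclamationTargets named numeric over codes "6".."10", summing to 1.
#' @slot reclamationReach numeric(1), columns seaward of the initial land
#'   edge within which reclamation can act.
#' @slot seed integer(1) RNG seed.
#' @export
setClass("CoastScenario",
  representation(shape = "integer", cellSize = "numeric", nDates = "integer",
                 rates = "numeric", reclamationTargets = "numeric",
                 reclamationReach = "numeric", seed = "integer"))

RATE_NAMES <- c("accretion", "succession", "regressive_succession",
                "erosion", "reclamation", "restoration")

setValidity("CoastScenario", function(object) {
  if (length(object@shape) != 2 || any(object@shape < 1))
    return("shape must be two positive integers")
  if (object@shape[2] < 3)
    return("degenerate shape: need at least 3 columns for a land-sea gradient")
  if (object@nDates < 2) return("nDates must be >= 2")
  if (!setequal(names(object@rates), RATE_NAMES))
    return(paste("rates must be named:", paste(RATE_NAMES, collapse = ", ")))
  if (any(object@rates < 0 | object@rates > 1))
    return("all rates must lie in [0, 1]")
  rt <- object@reclamationTargets
  if (!setequal(names(rt), as.character(6:10)))
    return("reclamationTargets must be named over codes 6..10")
  if (any(rt < 0) || abs(sum(rt) - 1) > 1e-8)
    return("reclamationTargets must be a distribution summing to 1")
  TRUE
})

#' ClusterResult: a clustered process-by-year matrix
#'
#' Holds the normalized matrix, the agglomerative merge tree and the
#' dendrogram leaf order.
#'
#' @slot matrix numeric matrix (rows = process chains, cols = dates),
#'   z-score normalized.
#' @slot tree the `stats::hclust` merge tree.
#' @slot order integer leaf order (row indices of `matrix`).
#' @export
setClass("ClusterResult",
  representation(matrix = "matrix", tree = "ANY", order = "integer"))

setValidity("ClusterResult", function(object) {
  if (!inherits(object@tree, "hclust")) return("tree must be an hclust object")
  if (!identical(sort(object@order), seq_len(nrow(object@matrix))))
    return("order must be a permutation of row indices")
  TRUE
})

## ---- show methods ----

setMethod("show", "LULCGrid", function(object) {
  d <- dim(object@cells)
  nd <- sum(object@cells == NODATA)
  cat(sprintf("LULCGrid '%s': %d x %d cells, %g m (%d nodata)\n",
              object@dateLabel, d[1], d[2], object@cellSize, nd))
  tab <- table(factor(object@cells[object@cells != NODATA], levels = 1:10))
  cls <- lulcClasses()
  nz <- which(tab > 0)
  for (i in nz)
    cat(sprintf("  %2d %-22s %d cells\n", i, cls$name[i], tab[i]))
})

setMethod("show", "LULCSeries", function(object) {
  cat(sprintf("LULCSeries: %d dates (%s), %d x %d cells @ %g m\n",
              length(object@grids),
              paste(vapply(object@grids, slot, "", "dateLabel"),
                    collapse = ", "),
              nrow(object@grids[[1]]@cells), ncol(object@grids[[1]]@cells),
              object@grids[[1]]@cellSize))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix %s -> %s (total %.2f km^2, changed %.2f km^2)\n",
              object@period[1], object@period[2], sum(object@areas),
              sum(object@areas) - sum(diag(object@areas))))
})

setMethod("show", "CarbonDensityTable", function(object) {
  cat("CarbonDensityTable (Mg/ha):\n")
  print(object@densities, row.names = FALSE)
})

setMethod("show", "CoastScenario", function(object) {
  cat(sprintf("CoastScenario: %d x %d cells @ %g m, %d dates, seed %d\n",
              object@shape[1], object@shape[2], object@cellSize,
              object@nDates, object@seed))
  cat("  rates:", paste(sprintf("%s=%.2f", names(object@rates),
                                object@rates), collapse = " "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d chains x %d dates, %s linkage\n",
              nrow(object@matrix), ncol(object@matrix),
              object@tree$method))
  cat("  leaf order:",
      paste(rownames(object@matrix)[object@order], collapse = ", "), "\n")
})
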