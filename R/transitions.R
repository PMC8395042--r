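#' Compute the land-cover transition matrix of a period
#'
#' Tallies, over all non-nodata cells, the area changing from each start
#' code to each end code between two congruent grids. Counts are exact
#' integers; areas are counts times the cell area in km^2.
#'
#' @param gridA start-date [LULCGrid-class].
#' @param gridB end-date [LULCGrid-class]; must be congruent with `gridA`
#'   (same shape, cell size, origin and nodata mask).
#' @return A [TransitionMatrix-class].
#' @examples
#' a <- LULCGrid(matrix(c(1L, 1L), 1), cellSize = 1000)
#' b <- LULCGrid(matrix(c(2L, 1L), 1), cellSize = 1000)
#' transitionAreas(transitionMatrix(a, b))[1, 1:2]
#' @export
transitionMatrix <- function(gridA, gridB) {
  stopifnot(is(gridA, "LULCGrid"), is(gridB, "LULCGrid"))
  if (!identical(dim(gridA@cells), dim(gridB@cells)) ||
      gridA@cellSize != gridB@cellSize)
    stop("grids are not congruent (shape or cell size differs)")
  maskA <- gridA@cells == NODATA
  if (!identical(maskA, gridB@cells == NODATA))
    stop("grids have differing nodata masks")
  a <- gridA@cells[!maskA]; b <- gridB@cells[!maskA]
  counts <- matrix(tabulate((a - 1L) * 10L + b, nbins = 100L),
                   nrow = 10, ncol = 10, byrow = TRUE)
  cellArea <- gridA@cellSize^2 / 1e6
  new("TransitionMatrix", areas = counts * cellArea,
      period = c(gridA@dateLabel, gridB@dateLabel),
      cellSize = gridA@cellSize)
}

#' Transfer-out area of a class
#'
#' Row sum of the transition matrix excluding the diagonal: the area a
#' class lost to other classes over the period.
#'
#' @param matrix a [TransitionMatrix-class].
#' @param code a code 1..10, or NULL for the full named vector.
#' @return area in km^2.
#' @export
transferOut <- function(matrix, code = NULL) {
  stopifnot(is(matrix, "TransitionMatrix"))
  a <- matrix@areas; diag(a) <- 0
  out <- rowSums(a)
  names(out) <- lulcClasses()$name
  if (is.null(code)) return(out)
  if (!(code %in% 1:10)) stop("code must be in 1..10")
  out[[code]]
}

#' Transfer-in area of a class
#'
#' Column sum of the transition matrix excluding the diagonal: the area a
#' class gained from other classes over the period.
#'
#' @inheritParams transferOut
#' @return area in km^2.
#' @export
transferIn <- function(matrix, code = NULL) {
  stopifnot(is(matrix, "TransitionMatrix"))
  a <- matrix@areas; diag(a) <- 0
  out <- colSums(a)
  names(out) <- lulcClasses()$name
  if (is.null(code)) return(out)
  if (!(code %in% 1:10)) stop("code must be in 1..10")
  out[[code]]
}

#' Write a transition matrix as CSV
#'
#' Canonical published-table layout: one row per start class, one column
#' per end class in code order 1..10 with explicit class-name labels, a
#' trailing transfer-out column and a trailing transfer-in row. Areas are
#' rounded to 0.01 km^2 at this point only.
#'
#' @param matrix a [TransitionMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [readTransitionCSV()]
#' @export
writeTransitionCSV <- function(matrix, path) {
  stopifnot(is(matrix, "TransitionMatrix"))
  cls <- lulcClasses()$name
  a <- round(matrix@areas, 2)
  df <- data.frame(class = cls, a, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("class", cls)
  df[["Transfer-out area"]] <- round(transferOut(matrix), 2)
  tin <- c(class = "Transfer-in area",
           as.list(round(transferIn(matrix), 2)),
           `Transfer-out area` = NA)
  df <- rbind(df, tin)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a transition matrix from CSV
#'
#' Inverse of [writeTransitionCSV()]; the marginal row/column are
#' re-derived, not trusted. Round trip is exact to the 0.01 km^2 written.
#'
#' @param path CSV path.
#' @param period character(2) date labels (the CSV carries none).
#' @param cellSize cell size in meters backing the areas (NA if unknown).
#' @return A [TransitionMatrix-class].
#' @export
readTransitionCSV <- function(path, period = c(NA, NA), cellSize = NA) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  cls <- lulcClasses()$name
  if (!all(cls %in% names(df)))
    stop("malformed transition CSV: missing class columns in ", path)
  body <- df[df$class %in% cls, cls, drop = FALSE]
  if (nrow(body) != 10) stop("malformed transition CSV: expected 10 class rows")
  a <- as.matrix(body)
  a <- a[match(cls, df$class[df$class %in% cls]), ]
  storage.mode(a) <- "double"
  dimnames(a) <- NULL
  if (any(is.na(a))) stop("malformed transition CSV: non-numeric cells")
  if (any(a < 0)) stop("negative area in transition CSV: ", path)
  new("TransitionMatrix", areas = a,
      period = as.character(period), cellSize = as.numeric(cellSize))
}

#' Packaged published transition matrices
#'
#' The four published period transition matrices of the Shanghai coastal
#' study area (km^2), shipped as package fixtures: "1990_2015",
#' "1990_2000", "2000_2009", "2009_2015". One marginal cell of the
#' published 2000--2009 block (grassland transfer-in, 5.97 km^2) is
#' inconsistent with its own column cells, which sum to 5.89 km^2; the
#' fixture realizes the cells, so the re-derived marginal is 5.89.
#'
#' @param period one of "1990_2015", "1990_2000", "2000_2009", "2009_2015".
#' @return A [TransitionMatrix-class] (100 m backing cell size, so every
#'   0.01-km^2 entry is an integral number of cells).
#' @examples
#' tm <- shanghaiTransitionMatrix("1990_2015")
#' transferOut(tm, 1)  # 469.22 km^2 leaving offshore waters
#' @export
shanghaiTransitionMatrix <- function(period = c("1990_2015", "1990_2000",
                                                "2000_2009", "2009_2015")) {
  period <- match.arg(period)
  readTransitionCSV(ccExtdata(paste0("transitions_", period, ".csv")),
                    period = strsplit(period, "_")[[1]], cellSize = 100)
}
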