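#' First-class group of a land-cover code
#'
#' Maps a code 1--10 to its first-class group: tidal flat, coastal marsh
#' and river/lake are natural wetland; fish pond, paddy and reservoir are
#' artificial wetland; construction, rainfed cropland and grassland are
#' other land; offshore waters form their own group. Grassland sits in
#' "other land" for group summaries even though it takes part in natural
#' succession and erosion; the process taxonomy is a separate lookup
#' (see [stepProcess()]).
#'
#' @param code integer vector of codes in 1..10.
#' @return character vector of group labels.
#' @examples
#' groupOf(c(3, 8, 1))
#' @export
groupOf <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code) | code < 1 | code > 10))
    stop("codes must be integers in 1..10")
  lulcClasses()$group[code]
}

#' Read a categorical LULC raster from an ESRI ASCII grid
#'
#' Parses a single-band integer ESRI ASCII grid (`.asc`). Values must be
#' codes 1--10 or the file's NODATA value; anything else is an error that
#' names the offending cell. Row 1 of the result is the northernmost row,
#' as in the file.
#'
#' @param path path to the `.asc` file.
#' @param dateLabel date label to attach (the format carries none).
#' @return An [LULCGrid-class].
#' @seealso [writeLULCRaster()]
#' @export
readLULCRaster <- function(path, dateLabel = "t0") {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, warn = FALSE)
  ## header: key value pairs until the first data row
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata_in <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == as.integer(nodata_in)] <- NODATA
  bad <- which(!(m %in% c(NODATA, 1:10)))
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf("invalid code %d at cell [%d, %d] in %s",
                 m[b], row(m)[b], col(m)[b], path))
  }
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  LULCGrid(m, cellSize = hdr$cellsize, dateLabel = dateLabel,
           origin = c(xll, yll + nr * hdr$cellsize))
}

#' Write a categorical LULC raster as an ESRI ASCII grid
#'
#' Nodata cells are written as -9999. A write/read round trip restores an
#' identical grid (bit-identical codes, same geometry).
#'
#' @param grid an [LULCGrid-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLULCRaster <- function(grid, path) {
  stopifnot(is(grid, "LULCGrid"))
  validObject(grid)
  m <- grid@cells
  m[m == NODATA] <- -9999L
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid@origin[1]),
    sprintf("yllcorner %.10g", grid@origin[2] - nr * grid@cellSize),
    sprintf("cellsize %.10g", grid@cellSize),
    "NODATA_value -9999")
  body <- apply(m, 1, paste, collapse = " ")
  ok <- tryCatch({
    writeLines(c(hdr, body), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write raster to ", path)
  invisible(path)
}

#' Path to a packaged data file
#' @param file file name under the package's `extdata`.
#' @keywords internal
ccExtdata <- function(file) {
  p <- system.file("extdata", file, package = "coastCarbon")
  if (p == "") stop("packaged file not found: ", file)
  p
}
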