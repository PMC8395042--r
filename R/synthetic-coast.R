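#' Construct a CoastScenario
#'
#' Parameters of the seeded coastal-dynamics simulator. The default rates
#' are illustrative per-interval probabilities for an accreting,
#' progressively reclaimed coast; no published rates exist for the real
#' processes, so defaults were chosen once as plausible for a
#' decadal-interval prograding delta coast (see the methods vignette).
#'
#' @param shape integer(2), (rows, cols) of the grid.
#' @param cellSize cell side length in meters (default 30, a Landsat-like
#'   resolution).
#' @param nDates number of dates in the generated series.
#' @param rates named per-interval probabilities for `accretion`,
#'   `succession`, `regressive_succession`, `erosion`, `reclamation`,
#'   `restoration`.
#' @param reclamationTargets distribution over target codes 6..10.
#' @param reclamationReach columns seaward of the initial land edge within
#'   which reclamation can act.
#' @param seed integer RNG seed; same seed + scenario gives a
#'   bit-identical series.
#' @return A [CoastScenario-class].
#' @examples
#' sc <- coastScenario(shape = c(40, 60), seed = 1)
#' @export
coastScenario <- function(shape = c(80, 120), cellSize = 30, nDates = 4,
                          rates = c(accretion = 0.40, succession = 0.30,
                                    regressive_succession = 0.05,
                                    erosion = 0.10, reclamation = 0.15,
                                    restoration = 0.05),
                          reclamationTargets = c(`6` = 0.30, `7` = 0.25,
                                                 `8` = 0.10, `9` = 0.20,
                                                 `10` = 0.15),
                          reclamationReach = 15, seed = 1L) {
  full <- c(accretion = 0, succession = 0, regressive_succession = 0,
            erosion = 0, reclamation = 0, restoration = 0)
  full[names(rates)] <- rates
  new("CoastScenario", shape = as.integer(shape),
      cellSize = as.numeric(cellSize), nDates = as.integer(nDates),
      rates = full, reclamationTargets = reclamationTargets,
      reclamationReach = as.numeric(reclamationReach),
      seed = as.integer(seed))
}

#' Read a CoastScenario from a YAML/JSON config file
#'
#' Keys mirror the [coastScenario()] arguments.
#'
#' @param path config file path.
#' @return A [CoastScenario-class].
#' @export
readScenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (k in c("shape", "cellSize", "nDates", "reclamationReach", "seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  if (!is.null(cfg$rates)) args$rates <- unlist(cfg$rates)
  if (!is.null(cfg$reclamationTargets))
    args$reclamationTargets <- unlist(cfg$reclamationTargets)
  do.call(coastScenario, args)
}

## indices of a logical mask in row-major (northwest to southeast) order,
## so a single RNG stream is consumed deterministically
rowMajorWhich <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(idx)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  idx[order(r, c)]
}

## 4-neighborhood test: TRUE where any rook neighbor satisfies `pred` matrix
adjacent4 <- function(pred) {
  nr <- nrow(pred); nc <- ncol(pred)
  out <- matrix(FALSE, nr, nc)
  out[-1, ] <- out[-1, ] | pred[-nr, ]
  out[-nr, ] <- out[-nr, ] | pred[-1, ]
  out[, -1] <- out[, -1] | pred[, -nc]
  out[, -nc] <- out[, -nc] | pred[, -1]
  out
}

#' Initial land-sea gradient grid
#'
#' Date-0 state of the simulator: a western strip of settled land (codes
#' 7, 9, 10 mixed at random), then bands of coastal marsh (3) and tidal
#' flat (2), then offshore waters (1) seaward. Consumes the current RNG
#' stream (for the land-strip mix).
#'
#' @param scenario a [CoastScenario-class].
#' @return list with `grid` (an [LULCGrid-class]) and `landEdge` (the last
#'   column of the land strip).
#' @keywords internal
initialCoast <- function(scenario) {
  nr <- scenario@shape[1]; nc <- scenario@shape[2]
  landW <- max(1L, as.integer(round(0.10 * nc)))
  marshW <- max(1L, as.integer(round(0.15 * nc)))
  flatW <- max(1L, as.integer(round(0.20 * nc)))
  m <- matrix(1L, nr, nc)
  land <- matrix(sample(c(7L, 9L, 10L), nr * landW, replace = TRUE,
                        prob = c(0.4, 0.3, 0.3)), nr, landW)
  m[, seq_len(landW)] <- land
  mcols <- seq(landW + 1L, min(nc, landW + marshW))
  m[, mcols] <- 3L
  fcols <- seq(landW + marshW + 1L, min(nc, landW + marshW + flatW))
  if (landW + marshW < nc) m[, fcols] <- 2L
  list(grid = LULCGrid(m, cellSize = scenario@cellSize, dateLabel = "t0"),
       landEdge = landW)
}

#' Advance a coastal grid by one interval
#'
#' Applies, in fixed order, accretion (1 to 2 on water cells 4-adjacent to
#' non-water), succession (2 to 3, 3 to 4), regressive succession (3 to 2),
#' erosion (2/3/4 to 1 on cells 4-adjacent to water), reclamation (1..5 to
#' a drawn target in 6..10, within reach of the initial land edge) and
#' restoration (6..10 to 2 or 3). Eligibility is judged on the
#' start-of-interval state and each cell changes at most once per
#' interval. Draws come from the session RNG in raster row-major order,
#' one process at a time, so a seeded caller is fully reproducible.
#'
#' @param grid an [LULCGrid-class] (nodata cells never change).
#' @param scenario a [CoastScenario-class] providing the rates.
#' @param landEdge column index of the initial land edge (reclamation acts
#'   in columns `<= landEdge + reclamationReach`).
#' @return the advanced [LULCGrid-class] (dateLabel unchanged).
#' @export
advanceCoast <- function(grid, scenario, landEdge = 1L) {
  g0 <- grid@cells
  g <- g0
  changed <- matrix(FALSE, nrow(g0), ncol(g0))
  rates <- scenario@rates
  valid <- g0 != NODATA

  apply_step <- function(eligible, rate, newCode) {
    idx <- rowMajorWhich(eligible & !changed & valid)
    if (!length(idx) || rate <= 0) return()
    u <- stats::runif(length(idx))
    hit <- idx[u < rate]
    if (is.function(newCode)) g[hit] <<- newCode(length(hit))
    else g[hit] <<- newCode
    changed[hit] <<- TRUE
  }

  nonwater <- valid & g0 != 1L
  water <- valid & g0 == 1L
  apply_step(g0 == 1L & adjacent4(nonwater), rates["accretion"], 2L)
  apply_step(g0 == 2L, rates["succession"], 3L)
  apply_step(g0 == 3L, rates["succession"], 4L)
  apply_step(g0 == 3L, rates["regressive_succession"], 2L)
  apply_step(g0 %in% c(2L, 3L, 4L) & adjacent4(water), rates["erosion"], 1L)
  reach <- col(g0) <= landEdge + scenario@reclamationReach
  tgt <- as.integer(names(scenario@reclamationTargets))
  apply_step(g0 %in% 1:5 & reach, rates["reclamation"], function(n)
    sample(tgt, n, replace = TRUE, prob = scenario@reclamationTargets))
  apply_step(g0 %in% 6:10, rates["restoration"], function(n)
    sample(c(2L, 3L), n, replace = TRUE))
  LULCGrid(g, cellSize = grid@cellSize, dateLabel = grid@dateLabel,
           origin = grid@origin)
}

#' Generate a synthetic multi-date coastal LULC series
#'
#' Builds the date-0 land-sea gradient, then advances it
#' `nDates - 1` times with [advanceCoast()]. All randomness flows from the
#' scenario seed through a single stream consumed in row-major order, so
#' the same scenario always yields a bit-identical series.
#'
#' @param scenario a [CoastScenario-class].
#' @return An [LULCSeries-class] of `nDates` grids labeled "t0", "t1", ...
#' @examples
#' s <- generateSeries(coastScenario(shape = c(20, 30), seed = 42))
#' @export
generateSeries <- function(scenario) {
  validObject(scenario)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario@seed)
  init <- initialCoast(scenario)
  grids <- vector("list", scenario@nDates)
  grids[[1]] <- init$grid
  for (t in seq_len(scenario@nDates - 1L)) {
    g <- advanceCoast(grids[[t]], scenario, init$landEdge)
    g@dateLabel <- paste0("t", t)
    grids[[t + 1L]] <- g
  }
  LULCSeries(grids)
}

#' Materialize a grid pair realizing a transition matrix
#'
#' Builds two congruent grids whose recomputed transition matrix equals
#' the input exactly. Every area must be a non-negative integral multiple
#' of the cell area (100 m cells make every 0.01-km^2 tabulated value
#' integral). Cell layout is arbitrary row-major fill; a zero matrix
#' yields a pair of all-nodata 1 x 1 grids.
#'
#' @param matrix a [TransitionMatrix-class] or plain 10 x 10 area matrix
#'   (km^2).
#' @param cellSize cell side length in meters (default 100).
#' @param period character(2) date labels for the pair.
#' @return list of two congruent [LULCGrid-class] objects.
#' @examples
#' m <- matrix(0, 10, 10); m[2, 3] <- 0.02
#' pair <- materializeFromMatrix(m, cellSize = 100)
#' @export
materializeFromMatrix <- function(matrix, cellSize = 100,
                                  period = c("t0", "t1")) {
  a <- if (is(matrix, "TransitionMatrix")) {
    if (!is.na(matrix@period[1])) period <- matrix@period
    matrix@areas
  } else matrix
  stopifnot(is.numeric(a), identical(dim(a), c(10L, 10L)), all(a >= 0))
  cellArea <- cellSize^2 / 1e6  # km^2
  counts <- a / cellArea
  off <- abs(counts - round(counts))
  if (any(off > 1e-6)) {
    b <- which(off > 1e-6)[1]
    stop(sprintf(
      "area %.6g km^2 (entry %d -> %d) is not an integral multiple of the %.4g km^2 cell area",
      a[b], row(a)[b], col(a)[b], cellArea))
  }
  counts <- round(counts)
  n <- sum(counts)
  if (n == 0) {
    g <- LULCGrid(matrix(NODATA, 1, 1), cellSize = cellSize)
    g1 <- g; g1@dateLabel <- period[1]
    g2 <- g; g2@dateLabel <- period[2]
    return(list(g1, g2))
  }
  ij <- which(counts > 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  reps <- counts[ij]
  aCodes <- rep(ij[, 1], reps)
  bCodes <- rep(ij[, 2], reps)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  pad <- nr * nc - n
  fill <- function(v) {
    m <- matrix(c(as.integer(v), rep(NODATA, pad)), nrow = nr, ncol = nc,
                byrow = TRUE)
    m
  }
  list(LULCGrid(fill(aCodes), cellSize = cellSize, dateLabel = period[1]),
       LULCGrid(fill(bCodes), cellSize = cellSize, dateLabel = period[2]))
}
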