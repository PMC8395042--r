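#' Total carbon density from the four pools
#'
#' Sums the above-ground, below-ground, soil and dead-matter carbon pools
#' of a land-cover class: `C = C_above + C_below + C_dead + C_soil`
#' (all Mg/ha).
#'
#' @param c_above,c_below,c_soil,c_dead pool densities in Mg/ha
#'   (vectorized).
#' @return total density, Mg/ha.
#' @examples
#' poolTotal(2.8, 1.8, 13.8, 0)  # tidal flat: 18.4
#' @export
poolTotal <- function(c_above, c_below, c_soil, c_dead) {
  v <- cbind(c_above, c_below, c_soil, c_dead)
  if (any(!is.finite(v)) || any(v < 0))
    stop("pool densities must be finite and non-negative")
  unname(rowSums(v))
}

#' Load a carbon-density table
#'
#' With no `path`, loads the packaged coastal density table (Mg/ha). In
#' the default mode the shipped `c_total` column is used as-is for all
#' storage computations; with `strict = TRUE` a warning names any class
#' whose printed total disagrees with its pool sum (three classes of the
#' shipped table do: coastal marsh, paddy field, rainfed cropland) and
#' the pool sums replace the totals.
#'
#' @param path CSV with columns code,name,c_above,c_below,c_soil,c_dead,
#'   c_total; NULL for the packaged table.
#' @param strict logical; recompute totals from pools and warn on
#'   disagreement.
#' @return A [CarbonDensityTable-class].
#' @examples
#' densityTable(carbonDensities())
#' @export
carbonDensities <- function(path = NULL, strict = FALSE) {
  if (is.null(path)) path <- ccExtdata("carbon_density.csv")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  obj <- new("CarbonDensityTable", densities = d)
  if (strict) {
    sums <- poolTotal(d$c_above, d$c_below, d$c_soil, d$c_dead)
    bad <- which(abs(sums - d$c_total) > 1e-9)
    if (length(bad))
      warning("pool sums disagree with c_total for: ",
              paste(sprintf("%s (pools %.1f vs total %.1f)", d$name[bad],
                            sums[bad], d$c_total[bad]), collapse = ", "),
              "; using pool sums")
    obj@densities$c_total <- sums
  }
  validObject(obj)
  obj
}

## density lookup vector indexed by code, Mg/ha
densityByCode <- function(table) {
  d <- table@densities
  dens <- rep(NA_real_, 10)
  dens[d$code] <- d$c_total
  dens
}

codeAreasHa <- function(grid) {
  cellHa <- grid@cellSize^2 / 1e4
  tabulate(grid@cells[grid@cells != NODATA], nbins = 10) * cellHa
}

#' Total carbon storage of a grid
#'
#' `C_tot = sum_i C_i * S_i` over the land-cover classes present, with
#' `C_i` the class total density (Mg/ha) and `S_i` its area (ha).
#'
#' @param grid an [LULCGrid-class].
#' @param table a [CarbonDensityTable-class].
#' @return total storage in Mg.
#' @examples
#' g <- LULCGrid(matrix(7L), cellSize = 100)  # one 1-ha paddy cell
#' totalStorage(g, carbonDensities())         # 25.5 Mg
#' @export
totalStorage <- function(grid, table) {
  stopifnot(is(grid, "LULCGrid"), is(table, "CarbonDensityTable"))
  dens <- densityByCode(table)
  areas <- codeAreasHa(grid)
  present <- which(areas > 0)
  if (any(is.na(dens[present])))
    stop("codes missing from density table: ",
         paste(present[is.na(dens[present])], collapse = ", "))
  sum(dens[present] * areas[present])
}

#' Per-cell carbon storage map
#'
#' @inheritParams totalStorage
#' @return numeric matrix of per-cell storage (Mg; NA on nodata). Its sum
#'   equals [totalStorage()].
#' @export
carbonMap <- function(grid, table) {
  dens <- densityByCode(table)
  cellHa <- grid@cellSize^2 / 1e4
  m <- matrix(NA_real_, nrow(grid@cells), ncol(grid@cells))
  live <- grid@cells != NODATA
  m[live] <- dens[grid@cells[live]] * cellHa
  m
}

#' Carbon sequestration between two dates
#'
#' Later-minus-earlier difference in storage; positive values are net
#' carbon gain. With `perCell = TRUE` returns the per-cell difference map.
#'
#' @param gridA,gridB congruent start and end [LULCGrid-class] objects.
#' @param table a [CarbonDensityTable-class].
#' @param perCell return a per-cell Mg difference matrix instead of the
#'   total.
#' @return Mg (or a matrix of Mg).
#' @examples
#' a <- LULCGrid(matrix(1L), cellSize = 100)
#' b <- LULCGrid(matrix(2L), cellSize = 100)
#' sequestration(a, b, carbonDensities())  # 18.4 - 14.0 = 4.4 Mg
#' @export
sequestration <- function(gridA, gridB, table, perCell = FALSE) {
  if (!identical(dim(gridA@cells), dim(gridB@cells)) ||
      gridA@cellSize != gridB@cellSize)
    stop("grids are not congruent")
  if (perCell) carbonMap(gridB, table) - carbonMap(gridA, table)
  else totalStorage(gridB, table) - totalStorage(gridA, table)
}

#' Carbon storage by first-class group
#'
#' Splits [totalStorage()] across the four groups (natural wetland,
#' artificial wetland, other land, waters); the four totals sum to the
#' grid total.
#'
#' @inheritParams totalStorage
#' @return named numeric(4), Mg.
#' @export
groupStorage <- function(grid, table) {
  dens <- densityByCode(table)
  areas <- codeAreasHa(grid)
  per <- ifelse(areas > 0, dens * areas, 0)
  if (any(is.na(per)))
    stop("codes missing from density table")
  groups <- c("natural wetland", "artificial wetland", "other land",
              "waters")
  out <- vapply(groups, function(g)
    sum(per[lulcClasses()$group == g]), numeric(1))
  out
}

#' Fisher-Jenks natural-breaks classification
#'
#' Partitions sorted values into `k` contiguous classes minimizing the
#' total within-class sum of squared deviations, by the exact dynamic
#' program. Deterministic: among equal-cost partitions the one whose
#' leftmost break index is smallest (then the next, and so on) is chosen.
#'
#' @param values numeric vector.
#' @param k number of classes; must not exceed the number of distinct
#'   values.
#' @return list with `classes` (list of k sorted numeric vectors),
#'   `breaks` (upper value bound of each class), and `ssd` (the total
#'   within-class sum of squared deviations).
#' @examples
#' jenksBreaks(c(1, 2, 11, 12, 101, 102), 3)$classes
#' @export
jenksBreaks <- function(values, k) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (k < 1) stop("k must be >= 1")
  if (k > length(unique(values)))
    stop(sprintf("k = %d exceeds the %d distinct values", k,
                 length(unique(values))))
  x <- sort(values)
  csum <- cumsum(x); csq <- cumsum(x^2)
  ## ssd of x[i..j], prefix-sum form
  ssd <- function(i, j) {
    s <- csum[j] - if (i > 1) csum[i - 1] else 0
    q <- csq[j] - if (i > 1) csq[i - 1] else 0
    q - s^2 / (j - i + 1)
  }
  ## D[m, j]: best cost of splitting x[1..j] into m classes;
  ## B[m, j]: start index of the last class under that best split.
  D <- matrix(Inf, k, n); B <- matrix(NA_integer_, k, n)
  for (j in 1:n) { D[1, j] <- ssd(1, j); B[1, j] <- 1L }
  if (k > 1) for (m in 2:k) for (j in m:n) {
    ## iterate last-class start ascending; strict improvement keeps the
    ## smallest break indices on ties
    for (i in m:j) {
      cost <- D[m - 1, i - 1] + ssd(i, j)
      if (cost < D[m, j] - 1e-12) { D[m, j] <- cost; B[m, j] <- i }
    }
  }
  starts <- integer(k); j <- n
  for (m in k:1) { starts[m] <- B[m, j]; j <- starts[m] - 1L }
  classes <- lapply(seq_len(k), function(m) {
    end <- if (m < k) starts[m + 1] - 1L else n
    x[starts[m]:end]
  })
  list(classes = classes,
       breaks = vapply(classes, max, numeric(1)),
       ssd = D[k, n])
}

#' Carbon-level map by natural breaks
#'
#' Classifies the per-class total carbon densities into `k` levels by
#' [jenksBreaks()] and labels every cell with its class's level. With the
#' default `k = 4` the levels are, in increasing density order, Lowest,
#' Lower, Higher, Highest.
#'
#' @inheritParams totalStorage
#' @param k number of levels (default 4).
#' @return list with `levels` (integer matrix 1..k, NA on nodata) and
#'   `legend` (data.frame: level, label, upper density bound Mg/ha).
#' @export
levelMap <- function(grid, table, k = 4) {
  dens <- densityByCode(table)
  jb <- jenksBreaks(dens[!is.na(dens)], k)
  lev <- findInterval(dens, jb$breaks, left.open = TRUE) + 1L
  lev[lev > k] <- as.integer(k)  # guard against fp on the max
  labels <- if (k == 4) c("Lowest", "Lower", "Higher", "Highest")
            else paste0("L", seq_len(k))
  m <- matrix(NA_integer_, nrow(grid@cells), ncol(grid@cells))
  live <- grid@cells != NODATA
  m[live] <- lev[grid@cells[live]]
  list(levels = m,
       legend = data.frame(level = seq_len(k), label = labels,
                           upper_density = jb$breaks))
}
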