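dens <- carbonDensities()

test_that("pool totals reproduce the consistent published class totals", {
  expect_equal(poolTotal(2.8, 1.8, 13.8, 0.0), 18.4)   # tidal flat
  expect_equal(poolTotal(2.5, 11.1, 26.5, 0.2), 40.3)  # grassland
  expect_equal(poolTotal(0, 0, 0, 0), 0)
  expect_error(poolTotal(-1, 0, 0, 0), "non-negative")
  d <- densityTable(dens)
  sums <- poolTotal(d$c_above, d$c_below, d$c_soil, d$c_dead)
  consistent <- abs(sums - d$c_total) < 1e-9
  expect_equal(sum(consistent), 7)
  expect_setequal(d$name[!consistent],
                  c("Coastal marsh", "Paddy field", "Rainfed cropland"))
})

test_that("strict density mode warns naming exactly the inconsistent classes", {
  expect_warning(strict <- carbonDensities(strict = TRUE),
                 "Coastal marsh.*Paddy field.*Rainfed cropland")
  d <- densityTable(strict)
  expect_equal(d$c_total[d$name == "Coastal marsh"], 64.0)
})

test_that("total storage: worked 1-ha examples and brute-force equality", {
  one <- function(code) LULCGrid(matrix(code), cellSize = 100)
  expect_equal(totalStorage(one(7L), dens), 25.5)  # paddy field
  expect_equal(totalStorage(one(0L), dens), 0)     # all nodata
  two <- LULCGrid(matrix(c(1L, 2L), 1), cellSize = 100)
  expect_equal(totalStorage(two, dens), 14.0 + 18.4)

  set.seed(31)
  for (rep in 1:4) {
    g <- randomGrid(15, 15, nodataFrac = 0.1)
    expect_equal(totalStorage(g, dens), oracleStorage(g, dens),
                 tolerance = 1e-9)
    expect_equal(sum(carbonMap(g, dens), na.rm = TRUE),
                 totalStorage(g, dens), tolerance = 1e-9)
  }
})

test_that("sequestration: hand examples, per-cell map, telescoping across periods", {
  one <- function(code) LULCGrid(matrix(code), cellSize = 100)
  expect_equal(sequestration(one(1L), one(1L), dens), 0)
  expect_equal(sequestration(one(1L), one(2L), dens), 4.4)
  expect_equal(sequestration(one(3L), one(9L), dens), -24.4)
  expect_equal(sequestration(one(1L), one(2L), dens, perCell = TRUE),
               matrix(4.4))

  set.seed(32)
  s <- randomSeries(4)
  g <- seriesGrids(s)
  parts <- sequestration(g[[1]], g[[2]], dens) +
    sequestration(g[[2]], g[[3]], dens) +
    sequestration(g[[3]], g[[4]], dens)
  expect_equal(parts, sequestration(g[[1]], g[[4]], dens),
               tolerance = 1e-9)
})

test_that("storage rises when a cell is replaced by a denser class", {
  set.seed(33)
  g <- randomGrid(10, 10)
  d <- densityTable(dens)
  base <- totalStorage(g, dens)
  i <- which(lulcCells(g) != 0L)[1]
  cur <- lulcCells(g)[i]
  higher <- d$code[d$c_total > d$c_total[d$code == cur]]
  for (h in higher) {
    m <- lulcCells(g); m[i] <- h
    expect_gt(totalStorage(LULCGrid(m, cellSize = 100), dens), base)
  }
})

test_that("group storage partitions total storage across the four groups", {
  marsh <- LULCGrid(matrix(3L), cellSize = 100)
  gs <- groupStorage(marsh, dens)
  expect_equal(gs[["natural wetland"]], 32.4)
  expect_equal(sum(gs[c("artificial wetland", "other land", "waters")]), 0)

  empty <- LULCGrid(matrix(0L), cellSize = 100)
  expect_true(all(groupStorage(empty, dens) == 0))

  set.seed(34)
  for (rep in 1:4) {
    g <- randomGrid(12, 12, nodataFrac = 0.2)
    expect_equal(sum(groupStorage(g, dens)), totalStorage(g, dens),
                 tolerance = 1e-9)
  }
})

test_that("natural-breaks classes equal exhaustive search for n <= 12, any k", {
  expect_equal(jenksBreaks(c(1, 2, 11, 12, 101, 102), 3)$classes,
               list(c(1, 2), c(11, 12), c(101, 102)))
  expect_equal(jenksBreaks(c(5, 1, 9), 1)$classes[[1]], c(1, 5, 9))

  set.seed(35)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    vals <- round(runif(n, 0, 100), 1)
    k <- sample(2:min(4, length(unique(vals))), 1)
    got <- jenksBreaks(vals, k)
    want <- oracleJenks(vals, k)
    expect_equal(got$classes, want$classes)
    expect_equal(got$ssd, want$ssd, tolerance = 1e-9)
  }

  d <- densityTable(dens)
  expect_equal(jenksBreaks(d$c_total, 4)$classes,
               oracleJenks(d$c_total, 4)$classes)
  expect_error(jenksBreaks(c(1, 1, 2), 3), "distinct")
})

test_that("carbon-level maps put construction land lowest and grassland highest", {
  g <- LULCGrid(matrix(c(9L, 4L, 7L, 0L), 2), cellSize = 100)
  lm <- levelMap(g, dens)
  expect_equal(lm$levels[1, 1], 1L)          # construction: 8.0 is the minimum
  expect_equal(lm$levels[2, 1], 4L)          # grassland: 40.3 is the maximum
  expect_true(is.na(lm$levels[2, 2]))
  expect_equal(lm$legend$label, c("Lowest", "Lower", "Higher", "Highest"))

  uni <- LULCGrid(matrix(3L, 4, 4), cellSize = 100)
  expect_equal(length(unique(as.vector(levelMap(uni, dens)$levels))), 1)
})
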