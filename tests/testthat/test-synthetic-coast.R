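zeroRates <- c(accretion = 0, succession = 0, regressive_succession = 0,
               erosion = 0, reclamation = 0, restoration = 0)

test_that("all-zero rates give a frozen coastline across all dates", {
  s <- generateSeries(coastScenario(shape = c(20, 30), rates = zeroRates,
                                    seed = 3))
  cells <- lapply(seriesGrids(s), lulcCells)
  for (t in 2:4) expect_identical(cells[[t]], cells[[1]])
})

test_that("seeding contract: same seed identical, different seeds differ", {
  sc1 <- coastScenario(shape = c(25, 40), seed = 1)
  sc2 <- coastScenario(shape = c(25, 40), seed = 2)
  a <- generateSeries(sc1); b <- generateSeries(sc1)
  c_ <- generateSeries(sc2)
  expect_identical(lapply(seriesGrids(a), lulcCells),
                   lapply(seriesGrids(b), lulcCells))
  expect_false(identical(lapply(seriesGrids(a), lulcCells),
                         lapply(seriesGrids(c_), lulcCells)))
})

test_that("accretion-only dynamics: every changing cell steps 1->2 once and classifies as Mono+ A", {
  rates <- zeroRates; rates["accretion"] <- 0.5
  s <- generateSeries(coastScenario(shape = c(30, 50), rates = rates,
                                    seed = 9))
  cells <- lapply(seriesGrids(s), lulcCells)
  codes <- sapply(cells, as.vector)
  changedRows <- which(apply(codes, 1, function(v) length(unique(v)) > 1))
  for (i in changedRows) {
    v <- codes[i, ]
    steps <- paste(v[-4], v[-1])[v[-4] != v[-1]]
    expect_identical(unique(steps), "1 2")
  }
  pt <- processTable(s, carbonDensities())
  expect_identical(pt$chain, "A")
  expect_gt(pt$total_dc, 0)
  expect_identical(pt$category, "Mono+")
  expect_identical(pt$attribute, "Natural")
})

test_that("with zero erosion the non-water area never shrinks", {
  sc <- coastScenario(shape = c(25, 40),
                      rates = c(accretion = 0.4, succession = 0.3,
                                regressive_succession = 0.1, erosion = 0,
                                reclamation = 0.2, restoration = 0.1),
                      seed = 17)
  s <- generateSeries(sc)
  nonwater <- vapply(seriesGrids(s), function(g)
    sum(lulcCells(g) != 1L & lulcCells(g) != 0L), integer(1))
  expect_true(all(diff(nonwater) >= 0))
})

test_that("succession-only rate is recovered within 3 SE on an all-flat grid", {
  rate <- 0.3
  n <- 10000
  sc <- coastScenario(shape = c(100, 100),
                      rates = replace(zeroRates, "succession", rate),
                      seed = 23)
  flat <- LULCGrid(matrix(2L, 100, 100), cellSize = 30)
  set.seed(23)
  adv <- advanceCoast(flat, sc)
  phat <- mean(lulcCells(adv) == 3L)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(phat - rate), 3 * se)
})

test_that("materialize-then-tally is the identity on transition matrices", {
  set.seed(5)
  m <- matrix(rpois(100, 3) * 0.01, 10, 10)
  pair <- materializeFromMatrix(m, cellSize = 100)
  tm <- transitionMatrix(pair[[1]], pair[[2]])
  expect_equal(tm@areas, m, tolerance = 1e-12)

  single <- matrix(0, 10, 10); single[2, 3] <- 0.02
  pair <- materializeFromMatrix(single, cellSize = 100)
  expect_equal(sum(lulcCells(pair[[1]]) == 2L), 2)
  expect_equal(sum(lulcCells(pair[[2]]) == 3L), 2)

  empty <- materializeFromMatrix(matrix(0, 10, 10), cellSize = 100)
  expect_true(all(lulcCells(empty[[1]]) == 0L))
  expect_true(all(lulcCells(empty[[2]]) == 0L))
})

test_that("materialize rejects non-integral cell multiples, naming the entry", {
  m <- matrix(0, 10, 10); m[4, 7] <- 0.015
  expect_error(materializeFromMatrix(m, cellSize = 100), "4 -> 7")
})

test_that("degenerate scenario shapes and bad rates are rejected", {
  expect_error(coastScenario(shape = c(10, 2)), "3 columns")
  expect_error(coastScenario(rates = replace(zeroRates, "erosion", 1.2)),
               "\\[0, 1\\]")
  expect_error(coastScenario(reclamationTargets = c(`6` = 0.5, `7` = 0.2,
                                                    `8` = 0.1, `9` = 0.1,
                                                    `10` = 0.2)),
               "summing to 1")
})

test_that("scenario YAML round trip preserves the configuration", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("shape: [12, 18]", "cellSize: 60", "nDates: 3", "seed: 77",
               "rates: {accretion: 0.2, erosion: 0.05}",
               "reclamationReach: 4"), p)
  sc <- readScenario(p)
  expect_identical(sc@shape, c(12L, 18L))
  expect_equal(sc@rates[["accretion"]], 0.2)
  expect_equal(sc@rates[["succession"]], 0)
  expect_identical(sc@seed, 77L)
})
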