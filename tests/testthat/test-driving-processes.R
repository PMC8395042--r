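dens <- carbonDensities()

test_that("step mapping is total over all 100 pairs with disjoint process sets", {
  pairs <- expand.grid(a = 1:10, b = 1:10)
  steps <- stepProcess(pairs$a, pairs$b)
  expect_equal(length(steps), 100)
  expect_true(all(steps %in% c("A", "S", "Rs", "E", "R", "Re", "Stable",
                               "U")))
  counts <- table(steps)
  expect_equal(counts[["Stable"]], 10)  # the diagonal
  expect_equal(counts[["A"]], 4)
  expect_equal(counts[["S"]], 3)
  expect_equal(counts[["Rs"]], 1)
  expect_equal(counts[["E"]], 3)
  expect_equal(counts[["R"]], 25)
  expect_equal(counts[["Re"]], 25)
  # each pair yields exactly one step, so the sets are disjoint by construction;
  # spot-check the named transitions
  expect_equal(stepProcess(1, 2), "A")
  expect_equal(stepProcess(3, 3), "Stable")
  expect_equal(stepProcess(3, 7), "R")
  expect_equal(stepProcess(9, 6), "U")
  expect_equal(stepProcess(2, 5), "U")
  expect_error(stepProcess(0, 2), "1..10")
})

test_that("pixel chains drop Stable, collapse duplicates, keep unclassified", {
  expect_equal(pixelChain(c(3, 7, 3, 9)), "R-Re-R")
  expect_equal(pixelChain(c(2, 2, 2, 2)), "Stable")
  expect_equal(pixelChain(c(1, 2, 1, 2)), "A-E-A")
  expect_equal(pixelChain(c(1, 2, 2, 3)), "A-S")
  expect_equal(pixelChain(c(1, 2, 3, 4)), "A-S")  # S,S collapses
  expect_equal(pixelChain(c(9, 6, 6, 6)), "U")
  expect_error(pixelChain(3L), "2 dates")
})

test_that("chain attributes split natural, human and coupled chains", {
  expect_equal(chainAttribute("Rs-E"), "Natural")
  expect_equal(chainAttribute("R-Re-R"), "Human")
  expect_equal(chainAttribute("E-R"), "Natural-Human")
  expect_error(chainAttribute("Stable"), "Stable")
  expect_error(chainAttribute("A-U"), "unclassified")
})

test_that("chain categories combine step count with carbon-change sign", {
  expect_equal(chainCategory("A", 315009.94), "Mono+")
  expect_equal(chainCategory("A-S", 381527.51), "Multiple+")
  expect_equal(chainCategory("R", -141945.05), "Mono-")
  expect_equal(chainCategory("Rs-R", -17943.62), "Multiple-")
  expect_equal(chainCategory("Stable", 0), "Stable")
  expect_equal(chainCategory("A-E", 0), "Neutral")
})

test_that("process table worked example: one 1-ha pixel (1,2,3,3)", {
  grids <- lapply(c(1L, 2L, 3L, 3L), function(v)
    LULCGrid(matrix(v), cellSize = 100))
  for (i in 1:4) grids[[i]]@dateLabel <- paste0("t", i - 1)
  pt <- processTable(LULCSeries(grids), dens)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$chain, "A-S")
  expect_equal(pt$total_dc, 32.4 - 14.0)
  expect_equal(pt$area_ha, 1)
  expect_equal(pt$magnitude, 18.4)
  expect_equal(pt$category, "Multiple+")
  expect_equal(pt$attribute, "Natural")
})

test_that("identical-grid series yield an empty process table", {
  g <- randomGrid(6, 6)
  g2 <- g; g2@dateLabel <- "t1"
  expect_equal(nrow(processTable(LULCSeries(g, g2), dens)), 0)
})

test_that("per-chain totals sum to the sequestration of classified pixels", {
  set.seed(51)
  s <- randomSeries(4)
  g <- seriesGrids(s)
  pt <- processTable(s, dens, includeUnclassified = TRUE)
  stable_and_all <- sequestration(g[[1]], g[[4]], dens)
  # stable pixels contribute zero, so chain totals must telescope to the
  # full first-to-last sequestration when unclassified chains are kept
  expect_equal(sum(pt$total_dc), stable_and_all, tolerance = 1e-9)
  # magnitude x area reproduces total_dc
  expect_equal(pt$magnitude * pt$area_ha, pt$total_dc, tolerance = 1e-9)
  # Mono records are exactly the one-step chains; labels never exceed 3 steps
  nsteps <- lengths(strsplit(pt$chain, "-"))
  expect_true(all(nsteps <= 3))
  expect_equal(grepl("^Mono", pt$category), nsteps == 1 & pt$total_dc != 0)
})

test_that("category map distinguishes per-cell signs within one chain", {
  mk <- function(...) {
    vs <- list(...)
    grids <- lapply(seq_along(vs), function(i)
      LULCGrid(matrix(vs[[i]], 1), cellSize = 100,
               dateLabel = paste0("t", i - 1)))
    LULCSeries(grids)
  }
  # cell 1: (1,2,2,2) single A, dC=+4.4; cell 2: (3,7,3,9) R-Re-R, dC<0;
  # cell 3: unchanged
  s <- mk(c(1L, 3L, 5L), c(2L, 7L, 5L), c(2L, 3L, 5L), c(2L, 9L, 5L))
  cm <- categoryMap(s, dens)
  lab <- cm$legend$label[cm$categories]
  expect_equal(lab, c("Mono+", "Multiple-", "Stable"))
  expect_equal(cm$chains[1, ], c("A", "R-Re-R", "Stable"))
})

test_that("single-process synthetic scenarios are recovered with correct labels", {
  zero <- c(accretion = 0, succession = 0, regressive_succession = 0,
            erosion = 0, reclamation = 0, restoration = 0)
  cases <- list(
    list(rate = "accretion", chain = "A", attr = "Natural"),
    list(rate = "reclamation", chain = "R", attr = "Human"),
    list(rate = "erosion", chain = "E", attr = "Natural"))
  for (cs in cases) {
    sc <- coastScenario(shape = c(25, 40),
                        rates = replace(zero, cs$rate, 0.4), seed = 61)
    pt <- processTable(generateSeries(sc), dens)
    expect_equal(pt$chain, cs$chain)
    expect_equal(pt$attribute, cs$attr)
    expect_match(pt$category, "^Mono")
  }
})
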