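# Independent brute-force oracles; deliberately naive implementations
# that never share code with the package's computation paths.

# per-cell double-loop transition tally (km^2)
oracleTransition <- function(gridA, gridB) {
  a <- lulcCells(gridA); b <- lulcCells(gridB)
  out <- matrix(0, 10, 10)
  for (r in seq_len(nrow(a))) for (cc in seq_len(ncol(a))) {
    if (a[r, cc] == 0L || b[r, cc] == 0L) next
    out[a[r, cc], b[r, cc]] <- out[a[r, cc], b[r, cc]] + 1
  }
  out * cellSize(gridA)^2 / 1e6
}

# per-cell storage sum (Mg)
oracleStorage <- function(grid, table) {
  d <- densityTable(table)
  cellHa <- cellSize(grid)^2 / 1e4
  total <- 0
  m <- lulcCells(grid)
  for (v in m[m != 0L]) total <- total + d$c_total[d$code == v] * cellHa
  total
}

# exhaustive search over all contiguous k-partitions of sorted values;
# first minimum in lexicographic break order wins (same tie rule as the
# package claims)
oracleJenks <- function(values, k) {
  x <- sort(as.numeric(values))
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(list(classes = list(x), ssd = ssd(x)))
  best <- NULL; bestCost <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    classes <- lapply(seq_len(k), function(m) x[(cuts[m] + 1):cuts[m + 1]])
    cost <- sum(vapply(classes, ssd, numeric(1)))
    if (cost < bestCost - 1e-12) { bestCost <- cost; best <- classes }
  }
  list(classes = best, ssd = bestCost)
}

# naive O(n^3) agglomerative clustering from a Euclidean distance matrix;
# returns per-merge member sets (sorted leaf indices) and heights
oracleHclust <- function(m, linkage = "complete") {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  merges <- list()
  linkdist <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    switch(linkage, complete = max(vals), single = min(vals),
           average = mean(vals))
  }
  while (length(clusters) > 1) {
    bestPair <- NULL; bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- linkdist(clusters[[i]], clusters[[j]])
      if (dd < bestD - 1e-12) { bestD <- dd; bestPair <- c(i, j) }
    }
    merged <- sort(c(clusters[[bestPair[1]]], clusters[[bestPair[2]]]))
    merges[[length(merges) + 1]] <- list(members = merged, height = bestD)
    clusters[[bestPair[1]]] <- merged
    clusters[[bestPair[2]]] <- NULL
  }
  merges
}

# hclust merge matrix -> per-merge member sets
hclustMembers <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    take <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(take(hc$merge[s, 1]), take(hc$merge[s, 2])))
  }
  sets
}

randomGrid <- function(nr = 20, nc = 20, cellSize = 100, nodataFrac = 0,
                       dateLabel = "t0") {
  m <- matrix(sample(1:10, nr * nc, replace = TRUE), nr, nc)
  if (nodataFrac > 0)
    m[sample(nr * nc, round(nodataFrac * nr * nc))] <- 0L
  LULCGrid(m, cellSize = cellSize, dateLabel = dateLabel)
}

# congruent random series: each date perturbs a fraction of the previous
randomSeries <- function(nDates = 4, nr = 15, nc = 15, changeFrac = 0.3) {
  g1 <- randomGrid(nr, nc, nodataFrac = 0.1)
  grids <- list(g1)
  for (t in 2:nDates) {
    prev <- lulcCells(grids[[t - 1]])
    m <- prev
    live <- which(prev != 0L)
    flip <- sample(live, round(changeFrac * length(live)))
    m[flip] <- sample(1:10, length(flip), replace = TRUE)
    grids[[t]] <- LULCGrid(m, cellSize = 100,
                           dateLabel = paste0("t", t - 1))
  }
  LULCSeries(grids)
}
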