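## step lookup: STEP_LOOKUP[a, b] for ordered code pair (a, b)
buildStepLookup <- function() {
  m <- matrix("U", 10, 10)
  diag(m) <- "Stable"
  for (p in list(c(1, 2), c(1, 3), c(5, 2), c(5, 3))) m[p[1], p[2]] <- "A"
  for (p in list(c(2, 3), c(2, 4), c(3, 4))) m[p[1], p[2]] <- "S"
  m[3, 2] <- "Rs"
  for (p in list(c(2, 1), c(3, 1), c(4, 1))) m[p[1], p[2]] <- "E"
  m[1:5, 6:10] <- "R"
  m[6:10, 1:5] <- "Re"
  m
}
STEP_LOOKUP <- buildStepLookup()

#' Driving process of an ordered code pair
#'
#' Maps a start/end land-cover pair to its driving-process step:
#' accretion (A: 1-2, 1-3, 5-2, 5-3), succession (S: 2-3, 2-4, 3-4),
#' regressive succession (Rs: 3-2), erosion (E: 2-1, 3-1, 4-1),
#' reclamation (R: any of 1..5 to any of 6..10), restoration (Re: any of
#' 6..10 to any of 1..5), Stable on equal codes, and "U" (unclassified)
#' for the remaining pairs the taxonomy never names (e.g. 9-6 or 2-5).
#' Total: every one of the 100 ordered pairs yields exactly one step.
#'
#' @param codeA,codeB integer code vectors (recycled to equal length).
#' @return character vector of steps.
#' @examples
#' stepProcess(1, 2)   # "A"
#' stepProcess(3, 7)   # "R"
#' @export
stepProcess <- function(codeA, codeB) {
  a <- as.integer(codeA); b <- as.integer(codeB)
  if (any(is.na(a) | a < 1 | a > 10) || any(is.na(b) | b < 1 | b > 10))
    stop("codes must be integers in 1..10")
  STEP_LOOKUP[cbind(a, b)]
}

#' Driving-process chain of one pixel trajectory
#'
#' Per-interval steps via [stepProcess()]; Stable steps are dropped and
#' consecutive duplicate steps collapse, so the chain records distinct
#' successive processes. A pixel that never changes has chain "Stable".
#' Unclassified steps are kept in the label as "U".
#'
#' @param codes integer vector, one code per date (>= 2 dates).
#' @return chain label, e.g. "A-S", "R-Re-R", "Stable".
#' @examples
#' pixelChain(c(3, 7, 3, 9))  # "R-Re-R"
#' pixelChain(c(1, 2, 2, 3))  # "A-S"
#' @export
pixelChain <- function(codes) {
  if (length(codes) < 2) stop("need at least 2 dates")
  steps <- stepProcess(codes[-length(codes)], codes[-1])
  steps <- steps[steps != "Stable"]
  if (!length(steps)) return("Stable")
  steps <- rle(steps)$values
  paste(steps, collapse = "-")
}

## vectorized chain labels for a code matrix (pixels x dates)
chainLabels <- function(codeMat) {
  nd <- ncol(codeMat)
  steps <- sapply(seq_len(nd - 1), function(t)
    stepProcess(codeMat[, t], codeMat[, t + 1]))
  if (is.null(dim(steps))) steps <- matrix(steps, ncol = nd - 1)
  apply(steps, 1, function(s) {
    s <- s[s != "Stable"]
    if (!length(s)) "Stable" else paste(rle(s)$values, collapse = "-")
  })
}

#' Attribute of a process chain
#'
#' Natural if every step is accretion, succession, regressive succession
#' or erosion; Human if every step is reclamation or restoration;
#' Natural-Human for mixtures.
#'
#' @param chain chain label (e.g. "Rs-E") or character vector of steps.
#' @return one of "Natural", "Human", "Natural-Human".
#' @examples
#' chainAttribute("E-R")  # "Natural-Human"
#' @export
chainAttribute <- function(chain) {
  steps <- if (length(chain) == 1) strsplit(chain, "-")[[1]] else chain
  if (!length(steps) || identical(steps, "Stable"))
    stop("attribute undefined for an empty/Stable chain")
  if ("U" %in% steps)
    stop("attribute undefined for chains with unclassified steps")
  natural <- c("A", "S", "Rs", "E"); human <- c("R", "Re")
  if (any(!steps %in% c(natural, human)))
    stop("unknown step in chain: ", paste(steps, collapse = "-"))
  if (all(steps %in% natural)) "Natural"
  else if (all(steps %in% human)) "Human"
  else "Natural-Human"
}

#' Category of a process chain
#'
#' Mono when the chain holds a single (distinct) process, Multiple when
#' several; sign from the net carbon change. A zero net change is the
#' boundary case "Neutral"; a Stable chain is "Stable".
#'
#' @param chain chain label.
#' @param totalDC net carbon change of the chain's pixels, Mg.
#' @return one of "Mono+", "Mono-", "Multiple+", "Multiple-", "Neutral",
#'   "Stable".
#' @examples
#' chainCategory("A-S", 381527.51)  # "Multiple+"
#' @export
chainCategory <- function(chain, totalDC) {
  if (identical(chain, "Stable") || !nzchar(chain)) return("Stable")
  nsteps <- length(strsplit(chain, "-")[[1]])
  if (totalDC == 0) return("Neutral")
  paste0(if (nsteps == 1) "Mono" else "Multiple",
         if (totalDC > 0) "+" else "-")
}

## pixels x dates code matrix of the non-nodata cells, plus their indices
seriesCodeMatrix <- function(series) {
  grids <- series@grids
  live <- which(grids[[1]]@cells != NODATA)
  codes <- vapply(grids, function(g) g@cells[live],
                  integer(length(live)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = length(live))
  list(codes = codes, idx = live)
}

#' Per-chain carbon-change table
#'
#' Groups all changed pixels by their driving-process chain and reports,
#' per chain: net carbon change (Mg, end minus start storage), area (ha),
#' magnitude (Mg/ha), category and attribute. Chains containing
#' unclassified steps are excluded by default and reported separately via
#' `includeUnclassified`.
#'
#' @param series an [LULCSeries-class].
#' @param table a [CarbonDensityTable-class].
#' @param includeUnclassified keep chains bearing unclassified ("U")
#'   steps; their attribute is NA.
#' @return data.frame with columns `chain`, `total_dc`, `area_ha`,
#'   `magnitude`, `category`, `attribute`, `n_pixels`, sorted by
#'   `total_dc`.
#' @export
processTable <- function(series, table, includeUnclassified = FALSE) {
  stopifnot(is(series, "LULCSeries"))
  validObject(series)
  sm <- seriesCodeMatrix(series)
  if (!nrow(sm$codes))
    return(data.frame(chain = character(), total_dc = numeric(),
                      area_ha = numeric(), magnitude = numeric(),
                      category = character(), attribute = character(),
                      n_pixels = integer()))
  chains <- chainLabels(sm$codes)
  cellHa <- series@grids[[1]]@cellSize^2 / 1e4
  dens <- densityByCode(table)
  dc <- (dens[sm$codes[, ncol(sm$codes)]] - dens[sm$codes[, 1]]) * cellHa
  keep <- chains != "Stable"
  if (!includeUnclassified)
    keep <- keep & !grepl("(^|-)U(-|$)", chains)
  if (!any(keep))
    return(data.frame(chain = character(), total_dc = numeric(),
                      area_ha = numeric(), magnitude = numeric(),
                      category = character(), attribute = character(),
                      n_pixels = integer()))
  agg <- tapply(dc[keep], chains[keep], sum)
  npix <- table(chains[keep])[names(agg)]
  out <- data.frame(
    chain = names(agg),
    total_dc = as.numeric(agg),
    area_ha = as.numeric(npix) * cellHa,
    n_pixels = as.integer(npix),
    stringsAsFactors = FALSE)
  out$magnitude <- out$total_dc / out$area_ha
  out$category <- mapply(chainCategory, out$chain, out$total_dc)
  out$attribute <- vapply(out$chain, function(ch) {
    if (grepl("(^|-)U(-|$)", ch)) NA_character_ else chainAttribute(ch)
  }, character(1))
  out <- out[order(out$total_dc), c("chain", "total_dc", "area_ha",
                                    "magnitude", "category", "attribute",
                                    "n_pixels")]
  rownames(out) <- NULL
  out
}

#' Per-cell driving-process category raster
#'
#' Labels each cell Mono+/Mono-/Multiple+/Multiple- from its own chain
#' length and its own carbon change; unchanged cells are Stable. Cells
#' whose chain bears an unclassified step are labeled "Unclassified"; a
#' changed cell with zero carbon change is "Neutral".
#'
#' @inheritParams processTable
#' @return list with `categories` (integer matrix, NA on nodata),
#'   `legend` (data.frame value/label) and `chains` (character matrix of
#'   chain labels).
#' @export
categoryMap <- function(series, table) {
  stopifnot(is(series, "LULCSeries"))
  validObject(series)
  sm <- seriesCodeMatrix(series)
  chains <- chainLabels(sm$codes)
  cellHa <- series@grids[[1]]@cellSize^2 / 1e4
  dens <- densityByCode(table)
  dc <- (dens[sm$codes[, ncol(sm$codes)]] - dens[sm$codes[, 1]]) * cellHa
  lab <- vapply(seq_along(chains), function(i) {
    if (grepl("(^|-)U(-|$)", chains[i]) && chains[i] != "Stable")
      "Unclassified"
    else chainCategory(chains[i], dc[i])
  }, character(1))
  legend <- data.frame(
    value = 1:7,
    label = c("Stable", "Mono+", "Mono-", "Multiple+", "Multiple-",
              "Neutral", "Unclassified"))
  dimref <- dim(series@grids[[1]]@cells)
  cats <- matrix(NA_integer_, dimref[1], dimref[2])
  cats[sm$idx] <- match(lab, legend$label)
  chmat <- matrix(NA_character_, dimref[1], dimref[2])
  chmat[sm$idx] <- chains
  list(categories = cats, legend = legend, chains = chmat)
}
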