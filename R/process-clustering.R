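#' Process-by-year carbon storage matrix
#'
#' For every driving-process chain present in the series, sums the carbon
#' stored by that chain's pixels at each date: value(chain, date) =
#' sum over the chain's pixels of density(code at date) x cell area (ha).
#' Stable pixels are excluded, as are chains bearing unclassified steps
#' unless `includeUnclassified`.
#'
#' @inheritParams processTable
#' @return numeric matrix, rows = chain labels, cols = date labels (Mg).
#' @export
buildProcessYearMatrix <- function(series, table,
                                   includeUnclassified = FALSE) {
  stopifnot(is(series, "LULCSeries"))
  validObject(series)
  sm <- seriesCodeMatrix(series)
  labels <- dateLabels(series)
  if (!nrow(sm$codes))
    return(matrix(numeric(), 0, length(labels),
                  dimnames = list(NULL, labels)))
  chains <- chainLabels(sm$codes)
  keep <- chains != "Stable"
  if (!includeUnclassified) keep <- keep & !grepl("(^|-)U(-|$)", chains)
  if (!any(keep))
    return(matrix(numeric(), 0, length(labels),
                  dimnames = list(NULL, labels)))
  cellHa <- series@grids[[1]]@cellSize^2 / 1e4
  dens <- densityByCode(table)
  codes <- sm$codes[keep, , drop = FALSE]
  ch <- chains[keep]
  out <- vapply(seq_len(ncol(codes)), function(t)
    as.numeric(tapply(dens[codes[, t]] * cellHa, ch, sum)),
    numeric(length(unique(ch))))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  rownames(out) <- sort(unique(ch))
  colnames(out) <- labels
  out
}

#' Z-score normalize a matrix column-by-column
#'
#' Each column (period) is centered by its mean over rows and scaled by
#' its standard deviation over rows: z = (x - mu) / sigma. The default
#' sigma divides by n (population form); `sample = TRUE` divides by
#' n - 1 for parity with common heatmap tooling. A zero-variance column
#' becomes all zeros.
#'
#' @param matrix numeric matrix with >= 2 rows.
#' @param sample use the sample (n - 1) standard deviation.
#' @return the normalized matrix, same dimnames.
#' @examples
#' zscoreByPeriod(cbind(a = c(0, 10), b = c(1, 1)))
#' @export
zscoreByPeriod <- function(matrix, sample = FALSE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("input must be a numeric matrix")
  if (nrow(matrix) < 2)
    stop("z-score needs at least 2 rows (sd undefined)")
  if (any(!is.finite(matrix))) stop("values must be finite")
  n <- nrow(matrix)
  mu <- colMeans(matrix)
  centered <- sweep(matrix, 2, mu)
  sigma <- sqrt(colSums(centered^2) / if (sample) n - 1 else n)
  out <- sweep(centered, 2, ifelse(sigma > 0, sigma, 1), "/")
  out[, sigma == 0] <- 0
  out
}

#' Agglomerative clustering of process rows
#'
#' Hierarchical clustering of the (normalized) process-by-year matrix
#' rows under Euclidean distance. Default linkage is complete, the common
#' clustered-heatmap default; average and single are available. Columns
#' (years) are left in chronological order.
#'
#' @param matrix numeric matrix with >= 2 rows and finite values
#'   (typically the output of [zscoreByPeriod()]).
#' @param linkage one of "complete", "average", "single".
#' @return A [ClusterResult-class].
#' @export
clusterRows <- function(matrix, linkage = c("complete", "average",
                                            "single")) {
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2) stop("need at least 2 rows to cluster")
  if (any(!is.finite(matrix))) stop("values must be finite")
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = linkage)
  new("ClusterResult", matrix = matrix, tree = hc,
      order = as.integer(hc$order))
}

#' Export clustering results as CSV + JSON
#'
#' Writes the normalized matrix in dendrogram leaf order
#' (`<prefix>_matrix.csv`) and the merge tree (`<prefix>_dendrogram.json`:
#' labels, merge pairs in `stats::hclust` convention, heights, leaf
#' order). Any image rendering (e.g. [plotProcessHeatmap()]) is a veneer
#' over these files.
#'
#' @param result a [ClusterResult-class].
#' @param prefix output path prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
exportHeatmap <- function(result, prefix) {
  stopifnot(is(result, "ClusterResult"))
  m <- result@matrix[result@order, , drop = FALSE]
  csv <- paste0(prefix, "_matrix.csv")
  jsn <- paste0(prefix, "_dendrogram.json")
  utils::write.csv(data.frame(chain = rownames(m), m, check.names = FALSE),
                   csv, row.names = FALSE)
  jsonlite::write_json(
    list(labels = rownames(result@matrix),
         merge = apply(result@tree$merge, 1, as.integer, simplify = FALSE),
         height = result@tree$height,
         order = result@order,
         linkage = result@tree$method),
    jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, jsn))
}

#' Render the clustered heatmap
#'
#' Thin veneer over pheatmap, drawing the normalized matrix with the
#' already-computed row dendrogram and chronological columns. Requires
#' the pheatmap package.
#'
#' @param result a [ClusterResult-class].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotProcessHeatmap <- function(result, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is not installed")
  invisible(pheatmap::pheatmap(
    result@matrix,
    cluster_rows = stats::as.hclust(result@tree),
    cluster_cols = FALSE,
    clustering_distance_rows = "euclidean", ...))
}
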