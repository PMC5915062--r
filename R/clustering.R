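#' Ward hierarchical clustering of abundance profiles
#'
#' Agglomerative clustering of rows under Ward's minimum-variance criterion
#' with Euclidean distance (\code{stats::hclust}, \code{method =
#' "ward.D2"}, which applies the Lance-Williams update on squared
#' dissimilarities). Merge heights equal the square root of twice the
#' increase in within-cluster sum of squares and are non-decreasing. For
#' heat-map style displays cluster proteins and samples independently, on
#' log2 zero-replaced counts.
#'
#' @param values numeric matrix (e.g. proteins x samples of log2
#'   zero-replaced counts) with at least 2 rows and finite entries.
#' @return list with \code{merge} (hclust-style merge matrix), \code{height}
#'   (merge heights), \code{order} (leaf order), \code{labels}, and the
#'   underlying \code{hclust} object.
#' @export
wardCluster <- function(values) {
    values <- as.matrix(values)
    if (nrow(values) < 2L) stop("at least 2 rows are required")
    if (!all(is.finite(values))) stop("values must be finite")
    hc <- stats::hclust(stats::dist(values), method = "ward.D2")
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels, hclust = hc)
}

#' Export a Ward clustering as a Newick tree
#'
#' @param clustering result of \code{\link{wardCluster}}.
#' @param path optional file path; when given the tree is written there.
#' @return the Newick string, invisibly when written to a file.
#' @export
clusterNewick <- function(clustering, path = NULL) {
    phy <- ape::as.phylo(clustering$hclust)
    txt <- ape::write.tree(phy)
    if (!is.null(path)) {
        writeLines(txt, path)
        return(invisible(txt))
    }
    txt
}

#' Cluster rows and columns of a value matrix for heat-map ordering
#'
#' @param values numeric matrix.
#' @return list with \code{rows} and \code{cols} clusterings (see
#'   \code{\link{wardCluster}}) and \code{ordered}, the input reordered by
#'   both leaf orders.
#' @export
biclusterMatrix <- function(values) {
    rows <- wardCluster(values)
    cols <- wardCluster(t(values))
    list(rows = rows, cols = cols,
         ordered = values[rows$order, cols$order, drop = FALSE])
}
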