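#' Heatmap of the scaled tag index with Ward clustering
#'
#' Renders the min/max-scaled tag index (bins x samples) as a heatmap with
#' columns ordered by Ward-linkage hierarchical clustering (`"ward.D"`,
#' Euclidean distance), with an optional annotation bar for control status —
#' the standard visual check that positive and negative samples separate.
#' A single-sample matrix is drawn without a dendrogram.
#'
#' @param scaled scaled tag-index matrix (bins x samples), e.g. from
#'   [scaledTagIndex()].
#' @param annotation optional `data.frame` (rownames = sample ids) of column
#'   annotations, e.g. control CDH status.
#' @param filename optional output file (png/pdf by extension); `NULL` draws
#'   to the active device.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return Invisibly, the pheatmap object (column dendrogram in
#'   `$tree_col`).
#' @export
plotCDHHeatmap <- function(scaled, annotation = NULL, filename = NA, ...) {
    clusterCols <- ncol(scaled) > 1
    args <- list(mat = scaled, cluster_rows = FALSE,
                 cluster_cols = clusterCols,
                 clustering_method = "ward.D",
                 clustering_distance_cols = "euclidean",
                 show_colnames = ncol(scaled) <= 40,
                 filename = filename, silent = TRUE, ...)
    if (!is.null(annotation)) args$annotation_col <- annotation
    ph <- do.call(pheatmap::pheatmap, args)
    invisible(ph)
}

#' Ward-clustered column order of a sample matrix
#'
#' Leaf order of the `"ward.D"` dendrogram over samples (columns), as used
#' by [plotCDHHeatmap()].
#'
#' @param scaled scaled tag-index matrix (bins x samples).
#' @return Character vector of sample ids in dendrogram leaf order.
#' @export
wardColumnOrder <- function(scaled) {
    if (ncol(scaled) < 2) return(colnames(scaled))
    hc <- hclust(dist(t(scaled)), method = "ward.D")
    colnames(scaled)[hc$order]
}
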