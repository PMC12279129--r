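#' Tile regions into non-overlapping 1 Mb bins
#'
#' Builds the fixed window grid over which the tag index is computed: each
#' region (chromosome or CDH interval) is tiled left to right with
#' non-overlapping windows of `binWidth` base pairs; the last window of a
#' region may be shorter.
#'
#' @param regions `GRanges` of the regions to tile, or a named numeric vector
#'   of region lengths.
#' @param binWidth window width in bp (default 1e6).
#' @return `GRanges` of bins with a `bin_id` metadata column.
#' @export
binGrid <- function(regions, binWidth = 1e6) {
    if (is.numeric(regions) && !is.null(names(regions)))
        regions <- GRanges(names(regions), IRanges(1L, unname(regions)))
    bins <- unlist(slidingWindows(regions, width = binWidth, step = binWidth))
    mcols(bins)$bin_id <- paste0(seqnames(bins), ":",
                                 start(bins) - 1L, "-", end(bins))
    names(bins) <- mcols(bins)$bin_id
    bins
}

#' Assign tags to bins by start coordinate
#'
#' Each tag belongs to exactly one bin, chosen by its start position; a tag
#' straddling a bin boundary stays in the bin containing its start. Tags on
#' regions outside the grid are unassigned (`NA`).
#'
#' @param tags `GRanges` of tag coordinates.
#' @param grid bin `GRanges` from [binGrid()].
#' @return Integer vector: for each tag, the index of its bin in `grid`, or
#'   `NA` if off-grid.
#' @export
binTags <- function(tags, grid) {
    starts <- resize(tags, width = 1L, fix = "start")
    findOverlaps(starts, grid, select = "first")
}

#' Compute the binned tag index
#'
#' For every sample `s` and bin `b`, the tag index is `sqrt(c) + d` where
#' `c` is the number of the bin's tag sites observed (depth > 0) in `s` and
#' `d` is the sum of the reads-per-million depth of the bin's tags in `s`.
#' Square-rooting `c` keeps the count of distinct observed sites from
#' dominating the summed depth while still rewarding breadth of coverage;
#' bins without tags score 0.
#'
#' @param te an RPM-normalized [TagExperiment-class].
#' @param grid bin `GRanges` from [binGrid()].
#' @param assayName which assay provides the depth `d` (default `"rpm"`).
#' @return A [TagIndexExperiment-class] (bins x samples) with assays `"c"`,
#'   `"d"` and `"index"`; column data is inherited from `te`.
#' @export
tagIndex <- function(te, grid, assayName = "rpm") {
    depth <- assay(te, assayName)
    hit <- binTags(rowRanges(te), grid)
    keep <- !is.na(hit)
    f <- factor(hit[keep], levels = seq_along(grid))
    dep <- depth[keep, , drop = FALSE]
    cmat <- rowsum((dep > 0) + 0, f)          # observed tag sites per bin
    dmat <- rowsum(dep, f)                    # summed depth per bin
    cmat[is.na(cmat)] <- 0; dmat[is.na(dmat)] <- 0
    # rowsum over a factor keeps all levels only when present; rebuild full grid
    full <- function(m) {
        out <- matrix(0, length(grid), ncol(depth),
                      dimnames = list(names(grid), colnames(depth)))
        out[as.integer(rownames(m)), ] <- m
        out
    }
    cmat <- full(cmat); dmat <- full(dmat)
    se <- SummarizedExperiment(
        assays = list(c = cmat, d = dmat, index = sqrt(cmat) + dmat),
        rowRanges = grid, colData = colData(te))
    new("TagIndexExperiment", se)
}

#' Min/max scale a matrix per feature (row)
#'
#' Per bin, over the given sample set: `x' = (x - min) / (max - min)`.
#' Constant bins scale to 0 (not `NaN`/`NA`), so uninformative features stay
#' inert under Euclidean clustering. Scaling is always recomputed within each
#' clustering batch over exactly the batch's samples, so every k-means run
#' sees features on `[0, 1]` regardless of batch membership.
#'
#' @param x numeric matrix (features x samples).
#' @param samples columns over which min and max are taken (and which are
#'   returned); defaults to all.
#' @return The scaled matrix, values in `[0, 1]`.
#' @export
minMaxScale <- function(x, samples = colnames(x)) {
    x <- x[, samples, drop = FALSE]
    rmin <- apply(x, 1, min)
    rmax <- apply(x, 1, max)
    rng <- rmax - rmin
    out <- (x - rmin) / ifelse(rng == 0, 1, rng)
    out[rng == 0, ] <- 0
    out
}

#' Min/max-scaled tag index of a TagIndexExperiment
#'
#' @param tie a [TagIndexExperiment-class].
#' @param samples sample set over which scaling is computed (default: all).
#' @param bins optional bin subset (ids or indices).
#' @return Scaled matrix bins x samples.
#' @export
scaledTagIndex <- function(tie, samples = colnames(tie), bins = NULL) {
    m <- assay(tie, "index")
    if (!is.null(bins)) m <- m[bins, , drop = FALSE]
    minMaxScale(m, samples)
}

#' Write a tag-index table to TSV
#'
#' Long-format export: one row per bin x sample with the raw components and
#' the cohort-scaled index.
#'
#' @param tie a [TagIndexExperiment-class].
#' @param path output TSV path.
#' @return Invisibly, the data.frame written.
#' @export
writeTagIndex <- function(tie, path) {
    rr <- rowRanges(tie)
    sc <- scaledTagIndex(tie)
    df <- data.frame(
        bin_id = rep(names(rr), ncol(tie)),
        chrom = rep(as.character(seqnames(rr)), ncol(tie)),
        start = rep(start(rr) - 1L, ncol(tie)),
        end = rep(end(rr), ncol(tie)),
        sample = rep(colnames(tie), each = nrow(tie)),
        c = as.vector(assay(tie, "c")),
        d = as.vector(assay(tie, "d")),
        index = as.vector(assay(tie, "index")),
        scaled_index = as.vector(sc))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
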