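#' Gene-space bins over single-copy core genes
#'
#' The copy-number baseline is the tag index over single-copy core genes,
#' binned in 1 Mb of *concatenated gene sequence* rather than genomic
#' coordinates: gene intervals are laid end to end in their given order and
#' the resulting gene-space axis is tiled with 1 Mb bins (the last bin may be
#' shorter). A tag maps into gene space through the gene containing its start
#' coordinate; tags outside every gene are excluded from the baseline.
#'
#' @param genes `GRanges` of non-overlapping single-copy core-gene intervals.
#' @param binWidth gene-space bin width in bp (default 1e6).
#' @return A `GeneSpaceBins` object.
#' @export
geneSpaceBins <- function(genes, binWidth = 1e6) {
    if (length(GenomicRanges::reduce(genes)) != length(genes) ||
        sum(GenomicRanges::width(GenomicRanges::reduce(genes))) !=
        sum(GenomicRanges::width(genes)))
        stop("gene intervals must be non-overlapping")
    offsets <- cumsum(as.numeric(GenomicRanges::width(genes))) -
        as.numeric(GenomicRanges::width(genes))
    total <- sum(as.numeric(GenomicRanges::width(genes)))
    new("GeneSpaceBins", genes = genes, offsets = offsets,
        binWidth = binWidth, nBins = as.integer(ceiling(total / binWidth)))
}

#' @rdname geneSpaceBins
#' @aliases GeneSpaceBins-class
#' @export
setClass("GeneSpaceBins", representation(
    genes = "GRanges", offsets = "numeric", binWidth = "numeric",
    nBins = "integer"))

setMethod("show", "GeneSpaceBins", function(object) {
    cat("GeneSpaceBins:", length(object@genes), "genes,",
        sum(as.numeric(GenomicRanges::width(object@genes))),
        "bp of gene space in", object@nBins, "bins\n")
})

# Map tag start coordinates into gene space; NA for tags outside genes.
.geneSpacePosition <- function(tags, gsb) {
    starts <- resize(tags, width = 1L, fix = "start")
    hit <- findOverlaps(starts, gsb@genes, select = "first")
    pos <- rep(NA_real_, length(tags))
    ok <- !is.na(hit)
    pos[ok] <- gsb@offsets[hit[ok]] +
        (GenomicRanges::start(starts)[ok] -
         GenomicRanges::start(gsb@genes)[hit[ok]])
    pos
}

#' Per-sample single-copy baseline tag index
#'
#' Computes the tag index (`sqrt(c) + d`) in each gene-space bin and averages
#' it across bins, giving each sample's expected tag index for single-copy
#' (diploid two-allele) sequence. Samples with an all-zero baseline are
#' flagged with `NA`.
#'
#' @param te an RPM-normalized [TagExperiment-class].
#' @param gsb a `GeneSpaceBins` object from [geneSpaceBins()].
#' @return Named numeric vector: mean gene-bin tag index per sample (`NA`
#'   when zero).
#' @export
coreGeneBaseline <- function(te, gsb) {
    pos <- .geneSpacePosition(rowRanges(te), gsb)
    keep <- !is.na(pos)
    bin <- floor(pos[keep] / gsb@binWidth) + 1
    f <- factor(bin, levels = seq_len(gsb@nBins))
    dep <- tagRPM(te)[keep, , drop = FALSE]
    cmat <- rowsum((dep > 0) + 0, f)
    dmat <- rowsum(dep, f)
    idx <- sqrt(cmat) + dmat
    base <- colMeans(idx) * nrow(idx) / gsb@nBins  # empty bins count as 0
    base <- setNames(as.numeric(base), colnames(te))
    base[base == 0] <- NA_real_
    base
}

#' CDH/core-gene relative tag index
#'
#' Divides each sample's mean tag index over the CDH diagnostic bins by its
#' single-copy core-gene baseline. Library size cancels in the ratio, so the
#' value tracks the dosage of the CDH relative to single-copy sequence. The
#' values need not be integers: much of a CDH is repetitive and poorly
#' conserved, so fewer tags align per Mb than in single-copy gene space.
#'
#' @param tie a [TagIndexExperiment-class] over the genomic bin grid.
#' @param bins CDH diagnostic bin ids.
#' @param baseline per-sample baseline from [coreGeneBaseline()].
#' @return Named numeric vector (`NA` and a warning where the baseline is 0).
#' @export
relativeIndex <- function(tie, bins, baseline) {
    cdhMean <- colMeans(assay(tie, "index")[bins, , drop = FALSE])
    baseline <- baseline[colnames(tie)]
    bad <- is.na(baseline)
    if (any(bad))
        warning("undefined relative index (zero baseline) for: ",
                paste(colnames(tie)[bad], collapse = ", "))
    setNames(as.numeric(cdhMean / baseline), colnames(tie))
}

#' Calibrate one-copy increments and integerize copy number
#'
#' Two-point calibration from control samples with known copy number: the
#' one-copy increment is `delta = median(two-copy) - median(one-copy)` of the
#' relative index, and the zero-copy offset is `median(one-copy) - delta`.
#' Estimated copies are `round((value - offset) / delta)` (ties to even),
#' clipped below at 0 and optionally above at `maxCopies` (2 for Ab10/K10L2,
#' where 2 copies means homozygous; the B chromosome is left unclipped).
#' Medians, not means, anchor the calibration: control strata are small and
#' a single outlying control should not tilt the increment.
#'
#' @param values named numeric vector of relative indices ([relativeIndex()]).
#' @param oneCopySamples,twoCopySamples ids of controls carrying exactly one /
#'   two copies of the CDH.
#' @param maxCopies optional upper clip for the estimate.
#' @return A list with `delta`, `offset` and `copies` (named integer vector;
#'   the raw `values` are returned alongside so the integerization can be
#'   ignored).
#' @export
calibrateCopies <- function(values, oneCopySamples, twoCopySamples,
                            maxCopies = Inf) {
    m1 <- median(values[oneCopySamples], na.rm = TRUE)
    m2 <- median(values[twoCopySamples], na.rm = TRUE)
    delta <- m2 - m1
    if (!is.finite(delta) || delta <= 0)
        stop("calibration failure: two-copy median (", signif(m2, 3),
             ") does not exceed one-copy median (", signif(m1, 3), ")")
    offset <- m1 - delta
    copies <- round((values - offset) / delta)
    copies <- pmin(pmax(copies, 0), maxCopies)
    list(delta = delta, offset = offset,
         copies = setNames(as.integer(copies), names(values)),
         values = values)
}

#' Copy-number table for one CDH
#'
#' Convenience wrapper: computes the relative index for the given samples and
#' calibrates copies from one- and two-copy controls.
#'
#' @inheritParams relativeIndex
#' @inheritParams calibrateCopies
#' @param samples samples to report (default: all columns).
#' @param cdh label recorded in the output.
#' @return `data.frame` with sample, cdh, relative_index, baseline,
#'   estimated_copies and the calibration constants.
#' @export
estimateCopyNumber <- function(tie, bins, baseline, oneCopySamples,
                               twoCopySamples, samples = colnames(tie),
                               cdh = "CDH", maxCopies = Inf) {
    ri <- relativeIndex(tie, bins, baseline)
    cal <- calibrateCopies(ri, oneCopySamples, twoCopySamples, maxCopies)
    data.frame(sample_id = samples, cdh = cdh,
               relative_index = unname(ri[samples]),
               baseline = unname(baseline[samples]),
               estimated_copies = unname(cal$copies[samples]),
               delta = cal$delta, offset = cal$offset, row.names = NULL)
}
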