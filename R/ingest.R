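#' Read a tag-by-taxa table with tag coordinates and sample metadata
#'
#' Joins the three on-disk pieces of a GBS tag-count dataset into a
#' [TagExperiment-class]: a counts TSV (rows = tags, columns = samples, first
#' column `tag_id`), a BED6+ file of tag coordinates whose name field is the
#' `tag_id` and whose score field is the BWA mapping quality, and a sample
#' metadata TSV with at least `sample_id` and `role` columns. Tags present in
#' the counts table but absent from the BED file are dropped with a warning.
#'
#' @param countsPath path to the counts TSV.
#' @param coordsPath path to the BED file of tag coordinates.
#' @param metaPath path to the sample metadata TSV.
#' @return A [TagExperiment-class].
#' @seealso [writeFixture()] writes the same layout.
#' @export
readTagTable <- function(countsPath, coordsPath, metaPath) {
    cts <- read.table(countsPath, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(cts)[1] != "tag_id")
        stop("counts table must have 'tag_id' as its first column")
    if (anyDuplicated(colnames(cts)[-1]))
        stop("duplicate sample ids in counts table")
    tagIds <- cts$tag_id
    mat <- as.matrix(cts[, -1, drop = FALSE])
    storage.mode(mat) <- "integer"
    rownames(mat) <- tagIds

    bed <- read.table(coordsPath, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(bed) < 5)
        stop("BED file must have at least 5 columns (chrom start end name score)")
    colnames(bed)[1:5] <- c("chrom", "start", "end", "tag_id", "mapq")
    # BED is 0-based half-open; GRanges is 1-based closed
    tags <- GRanges(bed$chrom, IRanges(bed$start + 1L, bed$end),
                    tag_id = bed$tag_id, mapq = as.integer(bed$mapq))

    keep <- tagIds %in% bed$tag_id
    if (!all(keep)) {
        warning(sum(!keep), " tag(s) in the counts table have no coordinates ",
                "in the BED file and were dropped")
        mat <- mat[keep, , drop = FALSE]
        tagIds <- tagIds[keep]
    }
    tags <- tags[match(tagIds, mcols(tags)$tag_id)]

    meta <- read.table(metaPath, header = TRUE, sep = "\t",
                       check.names = FALSE, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
    if (anyDuplicated(meta$sample_id))
        stop("duplicate sample ids in metadata")
    TagExperiment(mat, tags, meta)
}

#' Sum technical replicates into biological individuals
#'
#' Samples sharing a `replicate_group` have their tag counts summed
#' element-wise into a single column named after the group; samples without a
#' replicate group pass through unchanged. Column metadata for a merged group
#' is taken from its first member.
#'
#' @param te a [TagExperiment-class].
#' @return A `TagExperiment` with one column per biological individual.
#' @export
mergeReplicates <- function(te) {
    grp <- colData(te)$replicate_group
    if (all(is.na(grp))) return(te)
    key <- ifelse(is.na(grp), colnames(te), grp)
    if (any(!is.na(grp) & grp == ""))
        stop("empty replicate_group id")
    first <- !duplicated(key)
    cts <- tagCounts(te)
    merged <- vapply(unique(key), function(k)
        rowSums(cts[, key == k, drop = FALSE]),
        numeric(nrow(cts)))
    storage.mode(merged) <- "integer"
    cd <- colData(te)[first, , drop = FALSE]
    cd$sample_id <- unique(key)
    cd$replicate_group <- NA_character_
    TagExperiment(merged, rowRanges(te), cd)
}

#' Reads-per-million normalization
#'
#' Adds an `"rpm"` assay: `rpm[t, s] = counts[t, s] / total_s * 1e6`, so each
#' nonzero sample's column sums to one million. A sample with zero total reads
#' keeps an all-zero column (and is reported via a message).
#'
#' @param te a [TagExperiment-class].
#' @return The `TagExperiment` with an `"rpm"` assay added.
#' @export
rpmNormalize <- function(te) {
    cts <- tagCounts(te)
    totals <- colSums(cts)
    zero <- totals == 0
    if (any(zero))
        message("zero-read sample(s) kept all-zero: ",
                paste(colnames(te)[zero], collapse = ", "))
    denom <- ifelse(zero, 1, totals)
    assay(te, "rpm") <- sweep(cts, 2, denom, "/") * 1e6
    te
}

#' Per-sample missingness
#'
#' Fraction of tag sites with zero reads in each sample — the only notion of
#' "missing" observable at the tag-count level.
#'
#' @param te a [TagExperiment-class].
#' @return Named numeric vector in `[0, 1]`.
#' @export
sampleMissingness <- function(te) {
    colMeans(tagCounts(te) == 0)
}

#' Blank-derived sample missingness cutoff
#'
#' Blanks (no-DNA lanes) measure sequencing background; the cutoff is the
#' minimum missingness observed across blanks minus 0.001. Samples with more
#' missing data than this cutoff are indistinguishable from background and
#' are removed by [filterSamples()].
#'
#' @param te a [TagExperiment-class].
#' @param fallback explicit cutoff used (with a message) when the dataset has
#'   no blanks; without it the absence of blanks is an error.
#' @return A single proportion in `[0, 1]`.
#' @export
blankCutoff <- function(te, fallback = NULL) {
    blanks <- colnames(te)[sampleRole(te) == "blank"]
    if (length(blanks) == 0) {
        if (!is.null(fallback)) {
            message("no blank samples; using supplied cutoff ", fallback)
            return(fallback)
        }
        stop("no blank samples in the dataset; supply an explicit cutoff ",
             "via 'fallback'")
    }
    min(sampleMissingness(te)[blanks]) - 0.001
}

#' Remove samples exceeding the missingness cutoff
#'
#' Removal is strict: a sample is dropped only when its missingness is
#' strictly greater than the cutoff; samples exactly at the cutoff are kept.
#'
#' @param te a [TagExperiment-class].
#' @param cutoff maximum tolerated missingness (see [blankCutoff()]).
#' @return The filtered `TagExperiment`.
#' @export
filterSamples <- function(te, cutoff) {
    miss <- sampleMissingness(te)
    drop <- miss > cutoff
    if (all(drop))
        stop("all samples exceed the missingness cutoff ", cutoff)
    if (any(drop))
        message("removed ", sum(drop), " sample(s) above missingness cutoff ",
                signif(cutoff, 4), ": ",
                paste(colnames(te)[drop], collapse = ", "))
    te[, !drop]
}

#' Remove tags below a mapping-quality threshold
#'
#' @param te a [TagExperiment-class].
#' @param minMapq tags with `mapq < minMapq` are removed (default 20).
#' @return The filtered `TagExperiment`.
#' @export
filterTagsByMapq <- function(te, minMapq = 20) {
    te[tagMapq(te) >= minMapq, ]
}

#' Sample filter report
#'
#' @param te a [TagExperiment-class] (pre-filter).
#' @param cutoff the missingness cutoff applied.
#' @return `data.frame` with sample, role, missingness and kept/removed.
#' @export
filterReport <- function(te, cutoff) {
    miss <- sampleMissingness(te)
    data.frame(sample_id = colnames(te), role = unname(sampleRole(te)),
               missingness = unname(miss),
               status = ifelse(miss > cutoff, "removed", "kept"),
               row.names = NULL)
}

#' Standard ingest pipeline
#'
#' Merges technical replicates, derives the blank missingness cutoff, removes
#' failing samples, removes low-mapping-quality tags, and computes
#' reads-per-million — the full preprocessing chain in the narrative order of
#' the protocol.
#'
#' @param te a raw [TagExperiment-class].
#' @param minMapq mapping-quality threshold (default 20).
#' @param cutoff optional explicit missingness cutoff (otherwise from blanks).
#' @return A filtered, RPM-normalized `TagExperiment`.
#' @export
preprocessTags <- function(te, minMapq = 20, cutoff = NULL) {
    te <- mergeReplicates(te)
    if (is.null(cutoff)) cutoff <- blankCutoff(te)
    te <- filterSamples(te, cutoff)
    te <- filterTagsByMapq(te, minMapq)
    rpmNormalize(te)
}
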