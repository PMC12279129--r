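#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges findOverlaps resize slidingWindows seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqnames
#' @importFrom stats kmeans median prcomp predict rgamma rlnorm rnbinom rpois
#'   runif setNames hclust dist
#' @importFrom utils read.table write.table head
NULL

#' TagExperiment: GBS tag-by-taxa counts with tag coordinates and sample roles
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a genotyping-by-sequencing
#' (GBS) tag-by-taxa table: one row per tag site (a 64 bp read class mapped to
#' a unique genomic locus), one column per sample. The `"counts"` assay holds
#' non-negative integer read counts; an optional `"rpm"` assay holds
#' reads-per-million normalized depth. Row ranges carry the tag coordinates
#' (0-based half-open on disk in BED, 1-based closed inside GRanges) with
#' metadata columns `tag_id` and `mapq` (BWA mapping quality). Column data
#' must contain:
#' \describe{
#'   \item{sample_id}{unique sample identifier}
#'   \item{role}{one of `"blank"`, `"control"`, `"experimental"`}
#'   \item{control_cdh}{for controls, the chromosomal drive haplotype (CDH)
#'     the sample carries: `"Ab10"`, `"K10L2"`, `"B"`, or `"none"`}
#'   \item{copy_stratum}{optional `"low"` / `"high"` copy stratum of positive
#'     controls (heterozygous vs homozygous for Ab10/K10L2; few vs many copies
#'     for the B chromosome)}
#'   \item{ab10_type}{optional cytological type `"Ab10-I"`, `"Ab10-II"`,
#'     `"Ab10-III"` for Ab10 controls}
#'   \item{replicate_group}{optional technical-replicate grouping; replicates
#'     are summed into one biological individual by [mergeReplicates()]}
#' }
#'
#' @aliases TagExperiment-class
#' @seealso [readTagTable()], [simulateCohort()], [tagIndex()]
#' @export
setClass("TagExperiment", contains = "RangedSummarizedExperiment")

.validTagExperiment <- function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(cts < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    rr <- rowRanges(object)
    if (!all(c("tag_id", "mapq") %in% colnames(mcols(rr))))
        msg <- c(msg, "rowRanges must carry 'tag_id' and 'mapq'")
    else {
        if (anyDuplicated(mcols(rr)$tag_id))
            msg <- c(msg, "tag_id values must be unique")
        if (any(mcols(rr)$mapq < 0, na.rm = TRUE))
            msg <- c(msg, "mapq must be >= 0")
    }
    cd <- colData(object)
    need <- c("sample_id", "role")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must carry 'sample_id' and 'role'")
    else {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample_id values must be unique")
        if (!all(cd$role %in% c("blank", "control", "experimental")))
            msg <- c(msg, "role must be blank, control or experimental")
        if ("control_cdh" %in% colnames(cd)) {
            ctl <- cd$role == "control"
            if (any(ctl & (is.na(cd$control_cdh) |
                           !cd$control_cdh %in% c("Ab10", "K10L2", "B", "none"))))
                msg <- c(msg, "controls must have control_cdh in Ab10/K10L2/B/none")
            if (any(cd$role == "blank" & !is.na(cd$control_cdh) &
                    cd$control_cdh != "none"))
                msg <- c(msg, "blanks cannot carry a control_cdh")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("TagExperiment", .validTagExperiment)

#' Construct a TagExperiment
#'
#' @param counts integer matrix, tags x samples.
#' @param tags `GRanges` with one range per row of `counts`, carrying metadata
#'   columns `tag_id` and `mapq`.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata (see
#'   \linkS4class{TagExperiment}); rows are matched to `colnames(counts)` by
#'   `sample_id`.
#' @return A [TagExperiment-class] object.
#' @examples
#' tags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 64),
#'                                tag_id = c("t1", "t2"), mapq = c(60L, 42L))
#' counts <- matrix(c(3L, 0L, 1L, 5L), nrow = 2,
#'                  dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), role = "experimental")
#' TagExperiment(counts, tags, meta)
#' @export
TagExperiment <- function(counts, tags, sampleData) {
    stopifnot(nrow(counts) == length(tags))
    sampleData <- DataFrame(sampleData)
    if (is.null(colnames(counts)))
        colnames(counts) <- sampleData$sample_id
    if (!"control_cdh" %in% colnames(sampleData))
        sampleData$control_cdh <- NA_character_
    if (!"copy_stratum" %in% colnames(sampleData))
        sampleData$copy_stratum <- NA_character_
    if (!"ab10_type" %in% colnames(sampleData))
        sampleData$ab10_type <- NA_character_
    if (!"replicate_group" %in% colnames(sampleData))
        sampleData$replicate_group <- NA_character_
    idx <- match(colnames(counts), sampleData$sample_id)
    if (anyNA(idx))
        stop("samples in counts missing from sampleData: ",
             paste(colnames(counts)[is.na(idx)], collapse = ", "))
    if (!all(sampleData$sample_id %in% colnames(counts)))
        stop("sampleData lists samples absent from counts: ",
             paste(setdiff(sampleData$sample_id, colnames(counts)),
                   collapse = ", "))
    sampleData <- sampleData[idx, , drop = FALSE]
    rownames(sampleData) <- sampleData$sample_id
    names(tags) <- mcols(tags)$tag_id
    rownames(counts) <- mcols(tags)$tag_id
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = tags, colData = sampleData)
    new("TagExperiment", se)
}

#' TagIndexExperiment: the binned tag-index statistic
#'
#' A \linkS4class{RangedSummarizedExperiment} of 1 Mb bins x samples holding
#' the tag index `sqrt(c) + d` per bin and sample, where `c` is the number of
#' tag sites in the bin observed (read depth > 0) in that sample and `d` is
#' the summed reads-per-million depth of the bin's tags. Assays: `"c"`,
#' `"d"` and `"index"`. Row ranges are the bins ([binGrid()]); column data is
#' inherited from the source [TagExperiment-class].
#'
#' @aliases TagIndexExperiment-class
#' @seealso [tagIndex()], [scaledTagIndex()]
#' @export
setClass("TagIndexExperiment", contains = "RangedSummarizedExperiment")

setValidity("TagIndexExperiment", function(object) {
    msg <- NULL
    if (!all(c("c", "d", "index") %in% assayNames(object)))
        msg <- c(msg, "assays 'c', 'd' and 'index' are required")
    else {
        idx <- assay(object, "index")
        recon <- sqrt(assay(object, "c")) + assay(object, "d")
        if (max(abs(idx - recon)) > 1e-8)
            msg <- c(msg, "index must equal sqrt(c) + d")
        if (any(idx < 0)) msg <- c(msg, "index must be >= 0")
    }
    if (is.null(msg)) TRUE else msg
})

#' Parameters of the control-anchored k-means consensus caller
#'
#' Holds the tuning constants of the iterative k-means detection pipeline.
#' Defaults follow the published protocol: k = 2 clusters; a cluster is named
#' positive/negative only when at least 80% of its control samples share that
#' truth; 125 consensus rounds; a final call requires the same class in at
#' least 95% of completed rounds; experimental samples are spiked into each
#' batch at no more than 25% of the number of controls (10% for the B
#' chromosome); control validation uses 3 random groups repeated 100 times.
#'
#' @aliases CDHParam-class
#' @export
setClass("CDHParam", representation(
    k = "integer",
    purityThreshold = "numeric",
    consensusRounds = "integer",
    consensusThreshold = "numeric",
    spikeFraction = "numeric",
    controlValidationRounds = "integer",
    controlGroups = "integer",
    maxBatchRetries = "integer",
    separationThreshold = "numeric",
    nstart = "integer"
))

setValidity("CDHParam", function(object) {
    msg <- NULL
    if (object@purityThreshold <= 0 || object@purityThreshold > 1)
        msg <- c(msg, "purityThreshold must be in (0, 1]")
    if (object@consensusThreshold <= 0 || object@consensusThreshold > 1)
        msg <- c(msg, "consensusThreshold must be in (0, 1]")
    if (object@spikeFraction <= 0 || object@spikeFraction > 1)
        msg <- c(msg, "spikeFraction must be in (0, 1]")
    if (object@k < 2L) msg <- c(msg, "k must be >= 2")
    if (is.null(msg)) TRUE else msg
})

#' @param cdh which CDH the parameter set targets; sets the default spike
#'   fraction (0.25 for Ab10/K10L2, 0.10 for the B chromosome).
#' @param k number of k-means clusters.
#' @param purityThreshold minimum control purity for naming a cluster.
#' @param consensusRounds number of independent clustering rounds per sample.
#' @param consensusThreshold minimum agreeing fraction of completed rounds for
#'   a non-ambiguous call.
#' @param spikeFraction maximum experimental samples per batch, as a fraction
#'   of the batch's controls.
#' @param controlValidationRounds repetitions of the control-validation split.
#' @param controlGroups number of random control groups in validation.
#' @param maxBatchRetries re-randomizations allowed when a batch fails control
#'   verification before the batch is abandoned for that round.
#' @param separationThreshold minimum |mean(positive) - mean(negative)| of the
#'   min/max-scaled tag index for a bin to count as diagnostic.
#' @param nstart random restarts per k-means run.
#' @return A [CDHParam-class] object.
#' @examples
#' CDHParam("B")          # spike fraction 0.10
#' CDHParam("Ab10")       # spike fraction 0.25
#' @rdname CDHParam-class
#' @export
CDHParam <- function(cdh = c("Ab10", "K10L2", "B"), k = 2L,
                     purityThreshold = 0.80, consensusRounds = 125L,
                     consensusThreshold = 0.95,
                     spikeFraction = if (match.arg(cdh) == "B") 0.10 else 0.25,
                     controlValidationRounds = 100L, controlGroups = 3L,
                     maxBatchRetries = 50L, separationThreshold = 0.5,
                     nstart = 10L) {
    cdh <- match.arg(cdh)
    new("CDHParam", k = as.integer(k), purityThreshold = purityThreshold,
        consensusRounds = as.integer(consensusRounds),
        consensusThreshold = consensusThreshold,
        spikeFraction = spikeFraction,
        controlValidationRounds = as.integer(controlValidationRounds),
        controlGroups = as.integer(controlGroups),
        maxBatchRetries = as.integer(maxBatchRetries),
        separationThreshold = separationThreshold,
        nstart = as.integer(nstart))
}

setMethod("show", "CDHParam", function(object) {
    cat("CDHParam\n",
        "  k-means clusters:       ", object@k, "\n",
        "  cluster purity:         ", object@purityThreshold, "\n",
        "  consensus rounds:       ", object@consensusRounds, "\n",
        "  consensus threshold:    ", object@consensusThreshold, "\n",
        "  spike fraction:         ", object@spikeFraction, "\n",
        "  validation rounds:      ", object@controlValidationRounds,
        " (", object@controlGroups, " groups)\n",
        "  max batch retries:      ", object@maxBatchRetries, "\n",
        "  bin separation cutoff:  ", object@separationThreshold, "\n",
        sep = "")
})

#' Accessors for TagExperiment
#'
#' Convenience accessors over the assays and column data of a
#' [TagExperiment-class].
#'
#' @param x a `TagExperiment`.
#' @return `tagCounts` / `tagRPM`: a matrix; `tagMapq`: integer vector;
#'   `sampleRole`, `controlCDH`, `copyStratum`: character vectors named by
#'   sample.
#' @name TagExperiment-accessors
NULL

#' @rdname TagExperiment-accessors
#' @export
tagCounts <- function(x) assay(x, "counts")

#' @rdname TagExperiment-accessors
#' @export
tagRPM <- function(x) {
    if (!"rpm" %in% assayNames(x))
        stop("no 'rpm' assay; run rpmNormalize() first")
    assay(x, "rpm")
}

#' @rdname TagExperiment-accessors
#' @export
tagMapq <- function(x) mcols(rowRanges(x))$mapq

#' @rdname TagExperiment-accessors
#' @export
sampleRole <- function(x) setNames(colData(x)$role, colnames(x))

#' @rdname TagExperiment-accessors
#' @export
controlCDH <- function(x) setNames(colData(x)$control_cdh, colnames(x))

#' @rdname TagExperiment-accessors
#' @export
copyStratum <- function(x) setNames(colData(x)$copy_stratum, colnames(x))

setMethod("show", "TagExperiment", function(object) {
    callNextMethod()
    roles <- table(factor(colData(object)$role,
                          c("blank", "control", "experimental")))
    cat("roles: ", paste(names(roles), roles, sep = "=", collapse = " "), "\n")
})
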