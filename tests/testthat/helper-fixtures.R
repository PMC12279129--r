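suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
})

# Tiny hand-built TagExperiment: 4 tags on two chromosomes, 3 samples.
tinyTagExperiment <- function() {
    tags <- GRanges(c("chr1", "chr1", "chr1", "chr2"),
                    IRanges(c(1, 1500001, 999991, 21), width = 64),
                    tag_id = paste0("t", 1:4),
                    mapq = c(60L, 60L, 19L, 20L))
    counts <- matrix(c(5L, 0L, 2L,
                       2L, 1L, 0L,
                       0L, 3L, 0L,
                       1L, 0L, 0L), nrow = 4, byrow = TRUE,
                     dimnames = list(paste0("t", 1:4), c("s1", "s2", "s3")))
    meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                       role = c("experimental", "experimental", "blank"))
    TagExperiment(counts, tags, meta)
}

# One moderate simulated cohort shared across test files, built lazily and
# cached: the default control panel plus 60 experimental samples at the
# strong-signal preset, preprocessed, with the genomic bin grid and tag
# index precomputed.
.fixtureCache <- new.env(parent = emptyenv())

standardCohort <- function() {
    if (!is.null(.fixtureCache$std)) return(.fixtureCache$std)
    layout <- simLayout()
    panel <- makeControlPanel()
    panel$true_type <- panel$ab10_type
    exper <- simulateExperimentalTruth(n = 60, seed = 501)
    truth <- rbind(panel, exper[, colnames(panel)])
    te <- simulateCohort(layout, truth, simParam("strong"), seed = 502)
    tep <- suppressMessages(preprocessTags(te))
    rr <- rowRanges(tep)
    grid <- binGrid(vapply(split(end(rr), as.character(seqnames(rr))),
                           max, 0))
    tie <- tagIndex(tep, grid)
    .fixtureCache$std <- list(layout = layout, raw = te, te = tep,
                              grid = grid, tie = tie,
                              truth = as.data.frame(colData(tie)))
    .fixtureCache$std
}

# Control sample ids for a CDH/stratum from a TagIndexExperiment.
ctrlIds <- function(tie, cdh, stratum = NULL) {
    cd <- colData(tie)
    sel <- !is.na(cd$control_cdh) & cd$control_cdh == cdh
    if (!is.null(stratum)) sel <- sel & cd$copy_stratum %in% stratum
    colnames(tie)[sel]
}
negIds <- function(tie) ctrlIds(tie, "none")
expIds <- function(tie) colnames(tie)[colData(tie)$role == "experimental"]
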