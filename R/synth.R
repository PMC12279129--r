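#' Synthetic GBS reference layout
#'
#' Describes the reference world the simulator emulates: a normal chromosome
#' (diploid everywhere, carrying the single-copy core genes), an Ab10
#' haplotype region whose 1 Mb bins are modulated by cytological type, a
#' K10L2 region that also receives cross-mapped signal from Ab10 (the two
#' share TR-1 knob homology, which is why a K10L2 detector cannot tell them
#' apart), and a B chromosome present in 0 or more copies. Tag sites are
#' placed uniformly at a fixed density; a fraction of tags carries low
#' mapping quality to exercise the MAPQ filter.
#'
#' @param normalLength,ab10Length,k10l2Length,bLength region lengths in bp.
#'   The normal chromosome stands in for the whole diploid genome and must
#'   dwarf the CDH regions, as it does in maize (a B chromosome is ~150 Mb
#'   against a ~2.1 Gb genome): reads from a present CDH then perturb the
#'   library composition only mildly, as in real GBS data.
#' @param tagDensity tag sites per Mb.
#' @param geneCount,geneLength number and length of single-copy core genes
#'   (placed on alternating windows of the normal chromosome).
#' @param lowMapqFraction fraction of tags with mapping quality below 20.
#' @param crossMapAb10 cross-mapping rate of Ab10 copies onto the K10L2
#'   region (1 = full homologous signal).
#' @param typeProfiles optional matrix (3 types x Ab10 bins) of per-bin
#'   dosage multipliers; the default gives the three types a shared block
#'   plus type-specific blocks.
#' @param binWidth bin width used for the type profiles (default 1e6).
#' @return A `SimLayout` object.
#' @export
simLayout <- function(normalLength = 1e8, ab10Length = 20e6,
                      k10l2Length = 8e6, bLength = 15e6, tagDensity = 40,
                      geneCount = 120, geneLength = 5e4,
                      lowMapqFraction = 0.1, crossMapAb10 = 1.0,
                      typeProfiles = NULL, binWidth = 1e6) {
    regions <- GRanges(c("chr1", "Ab10", "K10L2", "chrB"),
                       IRanges(1L, c(normalLength, ab10Length, k10l2Length,
                                     bLength)),
                       role = c("normal", "ab10", "k10l2", "b"))
    geneStarts <- seq(1L, by = 2L * geneLength, length.out = geneCount)
    stopifnot(max(geneStarts) + geneLength <= normalLength)
    genes <- GRanges("chr1", IRanges(geneStarts, width = geneLength))
    nAbBins <- ceiling(ab10Length / binWidth)
    if (is.null(typeProfiles)) {
        typeProfiles <- matrix(0, 3, nAbBins,
                               dimnames = list(c("Ab10-I", "Ab10-II",
                                                 "Ab10-III"), NULL))
        shared <- seq_len(min(8, nAbBins))
        typeProfiles[, shared] <- 1
        blk <- function(a, b) intersect(seq(a, b), seq_len(nAbBins))
        typeProfiles["Ab10-I", blk(9, 12)] <- 1
        typeProfiles["Ab10-III", blk(9, 12)] <- 0.25
        typeProfiles["Ab10-II", blk(13, 16)] <- 1
        typeProfiles["Ab10-III", blk(13, 16)] <- 0.25
        typeProfiles["Ab10-I", blk(17, 20)] <- 0.25
        typeProfiles["Ab10-II", blk(17, 20)] <- 0.25
        typeProfiles["Ab10-III", blk(17, 20)] <- 1
    }
    new("SimLayout", regions = regions, genes = genes,
        tagDensity = tagDensity, lowMapqFraction = lowMapqFraction,
        crossMapAb10 = crossMapAb10, typeProfiles = typeProfiles,
        binWidth = binWidth)
}

#' @rdname simLayout
#' @aliases SimLayout-class
#' @export
setClass("SimLayout", representation(
    regions = "GRanges", genes = "GRanges", tagDensity = "numeric",
    lowMapqFraction = "numeric", crossMapAb10 = "numeric",
    typeProfiles = "matrix", binWidth = "numeric"))

setMethod("show", "SimLayout", function(object) {
    w <- GenomicRanges::width(object@regions)
    cat("SimLayout:", paste(as.character(seqnames(object@regions)),
                            paste0(round(w / 1e6, 1), "Mb"),
                            sep = "=", collapse = " "), "\n",
        length(object@genes), "core genes;", object@tagDensity,
        "tags/Mb\n")
})

#' Simulation parameters for synthetic GBS counts
#'
#' Counts are drawn as `count[t, s] ~ Poisson(lib_s * r * w_t * dose(t, s)
#' / 2)` where `r` is `meanReadsPerTag` (the expected depth of a diploid tag
#' site), `w_t` a per-tag gamma efficiency, `lib_s` a log-normal library-size
#' factor with unit mean, and `dose(t, s)` the local copy number (2 for
#' normal-genome and core-gene tags, one per CDH copy for CDH tags, scaled by
#' `effect` and shifted by the cross-mapping `background`). Blanks draw all
#' tags at the background-only `blankRate`. Setting a finite `dispersion`
#' switches to negative-binomial counts with that size parameter.
#'
#' The `"strong"` preset is the default study condition — positive and
#' negative controls separate starkly on the scaled tag index, as in a
#' well-behaved GBS control panel. The `"hard"` preset shrinks the dosage
#' effect and inflates the cross-mapping background toward class overlap.
#'
#' @param preset `"strong"` or `"hard"`.
#' @param meanReadsPerTag expected reads at a diploid tag site.
#' @param libSdLog sdlog of the log-normal library-size factor.
#' @param effect multiplier on CDH dosage (1 = full signal; 0 erases it).
#' @param background cross-mapping background dosage on CDH tags, as a
#'   fraction of diploid dose.
#' @param blankRate background dosage fraction for blank (no-DNA) lanes.
#' @param dispersion negative-binomial size; `Inf` means Poisson.
#' @return A named list of class `"simParam"`.
#' @export
simParam <- function(preset = c("strong", "hard"), meanReadsPerTag = NULL,
                     libSdLog = 0.4, effect = NULL, background = NULL,
                     blankRate = 0.01, dispersion = Inf) {
    preset <- match.arg(preset)
    def <- switch(preset,
                  strong = list(r = 4, eff = 1, bg = 0.03),
                  hard = list(r = 1.5, eff = 0.2, bg = 0.25))
    p <- list(preset = preset,
              meanReadsPerTag = if (is.null(meanReadsPerTag)) def$r
                                else meanReadsPerTag,
              libSdLog = libSdLog,
              effect = if (is.null(effect)) def$eff else effect,
              background = if (is.null(background)) def$bg else background,
              blankRate = blankRate, dispersion = dispersion)
    class(p) <- "simParam"
    p
}

#' Truth table for a control panel mirroring a real GBS control design
#'
#' Default class counts follow a realistic control panel: 49 Ab10 controls
#' spanning the three cytological types and both copy strata (heterozygous =
#' low, homozygous = high), 13 K10L2 controls (9 heterozygous, 4 homozygous),
#' 18 B-chromosome controls split into low (1-2 copies) and high (4-8
#' copies) strata, 18 no-CDH controls and 4 blanks.
#'
#' @param nAb10Low,nAb10High Ab10 controls per type (length-3 vectors,
#'   Ab10-I/II/III) in the low (1 copy) and high (2 copies) strata.
#' @param nK10Low,nK10High K10L2 controls with 1 / 2 copies.
#' @param nBLow,nBHigh B controls in the low / high copy strata.
#' @param bLowCopies,bHighCopies copy numbers cycled over the B controls.
#' @param nNegative no-CDH controls.
#' @param nBlanks no-DNA blank lanes.
#' @return A `data.frame` truth table for [simulateCohort()].
#' @export
makeControlPanel <- function(nAb10Low = c(10, 10, 9), nAb10High = c(7, 6, 7),
                             nK10Low = 9, nK10High = 4, nBLow = 8,
                             nBHigh = 10, bLowCopies = c(1, 2),
                             bHighCopies = 4:8, nNegative = 18, nBlanks = 4) {
    types <- c("Ab10-I", "Ab10-II", "Ab10-III")
    rows <- list()
    add <- function(n, cdh, stratum, type = NA, copies = 0, b = 0) {
        if (n == 0) return(NULL)
        data.frame(role = "control", control_cdh = cdh,
                   copy_stratum = stratum, ab10_type = type,
                   true_cdh = cdh, true_copies = copies, true_b_copies = b,
                   stringsAsFactors = FALSE)[rep(1, n), ]
    }
    for (i in 1:3) {
        rows <- c(rows, list(add(nAb10Low[i], "Ab10", "low", types[i], 1)))
        rows <- c(rows, list(add(nAb10High[i], "Ab10", "high", types[i], 2)))
    }
    rows <- c(rows, list(add(nK10Low, "K10L2", "low", copies = 1)))
    rows <- c(rows, list(add(nK10High, "K10L2", "high", copies = 2)))
    bl <- add(nBLow, "B", "low", b = 0)
    if (!is.null(bl)) bl$true_b_copies <- rep_len(bLowCopies, nBLow)
    bh <- add(nBHigh, "B", "high", b = 0)
    if (!is.null(bh)) bh$true_b_copies <- rep_len(bHighCopies, nBHigh)
    rows <- c(rows, list(bl, bh, add(nNegative, "none", NA)))
    if (nBlanks > 0) {
        blank <- data.frame(role = "blank", control_cdh = NA,
                            copy_stratum = NA, ab10_type = NA,
                            true_cdh = "none", true_copies = 0,
                            true_b_copies = 0,
                            stringsAsFactors = FALSE)[rep(1, nBlanks), ]
        rows <- c(rows, list(blank))
    }
    out <- do.call(rbind, rows)
    n <- nrow(out)
    out$sample_id <- sprintf("CTL%03d", seq_len(n))
    out$sample_id[out$role == "blank"] <-
        sprintf("BLANK%02d", seq_len(sum(out$role == "blank")))
    rownames(out) <- NULL
    out[, c("sample_id", setdiff(colnames(out), "sample_id"))]
}

#' Truth table for a simulated experimental cohort
#'
#' Samples carry at most one chromosome-10 CDH (Ab10 of a random type, or
#' K10L2) or a B chromosome, at the given frequencies; the remainder are
#' CDH-free. Chromosome-10 positives are homozygous with probability
#' `pHomozygous`, otherwise heterozygous; B positives carry a copy number
#' drawn uniformly from `bCopies`.
#'
#' @param n cohort size.
#' @param pAb10,pK10L2,pB CDH frequencies.
#' @param pHomozygous probability an Ab10/K10L2 positive carries two copies.
#' @param bCopies candidate B copy numbers.
#' @param seed integer seed.
#' @return A `data.frame` truth table for [simulateCohort()].
#' @export
simulateExperimentalTruth <- function(n = 500, pAb10 = 0.06, pK10L2 = 0.05,
                                      pB = 0.12, pHomozygous = 0.2,
                                      bCopies = 1:8, seed = 1L) {
    set.seed(seed)
    cat_ <- sample(c("Ab10", "K10L2", "B", "none"), n, replace = TRUE,
                   prob = c(pAb10, pK10L2, pB, 1 - pAb10 - pK10L2 - pB))
    copies <- ifelse(cat_ %in% c("Ab10", "K10L2"),
                     1L + (runif(n) < pHomozygous), 0L)
    bcop <- ifelse(cat_ == "B", sample(bCopies, n, replace = TRUE), 0L)
    type <- ifelse(cat_ == "Ab10",
                   sample(c("Ab10-I", "Ab10-II", "Ab10-III"), n,
                          replace = TRUE), NA)
    data.frame(sample_id = sprintf("EXP%04d", seq_len(n)),
               role = "experimental", control_cdh = NA_character_,
               copy_stratum = NA_character_, ab10_type = NA_character_,
               true_cdh = cat_, true_copies = copies, true_b_copies = bcop,
               true_type = type, stringsAsFactors = FALSE)
}

#' Simulate a GBS tag-by-taxa cohort with known truth
#'
#' Generates tag sites from the layout (positions, per-tag efficiencies,
#' mapping qualities) and draws counts for every sample in the truth table
#' under the dosage model of [simParam()]. The truth columns travel in the
#' returned object's `colData`, so detection results can be scored against
#' them directly. Identical `layout`, `truth`, `param` and `seed` reproduce
#' the cohort bit-identically.
#'
#' @param layout a `SimLayout` from [simLayout()].
#' @param truth a truth table ([makeControlPanel()],
#'   [simulateExperimentalTruth()], or both row-bound; duplicated ids are an
#'   error).
#' @param param a [simParam()] list.
#' @param seed integer seed.
#' @return A [TagExperiment-class] with truth columns in `colData`.
#' @export
simulateCohort <- function(layout, truth, param = simParam(), seed = 1L) {
    if (anyDuplicated(truth$sample_id))
        stop("duplicate sample ids in truth table")
    if (!"true_type" %in% colnames(truth)) truth$true_type <- truth$ab10_type
    set.seed(seed)
    ## tag sites
    reg <- layout@regions
    tagList <- lapply(seq_along(reg), function(i) {
        w <- GenomicRanges::width(reg)[i]
        n <- round(layout@tagDensity * w / 1e6)
        starts <- sort(sample.int(w - 64L, n))
        GRanges(seqnames(reg)[i], IRanges(starts, width = 64L))
    })
    tags <- suppressWarnings(do.call(c, tagList))
    nT <- length(tags)
    mcols(tags)$tag_id <- sprintf("tag%05d", seq_len(nT))
    low <- runif(nT) < layout@lowMapqFraction
    mcols(tags)$mapq <- ifelse(low, sample(0:19, nT, replace = TRUE), 60L)
    w <- rgamma(nT, shape = 3, rate = 3)        # per-tag efficiency, mean 1

    region <- as.character(seqnames(tags))
    abBin <- ifelse(region == "Ab10",
                    floor((GenomicRanges::start(tags) - 1) / layout@binWidth)
                    + 1, NA)
    bg <- 2 * param$background
    nS <- nrow(truth)
    lib <- rlnorm(nS, meanlog = -param$libSdLog^2 / 2,
                  sdlog = param$libSdLog)

    dose <- matrix(0, nT, nS)
    for (s in seq_len(nS)) {
        tr <- truth[s, ]
        if (tr$role == "blank") { dose[, s] <- 2 * param$blankRate; next }
        d <- numeric(nT)
        d[region == "chr1"] <- 2
        abCopies <- if (!is.na(tr$true_cdh) && tr$true_cdh == "Ab10")
            tr$true_copies else 0
        k10Copies <- if (!is.na(tr$true_cdh) && tr$true_cdh == "K10L2")
            tr$true_copies else 0
        isAb <- region == "Ab10"
        prof <- if (abCopies > 0)
            layout@typeProfiles[tr$true_type, abBin[isAb]] else 0
        d[isAb] <- abCopies * prof * param$effect + bg
        d[region == "K10L2"] <-
            (k10Copies + layout@crossMapAb10 * abCopies) * param$effect + bg
        d[region == "chrB"] <- tr$true_b_copies * param$effect + bg
        dose[, s] <- d
    }
    mu <- (param$meanReadsPerTag / 2) * (w * dose) %*% diag(lib, nS)
    cts <- if (is.finite(param$dispersion))
        matrix(rnbinom(length(mu), mu = mu, size = param$dispersion), nT, nS)
    else matrix(rpois(length(mu), mu), nT, nS)
    colnames(cts) <- truth$sample_id
    cd <- truth
    cd$library_factor <- lib
    TagExperiment(cts, tags, cd)
}

#' Write a simulated cohort as a plain-text fixture
#'
#' Writes the counts TSV, the tag BED (name = tag id, score = MAPQ), the
#' sample metadata TSV (including the truth columns) and a truth TSV, in the
#' exact dialect [readTagTable()] reads back: re-reading reproduces the
#' matrices exactly.
#'
#' @param te a [TagExperiment-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeFixture <- function(te, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, c("counts.tsv", "tags.bed", "samples.tsv",
                              "truth.tsv"))
    cts <- data.frame(tag_id = rownames(te), tagCounts(te),
                      check.names = FALSE)
    write.table(cts, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    rr <- rowRanges(te)
    bed <- data.frame(chrom = as.character(seqnames(rr)),
                      start = GenomicRanges::start(rr) - 1L,
                      end = GenomicRanges::end(rr),
                      name = mcols(rr)$tag_id, score = mcols(rr)$mapq,
                      strand = "+")
    write.table(bed, paths[2], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    cd <- as.data.frame(colData(te))
    meta <- cd[, intersect(c("sample_id", "role", "control_cdh",
                             "copy_stratum", "ab10_type", "replicate_group"),
                           colnames(cd))]
    write.table(meta, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
    truthCols <- grep("^true_", colnames(cd), value = TRUE)
    write.table(cd[, c("sample_id", truthCols)], paths[4], sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(paths)
}
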