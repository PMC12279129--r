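#' End-to-end validation workflows on synthetic cohorts
#'
#' These functions reproduce, on simulated data with known truth, the three
#' performance checks that establish the detector works: perfect
#' presence/absence discrimination of a control panel, a near-complete
#' confident-call rate on an experimental cohort, and perfect held-out
#' accuracy of the Ab10-type random forest. Each simulates its own cohort at
#' the strong-signal preset, runs the full pipeline from raw counts, and
#' measures the result against the simulation truth.
#'
#' @name benchmarks
NULL

.simulatePanelTie <- function(seed, extraTruth = NULL,
                              param = simParam("strong"),
                              layout = simLayout()) {
    panel <- makeControlPanel()
    panel$true_type <- panel$ab10_type
    truth <- if (is.null(extraTruth)) panel
             else rbind(panel, extraTruth[, colnames(panel)])
    te <- simulateCohort(layout, truth, param, seed = seed)
    te <- suppressMessages(preprocessTags(te))
    rr <- rowRanges(te)
    grid <- binGrid(vapply(split(end(rr), as.character(seqnames(rr))),
                           max, 0))
    list(te = te, tie = tagIndex(te, grid), layout = layout)
}

.cdhRegions <- c(Ab10 = "Ab10", K10L2 = "K10L2", B = "chrB")

#' @describeIn benchmarks Simulates fresh control panels (one per seed) and
#'   runs [controlValidation()] for every CDH and copy stratum: 3 random
#'   control groups, k-means with 80% purity naming, 100 repetitions.
#'   Returns per-run accuracies and the percentage of all control-by-round
#'   assignments that matched truth.
#' @param seeds integer vector; one control panel is simulated per seed.
#' @export
benchmarkControlValidation <- function(seeds = 1:5) {
    rows <- list()
    for (seed in seeds) {
        sim <- .simulatePanelTie(seed)
        tie <- sim$tie
        cd <- colData(tie)
        neg <- colnames(tie)[cd$control_cdh %in% "none"]
        for (cdh in names(.cdhRegions)) {
            strata <- unique(cd$copy_stratum[cd$control_cdh %in% cdh])
            strata <- strata[!is.na(strata)]
            for (st in strata) {
                pos <- colnames(tie)[cd$control_cdh %in% cdh &
                                     cd$copy_stratum %in% st]
                bins <- selectDiagnosticBins(tie, pos, neg,
                                             region = .cdhRegions[[cdh]])
                v <- controlValidation(tie, bins, pos, neg, CDHParam(cdh),
                                       seed = seed)
                rows[[length(rows) + 1]] <- data.frame(
                    seed = seed, cdh = cdh, stratum = st,
                    n_controls = length(pos) + length(neg),
                    single_group = metadata(v)$single_group,
                    accuracy = metadata(v)$overall_accuracy)
            }
        }
    }
    runs <- do.call(rbind, rows)
    list(runs = runs,
         percent_correct = 100 * sum(runs$accuracy * runs$n_controls) /
             sum(runs$n_controls),
         n_controls = sum(runs$n_controls))
}

#' @describeIn benchmarks Simulates an experimental cohort (default 500
#'   samples: 6% Ab10 across the three types, 5% K10L2, 12% B with 1-8
#'   copies) together with the default control panel, runs the stepwise
#'   Ab10 -> K10L2 pipeline and the two-stage B pipeline at 125 consensus
#'   rounds, and reports the percentage of samples receiving an unambiguous
#'   call per CDH along with call accuracy against truth.
#' @param n experimental cohort size.
#' @param seed integer seed for simulation and clustering.
#' @param consensusRounds clustering rounds per sample (default 125).
#' @export
benchmarkConsensusCohort <- function(n = 500, seed = 1L,
                                     consensusRounds = 125L) {
    exper <- simulateExperimentalTruth(n = n, seed = seed)
    sim <- .simulatePanelTie(seed + 1L, extraTruth = exper)
    tie <- sim$tie
    res10 <- chr10Pipeline(
        tie, paramAb10 = CDHParam("Ab10", consensusRounds = consensusRounds),
        paramK10L2 = CDHParam("K10L2", consensusRounds = consensusRounds),
        seed = seed + 2L)
    resB <- bChromPipeline(
        tie, param = CDHParam("B", consensusRounds = consensusRounds),
        seed = seed + 3L)
    calls <- rbind(as.data.frame(res10)[, c("sample_id", "cdh", "call")],
                   as.data.frame(resB)[, c("sample_id", "cdh", "call")])
    truth <- as.data.frame(colData(tie))
    tr <- truth[match(calls$sample_id, truth$sample_id), ]
    wantPos <- ifelse(calls$cdh == "B", tr$true_b_copies > 0,
                      tr$true_cdh == calls$cdh)
    calls$correct <- calls$call == ifelse(wantPos, "positive", "negative")
    summary <- do.call(rbind, lapply(split(calls, calls$cdh), function(d)
        data.frame(cdh = d$cdh[1],
                   pct_unambiguous = 100 * mean(d$call != "ambiguous"),
                   accuracy = mean(d$correct[d$call != "ambiguous"]))))
    rownames(summary) <- NULL
    list(calls = calls, summary = summary,
         min_pct_unambiguous = min(summary$pct_unambiguous), n = n)
}

#' @describeIn benchmarks Simulates the Ab10 control panel (three types,
#'   both copy strata), trains the type random forest on a stratified 70%
#'   split of the typed controls and returns the held-out accuracy on the
#'   remaining 30%, as a percentage.
#' @export
benchmarkTypeAccuracy <- function(seed = 1L) {
    sim <- .simulatePanelTie(seed)
    tie <- sim$tie
    cd <- colData(tie)
    bins <- names(rowRanges(tie))[
        as.character(seqnames(rowRanges(tie))) == "Ab10"]
    ctl <- colnames(tie)[cd$control_cdh %in% "Ab10" & !is.na(cd$ab10_type)]
    sc <- scaledTagIndex(tie, samples = ctl, bins = bins)
    types <- setNames(colData(tie)[ctl, "ab10_type"], ctl)
    model <- trainAb10TypeModel(sc, types, seed = seed)
    list(model = model, percent_accuracy = 100 * model@heldOutAccuracy,
         n_controls = length(ctl), n_test = length(model@testSamples))
}
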