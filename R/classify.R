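#' Select CDH-diagnostic bins
#'
#' Diagnostic bins are the CDH-specific portions of the reference: bins whose
#' min/max-scaled tag index differs starkly between CDH-positive and
#' CDH-negative controls. A bin is selected when
#' `|mean(positive) - mean(negative)|` on the scaled index (scaling computed
#' over the given controls) exceeds `separationThreshold`. Shared homologous
#' regions, which light up in both classes, are thereby excluded. A
#' user-supplied set of intervals overrides the automatic selection.
#'
#' @param tie a [TagIndexExperiment-class].
#' @param posControls,negControls sample ids of CDH-positive / negative
#'   controls (at least 2 of each).
#' @param region optional seqnames restricting the candidate bins (e.g. the
#'   CDH's reference chromosome).
#' @param separationThreshold minimum scaled-index separation (default 0.5).
#' @param binsOverride optional `GRanges` (or bin ids) of known diagnostic
#'   intervals; when given, selection is skipped and bins overlapping these
#'   intervals are returned.
#' @return Character vector of diagnostic bin ids.
#' @export
selectDiagnosticBins <- function(tie, posControls, negControls, region = NULL,
                                 separationThreshold = 0.5,
                                 binsOverride = NULL) {
    if (!is.null(binsOverride)) {
        if (is(binsOverride, "GRanges")) {
            hits <- unique(S4Vectors::queryHits(
                findOverlaps(rowRanges(tie), binsOverride)))
            return(names(rowRanges(tie))[sort(hits)])
        }
        return(as.character(binsOverride))
    }
    if (length(posControls) < 2 || length(negControls) < 2)
        stop("need at least 2 positive and 2 negative controls")
    cand <- seq_len(nrow(tie))
    if (!is.null(region))
        cand <- which(as.character(seqnames(rowRanges(tie))) %in% region)
    sc <- scaledTagIndex(tie, samples = c(posControls, negControls),
                         bins = cand)
    sep <- abs(rowMeans(sc[, posControls, drop = FALSE]) -
               rowMeans(sc[, negControls, drop = FALSE]))
    hit <- sep > separationThreshold
    if (!any(hit))
        stop("no bin separates the control classes; best observed separation ",
             signif(max(sep), 3), " (threshold ", separationThreshold, ")")
    rownames(sc)[hit]
}

# Downsample the larger control class to within 20% of the smaller so that
# clustering sees roughly equal class sizes. Membership of the downsampled
# class is redrawn on every call; sizes are deterministic.
.balanceControls <- function(pos, neg) {
    nSmall <- min(length(pos), length(neg))
    cap <- ceiling(1.2 * nSmall)
    if (length(pos) > cap) pos <- sample(pos, cap)
    if (length(neg) > cap) neg <- sample(neg, cap)
    list(pos = pos, neg = neg)
}

.balancedControlCount <- function(pos, neg) {
    nSmall <- min(length(pos), length(neg))
    cap <- ceiling(1.2 * nSmall)
    min(length(pos), cap) + min(length(neg), cap)
}

# Name k-means clusters by control purity: a cluster is called positive
# (negative) only when >= purityThreshold of its *control* members are
# positive (negative); experimental spikes never count toward purity.
.nameClusters <- function(cluster, truth, k, purityThreshold) {
    vapply(seq_len(k), function(j) {
        ctl <- truth[names(cluster)[cluster == j]]
        ctl <- ctl[!is.na(ctl)]
        if (length(ctl) == 0) return(NA_character_)
        fpos <- mean(ctl == "positive")
        if (fpos >= purityThreshold) "positive"
        else if (1 - fpos >= purityThreshold) "negative"
        else NA_character_
    }, character(1))
}

# One control-anchored k-means batch: balanced controls + spiked
# experimentals, min/max scaled within the batch, k-means, cluster naming,
# control verification. On verification failure the batch is redrawn with a
# fresh random control balance, up to maxBatchRetries; exhaustion abandons
# the batch (experimentals uncalled this round).
.runBatch <- function(features, pos, neg, experimentals, param) {
    truth <- c(setNames(rep("positive", length(pos)), pos),
               setNames(rep("negative", length(neg)), neg))
    for (attempt in seq_len(param@maxBatchRetries)) {
        bal <- .balanceControls(pos, neg)
        batch <- c(bal$pos, bal$neg, experimentals)
        sc <- minMaxScale(features, batch)
        km <- tryCatch(
            kmeans(t(sc), centers = param@k, nstart = param@nstart),
            error = function(e) NULL)
        if (is.null(km)) next
        cl <- km$cluster
        nm <- .nameClusters(cl, truth, param@k, param@purityThreshold)
        ctl <- c(bal$pos, bal$neg)
        ok <- all(!is.na(nm[cl[ctl]]) & nm[cl[ctl]] == truth[ctl])
        if (ok)
            return(list(calls = setNames(nm[cl[experimentals]], experimentals),
                        attempts = attempt))
    }
    list(calls = setNames(rep(NA_character_, length(experimentals)),
                          experimentals),
         attempts = param@maxBatchRetries)
}

#' Consensus CDH calls for experimental samples
#'
#' The iterative control-anchored caller. Each round, the experimental
#' samples are randomly partitioned into batches no larger than
#' `spikeFraction` times the (class-balanced) control count; each batch is
#' clustered with the controls by k-means (k = 2) on the min/max-scaled
#' diagnostic bins, clusters are named by control purity, and batches whose
#' controls are not all correctly identified are re-randomized until they
#' are. After `consensusRounds` rounds each sample is called the majority
#' class if that class was assigned in at least `consensusThreshold` of its
#' completed rounds, and `"ambiguous"` otherwise. Samples clustered in fewer
#' than half the rounds (abandoned batches) are ambiguous by fiat.
#'
#' @param tie a [TagIndexExperiment-class].
#' @param bins diagnostic bin ids (see [selectDiagnosticBins()]).
#' @param posControls,negControls control sample ids (positives from a single
#'   copy stratum).
#' @param experimentals sample ids to call.
#' @param param a [CDHParam-class].
#' @param seed integer seed; fixed seed reproduces identical calls.
#' @return `DataFrame` with `sample_id`, `call` (positive / negative /
#'   ambiguous), `consensus_fraction` and `rounds_used`.
#' @export
consensusCalls <- function(tie, bins, posControls, negControls,
                           experimentals, param = CDHParam(), seed = 1L) {
    features <- assay(tie, "index")[bins, , drop = FALSE]
    nCtl <- .balancedControlCount(posControls, negControls)
    cap <- max(1L, floor(param@spikeFraction * nCtl))
    nRounds <- param@consensusRounds
    calls <- matrix(NA_character_, nRounds, length(experimentals),
                    dimnames = list(NULL, experimentals))
    set.seed(seed)
    roundSeeds <- sample.int(.Machine$integer.max - 1L, nRounds)
    for (r in seq_len(nRounds)) {
        set.seed(roundSeeds[r])
        perm <- sample(experimentals)
        grp <- split(perm, ceiling(seq_along(perm) / cap))
        for (g in grp) {
            res <- .runBatch(features, posControls, negControls, g, param)
            calls[r, g] <- res$calls[g]
        }
    }
    .aggregateConsensus(calls, experimentals, param)
}

.aggregateConsensus <- function(calls, experimentals, param) {
    done <- colSums(!is.na(calls))
    fpos <- ifelse(done > 0,
                   colSums(calls == "positive", na.rm = TRUE) / pmax(done, 1),
                   NA_real_)
    frac <- pmax(fpos, 1 - fpos)
    call <- ifelse(is.na(fpos), "ambiguous",
            ifelse(fpos >= param@consensusThreshold, "positive",
            ifelse(1 - fpos >= param@consensusThreshold, "negative",
                   "ambiguous")))
    lowCoverage <- done < nrow(calls) / 2
    call[lowCoverage] <- "ambiguous"
    call <- unname(call); frac <- unname(frac)
    DataFrame(sample_id = experimentals, call = call,
              consensus_fraction = unname(frac),
              rounds_used = unname(done),
              low_coverage = unname(lowCoverage))
}

#' Validate the caller on control samples alone
#'
#' Controls are split into `controlGroups` random groups (each containing
#' both classes; degenerate panels fall back to a single group), each group
#' is k-means clustered on the scaled diagnostic bins and clusters are named
#' by purity; each control's named cluster is compared with its truth. The
#' split is repeated `controlValidationRounds` times. The returned table
#' gives, per control, the fraction of rounds in which it was correctly
#' assigned; the overall accuracy (fraction of control-by-round assignments
#' that were correct) is in `metadata(x)$overall_accuracy`.
#'
#' @inheritParams consensusCalls
#' @return `DataFrame` with `sample_id`, `truth` and `accuracy`.
#' @export
controlValidation <- function(tie, bins, posControls, negControls,
                              param = CDHParam(), seed = 1L) {
    features <- assay(tie, "index")[bins, , drop = FALSE]
    ctl <- c(posControls, negControls)
    truth <- c(setNames(rep("positive", length(posControls)), posControls),
               setNames(rep("negative", length(negControls)), negControls))
    nGroups <- param@controlGroups
    # panels too small to guarantee >= 3 controls of each class per group
    # are clustered as a single group (the low-copy B chromosome case)
    singleGroup <- min(length(posControls), length(negControls)) <
        3L * nGroups
    nRounds <- param@controlValidationRounds
    correct <- setNames(integer(length(ctl)), ctl)
    set.seed(seed)
    roundSeeds <- sample.int(.Machine$integer.max - 1L, nRounds)
    for (r in seq_len(nRounds)) {
        set.seed(roundSeeds[r])
        if (singleGroup) {
            groups <- list(ctl)
        } else {
            for (redraw in 1:100) {
                perm <- sample(ctl)
                groups <- split(perm, rep_len(seq_len(nGroups), length(perm)))
                ok <- all(vapply(groups, function(g)
                    any(truth[g] == "positive") && any(truth[g] == "negative"),
                    logical(1)))
                if (ok) break
            }
        }
        for (g in groups) {
            sc <- minMaxScale(features, g)
            km <- tryCatch(
                kmeans(t(sc), centers = param@k, nstart = param@nstart),
                error = function(e) NULL)
            if (is.null(km)) next
            nm <- .nameClusters(km$cluster, truth, param@k,
                                param@purityThreshold)
            got <- nm[km$cluster[g]]
            hit <- !is.na(got) & got == truth[g]
            correct[g[hit]] <- correct[g[hit]] + 1L
        }
    }
    out <- DataFrame(sample_id = ctl, truth = unname(truth),
                     accuracy = unname(correct) / nRounds)
    metadata(out)$overall_accuracy <- mean(correct) / nRounds
    metadata(out)$single_group <- singleGroup
    out
}

# Controls of one CDH and copy stratum, plus the shared negatives.
.cdhControls <- function(tie, cdh, stratum = NULL) {
    cd <- colData(tie)
    ctl <- cd$role == "control" & !is.na(cd$control_cdh)
    pos <- ctl & cd$control_cdh == cdh
    if (!is.null(stratum))
        pos <- pos & !is.na(cd$copy_stratum) & cd$copy_stratum == stratum
    neg <- ctl & cd$control_cdh == "none"
    list(pos = colnames(tie)[pos], neg = colnames(tie)[neg])
}

#' Presence call for one CDH, combining copy strata
#'
#' High and low copy-number controls are analyzed separately (so clustering
#' reflects presence/absence, not copy number) and the per-stratum consensus
#' calls are combined: a sample is positive if any stratum calls it
#' positive, negative if every stratum calls it negative, and ambiguous
#' otherwise.
#'
#' @param tie a [TagIndexExperiment-class] (controls + experimentals).
#' @param cdh `"Ab10"`, `"K10L2"` or `"B"`.
#' @param region seqnames of the CDH's reference region (defaults to `cdh`).
#' @param experimentals sample ids to call; default all `role ==
#'   "experimental"` samples.
#' @param param a [CDHParam-class] (defaults chosen per `cdh`).
#' @param seed integer seed.
#' @param strata copy strata to run; default: the strata present among the
#'   CDH's controls.
#' @return A list with `combined` (DataFrame of final calls) and
#'   `per_stratum` (DataFrame of stratum-level calls).
#' @export
cdhConsensus <- function(tie, cdh, region = cdh, experimentals = NULL,
                         param = CDHParam(cdh), seed = 1L, strata = NULL) {
    cd <- colData(tie)
    if (is.null(experimentals))
        experimentals <- colnames(tie)[cd$role == "experimental"]
    if (is.null(strata)) {
        s <- cd$copy_stratum[cd$role == "control" & cd$control_cdh %in% cdh]
        strata <- unique(s[!is.na(s)])
        if (length(strata) == 0) strata <- list(NULL)
    }
    per <- list()
    set.seed(seed)
    strataSeeds <- sample.int(.Machine$integer.max - 1L, length(strata))
    for (i in seq_along(strata)) {
        st <- if (is.list(strata)) strata[[i]] else strata[i]
        ctl <- .cdhControls(tie, cdh, st)
        bins <- selectDiagnosticBins(tie, ctl$pos, ctl$neg, region = region,
                                     separationThreshold =
                                         param@separationThreshold)
        res <- consensusCalls(tie, bins, ctl$pos, ctl$neg, experimentals,
                              param, seed = strataSeeds[i])
        res$stratum <- if (is.null(st)) NA_character_ else st
        res$cdh <- cdh
        per[[i]] <- res
    }
    per <- do.call(rbind, per)
    combined <- .combineStrata(per, experimentals, cdh)
    list(combined = combined, per_stratum = per)
}

.combineStrata <- function(per, experimentals, cdh) {
    call <- frac <- setNames(rep(NA, length(experimentals)), experimentals)
    call <- setNames(rep("ambiguous", length(experimentals)), experimentals)
    frac <- setNames(rep(NA_real_, length(experimentals)), experimentals)
    for (s in experimentals) {
        rows <- per[per$sample_id == s, , drop = FALSE]
        if (any(rows$call == "positive")) {
            call[s] <- "positive"
            frac[s] <- max(rows$consensus_fraction[rows$call == "positive"])
        } else if (all(rows$call == "negative")) {
            call[s] <- "negative"
            frac[s] <- min(rows$consensus_fraction)
        } else {
            frac[s] <- max(rows$consensus_fraction, na.rm = TRUE)
        }
    }
    DataFrame(sample_id = experimentals, cdh = cdh, call = unname(call),
              consensus_fraction = unname(frac))
}

#' Stepwise chromosome-10 pipeline: Ab10 first, then K10L2
#'
#' The K10L2 detector cannot distinguish Ab10 from K10L2 (the two share
#' TR-1 knob homology), so the Ab10 pipeline runs first and only samples it
#' calls negative are forwarded to K10L2 detection. Ab10-positive samples
#' are recorded as K10L2-negative by exclusion and are never assigned K10L2;
#' Ab10-ambiguous samples are not forwarded and stay ambiguous for K10L2.
#'
#' @param tie a [TagIndexExperiment-class].
#' @param regions named character: reference region per CDH.
#' @param experimentals sample ids to call (default: all experimental).
#' @param paramAb10,paramK10L2 [CDHParam-class] per stage.
#' @param seed integer seed.
#' @return `DataFrame` of calls for both CDHs (one row per sample per CDH),
#'   with a `note` column tracing the stepwise logic.
#' @export
chr10Pipeline <- function(tie, regions = c(Ab10 = "Ab10", K10L2 = "K10L2"),
                          experimentals = NULL,
                          paramAb10 = CDHParam("Ab10"),
                          paramK10L2 = CDHParam("K10L2"), seed = 1L) {
    cd <- colData(tie)
    if (is.null(experimentals))
        experimentals <- colnames(tie)[cd$role == "experimental"]
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max - 1L, 2)
    ab10 <- cdhConsensus(tie, "Ab10", region = regions[["Ab10"]],
                         experimentals = experimentals, param = paramAb10,
                         seed = seeds[1])
    abCall <- setNames(ab10$combined$call, ab10$combined$sample_id)
    fwd <- names(abCall)[abCall == "negative"]
    k10call <- setNames(rep("ambiguous", length(experimentals)), experimentals)
    k10frac <- setNames(rep(NA_real_, length(experimentals)), experimentals)
    note <- setNames(rep("", length(experimentals)), experimentals)
    k10call[abCall == "positive"] <- "negative"
    note[abCall == "positive"] <- "excluded: Ab10-positive"
    note[abCall == "ambiguous"] <- "not forwarded: Ab10 ambiguous"
    if (length(fwd) > 0) {
        k10 <- cdhConsensus(tie, "K10L2", region = regions[["K10L2"]],
                            experimentals = fwd, param = paramK10L2,
                            seed = seeds[2])
        k10call[k10$combined$sample_id] <- k10$combined$call
        k10frac[k10$combined$sample_id] <- k10$combined$consensus_fraction
    }
    rbind(
        DataFrame(sample_id = ab10$combined$sample_id, cdh = "Ab10",
                  call = ab10$combined$call,
                  consensus_fraction = ab10$combined$consensus_fraction,
                  note = ""),
        DataFrame(sample_id = experimentals, cdh = "K10L2",
                  call = unname(k10call),
                  consensus_fraction = unname(k10frac),
                  note = unname(note)))
}

#' Two-stage B-chromosome pipeline
#'
#' High-copy B samples can form their own k-means cluster and derail a
#' single-pass caller, so detection runs in two stages: stage 1 uses the
#' high-copy controls to extract high-copy positives; all samples not called
#' positive there are re-run against the low-copy controls. A sample is
#' B-positive if either stage calls it positive; otherwise it takes the
#' stage-2 call. The spike fraction is 0.10 at both stages.
#'
#' @param tie a [TagIndexExperiment-class].
#' @param region seqnames of the B chromosome in the reference.
#' @param experimentals sample ids to call (default: all experimental).
#' @param param a [CDHParam-class] (B defaults).
#' @param seed integer seed.
#' @return `DataFrame` of final B calls with the deciding `stage`.
#' @export
bChromPipeline <- function(tie, region = "chrB", experimentals = NULL,
                           param = CDHParam("B"), seed = 1L) {
    cd <- colData(tie)
    if (is.null(experimentals))
        experimentals <- colnames(tie)[cd$role == "experimental"]
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max - 1L, 2)
    run1 <- cdhConsensus(tie, "B", region = region,
                         experimentals = experimentals, param = param,
                         seed = seeds[1], strata = "high")
    call1 <- setNames(run1$combined$call, run1$combined$sample_id)
    frac1 <- setNames(run1$combined$consensus_fraction,
                      run1$combined$sample_id)
    rest <- names(call1)[call1 != "positive"]
    call <- call1; frac <- frac1
    stage <- setNames(rep(1L, length(experimentals)), experimentals)
    if (length(rest) > 0) {
        run2 <- cdhConsensus(tie, "B", region = region, experimentals = rest,
                             param = param, seed = seeds[2], strata = "low")
        call[run2$combined$sample_id] <- run2$combined$call
        frac[run2$combined$sample_id] <- run2$combined$consensus_fraction
        stage[rest] <- 2L
    }
    DataFrame(sample_id = experimentals, cdh = "B",
              call = unname(call[experimentals]),
              consensus_fraction = unname(frac[experimentals]),
              stage = unname(stage[experimentals]))
}
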