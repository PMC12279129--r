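test_that("fixture files round-trip through readTagTable exactly", {
    te <- standardCohort()$raw
    dir <- tempfile("fix")
    writeFixture(te, dir)
    back <- readTagTable(file.path(dir, "counts.tsv"),
                         file.path(dir, "tags.bed"),
                         file.path(dir, "samples.tsv"))
    expect_identical(tagCounts(back), tagCounts(te))
    expect_identical(as.character(seqnames(rowRanges(back))),
                     as.character(seqnames(rowRanges(te))))
    expect_identical(start(rowRanges(back)), start(rowRanges(te)))
    expect_identical(tagMapq(back), tagMapq(te))
    expect_identical(unname(sampleRole(back)), unname(sampleRole(te)))
    unlink(dir, recursive = TRUE)
})

test_that("readTagTable validates inputs and drops coordinate-less tags", {
    dir <- tempfile("fix2")
    dir.create(dir)
    writeLines(c("tag_id\ta\tb", "t1\t5\t0", "t2\t2\t1", "t3\t0\t3"),
               file.path(dir, "counts.tsv"))
    # BED lacks t3
    writeLines(c("chr1\t0\t64\tt1\t60\t+", "chr1\t100\t164\tt2\t42\t+"),
               file.path(dir, "tags.bed"))
    writeLines(c("sample_id\trole", "a\texperimental", "b\texperimental"),
               file.path(dir, "samples.tsv"))
    expect_warning(
        te <- readTagTable(file.path(dir, "counts.tsv"),
                           file.path(dir, "tags.bed"),
                           file.path(dir, "samples.tsv")),
        "no coordinates")
    expect_equal(nrow(te), 2)
    expect_equal(unname(tagCounts(te)["t1", ]), c(5L, 0L))

    # metadata naming a sample absent from the counts is an error
    writeLines(c("sample_id\trole", "a\texperimental", "zz\texperimental"),
               file.path(dir, "samples.tsv"))
    expect_error(suppressWarnings(
        readTagTable(file.path(dir, "counts.tsv"),
                     file.path(dir, "tags.bed"),
                     file.path(dir, "samples.tsv"))), "absent|missing")

    # duplicate sample ids are an error
    writeLines(c("tag_id\ta\ta", "t1\t5\t0"), file.path(dir, "counts.tsv"))
    writeLines(c("sample_id\trole", "a\texperimental"),
               file.path(dir, "samples.tsv"))
    expect_error(readTagTable(file.path(dir, "counts.tsv"),
                              file.path(dir, "tags.bed"),
                              file.path(dir, "samples.tsv")), "duplicate")
    unlink(dir, recursive = TRUE)
})

test_that("technical replicates sum element-wise and conserve totals", {
    tags <- GRanges("chr1", IRanges(c(1, 101), width = 64),
                    tag_id = c("t1", "t2"), mapq = c(60L, 60L))
    counts <- matrix(c(1L, 3L, 7L,
                       2L, 0L, 4L), nrow = 2, byrow = TRUE,
                     dimnames = list(c("t1", "t2"), c("A1", "A2", "Bx")))
    meta <- data.frame(sample_id = c("A1", "A2", "Bx"),
                       role = "experimental",
                       replicate_group = c("A", "A", NA))
    te <- TagExperiment(counts, tags, meta)
    merged <- mergeReplicates(te)
    expect_equal(colnames(merged), c("A", "Bx"))
    expect_equal(unname(tagCounts(merged)[, "A"]), c(4L, 2L))
    expect_equal(unname(tagCounts(merged)[, "Bx"]), c(7L, 4L))
    # conservation of total reads per tag
    expect_equal(rowSums(tagCounts(merged)), rowSums(tagCounts(te)))
    # no replicate groups: identity
    meta2 <- meta; meta2$replicate_group <- NA
    te2 <- TagExperiment(counts, tags, meta2)
    expect_identical(tagCounts(mergeReplicates(te2)), tagCounts(te2))
})

test_that("four technical libraries per individual collapse to one column", {
    tags <- GRanges("chr1", IRanges(c(1, 101, 201), width = 64),
                    tag_id = paste0("t", 1:3), mapq = 60L)
    set.seed(9)
    counts <- matrix(rpois(3 * 8, 4), 3,
                     dimnames = list(paste0("t", 1:3),
                                     paste0("L", 1:8)))
    meta <- data.frame(sample_id = paste0("L", 1:8), role = "experimental",
                       replicate_group = rep(c("ind1", "ind2"), each = 4))
    merged <- mergeReplicates(TagExperiment(counts, tags, meta))
    expect_equal(ncol(merged), 2)
    expect_equal(unname(tagCounts(merged)[, "ind1"]),
                 unname(rowSums(counts[, 1:4])))
})

test_that("RPM normalization follows the per-million formula", {
    tags <- GRanges("chr1", IRanges(c(1, 101), width = 64),
                    tag_id = c("t1", "t2"), mapq = 60L)
    counts <- matrix(c(4L, 1999996L, 0L, 0L), 2,
                     dimnames = list(c("t1", "t2"), c("big", "empty")))
    meta <- data.frame(sample_id = c("big", "empty"), role = "experimental")
    te <- suppressMessages(rpmNormalize(TagExperiment(counts, tags, meta)))
    expect_equal(tagRPM(te)["t1", "big"], 2)          # 4 / 2e6 * 1e6
    expect_equal(unname(tagRPM(te)[, "empty"]), c(0, 0))
    # column sums are 1e6 for every nonzero sample
    rpm <- tagRPM(suppressMessages(rpmNormalize(standardCohort()$raw)))
    sums <- colSums(rpm)
    expect_true(all(abs(sums - 1e6) < 1e-6 * 1e6 | sums == 0))
})

test_that("blank cutoff is min blank missingness minus 0.001", {
    tags <- GRanges("chr1", IRanges(seq(1, by = 100, length.out = 1000),
                                    width = 64),
                    tag_id = sprintf("t%04d", 1:1000), mapq = 60L)
    counts <- matrix(0L, 1000, 3,
                     dimnames = list(sprintf("t%04d", 1:1000),
                                     c("b1", "b2", "s1")))
    counts[1:7, "b1"] <- 1L    # missingness 0.993
    counts[1:12, "b2"] <- 1L   # missingness 0.988
    counts[, "s1"] <- 2L
    meta <- data.frame(sample_id = c("b1", "b2", "s1"),
                       role = c("blank", "blank", "experimental"))
    te <- TagExperiment(counts, tags, meta)
    expect_equal(blankCutoff(te), 0.987)
    # single blank
    expect_equal(blankCutoff(te[, c("b1", "s1")]), 0.992)
    # no blanks: error unless a fallback cutoff is supplied
    noBlank <- te[, "s1", drop = FALSE]
    expect_error(blankCutoff(noBlank), "blank")
    expect_message(cut <- blankCutoff(noBlank, fallback = 0.95), "0.95")
    expect_equal(cut, 0.95)
})

test_that("sample filter is strict and tag filter keeps mapq == threshold", {
    te <- tinyTagExperiment()
    miss <- sampleMissingness(te)
    # s3 has 3/4 zero counts
    expect_equal(unname(miss["s3"]), 0.75)
    kept <- suppressMessages(filterSamples(te, 0.6))
    expect_false("s3" %in% colnames(kept))
    # boundary: missingness exactly equal to the cutoff is retained
    keptEq <- filterSamples(te, 0.75)
    expect_true("s3" %in% colnames(keptEq))
    # cutoff 1.0 removes nothing; all-removed errors
    expect_equal(ncol(filterSamples(te, 1.0)), 3)
    expect_error(filterSamples(te, -0.1), "all samples")

    # mapq 19 removed, mapq 20 retained at the default threshold
    tf <- filterTagsByMapq(te)
    expect_false("t3" %in% rownames(tf))
    expect_true("t4" %in% rownames(tf))
    expect_equal(nrow(filterTagsByMapq(te, 0)), 4)
    # idempotence of both filters
    expect_identical(tagCounts(filterTagsByMapq(tf)), tagCounts(tf))
    expect_identical(tagCounts(suppressMessages(filterSamples(kept, 0.6))),
                     tagCounts(kept))
})

test_that("filter report records every sample's fate", {
    te <- tinyTagExperiment()
    rep <- filterReport(te, 0.6)
    expect_equal(nrow(rep), 3)
    expect_equal(rep$status[rep$sample_id == "s3"], "removed")
    expect_equal(sum(rep$status == "kept"), 2)
})
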