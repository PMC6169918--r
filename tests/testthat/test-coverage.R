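writeTestSam <- function(path, records, chrom = "chrT", seqlen = 1000L) {
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", chrom, seqlen),
                 records), path)
}
samRec <- function(name, flag, pos, mapq, cigar = "50M", chrom = "chrT") {
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    qlen <- sum(vapply(ops[grepl("[MIS=X]$", ops)],
                       function(o) as.integer(sub(".$", "", o)), integer(1)))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            name, flag, chrom, pos, mapq, cigar, strrep("A", qlen))
}

test_that("filterAlignments drops duplicates and sub-threshold MAPQ, keeps the boundary", {
    p <- withr::local_tempfile(fileext = ".sam")
    writeTestSam(p, c(
        samRec("keep30", 0, 101, 30),
        samRec("drop29", 0, 101, 29),
        samRec("dup", 1024, 101, 60),
        samRec("secondary", 256, 101, 60),
        samRec("suppl", 2048, 101, 60),
        samRec("keep60", 16, 120, 60)))
    aln <- readSamAlignments(p)
    kept <- filterAlignments(aln, minMapq = 30)
    expect_equal(length(kept), 2L)
    att <- attr(kept, "attrition")
    expect_equal(unname(att["duplicate"]), 1L)
    expect_equal(unname(att["low_mapq"]), 1L)
    expect_equal(unname(att["secondary_supplementary"]), 2L)
})

test_that("depthTrack counts reference-consuming bases inside the region only", {
    gm <- twoExonModels()
    p <- withr::local_tempfile(fileext = ".sam")
    writeTestSam(p, c(
        samRec("inExon", 0, 111, 60),           # [111,160] inside exon 1
        samRec("straddle", 0, 181, 60),         # [181,230]: 20 in-region bases
        samRec("withDel", 0, 301, 60, "10M5D10M"),  # deletion not counted
        samRec("offGene", 0, 600, 60)))
    tr <- depthTrack(filterAlignments(readSamAlignments(p)), gm, "GENE")
    expect_s4_class(tr, "DepthTrack")
    expect_equal(length(tr), 150)
    d <- depths(tr)
    pos <- regionPositions(gm, "GENE", "exon")
    # brute-force oracle over plain match reads
    expected <- bruteDepth(c(111, 181), c(50, 50), pos)
    # deletion read: covers [301,310] and [316,325], skips the 5 deleted
    expected <- expected + as.numeric(pos %in% c(301:310, 316:325))
    expect_equal(d, expected)
    # total depth equals total aligned bases falling in the region
    expect_equal(sum(d), 50 + 20 + 20)
})

test_that("depth accounting matches read placement on random synthetic SAM", {
    gm <- GeneModelSet(list(G = gr("chrS1", c(1001, 1501), c(1300, 1700))))
    p <- withr::local_tempfile(fileext = ".sam")
    simulateSamFile(gm, "G", p, nReads = 150, readLength = 100,
                    dupFrac = 0.2, lowMapqFrac = 0.2, seed = 5L)
    aln <- readSamAlignments(p)
    kept <- filterAlignments(aln)
    tr <- depthTrack(kept, gm, "G")
    pos <- regionPositions(gm, "G", "exon")
    oracle <- bruteDepth(start(GenomicRanges::granges(kept)),
                         rep(100, length(kept)), pos)
    expect_equal(depths(tr), oracle)
    overlapsRegion <- vapply(start(kept), function(s)
        any(pos >= s & pos <= s + 99), logical(1))
    expect_equal(countRegionReads(kept, gm, "G"), sum(overlapsRegion))
})

test_that("average coverage and the sufficiency boundary behave as specified", {
    expect_equal(averageExonCoverage(DepthTrack("g", c(10, 20, 30, 40))), 25)
    expect_equal(averageExonCoverage(DepthTrack("g", rep(0, 5))), 0)
    th <- auditThresholds()
    expect_false(isSufficient(24.9, th))
    expect_true(isSufficient(25, th))
    expect_false(isSufficient(6.4, th))
    expect_true(isSufficient(100, th))
})

test_that("undercovered cohort rule is strictly greater than 75%", {
    th <- auditThresholds()
    expect_true(undercoveredCohort(rep(c(FALSE, TRUE), c(76, 24)), th))
    expect_false(undercoveredCohort(rep(c(FALSE, TRUE), c(75, 25)), th))
    expect_false(undercoveredCohort(rep(TRUE, 10), th))
    expect_error(undercoveredCohort(logical(0), th), "zero samples")
})

test_that("meanDepthProfile averages elementwise and checks alignment", {
    t1 <- DepthTrack("g", c(10, 30), sampleId = "a")
    t2 <- DepthTrack("g", c(40, 10), sampleId = "b")
    prof <- meanDepthProfile(list(t1, t2))
    expect_equal(depths(prof), c(25, 20))
    expect_true(is.na(sampleId(prof)))
    expect_equal(depths(meanDepthProfile(list(t1))), depths(t1))
    expect_error(meanDepthProfile(list(t1, DepthTrack("g", c(1, 2, 3)))),
                 "length mismatch")
    expect_error(meanDepthProfile(list(t1, DepthTrack("other", c(1, 2)))),
                 "one gene")
})

test_that("gene-level undercoverage status uses strict base rule and modes", {
    th <- auditThresholds()
    # fraction 0.45 -> incomplete
    prof <- c(rep(50, 45), rep(5, 55))
    call <- callUndercoveredGene(prof, th, geneSymbol = "g")
    expect_equal(call$qualifying_fraction, 0.45)
    expect_equal(call$status, "undercovered_incomplete")
    # no qualifying base -> absent
    expect_equal(callUndercoveredGene(rep(3, 100), th, "g")$status,
                 "undercovered_absent")
    # base at exactly 20 does not qualify
    call2 <- callUndercoveredGene(c(25, 20), th, "g")
    expect_equal(call2$qualifying_fraction, 0.5)
    expect_equal(call2$status, "undercovered_incomplete")
    # 80% exactly is covered
    expect_equal(callUndercoveredGene(rep(c(30, 10), c(80, 20)), th, "g")$status,
                 "covered")
})

test_that("per-exon calls partition the profile by the gene model", {
    gm <- twoExonModels()
    th <- auditThresholds()
    # exon 1 (100 bases) fully deep, exon 2 (50 bases) at zero
    prof <- DepthTrack("GENE", c(rep(100, 100), rep(0, 50)))
    ex <- callUndercoveredExons(prof, gm, th)
    expect_equal(nrow(ex), 2L)
    expect_equal(ex$undercovered, c(FALSE, TRUE))
    expect_false(attr(ex, "all_exons_undercovered"))

    allZero <- callUndercoveredExons(DepthTrack("GENE", rep(0, 150)), gm, th)
    expect_true(all(allZero$undercovered))
    expect_true(attr(allZero, "all_exons_undercovered"))

    # single-exon gene: exon flag equals gene-level verdict
    g1 <- GeneModelSet(list(S = gr("c1", 1, 100)))
    prof1 <- DepthTrack("S", rep(c(30, 5), c(70, 30)))
    geneCall <- callUndercoveredGene(prof1, th)
    exCall <- callUndercoveredExons(prof1, g1, th)
    expect_equal(exCall$undercovered, geneCall$status != "covered")
    expect_error(callUndercoveredExons(DepthTrack("GENE", 1:10), gm, th),
                 "does not match")
})

test_that("undercovered_absent genes have every exon flagged", {
    gm <- twoExonModels()
    th <- auditThresholds()
    prof <- DepthTrack("GENE", rep(0, 150))
    expect_equal(callUndercoveredGene(prof, th)$status, "undercovered_absent")
    expect_true(attr(callUndercoveredExons(prof, gm, th),
                     "all_exons_undercovered"))
})

test_that("meanDepthInLoci averages inside loci and rejects outside ones", {
    gm <- twoExonModels()
    d <- rep(60, 150)
    tr <- DepthTrack("GENE", d)
    expect_equal(unname(meanDepthInLoci(tr, gm, gr("chrT", 110, 120))), 60)
    # depths 5,10,15 over a 3-base locus at region offsets 10..12
    d2 <- rep(0, 150); d2[10:12] <- c(5, 10, 15)
    expect_equal(unname(meanDepthInLoci(DepthTrack("GENE", d2), gm,
                                        gr("chrT", 110, 112))), 10)
    expect_equal(unname(meanDepthInLoci(DepthTrack("GENE", rep(0, 150)), gm,
                                        gr("chrT", 305, 310))), 0)
    expect_error(meanDepthInLoci(tr, gm, gr("chrT", 250, 260)), "outside")
    expect_error(meanDepthInLoci(tr, gm, gr("chrX", 110, 120)), "chromosome")
})

test_that("depth TSVs round-trip and validate", {
    gm <- twoExonModels()
    tracks <- list(
        sampleA = list(GENE = DepthTrack("GENE", seq_len(150), "sampleA")),
        sampleB = list(GENE = DepthTrack("GENE", rep(7, 150), "sampleB")))
    p <- withr::local_tempfile(fileext = ".tsv")
    writeDepthTsv(tracks, gm, p)
    back <- readDepthTsv(p, gm)
    expect_equal(depths(back$sampleA$GENE), as.numeric(seq_len(150)))
    expect_equal(depths(back$sampleB$GENE), rep(7, 150))

    # sparse file: missing positions fill with zero, stray rows warn
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("chrom\tpos\ts1", "chrT\t101\t9", "chrT\t301\t4",
                 "chrT\t900\t5"), p2)
    expect_warning(tr2 <- readDepthTsv(p2, gm), "outside")
    d <- depths(tr2$s1$GENE)
    expect_equal(d[1], 9)
    expect_equal(d[101], 4)
    expect_equal(sum(d), 13)

    p3 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("chrom\tpos\ts1", "chrT\t101\t9", "chrT\t101\t4"), p3)
    expect_error(readDepthTsv(p3, gm), "duplicate")
})

test_that("summarizeGeneCoverage recomputes cohort summary statistics", {
    cov <- data.frame(read_count = c(5, 12, 2000, 800),
                      avg_exon_coverage = c(0.1, 0.5, 30, 3))
    s <- summarizeGeneCoverage(cov)
    expect_equal(s$n_samples, 4L)
    expect_equal(s$n_below_read_count, 3L)
    expect_equal(s$median_read_count, 406)
    expect_equal(s$max_avg_coverage, 30)
    expect_equal(s$n_sufficient, 1L)
})
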