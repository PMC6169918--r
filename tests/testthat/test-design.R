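test_that("coveredFraction measures base-level design overlap", {
    gm <- GeneModelSet(list(G = gr("c1", c(101, 301), c(200, 350))),
                       list(G = gr("c1", c(101, 301), c(200, 350))))
    full <- CaptureDesign("full", gr("c1", 1, 1000))
    none <- CaptureDesign("none", gr("c9", 1, 1000))
    part <- CaptureDesign("part", gr("c1", 151, 320))
    expect_equal(coveredFraction(gm, "G", full), 1.0)
    expect_equal(coveredFraction(gm, "G", none), 0)
    expect_equal(coveredFraction(gm, "G", part), 70 / 150)  # 50 + 20 bases

    nc <- GeneModelSet(list(N = gr("c1", 1, 100)))
    expect_error(coveredFraction(nc, "N", full, mode = "cds"), "empty region")

    # padding recovers flanking bases
    nearMiss <- CaptureDesign("k", gr("c1", 90, 100))  # touches exon at 101
    expect_equal(coveredFraction(gm, "G", nearMiss), 0)
    expect_gt(coveredFraction(gm, "G", nearMiss, pad = 10), 0)
})

test_that("coveredFraction matches per-base brute force on random pairs", {
    set.seed(47)
    for (i in 1:150) {
        ex <- reduce(randomIntervalSet(chroms = "c1"))
        gm <- GeneModelSet(stats::setNames(list(ex), "G"))
        d <- CaptureDesign("k", randomIntervalSet(chroms = c("c1", "c2")))
        expect_equal(coveredFraction(gm, "G", d),
                     bruteIntersectBases(ex, targets(d)) / sum(width(ex)))
    }
})

test_that("auditDesign classifies genes and reports cds-mode exclusions", {
    gm <- GeneModelSet(
        list(A = gr("c1", 101, 200), B = gr("c1", 501, 600),
             C = gr("c1", 901, 1000), NC = gr("c1", 1500, 1599)),
        list(A = gr("c1", 101, 200), B = gr("c1", 501, 600),
             C = gr("c1", 901, 1000)))
    design <- CaptureDesign("kit", gr("c1", c(101, 501), c(200, 550)))
    audit <- auditDesign(design, gm, mode = "exon")
    expect_equal(nrow(audit), 4L)
    st <- setNames(audit$status, audit$gene_symbol)
    expect_equal(unname(st[c("A", "B", "C")]),
                 c("covered", "undercovered_incomplete", "undercovered_absent"))
    s <- attr(audit, "summary")
    expect_equal(s$covered, 1L)          # only A; NC has zero overlap too
    expect_equal(s$undercovered_absent, 2L)

    cds <- auditDesign(design, gm, mode = "cds")
    expect_equal(nrow(cds), 3L)
    expect_equal(attr(cds, "skipped"), "NC")
    expect_equal(attr(cds, "summary")$n_skipped, 1L)

    # exactly 80% covered is covered
    gm80 <- GeneModelSet(list(E = gr("c1", 1, 100)))
    d80 <- CaptureDesign("k", gr("c1", 1, 80))
    expect_equal(auditDesign(d80, gm80)$status, "covered")
    d79 <- CaptureDesign("k", gr("c1", 1, 79))
    expect_equal(auditDesign(d79, gm80)$status, "undercovered_incomplete")
})

test_that("auditExons flags exons independently", {
    gm <- GeneModelSet(list(G = gr("c1", c(101, 301, 501),
                                   c(200, 400, 600))))
    design <- CaptureDesign("kit", gr("c1", c(101, 301), c(200, 375)))
    ex <- auditExons(design, gm, "G")
    expect_equal(ex$status,
                 c("covered", "undercovered_incomplete", "undercovered_absent"))
    expect_equal(ex$covered_fraction[2], 0.75)
    expect_false(attr(ex, "all_exons_undercovered"))
    noneD <- CaptureDesign("kit", gr("c9", 1, 10))
    expect_true(attr(auditExons(noneD, gm, "G"), "all_exons_undercovered"))
})

test_that("gene covered fraction is the exon-length-weighted mean of exon fractions", {
    set.seed(53)
    for (i in 1:30) {
        ex <- reduce(randomIntervalSet(chroms = "c1"))
        gm <- GeneModelSet(stats::setNames(list(ex), "G"))
        d <- CaptureDesign("k", randomIntervalSet(chroms = "c1"))
        exAudit <- auditExons(d, gm, "G")
        expect_equal(coveredFraction(gm, "G", d),
                     sum(exAudit$covered_fraction * exAudit$region_length) /
                         sum(exAudit$region_length))
    }
})

test_that("adding targets never decreases covered fractions", {
    set.seed(59)
    ex <- reduce(randomIntervalSet(chroms = "c1"))
    gm <- GeneModelSet(stats::setNames(list(ex), "G"))
    base <- randomIntervalSet(chroms = "c1")
    for (i in 1:20) {
        extra <- randomIntervalSet(chroms = "c1")
        f0 <- coveredFraction(gm, "G", CaptureDesign("k", base))
        f1 <- coveredFraction(gm, "G", CaptureDesign("k", c(base, extra)))
        expect_gte(f1, f0)
    }
})

test_that("crossrefGeneList subsets audits and reports missing symbols", {
    rows <- data.frame(gene_symbol = c("A", "B", "C"),
                       status = c("undercovered_absent",
                                  "undercovered_incomplete", "covered"),
                       stringsAsFactors = FALSE)
    xr <- crossrefGeneList(rows, c("A", "B", "C", "MISSING"))
    expect_equal(nrow(xr), 3L)
    counts <- attr(xr, "status_counts")
    expect_equal(as.integer(counts[c("covered", "undercovered_incomplete",
                                     "undercovered_absent")]),
                 c(1L, 1L, 1L))
    expect_equal(attr(xr, "not_found"), "MISSING")
    expect_equal(nrow(crossrefGeneList(rows, character())), 0L)
})

test_that("design audit agrees with a depth audit driven by the same design", {
    # the cross-module oracle: simulate depth from a design (high
    # on-target, zero off-target) and expect identical gene statuses
    cfg <- simulationConfig(nGenes = 12, geneLengthRange = c(300, 800),
                            exonsPerGeneRange = c(1, 3), nonCodingFrac = 0,
                            seed = 61L)
    gm <- makeGenome(cfg)
    md <- makeDesign(gm, "kit", absentFrac = 0.25, partialFrac = 0.25,
                     partialRange = c(0.3, 0.7), seed = 62L)
    designAudit <- auditDesign(md$design, gm)
    sim <- simulateCohortDepthSummary(gm, md$design, nSamples = 40,
                                      meanOn = 100, meanOff = 0, seed = 63L)
    depthStatus <- vapply(geneSymbols(gm), function(g)
        callUndercoveredGene(sim$meanProfile[[g]])$status, character(1))
    expect_equal(unname(depthStatus[designAudit$gene_symbol]),
                 designAudit$status)
})
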