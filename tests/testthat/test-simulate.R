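test_that("makeGenome is deterministic and respects its geometry bounds", {
    cfg <- simulationConfig(nGenes = 10, geneLengthRange = c(200, 400),
                            exonsPerGeneRange = c(1, 3), seed = 1L)
    g1 <- makeGenome(cfg)
    g2 <- makeGenome(cfg)
    expect_identical(as.list(exonRanges(g1)), as.list(exonRanges(g2)))
    lens <- vapply(geneSymbols(g1), function(g)
        regionLength(g1, g, "exon"), numeric(1))
    expect_true(all(lens >= 200 & lens <= 400))
    # genes do not overlap
    allEx <- unlist(exonRanges(g1))
    expect_true(isDisjoint(allEx))

    single <- makeGenome(simulationConfig(nGenes = 5,
                                          exonsPerGeneRange = c(1, 1),
                                          seed = 2L))
    expect_true(all(lengths(exonRanges(single)) == 1L))
})

test_that("makeDesign plants absent and partial genes as requested", {
    cfg <- simulationConfig(nGenes = 20, nonCodingFrac = 0, seed = 3L)
    gm <- makeGenome(cfg)
    md <- makeDesign(gm, "kit", absentFrac = 0.2, partialFrac = 0.2,
                     partialRange = c(0.3, 0.7), seed = 4L)
    expect_equal(length(md$truth$absent), 4L)
    expect_equal(nrow(md$truth$partial), 4L)
    # planted partial fractions are recovered by the design audit to
    # within one base of rounding
    for (i in seq_len(nrow(md$truth$partial))) {
        g <- md$truth$partial$gene_symbol[i]
        f <- coveredFraction(gm, g, md$design)
        expect_equal(f, md$truth$partial$planted_fraction[i],
                     tolerance = 1.5 / regionLength(gm, g, "exon"))
    }
    for (g in md$truth$absent)
        expect_equal(coveredFraction(gm, g, md$design), 0)

    allAbsent <- makeDesign(gm, "k0", absentFrac = 1, seed = 5L)
    expect_equal(length(targets(allAbsent$design)), 0L)
    clean <- makeDesign(gm, "k1", seed = 6L)
    expect_true(all(auditDesign(clean$design, gm)$status == "covered"))
})

test_that("simulateDepth draws per-base counts under the design", {
    cfg <- simulationConfig(nGenes = 4, nonCodingFrac = 0,
                            geneLengthRange = c(200, 300),
                            exonsPerGeneRange = c(1, 2), seed = 7L)
    gm <- makeGenome(cfg)
    md <- makeDesign(gm, "kit", absentFrac = 0.25, seed = 8L)
    tr1 <- simulateDepth(gm, md$design, nSamples = 3, meanOn = 100,
                         meanOff = 0, seed = 9L)
    tr2 <- simulateDepth(gm, md$design, nSamples = 3, meanOn = 100,
                         meanOff = 0, seed = 9L)
    expect_identical(lapply(tr1, lapply, depths),
                     lapply(tr2, lapply, depths))
    absent <- md$truth$absent[1]
    expect_true(all(depths(tr1$S001[[absent]]) == 0))
    prof <- meanDepthProfile(lapply(tr1, `[[`, absent))
    expect_equal(callUndercoveredGene(prof)$status, "undercovered_absent")
    # covered gene at meanOn=100 qualifies essentially everywhere
    covered <- setdiff(geneSymbols(gm), absent)[1]
    profC <- meanDepthProfile(lapply(tr1, `[[`, covered))
    expect_gte(callUndercoveredGene(profC)$qualifying_fraction, 0.99)
    expect_error(simulateDepth(gm, md$design, 2,
                               depthModel = "negative_binomial",
                               dispersion = -1),
                 "dispersion")
})

test_that("aggregated depth summary matches the per-base model distributionally", {
    cfg <- simulationConfig(nGenes = 2, nonCodingFrac = 0,
                            geneLengthRange = c(400, 500),
                            exonsPerGeneRange = c(1, 1), seed = 10L)
    gm <- makeGenome(cfg)
    design <- CaptureDesign("full", unlist(exonRanges(gm)))
    g <- geneSymbols(gm)[1]
    L <- regionLength(gm, g, "exon")
    # per-base route
    perBase <- simulateDepth(gm, design, nSamples = 200, meanOn = 50,
                             seed = 11L)
    avgPB <- vapply(perBase, function(s) mean(depths(s[[g]])), numeric(1))
    # aggregated route
    agg <- simulateCohortDepthSummary(gm, design, nSamples = 200,
                                      meanOn = 50, seed = 12L)
    avgAG <- agg$avgDepth[g, ]
    # both are means of L iid Poisson(50): same mean and variance
    expect_equal(mean(avgPB), mean(avgAG), tolerance = 0.02)
    expect_equal(stats::sd(avgPB), stats::sd(avgAG), tolerance = 0.25)
    expect_equal(mean(depths(agg$meanProfile[[g]])), 50, tolerance = 0.02)
})

test_that("simulateMaf censors calls where the kit starves coverage", {
    cfg <- smallStudyConfig(seed = 13L)
    gm <- makeGenome(cfg)
    designs <- list(
        biased = makeDesign(gm, "biased",
                            absentFrac = cfg$kitSpecs$biased$absentFrac,
                            partialFrac = cfg$kitSpecs$biased$partialFrac,
                            seed = 14L)$design,
        complete = makeDesign(gm, "complete", seed = 15L)$design)
    sim <- simulateMaf(gm, cfg, designs, seed = 16L)
    expect_equal(nrow(sim$roster), 180L)
    expect_true(all(sim$maf$Variant_Classification %in% nonsilentClasses))
    # censored genes have zero calls in the biased cohorts
    for (ch in c("C1", "C2", "C3"))
        for (g in sim$truth$censoredByCohort[[ch]])
            expect_equal(sum(sim$maf$cohort_id == ch & sim$maf$Hugo_Symbol == g),
                         0L)
    # coverage rows conserve samples: one row per sample x gene
    expect_equal(nrow(sim$coverage), 180L * 20L)
})

test_that("zero mutation rate yields an empty MAF but full rosters", {
    cfg <- smallStudyConfig(seed = 17L)
    cfg$mutationRate <- 0
    gm <- makeGenome(cfg)
    designs <- list(biased = makeDesign(gm, "biased", seed = 18L)$design,
                    complete = makeDesign(gm, "complete", seed = 19L)$design)
    sim <- simulateMaf(gm, cfg, designs, seed = 20L)
    expect_equal(nrow(sim$maf), 0L)
    expect_equal(nrow(sim$roster), 180L)
})

test_that("uncensored observed rates stay inside exact binomial bounds", {
    cfg <- simulationConfig(
        nGenes = 6, nonCodingFrac = 0, geneLengthRange = c(300, 600),
        exonsPerGeneRange = c(1, 2),
        cohorts = data.frame(cohort_id = "U1", n_samples = 500L,
                             kit_name = "complete"),
        kitSpecs = list(complete = list(absentFrac = 0, partialFrac = 0,
                                        partialRange = c(0.3, 0.7))),
        mutationRate = 0.10, censorRule = "none", seed = 21L)
    gm <- makeGenome(cfg)
    designs <- list(complete = makeDesign(gm, "complete", seed = 22L)$design)
    sim <- simulateMaf(gm, cfg, designs, seed = 23L)
    ci <- stats::qbinom(c(0.005, 0.995), 500, 0.10)
    for (g in geneSymbols(gm)) {
        k <- length(unique(sim$maf$Tumor_Sample_Barcode[sim$maf$Hugo_Symbol == g]))
        expect_gte(k, ci[1])
        expect_lte(k, ci[2])
    }
})

test_that("the emitted bundle is byte-identical across runs of one seed", {
    cfg <- smallStudyConfig(seed = 24L)
    b1 <- simulateStudy(cfg)
    b2 <- simulateStudy(cfg)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    p1 <- writeSimulation(b1, d1)
    p2 <- writeSimulation(b2, d2)
    expect_identical(names(p1), names(p2))
    for (nm in names(p1))
        expect_identical(unname(tools::md5sum(p1[[nm]])),
                         unname(tools::md5sum(p2[[nm]])),
                         label = paste("file", nm))
})

test_that("synthetic SAM emitter respects its duplicate and MAPQ mix", {
    gm <- GeneModelSet(list(G = gr("chrS1", 2001, 2600)))
    p <- withr::local_tempfile(fileext = ".sam")
    simulateSamFile(gm, "G", p, nReads = 300, dupFrac = 0.3,
                    lowMapqFrac = 0.2, seed = 25L)
    aln <- readSamAlignments(p)
    expect_equal(length(aln), 300L)
    kept <- filterAlignments(aln)
    att <- attr(kept, "attrition")
    expect_equal(length(kept) + sum(att), 300L)
    expect_gt(att[["duplicate"]], 0)
    expect_gt(att[["low_mapq"]], 0)
    expect_true(all(S4Vectors::mcols(kept)$mapq >= 30))
})
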