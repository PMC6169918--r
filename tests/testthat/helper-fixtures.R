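suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

gr <- function(chrom, starts, ends, strand = "*") {
    GRanges(chrom, IRanges(starts, ends), strand = strand)
}

# two-exon test gene: exons chrT:[101,200] and [301,350] (150 bases),
# CDS trims 20 bases of UTR on each side: [121,200] and [301,330]
twoExonModels <- function() {
    GeneModelSet(list(GENE = gr("chrT", c(101, 301), c(200, 350), "+")),
                 list(GENE = gr("chrT", c(121, 301), c(200, 330))))
}

# per-base membership oracle for interval intersection, independent of
# any IRanges set arithmetic
bruteIntersectBases <- function(a, b) {
    expand <- function(x) {
        ch <- as.character(seqnames(x))
        unlist(lapply(seq_along(x), function(i)
            paste0(ch[i], ":", seq(start(x)[i], end(x)[i]))))
    }
    length(intersect(unique(expand(a)), unique(expand(b))))
}

randomIntervalSet <- function(nMax = 8, posMax = 500, chroms = c("c1", "c2")) {
    n <- sample.int(nMax, 1)
    st <- sample.int(posMax, n, replace = TRUE)
    w <- sample.int(50, n, replace = TRUE)
    gr(sample(chroms, n, replace = TRUE), st, st + w - 1L)
}

# per-base depth oracle: count kept reads (pos, width) covering each
# region position, from first principles
bruteDepth <- function(readStarts, readWidths, positions) {
    vapply(positions, function(p)
        sum(readStarts <= p & p <= readStarts + readWidths - 1L), numeric(1))
}

mafRecords <- function(genes, samples,
                       classes = "Missense_Mutation") {
    data.frame(gene_symbol = genes,
               variant_classification = rep_len(classes, length(genes)),
               sample_id = samples, stringsAsFactors = FALSE)
}

# cohort table straight from counts: nMut of nTotal samples mutated in
# each listed gene
countCohort <- function(cohortId, nTotal, genes = character(),
                        nMut = integer()) {
    roster <- sprintf("%s_s%03d", cohortId, seq_len(nTotal))
    mutated <- lapply(nMut, function(k) roster[seq_len(k)])
    names(mutated) <- genes
    recs <- do.call(rbind, lapply(seq_along(genes), function(i)
        mafRecords(rep(genes[i], nMut[i]), mutated[[i]])))
    if (is.null(recs)) recs <- mafRecords(character(), character())
    buildCohortTable(recs, roster, cohortId)
}

# a small study for pipeline tests: 20 genes, 6 cohorts of 30 samples
smallStudyConfig <- function(seed = 7L) {
    simulationConfig(
        nGenes = 20, geneLengthRange = c(300, 900),
        exonsPerGeneRange = c(1, 4), nonCodingFrac = 0.1,
        cohorts = data.frame(cohort_id = paste0("C", 1:6),
                             n_samples = 30L,
                             kit_name = rep(c("biased", "complete"), each = 3),
                             stringsAsFactors = FALSE),
        kitSpecs = list(biased = list(absentFrac = 0.1, partialFrac = 0.1,
                                      partialRange = c(0.3, 0.7)),
                        complete = list(absentFrac = 0, partialFrac = 0,
                                        partialRange = c(0.3, 0.7))),
        mutationRate = 0.2, seed = seed)
}

# synthetic stand-in for a per-sample coverage table of one gene in a
# cohort where no sample reaches sufficiency: 441 samples, 425 with
# fewer than 1000 filtered reads, median read count 12, maximum average
# exon coverage 6.4 over a 21470-base exon region.  Deterministic.
syntheticStadLikeCoverage <- function() {
    exonLength <- 21470
    n <- 441
    reads <- integer(n)
    reads[1:221] <- round(seq(0, 12, length.out = 221))     # lower half
    reads[221] <- 12                                        # median sits at 12
    reads[222:425] <- round(seq(13, 950, length.out = 204)) # still below 1000
    reads[426:441] <- round(seq(1050, 1374, length.out = 16)) # the 16 above
    avg <- reads * 100 / exonLength          # 100-base reads, full overlap
    avg <- pmin(avg, 6.4)
    data.frame(sample_id = sprintf("STAD_s%03d", seq_len(n)),
               cohort_id = "STADlike", gene_symbol = "BIGGENE",
               read_count = reads, avg_exon_coverage = avg,
               stringsAsFactors = FALSE)
}
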