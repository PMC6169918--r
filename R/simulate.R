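## Synthetic cohorts with planted capture-kit bias.
##
## The generator emulates the causal structure under audit: capture kits
## with absent or partial probe coverage of some genes; per-base depth
## high on probe-covered bases and near zero off probe; true per-gene
## mutation rates; and observed mutation calls censored wherever a
## sample's average depth falls below the caller-sensitivity threshold.

.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Simulation configuration
#'
#' Assembles and validates the knobs of the synthetic study.  The
#' defaults describe the reference conditions used throughout the
#' package's validation: 100 genes, 6 cohorts of 200 samples — three on
#' a biased kit whose design omits probes for 5 genes and partially
#' tiles 5 more, three on a complete kit — on-target mean depth 100x
#' (the depth regime of large tumor sequencing programs), off-target
#' mean 0.5x, Poisson counts, a 10% true mutation rate, and step
#' censoring at the 25x average-depth sufficiency threshold.
#'
#' @param nGenes number of genes in the synthetic genome.
#' @param geneLengthRange total exon length range per gene (bases).
#' @param exonsPerGeneRange exon count range per gene.
#' @param nonCodingFrac fraction of genes given an empty CDS.
#' @param cohorts data.frame with columns \code{cohort_id},
#'   \code{n_samples}, \code{kit_name}.
#' @param kitSpecs named list (by kit) of lists with \code{absentFrac},
#'   \code{partialFrac}, \code{partialRange} (covered-fraction range
#'   for partially tiled genes).
#' @param depthModel \code{"poisson"} or \code{"negative_binomial"}.
#' @param meanOn,meanOff mean per-base depth on and off probe targets.
#' @param dispersion negative-binomial size parameter (ignored for
#'   Poisson).
#' @param mutationRate true per-sample mutation rate, recycled over
#'   genes (or a named per-gene vector).
#' @param censorRule \code{"step_at_min_avg_depth"} (a call is emitted
#'   only when the sample's average region depth reaches
#'   \code{thresholds@minAvgDepth}) or \code{"none"}.
#' @param thresholds an [AuditThresholds-class]; supplies the censoring
#'   threshold.
#' @param seed integer seed; every emitter is deterministic under it.
#' @return a validated configuration list (class
#'   \code{"SimulationConfig"}).
#' @export
simulationConfig <- function(nGenes = 100,
                             geneLengthRange = c(900, 3000),
                             exonsPerGeneRange = c(1, 8),
                             nonCodingFrac = 0.05,
                             cohorts = data.frame(
                                 cohort_id = paste0("COH", 1:6),
                                 n_samples = 200L,
                                 kit_name = rep(c("kitBiased", "kitComplete"),
                                                each = 3),
                                 stringsAsFactors = FALSE),
                             kitSpecs = list(
                                 kitBiased = list(absentFrac = 0.05,
                                                  partialFrac = 0.05,
                                                  partialRange = c(0.3, 0.7)),
                                 kitComplete = list(absentFrac = 0,
                                                    partialFrac = 0,
                                                    partialRange = c(0.3, 0.7))),
                             depthModel = c("poisson", "negative_binomial"),
                             meanOn = 100, meanOff = 0.5, dispersion = 5,
                             mutationRate = 0.10,
                             censorRule = c("step_at_min_avg_depth", "none"),
                             thresholds = auditThresholds(),
                             seed = 1L) {
    depthModel <- match.arg(depthModel)
    censorRule <- match.arg(censorRule)
    stopifnot(nGenes >= 1,
              length(geneLengthRange) == 2L,
              geneLengthRange[1] >= 50, diff(geneLengthRange) >= 0,
              length(exonsPerGeneRange) == 2L, exonsPerGeneRange[1] >= 1,
              nonCodingFrac >= 0, nonCodingFrac < 1,
              is.data.frame(cohorts),
              all(c("cohort_id", "n_samples", "kit_name") %in% names(cohorts)),
              all(cohorts$n_samples >= 1),
              all(cohorts$kit_name %in% names(kitSpecs)),
              meanOn > 0, meanOff >= 0, meanOn > meanOff,
              is(thresholds, "AuditThresholds"),
              all(mutationRate >= 0 & mutationRate <= 1))
    for (ks in kitSpecs) {
        stopifnot(ks$absentFrac >= 0, ks$partialFrac >= 0,
                  ks$absentFrac + ks$partialFrac <= 1,
                  length(ks$partialRange) == 2L,
                  ks$partialRange[1] > 0, ks$partialRange[2] < 1,
                  diff(ks$partialRange) >= 0)
    }
    if (depthModel == "negative_binomial" &&
        !(is.numeric(dispersion) && dispersion > 0))
        stop("negative_binomial depth model needs a positive dispersion")
    structure(list(nGenes = as.integer(nGenes),
                   geneLengthRange = geneLengthRange,
                   exonsPerGeneRange = as.integer(exonsPerGeneRange),
                   nonCodingFrac = nonCodingFrac,
                   cohorts = cohorts, kitSpecs = kitSpecs,
                   depthModel = depthModel, meanOn = meanOn,
                   meanOff = meanOff, dispersion = dispersion,
                   mutationRate = mutationRate, censorRule = censorRule,
                   thresholds = thresholds, seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Generate a synthetic genome of gene models
#'
#' Places non-overlapping multi-exon genes on a synthetic chromosome
#' with intron gaps, deriving a CDS that trims the outermost bases as
#' untranslated region; a configured fraction of genes is non-coding
#' (empty CDS).  Deterministic under the config seed.
#'
#' @param config a [simulationConfig()].
#' @param seed overrides \code{config$seed} when given.
#' @return a [GeneModelSet-class].
#' @export
makeGenome <- function(config = simulationConfig(), seed = config$seed) {
    .withSeed(seed, {
        n <- config$nGenes
        syms <- sprintf("G%03d", seq_len(n))
        exl <- vector("list", n)
        cdl <- vector("list", n)
        cursor <- 1000L
        nonCoding <- if (config$nonCodingFrac > 0)
            sample(seq_len(n), round(config$nonCodingFrac * n)) else integer()
        for (i in seq_len(n)) {
            L <- round(stats::runif(1, config$geneLengthRange[1],
                                    config$geneLengthRange[2]))
            k <- sample(seq(config$exonsPerGeneRange[1],
                            config$exonsPerGeneRange[2]), 1L)
            k <- min(k, L %/% 50L)  # keep every exon >= ~50 bases
            cuts <- sort(sample(seq_len(L - 1L), k - 1L))
            widths <- diff(c(0L, cuts, L))
            gaps <- round(stats::runif(k, 200, 1500))
            starts <- cursor + cumsum(c(0L, widths[-k] + gaps[-k]))
            ex <- GenomicRanges::GRanges("chrS1",
                                         IRanges::IRanges(starts,
                                                          width = widths),
                                         strand = sample(c("+", "-"), 1L))
            exl[[i]] <- ex
            if (i %in% nonCoding) {
                cdl[[i]] <- GenomicRanges::GRanges()
            } else {
                utr5 <- round(stats::runif(1, 0.02, 0.15) * L)
                utr3 <- round(stats::runif(1, 0.02, 0.15) * L)
                cdsIR <- IRanges::restrict(GenomicRanges::ranges(ex),
                                           start = min(start(ex)) + utr5,
                                           end = max(end(ex)) - utr3)
                cdl[[i]] <- GenomicRanges::GRanges("chrS1",
                                                   cdsIR[width(cdsIR) > 0])
            }
            cursor <- max(end(ex)) + round(stats::runif(1, 5000, 20000))
        }
        names(exl) <- syms
        names(cdl) <- syms
        GeneModelSet(exl, cdl)
    })
}

.regionAsRanges <- function(positions) {
    # ascending base positions -> merged GRanges on chrS-style chrom
    IRanges::reduce(IRanges::IRanges(positions, width = 1L))
}

#' Generate a capture design with planted probe gaps
#'
#' Absent genes get zero targets; partial genes are tiled over a
#' contiguous prefix of their exon bases amounting to a uniform-random
#' covered fraction within the configured range; all other genes are
#' fully tiled.  The planted truth travels with the design.
#'
#' @param models a [GeneModelSet-class].
#' @param kitName kit identifier.
#' @param absentFrac,partialFrac fractions of genes with absent /
#'   partial probe coverage.
#' @param partialRange covered-fraction range for partial genes.
#' @param seed integer seed.
#' @return list with \code{design} (a [CaptureDesign-class]) and
#'   \code{truth} (list: \code{absent} gene symbols, \code{partial}
#'   data.frame of \code{gene_symbol}, \code{planted_fraction}).
#' @export
makeDesign <- function(models, kitName, absentFrac = 0, partialFrac = 0,
                       partialRange = c(0.3, 0.7), seed = 1L) {
    stopifnot(is(models, "GeneModelSet"),
              absentFrac >= 0, partialFrac >= 0, absentFrac + partialFrac <= 1)
    .withSeed(seed, {
        genes <- geneSymbols(models)
        n <- length(genes)
        nAbs <- round(absentFrac * n)
        nPar <- round(partialFrac * n)
        pick <- sample(genes, nAbs + nPar)
        absent <- sort(utils::head(pick, nAbs))
        partial <- sort(utils::tail(pick, nPar))
        fracs <- stats::runif(length(partial), partialRange[1], partialRange[2])
        tgt <- list()
        for (g in setdiff(genes, absent)) {
            rr <- exonRanges(models, g)
            chrom <- as.character(seqnames(rr))[1L]
            if (g %in% partial) {
                f <- fracs[match(g, partial)]
                pos <- regionPositions(models, g, "exon")
                nCov <- max(1L, round(f * length(pos)))
                ir <- .regionAsRanges(pos[seq_len(nCov)])
                tgt[[g]] <- GenomicRanges::GRanges(chrom, ir)
            } else {
                tgt[[g]] <- granges(rr)
            }
        }
        design <- CaptureDesign(kitName,
                                if (length(tgt)) unlist(GenomicRanges::GRangesList(tgt),
                                                        use.names = FALSE)
                                else GenomicRanges::GRanges())
        list(design = design,
             truth = list(absent = absent,
                          partial = data.frame(gene_symbol = partial,
                                               planted_fraction = fracs,
                                               stringsAsFactors = FALSE)))
    })
}

.drawCounts <- function(n, mu, model, dispersion) {
    if (model == "poisson")
        stats::rpois(n, mu)
    else
        stats::rnbinom(n, size = dispersion, mu = mu)
}

.baseLambda <- function(models, gene, mode, design, meanOn, meanOff) {
    pos <- regionPositions(models, gene, mode)
    rr <- regionRanges(models, gene, mode)
    chrom <- as.character(seqnames(rr))[1L]
    tg <- targets(design)
    tgIR <- GenomicRanges::ranges(tg[as.character(seqnames(tg)) == chrom])
    # plain IRanges arithmetic: this runs once per gene x kit and the
    # GRanges-level equivalent is an order of magnitude slower
    hit <- IRanges::intersect(GenomicRanges::ranges(rr), tgIR)
    on <- logical(length(pos))
    for (i in seq_along(hit))   # pos is sorted: mark covered runs directly
        on[pos >= start(hit)[i] & pos <= end(hit)[i]] <- TRUE
    ifelse(on, meanOn, meanOff)
}

# per-kit per-gene base lambdas, computed once and shared across cohorts
.kitLambdas <- function(models, designs, genes, mode, meanOn, meanOff) {
    lapply(designs, function(d) {
        out <- lapply(genes, function(g)
            .baseLambda(models, g, mode, d, meanOn, meanOff))
        names(out) <- genes
        out
    })
}

#' Simulate per-sample per-base depth tracks
#'
#' Each region base draws an independent count with mean
#' \code{meanOn} when the base lies under a design target and
#' \code{meanOff} otherwise, independently across bases and samples.
#'
#' @param models a [GeneModelSet-class].
#' @param design a [CaptureDesign-class].
#' @param nSamples number of samples.
#' @param genes genes to simulate (default all).
#' @param mode region mode.
#' @param depthModel \code{"poisson"} or \code{"negative_binomial"}.
#' @param meanOn,meanOff,dispersion depth model parameters.
#' @param sampleIds sample identifiers (default \code{S001...}).
#' @param seed integer seed.
#' @return named list (by sample) of named lists (by gene) of
#'   [DepthTrack-class] objects, the layout [readDepthTsv()] produces.
#' @export
simulateDepth <- function(models, design, nSamples,
                          genes = geneSymbols(models),
                          mode = c("exon", "cds"),
                          depthModel = c("poisson", "negative_binomial"),
                          meanOn = 100, meanOff = 0.5, dispersion = 5,
                          sampleIds = sprintf("S%03d", seq_len(nSamples)),
                          seed = 1L) {
    mode <- match.arg(mode)
    depthModel <- match.arg(depthModel)
    stopifnot(meanOn > 0)
    if (depthModel == "negative_binomial" &&
        !(is.numeric(dispersion) && dispersion > 0))
        stop("negative_binomial depth model needs a positive dispersion")
    lambda <- lapply(genes, function(g)
        .baseLambda(models, g, mode, design, meanOn, meanOff))
    names(lambda) <- genes
    .withSeed(seed, {
        out <- lapply(sampleIds, function(sid) {
            tr <- lapply(genes, function(g)
                DepthTrack(g, .drawCounts(length(lambda[[g]]), lambda[[g]],
                                          depthModel, dispersion),
                           sampleId = sid, regionMode = mode))
            names(tr) <- genes
            tr
        })
        names(out) <- sampleIds
        out
    })
}

#' Simulate per-sample average depths and cross-sample mean profiles
#'
#' Cohort-scale counterpart of [simulateDepth()].  Per-base counts are
#' never materialized per sample; instead the sums the audit consumes
#' are drawn directly from their exact distributions (a sum of
#' independent Poisson variables is Poisson in the summed mean, and a
#' sum of same-dispersion negative binomials adds both mean and size),
#' so results follow the identical generative model at a fraction of
#' the cost.
#'
#' @inheritParams simulateDepth
#' @param .lambda internal: precomputed per-gene base-lambda list
#'   (bypasses recomputing design membership for every cohort).
#' @return list with \code{avgDepth} (genes x samples matrix of average
#'   region depths) and \code{meanProfile} (named list of
#'   [DepthTrack-class] cross-sample mean tracks).
#' @export
simulateCohortDepthSummary <- function(models, design, nSamples,
                                       genes = geneSymbols(models),
                                       mode = c("exon", "cds"),
                                       depthModel = c("poisson",
                                                      "negative_binomial"),
                                       meanOn = 100, meanOff = 0.5,
                                       dispersion = 5,
                                       sampleIds = sprintf("S%03d",
                                                           seq_len(nSamples)),
                                       seed = 1L, .lambda = NULL) {
    mode <- match.arg(mode)
    depthModel <- match.arg(depthModel)
    if (is.null(.lambda)) {
        .lambda <- lapply(genes, function(g)
            .baseLambda(models, g, mode, design, meanOn, meanOff))
        names(.lambda) <- genes
    }
    .withSeed(seed, {
        avg <- matrix(NA_real_, length(genes), nSamples,
                      dimnames = list(genes, sampleIds))
        prof <- vector("list", length(genes))
        names(prof) <- genes
        for (g in genes) {
            lam <- .lambda[[g]]
            L <- length(lam)
            nOn <- sum(lam == meanOn)
            nOff <- L - nOn
            # per-sample total depth over the region, one draw per sample
            totOn <- if (nOn) .drawCounts(nSamples, nOn * meanOn, depthModel,
                                          nOn * dispersion) else 0
            totOff <- if (nOff && meanOff > 0)
                .drawCounts(nSamples, nOff * meanOff, depthModel,
                            nOff * dispersion) else 0
            avg[g, ] <- (totOn + totOff) / L
            # per-base total across samples, one draw per base
            tot <- .drawCounts(L, nSamples * lam, depthModel,
                               nSamples * dispersion)
            prof[[g]] <- DepthTrack(g, tot / nSamples, regionMode = mode)
        }
        list(avgDepth = avg, meanProfile = prof)
    })
}

#' Simulate coverage-censored cohort MAF data
#'
#' Every sample mutates each gene independently with its true rate; the
#' call reaches the MAF only if the sample's simulated average region
#' depth clears the sufficiency threshold (step rule) or always
#' (\code{censorRule = "none"}).  Rosters include unmutated samples, and
#' emitted rows draw a uniform non-silent classification (classification
#' identity affects no audited statistic).
#'
#' @param models a [GeneModelSet-class].
#' @param config a [simulationConfig()] supplying cohorts, kit specs,
#'   the depth model, rates and the censor rule.
#' @param designs named list of [CaptureDesign-class] per kit (one per
#'   kit named in \code{config$cohorts}).
#' @param seed overrides \code{config$seed}.
#' @return list: \code{maf} (data.frame in MAF column layout),
#'   \code{roster}, \code{kits}, \code{coverage} (per sample x gene
#'   average depth rows with sufficiency flags), \code{truth}
#'   (per-cohort censored gene sets and true rates).
#' @export
simulateMaf <- function(models, config, designs, seed = config$seed) {
    stopifnot(is(models, "GeneModelSet"), inherits(config, "SimulationConfig"),
              all(config$cohorts$kit_name %in% names(designs)))
    genes <- geneSymbols(models)
    rates <- config$mutationRate
    if (is.null(names(rates)))
        rates <- stats::setNames(rep_len(rates, length(genes)), genes)
    th <- config$thresholds
    lambdas <- .kitLambdas(models, designs[unique(config$cohorts$kit_name)],
                           genes, "exon", config$meanOn, config$meanOff)
    expAvgByKit <- lapply(lambdas, function(ll)
        vapply(ll, mean, numeric(1)))
    .withSeed(seed, {
        mafRows <- list()
        rosterRows <- list()
        kitRows <- list()
        covRows <- list()
        censored <- list()
        for (i in seq_len(nrow(config$cohorts))) {
            ch <- config$cohorts$cohort_id[i]
            nS <- config$cohorts$n_samples[i]
            kit <- config$cohorts$kit_name[i]
            sids <- sprintf("%s_S%03d", ch, seq_len(nS))
            sim <- simulateCohortDepthSummary(
                models, designs[[kit]], nS, genes = genes, mode = "exon",
                depthModel = config$depthModel, meanOn = config$meanOn,
                meanOff = config$meanOff, dispersion = config$dispersion,
                sampleIds = sids,
                seed = sample.int(.Machine$integer.max, 1L),
                .lambda = lambdas[[kit]])
            avg <- sim$avgDepth
            suff <- avg >= th@minAvgDepth
            # expected average depth under the kit decides planted censoring
            censored[[ch]] <- genes[expAvgByKit[[kit]] < th@minAvgDepth]
            for (g in genes) {
                mut <- stats::runif(nS) < rates[[g]]
                emit <- mut & (config$censorRule == "none" | suff[g, ])
                if (any(emit)) {
                    cls <- sample(nonsilentClasses, sum(emit), replace = TRUE)
                    mafRows[[length(mafRows) + 1L]] <-
                        data.frame(Hugo_Symbol = g,
                                   Variant_Classification = cls,
                                   Tumor_Sample_Barcode = sids[emit],
                                   cohort_id = ch, stringsAsFactors = FALSE)
                }
            }
            rosterRows[[ch]] <- data.frame(sample_id = sids, cohort_id = ch,
                                           stringsAsFactors = FALSE)
            kitRows[[ch]] <- data.frame(sample_id = sids, cohort_id = ch,
                                        kit_name = kit, center = "SIM",
                                        stringsAsFactors = FALSE)
            covRows[[ch]] <- data.frame(
                sample_id = rep(colnames(avg), each = nrow(avg)),
                cohort_id = ch,
                kit_name = kit,
                gene_symbol = rep(rownames(avg), ncol(avg)),
                read_count = NA_real_,
                avg_exon_coverage = as.vector(avg),
                sufficient = as.vector(suff),
                stringsAsFactors = FALSE)
        }
        maf <- if (length(mafRows)) do.call(rbind, mafRows) else
            data.frame(Hugo_Symbol = character(),
                       Variant_Classification = character(),
                       Tumor_Sample_Barcode = character(),
                       cohort_id = character())
        list(maf = maf,
             roster = do.call(rbind, c(rosterRows, list(make.row.names = FALSE))),
             kits = do.call(rbind, c(kitRows, list(make.row.names = FALSE))),
             coverage = do.call(rbind, c(covRows, list(make.row.names = FALSE))),
             truth = list(trueRates = rates, censoredByCohort = censored))
    })
}

#' Run the full synthetic study
#'
#' Genome, kit designs, coverage and censored MAF in one call; the
#' returned bundle carries every planted truth needed to score recovery.
#'
#' @param config a [simulationConfig()].
#' @param seed overrides \code{config$seed}.
#' @return list: \code{config}, \code{models}, \code{designs} (named
#'   list of [CaptureDesign-class]), \code{designTruth} (per kit),
#'   \code{maf}, \code{roster}, \code{kits}, \code{coverage},
#'   \code{truth}.
#' @export
simulateStudy <- function(config = simulationConfig(), seed = config$seed) {
    .withSeed(seed, {
        genomeSeed <- sample.int(.Machine$integer.max, 1L)
        kitSeeds <- sample.int(.Machine$integer.max, length(config$kitSpecs))
        mafSeed <- sample.int(.Machine$integer.max, 1L)
        models <- makeGenome(config, seed = genomeSeed)
        designs <- list()
        designTruth <- list()
        for (j in seq_along(config$kitSpecs)) {
            kit <- names(config$kitSpecs)[j]
            ks <- config$kitSpecs[[kit]]
            md <- makeDesign(models, kit, absentFrac = ks$absentFrac,
                             partialFrac = ks$partialFrac,
                             partialRange = ks$partialRange,
                             seed = kitSeeds[j])
            designs[[kit]] <- md$design
            designTruth[[kit]] <- md$truth
        }
        sim <- simulateMaf(models, config, designs, seed = mafSeed)
        c(list(config = config, models = models, designs = designs,
               designTruth = designTruth), sim)
    })
}

#' Write a gene-model set as a genePred-style table
#'
#' Emits the dialect [readGeneModels()] reads (0-based half-open,
#' comma-terminated exon lists).
#'
#' @param models a [GeneModelSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    stopifnot(is(models, "GeneModelSet"))
    rows <- lapply(geneSymbols(models), function(g) {
        ex <- sort(exonRanges(models, g))
        cd <- cdsRanges(models, g)
        data.frame(gene_symbol = g,
                   chrom = as.character(seqnames(ex))[1L],
                   strand = as.character(strand(ex))[1L],
                   cdsStart = if (length(cd)) min(start(cd)) - 1L else 0L,
                   cdsEnd = if (length(cd)) max(end(cd)) else 0L,
                   exonStarts = paste0(paste(start(ex) - 1L, collapse = ","), ","),
                   exonEnds = paste0(paste(end(ex), collapse = ","), ","),
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a simulated study bundle to disk
#'
#' Emits the file set the pipeline stages read: one MAF, roster TSV,
#' kit TSV, one BED per kit design, the gene-model table, the
#' per-sample coverage TSV and a ground-truth JSON.  Byte-identical
#' across runs with the same bundle.
#'
#' @param bundle result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeSimulation <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(maf = file.path(dir, "cohorts.maf"),
               roster = file.path(dir, "roster.tsv"),
               kits = file.path(dir, "kits.tsv"),
               models = file.path(dir, "gene_models.tsv"),
               coverage = file.path(dir, "coverage.tsv"),
               truth = file.path(dir, "ground_truth.json"))
    utils::write.table(bundle$maf, paths["maf"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(bundle$roster, paths["roster"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$kits, paths["kits"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeGeneModels(bundle$models, paths["models"])
    utils::write.table(bundle$coverage, paths["coverage"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (kit in names(bundle$designs)) {
        p <- file.path(dir, paste0("design_", gsub("\\W+", "_", kit), ".bed"))
        writeBed(bundle$designs[[kit]], p)
        paths[paste0("design_", kit)] <- p
    }
    truth <- list(designTruth = bundle$designTruth,
                  censoredByCohort = bundle$truth$censoredByCohort,
                  trueRates = as.list(bundle$truth$trueRates))
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}

#' Emit a small synthetic SAM file over one gene
#'
#' Exercises the alignment-filtering and depth paths end to end:
#' fixed-length fully-matching reads placed uniformly over the gene
#' span, with configurable fractions of duplicate-flagged and
#' low-MAPQ reads.
#'
#' @param models a [GeneModelSet-class].
#' @param gene gene symbol.
#' @param path output SAM path.
#' @param nReads number of reads.
#' @param readLength read length (bases, CIGAR \code{<len>M}).
#' @param dupFrac fraction of reads flagged as duplicates.
#' @param lowMapqFrac fraction of reads given MAPQ below 30.
#' @param mapq MAPQ for passing reads.
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
simulateSamFile <- function(models, gene, path, nReads = 200,
                            readLength = 100, dupFrac = 0.1,
                            lowMapqFrac = 0.1, mapq = 60, seed = 1L) {
    rr <- sort(exonRanges(models, gene))
    chrom <- as.character(seqnames(rr))[1L]
    lo <- min(start(rr))
    hi <- max(end(rr))
    .withSeed(seed, {
        pos <- sample(seq(max(1L, lo - readLength + 1L), hi), nReads,
                      replace = TRUE)
        dup <- stats::runif(nReads) < dupFrac
        lowq <- stats::runif(nReads) < lowMapqFrac
        flags <- ifelse(dup, 1024L, 0L)
        mapqs <- ifelse(lowq, sample(0:29, nReads, replace = TRUE), mapq)
        seqlen <- hi + readLength + 1000L
        header <- c("@HD\tVN:1.6\tSO:coordinate",
                    sprintf("@SQ\tSN:%s\tLN:%d", chrom, seqlen))
        ord <- order(pos)
        recs <- sprintf("r%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                        seq_len(nReads), flags[ord], chrom, pos[ord],
                        mapqs[ord], readLength,
                        strrep("A", readLength))
        writeLines(c(header, recs), path)
    })
    invisible(path)
}
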