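#' Score planted-truth recovery of a simulated study
#'
#' Runs the audit pipeline in memory over a [simulateStudy()] bundle and
#' scores each stage against the planted ground truth: does the
#' mutational-absence screen recover exactly the censored genes (with no
#' false positives among fully probe-covered genes); are the censoring
#' cohorts called undercovered for every probe-absent gene; and does the
#' design audit assign every gene its planted status.
#'
#' @param bundle a [simulateStudy()] result.
#' @return list of per-stage results with logical \code{*Pass} flags and
#'   an overall \code{pass}.
#' @export
evaluateRecovery <- function(bundle) {
    cfg <- bundle$config
    th <- cfg$thresholds
    rosters <- split(bundle$roster$sample_id, bundle$roster$cohort_id)
    tables <- lapply(names(rosters), function(ch) {
        rec <- bundle$maf[bundle$maf$cohort_id == ch, , drop = FALSE]
        buildCohortTable(
            data.frame(gene_symbol = rec$Hugo_Symbol,
                       variant_classification = rec$Variant_Classification,
                       sample_id = rec$Tumor_Sample_Barcode,
                       stringsAsFactors = FALSE),
            rosters[[ch]], ch)
    })
    candidates <- screenCandidates(tables, minRate = th@minRate,
                                   minZeroCohorts = th@minZeroCohorts)

    censorCount <- table(unlist(bundle$truth$censoredByCohort))
    planted <- sort(names(censorCount)[censorCount >= th@minZeroCohorts])
    biasedGenes <- unique(unlist(lapply(bundle$designTruth, function(tr)
        c(tr$absent, tr$partial$gene_symbol))))
    fullyCovered <- setdiff(geneSymbols(bundle$models), biasedGenes)
    falsePositives <- intersect(candidates$gene_symbol, fullyCovered)
    screenPass <- setequal(candidates$gene_symbol, planted) &&
        length(falsePositives) == 0L

    # cohort-level undercoverage for probe-absent genes of each kit
    cohortChecks <- logical()
    for (i in seq_len(nrow(cfg$cohorts))) {
        ch <- cfg$cohorts$cohort_id[i]
        kit <- cfg$cohorts$kit_name[i]
        for (g in bundle$designTruth[[kit]]$absent) {
            sub <- bundle$coverage[bundle$coverage$cohort_id == ch &
                                       bundle$coverage$gene_symbol == g, ]
            cohortChecks[paste(ch, g)] <-
                undercoveredCohort(sub$sufficient, th)
        }
        # fully covered genes must never yield an undercovered cohort
        for (g in utils::head(fullyCovered, 3)) {
            sub <- bundle$coverage[bundle$coverage$cohort_id == ch &
                                       bundle$coverage$gene_symbol == g, ]
            cohortChecks[paste(ch, g, "covered")] <-
                !undercoveredCohort(sub$sufficient, th)
        }
    }
    cohortPass <- length(cohortChecks) > 0L && all(cohortChecks)

    designPass <- TRUE
    designStatus <- list()
    for (kit in names(bundle$designs)) {
        audit <- auditDesign(bundle$designs[[kit]], bundle$models,
                             mode = "exon", thresholds = th)
        st <- stats::setNames(audit$status, audit$gene_symbol)
        tr <- bundle$designTruth[[kit]]
        expected <- stats::setNames(rep("covered", length(st)), names(st))
        expected[tr$absent] <- "undercovered_absent"
        expected[tr$partial$gene_symbol[tr$partial$planted_fraction <
                                            th@qualifyingFrac]] <-
            "undercovered_incomplete"
        designStatus[[kit]] <- st
        designPass <- designPass && identical(unname(st), unname(expected[names(st)]))
    }

    list(candidates = candidates$gene_symbol, planted = planted,
         falsePositives = falsePositives, screenPass = screenPass,
         cohortChecks = cohortChecks, cohortPass = cohortPass,
         designStatus = designStatus, designPass = designPass,
         pass = screenPass && cohortPass && designPass)
}

#' Run repeated recovery trials over seeds
#'
#' @param seeds integer vector of simulation seeds.
#' @param config a [simulationConfig()]; its seed slot is replaced by
#'   each trial seed.
#' @return data.frame with one row per seed and the stage pass flags.
#' @export
recoveryTrials <- function(seeds, config = simulationConfig()) {
    rows <- lapply(seeds, function(s) {
        config$seed <- as.integer(s)
        res <- evaluateRecovery(simulateStudy(config))
        data.frame(seed = s, screen_pass = res$screenPass,
                   cohort_pass = res$cohortPass,
                   design_pass = res$designPass, pass = res$pass,
                   n_candidates = length(res$candidates),
                   n_false_positives = length(res$falsePositives))
    })
    .rbindRows(rows, data.frame(seed = integer(), screen_pass = logical(),
                                cohort_pass = logical(),
                                design_pass = logical(), pass = logical(),
                                n_candidates = integer(),
                                n_false_positives = integer()))
}
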