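## Pipeline orchestration: each stage reads declared inputs, writes
## TSV/JSON reports whose header comments record the thresholds and
## input digests that produced them.

.pkgVersion <- function() {
    as.character(utils::packageVersion("captureBias"))
}

.thresholdLine <- function(th) {
    sprintf(paste0("min_mapq=%g min_avg_depth=%g cohort_insufficiency_frac=%g ",
                   "base_depth_gt=%g qualifying_frac=%g min_rate=%g ",
                   "min_zero_cohorts=%g"),
            th@minMapq, th@minAvgDepth, th@cohortInsufficiencyFrac,
            th@baseDepthGt, th@qualifyingFrac, th@minRate, th@minZeroCohorts)
}

.writeReport <- function(df, path, thresholds, inputs = character()) {
    hdr <- c(sprintf("# captureBias %s", .pkgVersion()),
             sprintf("# thresholds: %s", .thresholdLine(thresholds)))
    inputs <- inputs[file.exists(inputs)]
    if (length(inputs)) {
        digests <- tools::md5sum(inputs)
        hdr <- c(hdr, sprintf("# input: %s md5=%s", names(digests), digests))
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.logStage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Read a pipeline run configuration
#'
#' A single declarative YAML file: a \code{paths} block (any of
#' \code{maf}, \code{roster}, \code{gene_models}, \code{coverage},
#' \code{depth_tsv}, \code{kit_table}, \code{designs} (named kit to BED
#' map), \code{msi_bed}, \code{genes_of_interest}), a
#' \code{thresholds} block of [auditThresholds()] overrides, an
#' \code{outdir}, and an optional \code{seed}.  Threshold keys use the
#' constructor's argument names.
#'
#' @param path YAML file path.
#' @return a run-config list (class \code{"RunConfig"}).
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("cannot read run config: ", path)
    raw <- yaml::read_yaml(path)
    runConfig(paths = raw$paths, thresholds = raw$thresholds,
              outdir = raw$outdir, seed = raw$seed, configDir = dirname(path))
}

#' Assemble a run configuration in code
#'
#' @param paths named list of input paths (see [readRunConfig()]).
#' @param thresholds named list of [auditThresholds()] overrides, or an
#'   [AuditThresholds-class] object.
#' @param outdir output directory.
#' @param seed integer seed for stages that draw random numbers.
#' @param configDir directory relative paths are resolved against.
#' @return a run-config list (class \code{"RunConfig"}).
#' @export
runConfig <- function(paths = list(), thresholds = list(), outdir = ".",
                      seed = 1L, configDir = ".") {
    if (is.null(thresholds)) thresholds <- list()
    th <- if (is(thresholds, "AuditThresholds")) thresholds
          else do.call(auditThresholds, thresholds)
    resolve <- function(p) {
        if (is.list(p)) return(lapply(p, resolve))
        ifelse(file.exists(p) | grepl("^/", p), p, file.path(configDir, p))
    }
    if (length(paths)) paths <- lapply(paths, resolve)
    structure(list(paths = paths, thresholds = th,
                   outdir = if (is.null(outdir)) "." else outdir,
                   seed = if (is.null(seed)) 1L else as.integer(seed)),
              class = "RunConfig")
}

.needPaths <- function(config, keys, stage) {
    for (k in keys) {
        p <- config$paths[[k]]
        if (is.null(p))
            stop("stage '", stage, "' needs config path '", k, "'")
        for (pp in unlist(p))
            if (!file.exists(pp))
                stop("stage '", stage, "' input does not exist: ", pp)
    }
    invisible(TRUE)
}

.readCohortTables <- function(mafPath, rosterPath) {
    rosters <- readRoster(rosterPath)
    mafFiles <- if (dir.exists(mafPath))
        list.files(mafPath, pattern = "\\.maf$", full.names = TRUE)
    else mafPath
    records <- do.call(rbind, lapply(mafFiles, readMaf))
    sampleCohort <- stats::setNames(
        rep(names(rosters), lengths(rosters)), unlist(rosters))
    unknown <- !(records$sample_id %in% names(sampleCohort))
    if (any(unknown)) {
        warning(sum(unknown),
                " MAF record(s) with samples in no roster were skipped")
        records <- records[!unknown, , drop = FALSE]
    }
    recCohort <- sampleCohort[records$sample_id]
    tables <- lapply(names(rosters), function(ch)
        buildCohortTable(records[recCohort == ch, , drop = FALSE],
                         rosters[[ch]], ch))
    names(tables) <- names(rosters)
    tables
}

#' Run the mutational-absence screen
#'
#' Reads MAF and roster inputs, builds per-cohort mutation tables and
#' writes the candidate genes whose cohort-specific absence of calls
#' passes the screen.
#'
#' @param config a run config (see [readRunConfig()] / [runConfig()])
#'   with paths \code{maf} (file or directory) and \code{roster}.
#' @return the candidate \code{data.frame}, invisibly; writes
#'   \code{candidates.tsv} under the config's outdir.
#' @export
runScreen <- function(config) {
    .needPaths(config, c("maf", "roster"), "screen")
    th <- config$thresholds
    tables <- .readCohortTables(config$paths$maf, config$paths$roster)
    cand <- screenCandidates(tables, minRate = th@minRate,
                             minZeroCohorts = th@minZeroCohorts)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- file.path(config$outdir, "candidates.tsv")
    .writeReport(cand, out, th,
                 inputs = c(unlist(config$paths$maf), config$paths$roster))
    .logStage("screen", "%d cohort(s), %d candidate gene(s) -> %s",
              length(tables), nrow(cand), out)
    invisible(cand)
}

.readCoverageTable <- function(path, thresholds) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    need <- c("sample_id", "cohort_id", "gene_symbol", "avg_exon_coverage")
    miss <- setdiff(need, names(dt))
    if (length(miss))
        stop("coverage table missing column(s): ", paste(miss, collapse = ", "))
    df <- as.data.frame(dt)
    if (!("read_count" %in% names(df))) df$read_count <- NA_real_
    df$sufficient <- isSufficient(df$avg_exon_coverage, thresholds)
    df
}

#' Run the coverage-sufficiency stage
#'
#' Builds the per-sample coverage table (from a precomputed coverage
#' TSV, or from a per-base depth TSV plus gene models) and the
#' gene-by-cohort status matrix.  Cohorts with at least one non-silent
#' call in a gene are marked \code{not_considered} when MAF and roster
#' inputs are available.
#'
#' @param config run config with either path \code{coverage} or paths
#'   \code{depth_tsv} + \code{gene_models}; \code{maf}/\code{roster}
#'   optionally supply the called-mutation mask.
#' @return list with \code{coverage} (per-sample rows) and
#'   \code{matrix} (status matrix), invisibly; writes
#'   \code{sample_coverage.tsv} and \code{status_matrix.tsv}.
#' @export
runCoverage <- function(config) {
    th <- config$thresholds
    inputs <- character()
    if (!is.null(config$paths$coverage)) {
        .needPaths(config, "coverage", "coverage")
        cov <- .readCoverageTable(config$paths$coverage, th)
        inputs <- config$paths$coverage
    } else {
        .needPaths(config, c("depth_tsv", "gene_models"), "coverage")
        models <- readGeneModels(config$paths$gene_models)
        tracks <- readDepthTsv(config$paths$depth_tsv, models)
        rows <- list()
        for (sid in names(tracks)) for (g in names(tracks[[sid]])) {
            avg <- averageExonCoverage(tracks[[sid]][[g]])
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = sid, cohort_id = NA_character_, gene_symbol = g,
                read_count = NA_real_, avg_exon_coverage = avg,
                sufficient = isSufficient(avg, th), stringsAsFactors = FALSE)
        }
        cov <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
        if (!is.null(config$paths$roster)) {
            rosters <- readRoster(config$paths$roster)
            sampleCohort <- stats::setNames(
                rep(names(rosters), lengths(rosters)), unlist(rosters))
            cov$cohort_id <- unname(sampleCohort[cov$sample_id])
        }
        inputs <- c(config$paths$depth_tsv, config$paths$gene_models)
    }
    if (!nrow(cov))
        stop("no coverage rows available for the coverage stage")
    tables <- NULL
    if (!is.null(config$paths$maf) && !is.null(config$paths$roster))
        tables <- .readCohortTables(config$paths$maf, config$paths$roster)
    mat <- statusMatrix(cov, tables)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    covOut <- file.path(config$outdir, "sample_coverage.tsv")
    .writeReport(cov, covOut, th, inputs = inputs)
    matDf <- data.frame(gene_symbol = rownames(mat), mat, check.names = FALSE,
                        stringsAsFactors = FALSE)
    matOut <- file.path(config$outdir, "status_matrix.tsv")
    .writeReport(matDf, matOut, th, inputs = inputs)
    .logStage("coverage", "%d sample x gene row(s), %d sufficient -> %s",
              nrow(cov), sum(cov$sufficient), covOut)
    invisible(list(coverage = cov, matrix = mat))
}

#' Run the capture-design audit
#'
#' Audits every configured design BED against the gene models in exon
#' and CDS mode, writes per-gene audit tables, per-exon rows for the
#' undercovered genes, and (when a gene list of interest is configured)
#' the cross-reference subset.
#'
#' @param config run config with paths \code{designs} (named kit to BED
#'   map) and \code{gene_models}; optionally \code{genes_of_interest}
#'   (one symbol per line).
#' @return named list per kit of exon-mode audit data.frames,
#'   invisibly; writes \code{design_audit_<kit>_{exon,cds}.tsv},
#'   \code{design_audit_<kit>_exon_level.tsv} and
#'   \code{design_audit_<kit>_crossref.tsv}.
#' @export
runDesignAudit <- function(config) {
    .needPaths(config, c("designs", "gene_models"), "design-audit")
    th <- config$thresholds
    models <- readGeneModels(config$paths$gene_models)
    goi <- NULL
    if (!is.null(config$paths$genes_of_interest)) {
        .needPaths(config, "genes_of_interest", "design-audit")
        goi <- readLines(config$paths$genes_of_interest)
        goi <- goi[nzchar(goi)]
    }
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- list()
    for (kit in names(config$paths$designs)) {
        bed <- config$paths$designs[[kit]]
        design <- readBed(bed, kitName = kit)
        safe <- gsub("\\W+", "_", kit)
        for (mode in c("exon", "cds")) {
            audit <- auditDesign(design, models, mode = mode, thresholds = th)
            s <- attr(audit, "summary")
            p <- file.path(config$outdir,
                           sprintf("design_audit_%s_%s.tsv", safe, mode))
            .writeReport(audit, p, th, inputs = c(bed, config$paths$gene_models))
            .logStage("design-audit",
                      "%s [%s]: %d audited (%d covered, %d incomplete, %d absent, %d skipped)",
                      kit, mode, s$n_audited, s$covered,
                      s$undercovered_incomplete, s$undercovered_absent,
                      s$n_skipped)
            if (mode == "exon") out[[kit]] <- audit
        }
        under <- out[[kit]]$gene_symbol[out[[kit]]$status != "covered"]
        exonRows <- .rbindRows(
            lapply(under, function(g)
                auditExons(design, models, g, mode = "exon", thresholds = th)),
            data.frame(gene_symbol = character()))
        .writeReport(exonRows,
                     file.path(config$outdir,
                               sprintf("design_audit_%s_exon_level.tsv", safe)),
                     th, inputs = bed)
        if (!is.null(goi)) {
            xr <- crossrefGeneList(out[[kit]], goi)
            .writeReport(xr,
                         file.path(config$outdir,
                                   sprintf("design_audit_%s_crossref.tsv", safe)),
                         th, inputs = bed)
        }
    }
    invisible(out)
}

#' Run the kit-attribution stage
#'
#' Joins per-sample coverage with kit metadata and writes the
#' kit-stratified insufficiency summary for every gene in the coverage
#' table.
#'
#' @param config run config with paths \code{coverage} and
#'   \code{kit_table}.
#' @return the summary \code{data.frame}, invisibly; writes
#'   \code{kit_summary.tsv}.
#' @export
runKits <- function(config) {
    .needPaths(config, c("coverage", "kit_table"), "kits")
    th <- config$thresholds
    cov <- .readCoverageTable(config$paths$coverage, th)
    kits <- readKitTable(config$paths$kit_table)
    ann <- joinKits(cov[, setdiff(names(cov), "kit_name")], kits)
    genes <- sort(unique(ann$gene_symbol))
    summ <- do.call(rbind, c(lapply(genes, function(g) kitSummary(ann, g)),
                             list(make.row.names = FALSE)))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- file.path(config$outdir, "kit_summary.tsv")
    .writeReport(summ, out, th,
                 inputs = c(config$paths$coverage, config$paths$kit_table))
    .logStage("kits", "%d gene(s) x %d strata row(s) -> %s",
              length(genes), nrow(summ), out)
    invisible(summ)
}

#' Run the locus-depth stage (MSI loci)
#'
#' Averages cross-sample depth over each configured locus to decide
#' whether absence of events there is interpretable.
#'
#' @param config run config with paths \code{msi_bed},
#'   \code{depth_tsv}, \code{gene_models}.
#' @return per-locus data.frame, invisibly; writes
#'   \code{msi_locus_depth.tsv}.
#' @export
runMsi <- function(config) {
    .needPaths(config, c("msi_bed", "depth_tsv", "gene_models"), "msi")
    th <- config$thresholds
    models <- readGeneModels(config$paths$gene_models)
    loci <- targets(readBed(config$paths$msi_bed, kitName = "msi"))
    tracks <- readDepthTsv(config$paths$depth_tsv, models)
    rows <- list()
    for (g in geneSymbols(models)) {
        rr <- regionRanges(models, g, "exon")
        inGene <- loci[IRanges::overlapsAny(loci, rr, ignore.strand = TRUE)]
        if (!length(inGene)) next
        prof <- meanDepthProfile(lapply(tracks, `[[`, g))
        md <- meanDepthInLoci(prof, models, inGene)
        rows[[g]] <- data.frame(gene_symbol = g,
                                chrom = as.character(seqnames(inGene)),
                                locus_start = start(inGene) - 1L,
                                locus_end = end(inGene),
                                mean_depth = unname(md),
                                stringsAsFactors = FALSE)
    }
    out <- .rbindRows(rows,
                      data.frame(gene_symbol = character(),
                                 chrom = character(),
                                 locus_start = numeric(),
                                 locus_end = numeric(),
                                 mean_depth = numeric()))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(config$outdir, "msi_locus_depth.tsv")
    .writeReport(out, p, th,
                 inputs = c(config$paths$msi_bed, config$paths$depth_tsv))
    .logStage("msi", "%d locus/loci -> %s", nrow(out), p)
    invisible(out)
}

#' Run the synthetic-data stage
#'
#' Generates the synthetic study at the config seed and writes the
#' bundle under \code{<outdir>/simulation}.
#'
#' @param config run config (\code{seed} is honored).
#' @param simConfig a [simulationConfig()]; defaults to the reference
#'   conditions with the run config's seed.
#' @return the bundle from [simulateStudy()], invisibly.
#' @export
runSimulate <- function(config, simConfig = simulationConfig(seed = config$seed)) {
    bundle <- simulateStudy(simConfig)
    paths <- writeSimulation(bundle, file.path(config$outdir, "simulation"))
    .logStage("simulate", "%d file(s) under %s", length(paths),
              file.path(config$outdir, "simulation"))
    invisible(bundle)
}

#' Run all configured stages in dependency order
#'
#' Screen, coverage, kit attribution, design audit and locus depth run
#' whenever their inputs are configured; a machine-readable
#' \code{summary.json} aggregates the stage counts.  Any stage failure
#' aborts with the stage name.
#'
#' @param config run config.
#' @return the summary list, invisibly.
#' @export
runAll <- function(config) {
    summary <- list(thresholds = .thresholdLine(config$thresholds))
    tryStage <- function(stage, enabled, fun) {
        if (!enabled) return(NULL)
        tryCatch(fun(), error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    p <- config$paths
    cand <- tryStage("screen", !is.null(p$maf) && !is.null(p$roster),
                     function() runScreen(config))
    if (!is.null(cand))
        summary$screen <- list(n_candidates = nrow(cand),
                               candidates = cand$gene_symbol)
    covRes <- tryStage("coverage",
                       !is.null(p$coverage) ||
                           (!is.null(p$depth_tsv) && !is.null(p$gene_models)),
                       function() runCoverage(config))
    if (!is.null(covRes))
        summary$coverage <- list(n_rows = nrow(covRes$coverage),
                                 n_sufficient = sum(covRes$coverage$sufficient))
    kitsRes <- tryStage("kits", !is.null(p$coverage) && !is.null(p$kit_table),
                        function() runKits(config))
    if (!is.null(kitsRes))
        summary$kits <- list(n_rows = nrow(kitsRes))
    audits <- tryStage("design-audit",
                       !is.null(p$designs) && !is.null(p$gene_models),
                       function() runDesignAudit(config))
    if (!is.null(audits))
        summary$design_audit <- lapply(audits, function(a)
            attr(a, "summary")[c("covered", "undercovered_incomplete",
                                 "undercovered_absent", "n_audited")])
    msiRes <- tryStage("msi",
                       !is.null(p$msi_bed) && !is.null(p$depth_tsv) &&
                           !is.null(p$gene_models),
                       function() runMsi(config))
    if (!is.null(msiRes))
        summary$msi <- list(n_loci = nrow(msiRes))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
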