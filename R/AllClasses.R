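#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList reduce intersect seqnames strand width start end granges
#' @importFrom IRanges IRanges Views
#' @importFrom S4Vectors mcols mcols<- Rle runValue queryHits subjectHits
NULL

.REGION_MODES <- c("exon", "cds")

#' Numeric thresholds governing every coverage-sufficiency rule
#'
#' All boundary decisions of the audit live in one object so that every
#' report can record exactly which rules produced it.  Defaults are the
#' values used throughout the TCGA-scale audit: reads below mapping
#' quality 30 are discarded; a sample covers a gene sufficiently when the
#' average depth over the gene's region is at least 25x; a cohort is
#' undercovered for a gene when strictly more than 75% of its samples are
#' insufficient; a region base "qualifies" when its cross-sample mean
#' depth is strictly greater than 20; a gene (or exon, or capture design)
#' is covered when at least 80% of its bases qualify.  The two screening
#' parameters (5% pooled mutation rate, at least 3 zero-call cohorts)
#' are carried here as well so a single object configures a whole run.
#'
#' @slot minMapq minimum mapping quality retained (reads strictly below
#'   are discarded).
#' @slot minAvgDepth x-fold average depth at or above which a sample's
#'   coverage of a gene is sufficient.
#' @slot cohortInsufficiencyFrac fraction of insufficient samples above
#'   which (strictly) a cohort is called undercovered.
#' @slot baseDepthGt depth a base's mean must strictly exceed to qualify.
#' @slot qualifyingFrac fraction of qualifying bases at or above which a
#'   gene/exon/design region is considered covered.
#' @slot minRate minimum pooled non-silent mutation rate over cohorts
#'   with at least one call for a gene to be a screening candidate.
#' @slot minZeroCohorts minimum number of zero-call cohorts for a gene
#'   to be a screening candidate.
#' @aliases AuditThresholds
#' @exportClass AuditThresholds
setClass("AuditThresholds", representation(
    minMapq = "numeric",
    minAvgDepth = "numeric",
    cohortInsufficiencyFrac = "numeric",
    baseDepthGt = "numeric",
    qualifyingFrac = "numeric",
    minRate = "numeric",
    minZeroCohorts = "numeric"
))

setValidity("AuditThresholds", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && is.finite(x)
    if (!one(object@minMapq) || object@minMapq < 0)
        msg <- c(msg, "minMapq must be a single non-negative number")
    if (!one(object@minAvgDepth) || object@minAvgDepth <= 0)
        msg <- c(msg, "minAvgDepth must be a single positive number")
    if (!one(object@baseDepthGt) || object@baseDepthGt <= 0)
        msg <- c(msg, "baseDepthGt must be a single positive number")
    for (s in c("cohortInsufficiencyFrac", "qualifyingFrac")) {
        v <- slot(object, s)
        if (!one(v) || v <= 0 || v >= 1)
            msg <- c(msg, sprintf("%s must lie in (0, 1)", s))
    }
    if (!one(object@minRate) || object@minRate <= 0 || object@minRate > 1)
        msg <- c(msg, "minRate must lie in (0, 1]")
    if (!one(object@minZeroCohorts) || object@minZeroCohorts < 1)
        msg <- c(msg, "minZeroCohorts must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct an [AuditThresholds-class] object
#'
#' @param minMapq,minAvgDepth,cohortInsufficiencyFrac,baseDepthGt,qualifyingFrac,minRate,minZeroCohorts
#'   see the class documentation for the rule each governs.
#' @return an \code{AuditThresholds} object.
#' @examples
#' auditThresholds()
#' auditThresholds(minAvgDepth = 30)
#' @export
auditThresholds <- function(minMapq = 30, minAvgDepth = 25,
                            cohortInsufficiencyFrac = 0.75,
                            baseDepthGt = 20, qualifyingFrac = 0.80,
                            minRate = 0.05, minZeroCohorts = 3) {
    new("AuditThresholds",
        minMapq = as.numeric(minMapq),
        minAvgDepth = as.numeric(minAvgDepth),
        cohortInsufficiencyFrac = as.numeric(cohortInsufficiencyFrac),
        baseDepthGt = as.numeric(baseDepthGt),
        qualifyingFrac = as.numeric(qualifyingFrac),
        minRate = as.numeric(minRate),
        minZeroCohorts = as.numeric(minZeroCohorts))
}

setMethod("show", "AuditThresholds", function(object) {
    cat("AuditThresholds\n")
    cat(sprintf("  read filter      : MAPQ >= %g, no duplicates/secondary/supplementary\n",
                object@minMapq))
    cat(sprintf("  sample sufficient: average region depth >= %gx\n", object@minAvgDepth))
    cat(sprintf("  cohort undercov. : > %g%% of samples insufficient\n",
                100 * object@cohortInsufficiencyFrac))
    cat(sprintf("  base qualifies   : mean depth > %g\n", object@baseDepthGt))
    cat(sprintf("  region covered   : >= %g%% of bases qualify\n",
                100 * object@qualifyingFrac))
    cat(sprintf("  screen           : pooled rate >= %g, zero-call cohorts >= %g\n",
                object@minRate, object@minZeroCohorts))
})

#' A capture kit's merged target intervals
#'
#' Wraps the target regions of a whole-exome capture design (the probe
#' footprint a manufacturer ships as a BED file) as an unstranded,
#' merged \code{GRanges}: targets never overlap nor touch, so base-level
#' overlap arithmetic against gene models is unambiguous.
#'
#' @slot kitName kit identifier, e.g. \code{"SeqCap EZ HGSC VCRome"}.
#' @slot targets merged \code{GRanges} of target intervals.
#' @aliases CaptureDesign
#' @exportClass CaptureDesign
setClass("CaptureDesign", representation(
    kitName = "character",
    targets = "GRanges"
))

setValidity("CaptureDesign", function(object) {
    msg <- character()
    if (length(object@kitName) != 1L || is.na(object@kitName) ||
        !nzchar(object@kitName))
        msg <- c(msg, "kitName must be a single non-empty string")
    red <- GenomicRanges::reduce(object@targets, ignore.strand = TRUE)
    if (length(red) != length(object@targets) ||
        (length(red) && !identical(unname(GenomicRanges::start(red)),
                                   unname(GenomicRanges::start(object@targets)))))
        msg <- c(msg, "targets must be merged (sorted, no overlapping or touching intervals)")
    if (length(msg)) msg else TRUE
})

#' Construct a [CaptureDesign-class]
#'
#' Input targets are merged (overlapping or touching intervals are
#' coalesced) and strand is dropped; depth and overlap arithmetic are
#' strand-agnostic.
#'
#' @param kitName kit identifier.
#' @param targets a \code{GRanges} of target intervals (any state).
#' @return a \code{CaptureDesign}.
#' @export
CaptureDesign <- function(kitName, targets = GenomicRanges::GRanges()) {
    targets <- GenomicRanges::reduce(granges(targets), ignore.strand = TRUE)
    GenomicRanges::strand(targets) <- "*"
    new("CaptureDesign", kitName = as.character(kitName), targets = targets)
}

setMethod("show", "CaptureDesign", function(object) {
    cat("CaptureDesign:", object@kitName, "\n")
    cat(sprintf("  %d merged targets on %d chromosome(s), %d bases\n",
                length(object@targets),
                length(unique(as.character(seqnames(object@targets)))),
                sum(width(object@targets))))
})

#' A set of canonical gene models (exons and CDS per gene)
#'
#' One model per gene symbol: the canonical transcript's exon intervals
#' and the protein-coding subset (CDS).  Exons are stored merged and
#' sorted; every CDS base lies within an exon; non-coding genes carry an
#' empty CDS.  Strand is recorded on the exon ranges but ignored by all
#' coverage and overlap arithmetic.
#'
#' @slot exons named \code{GRangesList}, one element per gene symbol.
#' @slot cds named \code{GRangesList}, parallel to \code{exons}.
#' @aliases GeneModelSet
#' @exportClass GeneModelSet
setClass("GeneModelSet", representation(
    exons = "GRangesList",
    cds = "GRangesList"
))

setValidity("GeneModelSet", function(object) {
    msg <- character()
    nm <- names(object@exons)
    if (is.null(nm) || anyNA(nm) || !all(nzchar(nm)))
        msg <- c(msg, "exons must be named by gene symbol")
    else if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate gene symbol(s): %s",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (!identical(names(object@cds), nm))
        msg <- c(msg, "cds must carry the same names as exons")
    if (!length(msg)) {
        exx <- object@exons
        if (any(lengths(exx) == 0L))
            msg <- c(msg, "every gene needs at least one exon")
        nchrom <- lengths(unique(seqnames(exx)))
        if (any(nchrom > 1L))
            msg <- c(msg, "a gene's exons must lie on one chromosome")
        # CDS containment: cds bases not inside exons are a model defect
        stray <- sum(width(GenomicRanges::setdiff(unlist(object@cds),
                                                  unlist(exx),
                                                  ignore.strand = TRUE)))
        if (stray > 0)
            msg <- c(msg, "CDS intervals must lie within exons")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a [GeneModelSet-class]
#'
#' @param exons named \code{GRangesList} (or named list of \code{GRanges})
#'   of exon intervals per gene; merged per gene on construction.
#' @param cds like \code{exons} for CDS intervals; genes absent from
#'   \code{cds} get an empty CDS.
#' @return a \code{GeneModelSet}.
#' @export
GeneModelSet <- function(exons, cds = NULL) {
    if (!is(exons, "GRangesList"))
        exons <- GenomicRanges::GRangesList(exons)
    exons <- GenomicRanges::reduce(exons)
    empty <- GenomicRanges::GRangesList(rep(list(GenomicRanges::GRanges()),
                                            length(exons)))
    names(empty) <- names(exons)
    if (is.null(cds)) {
        cds <- empty
    } else {
        if (!is(cds, "GRangesList"))
            cds <- GenomicRanges::GRangesList(cds)
        cds <- GenomicRanges::reduce(cds)
        full <- empty
        keep <- intersect(names(cds), names(full))
        full[keep] <- cds[keep]
        cds <- full
    }
    new("GeneModelSet", exons = exons, cds = cds)
}

setMethod("show", "GeneModelSet", function(object) {
    n <- length(object@exons)
    cat(sprintf("GeneModelSet with %d gene(s)\n", n))
    coding <- sum(lengths(object@cds) > 0L)
    cat(sprintf("  coding: %d, non-coding: %d\n", coding, n - coding))
    if (n) {
        shown <- utils::head(names(object@exons), 5L)
        cat("  genes:", paste(shown, collapse = ", "),
            if (n > 5L) "..." else "", "\n")
    }
})

setMethod("length", "GeneModelSet", function(x) length(x@exons))

#' Per-base depth over a gene's region for one sample (or a mean track)
#'
#' Depth values are ordered by chromosomal coordinate over the
#' concatenated region bases of the gene in the chosen mode
#' (\code{"exon"} or \code{"cds"}); the vector length equals the total
#' region length.
#'
#' @slot geneSymbol gene the track belongs to.
#' @slot sampleId sample identifier, or \code{NA} for an aggregate track.
#' @slot regionMode \code{"exon"} or \code{"cds"}.
#' @slot depths non-negative depth per region base.
#' @aliases DepthTrack
#' @exportClass DepthTrack
setClass("DepthTrack", representation(
    geneSymbol = "character",
    sampleId = "character",
    regionMode = "character",
    depths = "numeric"
))

setValidity("DepthTrack", function(object) {
    msg <- character()
    if (length(object@geneSymbol) != 1L || !nzchar(object@geneSymbol))
        msg <- c(msg, "geneSymbol must be a single non-empty string")
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be length 1 (possibly NA)")
    if (!(length(object@regionMode) == 1L && object@regionMode %in% .REGION_MODES))
        msg <- c(msg, "regionMode must be 'exon' or 'cds'")
    if (length(object@depths) == 0L)
        msg <- c(msg, "depths must be non-empty")
    if (anyNA(object@depths) || any(object@depths < 0))
        msg <- c(msg, "depths must be non-negative and non-missing")
    if (length(msg)) msg else TRUE
})

#' Construct a [DepthTrack-class]
#' @param geneSymbol gene symbol.
#' @param depths numeric depth per region base, coordinate order.
#' @param sampleId sample identifier (\code{NA} for aggregates).
#' @param regionMode \code{"exon"} or \code{"cds"}.
#' @return a \code{DepthTrack}.
#' @export
DepthTrack <- function(geneSymbol, depths, sampleId = NA_character_,
                       regionMode = "exon") {
    new("DepthTrack", geneSymbol = as.character(geneSymbol),
        sampleId = as.character(sampleId),
        regionMode = match.arg(regionMode, .REGION_MODES),
        depths = as.numeric(depths))
}

setMethod("show", "DepthTrack", function(object) {
    cat(sprintf("DepthTrack: %s [%s]%s, %d bases, mean depth %.2f\n",
                object@geneSymbol, object@regionMode,
                if (is.na(object@sampleId)) "" else paste0(" sample ", object@sampleId),
                length(object@depths), mean(object@depths)))
})

setMethod("length", "DepthTrack", function(x) length(x@depths))

#' Per-cohort mutation-call table
#'
#' For one cohort: the full sample roster (denominator, including samples
#' with no calls at all) and, per gene, the set of samples carrying at
#' least one non-silent call.
#'
#' @slot cohortId cohort identifier (e.g. a TCGA tumor-type code).
#' @slot roster character vector of unique sample ids.
#' @slot mutated named list; per gene symbol, the subset of roster
#'   samples with a non-silent call.
#' @aliases CohortMutationTable
#' @exportClass CohortMutationTable
setClass("CohortMutationTable", representation(
    cohortId = "character",
    roster = "character",
    mutated = "list"
))

setValidity("CohortMutationTable", function(object) {
    msg <- character()
    if (length(object@cohortId) != 1L || !nzchar(object@cohortId))
        msg <- c(msg, "cohortId must be a single non-empty string")
    if (length(object@roster) < 1L)
        msg <- c(msg, "roster must contain at least one sample")
    if (anyDuplicated(object@roster))
        msg <- c(msg, "roster samples must be unique")
    if (length(object@mutated)) {
        if (is.null(names(object@mutated)) || !all(nzchar(names(object@mutated))))
            msg <- c(msg, "mutated must be named by gene symbol")
        bad <- vapply(object@mutated,
                      function(s) !all(s %in% object@roster), logical(1))
        if (any(bad))
            msg <- c(msg, sprintf("mutated samples outside roster for gene(s): %s",
                                  paste(names(object@mutated)[bad], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CohortMutationTable", function(object) {
    cat(sprintf("CohortMutationTable: %s (%d samples, %d mutated gene(s))\n",
                object@cohortId, length(object@roster), length(object@mutated)))
})
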