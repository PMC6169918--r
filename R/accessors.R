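#' Accessors for the audit's core classes
#'
#' Slot access goes through these generics; code outside the package
#' should never reach into slots directly.
#'
#' @param x the object.
#' @param gene a gene symbol present in the set.
#' @param mode region mode, \code{"exon"} or \code{"cds"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kitName", function(x) standardGeneric("kitName"))
#' @rdname accessors
#' @export
setMethod("kitName", "CaptureDesign", function(x) x@kitName)

#' @rdname accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))
#' @rdname accessors
#' @export
setMethod("targets", "CaptureDesign", function(x) x@targets)

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setMethod("geneSymbols", "GeneModelSet", function(x) names(x@exons))

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x, gene) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setMethod("exonRanges", "GeneModelSet", function(x, gene) {
    if (missing(gene)) return(x@exons)
    .checkGene(x, gene)
    x@exons[[gene]]
})

#' @rdname accessors
#' @export
setGeneric("cdsRanges", function(x, gene) standardGeneric("cdsRanges"))
#' @rdname accessors
#' @export
setMethod("cdsRanges", "GeneModelSet", function(x, gene) {
    if (missing(gene)) return(x@cds)
    .checkGene(x, gene)
    x@cds[[gene]]
})

.checkGene <- function(x, gene) {
    if (!(is.character(gene) && length(gene) == 1L && gene %in% names(x@exons)))
        stop("unknown gene symbol: ", gene, call. = FALSE)
    invisible(TRUE)
}

#' Region intervals of a gene in exon or CDS mode
#'
#' @param x a [GeneModelSet-class].
#' @param gene gene symbol.
#' @param mode \code{"exon"} or \code{"cds"}.
#' @return a sorted, merged \code{GRanges}; empty in cds mode for a
#'   non-coding gene.
#' @export
regionRanges <- function(x, gene, mode = c("exon", "cds")) {
    mode <- match.arg(mode)
    if (mode == "exon") exonRanges(x, gene) else cdsRanges(x, gene)
}

#' Total region length of a gene in bases
#'
#' @inheritParams regionRanges
#' @return integer base count (0 for cds mode on a non-coding gene).
#' @export
regionLength <- function(x, gene, mode = c("exon", "cds")) {
    sum(width(regionRanges(x, gene, mode)))
}

#' @rdname accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname accessors
#' @export
setMethod("depths", "DepthTrack", function(x) x@depths)

#' @rdname accessors
#' @export
setGeneric("regionMode", function(x) standardGeneric("regionMode"))
#' @rdname accessors
#' @export
setMethod("regionMode", "DepthTrack", function(x) x@regionMode)

#' @rdname accessors
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))
#' @rdname accessors
#' @export
setMethod("geneSymbol", "DepthTrack", function(x) x@geneSymbol)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "DepthTrack", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))
#' @rdname accessors
#' @export
setMethod("cohortId", "CohortMutationTable", function(x) x@cohortId)

#' @rdname accessors
#' @export
setGeneric("rosterSamples", function(x) standardGeneric("rosterSamples"))
#' @rdname accessors
#' @export
setMethod("rosterSamples", "CohortMutationTable", function(x) x@roster)

#' Samples of a cohort with at least one non-silent call in a gene
#'
#' @param x a [CohortMutationTable-class].
#' @param gene gene symbol; genes never seen in the cohort's MAF return
#'   an empty set (zero calls), not an error.
#' @return character vector of sample ids.
#' @export
mutatedSamples <- function(x, gene) {
    stopifnot(is(x, "CohortMutationTable"),
              is.character(gene), length(gene) == 1L)
    s <- x@mutated[[gene]]
    if (is.null(s)) character() else s
}
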