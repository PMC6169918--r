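#' Fraction of a gene's region covered by a capture design
#'
#' Base-level overlap between the gene's region (canonical exons or
#' CDS) and the design's merged targets, divided by region length.
#' An optional symmetric pad widens every target before the overlap is
#' taken, emulating the flanking bases real hybrid capture recovers
#' around each probe; the default of 0 audits the design file as
#' shipped.
#'
#' @param models a [GeneModelSet-class].
#' @param gene gene symbol.
#' @param design a [CaptureDesign-class].
#' @param mode region mode (\code{"exon"} or \code{"cds"}).
#' @param pad bases added on both sides of every target (default 0).
#' @return fraction in \[0, 1\].
#' @export
coveredFraction <- function(models, gene, design, mode = c("exon", "cds"),
                            pad = 0) {
    mode <- match.arg(mode)
    stopifnot(is(models, "GeneModelSet"), is(design, "CaptureDesign"),
              pad >= 0)
    rr <- regionRanges(models, gene, mode)
    if (!length(rr))
        stop("gene ", gene, " has an empty region in mode '", mode, "'")
    tg <- targets(design)
    if (pad > 0)
        tg <- GenomicRanges::reduce(tg + pad)
    intersectBases(rr, tg) / sum(width(rr))
}

#' Audit a capture design against a set of gene models
#'
#' Per gene: region length, overlapping bases, covered fraction and the
#' coverage status derived from the qualifying-fraction rule
#' (\code{covered} at or above the threshold, \code{undercovered_absent}
#' at exactly zero overlap, \code{undercovered_incomplete} in between).
#' In cds mode, non-coding genes cannot be audited — they are excluded
#' from the rows and reported via the \code{"skipped"} attribute, so the
#' denominator of any summary is explicit.
#'
#' @param design a [CaptureDesign-class].
#' @param models a [GeneModelSet-class].
#' @param mode region mode.
#' @param thresholds an [AuditThresholds-class].
#' @param pad target padding in bases, see [coveredFraction()].
#' @return a \code{data.frame} (one row per audited gene:
#'   \code{gene_symbol}, \code{kit_name}, \code{region_mode},
#'   \code{region_length}, \code{overlap_bases},
#'   \code{covered_fraction}, \code{status}) with attributes
#'   \code{"summary"} (named status counts) and \code{"skipped"}
#'   (genes excluded in cds mode).
#' @export
auditDesign <- function(design, models, mode = c("exon", "cds"),
                        thresholds = auditThresholds(), pad = 0) {
    mode <- match.arg(mode)
    stopifnot(is(design, "CaptureDesign"), is(models, "GeneModelSet"),
              is(thresholds, "AuditThresholds"), length(models) >= 1L)
    genes <- geneSymbols(models)
    lens <- vapply(genes, function(g) regionLength(models, g, mode), numeric(1))
    skipped <- genes[lens == 0]
    genes <- genes[lens > 0]
    tg <- targets(design)
    if (pad > 0)
        tg <- GenomicRanges::reduce(tg + pad)
    rows <- lapply(genes, function(g) {
        rr <- regionRanges(models, g, mode)
        L <- sum(width(rr))
        ov <- intersectBases(rr, tg)
        data.frame(gene_symbol = g, kit_name = kitName(design),
                   region_mode = mode, region_length = L, overlap_bases = ov,
                   covered_fraction = ov / L, stringsAsFactors = FALSE)
    })
    out <- .rbindRows(rows,
                      data.frame(gene_symbol = character(),
                                 kit_name = character(),
                                 region_mode = character(),
                                 region_length = numeric(),
                                 overlap_bases = numeric(),
                                 covered_fraction = numeric()))
    out$status <- .statusFromFraction(out$covered_fraction, thresholds)
    counts <- table(factor(out$status,
                           levels = c("covered", "undercovered_incomplete",
                                      "undercovered_absent")))
    attr(out, "summary") <- c(as.list(counts),
                              list(n_undercovered =
                                       sum(out$status != "covered"),
                                   n_audited = nrow(out),
                                   n_skipped = length(skipped)))
    attr(out, "skipped") <- skipped
    out
}

#' Per-exon design audit of one gene
#'
#' Applies the covered-fraction rule to each exon of the gene's region
#' separately, flagging undercovered exons and whether every exon is
#' undercovered (the most severe design failure: no usable probe
#' anywhere in the gene).
#'
#' @inheritParams auditDesign
#' @param gene gene symbol.
#' @return a \code{data.frame} (one row per exon: \code{gene_symbol},
#'   \code{exon_index}, \code{region_length}, \code{overlap_bases},
#'   \code{covered_fraction}, \code{status}, \code{undercovered}) with
#'   attribute \code{"all_exons_undercovered"}.
#' @export
auditExons <- function(design, models, gene, mode = c("exon", "cds"),
                       thresholds = auditThresholds(), pad = 0) {
    mode <- match.arg(mode)
    rr <- sort(regionRanges(models, gene, mode))
    if (!length(rr))
        stop("gene ", gene, " has no exons in mode '", mode, "'")
    tg <- targets(design)
    if (pad > 0)
        tg <- GenomicRanges::reduce(tg + pad)
    rows <- lapply(seq_along(rr), function(i) {
        L <- width(rr)[i]
        ov <- intersectBases(rr[i], tg)
        data.frame(gene_symbol = gene, exon_index = i, region_length = L,
                   overlap_bases = ov, covered_fraction = ov / L,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out$status <- .statusFromFraction(out$covered_fraction, thresholds)
    out$undercovered <- out$status != "covered"
    attr(out, "all_exons_undercovered") <- all(out$undercovered)
    out
}

#' Restrict an audit to a gene list of interest
#'
#' Cross-references audit rows (design- or depth-based) against a list
#' of genes of interest (e.g. known cancer genes) and counts statuses
#' among them; list members absent from the audit are reported, not
#' errors.
#'
#' @param rows a \code{data.frame} with \code{gene_symbol} and
#'   \code{status} columns (from [auditDesign()] or aggregated
#'   [callUndercoveredGene()] rows).
#' @param genesOfInterest character vector of gene symbols.
#' @return the subset rows, with attributes \code{"status_counts"}
#'   (named counts over the subset) and \code{"not_found"} (symbols
#'   missing from the audit).
#' @export
crossrefGeneList <- function(rows, genesOfInterest) {
    stopifnot(is.data.frame(rows),
              all(c("gene_symbol", "status") %in% names(rows)))
    genesOfInterest <- unique(as.character(genesOfInterest))
    sub <- rows[rows$gene_symbol %in% genesOfInterest, , drop = FALSE]
    counts <- table(factor(sub$status,
                           levels = c("covered", "undercovered_incomplete",
                                      "undercovered_absent")))
    attr(sub, "status_counts") <- counts
    attr(sub, "not_found") <- setdiff(genesOfInterest, rows$gene_symbol)
    sub
}
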