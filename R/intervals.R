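#' Merge genomic intervals on one chromosome
#'
#' Coalesces overlapping and touching intervals into a sorted disjoint
#' set.  All intervals must lie on a single chromosome; mixing
#' chromosomes is an error because callers of this primitive always work
#' per chromosome.
#'
#' @param x a \code{GRanges} (or \code{IRanges}) of intervals.
#' @return a sorted, disjoint \code{GRanges} covering the same bases.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 6), c(10, 15)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(x) {
    if (is(x, "IRanges"))
        x <- GenomicRanges::GRanges("chr", x)
    stopifnot(is(x, "GRanges"))
    if (length(unique(as.character(seqnames(x)))) > 1L)
        stop("mergeIntervals expects intervals on a single chromosome; got: ",
             paste(unique(as.character(seqnames(x))), collapse = ", "))
    GenomicRanges::reduce(granges(x), ignore.strand = TRUE)
}

#' Count bases shared by two interval sets
#'
#' Base-level intersection size, compared per chromosome; symmetric in
#' its arguments and strand-agnostic.  Empty inputs give 0.
#'
#' @param a,b \code{GRanges} interval sets.
#' @return non-negative integer count of shared bases.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 350)))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 320))
#' intersectBases(a, b)  # 70
#' @export
intersectBases <- function(a, b) {
    stopifnot(is(a, "GRanges"), is(b, "GRanges"))
    if (length(a) == 0L || length(b) == 0L)
        return(0L)
    a <- GenomicRanges::reduce(granges(a), ignore.strand = TRUE)
    b <- GenomicRanges::reduce(granges(b), ignore.strand = TRUE)
    chA <- as.character(seqnames(a))
    chB <- as.character(seqnames(b))
    total <- 0L
    for (ch in intersect(unique(chA), unique(chB))) {
        ra <- GenomicRanges::ranges(a)[chA == ch]
        rb <- GenomicRanges::ranges(b)[chB == ch]
        # inputs are reduced, so summed pairwise overlap widths are exact
        h <- IRanges::findOverlaps(ra, rb)
        if (length(h))
            total <- total +
                sum(pmin(end(ra)[S4Vectors::queryHits(h)],
                         end(rb)[S4Vectors::subjectHits(h)]) -
                    pmax(start(ra)[S4Vectors::queryHits(h)],
                         start(rb)[S4Vectors::subjectHits(h)]) + 1L)
    }
    total
}

#' Read a capture-design BED file
#'
#' Reads a BED3+ file (tab-separated, 0-based half-open) into a
#' [CaptureDesign-class]; intervals are merged per chromosome and
#' \code{track}/\code{browser}/comment lines are skipped.  A record with
#' \code{start >= end} is an error naming the offending line, because a
#' malformed probe file must never silently shrink a design.
#'
#' @param path BED file path.
#' @param kitName kit identifier; defaults to the file name.
#' @return a \code{CaptureDesign}.
#' @export
readBed <- function(path, kitName = tools::file_path_sans_ext(basename(path))) {
    if (!file.exists(path))
        stop("cannot read BED file: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (!length(idx)) {
        warning("BED file has no interval records: ", path)
        return(CaptureDesign(kitName))
    }
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("BED record with fewer than 3 fields at line %d of %s",
                     idx[which(nf < 3L)[1L]], path))
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(start0) || anyNA(end0))
        stop(sprintf("non-numeric BED coordinates at line %d of %s",
                     idx[which(is.na(start0) | is.na(end0))[1L]], path))
    bad <- start0 >= end0
    if (any(bad))
        stop(sprintf("BED record with start >= end at line %d of %s: '%s'",
                     idx[which(bad)[1L]], path, lines[idx[which(bad)[1L]]]))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
    CaptureDesign(kitName, gr)
}

#' Write a capture design as BED3
#'
#' Inverse of [readBed()]: emits the merged targets as 0-based half-open
#' records so a read/write cycle round-trips to an identical design.
#'
#' @param design a [CaptureDesign-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeBed <- function(design, path) {
    stopifnot(is(design, "CaptureDesign"))
    tg <- targets(design)
    df <- data.frame(chrom = as.character(seqnames(tg)),
                     start = start(tg) - 1L, end = end(tg))
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read canonical gene models
#'
#' Accepts either a genePred-style table (columns \code{gene_symbol},
#' \code{chrom}, \code{strand}, \code{cdsStart}, \code{cdsEnd},
#' \code{exonStarts}, \code{exonEnds}; the comma-terminated lists and
#' 0-based half-open coordinates of UCSC table dumps) or a directory of
#' per-gene BED files (\code{<SYMBOL>.bed}, exon intervals only, no CDS).
#' CDS intervals are derived as exon intersected with
#' \code{[cdsStart, cdsEnd)}; \code{cdsStart == cdsEnd} marks a
#' non-coding gene.  Duplicate gene symbols are an error: the audit
#' assumes one canonical transcript per gene, and ambiguous annotations
#' must be resolved upstream, not guessed at here.
#'
#' @param path a genePred-style TSV file, or a directory of per-gene BEDs.
#' @return a [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
    if (dir.exists(path))
        return(.readGeneModelsBedDir(path))
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c("exonStarts", "exonEnds")))
    need <- c("gene_symbol", "chrom", "strand", "cdsStart", "cdsEnd",
              "exonStarts", "exonEnds")
    miss <- setdiff(need, names(dt))
    if (length(miss))
        stop("gene-model table missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(dt$gene_symbol))
        stop("duplicate gene symbol(s) in gene-model table: ",
             paste(unique(dt$gene_symbol[duplicated(dt$gene_symbol)]),
                   collapse = ", "),
             " (deduplicate to one canonical transcript per gene)")
    parseList <- function(s) as.numeric(strsplit(sub(",$", "", s), ",")[[1L]])
    exl <- vector("list", nrow(dt))
    cdl <- vector("list", nrow(dt))
    for (i in seq_len(nrow(dt))) {
        st <- parseList(dt$exonStarts[i])
        en <- parseList(dt$exonEnds[i])
        if (length(st) != length(en))
            stop("exonStarts/exonEnds length mismatch for gene ",
                 dt$gene_symbol[i])
        if (any(st >= en))
            stop("exon with start >= end for gene ", dt$gene_symbol[i])
        ex <- GenomicRanges::GRanges(dt$chrom[i],
                                     IRanges::IRanges(st + 1L, en),
                                     strand = dt$strand[i])
        exl[[i]] <- ex
        if (dt$cdsStart[i] < dt$cdsEnd[i]) {
            cdsWin <- GenomicRanges::GRanges(dt$chrom[i],
                                             IRanges::IRanges(dt$cdsStart[i] + 1L,
                                                              dt$cdsEnd[i]))
            cdl[[i]] <- GenomicRanges::intersect(ex, cdsWin, ignore.strand = TRUE)
        } else {
            cdl[[i]] <- GenomicRanges::GRanges()
        }
    }
    names(exl) <- dt$gene_symbol
    names(cdl) <- dt$gene_symbol
    GeneModelSet(exl, cdl)
}

.readGeneModelsBedDir <- function(path) {
    beds <- list.files(path, pattern = "\\.bed$", full.names = TRUE)
    if (!length(beds))
        stop("no .bed files found in gene-model directory: ", path)
    syms <- tools::file_path_sans_ext(basename(beds))
    if (anyDuplicated(syms))
        stop("duplicate gene symbol(s) in BED directory: ",
             paste(unique(syms[duplicated(syms)]), collapse = ", "))
    exl <- lapply(beds, function(b) targets(readBed(b)))
    names(exl) <- syms
    GeneModelSet(exl)
}

#' Chromosomal positions of a gene's region bases
#'
#' Expands the region intervals of a gene into the ordered vector of
#' 1-based chromosomal positions its [DepthTrack-class] indexes; the
#' \emph{i}-th depth value belongs to the \emph{i}-th position.
#'
#' @inheritParams regionRanges
#' @return integer vector of positions, ascending.
#' @export
regionPositions <- function(x, gene, mode = c("exon", "cds")) {
    rr <- sort(regionRanges(x, gene, mode))
    if (!length(rr))
        stop("gene ", gene, " has an empty region in mode '",
             match.arg(mode), "'")
    unlist(lapply(seq_along(rr), function(i) seq(start(rr)[i], end(rr)[i])),
           use.names = FALSE)
}
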