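#' Read alignments from a SAM or BAM file
#'
#' SAM files are converted on the fly; records are returned with
#' \code{flag} and \code{mapq} metadata so [filterAlignments()] can apply
#' the audit's read filters.  Secondary and supplementary records are
#' read (not pre-filtered) so that filter attrition can be reported.
#'
#' @param path SAM or BAM file path.
#' @return a \code{GAlignments} with \code{flag} and \code{mapq} columns.
#' @export
readSamAlignments <- function(path) {
    if (!file.exists(path))
        stop("cannot read alignment file: ", path)
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(path, destination = dest,
                                overwrite = TRUE, indexDestination = TRUE)
    }
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    param <- Rsamtools::ScanBamParam(what = c("flag", "mapq"), flag = flags)
    GenomicAlignments::readGAlignments(bam, param = param)
}

.flagBit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Apply the audit's read filters
#'
#' Discards duplicate-flagged reads and reads below the minimum mapping
#' quality (MAPQ strictly below \code{minMapq}; a read at exactly the
#' threshold is kept).  Unmapped, secondary and supplementary records
#' are also removed: only one primary alignment per fragment may
#' contribute depth, otherwise a multi-mapping read would be counted
#' several times.  MAPQ 255 ("unavailable") passes the numeric filter;
#' aligners that emit it assert nothing about mapping confidence and the
#' audit takes the read at face value.
#'
#' @param alignments a \code{GAlignments} carrying \code{flag} and
#'   \code{mapq} metadata columns (see [readSamAlignments()]).
#' @param minMapq minimum mapping quality retained.
#' @return the filtered \code{GAlignments}; the number of records
#'   removed by each rule is attached as attribute \code{"attrition"}.
#' @export
filterAlignments <- function(alignments, minMapq = 30) {
    stopifnot(is(alignments, "GAlignments"))
    mc <- mcols(alignments)
    if (!all(c("flag", "mapq") %in% names(mc)))
        stop("alignments must carry 'flag' and 'mapq' metadata columns")
    if (any(GenomicAlignments::cigar(alignments) == "*"))
        stop("mapped record(s) without a CIGAR string")
    flag <- mc$flag
    mapq <- mc$mapq
    unmapped <- .flagBit(flag, 0x4L)
    dup <- .flagBit(flag, 0x400L)
    secondary <- .flagBit(flag, 0x100L)
    supplementary <- .flagBit(flag, 0x800L)
    lowq <- !is.na(mapq) & mapq < minMapq
    drop <- unmapped | dup | secondary | supplementary | lowq
    out <- alignments[!drop]
    attr(out, "attrition") <- c(unmapped = sum(unmapped),
                                duplicate = sum(dup & !unmapped),
                                secondary_supplementary =
                                    sum((secondary | supplementary) &
                                            !unmapped & !dup),
                                low_mapq = sum(lowq & !unmapped & !dup &
                                                   !secondary & !supplementary))
    out
}

.coverageAt <- function(covList, chrom, positions) {
    if (!(chrom %in% names(covList)))
        return(numeric(length(positions)))
    rle <- covList[[chrom]]
    d <- numeric(length(positions))
    inside <- positions <= length(rle)
    if (any(inside))
        d[inside] <- as.numeric(rle[positions[inside]])
    d
}

#' Per-base depth of filtered alignments over a gene's region
#'
#' Depth at a base is the number of alignments whose reference-consuming
#' segments (CIGAR M/=/X; deletions and skips excluded) cover it.  Bases
#' outside every alignment are 0.  Overlapping mates each count.
#'
#' @param alignments filtered \code{GAlignments} (see
#'   [filterAlignments()]).
#' @param models a [GeneModelSet-class].
#' @param gene gene symbol.
#' @param mode region mode (\code{"exon"} or \code{"cds"}).
#' @param sampleId recorded on the returned track.
#' @return a [DepthTrack-class].
#' @export
depthTrack <- function(alignments, models, gene, mode = c("exon", "cds"),
                       sampleId = NA_character_) {
    mode <- match.arg(mode)
    pos <- regionPositions(models, gene, mode)  # errors on empty region
    chrom <- as.character(seqnames(regionRanges(models, gene, mode)))[1L]
    cov <- GenomicAlignments::coverage(alignments, drop.D.ranges = TRUE)
    DepthTrack(gene, .coverageAt(cov, chrom, pos),
               sampleId = sampleId, regionMode = mode)
}

#' Count filtered reads overlapping a gene's region
#'
#' @inheritParams depthTrack
#' @return integer read count.
#' @export
countRegionReads <- function(alignments, models, gene, mode = c("exon", "cds")) {
    mode <- match.arg(mode)
    rr <- regionRanges(models, gene, mode)
    sum(IRanges::overlapsAny(GenomicRanges::granges(alignments), rr,
                             ignore.strand = TRUE))
}

#' Average depth over a gene's region
#'
#' The arithmetic mean of per-base depth across all region bases — the
#' quantity compared against the 25x sufficiency threshold.
#'
#' @param track a [DepthTrack-class] (or bare numeric depth vector).
#' @return mean depth (x-fold).
#' @export
averageExonCoverage <- function(track) {
    d <- if (is(track, "DepthTrack")) depths(track) else as.numeric(track)
    if (!length(d)) stop("empty depth track")
    mean(d)
}

#' Is an average depth sufficient to call mutations?
#'
#' Sufficient means at or above the minimum average depth threshold
#' (inclusive: a sample at exactly the threshold qualifies).
#'
#' @param avg average region depth (x-fold), vectorized.
#' @param thresholds an [AuditThresholds-class].
#' @return logical vector.
#' @export
isSufficient <- function(avg, thresholds = auditThresholds()) {
    stopifnot(is(thresholds, "AuditThresholds"), all(avg >= 0))
    avg >= thresholds@minAvgDepth
}

#' Is a cohort undercovered for a gene?
#'
#' True when strictly more than the configured fraction (default 75%)
#' of samples have insufficient coverage; exactly the fraction is not
#' undercovered.
#'
#' @param sufficient logical vector, one flag per sample in the cohort.
#' @param thresholds an [AuditThresholds-class].
#' @return logical flag.
#' @export
undercoveredCohort <- function(sufficient, thresholds = auditThresholds()) {
    stopifnot(is(thresholds, "AuditThresholds"))
    if (!length(sufficient))
        stop("cohort with zero samples")
    stopifnot(is.logical(sufficient), !anyNA(sufficient))
    sum(!sufficient) / length(sufficient) > thresholds@cohortInsufficiencyFrac
}

#' Cross-sample mean depth profile
#'
#' Elementwise arithmetic mean of per-sample depth tracks over the same
#' gene and region mode.
#'
#' @param tracks list of [DepthTrack-class] objects (same gene, mode and
#'   length).
#' @return a [DepthTrack-class] holding the mean profile
#'   (\code{sampleId} is \code{NA}).
#' @export
meanDepthProfile <- function(tracks) {
    stopifnot(length(tracks) >= 1L,
              all(vapply(tracks, is, logical(1), "DepthTrack")))
    g <- unique(vapply(tracks, geneSymbol, character(1)))
    m <- unique(vapply(tracks, regionMode, character(1)))
    if (length(g) != 1L || length(m) != 1L)
        stop("tracks must all belong to one gene and one region mode")
    lens <- unique(vapply(tracks, length, integer(1)))
    if (length(lens) != 1L)
        stop("track length mismatch for gene ", g)
    mat <- vapply(tracks, depths, numeric(lens))
    prof <- if (is.matrix(mat)) rowMeans(mat) else mean(mat)
    DepthTrack(g, prof, sampleId = NA_character_, regionMode = m)
}

.statusFromFraction <- function(frac, thresholds) {
    ifelse(frac >= thresholds@qualifyingFrac, "covered",
           ifelse(frac == 0, "undercovered_absent", "undercovered_incomplete"))
}

#' Call a gene's depth-based coverage status
#'
#' A base qualifies when its cross-sample mean depth strictly exceeds
#' the base threshold (default 20).  The gene is \code{covered} when at
#' least the qualifying fraction (default 80%) of its bases qualify;
#' otherwise it is undercovered in one of two modes:
#' \code{undercovered_absent} when no base qualifies (no probes at the
#' locus at all) and \code{undercovered_incomplete} when some do.
#'
#' @param profile a mean-depth [DepthTrack-class] (see
#'   [meanDepthProfile()]) or bare numeric vector.
#' @param thresholds an [AuditThresholds-class].
#' @param geneSymbol gene label when \code{profile} is bare numeric.
#' @return a one-row \code{data.frame}: \code{gene_symbol},
#'   \code{region_mode}, \code{n_bases}, \code{qualifying_fraction},
#'   \code{status}.
#' @export
callUndercoveredGene <- function(profile, thresholds = auditThresholds(),
                                 geneSymbol = NA_character_) {
    stopifnot(is(thresholds, "AuditThresholds"))
    if (is(profile, "DepthTrack")) {
        d <- depths(profile)
        g <- geneSymbol(profile)
        m <- regionMode(profile)
    } else {
        d <- as.numeric(profile)
        g <- geneSymbol
        m <- NA_character_
    }
    if (!length(d)) stop("empty depth profile")
    frac <- mean(d > thresholds@baseDepthGt)
    data.frame(gene_symbol = g, region_mode = m, n_bases = length(d),
               qualifying_fraction = frac,
               status = .statusFromFraction(frac, thresholds),
               stringsAsFactors = FALSE)
}

#' Call per-exon coverage status from a mean-depth profile
#'
#' Applies the base-qualification rule of [callUndercoveredGene()] to
#' each exon of the gene's region separately.  Exons are taken from the
#' gene model in the track's region mode (cds mode partitions the track
#' by coding exon).
#'
#' @param profile a mean-depth [DepthTrack-class] over the gene.
#' @param models a [GeneModelSet-class].
#' @param thresholds an [AuditThresholds-class].
#' @return a \code{data.frame} with one row per exon
#'   (\code{exon_index}, \code{n_bases}, \code{qualifying_fraction},
#'   \code{undercovered}) and attribute
#'   \code{"all_exons_undercovered"}.
#' @export
callUndercoveredExons <- function(profile, models,
                                  thresholds = auditThresholds()) {
    stopifnot(is(profile, "DepthTrack"), is(models, "GeneModelSet"),
              is(thresholds, "AuditThresholds"))
    g <- geneSymbol(profile)
    mode <- regionMode(profile)
    rr <- sort(regionRanges(models, g, mode))
    if (sum(width(rr)) != length(profile))
        stop("profile length does not match the ", mode, " region of ", g)
    idx <- rep(seq_along(rr), width(rr))
    d <- depths(profile)
    frac <- vapply(split(d > thresholds@baseDepthGt, idx), mean, numeric(1))
    out <- data.frame(gene_symbol = g, exon_index = seq_along(rr),
                      n_bases = width(rr),
                      qualifying_fraction = unname(frac),
                      undercovered = unname(frac < thresholds@qualifyingFrac),
                      stringsAsFactors = FALSE)
    attr(out, "all_exons_undercovered") <- all(out$undercovered)
    out
}

#' Mean depth within loci of interest (e.g. MSI loci)
#'
#' Averages a gene's depth track over each supplied locus — the check
#' used to decide whether absence of events at a microsatellite locus
#' is interpretable or just uncovered.
#'
#' @param track a [DepthTrack-class] over the gene.
#' @param models a [GeneModelSet-class].
#' @param loci a \code{GRanges} of loci; every locus base must fall in
#'   the gene's region (an out-of-region locus is an error naming it).
#' @return numeric vector of per-locus mean depths (named when
#'   \code{loci} has names).
#' @export
meanDepthInLoci <- function(track, models, loci) {
    stopifnot(is(track, "DepthTrack"), is(models, "GeneModelSet"),
              is(loci, "GRanges"))
    g <- geneSymbol(track)
    pos <- regionPositions(models, g, regionMode(track))
    lookup <- match(seq_len(max(pos)), pos)
    chrom <- as.character(seqnames(regionRanges(models, g, regionMode(track))))[1L]
    d <- depths(track)
    out <- vapply(seq_along(loci), function(i) {
        lc <- loci[i]
        nm <- if (!is.null(names(loci))) names(loci)[i] else as.character(i)
        if (as.character(seqnames(lc)) != chrom)
            stop("locus ", nm, " lies on ", as.character(seqnames(lc)),
                 ", not on the gene's chromosome ", chrom)
        p <- seq(start(lc), end(lc))
        if (any(p > max(pos)) || anyNA(lookup[p]))
            stop("locus ", nm, " falls outside the region of gene ", g)
        mean(d[lookup[p]])
    }, numeric(1))
    names(out) <- names(loci)
    out
}

#' Read per-base depth tables (samtools-depth layout)
#'
#' TSV with header: \code{chrom}, \code{pos} (1-based), then one depth
#' column per sample.  Positions are mapped into each gene's region;
#' region bases absent from the table get depth 0; positions outside
#' every requested region are skipped with one summary warning.
#' Duplicate (chrom, pos) rows are an error — they would make depth
#' ill-defined.
#'
#' @param path depth TSV path.
#' @param models a [GeneModelSet-class].
#' @param genes gene symbols to extract (default: all in \code{models}).
#' @param mode region mode.
#' @return named list (by sample) of named lists (by gene) of
#'   [DepthTrack-class] objects.
#' @export
readDepthTsv <- function(path, models, genes = geneSymbols(models),
                         mode = c("exon", "cds")) {
    mode <- match.arg(mode)
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    if (ncol(dt) >= 2L && !identical(names(dt)[1:2], c("chrom", "pos")))
        stop("depth TSV must start with columns 'chrom', 'pos'")
    sampleCols <- setdiff(names(dt), c("chrom", "pos"))
    if (nrow(dt) && anyDuplicated(dt[, c("chrom", "pos")]))
        stop("duplicate (chrom, pos) row(s) in depth TSV: ", path)
    used <- logical(nrow(dt))
    out <- lapply(sampleCols, function(sc) {
        tracks <- lapply(genes, function(g) {
            pos <- regionPositions(models, g, mode)
            chrom <- as.character(seqnames(regionRanges(models, g, mode)))[1L]
            d <- numeric(length(pos))
            sel <- which(dt$chrom == chrom)
            if (length(sel)) {
                hit <- match(dt$pos[sel], pos)
                ok <- !is.na(hit)
                d[hit[ok]] <- as.numeric(dt[[sc]][sel[ok]])
                used[sel[ok]] <<- TRUE
            }
            DepthTrack(g, d, sampleId = sc, regionMode = mode)
        })
        names(tracks) <- genes
        tracks
    })
    names(out) <- sampleCols
    if (nrow(dt) && any(!used))
        warning(sum(!used), " depth row(s) outside every requested gene region were skipped")
    out
}

#' Write per-base depth tracks as a samtools-depth-style TSV
#'
#' One row per region base with nonzero total depth is not assumed: all
#' region bases are written so the file round-trips through
#' [readDepthTsv()] exactly.
#'
#' @param tracksBySample named list (by sample) of named lists (by gene)
#'   of [DepthTrack-class] objects, as produced by [readDepthTsv()] or
#'   [simulateDepth()].
#' @param models a [GeneModelSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDepthTsv <- function(tracksBySample, models, path) {
    stopifnot(length(tracksBySample) >= 1L)
    genes <- names(tracksBySample[[1L]])
    mode <- regionMode(tracksBySample[[1L]][[1L]])
    rows <- lapply(genes, function(g) {
        pos <- regionPositions(models, g, mode)
        chrom <- as.character(seqnames(regionRanges(models, g, mode)))[1L]
        cols <- lapply(tracksBySample, function(tr) depths(tr[[g]]))
        do.call(data.frame, c(list(chrom = chrom, pos = pos), cols,
                              list(check.names = FALSE,
                                   stringsAsFactors = FALSE)))
    })
    df <- do.call(rbind, rows)
    names(df) <- c("chrom", "pos", names(tracksBySample))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Summarize a per-sample coverage table for one gene
#'
#' Cohort-level sufficiency statistics from per-sample rows: how many
#' samples fall below a read-count cutoff, the median filtered read
#' count, the maximum average region coverage, and how many samples are
#' sufficient at the average-depth threshold.
#'
#' @param coverage data.frame with columns \code{read_count} (may be
#'   \code{NA}) and \code{avg_exon_coverage}.
#' @param thresholds an [AuditThresholds-class].
#' @param readCountBelow report the count of samples with fewer than
#'   this many filtered reads.
#' @return one-row \code{data.frame}: \code{n_samples},
#'   \code{n_below_read_count}, \code{median_read_count},
#'   \code{max_avg_coverage}, \code{n_sufficient}.
#' @export
summarizeGeneCoverage <- function(coverage, thresholds = auditThresholds(),
                                  readCountBelow = 1000) {
    stopifnot(is.data.frame(coverage),
              all(c("read_count", "avg_exon_coverage") %in% names(coverage)))
    data.frame(
        n_samples = nrow(coverage),
        n_below_read_count = sum(coverage$read_count < readCountBelow,
                                 na.rm = TRUE),
        median_read_count = stats::median(coverage$read_count, na.rm = TRUE),
        max_avg_coverage = max(coverage$avg_exon_coverage),
        n_sufficient = sum(isSufficient(coverage$avg_exon_coverage,
                                        thresholds)))
}
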