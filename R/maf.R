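#' MAF variant classes treated as non-silent
#'
#' The mutation classes that change protein product or splicing; calls
#' in any other class (Silent, Intron, UTRs, Flank, IGR, RNA, ...) are
#' silent-class for screening purposes.  The set is the prevailing MAF
#' convention and is configurable wherever it is consumed.
#'
#' @format character vector of Variant_Classification terms.
#' @export
nonsilentClasses <- c(
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Splice_Site", "Translation_Start_Site"
)

.KNOWN_SILENT <- c(
    "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR",
    "RNA", "Targeted_Region", "De_novo_Start_InFrame",
    "De_novo_Start_OutOfFrame", "Start_Codon_SNP", "lincRNA"
)

#' Is a MAF variant classification non-silent?
#'
#' @param variantClassification character vector of
#'   \code{Variant_Classification} terms.
#' @param nonsilent the classes counted as non-silent.
#' @return logical vector.  Terms outside both the non-silent list and
#'   the recognized silent vocabulary raise one warning summarizing the
#'   unknown terms and are treated as silent.
#' @examples
#' isNonsilent(c("Missense_Mutation", "Silent", "Intron"))
#' @export
isNonsilent <- function(variantClassification, nonsilent = nonsilentClasses) {
    stopifnot(is.character(variantClassification))
    unknown <- setdiff(unique(variantClassification),
                       c(nonsilent, .KNOWN_SILENT))
    if (length(unknown))
        warning("unrecognized Variant_Classification term(s) treated as silent: ",
                paste(unknown, collapse = ", "))
    variantClassification %in% nonsilent
}

#' Read a MAF file
#'
#' Tab-separated with \code{#} comment lines skipped; requires at least
#' \code{Hugo_Symbol}, \code{Variant_Classification} and
#' \code{Tumor_Sample_Barcode}.  Extra columns are ignored.
#'
#' @param path MAF file path.
#' @return a \code{data.frame} with columns \code{gene_symbol},
#'   \code{variant_classification}, \code{sample_id}.
#' @export
readMaf <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = "Hugo_Symbol")
    need <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
    miss <- setdiff(need, names(dt))
    if (length(miss))
        stop("MAF file ", path, " missing required column(s): ",
             paste(miss, collapse = ", "))
    data.frame(gene_symbol = as.character(dt$Hugo_Symbol),
               variant_classification = as.character(dt$Variant_Classification),
               sample_id = as.character(dt$Tumor_Sample_Barcode),
               stringsAsFactors = FALSE)
}

#' Read a cohort roster table
#'
#' Rosters are supplied explicitly rather than inferred from MAF sample
#' columns: a sample with no called mutations at all would otherwise
#' vanish from every denominator.
#'
#' @param path TSV with header columns \code{sample_id}, \code{cohort_id}.
#' @return named list of character vectors, one per cohort.
#' @export
readRoster <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    miss <- setdiff(c("sample_id", "cohort_id"), names(dt))
    if (length(miss))
        stop("roster file missing column(s): ", paste(miss, collapse = ", "))
    split(as.character(dt$sample_id), as.character(dt$cohort_id))
}

#' Build a cohort mutation table from MAF records
#'
#' Per gene, each sample is counted at most once no matter how many rows
#' it contributes, and samples whose calls are all silent-class do not
#' enter the mutated set (they stay in the roster denominator).  MAF
#' samples absent from the roster are added to it with a warning, since
#' a call implies the sample was sequenced.
#'
#' @param records data.frame as from [readMaf()] (columns
#'   \code{gene_symbol}, \code{variant_classification}, \code{sample_id}).
#' @param roster character vector of the cohort's sample ids.
#' @param cohortId cohort identifier.
#' @param nonsilent non-silent classification terms.
#' @return a [CohortMutationTable-class].
#' @export
buildCohortTable <- function(records, roster, cohortId,
                             nonsilent = nonsilentClasses) {
    roster <- unique(as.character(roster))
    if (!length(roster))
        stop("empty roster for cohort ", cohortId)
    stopifnot(is.data.frame(records),
              all(c("gene_symbol", "variant_classification", "sample_id") %in%
                      names(records)))
    extra <- setdiff(unique(records$sample_id), roster)
    if (length(extra)) {
        warning(sprintf("cohort %s: %d MAF sample(s) absent from roster were added",
                        cohortId, length(extra)))
        roster <- c(roster, extra)
    }
    ns <- records[isNonsilent(records$variant_classification, nonsilent), ,
                  drop = FALSE]
    mutated <- lapply(split(ns$sample_id, ns$gene_symbol),
                      function(s) sort(unique(s)))
    new("CohortMutationTable", cohortId = as.character(cohortId),
        roster = roster, mutated = mutated)
}

#' Pooled mutation rate of a gene over cohorts with at least one call
#'
#' The denominator excludes cohorts where the gene has zero non-silent
#' calls: the screen must not let a censored cohort dilute the evidence
#' that the gene is commonly mutated elsewhere.  With
#' \code{method = "pooled"} the rate is total mutated samples over total
#' roster size across the non-zero cohorts; \code{method = "mean"}
#' averages the per-cohort rates instead.
#'
#' @param gene gene symbol.
#' @param tables list of [CohortMutationTable-class] objects.
#' @param method \code{"pooled"} (default) or \code{"mean"}.
#' @return list with \code{rate} (0 when no cohort has a call),
#'   \code{allZero} flag, and \code{zeroCohorts} (ids with zero calls).
#' @export
pooledMutationRate <- function(gene, tables, method = c("pooled", "mean")) {
    method <- match.arg(method)
    stopifnot(length(tables) >= 1L,
              all(vapply(tables, is, logical(1), "CohortMutationTable")))
    nMut <- vapply(tables, function(tb) length(mutatedSamples(tb, gene)),
                   integer(1))
    nRoster <- vapply(tables, function(tb) length(rosterSamples(tb)), integer(1))
    ids <- vapply(tables, cohortId, character(1))
    nz <- nMut >= 1L
    rate <- if (!any(nz)) {
        0
    } else if (method == "pooled") {
        sum(nMut[nz]) / sum(nRoster[nz])
    } else {
        mean(nMut[nz] / nRoster[nz])
    }
    list(rate = rate, allZero = !any(nz), zeroCohorts = sort(ids[!nz]))
}

#' Screen for genes with suspicious cohort-specific mutational absence
#'
#' A gene is a candidate when it is commonly mutated where it is called
#' at all (pooled non-silent rate over non-zero cohorts at least
#' \code{minRate}) yet at least \code{minZeroCohorts} whole cohorts have
#' zero non-silent calls in it.  Requiring several zero cohorts guards
#' against small cohorts where zero calls arise by chance even at the
#' minimum rate.
#'
#' @param tables list of [CohortMutationTable-class] objects, at least
#'   \code{minZeroCohorts} of them.
#' @param minRate pooled-rate filter, in (0, 1].
#' @param minZeroCohorts minimum number of zero-call cohorts.
#' @param method rate pooling method, see [pooledMutationRate()].
#' @param genes optional gene universe; defaults to every gene with a
#'   non-silent call in any supplied cohort.
#' @return a \code{data.frame} sorted by gene symbol with columns
#'   \code{gene_symbol}, \code{pooled_rate}, \code{n_zero_cohorts},
#'   \code{zero_cohorts} (comma-separated ids).
#' @export
screenCandidates <- function(tables, minRate = 0.05, minZeroCohorts = 3,
                             method = c("pooled", "mean"), genes = NULL) {
    method <- match.arg(method)
    if (!(is.numeric(minRate) && length(minRate) == 1L &&
          minRate > 0 && minRate <= 1))
        stop("minRate must lie in (0, 1]")
    if (length(tables) < minZeroCohorts)
        stop("need at least minZeroCohorts (", minZeroCohorts,
             ") cohort tables, got ", length(tables))
    if (is.null(genes))
        genes <- sort(unique(unlist(lapply(tables,
                                           function(tb) names(tb@mutated)))))
    rows <- lapply(genes, function(g) {
        pr <- pooledMutationRate(g, tables, method = method)
        data.frame(gene_symbol = g,
                   pooled_rate = pr$rate,
                   n_zero_cohorts = length(pr$zeroCohorts),
                   zero_cohorts = paste(pr$zeroCohorts, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- .rbindRows(rows,
                      data.frame(gene_symbol = character(),
                                 pooled_rate = numeric(),
                                 n_zero_cohorts = integer(),
                                 zero_cohorts = character()))
    keep <- out$pooled_rate >= minRate & out$n_zero_cohorts >= minZeroCohorts
    out <- out[keep, , drop = FALSE]
    out[order(out$gene_symbol), , drop = FALSE]
}
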