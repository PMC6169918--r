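#' Read a sample-to-kit metadata table
#'
#' TSV with header columns \code{sample_id}, \code{cohort_id},
#' \code{kit_name} and optionally \code{center}.  A sample listed twice
#' with conflicting kits is an error (metadata defect); exact duplicate
#' rows are collapsed.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
readKitTable <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    miss <- setdiff(c("sample_id", "cohort_id", "kit_name"), names(dt))
    if (length(miss))
        stop("kit table missing column(s): ", paste(miss, collapse = ", "))
    df <- as.data.frame(dt)
    if (!("center" %in% names(df))) df$center <- NA_character_
    df <- unique(df[, c("sample_id", "cohort_id", "kit_name", "center")])
    dup <- df$sample_id[duplicated(df$sample_id)]
    if (length(dup))
        stop("conflicting kit assignment(s) for sample(s): ",
             paste(unique(dup), collapse = ", "))
    df
}

#' Annotate per-sample coverage rows with capture kits
#'
#' Left-joins coverage rows to the kit table on \code{sample_id}.
#' Samples without metadata are annotated \code{"Unknown"} and kept as
#' their own stratum (dropping them would break sample-count
#' conservation in the summaries); their number is reported in one
#' warning.
#'
#' @param coverage data.frame of per-sample coverage rows (at least
#'   \code{sample_id}; typically also \code{cohort_id},
#'   \code{gene_symbol}, \code{avg_exon_coverage}, \code{sufficient}).
#' @param kits data.frame as from [readKitTable()] (unique
#'   \code{sample_id}; conflicting duplicates are an error).
#' @return \code{coverage} with a \code{kit_name} column appended.
#' @export
joinKits <- function(coverage, kits) {
    stopifnot(is.data.frame(coverage), "sample_id" %in% names(coverage),
              is.data.frame(kits),
              all(c("sample_id", "kit_name") %in% names(kits)))
    ktab <- unique(kits[, c("sample_id", "kit_name")])
    dup <- unique(ktab$sample_id[duplicated(ktab$sample_id)])
    if (length(dup))
        stop("conflicting kit assignment(s) for sample(s): ",
             paste(dup, collapse = ", "))
    i <- match(coverage$sample_id, ktab$sample_id)
    coverage$kit_name <- ktab$kit_name[i]
    nUnknown <- sum(is.na(i))
    if (nUnknown) {
        coverage$kit_name[is.na(i)] <- "Unknown"
        warning(nUnknown,
                " coverage sample(s) missing from the kit table were annotated 'Unknown'")
    }
    coverage
}

#' Kit-stratified insufficiency summary for one gene
#'
#' One row per cohort-by-kit stratum: sample count, insufficient count
#' and the insufficiency fraction — the tabulation that lets an
#' undercovered cohort be traced to the capture kit its samples used.
#'
#' @param annotated kit-annotated coverage rows (see [joinKits()]) with
#'   columns \code{cohort_id}, \code{kit_name}, \code{gene_symbol},
#'   \code{sufficient}.
#' @param gene gene symbol to summarize.
#' @return data.frame ordered by (cohort, kit): \code{cohort_id},
#'   \code{kit_name}, \code{gene_symbol}, \code{n_samples},
#'   \code{n_insufficient}, \code{insufficiency_fraction}.
#' @export
kitSummary <- function(annotated, gene) {
    stopifnot(is.data.frame(annotated),
              all(c("cohort_id", "kit_name", "gene_symbol", "sufficient") %in%
                      names(annotated)))
    rows <- annotated[annotated$gene_symbol == gene, , drop = FALSE]
    if (!nrow(rows))
        stop("no coverage rows for gene ", gene)
    agg <- stats::aggregate(cbind(n_samples = rep(1L, nrow(rows)),
                                  n_insufficient = !rows$sufficient),
                            by = list(cohort_id = rows$cohort_id,
                                      kit_name = rows$kit_name),
                            FUN = sum)
    agg$gene_symbol <- gene
    agg$insufficiency_fraction <- agg$n_insufficient / agg$n_samples
    agg <- agg[order(agg$cohort_id, agg$kit_name), , drop = FALSE]
    rownames(agg) <- NULL
    agg[, c("cohort_id", "kit_name", "gene_symbol", "n_samples",
            "n_insufficient", "insufficiency_fraction")]
}

#' Does a kit explain a cohort's insufficient coverage of a gene?
#'
#' Two set-containment checks within one cohort: does every sample with
#' insufficient coverage use the kit, and is every sample using the kit
#' insufficient?  Both true means kit membership and insufficiency
#' coincide exactly — the signature of probe absence in that kit's
#' design rather than sample-level noise.
#'
#' @param annotated kit-annotated coverage rows (see [joinKits()]).
#' @param gene gene symbol.
#' @param cohort cohort id.
#' @param kit kit name; must be used by at least one sample in the
#'   cohort.
#' @return named logical vector
#'   \code{c(all_insufficient_use_kit =, all_kit_users_insufficient =)}.
#' @export
kitExplains <- function(annotated, gene, cohort, kit) {
    rows <- annotated[annotated$gene_symbol == gene &
                          annotated$cohort_id == cohort, , drop = FALSE]
    if (!nrow(rows))
        stop("no coverage rows for gene ", gene, " in cohort ", cohort)
    onKit <- rows$kit_name == kit
    if (!any(onKit))
        stop("kit '", kit, "' is not used by any sample in cohort ", cohort)
    insuff <- !rows$sufficient
    c(all_insufficient_use_kit = !any(insuff & !onKit),
      all_kit_users_insufficient = !any(onKit & !insuff))
}

#' Exact association test between kit usage and insufficiency
#'
#' Optional extension beyond the tabulations: a 2x2 exact conditional
#' (Fisher) test of kit-vs-other against insufficient-vs-sufficient in
#' one cohort, with Benjamini-Hochberg adjustment across the gene set
#' supplied.  A degenerate margin (all samples on one kit, or all
#' sufficient/insufficient) is flagged and gets no p-value.
#'
#' @param annotated kit-annotated coverage rows (see [joinKits()]).
#' @param genes gene symbols to test (BH adjustment is across these).
#' @param cohort cohort id.
#' @param kit kit name.
#' @return data.frame per gene: \code{gene_symbol}, \code{odds_ratio},
#'   \code{p_value}, \code{q_value}, \code{degenerate}.
#' @export
kitAssociationTest <- function(annotated, genes, cohort, kit) {
    rows <- lapply(genes, function(g) {
        sub <- annotated[annotated$gene_symbol == g &
                             annotated$cohort_id == cohort, , drop = FALSE]
        if (!nrow(sub))
            return(data.frame(gene_symbol = g, odds_ratio = NA_real_,
                              p_value = NA_real_, degenerate = TRUE))
        tab <- table(factor(sub$kit_name == kit, levels = c(TRUE, FALSE)),
                     factor(!sub$sufficient, levels = c(TRUE, FALSE)))
        if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
            return(data.frame(gene_symbol = g, odds_ratio = NA_real_,
                              p_value = NA_real_, degenerate = TRUE))
        ft <- stats::fisher.test(tab)
        data.frame(gene_symbol = g, odds_ratio = unname(ft$estimate),
                   p_value = ft$p.value, degenerate = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out$q_value <- NA_real_
    ok <- !out$degenerate
    out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
    out[, c("gene_symbol", "odds_ratio", "p_value", "q_value", "degenerate")]
}

#' Gene-by-cohort coverage status matrix
#'
#' For each gene and cohort, the fraction of samples with sufficient
#' coverage — except that cohorts with at least one non-silent call in
#' the gene are marked \code{"not_considered"}: a called mutation means
#' absence is not in question there.
#'
#' @param annotated kit-annotated (or plain) coverage rows with
#'   \code{cohort_id}, \code{gene_symbol}, \code{sufficient}.
#' @param tables list of [CohortMutationTable-class] objects supplying
#'   the called-mutation mask (optional; with \code{NULL} no cell is
#'   masked).
#' @return character matrix (genes x cohorts) holding formatted
#'   fractions or \code{"not_considered"}; the numeric fractions are
#'   attached as attribute \code{"fractions"}.
#' @export
statusMatrix <- function(annotated, tables = NULL) {
    genes <- sort(unique(annotated$gene_symbol))
    cohorts <- sort(unique(annotated$cohort_id))
    frac <- matrix(NA_real_, length(genes), length(cohorts),
                   dimnames = list(genes, cohorts))
    for (g in genes) for (ch in cohorts) {
        sub <- annotated[annotated$gene_symbol == g &
                             annotated$cohort_id == ch, , drop = FALSE]
        if (nrow(sub))
            frac[g, ch] <- mean(sub$sufficient)
    }
    out <- matrix(sprintf("%.4f", frac), nrow(frac), ncol(frac),
                  dimnames = dimnames(frac))
    out[is.na(frac)] <- NA_character_
    if (!is.null(tables)) {
        for (tb in tables) {
            ch <- cohortId(tb)
            if (!(ch %in% cohorts)) next
            for (g in genes)
                if (length(mutatedSamples(tb, g)))
                    out[g, ch] <- "not_considered"
        }
    }
    attr(out, "fractions") <- frac
    out
}
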