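covRow <- function(sample, cohort, gene, sufficient, kit = NULL) {
    df <- data.frame(sample_id = sample, cohort_id = cohort,
                     gene_symbol = gene, avg_exon_coverage =
                         ifelse(sufficient, 60, 3),
                     sufficient = sufficient, stringsAsFactors = FALSE)
    if (!is.null(kit)) df$kit_name <- kit
    df
}

# KIRP-like toy cohort: 10 samples on a custom kit all insufficient for
# the gene, 5 on another kit all sufficient
mixedKitCohort <- function(gene = "G1", cohort = "KC") {
    rbind(covRow(sprintf("%s_c%02d", cohort, 1:10), cohort, gene, FALSE,
                 "CustomKit"),
          covRow(sprintf("%s_v%02d", cohort, 1:5), cohort, gene, TRUE,
                 "VCRomeKit"))
}

test_that("joinKits annotates and keeps unknown samples as a stratum", {
    cov <- covRow(c("s1", "s2", "s3"), "A", "G1", c(TRUE, FALSE, TRUE))
    kits <- data.frame(sample_id = c("s1", "s2"), cohort_id = "A",
                       kit_name = c("k1", "k2"), stringsAsFactors = FALSE)
    expect_warning(ann <- joinKits(cov, kits), "Unknown")
    expect_equal(ann$kit_name, c("k1", "k2", "Unknown"))
    annFull <- joinKits(cov[1:2, ], kits)
    expect_false(any(annFull$kit_name == "Unknown"))
    badKits <- rbind(kits, data.frame(sample_id = "s1", cohort_id = "A",
                                      kit_name = "other"))
    expect_error(joinKits(cov, badKits), "conflicting")
})

test_that("kitSummary tabulates insufficiency by cohort and kit", {
    ann <- rbind(covRow(sprintf("a%02d", 1:10), "C1", "G1",
                        rep(c(FALSE, TRUE), c(8, 2)), "kitA"),
                 covRow(sprintf("b%02d", 1:5), "C1", "G1", TRUE, "kitB"))
    s <- kitSummary(ann, "G1")
    expect_equal(nrow(s), 2L)
    expect_equal(s$insufficiency_fraction, c(0.8, 0))
    expect_equal(s$n_samples, c(10L, 5L))
    # conservation: strata sum to the cohort's row count
    expect_equal(sum(s$n_samples), nrow(ann))
    expect_error(kitSummary(ann, "NOPE"), "no coverage rows")
})

test_that("kitExplains detects exact coincidence of kit and insufficiency", {
    ann <- mixedKitCohort()
    res <- kitExplains(ann, "G1", "KC", "CustomKit")
    expect_true(res[["all_insufficient_use_kit"]])
    expect_true(res[["all_kit_users_insufficient"]])
    expect_identical(unname(res), unname(kitExplains(ann[sample(nrow(ann)), ],
                                                     "G1", "KC", "CustomKit")))
    # one insufficient sample on another kit breaks the first flag
    ann2 <- rbind(ann, covRow("KC_x1", "KC", "G1", FALSE, "VCRomeKit"))
    expect_false(kitExplains(ann2, "G1", "KC",
                             "CustomKit")[["all_insufficient_use_kit"]])
    # one sufficient sample on the kit breaks the second flag
    ann3 <- rbind(ann, covRow("KC_x2", "KC", "G1", TRUE, "CustomKit"))
    expect_false(kitExplains(ann3, "G1", "KC",
                             "CustomKit")[["all_kit_users_insufficient"]])
    expect_error(kitExplains(ann, "G1", "KC", "NoSuchKit"), "not used")
    expect_error(kitExplains(ann, "G9", "KC", "CustomKit"), "no coverage rows")
})

test_that("kitAssociationTest matches a hypergeometric enumeration oracle", {
    ann <- mixedKitCohort()
    res <- kitAssociationTest(ann, "G1", "KC", "CustomKit")
    expect_false(res$degenerate)
    expect_lt(res$p_value, 0.01)
    expect_true(is.infinite(res$odds_ratio))
    # independent oracle: two-sided Fisher p by enumerating the
    # hypergeometric distribution of the top-left cell
    m <- 10; n <- 5; k <- 10   # kit margin, other margin, insufficient margin
    probs <- dhyper(0:10, m, n, k)
    pOracle <- sum(probs[probs <= dhyper(10, m, n, k) * (1 + 1e-7)])
    expect_equal(res$p_value, pOracle, tolerance = 1e-10)

    # perfectly balanced independent table gives p = 1
    bal <- rbind(covRow(sprintf("p%02d", 1:10), "C", "G",
                        rep(c(TRUE, FALSE), 5), "kitA"),
                 covRow(sprintf("q%02d", 1:10), "C", "G",
                        rep(c(TRUE, FALSE), 5), "kitB"))
    expect_equal(kitAssociationTest(bal, "G", "C", "kitA")$p_value, 1)

    # degenerate margin: every sample insufficient
    deg <- covRow(sprintf("d%02d", 1:10), "C", "G", FALSE,
                  rep(c("kitA", "kitB"), 5))
    resd <- kitAssociationTest(deg, "G", "C", "kitA")
    expect_true(resd$degenerate)
    expect_true(is.na(resd$p_value))

    # BH adjustment spans the supplied gene set
    multi <- rbind(mixedKitCohort("G1"), mixedKitCohort("G2"))
    resm <- kitAssociationTest(multi, c("G1", "G2"), "KC", "CustomKit")
    expect_equal(resm$q_value, p.adjust(resm$p_value, "BH"))
})

test_that("statusMatrix reports sufficiency fractions and masks called cohorts", {
    ann <- rbind(covRow(sprintf("a%d", 1:4), "C1", "G1",
                        c(TRUE, TRUE, FALSE, FALSE)),
                 covRow(sprintf("b%d", 1:4), "C2", "G1", TRUE))
    tb <- buildCohortTable(mafRecords("G1", "b1"),
                           sprintf("b%d", 1:4), "C2")
    m <- statusMatrix(ann, list(tb))
    expect_equal(attr(m, "fractions")["G1", "C1"], 0.5)
    expect_equal(m["G1", "C2"], "not_considered")
    expect_equal(m["G1", "C1"], "0.5000")
})

test_that("kit table reader validates and deduplicates", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tcohort_id\tkit_name\tcenter",
                 "s1\tA\tk1\tBI", "s1\tA\tk1\tBI", "s2\tA\tk2\tWU"), p)
    k <- readKitTable(p)
    expect_equal(nrow(k), 2L)
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tcohort_id\tkit_name",
                 "s1\tA\tk1", "s1\tA\tk2"), p2)
    expect_error(readKitTable(p2), "conflicting")
})
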