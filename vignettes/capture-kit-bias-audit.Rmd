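---
title: "Auditing exome capture-kit coverage bias in tumor cohorts"
author: "captureBias package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing exome capture-kit coverage bias in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(captureBias))
```

## The problem

Whole-exome sequencing does not observe the exome directly: a capture
kit — a set of hybridization probes — pulls down the targeted fraction
of the genome before sequencing. A gene the kit's design omits receives
almost no reads in every sample prepared with that kit, and somatic
mutation callers, which need tens of reads to distinguish a variant
from noise, silently report nothing there. When different tumor
cohorts are sequenced with different kits, a gene can appear "mutated
in colon cancer but never in stomach cancer" purely because the stomach
cohort's kit never captured it. Such false negatives masquerade as
biology.

This package implements an audit that separates the two explanations.
It works backwards from the symptom (a cohort with zero calls in a gene
that is commonly mutated elsewhere) to the mechanism (insufficient read
depth, traced to the capture kit's probe design), and forwards from a
kit's design file to the set of genes any cohort using it cannot
reliably call.

## The audit, stage by stage

**Screen** (`screenCandidates`). Per cohort, a `CohortMutationTable`
records the roster and, per gene, the set of samples with at least one
non-silent call (`nonsilentClasses` holds the classification terms
counted as non-silent; every sample counts at most once however many
rows it contributes). A gene is a candidate when (a) its pooled
mutation rate over cohorts *with at least one call* is at least
`minRate` and (b) at least `minZeroCohorts` whole cohorts have zero
calls. The pooled rate (total mutated samples over total roster size
across non-zero cohorts) is the default because it weights cohorts by
the evidence they carry; a mean-of-cohort-rates variant is available
via `method = "mean"` for sensitivity analysis. Requiring several zero
cohorts protects against small cohorts where zero calls arise by
chance: at a 5% true rate a 40-sample cohort is empty with probability
$0.95^{40} \approx 0.13$, but three independent such cohorts only with
probability $\approx 0.002$.

**Coverage audit** (`filterAlignments`, `depthTrack`,
`callUndercoveredGene`, ...). Reads are filtered before any depth is
computed: duplicate-flagged reads, secondary and supplementary
alignments, and reads with mapping quality strictly below `minMapq`
are discarded. Depth at a base counts reference-consuming alignment
segments (CIGAR M/=/X), excluding deletions and skips, matching common
depth-tool semantics; overlapping mates both count, a simple contract
stated rather than hidden. Three rules then apply, each with an
explicit boundary:

| rule | statistic | boundary |
|---|---|---|
| sample sufficiency | average depth over the gene region | sufficient iff $\ge$ `minAvgDepth` (25x) |
| undercovered cohort | fraction of insufficient samples | undercovered iff $>$ `cohortInsufficiencyFrac` (0.75) |
| undercovered gene/exon | fraction of bases with cross-sample mean depth $>$ `baseDepthGt` (20) | covered iff $\ge$ `qualifyingFrac` (0.80) |

The 25x sufficiency threshold is the average depth at which a standard
somatic caller's sensitivity approaches 0.99 for an allele fraction of
0.3 — roughly a heterozygous mutation at the purity floor of large
tumor programs. "Minimum threshold" is read inclusively (25.0 is
sufficient); "over 75%" and "greater than 20" are strict. All
boundaries live in one `AuditThresholds` object and are echoed in the
header of every report the pipeline writes, so a report can always be
traced to the rules that produced it.

Undercovered genes split into two modes: `undercovered_absent`
(*no* base qualifies — the signature of a locus with no probes at all)
and `undercovered_incomplete` (some but fewer than 80% qualify —
partial tiling). The same per-fraction rule applies per exon
(`callUndercoveredExons`), with the cross-sample mean profile rather
than per-sample depth, for consistency with the gene-level rule.

**Design audit** (`coveredFraction`, `auditDesign`). Independently of
any sequencing data, a kit's BED design is compared base-by-base with
canonical exon (or CDS) models; the covered fraction takes the place of
the qualifying fraction in the same status taxonomy, so depth-based and
design-based audits are directly comparable (a test verifies they agree
on simulated data driven by the same design). In CDS mode, non-coding
genes cannot be scored and are excluded and counted rather than scored
as zero — exon-mode and CDS-mode denominators genuinely differ, and the
skip report makes the difference explicit. No padding is added around
targets by default (real capture recovers flanking bases; the audit
scores the design file as shipped), but a symmetric `pad` is exposed.

**Kit attribution** (`joinKits`, `kitSummary`, `kitExplains`).
Per-sample sufficiency joined with sample-to-kit metadata yields
cohort-by-kit insufficiency tabulations. `kitExplains` asks the sharp
question: within a cohort, does the set of insufficient samples
coincide exactly with the set of samples on one kit? Both containments
are reported separately. Samples missing from the metadata form an
explicit `"Unknown"` stratum so sample counts are conserved. An exact
2x2 association test (`kitAssociationTest`, Fisher, BH-adjusted across
genes) is provided as an optional extension; the audit's claims are
tabulations, and the test is clearly labelled as extra.

## The synthetic study

The generator (`simulationConfig`, `simulateStudy`) emulates exactly
the causal chain the audit is built to detect, with planted ground
truth at every link:

* a synthetic genome of non-overlapping multi-exon genes with
  UTR-trimmed CDS (default 100 genes, 900–3,000 exonic bases, 1–8
  exons, 5% non-coding);
* per-kit designs in three states: fully tiled, partially tiled
  (covered fraction uniform in 0.3–0.7), or absent (no probes);
* per-base depth with mean `meanOn = 100` on probe-covered bases —
  the on-target depth regime of large tumor sequencing programs —
  and `meanOff = 0.5` elsewhere, Poisson by default, negative
  binomial optionally;
* true mutation rates (default 10% per sample per gene) and step
  censoring: a call reaches the MAF only if the sample's average
  region depth reaches the 25x sufficiency threshold, treating
  sufficiency as full caller sensitivity. (A logistic sensitivity
  curve would smooth the step; the step is the audit's own working
  assumption and keeps planted truth crisp.)

The default study conditions are 6 cohorts of 200 samples, three on a
biased kit (5 probe-absent genes, 5 partially tiled) and three on a
complete kit. The partial range 0.3–0.7 is chosen so the two planted
failure modes stay distinct: a partially tiled gene at fraction $f$ has
expected average depth $100f + 0.5(1-f)$, and since the per-sample
average of thousands of per-base counts concentrates within a fraction
of a unit of its expectation, any $f$ near the censoring boundary
($f^* \approx 0.246$) would make the gene's "censored" status a coin
flip rather than a planted fact. Above 0.3, partial genes are reliably
callable (and detected by the *base-level* rules as incomplete), while
absent genes are reliably censored (and detected by both the screen
and the cohort rule). Mutation classifications are drawn uniformly
from the non-silent list; classification identity affects no audited
statistic.

**Aggregated sampling.** `simulateDepth` draws every base of every
sample. For cohort-scale runs, `simulateCohortDepthSummary` instead
draws the two statistics the audit actually consumes — each sample's
regional *total* depth and each base's cross-sample *total* — directly
from their exact distributions, using the identity that a sum of
independent Poisson variables is Poisson in the summed mean (and
same-dispersion negative binomials add in both mean and size). This is
not an approximation; it is the same generative model sampled at the
level of sufficient statistics, and a test verifies the two routes
agree distributionally.

What the simulation does *not* model: GC and sequence-composition
bias, fragment-size effects, mate overlap, alignment artifacts at
repeat loci, tumor purity and subclonality, and any correlation of
depth across neighboring bases. Passing the planted-truth suite
therefore demonstrates that the *audit logic* is correct under the
stated generative model — not that real capture data are this clean.
On real data the step from "undercovered" to "censored" is softer, and
borderline genes will behave stochastically in exactly the way the
partial-range choice above avoids by construction.

## Numerical and design choices

* **Coordinates.** All internal interval arithmetic uses
  `GRanges`/`IRanges` (1-based, closed), the native convention of the
  genomic-ranges stack; BED and depth-table dialects (0-based
  half-open; 1-based positions) convert at the I/O boundary. One
  internal convention, converted once per reader, eliminates off-by-one
  drift.
* **Touching intervals merge.** Adjacent probe targets are coalesced
  on read; base-overlap arithmetic is unaffected and no analysis here
  distinguishes adjacent probes.
* **Strand** is carried on gene models but ignored by all depth and
  overlap computations — sequencing depth is strand-agnostic.
* **Duplicate gene symbols** in annotation input are an error, never
  silently resolved: the audit assumes one canonical transcript per
  gene, and a symbol mapping to two loci (or two transcripts) must be
  resolved by the curator, not guessed by the code.
* **MAPQ 255** ("unavailable") passes the numeric filter; an aligner
  that refuses to state confidence is taken at face value rather than
  silently censored.
* **Determinism.** Every stochastic emitter takes a seed and restores
  the caller's RNG state; nested emitters derive child seeds from the
  parent stream, so one seed fixes the entire bundle byte-for-byte.
* **Validation problem sizes.** The test suite runs the planted-truth
  recovery at the full reference conditions (6x200 samples, 100 genes)
  over 20 seeds via the aggregated sampler, the per-base brute-force
  interval oracle at 1,000 random instances, and the per-base
  depth-route cross-checks at small (tens of samples, tens of genes)
  instances where the full per-base simulation is cheap.

## Limitations

The audit reasons at the level of average and per-base depth against
fixed thresholds; it does not re-call variants, model caller-specific
sensitivity curves, or correct for purity, and its cohort rule treats
samples as exchangeable within a cohort. Design audits score the BED
file as shipped; capture efficiency varies within targets in ways a
BED cannot express. Cross-assembly inputs are out of scope: all inputs
are assumed to be on one genome assembly, and liftover must happen
upstream.
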