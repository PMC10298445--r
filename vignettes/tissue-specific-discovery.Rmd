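---
title: "Discovering tissue-specific genes and promoters from FPKM atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering tissue-specific genes and promoters from FPKM atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsgenes)
```

## The problem

Crop genomics programmes routinely mine public expression atlases — one
FPKM value per gene per tissue, tens of thousands of genes, a handful of
tissues — for genes expressed in exactly one tissue. Such genes matter
twice over: they mark tissue identity, and their promoters are candidate
drivers for transgenes that must stay silent everywhere else. This
package implements that screen as a tested pipeline: a threshold-based
specificity caller, expression binning, enrichment testing of the called
sets, strand-aware promoter extraction, degenerate cis-element scanning,
and qPCR confirmation via the 2^−ΔCT method.

## The specificity model and its assumptions

The caller is deliberately the field's simple rule rather than a
continuous index (tau, entropy): gene *g* is specific for tissue *t*
when

* FPKM(g, t) > `high_threshold` (default 100 FPKM, strict), and
* FPKM(g, u) < `low_threshold` (default 10 FPKM, strict) for every
  other tissue *u*.

Since the high threshold exceeds the low one, at most one tissue can
qualify, so calls are unambiguous. The rule assumes a dense matrix with
one value per tissue — replicate libraries must be collapsed first
(`read_expression_matrix(group_map=)` averages them arithmetically), and
missing cells are a hard error rather than an imputation target.

Two boundary choices deserve note:

* **Silent off-targets.** A literal reading of "between 0 and 10 FPKM
  off-target" would exclude genes that are perfectly silent (FPKM = 0)
  outside their tissue — the most specific genes of all. The default
  therefore admits 0; `caller_config(off_target_strict_positive = TRUE)`
  restores the literal open interval.
* **Detection floor.** Genes never reaching 1 FPKM anywhere are reported
  as undetected rather than "not specific"; the floor is configurable
  because "minor expression" has no universal definition. The strict-`<`
  convention means a gene touching the floor exactly counts as detected.

### Binning

Calls are binned by target FPKM into 100–500, 500–1000, 1000–5000 and
\>5000. Published figures describe these as open intervals, which cannot
tile the axis; we use half-open bins `[a, b)` with boundary values
assigned upward, so every call above 100 lands in exactly one bin and
bin counts always sum to call counts. `bin_report()` divides any bin's
count by the call total to reproduce the percentage style of atlas
reports (e.g. 21 of 288 calls in 1000–5000 is 7.29%). When the caller
runs with a high threshold below 100 the bins are undefined for calls
under 100 FPKM; those get an `NA` bin rather than a silently invented
category.

### Heatmap preparation

`row_zscore()` standardises each gene to mean 0, sd 1 using the sample
(n − 1) standard deviation — the convention of R's heatmap tooling — and
maps constant rows to all-zero with a warning, since they carry no
pattern. `cluster_order()` returns the complete-linkage/Euclidean
dendrogram leaf order via `stats::hclust`, the exact algorithm behind
`pheatmap`'s row clustering; we return the order rather than a rendered
figure, keeping plotting a presentation concern. `hclust` is
deterministic, so leaf orders are reproducible across platforms;
merge-tie resolution follows `hclust`'s internal convention, which our
tests pin against a brute-force complete-linkage oracle on small
tie-free inputs.

## Enrichment

The test behind GO/KEGG enrichment reports is the one-sided
hypergeometric over-representation tail, computed with `stats::phyper`
and cross-checked in the tests against exhaustive enumeration for every
parameter combination with N ≤ 12. The significance flag uses the raw
p < α rule, because that is the rule such screens publish;
Benjamini–Hochberg adjusted values are always reported alongside and can
drive the flag instead. The background defaults to all annotated genes
and can be widened to the full matrix — the choice that most changes
published term lists, which is why it is explicit rather than implicit.
Ontology topology (DAG propagation) is out of scope: term membership is
taken as given.

## Promoters

"Promoter" here means the `length` bases (default 3000) immediately 5′
of the **translation** start — the first base of the representative
transcript's first CDS segment — not the transcription start; this is
the anchor used when promoters are cloned up to the ATG. On the plus
strand that is genomic `[cds_start − 1 − L, cds_start − 1)` (0-based
half-open); on the minus strand `[cds_start, cds_start + L)`
reverse-complemented. GFF3 coordinates (1-based closed) are converted at
the boundary and all outputs are BED-convention 0-based half-open.

* **Isoforms.** The representative transcript is the mRNA with the `.1`
  ID suffix, else the longest total CDS, else the lexicographically
  first — a deterministic rule for annotations that do not mark a
  canonical isoform.
* **Edges.** Windows running off a chromosome end are clipped and
  flagged `truncated`, never padded with N: padding would hand the motif
  scanner fabricated sequence context.

## Cis-element scanning

The scanner is written in the package rather than delegated, because its
semantics are the point:

* IUPAC degenerate matching: each consensus symbol admits its IUPAC set
  (K = G/T, W = A/T, …).
* A **sequence** N matches only a **consensus** N. This conservative rule
  means assembly gaps and masked bases can never create an element hit.
* Both strands are scanned (element databases report orientation-free
  occurrences); hits from the reverse-complemented consensus carry
  strand `-` at the same promoter coordinates, and a palindromic
  consensus matching a window both ways is counted once, as `+`.
* Overlapping occurrences all count — occurrences, not coverage.

The built-in library is a curated set of 11 experimentally characterised
tissue-specificity elements (seed, endosperm, embryo, pollen, fruit,
nodule, root-hair, anther/meristem classes); `load_motif_table()`
accepts arbitrary replacements. The tests check the scanner against an
independent oracle that expands every degenerate consensus into its
concrete words and string-searches both strands.

## qPCR validation

Relative expression is 2^−ΔCT with ΔCT = Ct(gene) − Ct(reference),
paired per replicate within a tissue; no amplification-efficiency
correction is applied (plain 2^−ΔCT, not Pfaffl or ΔΔCT). Comparisons
run on log2-transformed values — the scale qPCR figures plot, and the
one on which Ct noise is approximately additive — using the classic
equal-variance two-sample Student's t-test (`var_equal = FALSE` switches
to Welch). A prediction is confirmed when its tissue has the strictly
highest mean relative expression among detected tissues *and* every
pairwise comparison is significant at α. Tissues where the gene is
entirely non-detected contribute no comparison and cannot defeat
specificity — absence of signal off-target is evidence *for*
specificity, not missing data. Zero-variance ties are resolved without a
test (p = 1 for equal means, 0 otherwise) so degenerate noiseless
simulations behave sensibly.

## What the synthetic data emulates — and what it does not

The generator reproduces the *structure* of a real atlas screen at its
published scale: by default 56,044 genes over nine tissues, 288 planted
specific genes distributed 117 flower / 99 seed / 40 root / 21 leaf /
3 stem / 2 nodule, and 3,731 undetected genes. Planted target FPKM is
log-uniform on [150, 20000], populating all four bins including the
\>5000 extreme-expression tail seen for seed genes; off-target FPKM is
uniform on [0, 8]; undetected genes sit below 0.5 FPKM; background genes
draw skewed log-normal profiles constrained to violate the calling rule
in one of three ways (two high tissues, a leaky off-target in [10, 90],
or everything moderate). These margins — at least 1.25× clear of every
threshold — are what make planted truth *exactly* recoverable, and that
is the limit of what passing tests show: they certify the
implementation, not the biological truth of the 100/10 rule. Real data
have genes hovering at thresholds, correlated tissues, and batch
structure that no planted margin models. Likewise the toy genomes are
i.i.d. sequence with two-exon ATG-initiated genes on alternating
strands; they exercise coordinate arithmetic and strand handling, not
genome composition. Ct tables use additive Gaussian cycle noise
(default 0.2 cycles) around a planted fold-change, with the housekeeping
reference at Ct ≈ 20.

The validation experiment simulated by `scripts/acceptance.R` uses 12
predicted genes, 10 planted truly specific at 64-fold excess and 2
planted with their peak elsewhere, 3 replicates — a design whose correct
analysis confirms exactly 10/12 (83.33%); with 0.2-cycle noise and
64-fold margins the outcome is stable across seeds (checked over 100
seeds in the suite).

## Problem sizes and numerical choices

The test suite runs everything at small scale (catalogs of 300–3,000
genes, 10-kb scanner sequences, 6-gene toy genomes) plus one full-scale
56,044-gene detection-filter run, keeping the default suite under a
minute while still exercising the published catalog size. Matrix
round-trips serialise at 17 significant digits so doubles survive
exactly. All generators are pure functions of their seed, and each draws
from its own seeded stream so modules can be tested in isolation.
`run_pipeline()` is deterministic given its inputs: reruns are
byte-identical, which the suite asserts file by file.

## Known limitations

* The caller is a hard-threshold rule; genes at 99 or 11 FPKM fall off a
  cliff. Continuous specificity indices are deliberately out of scope.
* Enrichment ignores term topology and treats terms independently.
* Promoters are anchored on the ATG; genes with long 5′ UTRs will
  include transcribed sequence in their "promoter".
* The motif scanner is consensus-based (exact set membership), not a
  PWM/log-odds model, matching the element-database convention it
  reproduces.
* Replicate structure in qPCR (technical vs biological) is not
  distinguished; replicates are exchangeable units in the t-test.
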