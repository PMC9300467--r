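---
title: "Microenvironment-constrained cell-cell communication and TF prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microenvironment-constrained cell-cell communication and TF prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccomm)
```

This vignette documents the statistical model behind `sccomm`, the
parameters that matter, the synthetic study conditions the tests run under,
and the design decisions taken where reasonable alternatives existed. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute themselves.

## The retrieval model

An interaction database consists of *partners* — single genes, heteromeric
complexes with several member genes, or enzyme proxies standing in for
non-peptide ligands via the last bona fide enzyme of their biosynthesis
pathway — and curated ligand–receptor pairs over those partners. Retrieval
evaluates every ordered (sender, receiver) cell-type pair, including
autocrine pairs, against four gates:

1. **Detection fraction** (`min_fraction`, default 0.10, *inclusive*): every
   member gene of the ligand-side partner must be detected (raw count > 0)
   in at least 10% of sender cells, and likewise the receptor side in the
   receiver. "At least 10%" is inclusive language, so a fraction of exactly
   0.10 passes. Detection is evaluated on raw counts, not normalized values,
   matching how detection fractions are used in ligand–receptor practice.
2. **Differential expression** (`de_padj_max` 0.01, `de_log2fc_min` 0.2,
   both *strict*): at least one member gene of either partner must be a DE
   gene in its own cell type. "Below 0.01" and "above 0.2" are strict
   inequalities, so values exactly at the threshold fail. By default the DE
   gene must be DE specifically in the cell type where its partner is
   evaluated; `de_any_type = TRUE` relaxes this to DE in any type, since the
   stricter reading is an interpretation rather than a stated rule.
3. **Shared zone**: cell types carry sets of spatial zones (default
   vocabulary: `outer_cortex`, `inner_cortex`, `medulla`); an interaction
   survives iff the sender's and receiver's zone sets intersect. The filter
   only runs when a microenvironment table is supplied — analyses of tissues
   without zonal structure simply omit it — but when it runs, a cell type
   missing from the table is an error rather than a silent pass-through.
4. **Downstream-TF support**: a curated receptor→TF table is joined to the
   results; an interaction is `supported` when at least one TF downstream of
   its receptor is prioritized (see below) in the receiver type. "Active TF"
   is operationalised as "prioritized by the TF analysis in the receiver
   type"; support is an annotation, never a filter.

Directed interactions evaluate partner A as the ligand in the sender;
undirected interactions are tested in both orientations. The
permutation-based null model familiar from other ligand–receptor tools is
deliberately out of scope: this package implements the DEG-based variant
only.

## Differential expression machinery

All three evidence layers share one engine: a one-sided ("greater in the
in-group") Wilcoxon rank-sum test of each feature in each group against all
remaining cells pooled. Midranks handle ties. For small tie-free samples
(n + m ≤ 10) the p-value comes from the exact Mann–Whitney null
distribution; otherwise a normal approximation with tie and continuity
correction is used — at one-vs-all sample sizes the exact path is never
reached in practice, but it anchors the test suite to an enumeration oracle.
When every observation is tied the statistic is uninformative and p = 0.5 by
symmetry.

P-values are adjusted across features within each group. The default is
Bonferroni, matching the default of the widely used marker-detection
implementation this machinery mirrors; Benjamini–Hochberg is selectable
(`adjust_method = "bh"`). The upstream method statement names the test but
not the correction, so the choice is explicit and recorded in the run
configuration.

Fold changes on expression use the back-transformed convention
`log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` with pseudocount
1 — the dominant ecosystem convention; a "difference of log means / ln 2"
mode is available. For z-scored activity matrices a fold change is
undefined, so the effect size there is the difference of group means on the
z scale (`lfc_method = "meandiff"`), and the 0.75 activity threshold is
interpreted on that scale.

## TF prioritization

For each (TF, cell type): `prioritized = expr_pass AND (regulon_pass OR
motif_pass)`, with expression gates log₂FC > 0.5, adjusted P < 0.01 and
activity gates effect > 0.75, adjusted P < 0.01 (all strict). A missing
motif modality yields `motif_pass = FALSE`, not missing — prioritization
then rests on the regulon evidence alone.

**Regulon activity.** Gene signatures are per-gene z-scores across cells;
a TF's activity is `Σ mode·weight·z / sqrt(Σ weight²)`. This is a
deliberate simplification of the two-tailed GSEA-like enrichment used by
regulon tools: activity here feeds only a ranked one-vs-all test, and the
signed weighted mean preserves that ranking under the synthetic model while
being exactly testable in closed form. Regulons need ≥ 5 usable targets
(configurable); smaller ones are excluded loudly.

**Motif deviations.** For a peak set S and cell c,
`expected = (total accessibility of S across all cells) × (cell c's
fragments / all fragments)` and `y = (obs − expected)/expected`. Each motif
is compared with `n_background` (default 50) matched background sets: each
motif peak is matched to a nearest neighbour in the standardized
(GC content, mean accessibility) plane, sampled without replacement within a
set, seeded. The reported score is `(y_obs − mean(y_bg)) / sd(y_bg)` per
cell. Sampling from a k-nearest-neighbour pool (default `2 × n_background`)
rather than Mahalanobis bins or k-means is a simpler scheme with the same
intent; motifs whose background deviations are degenerate are dropped with a
warning. Motif→TF mapping is 1:1 in the synthetic data; many-to-one motif
families should be collapsed upstream (e.g. by max score) before
prioritization.

**Peak QC.** Peaks are dropped when they overlap a blacklist interval by
≥ 1 bp, when their width (end − start, 0-based half-open) falls outside
210–1,500 bp, or when they are accessible in < 4% of the cells of every
cluster. The width and fraction bounds are inclusive at 210, 1,500 and 4%:
the source phrasing ("outside the range", "less than 4%") excludes only the
strict outside.

## Cell and gene QC, normalization

Genes detected in fewer than 3 cells are removed first (the rules are stated
gene-first, and order changes results at the margin — a cell's detected-gene
count is evaluated on the gene-filtered matrix). Then cells are removed when
they detect fewer than 500 genes, exceed 20% mitochondrial content, or
jointly exceed 10% mitochondrial content with fewer than 1,500 counts.
Mitochondrial genes are recognised by a configurable identifier prefix
(default `"MT-"`) since naming is species-dependent; the mouse-style
variants (2,000 genes, 5%) are reachable through the same thresholds object.
Normalization is `value = ln(count/total × 10⁴ + 1)`, i.e.
log(CPM/100 + 1), natural log, recorded in the matrix provenance.
`qc_filter` is idempotent and aborts (with per-rule counts) if it would
remove every cell.

## The synthetic study conditions

The generator's defaults are the conditions the whole test battery runs
under: 6 cell types × 300 cells × 1,500 genes; negative-binomial counts with
variance mu + 0.5·mu²; per-gene baselines log-normal around 1 count/cell;
per-cell library factors log-normal(0, 0.3) so CPM normalization is
non-trivial; planted interaction log₂FC = 2; regulon effect = 1 natural-log
unit on target means (signed by regulation mode); motif effect = +0.3
accessibility probability; 1,000 peaks, 50 background sets. Ligand/receptor
role genes sit at 5% of the baseline scale so their detection fraction is
safely below the 10% gate outside their planted types, and marker genes are
near-absent outside their own type — planted effects are meant to be
recovered exactly, and decoys rejected exactly, under these settings.

Decoys exercise the two gates independently: *zone-mismatch* decoys are
fully planted interactions whose sender and receiver occupy disjoint zones
(only the microenvironment filter can remove them), and *sub-fraction*
decoys upregulate the ligand but leave the receptor below the detection
gate everywhere. Effects of exactly zero plant nothing, which is how null
datasets are built; a planted interaction effect in (0, 0.2] is rejected
outright because it would be logically indistinguishable from the
sub-threshold decoy regime. Each planted TF gets both a regulon and a motif
planted in the same cell type, and each planted receptor is linked to the
TF planted in its receiver, so CellSign support is expected to be TRUE for
every planted interaction.

What the generator does *not* emulate — and hence what passing tests do not
certify on real data: doublets, ambient RNA, batch effects, realistic
gene–gene correlation structure, zonal gradients within a cell type,
mitochondrial content (synthetic cells carry none, so the mito rules are
exercised on constructed fixtures instead), and genuine motif position
weight matrices (peak×motif annotations are inputs, not computed from
sequence).

## Numerical and determinism choices

All coordinates are 0-based half-open (width = end − start). Output tables
are sorted over all columns and doubles printed with 17 significant digits,
so identical runs are byte-identical; the acceptance tests verify this both
within a session and across two R sessions. Every stochastic stage
(simulation, background sampling) takes an explicit integer seed; the
pipeline re-seeds each stage from its configuration rather than relying on
ambient RNG state. Ties in TF-IDF marker ranking break by gene identifier.
Degenerate cases fail loudly rather than silently: zero-total cells in
normalization, empty surviving peak sets, regulons below the size floor,
cell types missing from the zone table.

## Problem sizes used by the test suite

Unit tests run on 4 types × 80–150 cells × 400–500 genes with 300 peaks and
10–25 background sets — large enough for every planted effect to clear its
gate with margin, small enough that the full suite and the acceptance
script each complete in a few minutes on one core. The acceptance tests use
the full default conditions above: 20 null seeds for type-I control, 10
planted seeds for recovery, and 50 background sets for the deviation-null
calibration.

## Known limitations

- The regulon score is a linear signed mean, not a two-tailed enrichment;
  regulons dominated by repressed targets with strong mutual correlation
  may rank differently than under the GSEA-like score.
- Activity "fold change" thresholds are applied to z-scale mean differences;
  comparisons with pipelines using expm1-style fold changes on activities
  need the `lfc_method` switch.
- One-vs-all DE uses the normal approximation at realistic sample sizes;
  exact inference is only engaged for tiny tie-free groups.
- The retrieval is threshold-based by design (no permutation p-values for
  interaction specificity).
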