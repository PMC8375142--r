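---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rnaevi` automates the downstream stage of bulk RNA-seq analysis: from a
sample sheet, a normalized expression matrix (EM), differential tables (DE)
and annotation databases to statistics, plots, re-runnable scripts and
reports. This vignette records the models, the parameters that matter, the
numerical conventions, and the design choices made where the design was
genuinely open — in more detail than the user-facing help pages.

## The master gene table

All workflows read a single per-gene join of: expression per sample, mean
per group, per-gene z-scores, annotation (symbol, chromosome, biotype), and
per-comparison statistics with a call in `{up, down, ns, untested}`.

* **Calls.** `up` iff adjusted p < threshold and log2FC > +t; `down` iff
  adjusted p < threshold and log2FC < −t; `untested` when the gene is
  absent from that DE table or its adjusted p is missing; `ns` otherwise.
  Defaults: adjusted p < 0.05, |log2FC| > 1, overridable per comparison.
  `untested` genes are excluded from significant-gene analyses but remain
  in the ORA universe, since they were measured.
* **z-scores** are computed per gene over *all* samples of the run (not per
  workflow instance), so that every workflow shares one scale; genes with
  zero variance get an all-zero z row rather than NaN. The input format
  does not fix where z-scores should be scoped, so this is a package
  decision, kept in one place.
* **Identifier policy.** EM, DE and background files are joined on the gene
  id exactly (case-sensitive), because annotation-database ids are stable;
  GMT and TRRUST databases are matched by *symbol*, case-insensitively,
  because curated databases use symbols with inconsistent capitalisation.
  Duplicate ids keep the first occurrence with a warning — deterministic
  and auditable.

## Statistical modules

**ORA.** Hypergeometric upper tail `P(X ≥ k)` for overlap `k` between a
query of size `n` and a set with `K` members in a universe of `N`, BH
correction across sets, enrichment ratio `(k/n)/(K/N)`. The universe is the
set of measured genes carrying a symbol — the genes that *could* have been
in the query. Sets are intersected with the universe first and kept when
`3 ≤ K ≤ 2000` (standard practice; small sets are untestable, huge sets
uninformative). The tail probability is delegated to `stats::phyper`, which
computes in log space; tests verify agreement with direct
binomial-coefficient enumeration to 1e−12 over all universes up to 60.

**URA.** Per regulator: the regulon ∩ universe is tested for overlap with
the significant genes (hypergeometric + BH across regulators), and the
activation z-score is computed from signed agreement:
`z = (consistent − inconsistent)/√(consistent + inconsistent)`, with
`z = 0` when no signed significant target exists. Unknown-mode edges count
toward the overlap (the target is regulated) but not toward z (they carry
no sign). Enrichment and activation are reported separately: a regulator
can be significantly enriched yet neither activated (z > 2) nor inhibited
(z < −2). Edges are unweighted.

**Spatial.** Three two-sided Fisher families per chromosome — expression
bias among annotated genes, differential bias *conditioned on expressed
genes* (so expression-level composition does not masquerade as differential
bias), direction bias among significant genes — each BH-corrected across
chromosomes. "Expressed" means mean expression above a threshold
(default 1, in the EM's own units; tunable because normalization units
differ). Genes without a chromosome are excluded from all three families
only.

**Overlap.** For lists A and B in universe N: expected overlap
`|A||B|/N`, enrichment observed/expected, hypergeometric p. Used pairwise
in the MDE workflow as Venn statistics.

**Shared-gene networks.** Nodes are significant rows (adjusted p < 0.05);
node size is the overlap count and intensity −log10 p; an edge joins nodes
sharing more than 50% of their genes. The denominator is the *smaller*
overlap set: "more than half shared" is ambiguous between the two set
sizes, and the smaller-set convention is symmetric and matches the visual
intent of linking similar hits. The layout is a fixed circle computed at
emission time, so scripts redraw without a layout engine and re-runs are
identical.

## Differential expression signatures

1. **Bin** all genes significant in ≥ 1 comparison by their call profile
   (at most `3^m − 1` bins for m comparisons; everywhere-ns genes are
   excluded; `untested` is treated as `ns` for profile purposes).
2. **Summarise** each bin by a meta-gene: the per-sample median of member
   z-scores (median, not mean, for robustness to stray members).
3. **Merge** iteratively: compute all pairwise Spearman correlations of the
   current meta-genes; while the maximum exceeds the SCC threshold
   (strictly), merge that pair, recompute the meta-gene *from the union of
   member genes* (the alternative — averaging the two meta-genes — would
   let early merges dominate later ones), and log the merge.

The threshold defaults to 0.9: high enough that only bins tracking the same
underlying pattern merge, low enough to absorb profile fragmentation caused
by borderline calls. A threshold of 1 can never be exceeded strictly, so it
yields maximal resolution (no merges) — useful when every distinct profile
matters. Ties on the maximal correlation are broken by the
lexicographically first pair of profile labels (determinism). With fewer
than three samples rank correlation is meaningless; the bins are returned
unmerged with a warning. Bins of size 1 are legal signatures (no arbitrary
floor). Signatures are ranked by member count, id 1 the largest.

## Clustering and PCA conventions

* **UPGMA with mean reordering.** Heatmap rows are clustered with
  average-linkage (UPGMA) agglomeration under a `1 − Spearman` distance.
  The implementation is written out (Lance–Williams size-weighted update)
  rather than delegated, because two conventions needed fixing exactly:
  ties in the minimum distance are broken toward the pair containing the
  lowest original row index, and the displayed leaf order applies *mean
  reordering* — at every internal node the subtree whose rows have the
  lower mean of row-means is placed first, so low-expression blocks sink
  to one side deterministically. Tests verify the merge heights and
  cluster composition against both a brute-force oracle (exhaustive
  recomputation of average distances each step) and `hclust(method =
  "average")`. Rows with zero variance have undefined correlation; their
  distance is fixed at 1 (with a warning) to keep the clustering total.
* **PCA.** Samples are projected by SVD of the per-gene mean-centred
  `log10(x + 1)` matrix — the standard transform for normalized expression;
  no unit scaling, so high-variance genes keep their weight. Percent
  variance sums to 100 by construction; tests check scores against a
  direct SVD oracle up to sign (sign is not identifiable).
* **Exact tests.** Two-sided Fisher p-values follow the classical
  convention: the sum of table probabilities not exceeding the observed
  probability (with the usual 1 + 1e−7 relative tolerance for floating
  ties). BH adjustment passes missing values through and counts only
  observed p-values as tests.

## The plot registry and the script engine

The catalogue of emitted visualisation types is a versioned manifest
(`inst/registry/plot_types.tsv`) with pinned per-category counts — quality
control 1, expression 7, differential expression 33, multiple differential
expression 9, 50 in total — under fixed counting rules: parameter-only
variants (labelled/unlabelled) count once; clustered and unclustered
heatmaps of the same data count once each; ORA visual types count once
regardless of database. The five DE summary-table renders are the top-up,
top-down, comparison-summary, ORA and URA tables. Tests pin these sums, so
any registry edit is a deliberate, reviewed change.

Every plot script is composed from a central bin of small snippets: a
master config lists each workflow's steps; a per-step config lists that
step's snippets in order; snippets carry `{{tag}}` placeholders (thresholds,
group names, file paths) substituted at composition time — an unresolved
tag is a build error naming the tag and step. Shared snippets (theme,
visual parameters, save function) appear in every script, so editing one
snippet file restyles every plot the pipeline will ever emit. The combined
per-workflow script contains the shared block once, then each plot's
load/plot/save section; because plot scripts re-read their saved data files
and fix the jitter seed, per-plot and combined runs produce byte-identical
images. Scripts resolve paths relative to their own `scripts/` directory
and are meant to be run from there.

Tables are rendered as text-grid images so that every registry type yields
an image artifact; the data file *is* the table. Reports embed PNGs as data
URIs, making each report a single portable file.

## The synthetic-data generator

The generator emulates the package's inputs with planted, machine-readable
truth; it is first-class, tested code.

* **Model.** Per-gene baseline log10 expression ~ Normal(1.5, 1) (spanning
  roughly 0.3–300 expression units, a plausible dynamic range for
  normalized bulk RNA-seq); planted genes add per-group shifts implied by
  their call profile (|log2FC| default 2, converted to log10); per-sample
  Gaussian noise (sd 0.25 on the log10 scale) on top.
* **Self-consistency.** The DE tables are *computed* from the generated EM
  (per-gene Welch t-test on log10 values, BH-adjusted), never invented
  separately, so MA/volcano/fold-vs-fold views can never contradict the
  expression data. The cost is honesty about power: with 3 replicates a
  t-test has ~4 degrees of freedom, and weakly planted genes will not all
  be recalled — which is exactly how real small-n experiments behave.
* **Databases.** Enriched gene-sets draw 75% of their members from the
  planted significant genes of the first comparison; null sets draw
  uniformly. Activated regulators point Activation edges at planted-up
  genes and Repression edges at planted-down genes (consistency fraction
  configurable; the remainder are planted inconsistent); inhibited
  regulators mirror this.
* **What it does not emulate.** Count-level noise (negative-binomial reads,
  library-size effects), batch effects, correlated gene modules beyond the
  planted ones, or any real organism's annotation. Passing tests therefore
  demonstrate algorithmic correctness and calibration on idealised data,
  not biological validity on any particular dataset.

### Study-condition choices (fixed a priori by power analysis)

* **Demonstration bundle** (`generate_minimal_demo`): 3 groups × 3
  replicates, 1200 genes, four planted profiles of 40 genes, |log2FC| = 4,
  noise sd 0.15, five enriched + 25 null gene-sets, 3 + 2 + 5 regulators.
  With n = 3 per group the Welch t has ≈ 4 degrees of freedom; at these
  settings the per-gene effect size (≈ 9.8 standard errors) makes planted
  genes reliably callable at adjusted p < 0.05 — the weakest effect for
  which a 3-replicate demonstration actually demonstrates the workflows.
* **Signature-recovery fixture**: 3 groups × 10 replicates, 180 genes,
  four planted profiles of 40 genes, |log2FC| = 4, default noise, calls at
  adjusted p < 1e−4. Exact-count recovery is fragile by construction: one
  false positive null gene, or one planted gene missing its call in a
  single comparison, creates a spurious partial-profile bin. The settings
  were chosen so both error rates are near zero per run (expected false
  positives ≈ 0.004; per-gene, per-comparison miss probability < 1e−5),
  and so that between-profile meta-gene correlations (~0.2) sit far below
  the 0.9 merge threshold.
* **ORA calibration fixture**: universe 2000, 100 null sets of size 200,
  random query of 500. Large sets make the discrete hypergeometric null
  near-uniform, so the raw p < 0.05 rate is interpretable as a calibration
  check (~0.04; a small-set design would be conservative by discreteness,
  not by miscalibration).

## Problem sizes and degenerate inputs

The shipped demonstration run (1200 genes, 9 samples, 2 DE + 1 MDE + 1 NE
instance, ~95 artifacts at 300 dpi PNG + SVG) completes in about two
minutes on one core well within 1 GB of memory; recovery suites use 50
seeded fixtures of 180–2000 genes each. These sizes were chosen to make the
full statistical surface exercisable at interactive speed.

Degenerate inputs are first-class: a comparison with zero significant genes
still emits every plot type (empty-state data files and notes in the
report), empty ORA/URA results produce empty bars and networks rather than
errors, constant genes get zero z rows and unit correlation distance, and a
run whose inputs are missing fails before any analysis with one
consolidated error listing every problem.

## Known limitations

* ORA treats gene-sets as flat lists; no ontology-aware redundancy pruning
  and no rank-based enrichment (GSEA-style) analysis.
* URA's z is unweighted; literature-confidence weights are not used.
* The spatial analysis uses chromosome names only — no positional
  clustering within chromosomes.
* Signature assignment is hard: each gene belongs to exactly one profile
  bin, and genes are not re-assigned after merging.
* Reports are static HTML; the emitted scripts are the supported route for
  plot customisation.
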