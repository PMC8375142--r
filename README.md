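# rnaevi

Automated **e**xploration, **v**isualisation and **i**nterpretation (EVI) of
bulk RNA-seq results.

Once an RNA-seq experiment has been processed — reads aligned, counts
normalized, differential tables produced by DESeq2, edgeR or similar — the
remaining work is downstream: quality overviews, PCA, heatmaps, volcano
plots, pathway and regulator analysis, multi-comparison signatures, and the
collation of all of it into figures a reader can interpret. Done by hand in
R this takes days. `rnaevi` automates it as a single command for
bioinformaticians, sequencing service providers and bench scientists. It is
strictly downstream: it performs no alignment, counting, normalization or
differential testing.

## What it computes

From a tab-delimited sample sheet, a normalized expression matrix (any
unit: FPKM/TPM/rlog), one or more differential tables, a Biomart-style
genome background file and optional GMT / TRRUST-format databases, the
package builds a single **master gene table** (expression, per-group means,
per-gene z-scores, annotation, and per-comparison log2 fold change / p /
adjusted p / call) and runs three workflows, any number of instances each:

* **NE (normalized expression)** — per-sample expression distributions,
  PCA (scores and % variance), sample–sample Spearman correlation heatmap,
  highly expressed gene tables and violins.
* **DE (differential expression)** — one contrast: up/down counts, MA and
  volcano plots, clustered/unclustered significant-gene heatmaps, top-gene
  tables and violins, per-chromosome (spatial) Fisher tests, and pathway
  analysis.
* **MDE (multiple differential expression)** — two or more contrasts:
  overlap (Venn) statistics, fold-versus-fold scatter plots, union
  heatmaps, and differential expression signature analysis.

The statistical core:

* **Over-representation analysis (ORA).** For a query list of `n` genes in
  a universe of `N`, a set with `K` members and overlap `k` is scored with
  the hypergeometric upper tail `P(X ≥ k)`, `X ~ Hypergeom(N, K, n)`, with
  Benjamini–Hochberg correction across sets and enrichment ratio
  `(k/n)/(K/N)`.
* **Upstream regulator analysis (URA).** Each regulator's regulon is tested
  for overlap with the significant genes (hypergeometric + BH), and its
  activation state is scored with the activation z-score
  `z = (consistent − inconsistent) / √(consistent + inconsistent)`,
  where a significant target is *consistent* when the edge mode agrees with
  the observed direction (Activation∧up or Repression∧down). `z > 2`
  declares activation, `z < −2` inhibition.
* **Spatial analysis.** Per chromosome, three families of two-sided Fisher
  exact tests (expression bias, differential bias among expressed genes,
  up/down direction bias among significant genes), BH-corrected within each
  family.
* **Signatures.** Genes significant anywhere are binned by their
  per-comparison call profile; each bin is summarised by a **meta-gene**
  (per-sample median of member z-scores); the two most correlated
  meta-genes (Spearman) are merged and recomputed, iteratively, until no
  pair exceeds the SCC threshold (default 0.9; a threshold of 1 yields
  maximal resolution, i.e. no merging).
* **Clustering.** Heatmap rows are ordered by UPGMA (average-linkage)
  clustering under a `1 − SCC` distance with *mean reordering*: at every
  node the subtree with the lower mean of row-means is placed first.

Every plot is emitted three ways: the exact data drawn (TSV), a standalone
re-runnable R/ggplot2 script composed from a central snippet bin, and the
image (PNG + SVG). A combined per-workflow script regenerates all plots at
once, so one edit (e.g. the font) restyles everything. Each workflow
instance gets a self-contained HTML report with a hyperlinked sidebar and
collapsible description/legend/methods/code sections.

## Worked example

No downloads are needed: the package ships a synthetic-data generator with
planted ground truth.

```r
library(rnaevi)

# a 3-group (LP / ML / MLN), 3-replicate bundle with planted signal
bundle <- generate_minimal_demo("demo_inputs", seed = 101)

cfg <- run_config(
  sample_sheet = bundle$paths$sample_sheet,
  em           = bundle$paths$em,
  background   = bundle$paths$background,
  de_tables    = as.list(bundle$paths$de),
  comparisons  = list(
    list(name = "ML_vs_LP",  test = "ML",  ref = "LP", de = "ML_vs_LP"),
    list(name = "MLN_vs_ML", test = "MLN", ref = "ML", de = "MLN_vs_ML")
  ),
  workflows = list(
    list(kind = "NE"),
    list(kind = "DE",  comparison  = "ML_vs_LP"),
    list(kind = "MDE", comparisons = c("ML_vs_LP", "MLN_vs_ML"))
  ),
  gmt = bundle$paths$gmt, trrust = bundle$paths$trrust, seed = 7
)
run <- run_pipeline(cfg, "demo_results")
```

On this bundle the run prints, per workflow, lines such as

```
workflow ne1 (NE): 8 plot artifacts
workflow de1 (DE): 33 plot artifacts
workflow mde1 (MDE): 21 plot artifacts
```

and `demo_results/` then contains `master_gene_table.tsv`, `manifest.json`,
one directory per workflow instance (`data/`, `scripts/`, `plots/`,
`report.html`) and an `index.html`. Inspecting the analysis files:

```r
ura <- read.delim("demo_results/de1/data/de1_ura_results.tsv")
head(ura[, c("regulator", "k", "activation_z", "adj_p", "state")])
#>   regulator  k activation_z        adj_p     state
#> 1  INHREG02 14    -3.207135 4.222839e-12 inhibited
#> 2  ACTREG01 13     3.050851 1.288747e-10 activated
#> 3  ACTREG03 12     2.886751 2.416715e-09 activated
```

The planted activated regulators come out with activation z-scores above 2
(`activated`), the planted inhibited ones below −2, and the planted
enriched gene-sets lead the ORA table — i.e. the pipeline recovers exactly
the structure the generator planted. Every file in `plots/` can be
regenerated by running its script in `scripts/` (they read only the saved
data files), and `scripts/<instance>_all_plots.R` regenerates a whole
workflow.

A shell entry point wrapping the same functions is included:

```sh
Rscript inst/cli/rnaevi.R --generate-demo demo_inputs --seed 101
Rscript inst/cli/rnaevi.R --config run.yaml --out results
```

## Scope

Emitted scripts and reports are static; there is no GUI, no interactive
plot editor, and no upstream processing (QC, alignment, counting,
differential testing or batch correction).
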