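# gsforge

Contrast-data management, gene-set extraction and enrichment analysis
for transcriptomics.

## The problem

A differential-expression analysis (limma, edgeR, DESeq2, ...) ends in a
*contrast* table: per gene or probe, an effect size **M** (e.g. log2 fold
change), an average signal **A**, a significance level **P** (p-value or
FDR) and a statistic **S** (e.g. moderated t). Those tables are where
most pipelines stop — and where comparative biology starts. gsforge
treats them as first-class, durable objects: it ingests them in a simple
tab-delimited format (idMAPS), maps any source-ID space (probe sets,
gene symbols, Entrez IDs) onto genes, collapses multi-probe measurements,
automatically distils each contrast into **UP** (up-regulated), **DN**
(down-regulated) and **AR** (all-regulated, UP ∪ DN) gene sets inside a
versioned knowledge base, and turns contrasts and gene-set collections
into enrichment results that can be compared across experiments.

The analytical core is authored in the package:

* **Preranked GSEA** — for a gene set with $N_H$ of $N$ ranked genes, the
  running statistic gains $|r_j|^p/\sum_{\text{hits}}|r_j|^p$ at members
  and loses $1/(N-N_H)$ at non-members; the enrichment score ES is the
  signed maximum deviation, normalized (NES) and assessed against a
  seeded gene-permutation null with sign-stratified FDR q-values and
  leading-edge extraction.
* **ORA** — hypergeometric upper tail $P[X \ge k]$ of the overlap between
  a DEG list and each gene set within an explicit universe, with
  Benjamini–Hochberg FDR across the collection.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()`
accessors, `autoplot()`/`plot_running_sum()` graphics, deterministic
under explicit seeds.

## Worked example

```r
library(gsforge)

# synthetic annotation + a two-contrast dataset with 50 planted genes
tab <- make_mapping_table(n_genes = 200, seed = 1)
ds  <- make_contrast_dataset(tab, n_contrasts = 2, n_significant = 50, seed = 2,
                             dataset_name = "DEMO")

mc <- map_and_collapse(ds, tab, strategy = "best_p")
mc$report
#> <mapping_report> (mapping version synthetic-1, strategy best_p)
#>   input rows         398
#>   unmapped rows        0
#>   multi-mapped         0
#>   via synonym          0
#>   collapsed genes    132
#>   output genes       200

sets <- extract_gene_sets(mc$dataset)
attr(sets, "report")
#> # A tibble: 6 × 6
#>   dataset contrast suffix emitted  size reason
#>   <chr>   <chr>    <chr>  <lgl>   <int> <chr>
#> 1 DEMO    C1       UP     TRUE       30 ""
#> 2 DEMO    C1       DN     TRUE       30 ""
#> 3 DEMO    C1       AR     TRUE       60 ""
#> 4 DEMO    C2       UP     TRUE       25 ""
#> 5 DEMO    C2       DN     TRUE       26 ""
#> 6 DEMO    C2       AR     TRUE       51 ""
```

398 probe rows collapse to one row per gene (200); of the 50 planted
genes, 30 + 30 pass the default FDR ≤ 0.05 filter in contrast C1 (the
counts differ between contrasts because noise is redrawn). AR always
partitions as |AR| = |UP| + |DN|.

Enrichment of C1's ranked list against the extracted sets:

```r
rl  <- create_ranked_list(mc$dataset, "C1", metric = "S")
res <- gsea_preranked(rl, sets, gsea_params(seed = 3, n_permutations = 1000))
dplyr::arrange(dplyr::select(tidy(res), set_name:rank_at_max), fdr_q)
#> # A tibble: 6 × 7
#>   set_name      size     es   nes p_value  fdr_q rank_at_max
#>   <chr>        <int>  <dbl> <dbl>   <dbl>  <dbl>       <int>
#> 1 DEMO_[C1]_UP    30  1      2.79 0.00187 0               30
#> 2 DEMO_[C1]_DN    30 -1     -2.82 0.00215 0              170
#> 3 DEMO_[C2]_UP    25  0.983  2.61 0.00187 0               25
#> 4 DEMO_[C2]_DN    26 -0.996 -2.68 0.00211 0              175
#> 5 DEMO_[C1]_AR    60  0.512  1.60 0.00556 0.0108          30
#> 6 DEMO_[C2]_AR    51  0.495  1.47 0.0293  0.0324          25
```

C1's own UP set sits perfectly at the top of C1's ranking (ES = 1, the
30 members occupy the top 30 ranks), its DN set mirrors it at the bottom
(ES = −1), and the sets extracted from the *other* contrast C2 are
recovered too — the planted genes are shared, which is exactly the
cross-experiment comparison the gene-set database exists for. The AR
sets mix both signs, so their one-sided ES is attenuated but still
significant.

The same comparison as over-representation:

```r
deg <- create_deg_list(mc$dataset, "C1", p_threshold = 0.05)
tidy(ora_hypergeometric(deg, sets["DEMO_[C2]_AR"]))
#> # A tibble: 1 × 5
#>   set_name     overlap set_size  p_value      fdr
#> 1 DEMO_[C2]_AR      49       51 2.51e-33 2.51e-33
```

A store persists all of it with version stamps
(`store_create()`, `submit_dataset()`, `store_export_gmt()`,
`membership_matrix()`, `overlap_matrix()`, `reprocess_all()`), and
`extract_results_matrix()` / `extract_leading_edge_matrix()` turn GSEA
results into cross-contrast spreadsheets.

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "gsforge", package = "gsforge")`:

```sh
gsforge submit-contrast-dataset --store db --mapping-table map.tsv --file data.idmaps
gsforge analyze gsea --store db --dataset DEMO --contrast C1 \
        --gmt sets.gmt --seed 7 --out demo_c1
gsforge extract-leading-edge-matrix --results demo_c1.json --out le.tsv --mode rank
```

Subcommands: `submit-contrast-dataset`, `submit-gene-set`, `export-gmt`,
`membership-matrix`, `overlap-matrix`, `create-ranked-list`,
`create-deg-list`, `analyze gsea|ora`, `extract-results-matrix`,
`extract-leading-edge-matrix`, `reprocess`, `make-fixtures`; all accept
`--help`. Stochastic commands require `--seed`.

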