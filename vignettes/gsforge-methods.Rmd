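---
title: "Methods: contrast-data management, gene-set extraction and enrichment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-data management, gene-set extraction and enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

gsforge manages the *results* of differential statistical analyses —
contrasts, summarised per gene by the effect size M (e.g. log2 fold
change), the average signal A, the significance level P (p-value or FDR)
and the statistic S (e.g. a moderated t) — and everything derived from
them: a gene-centric mapped/collapsed view, UP/DN/AR gene sets, a
versioned knowledge base, and preranked GSEA / hypergeometric ORA
enrichment analyses with leading-edge and results-matrix post-processing.
Sample-level expression data never enters the package; the contrast table
is the ingestion boundary.

# The idMAPS dialect

The interchange format is deliberately plain: tab-delimited, a metadata
header, one column-header row, then data rows. Two choices deserve
justification.

* **Header syntax.** Metadata lines use `#%key=value`. The `#` prefix
  keeps the lines comment-like for generic tabular tooling, the `%`
  distinguishes them from free comments, and `key=value` is greppable and
  trivially parseable. Multi-valued keys are comma-separated (so contrast
  names may not contain commas, and `|` is reserved for internal column
  naming). Per-contrast extraction overrides are encoded as
  `#%gene_set.<contrast>.<param>=value`.
* **Column groups.** Statistic columns repeat per contrast in groups drawn
  from the letters M/A/P/S. Any in-group order is accepted, but the same
  order is required for every contrast; group boundaries are detected
  where a letter repeats. This makes `ID M A P S M A P S` and
  `ID S M S M` valid and `ID M A P S M P A S` a hard error — silently
  guessing the grouping would corrupt downstream statistics.

M is mandatory and may not be missing; A, P and S may be absent as
columns or missing (`NA`/empty cell) per row, in which case the affected
row simply cannot satisfy a threshold on that quantity. Columns with any
other header are pass-through: preserved verbatim, ignored by every
computation — a property the test suite asserts directly.

Numbers are serialised with the fewest significant digits (at most 17)
that reproduce the double exactly, so write→parse is the identity on
parsed objects and repeated exports are byte-identical.

# ID mapping and collapsing

A mapping table relates source IDs to gene records (official symbol,
RefSeq curation status, synonyms) and carries a mandatory version tag;
every artifact derived from it is stamped with that tag.

Resolution rules, in decreasing strictness: Entrez IDs match directly;
gene symbols match the official symbol first and fall back to synonyms
only on failure (official symbols win symbol/synonym clashes); probe sets
return every mapped gene. Symbol matching is case-insensitive with
case-preserving output. When a single best gene is needed (external ID
lists), the RefSeq status ordering Reviewed > Validated > Provisional >
Predicted > Model > Inferred > Unknown decides, with the smallest gene ID
as a deterministic tie-break.

For contrast datasets, a probe mapping to k genes contributes its row to
all k gene groups (*fan-out*) and is counted as multi-mapped in the
report. The alternative — discarding multi-mapped probes — silently
removes signal; fan-out keeps it and leaves the decision visible in the
`MappingReport`.

Collapsing reduces each gene's group of rows to one representative:

* `best_p` — smallest P, ties by largest |S|, then input order;
* `max_abs_s` — largest |S|; `max_a` — largest A;
* `mean` — column-wise mean of M, A, S and the group *minimum* of P
  (a mean of p-values would not be a p-value; the minimum is
  conservatively optimistic and documented as such);
* the default (`auto`) picks `best_p` when P exists, else `max_abs_s`,
  else `max_a`, else `mean` — the most significant measurement is the
  common practice for probe collapsing.

For the row-picking strategies the representative is chosen **once per
dataset from the first contrast's values** and reused for every contrast.
Per-contrast selection would mix different probes within one gene across
contrasts and break cross-contrast comparability (a ranked list from
contrast 1 and one from contrast 2 would no longer measure the same
molecules). Rows missing the deciding value rank worst. Output rows are
ordered by gene ID, making the whole pipeline byte-deterministic given
the same inputs and mapping version.

# Gene-set extraction

Per contrast, candidates are the genes with `P <= p_threshold`,
`|M| >= m_threshold` and (if configured) `A >= a_threshold`. Genes with
M = 0 or missing P are never candidates: no direction can be assigned to
the former, no significance established for the latter. UP keeps
candidates with M > 0, DN those with M < 0, and AR — the global response
of the system to the stimulus — is exactly UP ∪ DN, so
|AR| = |UP| + |DN| at candidate level. The union semantics (rather than
an independently thresholded two-sided set) keeps the three sets
consistent by construction.

Within a set, members are ordered by ascending P, ties by descending |S|,
then descending |M|, then gene ID — a fully deterministic significance
order. Sets larger than `max_size` keep their top `max_size` members
(AR irrespective of sign); sets smaller than `min_size` (default 10) are
recorded in the extraction report but not emitted. `fixed_size` replaces
the significance *filter* with a size target: UP/DN/AR take exactly their
top-k genes by the same ordering regardless of `p_threshold` — a desired
size is an alternative to a cutoff, not an addition to it. Defaults
(`p_threshold` 0.05, sizes 10–500) follow common gene-set practice and
are per-contrast overridable from the idMAPS header, including `skip`
for contrasts (such as intercept terms) that should produce no sets.

Set names follow `<dataset>_[<contrast>]_<suffix>`.

# The knowledge base

The store is a versioned directory: a JSON index, the raw idMAPS sources,
the processed gene-level tables, the processing reports, and one JSON
record per gene set. A relational server adds operational weight without
changing any contract here, and keeping records as plain files keeps the
store greppable and diffable. Invariants: names are unique per kind, no
gene set exists without its originating dataset (deletion cascades), and
all records born in one submission share one `annotation_version`.

`reprocess_all()` re-runs the full pipeline for every dataset from its
stored raw source against a new mapping table, with the dataset's
original strategy and parameters. Old gene sets are marked *superseded*,
never deleted — provenance chains stay auditable, and reprocessing with
the identical table is a byte-identical no-op on the live GMT export
(asserted in the tests).

# Enrichment analysis

## Preranked GSEA

A ranked list orders *all* genes of a contrast by S or M (GSEA is
threshold-independent), ties broken by gene ID — the running statistic is
tie-order sensitive, so the order must be reproducible. For a set with
N~H~ of N genes present, the running sum gains
$|r_j|^p / \sum_{hits}|r_j|^p$ at members and loses $1/(N-N_H)$
elsewhere; the enrichment score ES is the signed maximum deviation from
zero and `rank_at_max` the first rank attaining it. `p = 1` (default)
weights by score; `p = 0` is the classic Kolmogorov–Smirnov form. If the
positive and negative extrema tie exactly — possible with `p = 0` on
symmetric hit patterns — the earlier rank wins; the sign of ES is then a
convention, not information. The degenerate case of all hit scores being
exactly zero falls back to equal steps of 1/N~H~.

The null is the gene-label permutation (the only null available for
preranked input): member positions are redrawn uniformly, the statistic
recomputed, `n_permutations` times (default 1000) under a mandatory
integer seed. Per set:

* NES = ES / mean(|null ES| of the matching sign); a sign with no null
  realisations yields `NA`, never a fabricated value;
* nominal p = (1 + #{same-sign nulls at least as extreme}) /
  (1 + #same-sign nulls), which is never exactly 0 and respects the
  permutation-test bound;
* FDR q by the sign-stratified pooled procedure: all null ES are rescaled
  by their set's sign mean and pooled; q(NES\*) is the ratio of the
  pooled-null tail fraction to the observed-NES tail fraction, clipped to
  [0, 1], then made monotone so a more extreme NES never reports a larger
  q (step-up, borrowing the minimum from less extreme sets).

The leading edge — the members driving the enrichment — are the set's
genes at ranks ≤ `rank_at_max` for positive ES and ≥ `rank_at_max` for
negative ES.

## ORA

The DEG list is the genes with `P <= p_threshold`; the test is the
hypergeometric upper tail P[X ≥ k] for the overlap k between DEG list and
gene set, within a universe N. The universe is not uniquely defined by
common practice, so the policy is explicit and recorded in the result:
default `contrast` (all genes of the originating contrast after
collapsing — the measured background) or `collection` (union of the
collection's genes). P-values are Benjamini–Hochberg adjusted across the
collection; `bh_adjust()` delegates to `stats::p.adjust` and is checked
against an independently coded step-up in the tests.

## Post-processing

The results matrix unions set names across several GSEA runs
(alphabetical row order) with per-run NES/FDR/rank column groups; absent
set/run combinations are explicit `NA`, never 0. The leading-edge matrix
holds, for all sets passing an FDR filter (default 0.05), the union of
their leading-edge genes in ranked-list order, with boolean, rank-metric
score, or 1-based rank cells. TSV exports use `NA` as the missing token.

# Synthetic data

The generators exist so every stage is testable without downloads, and
their defaults define the study conditions of the test suite:

* `make_mapping_table()` — sequential gene IDs and symbols, statuses over
  the full RefSeq vocabulary, 1–3 probes per gene, optional planted
  official-symbol/synonym clashes.
* `make_contrast_dataset()` — per probe a standard error from a scaled
  chi distribution (≈ 0.33, as a moderated-variance analysis would
  estimate from a few replicates), M = true effect + Normal(0, SE) error,
  S = M/SE (standard normal under the null), P the BH-adjusted two-sided
  normal tail of S, A ~ Normal(8, 2) on a log2-like scale. P values are
  genuinely valid tail probabilities so downstream FDR semantics are
  meaningful. Defaults: 50 planted genes (half up, half down) at
  |M| = 2.
* `make_ranked_fixture()` — standard-normal scores over 1000 genes;
  planted 25-gene sets have members shifted by +2 SD; zero shift gives
  the null-calibration fixture.

All generators require a seed and are bit-reproducible under it. What
they do *not* emulate: correlated genes (sets of co-regulated genes share
noise in real data, inflating GSEA variance), heavy-tailed effect
distributions, platform-specific probe biases, and real annotation churn.
Passing the planted-recovery and calibration tests therefore demonstrates
correctness of the statistics under independence, not field performance
on real arrays.

# Numerical and design notes

* All stochastic paths take explicit integer seeds; identical inputs,
  parameters and mapping version give byte-identical outputs.
* Every ordering in the package (collapsing ties, set membership, ranked
  lists, exports) has a stated deterministic tie-break, usually the gene
  ID or input order.
* The test suite's problem sizes — e.g. 200 random datasets for the
  serialisation identity, 500 random table/dataset pairs against a naive
  group-by oracle, all hypergeometric configurations with N ≤ 25 against
  exact enumeration, a 200-set/500-permutation calibration and a
  20-replicate/1000-permutation power study — were chosen to exercise the
  contracts densely while keeping a full run in the low minutes on one
  core.
* Known limitations: no sample-level (phenotype-permutation) GSEA, no
  cross-species translation, no vendor-annotation downloading; the
  mapping table is the package's annotation boundary.
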