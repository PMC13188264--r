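---
title: "Composite DE-score analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite DE-score analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descore)
```

# The problem

Very small two-group RNA-seq designs (the motivating case is a
hemizygous-microdeletion mouse model, three mutants against three
wild-type littermates) sit in an awkward statistical regime: hard
fold-change cutoffs discard genes whose changes are modest but
coordinated and well supported (a hemizygous gene-dosage effect is only
log2FC ≈ −1, and often shallower), while nominal p-value thresholds
admit low-expression genes whose fold-change estimates are noise.
`descore` implements a composite ranking that trades both cliffs for a
continuous score, and surrounds it with the machinery needed to trust a
ranking produced from n = 3: resampling-based reproducibility checks,
exhaustively enumerated multivariate separation tests, pathway-level
integration of over-representation and enrichment analyses, and a
cross-species concordance module.

# The composite DE score

For each gene the pipeline produces `m_value` (log2 fold change, group 2
vs group 1), `a_value` (average log2 counts-per-million) and a p-value
from a negative-binomial exact test. After a mild expression filter
(`a_value >= a_min`, default 0.5, i.e. CPM of about 1.4), the score is

    DE score = sign(log2FC) x (-log10 p) x scaled_a

where `scaled_a` min–max-scales `a_value` to [0, 1] over the *filtered*
gene universe. The three factors keep direction, weight statistical
confidence, and down-weight low-abundance genes whose fold changes are
unreliable. The score is related to signed `-log10 p` rankings and the
pi-value family of significance-by-effect-size composites; the abundance
factor is the distinguishing third term.

DEGs are the `k` largest positive and `k` most negative scores among
genes passing nominal significance (`p < p_threshold`); defaults
`k = 300`, `p_threshold = 0.05`. When a direction holds fewer than `k`
eligible genes, all are taken and a warning is raised. The filtered
universe is retained as the enrichment background.

Numerical conventions, chosen once and applied everywhere:

* `p = 0` is replaced by half the smallest nonzero p before the log
  transform, extending the same half-minimum rule used for q-values in
  the `-log10 q` transform. This keeps every score finite.
* If all `a_value`s are equal, `scaled_a` is set to 1 (not 0) so that
  significance still ranks genes; a warning marks the degenerate input.
* Ties in `de_score` (and every other ranking in the package) are broken
  by lexicographic gene id. Gene ids emitted by the simulator are
  zero-padded so lexicographic order equals numeric order.

# Normalization and the exact test

Between-sample normalization is trimmed-mean-of-M-values (TMM): the
reference sample is the one whose upper-quartile CPM is closest to the
mean upper-quartile; factors are inverse-asymptotic-variance weighted
means of M-values after trimming 30% of M-values and 5% of A-values
(symmetric tails), renormalized to unit geometric mean. The trim
fractions and weights follow the originating TMM formulation. The DEGES
variant iterates (default 3 times): test, flag putative DEGs (BH
q < 0.1, falling back to p < 0.05 when none), recompute TMM on the
remaining genes. Low-count genes are never filtered inside the test;
filtering happens only at the scoring stage.

The differential test is a doubly conditional NB exact test. Counts are
depth-equalized to the geometric-mean effective library size (rounded
pseudo-counts), a common dispersion is estimated by maximizing the
conditional likelihood of the within-group pseudo-count configurations —
a one-dimensional search on log-dispersion over [1e-6, 10] — and each
gene's group totals are tested conditionally on their sum, summing the
probabilities of all splits at most as probable as the observed one
(two-sided, ties included). Fold changes are moderated with a prior
count (default 0.125, expressed on the CPM scale at average depth).
Tag-wise or trended dispersion is out of scope; any external backend
that produces a `gene_id / m.value / a.value / p.value` TSV can replace
this module via `read_gene_stats()`.

In the test suite the implementation is cross-checked against an
independent reference implementation of TMM and the exact test (edgeR):
factors agree to 1e-10 and p-value rankings correlate above 0.99; the
test is not bit-compatible by design (the dispersion estimator and the
depth equalization differ in detail).

# Reproducibility validation

Three resampling schemes rerun the *entire* pipeline (normalization,
test, scoring, selection) and compare resampled DEG lists against the
full-data lists with Jaccard indices:

* stratified bootstrap (`n_iter = 500`): samples drawn with replacement
  within each group, group sizes preserved;
* leave-one-out subsampling (`n_iter = 100`): one randomly chosen sample
  dropped *per group* each iteration (the alternative — dropping one
  sample in total — would unbalance a 3v3 design half the time; the
  per-group convention was chosen and is noted here because the
  convention is genuinely ambiguous);
* a permutation null (`n_iter = 1000`): the statistic is the mean
  `|DE score|` over the selected DEGs, a direct measure of ranking
  strength; the null permutes group labels, enumerating all distinct
  label assignments when there are at most `n_iter` of them (a 3v3
  design has 20, so enumeration is always exhaustive there) and the
  empirical p-value uses the add-one rule
  `(1 + #{T_null >= T_obs}) / (1 + N)`, which never returns zero. Note
  that with equal group sizes the complement of the observed assignment
  reproduces the observed statistic, so the smallest achievable p in a
  3v3 design is 2/20 = 0.1.

All schemes take a `seed` (default 123) and are byte-reproducible.

Group separation on the selected genes is summarized on the
`log2(CPM + 1)` matrix: PCA (column-centered SVD), PERMANOVA and ANOSIM
on Euclidean distances, and MANOVA (Wilks' lambda with Rao's F
approximation) on the first two principal components — two components
because six samples admit no more. Euclidean distance on log-CPM is the
package's choice; the input matrix is fixed by the method, the metric is
not, and the choice is configurable in code. For PERMANOVA/ANOSIM, when
the number of non-identity sample orderings is at most `max_perms`
(default 999; six samples give 719) every ordering is enumerated and the
p-value is exact on the grid `m / (n_enumerated + 1)`; perfectly
separated 3v3 data therefore report ANOSIM R = 1.000 with p exactly
72/720 = 0.100, the combinatorial floor.

# Enrichment

ORA is a plain hypergeometric upper-tail test of each DEG list against
each gene set, both restricted to the background universe, with BH
adjustment across sets. The bespoke multiple-testing corrections of web
ORA services are deliberately not reproduced.

Preranked GSEA walks the full score-ranked list with weighted hits
(`|score|^weight`, default weight 1, normalized to sum 1) against
uniform misses; ES is the maximal running-sum deviation, computed at the
hit boundaries where the extrema must lie (an O(set size) form verified
in tests against the O(n) running sum). Set-size bounds default to
15/500. The null distribution permutes *gene labels* (random sets of
equal size, 1000 permutations): a ranked list admits no phenotype
permutation, so the gene-label null is the only coherent choice for
preranked input, and this deviation from a phenotype-permuting desktop
implementation is intentional. NES divides ES by the mean same-sign null
|ES|; FDR q follows the pooled sign-stratified normalized-null
procedure, with an explicit monotonization so a larger |NES| never
receives a larger q within its direction. The leading edge follows the
usual convention: hits from the start of the list to the positive
extremum, or from the negative extremum to the end. When the positive
and negative deviations tie exactly in magnitude, the one encountered
first along the list wins. Zero q-values are replaced by half the
smallest nonzero q and `-log10 q` is capped at 50.

# Term clustering and integration

Enriched terms are clustered by Wang semantic similarity over an
ontology DAG supplied as a typed edge list (`is_a` weight 0.8, `part_of`
0.6 — the conventional contribution weights; OBO parsing is out of
scope, real ontologies can be pre-converted). Each term's ancestors
carry S-values (max over paths of the product of edge weights);
similarity is the shared-ancestor S-value mass over the total. Complete
linkage on `1 - similarity` is cut at 0.7: clusters are the dendrogram
components formed by merges at heights *strictly below* the cut (the
open boundary convention; ties at exactly the cut height are vanishingly
rare with continuous similarities but the convention is fixed). Each
cluster is represented by its smallest-q member.

Hub genes are ranked by term count — the number of representative ORA
terms containing the gene, or the number of significant GSEA pathways
carrying it in their leading edge — with ties broken by `|DE score|`,
then gene id; the top 20 per direction are reported.

For pathways significant in both ORA and GSEA (with matching direction:
the ORA query's DEG list must match the GSEA enrichment sign),

    ORAscore  = -log10(ORA q)
    GSEAscore = |NES| x -log10(GSEA q)
    combined  = sqrt(ORAscore^2 + GSEAscore^2)

and per gene

    priority = (consensus pathways containing the gene)
               x mean(combined score of those pathways) x |DE score|.

`pathway count` counts *consensus* pathways (not all significant ones),
and the mean runs over the pathways containing the gene — the pairing
implied by counting per gene. Chord-plot exports take the top 5
pathways by combined score and up to 20 genes per pathway by priority.

# Cross-species concordance

An ortholog map (strictly one-to-one, supplied as a two-column TSV) inner-joins
the two species' filtered scored tables. Gene-level concordance uses
Spearman and Pearson correlations of DE scores, a two-sided Fisher exact
test of DEG overlap on the joined universe (the sample cross-product
odds ratio is reported; with a zero margin the OR is undefined and
reported as missing), and the concordance rate — the fraction of shared
DEGs with matching DE-score sign. Pathway-level results distinguish
strict consensus (significant by both methods in both species, per
direction) from union-shared pathways (significant by either method in
each species), over which combined scores are correlated across species.
In the end-to-end runner, the second species' enrichment runs in the
shared pathway namespace: ortholog-mapped genes are relabeled with the
first species' ids, mirroring how cross-species pathway comparisons
project both species onto one gene-set collection.

# The synthetic-data generator

`simulate_counts()` draws `counts ~ NB(lib_s x q_g x 2^(log2FC_g x
[group 2]), phi)` with `Var = mu + phi mu^2`, log-normal relative
abundances `q_g` (normalized to sum 1) and log-normal library sizes with
a stated coefficient of variation — realistic depth variation without
extra configuration surface. It emulates the structure the analysis
assumes: a contiguous deletion block at 0.5 dosage in one group (true
log2FC exactly −1), sparse up/down genes with uniform |log2FC| in a
stated range, and coordinated pathway shifts applied to named gene sets
that `simulate_gene_sets()` also emits as a GMT, together with a rooted
toy DAG. `simulate_species_pair()` adds a partial one-to-one ortholog
map (75% of genes by default, echoing the roughly three-quarters overlap
typical of mouse–human filtered transcriptomes) and shares a stated
fraction of DE-gene signs across species; at fraction 0 concordance sits
at chance, at 1 it is total.

What the generator does *not* emulate: gene-length effects, GC and
batch artifacts, correlated gene-gene noise, isoform structure, and
outlier samples. Passing tests therefore demonstrate the pipeline's
internal correctness and its behaviour under the idealized count model,
not robustness to every failure mode of real libraries.

Default study-like conditions used in tests: 3 vs 3 samples, dispersion
0.05, a 20-gene deletion block at dosage 0.5, and per-gene depth of
about 500 reads per sample (2000 genes at a mean library of 1e6 in the
recovery tests — the per-gene depth of a ten-million-read library over a
twenty-thousand-gene transcriptome). Under those conditions the pipeline
recovers at least 90% of deletion-block genes among the downregulated
DEGs with a median `m_value` close to −1, and the exact test's type-I
error at nominal 0.05 stays within [0.03, 0.08] across seeds. Resampling
tests use 400-gene, shallower simulations with 20–30 iterations so the
whole suite stays within desk-scale runtimes; iteration *defaults* in
the API remain at the full 500/100/1000.

# Known limitations

* The exact test assumes a common dispersion; strongly gene-specific
  overdispersion will miscalibrate extreme tails.
* Depth equalization rounds pseudo-counts; at very shallow depths this
  adds discreteness noise.
* GSEA FDR q-values inherit the permutation-null granularity
  (`1/n_perm`); with few permutations small q-values saturate.
* The Wang similarity implementation recomputes S-values per term pair
  batch; very large term sets (thousands) would want memoized ancestors.
* `run_all()` is sequential; determinism, not throughput, was the
  design goal.
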