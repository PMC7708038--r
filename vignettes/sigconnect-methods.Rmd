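---
title: "sigconnect: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sigconnect: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical methods implemented in
`sigconnect`, the parameters that matter, the numerical conventions the
package commits to, and the limits of what its synthetic-data tests can
show about real perturbation data.

# Data model

A gene expression signature (GES) is either a quantitative profile
(`ExpressionProfile`: a per-gene numeric vector with a declared
`value_kind` — normalized `intensity`/`count`, `LFC`, `zscore`, or `rank`)
or an up/down gene-set pair (`GeneSetPair`). Rank profiles use the
convention **rank 1 = most up-regulated**, with ties carrying average
ranks; the convention makes "highest ranks" coincide with the up set when
sets are extracted from profile extremes (`top_n_sets()`). Boundary ties
in `top_n_sets()` are broken lexicographically by gene id, so set
extraction is deterministic.

Reference databases (`SignatureDB`) are gene × treatment matrices stored
in HDF5: a float32 `/assay` dataset chunked in blocks of whole treatment
columns (so a batched scan reads whole chunks), string datasets
`/rownames` and `/colnames`, and `/value_kind`. Gene-set databases
serialize per-treatment up/down sets as pipe-joined strings aligned with
`/colnames`, keeping every database a single file. Treatments are keyed by
the composite id `pert__cell__perttype`; parsing splits on the *last two*
`"__"` occurrences so perturbagen names containing underscores survive.
Batch access is 1-based (`read_batch(db, start, size)`), and the search
engine guarantees that neither `batch_size` nor `workers` ever changes a
score — batches only partition the scan.

Float32 storage bounds round-trip error at ~1e-7 relative, far below any
score difference the methods can resolve; exact-value guarantees in this
package (self-correlation 1, scaled connectivity 1) are not affected
because they arise after rank or comparison operations.

# Search methods

All five searches are declared through a `qSig` object, which enforces the
method/data-type compatibility matrix at construction time (gene-set query
× rank database for `cmap`, gene-set × z-score for `lincs`, rank profile ×
gene-set database for `gcmap`, gene-set × gene-set for `fisher`,
quantitative profile × quantitative database for `cor`). `lincs` accepts
an LFC database with a warning rather than an error — the statistic is
well-defined there, but z-scores are its intended input.

**CMAP.** For query positions `V(1..t)` (sorted) in a treatment's ranked
list of `n` genes, `a = max_j(j/t − V(j)/n)` and
`b = max_j(V(j)/n − (j−1)/t)`; the signed statistic is `a` if `a ≥ b`,
else `−b`. The raw score is `ks_up − ks_down` when the two tails disagree
in sign and 0 otherwise (the classical "exception" rule; a treatment where
both query sets pile onto the same tail carries no connectivity
information). Raw scores are scaled to [−1, 1] **within the current
search**: positives divided by the search maximum, negatives by the
magnitude of the search minimum. The scaling scope is a design choice the
original method description leaves open; per-search scaling makes a
perfectly concordant planted entry score exactly 1 regardless of database
composition. Query genes absent from the database gene space are dropped
with a warning and `t` reflects retained genes; a non-empty set losing
*all* genes is an error naming the set. One-sided queries (an empty up or
down set) fall back to the single available tail statistic.

**LINCS.** The weighted KS enrichment score sorts a treatment's profile
descending (ties broken by gene id), advances the running sum at hits by
`|z|^exponent` normalized by the hit total, retreats at misses by
`1/(n−t)`, and takes the signed extreme of maximal magnitude — when the
positive and negative extremes tie exactly, the positive one wins
(deterministic). `WTCS = (ES_up − ES_down)/2` on sign disagreement, else
0. The default `exponent = 1` is the weighting that distinguishes the
method from CMAP; `exponent = 0` recovers the unweighted KS running sum.

WTCS values are normalized to NCS within (cell, perttype) groups parsed
from the treatment ids, separately by sign: `ncs = wtcs / |mean(same-sign
group values)|`. A group/sign stratum with a single value therefore
normalizes to ±1 — the stratum mean is the value itself. τ standardizes
NCS against a reference population: the signed percentage of reference
magnitudes strictly below the entry's. The reference compendium of the
original large-scale implementation is not redistributable, so the default
reference is the search's own NCS values within the same group; an
external reference vector can be supplied via `params$tau_reference`. τ
values are therefore comparable *within* a search by default and across
searches only with a shared external reference.

**gCMAP** swaps the roles: the query is a rank profile, each database
entry an up/down set located within it; raw/zero/scaling rules are
identical (verified against `gess_cmap` by role-swap equivalence).
Database entries sharing no gene with the query score 0 and are flagged
(`no_overlap`) rather than dropped, so the result always covers every
treatment.

**Fisher** compares the pooled query genes against each entry's pooled
genes over a universe (default: the database gene space); the p-value is
the exact hypergeometric upper tail, BH-adjusted across entries. A
quantitative database is converted on the fly to a gene-set database with
user cutoffs (`gep_to_gs_db()`, up = values ≥ `higher`, down = values ≤
`lower`); treatments whose cutoffs select nothing are retained with empty
sets and a warning.

**Correlation** computes Spearman (default) or Pearson coefficients over
the common gene space — all shared genes (*SPall*) or a subset (*SPsub*,
default subset: the query's own genes, typically its top up/down sets).
Entries with fewer than 3 shared genes or zero variance are flagged `NA`
rather than scored. Results are ranked by |r|, matching the convention of
reporting the strongest connections of either sign first.

Ranking ties in every method are broken lexicographically by treatment id.
Primary sort keys: scaled score (cmap/gcmap), WTCS (lincs), ascending
p-value (fisher), |r| (cor).

# Enrichment methods

`drugs_to_targets()` pools the target sets of the top-ranked drugs into a
multiset; the multiplicity of a target counts the test drugs sharing it.
This frequency is the signal the TSEA methods weight by — collapsing
duplicates would erase exactly the information that several top drugs
converge on one target. Promiscuous binders can be excluded with
`max_targets_per_drug`; the cap is **off by default** (filtering is an
option, not a mandate). Scored input lets each target inherit the
best-magnitude score among its drugs, producing the ranked target list for
`tsea_mGSEA`. The default test-set size for enrichment of a search result
is the top 100 drugs.

**dup_hyperG** adjusts the test-set size (`n_test` = total multiplicity)
and the match count (`n_match` = summed multiplicity inside the category)
while the category size `K` and universe `N` stay unweighted — the reading
of "remove the duplications but keep their frequency as weights" that
leaves the annotation system untouched. Two pathologies of this weighting
are handled explicitly: `n_match > K` makes the upper tail 0 by
definition, and heavy duplication against a small universe can push
`n_test` beyond `N`, in which case the draw count is capped at `N` (the
match count is not). Both arise only when the universe is small relative
to the duplication level.

**mGSEA** runs the weighted KS running sum over the score-ranked target
list with hit increments `mult × |score|^exponent` (normalized by the hit
total) and miss decrements `1/#misses`. Unit multiplicities reduce it
exactly to classic weighted GSEA, which is how it is validated (an
independent running-sum oracle plus an external GSEA implementation).
Significance comes from permuting the *gene labels* of the ranked list
(`nperm` default 1000, seeded): the category's genes, carrying their
multiplicities, land on random positions; the p-value is the fraction of
same-sign permutation scores at least as extreme as the observed ES, with
the same-sign count as denominator — the convention under which null
p-values are uniform — and `NES = ES / mean(|same-sign permutation ES|)`.
Categories with no member in the list are skipped and recorded.

**mabs** scores a category by the mean absolute statistic of its scored
members; the null is `nperm` random same-size sets drawn from the scored
genes, `p = fraction(null ≥ observed)` — a plain fraction, so exhaustive
enumeration is the small-sample limit (on a 4-gene universe with one
2-gene category achieving the maximum, p converges to 1/6).

**DSEA** applies the classical hypergeometric test or the unit-multiplicity
GSEA to drug-level categories; drug test sets are unique by construction,
so duplicate input drugs are removed with a warning. TSEA and DSEA on the
same search result generally *disagree* in ranking when targets repeat —
that divergence is a regression-tested property, not a bug.

Seven p-value adjustment methods are supported (BH default, bonferroni,
holm, hochberg, hommel, BY, none), all via the standard step-up/step-down
procedures.

# Drug-target networks

`build_dtn()` restricts the annotation table to (drug set) × (category
members): targets keep only category members hit by at least one drug,
isolated drugs are dropped, and each vertex carries `type` and `degree`
attributes (a target's degree — its number of connecting drugs — is the
quantity the visualizations encode). Interactive rendering is deliberately
replaced by static GraphML/JSON exports (`export_dtn()`/`import_dtn()`
round-trip) plus a small base-graphics helper, keeping the core headless
and testable.

# Benchmarking

`run_benchmark()` implements the recall evaluation: every treatment whose
perturbagen belongs to a category queries the whole database with each
method; set methods use the treatment's top 150/150 gene sets (the
package-wide default query size), correlation methods the profile
subsetted to those genes (`cor_sub`) or the full profile (`cor_all`). The
query's own database entry is **excluded** from its relevance vector —
otherwise every method banks a guaranteed true positive and differences
compress. Per-category score/label vectors are concatenated and re-sorted;
ROC curves collapse tied scores into single points and are integrated by
the trapezoidal rule. Partial AUCs at FPR caps 1/5/10% are reported
**unnormalized** (range [0, cap]): no correction is prescribed for them,
and the ranking of methods is invariant to the common normalizations.

Category filtering ranks categories by a recall rate computed as the mean
category-level AUC **across all methods** (so no single method biases the
selection) and keeps the top `ceiling(fraction × n)` (default 25%), with
ties at the cutoff all retained. The mean-AUC proxy is this package's
concrete definition of "recall rate"; the filtering intent — drop
categories whose members cannot recall each other under any method — is
preserved.

AUC differences between methods are tested with a paired, label-stratified
bootstrap (positives and negatives resampled separately, the same indices
applied to both methods; default 2000 replicates):
`D = (AUC₁ − AUC₂)/sd(bootstrap differences)`, `p = 2Φ(−|D|)`, pairwise
matrices BH-adjusted. Zero bootstrap variance with a non-zero observed
difference is degenerate and reported as p = 0 with a flag.

# Synthetic data: what it emulates and what it does not

`simulate_gep_db()` emulates the structure that recall benchmarking
relies on: clusters of treatments (drugs sharing a mode of action) with
shared up/down signature genes, against independent Gaussian noise.
Defaults — 1000 genes × 200 treatments, 10 clusters of 5, effect 3,
noise 1 — are the package's standard test conditions; the signature size
(100 genes per direction) is chosen at the same order as the 150/150
query sets so that planted signal and query extraction overlap
substantially. The Gaussian shift model is analytically tractable: at
effect 3 and noise 1, within-cluster correlations dominate
between-cluster ones almost surely, and correlation methods should reach
near-perfect recall (global AUC > 0.9); at effect 0 recall must collapse
to chance (AUC ≈ 0.5). Both ends anchor the benchmark's calibration.

What the simulator does **not** model: heavy-tailed and gene-dependent
noise, correlated gene modules, imputed-gene artifacts of reduced
representation assays, dose/time structure, or partially overlapping
modes of action. Passing the planted-cluster tests therefore shows the
machinery is correct and well-calibrated, not that any particular method
will reach a given AUC on real perturbation compendia — on real data,
category heterogeneity, promiscuous binders and noise push all global
AUCs far below 1, and only the *ranking* of methods is meaningful.

Generators are pure functions of their `seed` (RNG state is saved and
restored), so every simulated fixture is reproducible byte for byte.

# Numerical choices and test scale

* Positive extreme wins exact ES ties; lexicographic tie-breaks for gene
  and treatment ids everywhere ordering matters.
* Fisher/hypergeometric tails via the exact distribution function, never
  normal approximations; equality with pmf summation is asserted to 1e-12.
* mGSEA/mabs permutation p-values are plain (or same-sign-conditional)
  fractions; calibration tests check uniformity under the null with a KS
  test at 500 replicates.
* Test problem sizes are chosen for speed at full coverage: the
  full-scale planted-cluster benchmark runs the default 1000 × 200
  database for the correlation methods; the all-methods
  batching-invariance checks and unit tests use 30–500-gene databases
  with up to 20 treatments, sizes at which every oracle (brute-force KS
  maximization, O(n²) concordance counting, exhaustive enumeration) is
  exact and fast.

# Known limitations

* τ scores without an external reference are only comparable within one
  search group.
* `dup_hyperG`'s weighting is one reading of duplication adjustment
  (category size and universe unweighted); its small-universe pathologies
  are documented above and guarded, but analyses with test multiplicities
  approaching the universe size should prefer `mGSEA`/`mabs`.
* Categories are flat sets: no ontology traversal or term propagation.
* Identifier mapping (protein → gene, cross-organism) is the caller's
  responsibility; all tests operate on gene-level identifiers.
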