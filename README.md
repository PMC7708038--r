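# sigconnect

Gene expression signature searching (GESS) with duplication-aware
functional enrichment and drug-target networks, in one R package.

## The problem

A gene expression signature (GES) — either an up/down gene set (GS) or a
quantitative gene expression profile (GEP) — captures the transcriptional
response of cells to a perturbation: a drug treatment, a mutation, a
disease state. Searching a query signature against a reference database of
thousands of perturbation signatures ("connectivity" searching) finds
treatments that induce similar or opposing responses, which is the basis of
mode-of-action discovery and drug repurposing: drugs whose signatures
mimic (or reverse) a query are likely to act through connected mechanisms.

`sigconnect` provides:

* **Signature databases** — gene × treatment matrices (intensities, log
  fold changes, z-scores, ranks, or per-treatment gene sets) stored in
  HDF5 and scanned in batches, so databases far larger than memory can be
  searched.
* **Five search methods** — the classical CMAP Kolmogorov–Smirnov
  connectivity score; the LINCS bi-directional *weighted* KS statistic
  (WTCS) with its group-normalized (NCS) and percentile-standardized (τ)
  derivatives; the role-swapped gCMAP variant; Fisher's exact
  over-representation test; and Spearman/Pearson correlation on all shared
  genes (*SPall*) or a gene subset (*SPsub*).
* **Enrichment (FEA)** — the top drugs of a search are mapped to their
  target genes, which typically contain *duplicates* (several drugs
  sharing a target). Three target-set enrichment methods preserve that
  frequency information as weights — the duplication-adjusted
  hypergeometric test (`tsea_dup_hyperG`), multiplicity-weighted GSEA
  (`tsea_mGSEA`) and the mean-absolute-score statistic (`tsea_mabs`) —
  alongside drug-level enrichment (`dsea_hyperG`, `dsea_GSEA`).
* **Networks** — bipartite drug–target graphs for enriched categories,
  exported to GraphML/JSON.
* **Benchmarking** — the ROC/pAUC machinery for comparing search methods
  on categorized perturbagens (MOA-style ground truth): per-category and
  global AUCs, partial AUCs at 1/5/10% FPR, top-fraction category
  filtering, and stratified-bootstrap significance tests of AUC
  differences.
* **Synthetic data** — planted-cluster signature databases, drug-target
  annotations and category collections, so the entire workflow is testable
  without any download.

## Core scores

For a query gene set with sorted positions `V(1..t)` in a treatment's
ranked list of `n` genes, the CMAP statistic is `a = max_j (j/t − V(j)/n)`,
`b = max_j (V(j)/n − (j−1)/t)`, signed as `a` if `a ≥ b` else `−b`. The raw
connectivity score of a treatment is `ks_up − ks_down` when the two tail
statistics disagree in sign and 0 otherwise, then scaled over the search to
[−1, 1]. The LINCS method replaces the KS statistic with a weighted running
sum (hits advance by `|z|^exponent`, normalized; misses retreat by
`1/(n−t)`) and combines the two enrichment scores as
`WTCS = (ES_up − ES_down)/2` on sign disagreement, 0 otherwise.

## Worked example

```r
library(sigconnect)

# synthetic z-score database: 1000 genes x 200 treatments, 10 planted
# clusters of 5 treatments sharing up/down signatures (effect 3, noise 1)
sim <- simulate_gep_db(seed = 42)
db  <- sim$db

# query: the first treatment's own profile, searched with SPsub
# (Spearman on its 150 most up- and 150 most down-regulated genes)
profile <- ExpressionProfile(db@gene_ids, read_batch(db, 1, 1)[, 1], "zscore")
sets    <- top_n_sets(profile, 150, 150)
qs  <- qSig(profile, "cor", db,
            params = list(flavor = "spearman", subset = "sub",
                          gene_subset = c(sets@up, sets@down)))
res <- gess_search(qs)
head(result(res)[, c("treatment_id", "pert", "cell", "cor_score", "trend")])
#>            treatment_id    pert cell cor_score trend
#> 1  drug001__PC3__trt_cp drug001  PC3     1.000    up
#> 2 drug002__MCF7__trt_cp drug002 MCF7     0.828    up
#> 3 drug004__MCF7__trt_cp drug004 MCF7     0.813    up
#> 4  drug003__PC3__trt_cp drug003  PC3     0.808    up
#> 5  drug005__PC3__trt_cp drug005  PC3     0.807    up
#> 6 drug116__MCF7__trt_cp drug116 MCF7    -0.170  down
```

The query's own database entry sits at rank 1 with a correlation of
exactly 1.00, followed by the other four members of its planted cluster
(drug002–drug005, correlations ≈ 0.81–0.83); unrelated treatments drop to
|r| ≤ 0.17. The same query sets run through the LINCS method rank the
cluster identically with WTCS 1.00 for the self entry and τ ≈ 97–99 for
the cluster members.

Enrichment of the top drugs' targets then recovers a planted category:

```r
top_drugs <- unique(result(res)$pert)[1:10]
ann <- simulate_annotations(parse_treatment_ids(db@treatment_ids)$pert,
                            n_targets = 100, seed = 1)
tm   <- drugs_to_targets(top_drugs, ann, scores = result(res)$cor_score[1:10])
cats <- simulate_categories(sprintf("T%03d", 1:100), n_categories = 10,
                            enriched_set = tm$targets$target, seed = 2)
head(result(tsea_dup_hyperG(tm, cats)), 4)
#>   category description n_category n_test n_match   pvalue     padj
#> 1  planted     planted         10     30      10 1.74e-06 1.91e-05
#> 2   cat006      cat006         11     30       5 1.98e-01 9.20e-01
#> 3   cat005      cat005          6     30       3 2.51e-01 9.20e-01
#> 4   cat008      cat008          5     30       2 4.74e-01 9.63e-01
```

`n_test` and `n_match` count target *multiplicities* (30 target slots from
10 drugs), the duplication weighting that distinguishes these tests from
their classical counterparts. `build_dtn(top_drugs, cats$sets$planted, ann)`
then yields the drug–target graph of the winning category (here 16 nodes,
10 edges) for export with `export_dtn()`.

A command-line front end wraps the same functions
(`inst/cli/sigconnect`): subcommands `build-db`, `search`, `fea`, `dtn`,
`benchmark`, `simulate`.

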