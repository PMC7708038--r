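# Synthetic data: signature databases with planted perturbagen clusters,
# drug-target annotations and category collections. All generators are pure
# functions of their seed.

#' Simulate a signature database with planted perturbagen clusters
#'
#' Generates a gene x treatment z-score matrix of independent
#' `Normal(0, noise_sd)` values and plants `n_clusters` clusters of
#' `cluster_size` treatments each: every cluster owns a random up-signature
#' and down-signature gene set (of `n_sig` genes each) whose values are
#' shifted by `+effect` and `-effect` in all of the cluster's treatments.
#' Cluster members thus share correlated signatures, emulating drugs with a
#' common mode of action, while the remaining treatments are pure noise.
#' Treatments are named `"drugK__CELL__trt_cp"` with cells cycled from
#' `cells`, exercising the composite-id parser and the (cell, perttype)
#' grouping of the NCS normalization.
#'
#' @param n_genes,n_treatments Matrix dimensions (defaults 1000 x 200).
#' @param n_clusters,cluster_size Planted structure (default 10 clusters of
#'   5); `n_clusters * cluster_size <= n_treatments`.
#' @param effect Mean shift added to signature genes (default 3; 0 gives a
#'   pure-noise database).
#' @param noise_sd Noise standard deviation (default 1).
#' @param n_sig Signature genes per direction per cluster (default 100).
#' @param seed RNG seed; identical seeds give identical databases.
#' @param out_path HDF5 output path (default: a tempfile).
#' @param cells Cell names to cycle over treatments.
#' @return A list with `db` (a [SignatureDB], `value_kind = "zscore"`) and
#'   `truth`: cluster assignment (`clusters`: named list cluster ->
#'   treatment ids; `categories`: cluster -> drug names, the drug-level
#'   ground truth used for benchmarking), per-cluster signature gene sets
#'   (`sig_up`, `sig_down`) and the generator parameters.
#' @export
simulate_gep_db <- function(n_genes = 1000L, n_treatments = 200L,
                            n_clusters = 10L, cluster_size = 5L,
                            effect = 3, noise_sd = 1, n_sig = 100L,
                            seed = 1L, out_path = tempfile(fileext = ".h5"),
                            cells = c("PC3", "MCF7")) {
  if (n_clusters * cluster_size > n_treatments)
    vstop("n_clusters * cluster_size (%d) exceeds n_treatments (%d)",
          n_clusters * cluster_size, n_treatments)
  if (effect < 0) vstop("effect must be >= 0")
  if (2L * n_sig > n_genes)
    vstop("2 * n_sig (%d) exceeds n_genes (%d)", 2L * n_sig, n_genes)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    drugs <- sprintf("drug%03d", seq_len(n_treatments))
    tid <- make_treatment_id(drugs,
                             rep_len(cells, n_treatments), "trt_cp")
    mat <- matrix(stats::rnorm(n_genes * n_treatments, sd = noise_sd),
                  n_genes, n_treatments, dimnames = list(genes, tid))
    clusters <- sig_up <- sig_dn <- list()
    idx <- 1L
    for (k in seq_len(n_clusters)) {
      cname <- sprintf("cluster%02d", k)
      cols <- idx:(idx + cluster_size - 1L)
      idx <- idx + cluster_size
      gsel <- sample.int(n_genes, 2L * n_sig)
      up <- gsel[seq_len(n_sig)]
      dn <- gsel[n_sig + seq_len(n_sig)]
      mat[up, cols] <- mat[up, cols] + effect
      mat[dn, cols] <- mat[dn, cols] - effect
      clusters[[cname]] <- tid[cols]
      sig_up[[cname]] <- genes[up]
      sig_dn[[cname]] <- genes[dn]
    }
    db <- build_sig_db(mat, value_kind = "zscore", out_path = out_path)
    truth <- list(clusters = clusters,
                  categories = lapply(clusters, function(ids)
                    parse_treatment_ids(ids)$pert),
                  sig_up = sig_up, sig_down = sig_dn, effect = effect,
                  noise_sd = noise_sd, seed = seed)
    list(db = db, truth = truth)
  })
}

#' Simulate drug-target annotations
#'
#' Assigns each drug a random target set whose size is drawn uniformly from
#' `targets_per_drug_range`; a chosen fraction of drugs is made promiscuous
#' (receiving `promiscuous_targets` distinct targets) to exercise the
#' promiscuity filtering of [drugs_to_targets()].
#'
#' @param drugs Character vector of drug identifiers.
#' @param n_targets Size of the target gene universe (ids `"T001"`, ...).
#' @param targets_per_drug_range Integer range `c(min, max)`.
#' @param promiscuous_fraction Fraction of drugs made promiscuous.
#' @param promiscuous_targets Targets per promiscuous drug (must exceed
#'   `max(targets_per_drug_range)`).
#' @param seed RNG seed.
#' @return A `DrugTargetTable` (empty list for zero drugs).
#' @export
simulate_annotations <- function(drugs, n_targets = 50L,
                                 targets_per_drug_range = c(1L, 5L),
                                 promiscuous_fraction = 0,
                                 promiscuous_targets = 20L, seed = 1L) {
  if (length(drugs) == 0L)
    return(structure(list(), class = "DrugTargetTable"))
  if (targets_per_drug_range[1] < 1L ||
      targets_per_drug_range[2] < targets_per_drug_range[1] ||
      targets_per_drug_range[2] > n_targets)
    vstop("invalid targets_per_drug_range")
  if (promiscuous_fraction > 0 && promiscuous_targets > n_targets)
    vstop("promiscuous_targets exceeds the target universe")
  with_seed(seed, {
    universe <- sprintf("T%03d", seq_len(n_targets))
    n_prom <- round(promiscuous_fraction * length(drugs))
    prom <- sample(drugs, n_prom)
    sets <- lapply(drugs, function(d) {
      k <- if (d %in% prom) promiscuous_targets
           else sample(targets_per_drug_range[1]:targets_per_drug_range[2], 1L)
      sample(universe, k)
    })
    names(sets) <- drugs
    drug_target_table(sets)
  })
}

#' Simulate a functional category collection
#'
#' Random flat categories over an identifier universe; optionally one extra
#' category (`"planted"`) packed with members of a supplied test set so the
#' enrichment methods have a known positive.
#'
#' @param ids Identifier universe.
#' @param n_categories Number of random categories.
#' @param size_range Category size range `c(min, max)`.
#' @param enriched_set Optional identifier vector to plant a category from.
#' @param enriched_size Size of the planted category (capped at
#'   `length(enriched_set)`).
#' @param seed RNG seed.
#' @return A `CategoryCollection` with universe `ids`.
#' @export
simulate_categories <- function(ids, n_categories = 20L,
                                size_range = c(5L, 15L),
                                enriched_set = NULL, enriched_size = 10L,
                                seed = 1L) {
  ids <- unique(as.character(ids))
  if (size_range[2] > length(ids))
    vstop("size_range exceeds the universe size (%d)", length(ids))
  with_seed(seed, {
    sets <- lapply(seq_len(n_categories), function(i) {
      sample(ids, sample(size_range[1]:size_range[2], 1L))
    })
    names(sets) <- sprintf("cat%03d", seq_len(n_categories))
    if (!is.null(enriched_set)) {
      enriched_set <- intersect(enriched_set, ids)
      if (length(enriched_set) == 0L)
        vstop("enriched_set has no member in the universe")
      sets[["planted"]] <-
        sample(enriched_set, min(enriched_size, length(enriched_set)))
    }
    category_collection(sets, universe = ids)
  })
}
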