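# ROC/pAUC recall benchmarking of the search methods against perturbagen
# categories (MOA / structure-cluster style ground truth), with bootstrap
# significance tests for AUC differences.

category_sets <- function(categories) {
  if (inherits(categories, "CategoryCollection")) categories$sets
  else if (is.list(categories)) categories
  else vstop("categories must be a CategoryCollection or a named list")
}

#' Assemble a binary relevance vector from search results
#'
#' For each query of a perturbagen category, database entries from the same
#' category are labeled 1 and all others 0; the query's own database entry
#' (the guaranteed self-match) is excluded. The per-query score/label
#' vectors are concatenated and re-sorted by score (descending), yielding
#' the labeled score vector the ROC machinery consumes.
#'
#' @param results Named list of [gessResult] objects, one per query; names
#'   are the queries' own treatment ids.
#' @param categories Perturbagen category map: a `CategoryCollection` over
#'   drug (pert) identifiers or a named list of member vectors.
#' @param query_category Category id the queries belong to.
#' @return A data.frame with columns `score`, `label`, `treatment_id`,
#'   `query_id`, sorted by decreasing score.
#' @export
assemble_labels <- function(results, categories, query_category) {
  sets <- category_sets(categories)
  if (!query_category %in% names(sets))
    vstop("category '%s' absent from the category map", query_category)
  members <- sets[[query_category]]
  if (is.null(names(results)))
    vstop("results must be named by their query treatment ids")
  pieces <- lapply(names(results), function(qid) {
    gr <- results[[qid]]
    df <- result(gr)
    qpert <- parse_treatment_ids(qid)$pert
    if (!qpert %in% members)
      vstop("query '%s' (pert '%s') is not a member of category '%s'",
            qid, qpert, query_category)
    sc <- primary_score(gr)
    keep <- df$treatment_id != qid
    data.frame(score = sc[keep],
               label = as.integer(df$pert[keep] %in% members),
               treatment_id = df$treatment_id[keep], query_id = qid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(-out$score, out$treatment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC area under the curve with an optional false-positive-rate cap
#'
#' Sorts the binary labels by decreasing score, accumulates true- and
#' false-positive rates (tied scores collapse into single ROC points) and
#' integrates the curve by the trapezoidal rule up to `fpr_max`, linearly
#' interpolating at the cap. `fpr_max = 1` gives the full AUC; smaller caps
#' give unnormalized partial AUCs in `[0, fpr_max]`, the early-enrichment
#' metric reported at FPR caps of 1%, 5% and 10%.
#'
#' @param scores Numeric similarity scores (larger = more similar).
#' @param labels Binary relevance labels (0/1); both classes must occur.
#' @param fpr_max Cap in `(0, 1]`.
#' @return The (partial) area.
#' @examples
#' roc_auc(c(4, 3, 2, 1), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels, fpr_max = 1) {
  if (length(scores) != length(labels)) vstop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) vstop("labels must be binary 0/1")
  P <- sum(labels == 1); Nn <- sum(labels == 0)
  if (P == 0L || Nn == 0L)
    vstop("both label classes must be present for a ROC curve")
  if (!(fpr_max > 0 && fpr_max <= 1)) vstop("fpr_max must be in (0, 1]")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tpr <- c(0, cumsum(l)[last] / P)
  fpr <- c(0, cumsum(1 - l)[last] / Nn)
  if (fpr_max < 1) {
    i <- max(which(fpr <= fpr_max))
    if (fpr[i] < fpr_max && i < length(fpr)) {
      yc <- tpr[i] + (tpr[i + 1] - tpr[i]) *
        (fpr_max - fpr[i]) / (fpr[i + 1] - fpr[i])
      fpr <- c(fpr[seq_len(i)], fpr_max)
      tpr <- c(tpr[seq_len(i)], yc)
    } else {
      fpr <- fpr[seq_len(i)]; tpr <- tpr[seq_len(i)]
    }
  }
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

#' Retain the top-performing categories
#'
#' Ranks categories by their recall rate, computed as the mean
#' category-level AUC across all methods (so no single method biases the
#' selection), and retains the top `ceiling(fraction * n)`; ties at the
#' cutoff are all retained.
#'
#' @param per_category_auc Numeric matrix or data.frame: rows = categories,
#'   columns = methods, entries = category-level AUC.
#' @param fraction Fraction of categories to keep (default 0.25).
#' @return Character vector of retained category ids.
#' @export
filter_top_categories <- function(per_category_auc, fraction = 0.25) {
  m <- as.matrix(per_category_auc)
  if (nrow(m) == 0L) vstop("empty AUC table")
  if (is.null(rownames(m))) vstop("AUC table needs category row names")
  means <- rowMeans(m, na.rm = TRUE)
  nkeep <- ceiling(fraction * nrow(m))
  cutoff <- sort(means, decreasing = TRUE)[nkeep]
  names(means)[means >= cutoff]
}

#' Bootstrap test for the difference of two AUCs
#'
#' Paired, label-stratified bootstrap: positives and negatives are
#' resampled separately (the same resampled indices applied to both
#' methods' scores), the AUC difference recomputed `nboot` times, and the
#' observed difference standardized by the bootstrap standard deviation:
#' `D = (AUC1 - AUC2) / sd(boot diffs)`, `p = 2 * pnorm(-|D|)` (two-sided).
#'
#' @param scores1,scores2 Score vectors of the two methods over the same
#'   labeled instances.
#' @param labels Shared binary labels.
#' @param fpr_max Optional cap to compare partial AUCs instead.
#' @param nboot Bootstrap replicates (default 2000, minimum 200).
#' @param seed Optional RNG seed.
#' @return List with `auc1`, `auc2`, `D`, `pvalue`, `boot_sd` and
#'   `degenerate` (TRUE when the bootstrap variance collapsed to zero with
#'   a non-zero observed difference; then `pvalue = 0`).
#' @export
bootstrap_auc_test <- function(scores1, scores2, labels, fpr_max = 1,
                               nboot = 2000L, seed = NULL) {
  if (length(scores1) != length(labels) ||
      length(scores2) != length(labels))
    vstop("scores and labels must align (paired test on the same queries)")
  if (nboot < 200L) vstop("nboot must be >= 200")
  auc1 <- roc_auc(scores1, labels, fpr_max)
  auc2 <- roc_auc(scores2, labels, fpr_max)
  pos <- which(labels == 1); neg <- which(labels == 0)
  diffs <- with_seed(seed, {
    vapply(seq_len(nboot), function(b) {
      idx <- c(pos[sample.int(length(pos), replace = TRUE)],
               neg[sample.int(length(neg), replace = TRUE)])
      roc_auc(scores1[idx], labels[idx], fpr_max) -
        roc_auc(scores2[idx], labels[idx], fpr_max)
    }, numeric(1))
  })
  sdd <- stats::sd(diffs)
  obs <- auc1 - auc2
  if (sdd == 0) {
    return(list(auc1 = auc1, auc2 = auc2, D = if (obs == 0) 0 else Inf,
                pvalue = if (obs == 0) 1 else 0, boot_sd = 0,
                degenerate = obs != 0))
  }
  D <- obs / sdd
  list(auc1 = auc1, auc2 = auc2, D = D, pvalue = 2 * stats::pnorm(-abs(D)),
       boot_sd = sdd, degenerate = FALSE)
}

build_benchmark_query <- function(method, profile, sets, rank_db, gs_db,
                                  db, n_up, n_down) {
  switch(method,
         cmap = qSig(sets, "cmap", rank_db),
         lincs = qSig(sets, "lincs", db),
         gcmap = qSig(rank_transform(profile), "gcmap", gs_db),
         fisher = qSig(sets, "fisher", gs_db),
         cor_sub = qSig(profile, "cor", db,
                        params = list(flavor = "spearman", subset = "sub",
                                      gene_subset = c(sets@up, sets@down))),
         cor_all = qSig(profile, "cor", db,
                        params = list(flavor = "spearman", subset = "all")),
         vstop("unknown benchmark method '%s'", method))
}

#' Benchmark search methods on categorized perturbagens
#'
#' The full recall-evaluation machinery: every treatment whose perturbagen
#' belongs to a category is used as a query against the whole database with
#' each method (set methods query the top `n_up`/`n_down` gene sets of the
#' treatment's profile; correlation methods the profile subsetted to those
#' genes, or the full profile), self-matches are excluded, and binary
#' relevance vectors are assembled per category ([assemble_labels()]).
#' Category-level and global ROC AUCs plus partial AUCs at the FPR caps are
#' computed, the top-performing categories retained
#' ([filter_top_categories()]), and (optionally) all pairwise global AUC
#' differences tested by stratified bootstrap with BH correction.
#'
#' @param db A quantitative [SignatureDB] (z-scores). Rank and gene-set
#'   views required by the set methods are derived on the fly
#'   ([rank_transform()] per treatment; [gep_to_gs_db()] at the
#'   `higher`/`lower` cutoffs).
#' @param categories Drug-level category map (`CategoryCollection` or named
#'   list); categories with fewer than 2 members present in the database
#'   are skipped with a flag.
#' @param methods Subset of `c("cmap", "lincs", "gcmap", "fisher",
#'   "cor_sub", "cor_all")`.
#' @param n_up,n_down Query set sizes (default 150/150).
#' @param higher,lower Cutoffs for the derived gene-set database.
#' @param fraction Top-category fraction to retain.
#' @param fpr_caps Partial-AUC caps.
#' @param nboot Bootstrap replicates for the pairwise AUC tests (0 = skip).
#' @param seed RNG seed for the bootstrap.
#' @param batch_size,workers Search engine settings.
#' @return A list: `global` (data.frame method x AUC/pAUCs over all
#'   categories), `per_category` (long data.frame), `retained` (category
#'   ids kept by the top-fraction filter), `global_retained` (global
#'   summary restricted to retained categories), `skipped` (categories with
#'   <2 members), `auc_test` (BH-adjusted pairwise bootstrap p-value
#'   matrix, or NULL), `labeled` (per-method global score/label vectors).
#' @export
run_benchmark <- function(db, categories,
                          methods = c("cmap", "lincs", "gcmap", "fisher",
                                      "cor_sub", "cor_all"),
                          n_up = 150L, n_down = 150L, higher = 1,
                          lower = -1, fraction = 0.25,
                          fpr_caps = c(0.01, 0.05, 0.10), nboot = 0L,
                          seed = NULL, batch_size = 5000L, workers = 1L) {
  stopifnot(is(db, "SignatureDB"))
  sets_map <- category_sets(categories)
  meta <- parse_treatment_ids(db@treatment_ids)

  need_rank <- "cmap" %in% methods
  need_gs <- any(c("gcmap", "fisher") %in% methods)
  full <- read_batch(db, 1L, db@n_treatments)
  rank_db <- NULL
  if (need_rank) {
    rank_db <- build_sig_db(rank_transform_matrix(full),
                            value_kind = "rank",
                            out_path = tempfile(fileext = ".h5"),
                            chunk_treatments = batch_size)
  }
  gs_db <- NULL
  if (need_gs) {
    gs_db <- gep_to_gs_db(db, higher = higher, lower = lower,
                          out_path = tempfile(fileext = ".h5"),
                          batch_size = batch_size)
  }

  usable <- skipped <- character(0)
  members_by_cat <- list()
  for (cat in names(sets_map)) {
    qids <- meta$treatment_id[meta$pert %in% sets_map[[cat]]]
    if (length(qids) < 2L) skipped <- c(skipped, cat)
    else { usable <- c(usable, cat); members_by_cat[[cat]] <- qids }
  }
  if (length(usable) == 0L) vstop("no category has >= 2 database members")

  labeled <- list()      # method -> per-category labeled score frames
  for (method in methods) labeled[[method]] <- list()
  for (cat in usable) {
    qids <- members_by_cat[[cat]]
    for (method in methods) {
      res <- list()
      for (qid in qids) {
        col <- full[, qid]
        profile <- ExpressionProfile(db@gene_ids, col, db@value_kind)
        qsets <- top_n_sets(profile, n_up, n_down)
        qs <- build_benchmark_query(method, profile, qsets, rank_db,
                                    gs_db, db, n_up, n_down)
        res[[qid]] <- gess_search(qs, batch_size, workers)
      }
      labeled[[method]][[cat]] <- assemble_labels(res, sets_map, cat)
    }
  }

  summarize <- function(ls) {
    out <- c(auc = roc_auc(ls$score, ls$label, 1))
    for (f in fpr_caps)
      out[sprintf("pauc_%g", f)] <- roc_auc(ls$score, ls$label, f)
    out
  }
  per_category <- do.call(rbind, lapply(names(labeled), function(method) {
    do.call(rbind, lapply(usable, function(cat) {
      ls <- labeled[[method]][[cat]]
      if (length(unique(ls$label)) < 2L) return(NULL)
      data.frame(category = cat, method = method, t(summarize(ls)),
                 stringsAsFactors = FALSE)
    }))
  }))
  globalize <- function(cats) {
    do.call(rbind, lapply(names(labeled), function(method) {
      all <- do.call(rbind, labeled[[method]][cats])
      data.frame(method = method, t(summarize(all)),
                 stringsAsFactors = FALSE)
    }))
  }
  global <- globalize(usable)

  auc_mat <- with(per_category,
                  tapply(auc, list(category, method), identity))
  retained <- filter_top_categories(auc_mat, fraction)
  global_retained <- globalize(intersect(usable, retained))

  global_scores <- lapply(names(labeled), function(method) {
    all <- do.call(rbind, labeled[[method]][usable])
    key <- paste(all$query_id, all$treatment_id)
    all[order(key), c("score", "label")]
  })
  names(global_scores) <- names(labeled)

  auc_test <- NULL
  if (nboot > 0L && length(methods) > 1L) {
    pm <- matrix(NA_real_, length(methods), length(methods),
                 dimnames = list(methods, methods))
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    for (i in seq_along(pairs)) {
      m1 <- pairs[[i]][1]; m2 <- pairs[[i]][2]
      bt <- bootstrap_auc_test(global_scores[[m1]]$score,
                               global_scores[[m2]]$score,
                               global_scores[[m1]]$label,
                               nboot = nboot,
                               seed = if (is.null(seed)) NULL else seed + i)
      pm[m1, m2] <- pm[m2, m1] <- bt$pvalue
    }
    padj <- adjust_pvalues(
      pm[upper.tri(pm)][!is.na(pm[upper.tri(pm)])], "BH")
    pm[upper.tri(pm)] <- padj
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    auc_test <- pm
  }

  list(global = global, per_category = per_category, retained = retained,
       global_retained = global_retained, skipped = skipped,
       auc_test = auc_test, labeled = global_scores)
}
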