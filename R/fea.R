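# Functional enrichment of search results: duplication-aware target set
# enrichment (dup_hyperG, mGSEA, mabs), drug set enrichment (hyperG, GSEA),
# drug->target mapping with promiscuity filtering.

#' Functional category collections
#'
#' A flat collection of functional annotation categories (GO terms,
#' pathways, drug MOAs, ...) over a common universe of annotatable
#' identifiers. Categories are taken as given sets; no ontology structure
#' is traversed.
#'
#' @param sets Named list of member identifier vectors.
#' @param descriptions Optional named character vector of category
#'   descriptions.
#' @param universe Identifier universe; defaults to the union of all
#'   members. All members must be contained in it.
#' @return A `CategoryCollection` (list with elements `sets`,
#'   `descriptions`, `universe`).
#' @export
category_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    vstop("sets must be a uniquely named list")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  outside <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(outside))
    vstop("category members outside the universe: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "CategoryCollection")
}

#' Read / write GMT category files
#'
#' Standard GMT format: one category per line,
#' `id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @param universe Optional universe passed to [category_collection()].
#' @return `read_gmt()`: a `CategoryCollection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) vstop("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  category_collection(sets, stats::setNames(desc, ids), universe)
}

#' @param categories A `CategoryCollection` to write.
#' @rdname read_gmt
#' @export
write_gmt <- function(categories, path) {
  lines <- vapply(names(categories$sets), function(id) {
    paste(c(id, categories$descriptions[[id]], categories$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Drug-target annotation tables
#'
#' @param targets Named list: drug id -> character vector of target gene
#'   identifiers (non-empty, unique drugs).
#' @return A `DrugTargetTable` (named list of target sets).
#' @export
drug_target_table <- function(targets) {
  if (is.null(names(targets)) || anyDuplicated(names(targets)))
    vstop("targets must be a uniquely named list keyed by drug id")
  targets <- lapply(targets, function(t) unique(as.character(t)))
  if (any(lengths(targets) == 0L)) vstop("target sets must be non-empty")
  structure(targets, class = "DrugTargetTable")
}

#' Read a drug-target annotation TSV
#'
#' Two columns (`drug<TAB>target`), one pair per row, optional header.
#'
#' @param path File path.
#' @return A `DrugTargetTable`.
#' @export
read_drug_targets <- function(path) {
  if (!file.exists(path)) vstop("annotation file not found: %s", path)
  dt <- data.table::fread(path, header = "auto",
                          col.names = c("drug", "target"))
  drug_target_table(split(as.character(dt$target), as.character(dt$drug)))
}

#' @rdname read_drug_targets
#' @param annotations A `DrugTargetTable` to write.
#' @export
write_drug_targets <- function(annotations, path) {
  df <- data.frame(drug = rep(names(annotations), lengths(annotations)),
                   target = unlist(annotations, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Convert a ranked drug list into a target multiset
#'
#' Pools the target sets of the annotated drugs into a multiset: the
#' multiplicity of each target counts how many of the test drugs share it,
#' the frequency information that the duplication-aware TSEA methods weight
#' by. Drugs binding more than `max_targets_per_drug` distinct targets
#' (promiscuous binders) are excluded before pooling; unannotated drugs are
#' recorded but not fatal. For scored input every target also inherits the
#' best score (maximal magnitude) among its drugs, giving the score-ranked
#' target list consumed by [tsea_mGSEA()].
#'
#' @param drugs Character vector of drug identifiers (ranked, e.g. the top
#'   drugs of a search result).
#' @param annotations A `DrugTargetTable`.
#' @param scores Optional numeric vector aligned with `drugs` (e.g. their
#'   similarity scores).
#' @param max_targets_per_drug Promiscuity cap (default `Inf`, i.e. off).
#' @return A `TargetMultiset`: list with `counts` (named multiplicities),
#'   `total`, `targets` (data.frame `target`, `mult`, `score` sorted by
#'   decreasing score magnitude), `unannotated`, `excluded`.
#' @export
drugs_to_targets <- function(drugs, annotations, scores = NULL,
                             max_targets_per_drug = Inf) {
  drugs <- as.character(drugs)
  if (length(drugs) == 0L) vstop("drugs must be non-empty")
  if (!inherits(annotations, "DrugTargetTable"))
    annotations <- drug_target_table(annotations)
  known <- drugs %in% names(annotations)
  unannotated <- drugs[!known]
  kept <- drugs[known]
  if (length(kept) == 0L) vstop("none of the drugs is annotated")
  sizes <- lengths(annotations[kept])
  excluded <- kept[sizes > max_targets_per_drug]
  kept <- kept[sizes <= max_targets_per_drug]
  if (length(kept) == 0L)
    vstop("all annotated drugs exceed the promiscuity cap (%s)",
          format(max_targets_per_drug))
  tsets <- annotations[kept]
  all_targets <- unlist(tsets, use.names = FALSE)
  counts <- table(all_targets)
  counts <- stats::setNames(as.integer(counts), names(counts))
  tscore <- rep(NA_real_, length(counts))
  names(tscore) <- names(counts)
  if (!is.null(scores)) {
    if (length(scores) != length(drugs))
      vstop("scores must align with drugs")
    dscore <- stats::setNames(as.numeric(scores), drugs)[kept]
    for (d in kept) {
      for (tg in tsets[[d]]) {
        if (is.na(tscore[tg]) || abs(dscore[d]) > abs(tscore[tg]))
          tscore[tg] <- dscore[d]
      }
    }
  }
  tdf <- data.frame(target = names(counts), mult = unname(counts),
                    score = unname(tscore), stringsAsFactors = FALSE)
  tdf <- tdf[order(-abs(tdf$score), tdf$target), , drop = FALSE]
  rownames(tdf) <- NULL
  structure(list(counts = counts, total = sum(counts), targets = tdf,
                 unannotated = unannotated, excluded = excluded),
            class = "TargetMultiset")
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over the standard step-up/step-down procedures with input
#' validation; supported methods are BH (default), bonferroni, holm,
#' hochberg, hommel, BY and none.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment method.
#' @return Adjusted p-values (monotone in `p`, capped at 1).
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm",
                                         "hochberg", "hommel", "BY",
                                         "none")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    vstop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

fea_result_df <- function(categories, rows, adjust) {
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L)
    vstop("no category could be tested")
  df$description <- unname(categories$descriptions[df$category])
  df$padj <- adjust_pvalues(df$pvalue, adjust)
  df <- df[order(df$pvalue, df$category), , drop = FALSE]
  rownames(df) <- NULL
  cols <- c("category", "description",
            setdiff(names(df), c("category", "description")))
  df[, cols]
}

#' Duplication-adjusted hypergeometric target set enrichment
#'
#' Hypergeometric over-representation test in which the test-set size and
#' the match count are both weighted by the multiplicities of the targets
#' in the test multiset: `n_test` is the total multiplicity and `n_match`
#' the summed multiplicity of test genes inside the category, while the
#' category size and universe stay unweighted. With unit multiplicities
#' this reduces exactly to the classical hypergeometric test. The p-value
#' is the upper tail `P(X >= n_match)` with
#' `X ~ Hypergeom(N = |universe|, K = n_category, n = n_test)`; when
#' `n_match > K` the tail is 0 by definition.
#'
#' @param targets A `TargetMultiset` from [drugs_to_targets()], or a named
#'   numeric vector of multiplicities.
#' @param categories A `CategoryCollection` (gene level).
#' @param adjust P-value adjustment method (see [adjust_pvalues()]).
#' @return A [feaResult] with columns `n_category`, `n_test`, `n_match`,
#'   `pvalue`, `padj`, sorted by p-value.
#' @export
tsea_dup_hyperG <- function(targets, categories, adjust = "BH") {
  counts <- if (inherits(targets, "TargetMultiset")) targets$counts
            else stats::setNames(as.integer(targets), names(targets))
  universe <- categories$universe
  if (length(universe) == 0L) vstop("empty universe")
  in_univ <- names(counts) %in% universe
  if (!any(in_univ))
    vstop("no test target is contained in the annotation universe")
  counts <- counts[in_univ]
  N <- length(universe)
  n_test <- sum(counts)
  # heavy duplication against a small universe can push the weighted test
  # size beyond the population; the draw count is capped at N (the match
  # count is not, so extreme overlaps still drive the tail to 0)
  n_draw <- min(n_test, N)
  rows <- lapply(names(categories$sets), function(id) {
    members <- intersect(categories$sets[[id]], universe)
    K <- length(members)
    k <- sum(counts[names(counts) %in% members])
    p <- stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(category = id, n_category = K, n_test = n_test,
               n_match = k, pvalue = p, stringsAsFactors = FALSE)
  })
  df <- fea_result_df(categories, rows, adjust)
  new("feaResult", result = df, drugs = character(0), targets = targets,
      method = "dup_hyperG", params = list(adjust = adjust))
}

# Shared multiplicity-weighted GSEA core over a ranked list.
# list_ids: identifiers sorted by decreasing score; scores aligned; mult
# aligned multiplicities. Returns per-category ES/NES/p plus permutation
# diagnostics.
mgsea_core <- function(list_ids, scores, mult, categories, exponent, nperm,
                       seed, adjust, method_label) {
  n <- length(list_ids)
  if (n < 2L) vstop("ranked list too short")
  ord <- order(-scores, list_ids)
  list_ids <- list_ids[ord]; scores <- scores[ord]; mult <- mult[ord]
  base_w <- abs(scores)^exponent
  skipped <- character(0)
  rows <- list()
  perm_stats <- list()
  with_seed(seed, {
    for (id in names(categories$sets)) {
      hit <- list_ids %in% categories$sets[[id]]
      t <- sum(hit)
      if (t == 0L) { skipped <- c(skipped, id); next }
      idx <- which(hit)
      es <- gsea_es_sparse(idx, mult[idx] * base_w[idx], n)
      perm <- vapply(seq_len(nperm), function(b) {
        pidx <- sort.int(sample.int(n, t))
        # gene labels are permuted: the category's genes (with their
        # multiplicities) land on random positions of the score-ranked list
        pm <- mult[idx][sample.int(t)]
        gsea_es_sparse(pidx, pm * base_w[pidx], n)
      }, numeric(1))
      same_sign <- perm[sign(perm) == sign(es)]
      if (length(same_sign) == 0L) {
        p <- 1 / (nperm + 1)
        nes <- NA_real_
      } else {
        p <- mean(abs(same_sign) >= abs(es))
        nes <- es / mean(abs(same_sign))
      }
      rows[[id]] <- data.frame(category = id, n_category =
                                 length(categories$sets[[id]]),
                               n_test = n, n_match = t, ES = es, NES = nes,
                               pvalue = p, stringsAsFactors = FALSE)
    }
  })
  if (length(skipped))
    warning(sprintf("%d categor(ies) with no member in the ranked list were skipped",
                    length(skipped)), call. = FALSE)
  df <- fea_result_df(categories, rows, adjust)
  attr(df, "skipped") <- skipped
  df
}

#' Multiplicity-weighted GSEA (mGSEA) target set enrichment
#'
#' GSEA running-sum enrichment over a score-ranked target list in which a
#' hit at position *i* advances the running sum by
#' `mult_i * |score_i|^exponent` (normalized by the total over hits) and a
#' miss retreats it by `1/#misses`, so the frequency of duplicated targets
#' is preserved as weight. Significance comes from `nperm` permutations of
#' the gene labels of the ranked list: the p-value is the fraction of
#' same-sign permutation scores at least as extreme as the observed ES, and
#' `NES = ES / mean(|same-sign permutation ES|)`. Categories without any
#' member in the list are skipped (recorded in the `skipped` attribute of
#' the result table).
#'
#' @param targets A `TargetMultiset` (from [drugs_to_targets()] with
#'   scores) or a data.frame with columns `target`, `score`, `mult`.
#' @param categories A `CategoryCollection`.
#' @param exponent Weight power (default 1).
#' @param nperm Number of label permutations (default 1000, minimum 100).
#' @param seed Optional RNG seed for the permutation null.
#' @param adjust P-value adjustment method.
#' @return A [feaResult] with columns `ES`, `NES`, `pvalue`, `padj`.
#' @export
tsea_mGSEA <- function(targets, categories, exponent = 1, nperm = 1000L,
                       seed = NULL, adjust = "BH") {
  if (nperm < 100L) vstop("nperm must be >= 100")
  tdf <- if (inherits(targets, "TargetMultiset")) targets$targets
         else as.data.frame(targets)
  if (!all(c("target", "score", "mult") %in% names(tdf)))
    vstop("targets must provide columns target/score/mult")
  if (any(is.na(tdf$score)))
    vstop("mGSEA needs a scored target list (run drugs_to_targets with scores)")
  df <- mgsea_core(tdf$target, tdf$score, tdf$mult, categories, exponent,
                   nperm, seed, adjust, "mGSEA")
  new("feaResult", result = df, drugs = character(0), targets = targets,
      method = "mGSEA",
      params = list(exponent = exponent, nperm = nperm, adjust = adjust))
}

#' MeanAbs (mabs) target set enrichment
#'
#' Scores each category by the mean of the absolute statistic values of its
#' members present in the scored target vector; significance is the
#' fraction of `nperm` random same-size gene sets (drawn from the scored
#' genes) reaching an equal or larger mean.
#'
#' @param scored_targets Named numeric vector: gene -> statistic (e.g.
#'   z-score or LFC).
#' @param categories A `CategoryCollection`.
#' @param nperm Number of random sets per category (default 1000).
#' @param seed Optional RNG seed.
#' @param adjust P-value adjustment method.
#' @return A [feaResult] with columns `mabs`, `pvalue`, `padj`.
#' @export
tsea_mabs <- function(scored_targets, categories, nperm = 1000L,
                      seed = NULL, adjust = "BH") {
  if (is.null(names(scored_targets)) || length(scored_targets) == 0L)
    vstop("scored_targets must be a non-empty named vector")
  absval <- abs(scored_targets)
  genes <- names(scored_targets)
  skipped <- character(0)
  rows <- list()
  with_seed(seed, {
    for (id in names(categories$sets)) {
      members <- intersect(categories$sets[[id]], genes)
      k <- length(members)
      if (k == 0L) { skipped <- c(skipped, id); next }
      obs <- mean(absval[members])
      null <- vapply(seq_len(nperm), function(b) {
        mean(absval[sample.int(length(absval), k)])
      }, numeric(1))
      rows[[id]] <- data.frame(category = id,
                               n_category = length(categories$sets[[id]]),
                               n_test = length(genes), n_match = k,
                               mabs = obs, pvalue = mean(null >= obs),
                               stringsAsFactors = FALSE)
    }
  })
  if (length(skipped))
    warning(sprintf("%d categor(ies) with no scored member were skipped",
                    length(skipped)), call. = FALSE)
  df <- fea_result_df(categories, rows, adjust)
  attr(df, "skipped") <- skipped
  new("feaResult", result = df, drugs = character(0),
      targets = scored_targets, method = "mabs",
      params = list(nperm = nperm, adjust = adjust))
}

#' Hypergeometric drug set enrichment
#'
#' Classical hypergeometric over-representation of a drug set in drug-level
#' annotation categories (the functional categories of the targets assigned
#' directly to the drugs). Duplicate input drugs are removed with a
#' warning: drug test sets are unique by construction.
#'
#' @param drugs Character vector of drugs (the test set).
#' @param drug_categories A `CategoryCollection` over drug identifiers.
#' @param adjust P-value adjustment method.
#' @return A [feaResult].
#' @export
dsea_hyperG <- function(drugs, drug_categories, adjust = "BH") {
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs)) {
    warning("duplicate drugs in the test set were removed", call. = FALSE)
    drugs <- unique(drugs)
  }
  universe <- drug_categories$universe
  test <- intersect(drugs, universe)
  if (length(test) == 0L)
    vstop("no test drug is contained in the annotation universe")
  N <- length(universe)
  n <- length(test)
  rows <- lapply(names(drug_categories$sets), function(id) {
    members <- drug_categories$sets[[id]]
    K <- length(members)
    k <- length(intersect(test, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = id, n_category = K, n_test = n, n_match = k,
               pvalue = p, stringsAsFactors = FALSE)
  })
  df <- fea_result_df(drug_categories, rows, adjust)
  new("feaResult", result = df, drugs = drugs, targets = NULL,
      method = "dsea_hyperG", params = list(adjust = adjust))
}

#' GSEA drug set enrichment
#'
#' The GSEA running-sum enrichment of [tsea_mGSEA()] applied to a
#' score-ranked drug list with unit multiplicities, against drug-level
#' categories.
#'
#' @param ranked_drugs data.frame with columns `drug` and `score`, or a
#'   named numeric score vector.
#' @inheritParams tsea_mGSEA
#' @param drug_categories A `CategoryCollection` over drug identifiers.
#' @return A [feaResult].
#' @export
dsea_GSEA <- function(ranked_drugs, drug_categories, exponent = 1,
                      nperm = 1000L, seed = NULL, adjust = "BH") {
  if (nperm < 100L) vstop("nperm must be >= 100")
  if (is.numeric(ranked_drugs) && !is.null(names(ranked_drugs))) {
    ranked_drugs <- data.frame(drug = names(ranked_drugs),
                               score = unname(ranked_drugs),
                               stringsAsFactors = FALSE)
  }
  if (!all(c("drug", "score") %in% names(ranked_drugs)))
    vstop("ranked_drugs must provide columns drug/score")
  df <- mgsea_core(ranked_drugs$drug, ranked_drugs$score,
                   rep(1L, nrow(ranked_drugs)), drug_categories, exponent,
                   nperm, seed, adjust, "dsea_GSEA")
  new("feaResult", result = df, drugs = ranked_drugs$drug, targets = NULL,
      method = "dsea_GSEA",
      params = list(exponent = exponent, nperm = nperm, adjust = adjust))
}
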