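# The five signature search methods and the batched search engine.

# Map query set genes to the database gene space; absent genes are dropped
# with a warning (the KS set size t reflects retained genes only). A
# non-empty set losing all genes is an error naming the set.
match_query_set <- function(set, gene_ids, set_name) {
  if (length(set) == 0L) return(integer(0))
  idx <- match(set, gene_ids)
  if (anyNA(idx)) {
    dropped <- sum(is.na(idx))
    if (dropped == length(set))
      vstop("query '%s' set has no overlap with the database gene space",
            set_name)
    warning(sprintf("%d of %d '%s' query genes absent from the database; dropped",
                    dropped, length(set), set_name), call. = FALSE)
    idx <- idx[!is.na(idx)]
  }
  idx
}

finish_gess <- function(df, qsig, params, order_by, decreasing = TRUE,
                        absolute = FALSE) {
  key <- df[[order_by]]
  if (absolute) key <- abs(key)
  ord <- order(if (decreasing) -key else key, df$treatment_id, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  new("gessResult", result = df, query = qsig@query, method = qsig@method,
      params = params)
}

#' CMAP signature search
#'
#' Searches a rank-transformed database with an up/down gene-set query.
#' For each treatment the KS statistics of the up and down sets within the
#' treatment's ranked gene list are computed ([ks_statistic()]); the raw
#' connectivity score is their difference `ks_up - ks_down` when the two
#' statistics have opposite signs and 0 otherwise. Raw scores are then
#' scaled over the whole search to `[-1, 1]`: positives divided by the
#' search maximum, negatives by the magnitude of the search minimum. A
#' scaled score of 1 marks the most query-like entry, -1 the most opposed.
#'
#' @param qsig A [qSig] with a [GeneSetPair] query and a rank database.
#' @param batch_size Treatments per database scan batch.
#' @param workers Parallel workers (forked); results are identical for any
#'   value.
#' @return A [gessResult] sorted by scaled score (descending), columns
#'   `treatment_id`, `pert`, `cell`, `perttype`, `ks_up`, `ks_down`,
#'   `raw_score`, `scaled_score`, `trend`.
#' @export
gess_cmap <- function(qsig, batch_size = 5000L, workers = 1L) {
  stopifnot(is(qsig, "qSig"), qsig@method == "cmap")
  db <- qsig@db
  q <- qsig@query
  idx_up <- match_query_set(q@up, db@gene_ids, "up")
  idx_dn <- match_query_set(q@down, db@gene_ids, "down")
  n <- db@n_genes
  pieces <- scan_db(db, batch_size, function(mat, s) {
    t(vapply(seq_len(ncol(mat)), function(j) {
      r <- mat[, j]
      ku <- if (length(idx_up)) ks_statistic_fast(sort(r[idx_up]), n)$ks
            else NA_real_
      kd <- if (length(idx_dn)) ks_statistic_fast(sort(r[idx_dn]), n)$ks
            else NA_real_
      c(ks_up = ku, ks_down = kd)
    }, numeric(2)))
  }, workers)
  ks <- do.call(rbind, pieces)
  raw <- vapply(seq_len(nrow(ks)), function(i) {
    cmap_raw_score(ks[i, 1], ks[i, 2])
  }, numeric(1))
  scaled <- scale_connectivity_scores(raw)
  meta <- parse_treatment_ids(db@treatment_ids)
  df <- cbind(meta, data.frame(ks_up = ks[, 1], ks_down = ks[, 2],
                               raw_score = raw, scaled_score = scaled,
                               trend = ifelse(scaled >= 0, "up", "down"),
                               stringsAsFactors = FALSE))
  finish_gess(df, qsig, list(batch_size = batch_size, workers = workers),
              "scaled_score")
}

#' LINCS weighted connectivity search
#'
#' Searches a z-score database with an up/down gene-set query using the
#' bi-directional weighted KS enrichment statistic ([weighted_ks_es()]).
#' Per treatment, enrichment scores `es_up` and `es_down` of the two query
#' sets are combined into the weighted connectivity score
#' `WTCS = (es_up - es_down)/2` when the two have opposite signs and 0
#' otherwise (one-sided queries use the single available score). WTCS
#' values are normalized within (cell, perttype) groups to NCS by dividing
#' by the magnitude of the same-sign group mean, and standardized to tau,
#' the signed percentage of reference NCS magnitudes (by default the
#' search's own values within the group) smaller than the entry's.
#'
#' @param qsig A [qSig] with method `"lincs"`. Recognized params:
#'   `exponent` (weight power, default 1), `tau` (logical, compute NCS/tau,
#'   default TRUE), `tau_reference` (optional external numeric vector of
#'   reference NCS values).
#' @inheritParams gess_cmap
#' @return A [gessResult] sorted by WTCS, columns `treatment_id`, `pert`,
#'   `cell`, `perttype`, `n_up`, `n_down`, `es_up`, `es_down`, `wtcs`,
#'   `ncs`, `tau`.
#' @export
gess_lincs <- function(qsig, batch_size = 5000L, workers = 1L) {
  stopifnot(is(qsig, "qSig"), qsig@method == "lincs")
  db <- qsig@db
  q <- qsig@query
  exponent <- qsig@params$exponent %||% 1
  want_tau <- qsig@params$tau %||% TRUE
  up <- intersect(q@up, db@gene_ids)
  dn <- intersect(q@down, db@gene_ids)
  if (length(up) < length(q@up) || length(dn) < length(q@down))
    warning("query genes absent from the database were dropped",
            call. = FALSE)
  if (length(up) == 0L && length(dn) == 0L)
    vstop("both query sets are empty after intersecting with the database")
  gene_ids <- db@gene_ids
  pieces <- scan_db(db, batch_size, function(mat, s) {
    t(vapply(seq_len(ncol(mat)), function(j) {
      sc <- mat[, j]
      names(sc) <- gene_ids
      eu <- if (length(up)) weighted_ks_es(up, sc, exponent) else NA_real_
      ed <- if (length(dn)) weighted_ks_es(dn, sc, exponent) else NA_real_
      c(es_up = eu, es_down = ed)
    }, numeric(2)))
  }, workers)
  es <- do.call(rbind, pieces)
  wtcs <- vapply(seq_len(nrow(es)), function(i) {
    eu <- es[i, 1]; ed <- es[i, 2]
    if (is.na(ed)) return(eu)
    if (is.na(eu)) return(-ed)
    if (sign(eu) != sign(ed)) (eu - ed) / 2 else 0
  }, numeric(1))
  meta <- parse_treatment_ids(db@treatment_ids)
  ncs <- tau <- rep(NA_real_, length(wtcs))
  if (isTRUE(want_tau)) {
    ncs <- normalize_ncs(wtcs, meta$cell, meta$perttype)
    grp <- paste(meta$cell, meta$perttype, sep = "\r")
    ref <- qsig@params$tau_reference
    for (g in unique(grp)) {
      i <- grp == g
      tau[i] <- compute_tau(ncs[i], if (is.null(ref)) ncs[i] else ref)
    }
  }
  df <- cbind(meta, data.frame(n_up = length(up), n_down = length(dn),
                               es_up = es[, 1], es_down = es[, 2],
                               wtcs = wtcs, ncs = ncs, tau = tau,
                               stringsAsFactors = FALSE))
  finish_gess(df, qsig,
              list(batch_size = batch_size, workers = workers,
                   exponent = exponent), "wtcs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize WTCS values to NCS within experimental groups
#'
#' Within each (cell, perttype) group and score sign, the normalized
#' connectivity score is the WTCS divided by the magnitude of the mean of
#' the same-sign WTCS values of the group; signs are preserved and zeros
#' stay zero. A group/sign stratum containing a single value normalizes it
#' to +/-1.
#'
#' @param wtcs Numeric vector of weighted connectivity scores.
#' @param cell,perttype Group keys, recycled to `length(wtcs)`.
#' @return Numeric vector of NCS values.
#' @examples
#' normalize_ncs(c(0.2, 0.4), "PC3", "trt_cp")  # 0.667 1.333
#' @export
normalize_ncs <- function(wtcs, cell, perttype) {
  grp <- paste(rep_len(cell, length(wtcs)),
               rep_len(perttype, length(wtcs)), sep = "\r")
  ncs <- numeric(length(wtcs))
  for (g in unique(grp)) {
    for (s in c(1, -1)) {
      i <- grp == g & !is.na(wtcs) & sign(wtcs) == s
      if (!any(i)) next
      ncs[i] <- wtcs[i] / abs(mean(wtcs[i]))
    }
  }
  ncs[is.na(wtcs)] <- NA_real_
  ncs
}

#' Standardize NCS values to tau scores
#'
#' `tau = sign(ncs) * 100/N * #\{r in reference : |r| < |ncs|\}`: the signed
#' percentage of reference score magnitudes strictly smaller than the
#' entry's, in `[-100, 100]`.
#'
#' @param ncs Numeric vector of normalized connectivity scores.
#' @param reference Numeric vector of reference NCS values (magnitudes are
#'   used); must be non-empty.
#' @return Numeric vector of tau scores.
#' @examples
#' compute_tau(2.0, c(0.5, 1.0, 1.5, 2.5))  # 75
#' @export
compute_tau <- function(ncs, reference) {
  if (length(reference) == 0L) vstop("reference must be non-empty")
  refmag <- abs(reference)
  nref <- length(refmag)
  vapply(ncs, function(x) {
    if (is.na(x)) return(NA_real_)
    sign(x) * 100 / nref * sum(refmag < abs(x))
  }, numeric(1))
}

#' gCMAP signature search
#'
#' The role-swapped counterpart of [gess_cmap()]: the query is a
#' rank-transformed profile and each database entry is an up/down gene-set
#' pair. Per entry, the KS statistics of the entry's up and down sets are
#' located within the query's ranked profile; raw score, zero-exception and
#' scaling rules are identical to the CMAP method. Entries with no gene in
#' common with the query score 0 and are flagged in the `no_overlap`
#' column.
#'
#' @param qsig A [qSig] with a rank [ExpressionProfile] query and a
#'   gene-set database.
#' @inheritParams gess_cmap
#' @return A [gessResult] sorted by scaled score.
#' @export
gess_gcmap <- function(qsig, batch_size = 5000L, workers = 1L) {
  stopifnot(is(qsig, "qSig"), qsig@method == "gcmap")
  db <- qsig@db
  q <- qsig@query
  ranks <- q@values
  names(ranks) <- q@gene_ids
  n <- length(ranks)
  pieces <- scan_db(db, batch_size, function(batch, s) {
    lapply(seq_along(batch$treatment_ids), function(j) {
      pu <- sort(ranks[intersect(batch$up[[j]], q@gene_ids)])
      pd <- sort(ranks[intersect(batch$down[[j]], q@gene_ids)])
      ku <- if (length(pu)) ks_statistic_fast(unname(pu), n)$ks else NA_real_
      kd <- if (length(pd)) ks_statistic_fast(unname(pd), n)$ks else NA_real_
      no_overlap <- length(pu) == 0L && length(pd) == 0L
      raw <- if (no_overlap) 0 else cmap_raw_score(ku, kd)
      c(ks_up = ku, ks_down = kd, raw_score = raw,
        no_overlap = as.numeric(no_overlap))
    })
  }, workers)
  rows <- do.call(rbind, unlist(pieces, recursive = FALSE))
  if (any(rows[, "no_overlap"] > 0))
    warning(sprintf("%d database entrie(s) share no genes with the query; scored 0",
                    sum(rows[, "no_overlap"] > 0)), call. = FALSE)
  scaled <- scale_connectivity_scores(rows[, "raw_score"])
  meta <- parse_treatment_ids(db@treatment_ids)
  df <- cbind(meta, data.frame(ks_up = rows[, "ks_up"],
                               ks_down = rows[, "ks_down"],
                               raw_score = rows[, "raw_score"],
                               scaled_score = scaled,
                               trend = ifelse(scaled >= 0, "up", "down"),
                               no_overlap = rows[, "no_overlap"] > 0,
                               stringsAsFactors = FALSE))
  finish_gess(df, qsig, list(batch_size = batch_size, workers = workers),
              "scaled_score")
}

#' Fisher's exact test signature search
#'
#' Over-representation search of a gene-set query against a gene-set
#' database. Per entry, the query genes (up and down combined) and the
#' entry genes are compared in a 2x2 incidence matrix over the gene
#' universe; the p-value is the upper hypergeometric tail
#' `P(X >= overlap)`, adjusted across all entries with Benjamini-Hochberg.
#'
#' @param qsig A [qSig] with method `"fisher"`. Param `universe` may supply
#'   the background gene universe (default: the database gene space); both
#'   query and entry sets must be contained in it.
#' @inheritParams gess_cmap
#' @return A [gessResult] sorted by p-value, columns `overlap`, `n_query`,
#'   `n_set`, `n_universe`, `odds_ratio`, `pvalue`, `padj`.
#' @export
gess_fisher <- function(qsig, batch_size = 5000L, workers = 1L) {
  stopifnot(is(qsig, "qSig"), qsig@method == "fisher")
  db <- qsig@db
  q <- qsig@query
  universe <- qsig@params$universe %||% db@gene_ids
  qgenes <- union(q@up, q@down)
  if (!all(qgenes %in% universe))
    vstop("query genes outside the universe (%d missing)",
          sum(!qgenes %in% universe))
  N <- length(universe)
  m <- length(qgenes)
  pieces <- scan_db(db, batch_size, function(batch, s) {
    t(vapply(seq_along(batch$treatment_ids), function(j) {
      eg <- union(batch$up[[j]], batch$down[[j]])
      if (!all(eg %in% universe))
        vstop("database entry '%s' has genes outside the universe",
              batch$treatment_ids[j])
      s_ <- length(eg)
      k <- length(intersect(qgenes, eg))
      p <- stats::phyper(k - 1, m, N - m, s_, lower.tail = FALSE)
      orr <- (k * (N - m - s_ + k)) / ((m - k) * (s_ - k))
      c(overlap = k, n_set = s_, pvalue = p, odds_ratio = orr)
    }, numeric(4)))
  }, workers)
  st <- do.call(rbind, pieces)
  meta <- parse_treatment_ids(db@treatment_ids)
  df <- cbind(meta, data.frame(overlap = as.integer(st[, "overlap"]),
                               n_query = m, n_set = as.integer(st[, "n_set"]),
                               n_universe = N,
                               odds_ratio = st[, "odds_ratio"],
                               pvalue = st[, "pvalue"],
                               padj = stats::p.adjust(st[, "pvalue"], "BH"),
                               stringsAsFactors = FALSE))
  finish_gess(df, qsig, list(batch_size = batch_size, workers = workers,
                             universe_size = N), "pvalue",
              decreasing = FALSE)
}

#' Correlation-based signature search
#'
#' Computes Spearman or Pearson correlations between a quantitative query
#' profile and every database entry over their common gene space. With
#' `subset = "sub"` the computation is restricted to a gene subset (by
#' default the query's own genes, typically its top up/down DEGs: the
#' *SPsub* configuration); `subset = "all"` uses all shared genes
#' (*SPall*).
#'
#' @param qsig A [qSig] with method `"cor"`. Recognized params: `flavor`
#'   (`"spearman"` or `"pearson"`, default spearman), `subset` (`"all"` or
#'   `"sub"`, default `"all"`), `gene_subset` (optional identifier vector
#'   used when `subset = "sub"`).
#' @inheritParams gess_cmap
#' @return A [gessResult] sorted by absolute correlation, columns
#'   `cor_score`, `trend`, `n_genes_used`, `flag` (`"ok"`,
#'   `"few_genes"` for fewer than 3 shared genes, `"zero_variance"`).
#' @export
gess_cor <- function(qsig, batch_size = 5000L, workers = 1L) {
  stopifnot(is(qsig, "qSig"), qsig@method == "cor")
  db <- qsig@db
  q <- qsig@query
  flavor <- match.arg(qsig@params$flavor %||% "spearman",
                      c("spearman", "pearson"))
  subset <- match.arg(qsig@params$subset %||% "all", c("all", "sub"))
  genes <- q@gene_ids
  if (subset == "sub")
    genes <- intersect(qsig@params$gene_subset %||% q@gene_ids, q@gene_ids)
  common <- intersect(genes, db@gene_ids)
  few <- length(common) < 3L
  qv <- q@values[match(common, q@gene_ids)]
  pieces <- scan_db(db, batch_size, function(mat, s) {
    if (few) {
      cbind(cor_score = rep(NA_real_, ncol(mat)),
            zero_var = rep(0, ncol(mat)))
    } else {
      sub <- mat[common, , drop = FALSE]
      sds <- apply(sub, 2L, stats::sd)
      r <- suppressWarnings(as.numeric(
        stats::cor(qv, sub, method = flavor)))
      cbind(cor_score = r, zero_var = as.numeric(sds == 0 | is.na(sds)))
    }
  }, workers)
  st <- do.call(rbind, pieces)
  flag <- rep("ok", nrow(st))
  if (few) flag[] <- "few_genes"
  flag[st[, "zero_var"] > 0] <- "zero_variance"
  meta <- parse_treatment_ids(db@treatment_ids)
  r <- st[, "cor_score"]
  df <- cbind(meta, data.frame(cor_score = r,
                               trend = ifelse(is.na(r), NA_character_,
                                              ifelse(r > 0, "up", "down")),
                               n_genes_used = length(common), flag = flag,
                               stringsAsFactors = FALSE))
  finish_gess(df, qsig, list(batch_size = batch_size, workers = workers,
                             flavor = flavor, subset = subset),
              "cor_score", absolute = TRUE)
}

#' Run a signature search
#'
#' Dispatches a validated [qSig] to its search method. Results are
#' independent of `batch_size` and `workers`: batching and parallelism
#' partition the database scan but never change any score.
#'
#' @param qsig A [qSig].
#' @param batch_size Treatments per scan batch (default 5000).
#' @param workers Forked parallel workers (default 1).
#' @return A [gessResult].
#' @export
gess_search <- function(qsig, batch_size = 5000L, workers = 1L) {
  stopifnot(is(qsig, "qSig"))
  switch(qsig@method,
         cmap = gess_cmap(qsig, batch_size, workers),
         lincs = gess_lincs(qsig, batch_size, workers),
         gcmap = gess_gcmap(qsig, batch_size, workers),
         fisher = gess_fisher(qsig, batch_size, workers),
         cor = gess_cor(qsig, batch_size, workers),
         vstop("unknown method '%s'", qsig@method))
}

# Primary similarity score of a gessResult, oriented so larger = more
# similar (fisher p-values are negated). Used by the benchmarking module.
primary_score <- function(gr) {
  df <- result(gr)
  switch(gr@method,
         cmap = df$scaled_score,
         gcmap = df$scaled_score,
         lincs = df$wtcs,
         fisher = -df$pvalue,
         cor = abs(df$cor_score),
         vstop("unknown method '%s'", gr@method))
}
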