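# Core statistics of the set-based search methods: the CMAP
# Kolmogorov-Smirnov connectivity statistic and the weighted KS enrichment
# score used by the LINCS method.

#' CMAP Kolmogorov-Smirnov connectivity statistic
#'
#' Given the positions (ranks) of a query gene set within a ranked list of
#' `n` genes, computes the two one-sided maxima of the vectorized rank
#' difference
#' \deqn{a = \max_j (j/t - V_j/n), \qquad b = \max_j (V_j/n - (j-1)/t)}
#' where `V` are the sorted positions and `t` the set size. The signed
#' statistic is `a` if `a >= b`, else `-b`: positive when the set
#' concentrates at the top of the list, negative at the bottom.
#'
#' @param tag_positions Strictly increasing positions in `[1, n]`.
#' @param n Length of the ranked list.
#' @return A list with elements `a`, `b` and `ks`.
#' @examples
#' ks_statistic(c(1, 2), 10)$ks   #  0.8
#' ks_statistic(c(9, 10), 10)$ks  # -0.9
#' @export
ks_statistic <- function(tag_positions, n) {
  t <- length(tag_positions)
  if (t == 0L) vstop("tag_positions must be non-empty")
  if (any(tag_positions < 1) || any(tag_positions > n))
    vstop("tag positions must lie in [1, %d]", n)
  if (is.unsorted(tag_positions, strictly = TRUE))
    vstop("tag_positions must be strictly increasing")
  ks_statistic_fast(as.numeric(tag_positions), n)
}

# Same computation without input validation; positions need only be
# non-decreasing (rank ties in real databases can yield equal average
# ranks). Called per treatment in the search loops.
ks_statistic_fast <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  list(a = a, b = b, ks = if (a >= b) a else -b)
}

# Raw CMAP connectivity score from the up- and down-set KS statistics:
# their difference when the signs disagree, zero otherwise (the "certain
# exceptions" rule). One-sided queries fall back to the single available
# tail.
cmap_raw_score <- function(ks_up, ks_down) {
  if (is.na(ks_up) && is.na(ks_down)) return(NA_real_)
  if (is.na(ks_down)) return(ks_up)
  if (is.na(ks_up)) return(-ks_down)
  if (ks_up != 0 && ks_down != 0 && sign(ks_up) == sign(ks_down)) return(0)
  ks_up - ks_down
}

# Scale raw connectivity scores to [-1, 1]: positives divided by the search
# maximum p, negatives by |q| where q is the search minimum, zeros stay 0.
scale_connectivity_scores <- function(raw) {
  p <- suppressWarnings(max(raw, na.rm = TRUE))
  q <- suppressWarnings(min(raw, na.rm = TRUE))
  out <- numeric(length(raw))
  pos <- !is.na(raw) & raw > 0
  neg <- !is.na(raw) & raw < 0
  if (any(pos)) out[pos] <- raw[pos] / p
  if (any(neg)) out[neg] <- raw[neg] / abs(q)
  out[is.na(raw)] <- NA_real_
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The bi-directional weighted KS running-sum statistic: genes are sorted by
#' score (descending, ties broken by gene id); each gene-set hit advances
#' the running sum by `|score|^exponent` normalized by the total over hits,
#' each miss retreats it by `1/(n - t)`. The enrichment score is the
#' running-sum value of maximal absolute deviation from zero (signed; when
#' the positive and negative extremes tie in magnitude the positive extreme
#' wins).
#'
#' @param gene_set Character vector of gene identifiers.
#' @param scores Named numeric vector: the full signed profile of one
#'   treatment.
#' @param exponent Weighting power (1 = LINCS weighting; 0 = classic
#'   unweighted KS).
#' @return The enrichment score in `[-1, 1]`.
#' @examples
#' s <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
#' weighted_ks_es(c("a", "b"), s)  # 1
#' weighted_ks_es("e", s)          # -1
#' @export
weighted_ks_es <- function(gene_set, scores, exponent = 1) {
  if (is.null(names(scores))) vstop("scores must be a named vector")
  hitmask <- names(scores) %in% gene_set
  if (!any(hitmask)) vstop("gene set has no overlap with the profile genes")
  ord <- order(-scores, names(scores))
  hit <- hitmask[ord]
  w <- abs(scores[ord])^exponent
  gsea_es_from_hits(hit, w)
}

# Running-sum ES given an ordered hit mask and per-position hit weights.
gsea_es_from_hits <- function(hit, w) {
  n <- length(hit)
  t <- sum(hit)
  nr <- sum(w[hit])
  inc <- numeric(n)
  if (nr > 0) inc[hit] <- w[hit] / nr else inc[hit] <- 1 / t
  if (n > t) inc[!hit] <- -1 / (n - t)
  run <- cumsum(inc)
  hi <- max(run)
  lo <- min(run)
  if (hi >= abs(lo)) hi else lo
}

# ES evaluated only at hit positions (O(t) per evaluation) -- used by the
# permutation loops. idx: sorted hit positions; w: their weights (already
# multiplicity * |score|^exponent); n: list length.
gsea_es_sparse <- function(idx, w, n) {
  t <- length(idx)
  n_miss <- n - t
  nr <- sum(w)
  cumhit <- if (nr > 0) cumsum(w) / nr else seq_len(t) / t
  j <- seq_len(t)
  if (n_miss == 0L) return(1)
  # deviation just after each hit, and just before each hit
  dev_at <- cumhit - (idx - j) / n_miss
  dev_before <- c(0, cumhit[-t]) - (idx - j) / n_miss
  hi <- max(dev_at)
  lo <- min(dev_before)
  if (hi >= abs(lo)) hi else lo
}
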