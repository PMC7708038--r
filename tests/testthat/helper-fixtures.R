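# Fixtures are built in code; databases live in per-test tempfiles.

make_ids <- function(n, prefix = "g") sprintf("%s%03d", prefix, seq_len(n))

make_treatments <- function(n, cells = c("PC3", "MCF7")) {
  make_treatment_id(sprintf("drug%03d", seq_len(n)),
                    rep_len(cells, n), "trt_cp")
}

random_db <- function(n_genes = 50, n_treatments = 8, value_kind = "zscore",
                      seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_treatments), n_genes, n_treatments,
              dimnames = list(make_ids(n_genes),
                              make_treatments(n_treatments)))
  list(mat = m,
       db = build_sig_db(m, value_kind = value_kind,
                         out_path = tempfile(fileext = ".h5")))
}

# Rank database with one perfectly concordant entry (query up genes on the
# top ranks, down genes on the bottom), one perfectly anti-concordant entry
# and noise entries.
planted_rank_db <- function(n_genes = 100, n_treatments = 10, n_up = 5,
                            n_down = 5, seed = 1) {
  set.seed(seed)
  genes <- make_ids(n_genes)
  perfect <- seq_len(n_genes)                       # rank i for gene i
  m <- sapply(seq_len(n_treatments - 2), function(j) sample(n_genes))
  m <- cbind(perfect, rev(perfect), m)
  dimnames(m) <- list(genes, make_treatments(n_treatments))
  db <- build_sig_db(m, value_kind = "rank",
                     out_path = tempfile(fileext = ".h5"))
  list(db = db, genes = genes,
       query = GeneSetPair(up = genes[seq_len(n_up)],
                           down = genes[n_genes - seq_len(n_down) + 1L]),
       concordant = colnames(m)[1], anticoncordant = colnames(m)[2])
}

# Unweighted-GSEA running-sum oracle, coded independently of the package
# internals: full-length cumulative sum, signed maximal deviation.
oracle_gsea_es <- function(ranked_ids, scores, set, exponent = 1,
                           mult = NULL) {
  if (is.null(mult)) mult <- rep(1, length(ranked_ids))
  hit <- ranked_ids %in% set
  w <- mult * abs(scores)^exponent
  nr <- sum(w[hit])
  step <- numeric(length(ranked_ids))
  step[hit] <- if (nr > 0) w[hit] / nr else 1 / sum(hit)
  step[!hit] <- -1 / sum(!hit)
  run <- cumsum(step)
  ex <- c(max(run), min(run))
  if (ex[1] >= abs(ex[2])) ex[1] else ex[2]
}

# O(n^2) concordance-pair oracle for the AUC (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exact upper-tail hypergeometric by pmf summation.
oracle_hyper_upper <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}
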