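# The five search methods.

test_that("raw connectivity combines tails and zeroes sign agreement", {
  expect_equal(sigconnect:::cmap_raw_score(0.8, -0.9), 1.7)
  expect_equal(sigconnect:::cmap_raw_score(0.5, 0.3), 0)
  expect_equal(sigconnect:::cmap_raw_score(-0.4, -0.2), 0)
  expect_equal(sigconnect:::scale_connectivity_scores(c(1.7, -0.85, 0)),
               c(1, -1, 0))
})

test_that("gess_cmap scores planted concordant/anti-concordant entries at +/-1", {
  x <- planted_rank_db()
  qs <- qSig(x$query, "cmap", x$db)
  res <- result(gess_cmap(qs))
  expect_setequal(res$treatment_id, x$db@treatment_ids)
  expect_equal(res$treatment_id[1], x$concordant)
  expect_equal(res$scaled_score[1], 1)
  expect_equal(res$scaled_score[nrow(res)], -1)
  expect_equal(res$treatment_id[nrow(res)], x$anticoncordant)
  expect_true(all(res$scaled_score >= -1 & res$scaled_score <= 1))
})

test_that("gess_cmap assigns zero when both query sets enrich the same tail", {
  genes <- make_ids(20)
  m <- matrix(1:20, 20, 1, dimnames = list(genes, make_treatments(1)))
  db <- build_sig_db(m, value_kind = "rank",
                     out_path = tempfile(fileext = ".h5"))
  q <- GeneSetPair(up = genes[1:3], down = genes[4:6])  # both at the top
  res <- result(gess_cmap(qSig(q, "cmap", db)))
  expect_equal(res$raw_score, 0)
  expect_equal(res$scaled_score, 0)
})

test_that("gess_cmap drops absent query genes and errors on empty sets", {
  x <- planted_rank_db()
  q <- GeneSetPair(up = c(x$genes[1:3], "not_a_gene"),
                   down = x$genes[96:100])
  expect_warning(gess_cmap(qSig(q, "cmap", x$db)), "dropped")
  q2 <- GeneSetPair(up = c("nope1", "nope2"), down = x$genes[96:100])
  expect_error(gess_cmap(qSig(q2, "cmap", x$db)), "'up'")
})

lincs_toy <- function(n_genes = 60, n_up = 6, n_down = 6, seed = 5) {
  set.seed(seed)
  genes <- make_ids(n_genes)
  perfect <- seq(3, -3, length.out = n_genes)   # monotone decreasing z
  m <- cbind(perfect,
             sapply(1:5, function(j) rnorm(n_genes)))
  dimnames(m) <- list(genes, make_treatments(6))
  db <- build_sig_db(m, value_kind = "zscore",
                     out_path = tempfile(fileext = ".h5"))
  list(db = db, genes = genes,
       query = GeneSetPair(up = genes[seq_len(n_up)],
                           down = genes[n_genes - seq_len(n_down) + 1L]),
       perfect = colnames(m)[1])
}

test_that("gess_lincs gives WTCS 1 for a perfectly concordant entry", {
  x <- lincs_toy()
  res <- result(gess_lincs(qSig(x$query, "lincs", x$db)))
  expect_equal(res$treatment_id[1], x$perfect)
  expect_equal(res$wtcs[1], 1)
  expect_true(all(abs(res$wtcs) <= 1))
  expect_setequal(res$treatment_id, x$db@treatment_ids)
})

test_that("WTCS is zero on sign agreement and antisymmetric under set swap", {
  x <- lincs_toy()
  # both sets at the top: es_up and es_down share sign -> 0
  q_same <- GeneSetPair(up = x$genes[1:5], down = x$genes[6:10])
  res <- result(gess_lincs(qSig(q_same, "lincs", x$db)))
  expect_equal(res$wtcs[res$treatment_id == x$perfect], 0)
  # swap negates on tie-free profiles
  q_sw <- GeneSetPair(up = x$query@down, down = x$query@up)
  r1 <- result(gess_lincs(qSig(x$query, "lincs", x$db)))
  r2 <- result(gess_lincs(qSig(q_sw, "lincs", x$db)))
  m1 <- r1$wtcs[order(r1$treatment_id)]
  m2 <- r2$wtcs[order(r2$treatment_id)]
  expect_equal(m1, -m2)
})

test_that("NCS normalizes within group and sign, preserving zeros and signs", {
  expect_equal(normalize_ncs(c(0.2, 0.4), "PC3", "t"),
               c(2 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(normalize_ncs(0, "PC3", "t"), 0)
  expect_equal(normalize_ncs(-0.5, "PC3", "t"), -1)
  # groups are independent
  got <- normalize_ncs(c(0.2, 0.4, 0.2), c("A", "A", "B"), "t")
  expect_equal(got, c(2 / 3, 4 / 3, 1), tolerance = 1e-12)
})

test_that("tau is the signed percentile of reference magnitudes", {
  expect_equal(compute_tau(2.0, c(0.5, 1.0, 1.5, 2.5)), 75)
  expect_equal(compute_tau(-2.0, c(0.5, 1.0, 1.5, 2.5)), -75)
  expect_equal(compute_tau(9, c(0.5, 1.0)), 100)
  expect_equal(compute_tau(-9, c(0.5, 1.0)), -100)
  expect_error(compute_tau(1, numeric(0)), "non-empty")
})

test_that("gess_gcmap equals gess_cmap with query and database roles swapped", {
  set.seed(17)
  genes <- make_ids(30)
  for (i in 1:3) {
    ranks <- sample(30)
    sets <- GeneSetPair(up = genes[1:4], down = sample(genes[10:30], 4))
    # cmap route: sets vs 1-entry rank db
    m <- matrix(ranks, 30, 1, dimnames = list(genes, make_treatments(1)))
    rank_db <- build_sig_db(m, value_kind = "rank",
                            out_path = tempfile(fileext = ".h5"))
    cm <- result(gess_cmap(qSig(sets, "cmap", rank_db)))
    # gcmap route: rank profile vs 1-entry GS db
    gs_db <- build_gs_db(list(sets@up), list(sets@down), genes,
                         make_treatments(1),
                         out_path = tempfile(fileext = ".h5"))
    prof <- ExpressionProfile(genes, ranks, "rank")
    gc <- result(gess_gcmap(qSig(prof, "gcmap", gs_db)))
    expect_equal(gc$raw_score, cm$raw_score)
  }
})

test_that("gess_gcmap flags entries sharing no genes with the query", {
  genes <- make_ids(10)
  gs_db <- build_gs_db(list(genes[1:2], c("x1", "x2")),
                       list(genes[9:10], "x3"),
                       c(genes, paste0("x", 1:3)), make_treatments(2),
                       out_path = tempfile(fileext = ".h5"))
  prof <- ExpressionProfile(genes, 1:10, "rank")
  expect_warning(res <- result(gess_gcmap(qSig(prof, "gcmap", gs_db))),
                 "no genes")
  off <- res[res$no_overlap, ]
  expect_equal(nrow(off), 1L)
  expect_equal(off$raw_score, 0)
})

test_that("gess_fisher computes exact hypergeometric upper tails", {
  genes <- make_ids(10)
  qset <- GeneSetPair(up = genes[1:3], down = genes[4:5])
  up_sets <- list(genes[1:3], genes[6:8], character(0))
  dn_sets <- list(genes[4:5], genes[9:10], genes[7])
  db <- build_gs_db(up_sets, dn_sets, genes, make_treatments(3),
                    out_path = tempfile(fileext = ".h5"))
  res <- result(gess_fisher(qSig(qset, "fisher", db)))
  hit <- res[res$overlap == 5, ]
  expect_equal(hit$pvalue, 1 / 252, tolerance = 1e-12)
  expect_equal(hit$treatment_id, res$treatment_id[1])  # sorted by p
  expect_equal(res$pvalue[res$overlap == 0], c(1, 1))
  expect_equal(res$padj, p.adjust(res$pvalue, "BH"))
})

test_that("gess_fisher p-values match pmf summation to 1e-12", {
  set.seed(41)
  genes <- make_ids(25)
  for (i in 1:5) {
    qset <- GeneSetPair(up = genes[1:4], down = sample(genes[5:25], 3))
    ups <- lapply(1:4, function(j) sample(genes, sample(2:6, 1)))
    dns <- lapply(1:4, function(j)
      sample(setdiff(genes, ups[[j]]), sample(2:6, 1)))
    db <- build_gs_db(ups, dns, genes, make_treatments(4),
                      out_path = tempfile(fileext = ".h5"))
    res <- result(gess_fisher(qSig(qset, "fisher", db)))
    qg <- union(qset@up, qset@down)
    for (r in seq_len(nrow(res))) {
      j <- match(res$treatment_id[r], make_treatments(4))
      eg <- union(ups[[j]], dns[[j]])
      expect_equal(res$pvalue[r],
                   oracle_hyper_upper(length(intersect(qg, eg)),
                                      length(qg), 25, length(eg)),
                   tolerance = 1e-12)
    }
  }
})

test_that("gess_cor recovers self-hits, reversals and degenerate entries", {
  set.seed(3)
  genes <- make_ids(40)
  q <- rnorm(40)
  m <- cbind(q, -q, rep(1, 40), rnorm(40))
  dimnames(m) <- list(genes, make_treatments(4))
  db <- build_sig_db(m, value_kind = "zscore",
                     out_path = tempfile(fileext = ".h5"))
  prof <- ExpressionProfile(genes, q, "zscore")
  res <- result(gess_cor(qSig(prof, "cor", db,
                              params = list(flavor = "spearman"))))
  self <- colnames(m)[1]
  expect_equal(res$treatment_id[1], self)
  expect_equal(res$cor_score[1], 1)
  expect_equal(res$cor_score[res$treatment_id == colnames(m)[2]], -1)
  const <- res[res$treatment_id == colnames(m)[3], ]
  expect_true(is.na(const$cor_score))
  expect_equal(const$flag, "zero_variance")
})

test_that("Spearman search is invariant to monotone query transforms", {
  x <- random_db(n_genes = 30, n_treatments = 5)
  prof <- ExpressionProfile(rownames(x$mat), x$mat[, 1], "zscore")
  warped <- ExpressionProfile(rownames(x$mat), exp(2 * x$mat[, 1]),
                              "zscore")
  r1 <- result(gess_cor(qSig(prof, "cor", x$db,
                             params = list(flavor = "spearman"))))
  r2 <- result(gess_cor(qSig(warped, "cor", x$db,
                             params = list(flavor = "spearman"))))
  expect_equal(r1$cor_score, r2$cor_score, tolerance = 1e-6)
})

test_that("subset correlation with too few shared genes is flagged NA", {
  x <- random_db(n_genes = 30, n_treatments = 4)
  prof <- ExpressionProfile(rownames(x$mat), x$mat[, 1], "zscore")
  res <- result(gess_cor(qSig(prof, "cor", x$db,
                              params = list(subset = "sub",
                                            gene_subset = rownames(x$mat)[1:2]))))
  expect_true(all(is.na(res$cor_score)))
  expect_true(all(res$flag == "few_genes"))
})

test_that("qSig enforces the method/data-type compatibility matrix", {
  x <- random_db(value_kind = "zscore")
  gsq <- GeneSetPair(up = rownames(x$mat)[1:5])
  prof <- ExpressionProfile(rownames(x$mat), x$mat[, 1], "zscore")
  expect_error(qSig(gsq, "cor", x$db), "incompatible")
  expect_error(qSig(gsq, "cmap", x$db), "incompatible")   # needs rank db
  expect_error(qSig(prof, "lincs", x$db), "incompatible") # needs GS query
  expect_error(qSig(prof, "nope", x$db), "unknown")
  expect_silent(qSig(gsq, "lincs", x$db))
})

test_that("batching and parallelism never change any score", {
  x <- planted_rank_db(n_genes = 60, n_treatments = 9)
  qs <- qSig(x$query, "cmap", x$db)
  r_all <- result(gess_search(qs, batch_size = 9))
  r_b1 <- result(gess_search(qs, batch_size = 1))
  r_b4 <- result(gess_search(qs, batch_size = 4))
  r_w2 <- result(gess_search(qs, batch_size = 2, workers = 2))
  expect_equal(r_b1, r_all)
  expect_equal(r_b4, r_all)
  expect_equal(r_w2, r_all)

  y <- lincs_toy()
  qs2 <- qSig(y$query, "lincs", y$db)
  expect_equal(result(gess_search(qs2, batch_size = 2)),
               result(gess_search(qs2, batch_size = 6)))
})
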