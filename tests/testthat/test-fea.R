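# Duplication-aware enrichment methods and drug->target mapping.

toy_annotations <- function() {
  drug_target_table(list(A = c("T1", "T2"), B = "T1", C = c("T3", "T4")))
}

test_that("drugs_to_targets pools targets into a multiset", {
  tm <- drugs_to_targets(c("A", "B"), toy_annotations())
  expect_equal(tm$counts[["T1"]], 2L)
  expect_equal(tm$counts[["T2"]], 1L)
  expect_equal(tm$total, 3L)
  expect_length(tm$unannotated, 0)
})

test_that("promiscuity cap and unannotated drugs are handled", {
  tm <- drugs_to_targets(c("A", "B"), toy_annotations(),
                         max_targets_per_drug = 1)
  expect_equal(tm$excluded, "A")
  expect_equal(tm$counts, c(T1 = 1L))
  tm2 <- drugs_to_targets(c("A", "zzz"), toy_annotations())
  expect_equal(tm2$unannotated, "zzz")
  expect_error(drugs_to_targets(c("x", "y"), toy_annotations()),
               "none of the drugs")
})

test_that("targets inherit the best-magnitude score of their drugs", {
  tm <- drugs_to_targets(c("A", "B"), toy_annotations(),
                         scores = c(0.4, -0.9))
  sc <- setNames(tm$targets$score, tm$targets$target)
  expect_equal(sc[["T1"]], -0.9)  # B's stronger score wins for shared T1
  expect_equal(sc[["T2"]], 0.4)
  expect_equal(tm$targets$target[1], "T1")  # ranked by |score|
})

test_that("dup_hyperG reproduces the duplication-weighted worked example", {
  universe <- make_ids(20)
  cats <- category_collection(list(C = universe[1:5]), universe = universe)
  fr <- tsea_dup_hyperG(c(g001 = 2, g002 = 1), cats)
  df <- result(fr)
  expect_equal(df$n_test, 3L)
  expect_equal(df$n_match, 3L)
  expect_equal(df$n_category, 5L)
  expect_equal(df$pvalue, 10 / 1140, tolerance = 1e-12)
})

test_that("dup_hyperG with unit multiplicities is the classical test", {
  set.seed(8)
  universe <- make_ids(30)
  for (i in 1:5) {
    sets <- list(a = sample(universe, 8), b = sample(universe, 5))
    cats <- category_collection(sets, universe = universe)
    test_genes <- sample(universe, 6)
    fr <- result(tsea_dup_hyperG(setNames(rep(1, 6), test_genes), cats))
    for (r in seq_len(nrow(fr))) {
      k <- length(intersect(test_genes, sets[[fr$category[r]]]))
      expect_equal(fr$pvalue[r],
                   oracle_hyper_upper(k, length(sets[[fr$category[r]]]),
                                      30, 6),
                   tolerance = 1e-12)
    }
  }
})

test_that("dup_hyperG handles disjoint tests and the k > K tail", {
  universe <- make_ids(20)
  cats <- category_collection(list(C = universe[1:3]), universe = universe)
  # disjoint: p = P(X >= 0) = 1
  expect_equal(result(tsea_dup_hyperG(c(g010 = 1, g011 = 1), cats))$pvalue,
               1)
  # multiplicity pushes the match count beyond the category size: tail is 0
  fr <- result(tsea_dup_hyperG(c(g001 = 5), cats))
  expect_equal(fr$n_match, 5)
  expect_equal(fr$pvalue, 0)
})

test_that("mGSEA with unit multiplicities equals the running-sum oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- 30
    ids <- make_ids(n)
    sc <- sort(rnorm(n), decreasing = TRUE)
    cats <- category_collection(list(C1 = sample(ids, 6),
                                     C2 = sample(ids, 4)),
                                universe = ids)
    tdf <- data.frame(target = ids, score = sc, mult = 1)
    fr <- result(tsea_mGSEA(tdf, cats, nperm = 100, seed = 1))
    for (r in seq_len(nrow(fr))) {
      expect_equal(fr$ES[r],
                   oracle_gsea_es(ids, sc, cats$sets[[fr$category[r]]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("mGSEA weights duplicated targets by multiplicity", {
  ids <- c("t1", "t2", "t3")
  sc <- c(3, 2, 1)
  cats <- category_collection(list(top = "t1", last = "t3"),
                              universe = ids)
  fr <- result(tsea_mGSEA(data.frame(target = ids, score = sc, mult = 1),
                          cats, nperm = 100, seed = 1))
  expect_equal(fr$ES[fr$category == "top"], 1.0)
  # multiplicity changes the ES of a multi-member category
  cats2 <- category_collection(list(C = c("t1", "t3")), universe = ids)
  es1 <- result(tsea_mGSEA(data.frame(target = ids, score = sc,
                                      mult = c(1, 1, 1)),
                           cats2, nperm = 100, seed = 1))$ES
  es2 <- result(tsea_mGSEA(data.frame(target = ids, score = sc,
                                      mult = c(5, 1, 1)),
                           cats2, nperm = 100, seed = 1))$ES
  expect_equal(oracle_gsea_es(ids, sc, c("t1", "t3"),
                              mult = c(5, 1, 1)), es2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(es1, es2)))
})

test_that("mabs scores categories by mean absolute statistic", {
  cats <- category_collection(list(C = c("g1", "g2")),
                              universe = c("g1", "g2", "g3", "g4"))
  fr <- result(tsea_mabs(c(g1 = 2, g2 = -2, g3 = 0, g4 = 0), cats,
                         nperm = 3000, seed = 1))
  expect_equal(fr$mabs, 2)
  # exhaustive null over the 6 two-gene subsets gives p = 1/6
  expect_equal(fr$pvalue, 1 / 6, tolerance = 0.1)
  # all magnitudes equal: every random set reaches the observed mean
  fr2 <- result(tsea_mabs(c(g1 = 1, g2 = -1, g3 = 1, g4 = -1), cats,
                          nperm = 500, seed = 1))
  expect_equal(fr2$pvalue, 1)
})

test_that("dsea_hyperG is the classical drug-level test", {
  drugs <- sprintf("d%02d", 1:10)
  cats <- category_collection(list(C = drugs[1:5], D = drugs[6:10]),
                              universe = drugs)
  fr <- result(dsea_hyperG(drugs[1:5], cats))
  expect_equal(fr$pvalue[fr$category == "C"], 1 / 252, tolerance = 1e-12)
  expect_equal(fr$pvalue[fr$category == "D"], 1)
  expect_warning(dsea_hyperG(c("d01", "d01", "d02"), cats), "duplicate")
})

test_that("dsea_GSEA equals mGSEA with unit multiplicities", {
  set.seed(12)
  drugs <- sprintf("d%02d", 1:20)
  sc <- sort(rnorm(20), decreasing = TRUE)
  cats <- category_collection(list(C = sample(drugs, 5)),
                              universe = drugs)
  a <- result(dsea_GSEA(data.frame(drug = drugs, score = sc), cats,
                        nperm = 200, seed = 7))
  b <- result(tsea_mGSEA(data.frame(target = drugs, score = sc, mult = 1),
                         cats, nperm = 200, seed = 7))
  expect_equal(a$ES, b$ES)
  expect_equal(a$pvalue, b$pvalue)
})

test_that("adjust_pvalues supports the seven methods and validates input", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.3, 0.4), "bonferroni"), c(0.6, 0.8))
  expect_equal(adjust_pvalues(c(0.3, 0.4), "none"), c(0.3, 0.4))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.5)
  for (m in c("BH", "bonferroni", "holm", "hochberg", "hommel", "BY")) {
    adj <- adjust_pvalues(p, m)
    expect_true(all(adj >= p - 1e-15))
    # order-preserving in p
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(-0.1), "\\[0, 1\\]")
})

test_that("TSEA and DSEA rank categories differently when targets repeat", {
  # five drugs all hitting T1 (plus private targets); drug-level categories
  # split the drugs evenly, gene-level categories separate T1 from the rest
  ann <- drug_target_table(list(
    d1 = c("T1", "T2"), d2 = c("T1", "T3"), d3 = c("T1", "T4"),
    d4 = "T5", d5 = "T6"))
  tm <- drugs_to_targets(paste0("d", 1:5), ann)
  gene_cats <- category_collection(
    list(shared = "T1", private = c("T5", "T6")),
    universe = c(paste0("T", 1:6), make_ids(20)))
  tres <- result(tsea_dup_hyperG(tm, gene_cats))
  drug_cats <- category_collection(
    list(shared = c("d1", "d2", "d3"), private = c("d4", "d5")),
    universe = c(paste0("d", 1:5), sprintf("x%02d", 1:20)))
  dres <- result(dsea_hyperG(paste0("d", 1:5), drug_cats))
  # the duplicated target T1 makes the TSEA 'shared' category much stronger
  # relative to 'private' than the drug-level view suggests
  t_ratio <- tres$pvalue[tres$category == "shared"] /
    tres$pvalue[tres$category == "private"]
  d_ratio <- dres$pvalue[dres$category == "shared"] /
    dres$pvalue[dres$category == "private"]
  expect_true(t_ratio < d_ratio)
})

test_that("GMT and drug-target files round-trip", {
  cats <- category_collection(list(a = c("g1", "g2"), b = c("g2", "g3")),
                              descriptions = c(a = "first", b = "second"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(cats, f)
  back <- read_gmt(f)
  expect_equal(back$sets, cats$sets)
  expect_equal(back$descriptions, cats$descriptions)

  ann <- toy_annotations()
  f2 <- tempfile(fileext = ".tsv")
  write_drug_targets(ann, f2)
  back2 <- read_drug_targets(f2)
  expect_equal(back2[order(names(back2))],
               ann[order(names(ann))], ignore_attr = TRUE)
})
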