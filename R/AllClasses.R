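# S4 data model: signatures, query objects, search and enrichment results.

VALUE_KINDS <- c("intensity", "count", "LFC", "zscore", "rank")
DB_VALUE_KINDS <- c(VALUE_KINDS, "gene_set")

#' ExpressionProfile: a quantitative gene expression signature (GEP)
#'
#' A per-gene numeric vector with a declared value kind. Supported kinds are
#' `"intensity"` and `"count"` (normalized hybridization / sequencing
#' values), `"LFC"` (log fold changes), `"zscore"` (differential expression
#' z-scores) and `"rank"` (a rank transformation where rank 1 is the most
#' up-regulated gene and ties carry average ranks).
#'
#' @slot gene_ids Character vector of unique gene identifiers.
#' @slot values Numeric vector aligned with `gene_ids`.
#' @slot value_kind One of `"intensity"`, `"count"`, `"LFC"`, `"zscore"`,
#'   `"rank"`.
#' @export
setClass("ExpressionProfile", representation(
  gene_ids = "character",
  values = "numeric",
  value_kind = "character"
))

setValidity("ExpressionProfile", function(object) {
  n <- length(object@gene_ids)
  if (length(object@values) != n)
    return("gene_ids and values must have equal length")
  if (n == 0L) return("profile must contain at least one gene")
  if (anyDuplicated(object@gene_ids))
    return("gene_ids must be unique")
  if (length(object@value_kind) != 1L ||
      !object@value_kind %in% VALUE_KINDS)
    return(sprintf("value_kind must be one of: %s",
                   paste(VALUE_KINDS, collapse = ", ")))
  if (object@value_kind == "rank") {
    v <- object@values
    if (any(v < 1 - 1e-9) || any(v > n + 1e-9))
      return("rank values must lie in [1, n]")
    if (abs(sum(v) - n * (n + 1) / 2) > 1e-6)
      return("rank values must be a permutation-with-ties of 1..n")
  }
  TRUE
})

#' @param gene_ids,values,value_kind See slots.
#' @rdname ExpressionProfile-class
#' @return An `ExpressionProfile` object.
#' @examples
#' ExpressionProfile(c("g1", "g2", "g3"), c(1.2, -0.4, 0.1), "zscore")
#' @export
ExpressionProfile <- function(gene_ids, values, value_kind) {
  if (is.null(names(values)) || !missing(gene_ids)) {
    prof <- new("ExpressionProfile", gene_ids = as.character(gene_ids),
                values = unname(as.numeric(values)), value_kind = value_kind)
  } else {
    prof <- new("ExpressionProfile", gene_ids = names(values),
                values = unname(as.numeric(values)), value_kind = value_kind)
  }
  prof
}

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile: %d genes, value_kind = %s\n",
              length(object@gene_ids), object@value_kind))
})

#' GeneSetPair: an up/down gene-set query (GS-Q)
#'
#' Ordered sets of up- and down-regulated gene identifiers, typically the
#' most strongly induced and repressed differentially expressed genes of a
#' perturbation. The two sets must be disjoint and at least one must be
#' non-empty (one-sided queries are allowed).
#'
#' @slot up,down Character vectors of gene identifiers.
#' @export
setClass("GeneSetPair", representation(up = "character", down = "character"))

setValidity("GeneSetPair", function(object) {
  if (length(object@up) == 0L && length(object@down) == 0L)
    return("at least one of up/down must be non-empty")
  if (anyDuplicated(object@up) || anyDuplicated(object@down))
    return("gene identifiers within a set must be unique")
  if (length(intersect(object@up, object@down)) > 0L)
    return("up and down sets must be disjoint")
  TRUE
})

#' @param up,down Character vectors of gene identifiers (either may be
#'   empty, not both).
#' @rdname GeneSetPair-class
#' @return A `GeneSetPair` object.
#' @examples
#' GeneSetPair(up = c("g1", "g2"), down = "g9")
#' @export
GeneSetPair <- function(up = character(), down = character()) {
  new("GeneSetPair", up = as.character(up), down = as.character(down))
}

setMethod("show", "GeneSetPair", function(object) {
  cat(sprintf("GeneSetPair: %d up / %d down genes\n",
              length(object@up), length(object@down)))
})

#' SignatureDB: handle to an HDF5-backed signature database
#'
#' A gene x treatment signature database stored on disk in HDF5. Quantitative
#' databases (GEP-DBs) keep the matrix in a float32 `/assay` dataset chunked
#' by blocks of treatment columns; gene-set databases (GS-DBs,
#' `value_kind = "gene_set"`) store per-treatment up/down identifier sets.
#' Objects of this class are lightweight handles; data are read on demand in
#' batches with [read_batch()].
#'
#' @slot path Path of the HDF5 file.
#' @slot gene_ids,treatment_ids Ordered identifiers (treatment ids are
#'   composite `"pert__cell__perttype"` strings).
#' @slot value_kind Value kind of the stored signatures, or `"gene_set"`.
#' @slot n_genes,n_treatments Matrix dimensions.
#' @export
setClass("SignatureDB", representation(
  path = "character",
  gene_ids = "character",
  treatment_ids = "character",
  value_kind = "character",
  n_genes = "integer",
  n_treatments = "integer"
))

setValidity("SignatureDB", function(object) {
  if (anyDuplicated(object@treatment_ids))
    return("treatment_ids must be unique")
  if (anyDuplicated(object@gene_ids))
    return("gene_ids must be unique")
  if (!object@value_kind %in% DB_VALUE_KINDS)
    return("invalid value_kind")
  if (length(object@gene_ids) != object@n_genes ||
      length(object@treatment_ids) != object@n_treatments)
    return("identifier lengths disagree with recorded dimensions")
  TRUE
})

setMethod("show", "SignatureDB", function(object) {
  cat(sprintf("SignatureDB: %d genes x %d treatments [%s]\n  %s\n",
              object@n_genes, object@n_treatments, object@value_kind,
              object@path))
})

#' qSig: a fully specified signature search
#'
#' Bundles the query signature, the search method, the reference database
#' and all method parameters. Construction enforces the compatibility of the
#' (query type, database value kind) pair so incompatible searches fail
#' early:
#'
#' | method  | query               | database              |
#' |---------|---------------------|-----------------------|
#' | cmap    | GeneSetPair         | rank                  |
#' | lincs   | GeneSetPair         | zscore (LFC warns)    |
#' | gcmap   | ExpressionProfile (rank) | gene_set         |
#' | fisher  | GeneSetPair         | gene_set              |
#' | cor     | ExpressionProfile (quantitative) | intensity/count/LFC/zscore |
#'
#' @slot query A [GeneSetPair] or [ExpressionProfile].
#' @slot method One of `"cmap"`, `"lincs"`, `"gcmap"`, `"fisher"`, `"cor"`.
#' @slot db A [SignatureDB].
#' @slot params Named list of method parameters (e.g. `exponent` for lincs,
#'   `flavor`/`subset` for cor, `higher`/`lower` cutoffs).
#' @export
setClass("qSig", representation(
  query = "ANY",
  method = "character",
  db = "SignatureDB",
  params = "list"
))

GESS_METHODS <- c("cmap", "lincs", "gcmap", "fisher", "cor")

check_compatibility <- function(query, method, db) {
  qtype <- if (is(query, "GeneSetPair")) "GS" else
    if (is(query, "ExpressionProfile")) "GEP" else "other"
  if (qtype == "other")
    vstop("query must be a GeneSetPair or an ExpressionProfile")
  bad <- function(need_q, need_db) {
    vstop(paste0(
      "incompatible query/database combination for method '%s': requires %s",
      " query and %s database, got %s query and '%s' database",
      " (see the method/data-type compatibility table in ?qSig)"),
      method, need_q, need_db,
      if (qtype == "GS") "gene-set" else
        sprintf("'%s' profile", query@value_kind),
      db@value_kind)
  }
  switch(method,
    cmap = {
      if (qtype != "GS" || db@value_kind != "rank")
        bad("a gene-set (up/down)", "a rank-transformed")
    },
    lincs = {
      if (qtype != "GS" || !db@value_kind %in% c("zscore", "LFC"))
        bad("a gene-set (up/down)", "a z-score")
      if (db@value_kind == "LFC")
        warning("lincs method is defined on z-score databases; ",
                "proceeding with LFC values", call. = FALSE)
    },
    gcmap = {
      if (qtype != "GEP" || query@value_kind != "rank" ||
          db@value_kind != "gene_set")
        bad("a rank-transformed profile", "a gene-set")
    },
    fisher = {
      if (qtype != "GS" || db@value_kind != "gene_set")
        bad("a gene-set (up/down)", "a gene-set")
    },
    cor = {
      if (qtype != "GEP" || query@value_kind == "rank" ||
          !db@value_kind %in% c("intensity", "count", "LFC", "zscore"))
        bad("a quantitative profile", "a quantitative (non-rank)")
    },
    vstop("unknown GESS method '%s' (available: %s)", method,
          paste(GESS_METHODS, collapse = ", "))
  )
  invisible(TRUE)
}

#' @param query,method,db,params See slots.
#' @rdname qSig-class
#' @return A validated `qSig` object.
#' @export
qSig <- function(query, method, db, params = list()) {
  method <- as.character(method)[1]
  check_compatibility(query, method, db)
  new("qSig", query = query, method = method, db = db, params = params)
}

setMethod("show", "qSig", function(object) {
  cat(sprintf("qSig: method = %s\n", object@method))
  show(object@query)
  show(object@db)
})

#' gessResult: ranked signature search result
#'
#' Holds the ranked per-treatment score table of a signature search together
#' with an echo of the query and the search parameters. Every database
#' treatment appears exactly once; rows are sorted by the method's primary
#' score (scaled connectivity score for cmap/gcmap, WTCS for lincs,
#' ascending p-value for fisher, absolute correlation for cor), with ties
#' broken by treatment id.
#'
#' @slot result A `data.frame` with method-specific score columns.
#' @slot query Echo of the query signature.
#' @slot method The GESS method used.
#' @slot params Named list of search parameters.
#' @export
setClass("gessResult", representation(
  result = "data.frame",
  query = "ANY",
  method = "character",
  params = "list"
))

#' feaResult: functional enrichment result
#'
#' Per-category enrichment statistics produced by the TSEA/DSEA methods,
#' plus the drugs used for testing and their target information.
#'
#' @slot result A `data.frame` with one row per tested category.
#' @slot drugs Character vector of drugs used for the test (if applicable).
#' @slot targets Target information used for the test (if applicable).
#' @slot method The FEA method used.
#' @slot params Named list of parameters.
#' @export
setClass("feaResult", representation(
  result = "data.frame",
  drugs = "character",
  targets = "ANY",
  method = "character",
  params = "list"
))

#' Extract the result table from a search or enrichment result
#'
#' @param x A [gessResult] or [feaResult].
#' @return The embedded `data.frame`.
#' @export
setGeneric("result", function(x) standardGeneric("result"))

#' @rdname result
#' @export
setMethod("result", "gessResult", function(x) x@result)

#' @rdname result
#' @export
setMethod("result", "feaResult", function(x) x@result)

setMethod("show", "gessResult", function(object) {
  cat(sprintf("gessResult [%s]: %d treatments\n", object@method,
              nrow(object@result)))
  print(utils::head(object@result, 5))
  if (nrow(object@result) > 5) cat("...\n")
})

setMethod("show", "feaResult", function(object) {
  cat(sprintf("feaResult [%s]: %d categories\n", object@method,
              nrow(object@result)))
  print(utils::head(object@result, 5))
  if (nrow(object@result) > 5) cat("...\n")
})
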