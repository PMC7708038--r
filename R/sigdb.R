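# HDF5-backed signature databases: construction, batched access and
# derivation of query/database signature types.

#' Build an HDF5 signature database from a gene x treatment matrix
#'
#' Writes the matrix to an HDF5 file with datasets `/assay` (float32,
#' genes x treatments, chunked in blocks of `chunk_treatments` columns so
#' that batched scanning over treatments reads whole chunks), `/rownames`
#' and `/colnames` (UTF-8 identifier strings) and `/value_kind`.
#'
#' @param mat Numeric matrix (genes in rows, treatments in columns).
#' @param gene_ids,treatment_ids Identifier vectors; default to the
#'   `dimnames` of `mat`. Treatment ids are composite
#'   `"pert__cell__perttype"` strings (see [make_treatment_id()]).
#' @param value_kind One of `"intensity"`, `"count"`, `"LFC"`, `"zscore"`,
#'   `"rank"`.
#' @param out_path Path of the HDF5 file to create (overwritten if present).
#' @param chunk_treatments Number of treatment columns per HDF5 chunk
#'   (default 5000).
#' @return A [SignatureDB] handle for the new file.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3),
#'                             make_treatment_id(c("d1", "d2"), "PC3", "trt_cp")))
#' db <- build_sig_db(m, value_kind = "zscore", out_path = tempfile())
#' read_batch(db, 1, 2)
#' @export
build_sig_db <- function(mat, gene_ids = rownames(mat),
                         treatment_ids = colnames(mat), value_kind,
                         out_path, chunk_treatments = 5000L) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    vstop("empty matrix: need at least one gene and one treatment")
  if (is.null(gene_ids) || is.null(treatment_ids))
    vstop("gene_ids and treatment_ids are required (or dimnames on mat)")
  gene_ids <- as.character(gene_ids)
  treatment_ids <- as.character(treatment_ids)
  if (nrow(mat) != length(gene_ids) || ncol(mat) != length(treatment_ids))
    vstop("matrix dimensions (%d x %d) disagree with identifier lengths (%d, %d)",
          nrow(mat), ncol(mat), length(gene_ids), length(treatment_ids))
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    vstop("empty matrix: need at least one gene and one treatment")
  if (anyDuplicated(gene_ids)) vstop("duplicate gene_ids")
  if (anyDuplicated(treatment_ids)) vstop("duplicate treatment_ids")
  if (!value_kind %in% VALUE_KINDS)
    vstop("value_kind must be one of: %s", paste(VALUE_KINDS, collapse = ", "))
  chunk_treatments <- as.integer(chunk_treatments)
  if (is.na(chunk_treatments) || chunk_treatments < 1L)
    vstop("chunk_treatments must be >= 1")

  if (file.exists(out_path)) unlink(out_path)
  rhdf5::h5createFile(out_path)
  chunk <- c(nrow(mat), min(chunk_treatments, ncol(mat)))
  rhdf5::h5createDataset(out_path, "assay", dims = dim(mat),
                         H5type = "H5T_IEEE_F32LE", chunk = chunk, level = 4)
  rhdf5::h5write(unname(mat), out_path, "assay")
  rhdf5::h5write(gene_ids, out_path, "rownames")
  rhdf5::h5write(treatment_ids, out_path, "colnames")
  rhdf5::h5write(value_kind, out_path, "value_kind")
  rhdf5::h5closeAll()
  new("SignatureDB", path = out_path, gene_ids = gene_ids,
      treatment_ids = treatment_ids, value_kind = value_kind,
      n_genes = nrow(mat), n_treatments = ncol(mat))
}

# Writer for gene-set databases: up/down sets serialized as pipe-joined
# identifier strings aligned with /colnames; /rownames keeps the gene
# universe of the source profiles.
write_gs_db <- function(up_sets, down_sets, gene_ids, treatment_ids,
                        out_path) {
  if (file.exists(out_path)) unlink(out_path)
  rhdf5::h5createFile(out_path)
  rhdf5::h5write(vapply(up_sets, paste, character(1), collapse = "|"),
                 out_path, "up")
  rhdf5::h5write(vapply(down_sets, paste, character(1), collapse = "|"),
                 out_path, "down")
  rhdf5::h5write(as.character(gene_ids), out_path, "rownames")
  rhdf5::h5write(as.character(treatment_ids), out_path, "colnames")
  rhdf5::h5write("gene_set", out_path, "value_kind")
  rhdf5::h5closeAll()
  new("SignatureDB", path = out_path, gene_ids = as.character(gene_ids),
      treatment_ids = as.character(treatment_ids), value_kind = "gene_set",
      n_genes = length(gene_ids), n_treatments = length(treatment_ids))
}

#' Open an existing signature database file
#'
#' @param path Path to an HDF5 file written by [build_sig_db()],
#'   [gep_to_gs_db()] or [build_gs_db()].
#' @return A [SignatureDB] handle.
#' @export
load_sig_db <- function(path) {
  if (!file.exists(path)) vstop("database file not found: %s", path)
  gene_ids <- as.character(rhdf5::h5read(path, "rownames"))
  treatment_ids <- as.character(rhdf5::h5read(path, "colnames"))
  value_kind <- as.character(rhdf5::h5read(path, "value_kind"))[1]
  rhdf5::h5closeAll()
  new("SignatureDB", path = path, gene_ids = gene_ids,
      treatment_ids = treatment_ids, value_kind = value_kind,
      n_genes = length(gene_ids), n_treatments = length(treatment_ids))
}

#' Read a batch of treatment columns from a signature database
#'
#' Returns the columns `[start, min(start + size - 1, n_treatments)]`
#' (1-based, inclusive). Concatenating consecutive batches reconstructs the
#' full database, which is how the search engine scans large databases at a
#' bounded memory footprint.
#'
#' @param db A [SignatureDB].
#' @param start First column (1-based); must satisfy
#'   `1 <= start <= n_treatments`.
#' @param size Maximal number of columns to read (`>= 1`); the last batch
#'   is truncated at the database end.
#' @return For quantitative databases, a numeric matrix with gene row names
#'   and treatment column names. For gene-set databases, a list with
#'   elements `up`, `down` (lists of identifier vectors) and
#'   `treatment_ids`.
#' @export
read_batch <- function(db, start, size) {
  start <- as.integer(start); size <- as.integer(size)
  if (is.na(start) || start < 1L || start > db@n_treatments)
    vstop("start = %d out of range [1, %d]", start, db@n_treatments)
  if (is.na(size) || size < 1L) vstop("size must be >= 1")
  end <- min(start + size - 1L, db@n_treatments)
  idx <- start:end
  if (db@value_kind == "gene_set") {
    up <- as.character(rhdf5::h5read(db@path, "up", index = list(idx)))
    dn <- as.character(rhdf5::h5read(db@path, "down", index = list(idx)))
    rhdf5::h5closeAll()
    split_sets <- function(x) {
      s <- strsplit(x, "|", fixed = TRUE)
      lapply(s, function(g) g[nzchar(g)])
    }
    list(up = split_sets(up), down = split_sets(dn),
         treatment_ids = db@treatment_ids[idx])
  } else {
    m <- rhdf5::h5read(db@path, "assay", index = list(NULL, idx))
    rhdf5::h5closeAll()
    m <- matrix(as.numeric(m), nrow = db@n_genes,
                dimnames = list(db@gene_ids, db@treatment_ids[idx]))
    m
  }
}

# Iterate over all batches of a database, applying fun(batch, start_index).
# Used by the search engine; workers > 1 distributes batches over forked
# processes (results are order-stable, so parallelism never changes scores).
scan_db <- function(db, batch_size, fun, workers = 1L) {
  starts <- seq(1L, db@n_treatments, by = as.integer(batch_size))
  run1 <- function(s) fun(read_batch(db, s, batch_size), s)
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(starts, run1, mc.cores = workers)
  } else {
    lapply(starts, run1)
  }
}

#' Rank-transform an expression profile
#'
#' Converts a quantitative profile to ranks where rank 1 is the most
#' up-regulated (largest) value and ties receive the average of the ranks
#' they span. This is the transformation that turns level i/ii profiles
#' (intensities, counts, LFC, z-scores) into the rank profiles consumed by
#' the CMAP database side and the gCMAP query side.
#'
#' @param profile An [ExpressionProfile] with a non-rank value kind.
#' @return An [ExpressionProfile] with `value_kind = "rank"`.
#' @examples
#' p <- ExpressionProfile(c("a", "b", "c"), c(5, 1, 3), "zscore")
#' rank_transform(p)@values  # 1 3 2
#' @export
rank_transform <- function(profile) {
  stopifnot(is(profile, "ExpressionProfile"))
  if (profile@value_kind == "rank")
    vstop("profile is already rank-transformed")
  ExpressionProfile(profile@gene_ids,
                    rank(-profile@values, ties.method = "average"),
                    "rank")
}

# Per-treatment rank transform of a gene x treatment matrix (rank 1 = most
# up-regulated within each treatment, average ties).
rank_transform_matrix <- function(mat) {
  r <- apply(mat, 2L, function(v) rank(-v, ties.method = "average"))
  dimnames(r) <- dimnames(mat)
  r
}

#' Extract top up/down gene sets from a profile
#'
#' Returns the `n_up` genes with the largest and the `n_down` genes with the
#' smallest values, i.e. the most strongly up- and down-regulated genes of a
#' signature, as a [GeneSetPair]. The up set is ordered by decreasing and
#' the down set by increasing value; ties at a set boundary are broken
#' lexicographically by gene id so the extraction is deterministic.
#'
#' @param profile An [ExpressionProfile] (for rank profiles the smallest
#'   rank, i.e. most up-regulated, goes to the up set).
#' @param n_up,n_down Set sizes; `n_up + n_down` must not exceed the number
#'   of genes, which guarantees disjointness.
#' @return A [GeneSetPair].
#' @export
top_n_sets <- function(profile, n_up, n_down) {
  stopifnot(is(profile, "ExpressionProfile"))
  n <- length(profile@gene_ids)
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  if (n_up < 0L || n_down < 0L) vstop("set sizes must be non-negative")
  if (n_up + n_down > n)
    vstop("n_up + n_down = %d exceeds the number of genes (%d)",
          n_up + n_down, n)
  v <- profile@values
  if (profile@value_kind == "rank") v <- -v  # small rank = most up-regulated
  ord_up <- order(-v, profile@gene_ids)
  ord_dn <- order(v, profile@gene_ids)
  GeneSetPair(up = profile@gene_ids[ord_up[seq_len(n_up)]],
              down = profile@gene_ids[ord_dn[seq_len(n_down)]])
}

#' Convert a quantitative database to a gene-set database
#'
#' For each treatment, the up set collects genes with values `>= higher` and
#' the down set genes with values `<= lower`. This is the on-the-fly GS-DB
#' conversion used to search quantitative databases with the set-only
#' methods (fisher, gcmap database side).
#'
#' @param db A [SignatureDB] with `value_kind` `"zscore"` or `"LFC"`.
#' @param higher,lower Cutoffs with `higher > lower` (e.g. 1 / -1 on
#'   z-scores).
#' @param out_path Path of the gene-set HDF5 file to create.
#' @param batch_size Treatments per scan batch.
#' @return A [SignatureDB] with `value_kind = "gene_set"`. Treatments whose
#'   cutoffs select no genes are retained with empty sets and reported in a
#'   warning.
#' @export
gep_to_gs_db <- function(db, higher, lower, out_path, batch_size = 5000L) {
  stopifnot(is(db, "SignatureDB"))
  if (!db@value_kind %in% c("zscore", "LFC"))
    vstop("gep_to_gs_db requires a zscore or LFC database (got '%s')",
          db@value_kind)
  if (!(higher > lower)) vstop("higher (%s) must be > lower (%s)",
                               format(higher), format(lower))
  pieces <- scan_db(db, batch_size, function(mat, s) {
    up <- apply(mat, 2L, function(v) rownames(mat)[v >= higher],
                simplify = FALSE)
    dn <- apply(mat, 2L, function(v) rownames(mat)[v <= lower],
                simplify = FALSE)
    list(up = up, down = dn)
  })
  up_sets <- do.call(c, lapply(pieces, `[[`, "up"))
  down_sets <- do.call(c, lapply(pieces, `[[`, "down"))
  empty <- vapply(seq_along(up_sets), function(i) {
    length(up_sets[[i]]) == 0L && length(down_sets[[i]]) == 0L
  }, logical(1))
  if (any(empty))
    warning(sprintf("%d treatment(s) have empty up and down sets at cutoffs [%s, %s]",
                    sum(empty), format(lower), format(higher)), call. = FALSE)
  write_gs_db(up_sets, down_sets, db@gene_ids, db@treatment_ids, out_path)
}

#' Build a gene-set database directly from up/down set lists
#'
#' @param up_sets,down_sets Named lists of gene identifier vectors, one
#'   element per treatment (names = treatment ids, or supply
#'   `treatment_ids`).
#' @param gene_ids Gene universe of the database.
#' @param treatment_ids Composite treatment identifiers.
#' @param out_path Path of the HDF5 file to create.
#' @return A [SignatureDB] with `value_kind = "gene_set"`.
#' @export
build_gs_db <- function(up_sets, down_sets, gene_ids,
                        treatment_ids = names(up_sets), out_path) {
  if (length(up_sets) != length(down_sets))
    vstop("up_sets and down_sets must have equal length")
  if (is.null(treatment_ids)) vstop("treatment_ids required")
  if (anyDuplicated(treatment_ids)) vstop("duplicate treatment_ids")
  if (length(treatment_ids) == 0L) vstop("empty database")
  write_gs_db(up_sets, down_sets, gene_ids, treatment_ids, out_path)
}

#' Read a delimited gene x treatment matrix
#'
#' Expects genes in rows with a header line of treatment ids; the first
#' column holds gene identifiers.
#'
#' @param path TSV/CSV file path (separator auto-detected).
#' @return Numeric matrix with dimnames.
#' @export
read_gep_matrix <- function(path) {
  if (!file.exists(path)) vstop("matrix file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE)
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read / write plain-text gene identifier lists
#'
#' One identifier per line; used for up/down query set files.
#'
#' @param path File path.
#' @return `read_id_list()`: a character vector.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) vstop("file not found: %s", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @param ids Character vector to write.
#' @rdname read_id_list
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(ids), path)
}
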