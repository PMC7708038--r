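# Internal helpers shared across modules.

# Validation failures get their own condition class so the CLI can map them
# to exit code 2, distinct from runtime failures (exit 1).
vstop <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("sigconnect_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_validation_error <- function(e) inherits(e, "sigconnect_validation_error")

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so simulations stay pure functions of
# their seed argument.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Compose and parse composite treatment identifiers
#'
#' Treatments are keyed by the composite identifier
#' `"pert__cell__perttype"` (double-underscore separator). Parsing splits on
#' the *last two* `"__"` occurrences so perturbagen names that themselves
#' contain underscores (or a literal `"__"`) survive a round trip.
#'
#' @param pert,cell,perttype Character vectors (recycled) with the
#'   perturbagen (e.g. drug) name, cell type and treatment type.
#' @return `make_treatment_id()` returns a character vector of composite ids;
#'   `parse_treatment_ids()` returns a `data.frame` with columns
#'   `treatment_id`, `pert`, `cell`, `perttype`.
#' @examples
#' ids <- make_treatment_id(c("vorinostat", "BRD_K81418486"), "PC3", "trt_cp")
#' parse_treatment_ids(ids)
#' @export
make_treatment_id <- function(pert, cell, perttype) {
  paste(pert, cell, perttype, sep = "__")
}

#' @param ids Character vector of composite treatment identifiers.
#' @rdname make_treatment_id
#' @export
parse_treatment_ids <- function(ids) {
  parts <- strsplit(ids, "__", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) {
    vstop("malformed treatment id (need 'pert__cell__perttype'): %s",
          paste(ids[bad], collapse = ", "))
  }
  pert <- vapply(parts, function(p) {
    paste(p[seq_len(length(p) - 2L)], collapse = "__")
  }, character(1))
  cell <- vapply(parts, function(p) p[length(p) - 1L], character(1))
  ptype <- vapply(parts, function(p) p[length(p)], character(1))
  data.frame(treatment_id = ids, pert = pert, cell = cell, perttype = ptype,
             stringsAsFactors = FALSE)
}
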