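#' Log2 fold change between diseased and control expression
#'
#' `fd = log2(a) - log2(b)` where `a` is a gene's expression in diseased
#' tissue and `b` its expression in the control. Positive values are
#' up-regulation in disease, negative values down-regulation.
#'
#' @param a,b Positive numeric vectors (recycled to a common length),
#'   expression values in arbitrary but common units.
#' @return Numeric vector of log2 fold changes.
#' @export
#' @examples
#' compute_fold_change(8, 2) # 2
compute_fold_change <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    abort_domain("`a` and `b` must be numeric")
  }
  if (any(is.na(a)) || any(is.na(b)) || any(a <= 0) || any(b <= 0)) {
    abort_domain("expression values must be positive to take log2 fold changes")
  }
  log2(a) - log2(b)
}

#' Differential-expression table
#'
#' Validates and classes a per-gene differential-expression table. Each
#' record has an opaque unique `record_id`, a gene `symbol` (canonicalized),
#' and either a pair of positive expression values (`a` diseased, `b`
#' control) or a precomputed log2 fold change `fd`. Symbols may repeat
#' across records (distinct loci can share a gene symbol); record ids may
#' not.
#'
#' @param x A data frame with columns `record_id`, `symbol` and optionally
#'   `a`, `b` and/or `fd` (or `log2fc`, renamed to `fd`).
#' @return A tibble of class `deg_table`, rows in input order, with `fd`
#'   filled in from `a` and `b` where possible.
#' @export
deg_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("record_id", "symbol")
  if (!all(required %in% names(x))) {
    abort_domain("a DEG table needs `record_id` and `symbol` columns")
  }
  if ("log2fc" %in% names(x) && !"fd" %in% names(x)) {
    x <- dplyr::rename(x, fd = "log2fc")
  }
  x$record_id <- trimws(as.character(x$record_id))
  x$symbol <- canonical_symbol(x$symbol)
  if (anyDuplicated(x$record_id)) {
    dup <- x$record_id[duplicated(x$record_id)][1L]
    abort_domain(paste0("duplicate record_id in DEG table: ", dup))
  }
  if (!"a" %in% names(x)) x$a <- NA_real_
  if (!"b" %in% names(x)) x$b <- NA_real_
  if (!"fd" %in% names(x)) x$fd <- NA_real_
  x$a <- as.numeric(x$a)
  x$b <- as.numeric(x$b)
  x$fd <- as.numeric(x$fd)

  has_ab <- !is.na(x$a) & !is.na(x$b)
  if (any(has_ab & (x$a <= 0 | x$b <= 0))) {
    abort_domain("expression values `a` and `b` must be positive")
  }
  computed <- ifelse(has_ab, log2(x$a) - log2(x$b), NA_real_)
  both <- has_ab & !is.na(x$fd)
  if (any(both) && max(abs(x$fd[both] - computed[both])) > 1e-6) {
    abort_domain(
      "stored fd disagrees with log2(a) - log2(b) beyond 1e-6 for some records"
    )
  }
  x$fd <- ifelse(has_ab, computed, x$fd)

  class(x) <- c("deg_table", class(tibble::tibble()))
  x
}

#' Read a differential-expression table
#'
#' Accepts a TSV with header and columns `(record_id, symbol, a, b)` or
#' `(record_id, symbol, log2fc)`; a bare `(record_id, symbol)` table (e.g.
#' a published match list without printed fold changes) is also accepted,
#' with `fd` left missing. With expression columns, `fd` is computed as
#' `log2(a + pseudocount) - log2(b + pseudocount)` and the stored `a`, `b`
#' are the pseudocounted values, so the `fd = log2(a) - log2(b)` invariant
#' holds on the returned table.
#'
#' @param path Path to the TSV file.
#' @param pseudocount Non-negative value added to `a` and `b` before taking
#'   logs (default 0).
#' @return A [deg_table].
#' @export
read_deg_table <- function(path, pseudocount = 0) {
  if (!file.exists(path)) {
    abort_io(paste0("DEG table file not found: ", path))
  }
  check_scalar_number(pseudocount, "pseudocount", lower = 0)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  names(x) <- tolower(trimws(names(x)))
  if (!all(c("record_id", "symbol") %in% names(x))) {
    abort_parse(paste0(
      "DEG table must have `record_id` and `symbol` columns: ", path
    ))
  }
  if (all(c("a", "b") %in% names(x)) && pseudocount > 0) {
    x$a <- as.numeric(x$a) + pseudocount
    x$b <- as.numeric(x$b) + pseudocount
  }
  deg_table(x)
}

#' Write a differential-expression table as TSV
#'
#' @param degs A [deg_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(degs, path) {
  stopifnot(inherits(degs, "deg_table"))
  cols <- intersect(c("record_id", "symbol", "a", "b", "fd"), names(degs))
  out <- degs[cols]
  if (all(c("a", "b") %in% cols) && !anyNA(out$a) && !anyNA(out$b)) {
    out$fd <- NULL # recomputed on read from a and b
  }
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}
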