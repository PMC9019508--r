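#' Canonicalize gene, ingredient and herb names
#'
#' All matching in herbrank is done on canonical names: leading/trailing
#' whitespace stripped and everything lower-cased. Databases and published
#' tables mix case conventions (p53 vs P53, Acacb vs acacb), so names are
#' canonicalized at every ingest point.
#'
#' @param x Character vector of names.
#' @return Character vector of the same length, trimmed and lower-cased.
#' @export
#' @examples
#' canonical_symbol(c("  P53 ", "Acacb"))
canonical_symbol <- function(x) {
  tolower(trimws(as.character(x)))
}

abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "herbrank_parse_error", ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "herbrank_domain_error", ...)
}

abort_empty <- function(msg, ...) {
  rlang::abort(msg, class = "herbrank_empty_error", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "herbrank_io_error", ...)
}

# annotate and rethrow an error with the pipeline stage it came from
with_stage <- function(stage, expr) {
  tryCatch(
    expr,
    error = function(e) {
      rlang::abort(
        paste0("[stage: ", stage, "] ", conditionMessage(e)),
        class = c("herbrank_stage_error", class(e)[1]),
        parent = e,
        stage = stage
      )
    }
  )
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_domain(paste0("`", name, "` must be a single non-missing number"))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_domain(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}
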