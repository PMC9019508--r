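#' Herb / ingredient / target compound database
#'
#' A relational model of a compound-target resource such as TCMID: each herb
#' has a set of ingredients (effective compounds), and each ingredient has a
#' set of target gene symbols. All names are canonicalized (trimmed,
#' lower-cased); every ingredient referenced by a herb gets a target entry,
#' possibly empty.
#'
#' @param herbs Named list: herb name -> character vector of ingredients.
#' @param targets Named list: ingredient name -> character vector of target
#'   gene symbols.
#' @return An object of class `compound_db` with canonicalized `herbs` and
#'   `targets` lists.
#' @export
compound_db <- function(herbs = list(), targets = list()) {
  if (length(herbs) > 0 && is.null(names(herbs))) {
    abort_domain("`herbs` must be a named list")
  }
  herbs <- lapply(herbs, function(i) unique(canonical_symbol(i)))
  names(herbs) <- canonical_symbol(names(herbs) %||% character(0))
  targets <- lapply(targets, function(t) {
    sort(unique(canonical_symbol(t)))
  })
  names(targets) <- canonical_symbol(names(targets) %||% character(0))

  empty <- names(herbs)[lengths(herbs) == 0L]
  if (length(empty) > 0) {
    rlang::warn(paste0(
      "herb(s) with zero ingredients retained: ",
      paste(empty, collapse = ", ")
    ))
  }
  referenced <- unique(unlist(herbs, use.names = FALSE)) %||% character(0)
  missing <- setdiff(referenced, names(targets))
  for (m in missing) targets[[m]] <- character(0)

  structure(list(herbs = herbs, targets = targets), class = "compound_db")
}

#' @export
print.compound_db <- function(x, ...) {
  cat(sprintf(
    "<compound_db> %d herbs, %d ingredients, %d distinct targets\n",
    length(x$herbs), length(x$targets),
    length(unique(unlist(x$targets, use.names = FALSE)))
  ))
  invisible(x)
}

#' @export
as_tibble.compound_db <- function(x, ...) {
  if (length(x$herbs) == 0L) {
    return(tibble::tibble(herb = character(0), ingredient = character(0),
                          target = character(0)))
  }
  purrr::map_dfr(names(x$herbs), function(h) {
    ings <- x$herbs[[h]]
    if (length(ings) == 0L) {
      return(tibble::tibble(herb = h, ingredient = NA_character_,
                            target = NA_character_))
    }
    purrr::map_dfr(ings, function(i) {
      tg <- x$targets[[i]]
      tibble::tibble(
        herb = h, ingredient = i,
        target = if (length(tg) == 0L) NA_character_ else tg
      )
    })
  })
}

#' Read a compound database
#'
#' Two on-disk layouts are supported:
#' * a single JSON document `{herb: {ingredient: [target, ...]}}`;
#' * a directory containing `herb_ingredient.tsv` (columns herb, ingredient)
#'   and `ingredient_target.tsv` (columns ingredient, target), header line
#'   optional.
#'
#' @param path Path to the JSON file or the directory.
#' @return A [compound_db].
#' @export
read_compound_db <- function(path) {
  if (dir.exists(path)) {
    return(read_compound_db_dir(path))
  }
  if (!file.exists(path)) {
    abort_io(paste0("compound database not found: ", path))
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      abort_parse(paste0("cannot parse compound database JSON: ",
                         conditionMessage(e)))
    }
  )
  if (length(doc) == 0L) {
    return(compound_db())
  }
  if (!is.list(doc) || is.null(names(doc))) {
    abort_parse("compound database JSON must map herb -> ingredient -> targets")
  }
  herbs <- lapply(doc, names)
  targets <- list()
  for (h in names(doc)) {
    for (i in names(doc[[h]])) {
      targets[[i]] <- unique(c(targets[[i]], unlist(doc[[h]][[i]])))
    }
  }
  compound_db(herbs = herbs, targets = targets)
}

read_two_col_tsv <- function(path, expected_names) {
  if (!file.exists(path)) {
    abort_io(paste0("compound database file not found: ", path))
  }
  first <- tolower(trimws(strsplit(readLines(path, n = 1L), "\t")[[1L]]))
  has_header <- identical(first[seq_along(expected_names)], expected_names)
  x <- utils::read.delim(path, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 2L) {
    abort_parse(paste0("expected two tab-separated columns in ", path))
  }
  stats::setNames(x[1:2], expected_names)
}

read_compound_db_dir <- function(path) {
  hi <- read_two_col_tsv(file.path(path, "herb_ingredient.tsv"),
                         c("herb", "ingredient"))
  it <- read_two_col_tsv(file.path(path, "ingredient_target.tsv"),
                         c("ingredient", "target"))
  herbs <- split(hi$ingredient, hi$herb)
  targets <- split(it$target, it$ingredient)
  compound_db(herbs = herbs, targets = targets)
}

#' Write a compound database as JSON
#'
#' Inverse of [read_compound_db()]'s JSON layout.
#'
#' @param db A [compound_db].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_compound_db <- function(db, path) {
  stopifnot(inherits(db, "compound_db"))
  doc <- lapply(db$herbs, function(ings) {
    stats::setNames(lapply(ings, function(i) as.list(db$targets[[i]])), ings)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
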