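#' Herb-screening configuration
#'
#' @param min_overlap Minimum number of key genes an ingredient's target set
#'   must intersect for the ingredient to count as effective. Default 1 (any
#'   key-gene target makes a component effective).
#' @param restrict_to_degs If `TRUE` (default), key genes are selected from
#'   the ranking restricted to symbols present in the DEG table, so the
#'   key-gene set is a prioritized subset of the measured DEGs rather than
#'   of the whole network.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_overlap = 1L, restrict_to_degs = TRUE) {
  check_scalar_number(min_overlap, "min_overlap", lower = 1)
  structure(
    list(min_overlap = as.integer(min_overlap),
         restrict_to_degs = isTRUE(restrict_to_degs)),
    class = "screen_config"
  )
}

#' Match herbal components against the key-gene set
#'
#' An ingredient is *effective* when its database target set intersects the
#' key genes in at least `min_overlap` symbols. An ingredient shared by
#' several herbs can be effective for each of them.
#'
#' @param db A [compound_db].
#' @param key_genes Character vector of key gene symbols (canonicalized
#'   internally).
#' @param config A [screen_config].
#' @return Named list: herb -> sorted character vector of effective
#'   ingredients (possibly empty).
#' @export
match_components <- function(db, key_genes, config = screen_config()) {
  stopifnot(inherits(db, "compound_db"))
  key <- unique(canonical_symbol(key_genes))
  lapply(db$herbs, function(ings) {
    eff <- vapply(ings, function(i) {
      length(intersect(db$targets[[i]], key)) >= config$min_overlap
    }, logical(1))
    sort(ings[eff])
  })
}

#' Score herbs by their number of effective components
#'
#' @param effective Named list from [match_components()].
#' @return A tibble with columns `herb` and `score` (integer count of
#'   effective ingredients), sorted by descending score, then herb name.
#' @export
score_herbs <- function(effective) {
  out <- tibble::tibble(
    herb = names(effective) %||% character(0),
    score = as.integer(lengths(effective))
  )
  dplyr::arrange(out, dplyr::desc(.data$score), .data$herb)
}

#' Select the top-scoring herb(s)
#'
#' All herbs attaining the maximal score are returned, sorted by name; ties
#' are reported rather than silently broken.
#'
#' @param scores A tibble from [score_herbs()] (columns `herb`, `score`) or
#'   a named numeric vector.
#' @return Character vector of the maximal-score herbs.
#' @export
select_top_herb <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble::tibble(herb = names(scores), score = unname(scores))
  }
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    abort_empty("cannot select a top herb from an empty score table")
  }
  sort(scores$herb[scores$score == max(scores$score)])
}

#' Match DEG records to a herb's effective components
#'
#' Returns one row per DEG record whose symbol lies in the union of the
#' effective components' full database target sets. Matching is per record:
#' duplicate symbols under distinct record ids each produce a row.
#'
#' @param degs A [deg_table].
#' @param herb Herb name (must exist in `db`).
#' @param db A [compound_db].
#' @param effective Character vector of effective ingredients of `herb`
#'   (a subset of the herb's ingredient list).
#' @return A tibble with columns `record_id`, `symbol` and `ingredients`
#'   (list column: the effective ingredients targeting that symbol), rows
#'   in DEG-table order.
#' @export
match_degs_to_components <- function(degs, herb, db, effective) {
  stopifnot(inherits(degs, "deg_table"), inherits(db, "compound_db"))
  herb <- canonical_symbol(herb)
  if (!herb %in% names(db$herbs)) {
    abort_domain(paste0("unknown herb: ", herb))
  }
  effective <- canonical_symbol(effective)
  if (!all(effective %in% db$herbs[[herb]])) {
    abort_domain("`effective` must be a subset of the herb's ingredients")
  }
  target_union <- sort(unique(unlist(db$targets[effective],
                                     use.names = FALSE)))
  hit <- degs$symbol %in% target_union
  matched <- degs[hit, , drop = FALSE]
  tibble::tibble(
    record_id = matched$record_id,
    symbol = matched$symbol,
    ingredients = lapply(matched$symbol, function(s) {
      sort(effective[vapply(effective, function(i) s %in% db$targets[[i]],
                            logical(1))])
    })
  )
}

#' Run the full herb-screening pipeline
#'
#' Composes the stages: initial importance from fold changes, iterative
#' GeneRank propagation, ranking, top-k key-gene selection (restricted to
#' DEG symbols by default), component matching, herb scoring, top-herb
#' selection, and DEG-record matching for each top herb. Any stage error is
#' re-raised annotated with the stage name.
#'
#' @param network A [gene_network].
#' @param degs A [deg_table].
#' @param db A [compound_db].
#' @param generank_config A [generank_config].
#' @param screen_config A [screen_config].
#' @return An object of class `screen_report`: a list with `key_genes`,
#'   `effective_components` (named list), `herb_scores` (tibble),
#'   `top_herbs`, `deg_matches` (tibble with a `herb` column), `generank`
#'   (one-row convergence summary) and the two configs.
#' @export
run_screen <- function(network, degs, db,
                       generank_config = herbrank::generank_config(),
                       screen_config = herbrank::screen_config()) {
  init <- with_stage("build_initial_importance",
                     build_initial_importance(degs, network, generank_config))
  fit <- with_stage("generank", generank(network, init, generank_config))
  ranking <- with_stage("rank_genes", rank_genes(fit))
  if (screen_config$restrict_to_degs) {
    ranking <- ranking[ranking %in% unique(degs$symbol)]
  }
  key_genes <- with_stage("select_top_k",
                          select_top_k(ranking, generank_config$top_k))
  effective <- with_stage("match_components",
                          match_components(db, key_genes, screen_config))
  herb_scores <- with_stage("score_herbs", score_herbs(effective))
  top_herbs <- with_stage("select_top_herb", select_top_herb(herb_scores))
  deg_matches <- with_stage("match_degs_to_components",
    purrr::map_dfr(top_herbs, function(h) {
      m <- match_degs_to_components(degs, h, db, effective[[h]])
      if (nrow(m) == 0L) return(m)
      tibble::add_column(m, herb = h, .before = 1L)
    })
  )
  if (nrow(deg_matches) == 0L) {
    deg_matches <- tibble::tibble(herb = character(0),
                                  record_id = character(0),
                                  symbol = character(0),
                                  ingredients = list())
  }

  structure(
    list(
      key_genes = key_genes,
      effective_components = effective,
      herb_scores = herb_scores,
      top_herbs = top_herbs,
      deg_matches = deg_matches,
      generank = glance.generank_fit(fit),
      generank_config = generank_config,
      screen_config = screen_config
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf(
    "<screen_report> %d key genes, %d herbs screened\n",
    length(x$key_genes), nrow(x$herb_scores)
  ))
  cat("  top herb(s):",
      paste(sprintf("%s (score %d)", x$top_herbs,
                    x$herb_scores$score[match(x$top_herbs, x$herb_scores$herb)]),
            collapse = ", "), "\n")
  cat(sprintf("  matched DEG records: %d\n", nrow(x$deg_matches)))
  invisible(x)
}

#' Tidy a screen report into the herb-score table
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A tibble with `herb`, `score`, `effective` (list column of
#'   effective ingredients) and `is_top`.
#' @export
tidy.screen_report <- function(x, ...) {
  dplyr::mutate(
    x$herb_scores,
    effective = unname(x$effective_components[.data$herb]),
    is_top = .data$herb %in% x$top_herbs
  )
}

#' One-row summary of a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A one-row tibble: key-gene count, herb counts, top herb(s), DEG
#'   matches and GeneRank convergence record.
#' @export
glance.screen_report <- function(x, ...) {
  tibble::tibble(
    n_key_genes = length(x$key_genes),
    n_herbs = nrow(x$herb_scores),
    top_herbs = paste(x$top_herbs, collapse = ";"),
    top_score = max(x$herb_scores$score),
    n_deg_matches = nrow(x$deg_matches),
    generank_iterations = x$generank$iterations,
    generank_residual = x$generank$final_residual
  )
}

#' Plot herb scores from a screen report
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of effective-component counts per herb, top
#'   herb(s) highlighted.
#' @export
autoplot.screen_report <- function(object, ...) {
  dat <- tidy.screen_report(object)
  dat$herb <- factor(dat$herb, levels = rev(dat$herb))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$herb,
                                    fill = .data$is_top)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#2b8cbe")) +
    ggplot2::labs(x = "effective components", y = NULL,
                  title = "Herb scores") +
    ggplot2::theme_minimal()
}

#' Write a screen report to disk
#'
#' Writes `report.json` (the full report; deterministic, no timestamps) and
#' `herb_scores.tsv` (herbs sorted by descending score, then name) into a
#' directory. [read_screen_report()] round-trips the JSON form losslessly
#' for all set-valued and tabular fields.
#'
#' @param report A `screen_report`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort_io(paste0("cannot create report directory: ", path))
  }
  doc <- list(
    key_genes = report$key_genes,
    effective_components = lapply(report$effective_components, as.list),
    herb_scores = purrr::map2(report$herb_scores$herb,
                              report$herb_scores$score,
                              ~list(herb = .x, score = .y)),
    top_herbs = report$top_herbs,
    deg_matches = purrr::pmap(report$deg_matches,
                              function(herb, record_id, symbol, ingredients) {
                                list(herb = herb, record_id = record_id,
                                     symbol = symbol,
                                     ingredients = as.list(ingredients))
                              }),
    generank = as.list(report$generank),
    config = list(
      generank = unclass(report$generank_config),
      screen = unclass(report$screen_config)
    )
  )
  jsonlite::write_json(doc, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(report$herb_scores, file.path(path, "herb_scores.tsv"),
                   progress = FALSE)
  invisible(path)
}

#' Read a screen report written by [write_screen_report()]
#'
#' @param path Directory containing `report.json`.
#' @return A `screen_report`.
#' @export
read_screen_report <- function(path) {
  f <- file.path(path, "report.json")
  if (!file.exists(f)) {
    abort_io(paste0("no report.json under ", path))
  }
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  herb_scores <- tibble::tibble(
    herb = purrr::map_chr(doc$herb_scores, "herb"),
    score = purrr::map_int(doc$herb_scores, "score")
  )
  deg_matches <- tibble::tibble(
    herb = purrr::map_chr(doc$deg_matches, "herb"),
    record_id = purrr::map_chr(doc$deg_matches, "record_id"),
    symbol = purrr::map_chr(doc$deg_matches, "symbol"),
    ingredients = purrr::map(doc$deg_matches,
                             ~as.character(unlist(.x$ingredients)))
  )
  structure(
    list(
      key_genes = as.character(unlist(doc$key_genes)),
      effective_components = lapply(doc$effective_components,
                                    function(x) as.character(unlist(x))),
      herb_scores = herb_scores,
      top_herbs = as.character(unlist(doc$top_herbs)),
      deg_matches = deg_matches,
      generank = tibble::as_tibble(doc$generank),
      generank_config = do.call(generank_config,
                                doc$config$generank[
                                  setdiff(names(doc$config$generank), character(0))]),
      screen_config = do.call(screen_config, doc$config$screen)
    ),
    class = "screen_report"
  )
}
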