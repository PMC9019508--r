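#' Gene dependence network
#'
#' An undirected, unweighted graph over gene symbols, the carrier for
#' protein-protein dependence information (e.g. a thresholded STRING
#' export). Edges are stored canonically (symbols trimmed and lower-cased,
#' each unordered pair once, no self-loops); nodes may include isolated
#' genes with degree zero.
#'
#' @param edges A data frame with at least two character columns (`from`,
#'   `to`), or `NULL` for an edgeless network. Extra columns are ignored.
#' @param nodes Optional character vector of node symbols to include even if
#'   they touch no edge.
#' @return An object of class `gene_network`: a list with elements
#'   `nodes` (character), `edges` (tibble with columns `from`, `to`) and
#'   `degree` (named integer vector over `nodes`).
#' @export
#' @examples
#' net <- gene_network(data.frame(from = c("g1", "g2"), to = c("g2", "g3")))
#' net$degree[["g2"]]
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    from <- character(0)
    to <- character(0)
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L) {
      abort_domain("`edges` must have at least two columns (from, to)")
    }
    from <- canonical_symbol(edges[[1L]])
    to <- canonical_symbol(edges[[2L]])
  }
  nodes <- unique(c(canonical_symbol(nodes %||% character(0)),
                    as.vector(rbind(from, to))))
  nodes <- nodes[nzchar(nodes)]

  # canonical unordered pairs; drop self-loops and duplicates
  keep <- from != to & nzchar(from) & nzchar(to)
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  pair <- paste(a, b, sep = "\r")
  dup <- duplicated(pair)
  edge_tbl <- tibble::tibble(from = a[!dup], to = b[!dup])

  deg <- table(factor(c(edge_tbl$from, edge_tbl$to), levels = nodes))
  degree <- stats::setNames(as.integer(deg), nodes)

  structure(
    list(nodes = nodes, edges = edge_tbl, degree = degree),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d nodes, %d edges (%d isolated)\n",
    length(x$nodes), nrow(x$edges), sum(x$degree == 0L)
  ))
  invisible(x)
}

#' @export
as_tibble.gene_network <- function(x, ...) {
  x$edges
}

#' Per-node degree as a tibble
#'
#' @param network A [gene_network].
#' @return A tibble with columns `symbol` and `degree`.
#' @export
network_degree <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  tibble::tibble(symbol = network$nodes,
                 degree = unname(network$degree))
}

#' Read a gene dependence network from an edge list
#'
#' Parses a whitespace/tab-separated edge list with columns
#' `geneA geneB [score]`. Lines starting with `#` and blank lines are
#' skipped. A header line is detected when the first data line has a
#' non-numeric third field. Self-loop rows are dropped as edges but their
#' symbol is kept as an (isolated) node, which is also how
#' [write_edge_list()] encodes isolated nodes.
#'
#' @param path Path to the edge-list file.
#' @param min_score Optional numeric threshold; rows whose third-column score
#'   is below it are excluded. Rows without a score are kept.
#' @return A [gene_network].
#' @export
read_edge_list <- function(path, min_score = NULL) {
  if (!file.exists(path)) {
    abort_io(paste0("edge-list file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    abort_parse(paste0("no data rows in edge list: ", path))
  }

  fields <- strsplit(trimws(lines[idx]), "[ \t]+")

  # optional header: first retained line whose third field is non-numeric
  first <- fields[[1L]]
  if (length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[3L])))) {
    fields <- fields[-1L]
    idx <- idx[-1L]
    if (length(fields) == 0L) {
      abort_parse(paste0("no data rows in edge list: ", path))
    }
  }

  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    abort_parse(sprintf(
      "malformed edge-list row at line %d of %s: fewer than 2 fields",
      bad, path
    ))
  }

  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  score <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_
  }, numeric(1))

  nodes <- canonical_symbol(c(from, to))
  if (!is.null(min_score)) {
    check_scalar_number(min_score, "min_score")
    drop <- !is.na(score) & score < min_score
    from <- from[!drop]
    to <- to[!drop]
  }
  gene_network(data.frame(from = from, to = to), nodes = nodes)
}

#' Write a gene dependence network as an edge list
#'
#' Edges are written as `from<TAB>to` rows; isolated nodes are written as
#' self-pair rows (`g<TAB>g`), which [read_edge_list()] turns back into
#' degree-0 nodes, so write/read round-trips exactly.
#'
#' @param network A [gene_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  isolated <- network$nodes[network$degree == 0L]
  lines <- c(
    paste(network$edges$from, network$edges$to, sep = "\t"),
    paste(isolated, isolated, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
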