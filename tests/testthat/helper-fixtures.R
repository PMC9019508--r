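# shared builders for tiny in-test fixtures

# the hand-solved two-node system: edge g1-g2, ex = (1, 0), d = 0.5
# r1 = 0.5 + 0.5 r2, r2 = 0.5 r1  =>  r = (2/3, 1/3)
two_node_network <- function() {
  gene_network(data.frame(from = "g1", to = "g2"))
}

two_node_init <- function(config = generank_config()) {
  degs <- deg_table(data.frame(record_id = "r1", symbol = "g1", log2fc = 1))
  build_initial_importance(degs, two_node_network(), config)
}

# write the two-node instance as CLI input files; returns the paths
two_node_files <- function(dir) {
  network <- file.path(dir, "network.tsv")
  degs <- file.path(dir, "degs.tsv")
  writeLines("g1\tg2", network)
  writeLines(c("record_id\tsymbol\tlog2fc", "r1\tg1\t1"), degs)
  list(network = network, degs = degs)
}

# Erdos-Renyi gene_network sampled with base R only (independent of the
# package's igraph-backed generator)
base_er_network <- function(n, p, seed) {
  set.seed(seed)
  syms <- sprintf("n%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  gene_network(
    data.frame(from = syms[pairs[1, keep]], to = syms[pairs[2, keep]]),
    nodes = syms
  )
}

random_init <- function(network, seed, config = generank_config()) {
  set.seed(seed)
  n <- length(network$nodes)
  degs <- deg_table(data.frame(
    record_id = paste0("r", seq_len(n)),
    symbol = network$nodes,
    log2fc = stats::rnorm(n)
  ))
  build_initial_importance(degs, network, config)
}

# the 23 distinct gene symbols of the packaged DEG-match fixture, used as
# the explicit target union for full-coverage matching
sbmie_symbol_union <- function() {
  sort(unique(load_sbmie_degs()$symbol))
}

# a compound database whose single herb keeps the packaged component list
# but whose target union is extended to cover `symbols`
extended_seabuckthorn_db <- function(symbols) {
  db <- load_seabuckthorn_targets()
  extra <- setdiff(symbols, sort(unique(unlist(db$targets))))
  targets <- db$targets
  targets[["gallic acid"]] <- c(targets[["gallic acid"]], extra)
  compound_db(herbs = db$herbs, targets = targets)
}
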