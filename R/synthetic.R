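#' Synthetic-data configuration
#'
#' Parameters of the seeded generator that emulates the screening pipeline's
#' inputs: a sparse undirected dependence network (heavy-tailed degrees under
#' the preferential-attachment model), a DEG profile in which a minority of
#' disease genes carry large fold changes over small background noise, and a
#' compound database in which one planted herb's ingredients preferentially
#' target the true disease genes.
#'
#' @param n_genes Number of genes (network nodes). Default 500.
#' @param network_model `"preferential_attachment"` (default; heavy-tailed
#'   degrees, like curated interactome exports) or `"erdos_renyi"`.
#' @param pa_m Edges attached per new node under preferential attachment.
#'   Default 3 (mean degree about 6, a sparse interactome-like graph).
#' @param er_p Edge probability under the Erdős–Rényi model. Default 0.012
#'   (matches the preferential-attachment default's edge count at
#'   `n_genes = 500`).
#' @param n_disease_genes Number of planted disease genes. Default 50.
#' @param effect_size Mean `|log2 fold change|` of disease genes. Default 2.
#' @param noise_sd Standard deviation of background log2 fold changes (and
#'   of the jitter on disease-gene effects). Default 0.25.
#' @param n_herbs Number of herbs, one of which is planted. Default 20.
#' @param ingredients_per_herb Ingredients per herb. Default 5.
#' @param targets_per_ingredient Target genes per ingredient. Default 3.
#' @param planted_overlap Fraction of each planted-herb ingredient's targets
#'   drawn from the true disease genes (the remainder is drawn uniformly
#'   from the other genes). Default 0.8.
#' @param seed Master seed; all generator randomness derives from it.
#'   Default 1.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500L,
                         network_model = c("preferential_attachment",
                                           "erdos_renyi"),
                         pa_m = 3L,
                         er_p = 0.012,
                         n_disease_genes = 50L,
                         effect_size = 2,
                         noise_sd = 0.25,
                         n_herbs = 20L,
                         ingredients_per_herb = 5L,
                         targets_per_ingredient = 3L,
                         planted_overlap = 0.8,
                         seed = 1L) {
  network_model <- match.arg(network_model)
  check_scalar_number(n_genes, "n_genes", lower = 1)
  check_scalar_number(pa_m, "pa_m", lower = 1)
  check_scalar_number(er_p, "er_p", lower = 0, upper = 1)
  check_scalar_number(n_disease_genes, "n_disease_genes", lower = 0,
                      upper = n_genes)
  check_scalar_number(effect_size, "effect_size", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(n_herbs, "n_herbs", lower = 1)
  check_scalar_number(ingredients_per_herb, "ingredients_per_herb", lower = 1)
  check_scalar_number(targets_per_ingredient, "targets_per_ingredient",
                      lower = 1)
  check_scalar_number(planted_overlap, "planted_overlap", lower = 0,
                      upper = 1)
  check_scalar_number(seed, "seed")
  structure(
    list(n_genes = as.integer(n_genes), network_model = network_model,
         pa_m = as.integer(pa_m), er_p = er_p,
         n_disease_genes = as.integer(n_disease_genes),
         effect_size = effect_size, noise_sd = noise_sd,
         n_herbs = as.integer(n_herbs),
         ingredients_per_herb = as.integer(ingredients_per_herb),
         targets_per_ingredient = as.integer(targets_per_ingredient),
         planted_overlap = planted_overlap, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# fixed sub-seed offsets so the three generator stages draw from
# independent streams while staying reproducible from one master seed
SEED_OFFSET_DEGS <- 500009L
SEED_OFFSET_DB <- 1000003L

gene_symbols <- function(n) {
  sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
}

#' Generate a synthetic gene dependence network
#'
#' Nodes are named `g0001`, `g0002`, ...; the edge structure is drawn from
#' the configured random-graph model with `set.seed(config$seed)`, so equal
#' configs give identical networks.
#'
#' @param config A [synth_config].
#' @return A [gene_network].
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes
  set.seed(config$seed)
  g <- switch(config$network_model,
    erdos_renyi = igraph::sample_gnp(n, config$er_p),
    preferential_attachment = igraph::sample_pa(n, m = config$pa_m,
                                                directed = FALSE)
  )
  syms <- gene_symbols(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = syms[el[, 1L]], to = syms[el[, 2L]])
  gene_network(edges, nodes = syms)
}

#' Simulate a DEG profile with planted disease genes
#'
#' `n_disease_genes` genes are sampled uniformly without replacement; their
#' fold changes are `sign * (effect_size + N(0, noise_sd))` with a random
#' sign, background genes get `N(0, noise_sd)`. Expression values are
#' back-filled as `b = 1`, `a = 2^fd`, so the fold-change invariant holds by
#' construction and both input dialects are exercised by the same generator.
#'
#' @param network A [gene_network] (its node set defines the genes).
#' @param config A [synth_config].
#' @return A list with `degs` (a [deg_table], one record per gene in node
#'   order) and `disease_genes` (sorted character vector).
#' @export
simulate_degs <- function(network, config) {
  stopifnot(inherits(network, "gene_network"),
            inherits(config, "synth_config"))
  genes <- network$nodes
  if (config$n_disease_genes > length(genes)) {
    abort_domain("n_disease_genes exceeds the number of genes in the network")
  }
  set.seed(config$seed + SEED_OFFSET_DEGS)
  disease <- sort(sample(genes, config$n_disease_genes))
  fd <- stats::rnorm(length(genes), mean = 0, sd = config$noise_sd)
  is_disease <- genes %in% disease
  n_d <- sum(is_disease)
  if (n_d > 0) {
    signs <- sample(c(-1, 1), n_d, replace = TRUE)
    fd[is_disease] <- signs *
      (config$effect_size + stats::rnorm(n_d, 0, config$noise_sd))
  }
  degs <- deg_table(tibble::tibble(
    record_id = sprintf("rec%0*d", max(4L, nchar(length(genes))),
                        seq_along(genes)),
    symbol = genes,
    a = 2^fd,
    b = 1
  ))
  list(degs = degs, disease_genes = disease)
}

#' Build a synthetic compound database with a planted herb
#'
#' Every herb gets `ingredients_per_herb` ingredients with
#' `targets_per_ingredient` targets each. Each planted-herb ingredient draws
#' `ceiling(planted_overlap * targets_per_ingredient)` targets from the true
#' disease genes and the remainder uniformly from the other (non-disease)
#' genes; decoy-herb ingredients draw uniformly from all genes.
#'
#' @param true_genes Character vector of true disease genes.
#' @param network A [gene_network].
#' @param config A [synth_config].
#' @return A list with `db` (a [compound_db]) and `planted_herb` (name).
#' @export
build_compound_db <- function(true_genes, network, config) {
  stopifnot(inherits(network, "gene_network"),
            inherits(config, "synth_config"))
  genes <- network$nodes
  t_per <- config$targets_per_ingredient
  k_true <- as.integer(ceiling(config$planted_overlap * t_per))
  if (length(true_genes) == 0L && config$planted_overlap > 0) {
    abort_domain("planted_overlap > 0 requires a non-empty true gene set")
  }
  if (k_true > length(true_genes) && config$planted_overlap > 0) {
    abort_domain("not enough true disease genes to draw planted targets from")
  }
  other <- setdiff(genes, true_genes)

  set.seed(config$seed + SEED_OFFSET_DB)
  herb_names <- sprintf("herb%0*d", max(2L, nchar(config$n_herbs)),
                        seq_len(config$n_herbs))
  planted <- sample(herb_names, 1L)

  herbs <- list()
  targets <- list()
  for (h in herb_names) {
    ings <- sprintf("%s_c%d", h, seq_len(config$ingredients_per_herb))
    herbs[[h]] <- ings
    for (ing in ings) {
      if (h == planted) {
        tg <- c(
          if (k_true > 0) sample(true_genes, k_true) else character(0),
          if (t_per - k_true > 0) sample(other, t_per - k_true)
          else character(0)
        )
      } else {
        tg <- sample(genes, t_per)
      }
      targets[[ing]] <- tg
    }
  }
  list(db = compound_db(herbs = herbs, targets = targets),
       planted_herb = planted)
}

#' Generate one full synthetic screening instance
#'
#' Convenience wrapper chaining [generate_network()], [simulate_degs()] and
#' [build_compound_db()] under one config.
#'
#' @param config A [synth_config].
#' @return A list with `network`, `degs`, `disease_genes`, `db` and
#'   `planted_herb`.
#' @export
generate_instance <- function(config = synth_config()) {
  network <- generate_network(config)
  sim <- simulate_degs(network, config)
  cdb <- build_compound_db(sim$disease_genes, network, config)
  list(network = network, degs = sim$degs,
       disease_genes = sim$disease_genes,
       db = cdb$db, planted_herb = cdb$planted_herb)
}

#' Planted-herb recovery experiment
#'
#' For each replicate `i` (seed `config$seed + i`), generates a full
#' synthetic instance and runs the screening pipeline with `d = 0.5` and
#' `top_k = 2 * n_disease_genes`; a replicate succeeds when the planted herb
#' is among the reported top herbs (ties included). Stage errors abort the
#' experiment, annotated with the replicate number.
#'
#' @param config A [synth_config] (its `seed` is the master seed).
#' @param n_replicates Number of replicates (>= 1).
#' @return A list of class `recovery_result`: `rate`, `successes`,
#'   `n_replicates`, `replicates` (per-replicate tibble) and `config`.
#' @export
run_recovery_experiment <- function(config = synth_config(),
                                    n_replicates = 50L) {
  check_scalar_number(n_replicates, "n_replicates", lower = 1)
  n_replicates <- as.integer(n_replicates)
  grc <- generank_config(d = 0.5,
                         top_k = max(1L, 2L * config$n_disease_genes))
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + i
    inst <- with_stage(sprintf("replicate %d", i), generate_instance(cfg))
    report <- with_stage(sprintf("replicate %d screen", i),
                         run_screen(inst$network, inst$degs, inst$db,
                                    generank_config = grc))
    rows[[i]] <- tibble::tibble(
      replicate = i,
      seed = cfg$seed,
      planted_herb = inst$planted_herb,
      top_herbs = paste(report$top_herbs, collapse = ";"),
      top_score = max(report$herb_scores$score),
      success = inst$planted_herb %in% report$top_herbs
    )
  }
  replicates <- dplyr::bind_rows(rows)
  structure(
    list(rate = mean(replicates$success),
         successes = sum(replicates$success),
         n_replicates = n_replicates,
         replicates = replicates,
         config = config),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> planted herb recovered in %d/%d replicates (rate %.2f)\n",
    x$successes, x$n_replicates, x$rate
  ))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `network.tsv` (edge list), `degs.tsv` (record_id, symbol, a, b),
#' `compounds.json` (herb -> ingredient -> targets) and `truth.json`
#' (disease genes, planted herb and the generating config). Outputs are
#' fully determined by the config (no timestamps).
#'
#' @param config A [synth_config].
#' @param path Output directory (created if needed).
#' @return The instance (as from [generate_instance()]), invisibly.
#' @export
write_synthetic_dataset <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  inst <- generate_instance(config)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort_io(paste0("cannot create output directory: ", path))
  }
  write_edge_list(inst$network, file.path(path, "network.tsv"))
  write_deg_table(inst$degs, file.path(path, "degs.tsv"))
  write_compound_db(inst$db, file.path(path, "compounds.json"))
  jsonlite::write_json(
    list(disease_genes = inst$disease_genes,
         planted_herb = inst$planted_herb,
         config = unclass(config)),
    file.path(path, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(inst)
}
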