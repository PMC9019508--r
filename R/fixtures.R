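#' Seabuckthorn effective components and their TCMID target genes
#'
#' The published component-target mapping for seabuckthorn (*Hippophae
#' rhamnoides*) in the fish soybean-meal-induced enteritis (SBMIE) screen:
#' five effective components (capric, caproic, caprylic, gallic and malic
#' acids) with their key regulated target genes as mined from the TCMID
#' database. Packaged as a reference dataset so the screening stage can be
#' run and tested without database access.
#'
#' @return A [compound_db] with one herb ("seabuckthorn") and five
#'   ingredients (nine distinct target symbols).
#' @export
#' @examples
#' db <- load_seabuckthorn_targets()
#' db$targets[["malic acid"]]
load_seabuckthorn_targets <- function() {
  read_compound_db(system.file("extdata", "seabuckthorn_components.json",
                               package = "herbrank", mustWork = TRUE))
}

#' Seabuckthorn-targeted DEG records from the grass carp SBMIE transcriptome
#'
#' The 33 differentially expressed gene records (by locus id) from the grass
#' carp soybean-meal-induced enteritis transcriptome that matched the
#' effective components of seabuckthorn. Symbols repeat across records
#' (e.g. three distinct p53 loci); fold changes were not part of the
#' published match list, so `fd` is `NA`. One locus id appears twice in the
#' published table (the two casr rows); the second occurrence is suffixed
#' `_2` to keep record ids unique.
#'
#' @return A [deg_table] with 33 records and an `annotation` column.
#' @export
#' @examples
#' degs <- load_sbmie_degs()
#' sum(degs$symbol == "p53")
load_sbmie_degs <- function() {
  read_deg_table(system.file("extdata", "sbmie_deg_records.tsv",
                             package = "herbrank", mustWork = TRUE))
}
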