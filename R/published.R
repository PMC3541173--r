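# Published reference tables shipped as plain-text TSV: the per-genome SDR
# type counts and the 49-family classification with occurrence classes.
# Totals and tallies are always recomputed from the rows, never stored.

#' Published per-genome SDR type counts
#'
#' The type-level census of ten plant genomes (classical, divergent,
#' extended, atypical, unknown, plus the printed total per genome).
#'
#' @return A tibble, one row per genome.
#' @export
sdr_type_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "sdr_type_counts.tsv", package = "sdrinventory"),
    show_col_types = FALSE
  )
}

#' Published plant SDR family classification
#'
#' The 49-family classification: representative gene, nomenclature family id
#' (`NA` for the similarity-defined orphan families), occurrence class over
#' the taxon hierarchy (starred where algal presence was inferred from
#' genomes outside the surveyed set), and average within-family identity (%).
#'
#' @return A tibble, one row per family.
#' @export
sdr_family_classification <- function() {
  readr::read_tsv(
    system.file("extdata", "sdr_family_classification.tsv",
                package = "sdrinventory"),
    show_col_types = FALSE,
    col_types = readr::cols(starred = readr::col_logical())
  )
}

#' Recount summary statistics from the published tables
#'
#' Recomputes, from the shipped rows: the number of families, how many are
#' tied to a nomenclature HMM versus defined only by sequence conservation,
#' the occurrence-class tallies, and the per-genome SDR totals as the sum of
#' the five type columns (which should reproduce the printed totals).
#'
#' @return A list with `n_families`, `n_hmm_families`, `n_orphan_families`,
#'   `occurrence_tally`, `genome_totals` (tibble `species`, `printed_total`,
#'   `recounted_total`).
#' @export
recount_published_tables <- function() {
  fam <- sdr_family_classification()
  cnt <- sdr_type_counts()
  list(
    n_families = nrow(fam),
    n_hmm_families = sum(!is.na(fam$family_id)),
    n_orphan_families = sum(is.na(fam$family_id)),
    occurrence_tally = dplyr::count(fam, .data$occurrence, name = "n"),
    genome_totals = tibble(
      species = cnt$species,
      printed_total = cnt$total,
      recounted_total = cnt$classical + cnt$divergent + cnt$extended +
        cnt$atypical + cnt$unknown
    )
  )
}
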