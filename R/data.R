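#' Reference lesion counts of a 260-patient B-ALL discovery cohort
#'
#' Subchromosomal copy-number aberration counts per target gene from a
#' nationwide pediatric B-cell precursor ALL discovery cohort of 260
#' patients, ranked by frequency: total aberrations, how many were
#' biallelic losses (or multiple gains, for gained genes) and how many
#' subclonal. Shipped as a plain-text table; useful as a realistic
#' frequency reference and for worked examples of the selection filter.
#'
#' @return data.frame with columns `direction` (`loss`/`gain`), `gene`,
#'   `total`, `biallelic_or_multiple`, `subclonal`.
#' @export
lesion_count_table <- function() {
  utils::read.delim(system.file("extdata", "discovery_lesion_counts.tsv",
                                package = "personALL", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Headline counts of the discovery cohort
#'
#' @return named list: cohort size, patients with any CNA, patients with
#'   subchromosomal CNAs, high-hyperdiploid patients, total CNAs detected.
#' @export
cohort_counts <- function() {
  jsonlite::read_json(system.file("extdata", "discovery_cohort_counts.json",
                                  package = "personALL", mustWork = TRUE),
                      simplifyVector = TRUE)
}

#' Summary statistics computed from the discovery lesion counts
#'
#' Recomputes, from the shipped count tables, the quantities a frequency
#' screen reports: per-gene cohort frequencies, the CNA detection rate,
#' the share of biallelic losses contributed by VPREB1 and CDKN2A/B, the
#' share of multiple gains affecting RUNX1, the subclonal fraction of all
#' subchromosomal CNAs, and which lesions clear the >1.5% frequency
#' criterion of the score-derivation filter.
#'
#' @return named list of computed summaries.
#' @export
cohort_lesion_summary <- function() {
  tab <- lesion_count_table()
  cc <- cohort_counts()
  n <- cc$n_patients
  freq <- stats::setNames(tab$total / n,
                          paste0(tab$gene, ":", tab$direction))
  losses <- tab[tab$direction == "loss", ]
  gains <- tab[tab$direction == "gain", ]
  list(
    n_patients = n,
    detection_rate = cc$patients_with_any_cna / n,
    subchromosomal_rate = cc$patients_with_subchromosomal_cna / n,
    frequency = freq,
    biallelic_share_vpreb1_cdkn2ab =
      sum(losses$biallelic_or_multiple[losses$gene %in%
                                       c("VPREB1", "CDKN2A/B")]) /
      sum(losses$biallelic_or_multiple),
    multiple_gain_share_runx1 =
      gains$biallelic_or_multiple[gains$gene == "RUNX1"] /
      sum(gains$biallelic_or_multiple),
    subclonal_fraction = sum(tab$subclonal) / sum(tab$total),
    frequency_filter_pass = names(freq)[freq > 0.015])
}
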