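#' Published flight-study gene summaries
#'
#' Gene-level condition summaries (mean linear FI, SD across probes,
#' retained probe count) for the 12 genes analyzed in detail in the flight
#' screening study — 7 literature reference-gene candidates and 5 ABC
#' transporters — over the parabolic-flight (PFC) and sounding-rocket
#' (TEXUS) campaigns, transcribed from the published per-campaign summary
#' tables. These summaries enter the pipeline at the CV-screen and
#' contrast-testing stages.
#'
#' @return A tibble with `gene_symbol`, `gene_group`, `campaign`,
#'   `condition`, `mean_fi`, `sd`, `n`.
#' @export
flight_gene_summaries <- function() {
  read_fixture("flight_gene_summaries.tsv",
               readr::cols(mean_fi = "d", sd = "d", n = "i",
                           .default = "c"))
}

#' Published per-contrast p-values
#'
#' The two-tailed Welch p-values printed alongside the flight-study summary
#' tables, one per gene and condition contrast. Used to cross-check the
#' package's Welch test against the published analysis.
#'
#' @return A tibble with `gene_symbol`, `campaign`, `cond_a`, `cond_b`,
#'   `p_printed`.
#' @export
flight_printed_pvalues <- function() {
  read_fixture("flight_printed_pvalues.tsv",
               readr::cols(p_printed = "d", .default = "c"))
}

#' Published g-stable / g-sensitive verdict matrix
#'
#' The `+` (stable) / `-` (sensitive) call per gene and contrast from the
#' flight study's overview table, covering the 15 genes it lists (including
#' three ABC transporters whose per-condition summaries are not printed).
#'
#' @return A tibble with `gene_symbol`, `gene_group`, `campaign`, `cond_a`,
#'   `cond_b`, `symbol`.
#' @export
flight_verdicts <- function() {
  read_fixture("flight_verdicts.tsv", readr::cols(.default = "c"))
}

read_fixture <- function(name, col_types) {
  path <- system.file("extdata", name, package = "refstab", mustWork = TRUE)
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}
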