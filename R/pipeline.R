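#' Run the full reference-gene screening pipeline
#'
#' Chains the pipeline stages on a probe-level expression table: probe
#' condensation, gene aggregation with the minimum-probe rule, inter-probe
#' variance exclusion, CV stability screening, pairwise Welch tests over the
#' campaign's contrasts, one-way ANOVA with BH correction, and the
#' g-stable/g-sensitive classification.
#'
#' @param x A probe-level expression table; log2 tables are back-transformed
#'   to linear first.
#' @param design A `refstab_design` covering the arrays.
#' @param min_probes Minimum retained probes per gene (default 3).
#' @param outlier_rule Probe outlier rule, see [detect_probe_outliers()].
#' @param variance_threshold Inter-probe CV exclusion threshold in percent.
#' @param exclude_genes Genes to exclude unconditionally.
#' @param group_type CV screen group type (default heterogeneous).
#' @param alpha Significance level for contrast tests (default 0.05).
#' @return A list of class `refstab_screen`: `aggregation`, `cv`, `tests`,
#'   `anova`, `verdicts`, `verdict_matrix`, `counts`.
#' @export
screen_reference_genes <- function(x, design, min_probes = 3,
                                   outlier_rule = "none",
                                   variance_threshold = 100,
                                   exclude_genes = NULL,
                                   group_type = "heterogeneous",
                                   alpha = 0.05) {
  if (fi_scale(x) == "log2") x <- to_linear(x)
  probe_means <- condense_probe_values(x, design)
  agg <- aggregate_genes(probe_means, min_probes = min_probes,
                         outlier_rule = outlier_rule)
  agg <- exclude_high_variance(agg, threshold = variance_threshold,
                               exclude_genes = exclude_genes)
  cv <- cv_screen(agg$summaries, group_type = group_type)
  contrasts <- design_contrasts(design)
  tests <- test_contrasts(agg$summaries, contrasts, alpha = alpha)
  anova <- anova_fdr(
    dplyr::semi_join(probe_means, agg$summaries, by = "gene_symbol"),
    alpha = alpha)
  verdicts <- classify_genes(tests, alpha = alpha, gene_status = agg$genes)
  vm <- verdict_matrix(verdicts)
  structure(list(aggregation = agg, cv = cv, tests = tests, anova = anova,
                 verdicts = verdicts, verdict_matrix = vm$matrix,
                 counts = vm$counts),
            class = "refstab_screen")
}

#' @export
print.refstab_screen <- function(x, ...) {
  cat("# Reference-gene screen\n")
  print(x$counts)
  invisible(x)
}

#' Tidy a reference-gene screen
#'
#' @param x A `refstab_screen`.
#' @param ... Unused.
#' @return The per-gene, per-contrast verdict tibble.
#' @method tidy refstab_screen
#' @export
tidy.refstab_screen <- function(x, ...) x$verdicts

#' One-row summary of a reference-gene screen
#'
#' @inheritParams tidy.refstab_screen
#' @return A tibble with stable / sensitive / unassigned gene counts.
#' @method glance refstab_screen
#' @export
glance.refstab_screen <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "overall", values_from = "n",
                     names_prefix = "n_")
}
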