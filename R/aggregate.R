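#' Per-probe condition means
#'
#' Averages each probe's replicate arrays within a gravity condition, on the
#' linear scale. These per-probe condition means are the replicates that
#' enter all cross-probe statistics: a gene represented by k probes
#' contributes k values per condition downstream.
#'
#' @param x A linear-scale expression table.
#' @param design A `refstab_design` covering the table's arrays.
#' @return A tibble with columns `gene_symbol`, `probe_id`, `campaign`,
#'   `condition`, `mean_fi`.
#' @export
condense_probe_values <- function(x, design) {
  if (fi_scale(x) != "linear") {
    stop("condense_probe_values expects a linear-scale table; ",
         "call to_linear() first", call. = FALSE)
  }
  missing_arrays <- setdiff(array_ids(x), design$array_id)
  if (length(missing_arrays) > 0L) {
    stop("arrays not in design: ", paste(missing_arrays, collapse = ", "),
         call. = FALSE)
  }
  present <- unique(design$condition[design$array_id %in% array_ids(x)])
  empty <- setdiff(design_conditions(design)[
    design_conditions(design) %in% design$condition], present)
  if (length(empty) > 0L) {
    stop("condition(s) with zero arrays: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(array_ids(x)),
                        names_to = "array_id", values_to = "fi") |>
    dplyr::inner_join(tibble::as_tibble(design), by = "array_id") |>
    dplyr::group_by(.data$gene_symbol, .data$probe_id, .data$campaign,
                    .data$condition) |>
    dplyr::summarise(mean_fi = mean(.data$fi), .groups = "drop")
}

#' Flag outlier probes within a gene
#'
#' With `rule = "mad"`, a probe is flagged when its condition mean lies
#' outside median +/- `k` * MAD of the gene's probes in any condition
#' (flags are unioned over conditions). With `rule = "none"` every probe is
#' retained; this is the default because the upstream convention for probe
#' outliers is not standardized.
#'
#' @param probe_means Output of [condense_probe_values()].
#' @param rule `"none"` or `"mad"`.
#' @param k MAD multiplier for the `"mad"` rule.
#' @return `probe_means` with a logical `retained` column.
#' @export
detect_probe_outliers <- function(probe_means, rule = c("none", "mad"),
                                  k = 3) {
  rule <- match.arg(rule)
  if (rule == "none") {
    return(dplyr::mutate(probe_means, retained = TRUE))
  }
  flagged <- probe_means |>
    dplyr::group_by(.data$gene_symbol, .data$campaign, .data$condition) |>
    dplyr::mutate(
      .med = stats::median(.data$mean_fi),
      .mad = stats::mad(.data$mean_fi),
      .out = .data$.mad > 0 & abs(.data$mean_fi - .data$.med) > k * .data$.mad
    ) |>
    dplyr::ungroup()
  flagged |>
    dplyr::group_by(.data$gene_symbol, .data$campaign, .data$probe_id) |>
    dplyr::mutate(retained = !any(.data$.out)) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(c(".med", ".mad", ".out")))
}

#' Aggregate probes to gene-level condition summaries
#'
#' For each gene with at least `min_probes` retained probes, computes the
#' mean and sample standard deviation (n - 1 divisor) of its per-probe
#' condition means, per condition. Genes below the probe minimum receive
#' status `too_few_probes` and produce no summaries; probe removal by the
#' outlier rule is recorded as status `outlier_trimmed`.
#'
#' @param probe_means Output of [condense_probe_values()].
#' @param min_probes Minimum retained probes for eligibility (default 3).
#' @param outlier_rule Passed to [detect_probe_outliers()].
#' @param k MAD multiplier for the `"mad"` outlier rule.
#' @return A list of class `refstab_aggregation` with elements
#'   `summaries` (tibble: `gene_symbol`, `campaign`, `condition`, `mean_fi`,
#'   `sd`, `n`) and `genes` (tibble: `gene_symbol`, `campaign`, `n_probes`,
#'   `n_retained`, `status`).
#' @export
aggregate_genes <- function(probe_means, min_probes = 3,
                            outlier_rule = c("none", "mad"), k = 3) {
  outlier_rule <- match.arg(outlier_rule)
  pm <- detect_probe_outliers(probe_means, rule = outlier_rule, k = k)
  genes <- pm |>
    dplyr::distinct(.data$gene_symbol, .data$campaign, .data$probe_id,
                    .data$retained) |>
    dplyr::group_by(.data$gene_symbol, .data$campaign) |>
    dplyr::summarise(n_probes = dplyr::n(),
                     n_retained = sum(.data$retained), .groups = "drop") |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_retained < min_probes ~ "too_few_probes",
      .data$n_retained < .data$n_probes ~ "outlier_trimmed",
      TRUE ~ "eligible"
    ))
  eligible <- genes$gene_symbol[genes$status != "too_few_probes"]
  summaries <- pm |>
    dplyr::filter(.data$retained, .data$gene_symbol %in% eligible) |>
    dplyr::group_by(.data$gene_symbol, .data$campaign, .data$condition) |>
    dplyr::summarise(sd = stats::sd(.data$mean_fi),
                     mean_fi = mean(.data$mean_fi),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::relocate(dplyr::all_of("sd"), .after = "mean_fi")
  structure(list(summaries = summaries, genes = genes),
            class = "refstab_aggregation")
}

#' @export
print.refstab_aggregation <- function(x, ...) {
  cat(sprintf("# Gene aggregation: %d genes (%d eligible/trimmed, %d too few probes)\n",
              nrow(x$genes),
              sum(x$genes$status != "too_few_probes"),
              sum(x$genes$status == "too_few_probes")))
  print(x$summaries)
  invisible(x)
}

#' Exclude genes with high inter-probe variance
#'
#' A gene whose probes disagree strongly (inter-probe coefficient of
#' variation above `threshold` percent in any condition) is flagged
#' `high_variance_excluded` and dropped from the summaries. An explicit
#' `exclude_genes` list is also honoured, for reproducing a published
#' exclusion exactly.
#'
#' @param aggregation A `refstab_aggregation` from [aggregate_genes()].
#' @param threshold Inter-probe CV threshold in percent (default 100).
#' @param exclude_genes Optional character vector of genes to exclude
#'   unconditionally.
#' @return The filtered `refstab_aggregation`.
#' @export
exclude_high_variance <- function(aggregation, threshold = 100,
                                  exclude_genes = NULL) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  s <- aggregation$summaries
  flagged <- s |>
    dplyr::group_by(.data$gene_symbol, .data$campaign) |>
    dplyr::summarise(
      hv = any(100 * .data$sd / .data$mean_fi > threshold),
      .groups = "drop") |>
    dplyr::filter(.data$hv)
  bad <- union(flagged$gene_symbol, exclude_genes)
  aggregation$genes <- aggregation$genes |>
    dplyr::mutate(status = ifelse(.data$gene_symbol %in% bad &
                                    .data$status != "too_few_probes",
                                  "high_variance_excluded", .data$status))
  aggregation$summaries <- dplyr::filter(s, !.data$gene_symbol %in% bad)
  aggregation
}
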