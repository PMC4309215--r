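#' Coefficient of variation in percent
#'
#' The primary stability screen: 100 times the sample standard deviation
#' divided by the mean. Computed here across a gene's per-condition mean
#' fluorescence values within a campaign, on the linear scale.
#'
#' @param values Numeric vector (at least 2 values, positive mean).
#' @return CV in percent.
#' @examples
#' cv_percent(c(4158.56, 3271.43, 2287.20, 2776.82)) # ~25.6
#' @export
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("cv_percent needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("cv_percent needs a positive mean",
                                    call. = FALSE)
  100 * stats::sd(values) / m
}

#' CV stability screen over gravity conditions
#'
#' Computes each gene's CV across its per-condition mean FI values within a
#' campaign and applies the acceptability threshold: below 25% for
#' homogeneous sample groups, below 50% for heterogeneous groups.
#' Comparisons are strict (a CV exactly at the threshold fails). Rapidly
#' changing gravity makes flight samples heterogeneous, hence the default.
#'
#' @param summaries Gene-level condition summaries (tibble with
#'   `gene_symbol`, `campaign`, `condition`, `mean_fi`), e.g. from
#'   [aggregate_genes()].
#' @param group_type `"heterogeneous"` (default) or `"homogeneous"`.
#' @param thresholds Named CV thresholds in percent.
#' @param per `"condition_means"` (default: CV across the campaign's
#'   condition means) or `"arrays"` (CV across per-array gene values; only
#'   available when `summaries` carries an `array_id`/`fi` long layout).
#' @return A tibble with `gene_symbol`, `campaign`, `cv_percent`,
#'   `group_type`, `threshold`, `verdict` (`"pass"`/`"fail"`).
#' @export
cv_screen <- function(summaries,
                      group_type = c("heterogeneous", "homogeneous"),
                      thresholds = c(homogeneous = 25, heterogeneous = 50),
                      per = c("condition_means", "arrays")) {
  group_type <- match.arg(group_type)
  per <- match.arg(per)
  stopifnot(thresholds[["homogeneous"]] > 0,
            thresholds[["homogeneous"]] < thresholds[["heterogeneous"]])
  value_col <- if (per == "arrays") "fi" else "mean_fi"
  if (!value_col %in% names(summaries)) {
    stop("summaries lack column '", value_col, "' for per = '", per, "'",
         call. = FALSE)
  }
  thr <- thresholds[[group_type]]
  summaries |>
    dplyr::group_by(.data$gene_symbol, .data$campaign) |>
    dplyr::summarise(cv_percent = cv_percent(.data[[value_col]]),
                     .groups = "drop") |>
    dplyr::mutate(group_type = group_type, threshold = thr,
                  verdict = ifelse(.data$cv_percent < thr, "pass", "fail"),
                  cv_basis = per)
}

#' Count genes per CV band
#'
#' Tallies, per campaign, how many genes fall strictly below the first
#' threshold, between the two, and at or above the second.
#'
#' @param cv_records Output of [cv_screen()].
#' @param thresholds Two increasing CV thresholds in percent.
#' @return A tibble with `campaign`, `n_total`, `n_below_25`,
#'   `n_25_to_50`, `n_above_50` (column names follow the thresholds given).
#' @export
threshold_counts <- function(cv_records, thresholds = c(25, 50)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  lo <- thresholds[1]; hi <- thresholds[2]
  out <- cv_records |>
    dplyr::group_by(.data$campaign) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      below_lo = sum(.data$cv_percent < lo),
      between = sum(.data$cv_percent >= lo & .data$cv_percent < hi),
      above_hi = sum(.data$cv_percent >= hi),
      .groups = "drop")
  names(out) <- c("campaign", "n_total",
                  paste0("n_below_", lo),
                  paste0("n_", lo, "_to_", hi),
                  paste0("n_above_", hi))
  out
}

#' Gene-by-condition mean FI matrix for heatmap-style export
#'
#' @param summaries Gene-level condition summaries.
#' @param campaign Campaign to extract.
#' @return A tibble, genes in rows, one column per condition.
#' @export
heatmap_matrix <- function(summaries, campaign) {
  summaries |>
    dplyr::filter(.data$campaign == !!campaign) |>
    dplyr::select(dplyr::all_of(c("gene_symbol", "condition", "mean_fi"))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_fi")
}
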