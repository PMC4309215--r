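#' Welch two-sample t-test from summary statistics
#'
#' Unpaired t-test with Welch correction, computed from group means, sample
#' standard deviations and sizes (the spreadsheet "tails 2, type 3"
#' convention). Degrees of freedom follow Welch-Satterthwaite and are left
#' unrounded. If both SDs are zero the test degenerates: p = 1 when the
#' means are equal, p = 0 otherwise.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (vectorized).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A tibble with columns `t`, `df`, `p`.
#' @examples
#' welch_t_test(3738.25, 143.90, 3, 4466.01, 257.59, 3) # p ~ 0.0215
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(n1, n2) < 2)) stop("welch_t_test needs n >= 2 per group",
                               call. = FALSE)
  if (any(c(sd1, sd2) < 0)) stop("standard deviations must be >= 0",
                                 call. = FALSE)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (mean1 == mean2)
    t[eq] <- 0; p[eq] <- 1
    t[degenerate & !eq] <- sign(mean1 - mean2)[degenerate & !eq] * Inf
    p[degenerate & !eq] <- 0
    df[degenerate] <- n1 + n2 - 2
  }
  tibble::tibble(t = t, df = df, p = p)
}

#' Pairwise Welch tests over campaign contrasts
#'
#' Runs [welch_t_test()] for every gene over each of its campaign's ordered
#' condition contrasts, using the gene's per-condition mean, SD and retained
#' probe count as the group summaries.
#'
#' @param summaries Gene-level condition summaries (`gene_symbol`,
#'   `campaign`, `condition`, `mean_fi`, `sd`, `n`).
#' @param contrasts Contrast table as from [flight_contrasts()] (columns
#'   `campaign`, `contrast`, `cond_a`, `cond_b`).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A tibble with one row per gene x contrast: `gene_symbol`,
#'   `campaign`, `contrast`, `cond_a`, `cond_b`, `t`, `df`, `p`,
#'   `significant`.
#' @export
test_contrasts <- function(summaries, contrasts = flight_contrasts(),
                           alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  contrasts <- dplyr::semi_join(contrasts, summaries, by = "campaign")
  a <- dplyr::inner_join(
    contrasts, summaries,
    by = c(campaign = "campaign", cond_a = "condition"),
    relationship = "many-to-many")
  ab <- dplyr::inner_join(
    a, summaries,
    by = c(campaign = "campaign", cond_b = "condition",
           gene_symbol = "gene_symbol"),
    suffix = c("_a", "_b"))
  res <- welch_t_test(ab$mean_fi_a, ab$sd_a, ab$n_a,
                      ab$mean_fi_b, ab$sd_b, ab$n_b)
  ab |>
    dplyr::select(dplyr::all_of(c("gene_symbol", "campaign", "contrast",
                                  "cond_a", "cond_b"))) |>
    dplyr::bind_cols(res) |>
    dplyr::mutate(significant = .data$p < alpha) |>
    dplyr::arrange(.data$gene_symbol, .data$campaign)
}

#' One-way ANOVA across conditions with Benjamini-Hochberg correction
#'
#' Classical (equal-variance) one-way ANOVA per gene over all conditions of
#' a campaign, using per-probe condition means as replicates, followed by
#' BH step-up adjustment across genes. This gives an overall per-gene
#' changed/unchanged call; the pairwise verdict matrix is built from the
#' unadjusted contrast tests, so this pass is reported alongside rather than
#' gating it.
#'
#' @param probe_means Output of [condense_probe_values()].
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @return A tibble with `gene_symbol`, `campaign`, `f`, `p`, `q`,
#'   `significant`, `degenerate`.
#' @export
anova_fdr <- function(probe_means, alpha = 0.05) {
  per_gene <- probe_means |>
    dplyr::group_by(.data$gene_symbol, .data$campaign) |>
    dplyr::group_modify(function(d, key) {
      counts <- table(d$condition)
      if (length(counts) < 2L || any(counts < 2L)) {
        stop("gene '", key$gene_symbol,
             "': ANOVA needs >= 2 conditions with >= 2 replicates each",
             call. = FALSE)
      }
      if (stats::var(d$mean_fi) == 0) {
        return(tibble::tibble(f = NA_real_, p = 1, degenerate = TRUE))
      }
      within_var <- tapply(d$mean_fi, d$condition, stats::var)
      if (all(within_var == 0)) {
        # groups internally constant but shifted: infinitely strong signal
        return(tibble::tibble(f = Inf, p = 0, degenerate = TRUE))
      }
      fit <- stats::oneway.test(mean_fi ~ condition, data = d,
                                var.equal = TRUE)
      tibble::tibble(f = unname(fit$statistic), p = fit$p.value,
                     degenerate = FALSE)
    }) |>
    dplyr::ungroup()
  per_gene |>
    dplyr::group_by(.data$campaign) |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q < alpha) |>
    dplyr::relocate(dplyr::all_of("degenerate"), .after = "significant")
}

#' Classify genes as g-stable or g-sensitive
#'
#' Turns contrast test results into the verdict vector used in the overview
#' matrix: `-` where p < alpha (g-sensitive in that contrast), `+`
#' otherwise. A gene is overall `stable` only if every tested contrast is
#' `+`; genes that were ineligible upstream (too few probes, high
#' inter-probe variance) are `unassigned`.
#'
#' @param tests Output of [test_contrasts()].
#' @param alpha Significance level for a `-` call (default 0.05).
#' @param gene_status Optional tibble (`gene_symbol`, `status`) from
#'   [aggregate_genes()]`$genes`; non-eligible genes become `unassigned`.
#' @return A tibble with `gene_symbol`, `campaign`, `contrast`, `symbol`
#'   plus an `overall` column repeated per gene.
#' @export
classify_genes <- function(tests, alpha = 0.05, gene_status = NULL) {
  expected <- tests |>
    dplyr::distinct(.data$campaign, .data$contrast) |>
    dplyr::count(.data$campaign, name = "n_expected")
  got <- tests |>
    dplyr::count(.data$gene_symbol, .data$campaign, name = "n_got") |>
    dplyr::inner_join(expected, by = "campaign")
  if (any(got$n_got != got$n_expected)) {
    bad <- got$gene_symbol[got$n_got != got$n_expected]
    stop("missing contrast result(s) for: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  verdicts <- tests |>
    dplyr::mutate(symbol = ifelse(.data$p < alpha, "-", "+")) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::mutate(overall = ifelse(all(.data$symbol == "+"),
                                   "stable", "sensitive")) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("gene_symbol", "campaign", "contrast",
                                  "symbol", "p", "overall")))
  if (!is.null(gene_status)) {
    unassigned <- unique(gene_status$gene_symbol[
      !gene_status$status %in% c("eligible", "outlier_trimmed")])
    extra <- tibble::tibble(gene_symbol = setdiff(unassigned,
                                                  verdicts$gene_symbol),
                            campaign = NA_character_,
                            contrast = NA_character_, symbol = NA_character_,
                            p = NA_real_, overall = "unassigned")
    verdicts <- verdicts |>
      dplyr::mutate(overall = ifelse(.data$gene_symbol %in% unassigned,
                                     "unassigned", .data$overall)) |>
      dplyr::bind_rows(extra)
  }
  verdicts
}

#' Verdict overview matrix and counts
#'
#' Reshapes per-contrast verdicts into the gene x contrast `+`/`-` overview
#' (one column per contrast, both campaigns side by side) and tallies
#' stable / sensitive / unassigned genes.
#'
#' @param verdicts Output of [classify_genes()].
#' @return A list with `matrix` (wide tibble) and `counts` (tibble with
#'   `overall`, `n`).
#' @export
verdict_matrix <- function(verdicts) {
  overall <- dplyr::distinct(verdicts, .data$gene_symbol, .data$overall)
  wide <- verdicts |>
    dplyr::filter(!is.na(.data$contrast)) |>
    dplyr::select(dplyr::all_of(c("gene_symbol", "campaign", "contrast",
                                  "symbol"))) |>
    dplyr::mutate(col = paste0(.data$campaign, ": ", .data$contrast)) |>
    dplyr::select(-dplyr::all_of(c("campaign", "contrast"))) |>
    tidyr::pivot_wider(names_from = "col", values_from = "symbol") |>
    dplyr::right_join(overall, by = "gene_symbol") |>
    dplyr::arrange(.data$overall, .data$gene_symbol)
  counts <- overall |>
    dplyr::count(.data$overall, name = "n") |>
    tidyr::complete(overall = c("stable", "sensitive", "unassigned"),
                    fill = list(n = 0L))
  list(matrix = wide, counts = counts)
}
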