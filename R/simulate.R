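#' Specify synthetic genes
#'
#' Each gene is described by a baseline linear fluorescence, a probe count,
#' a per-probe affinity spread (log2 units, constant per probe across all
#' arrays), per-condition multiplicative fold changes, and a per-measurement
#' noise SD (log2 units). The generative model for probe p of gene g on an
#' array in condition c is
#' `FI = baseline * 2^(probe_effect_p + log2(fold_change_gc) + eps)`,
#' `eps ~ Normal(0, noise_sd_log2)` — i.e. lognormal noise, matching the
#' log-scale statistics the pipeline computes.
#'
#' @param gene_symbol Character vector of gene names.
#' @param baseline_fi Positive baseline linear FI per gene.
#' @param n_probes Integer probe count per gene.
#' @param probe_affinity_sd SD (log2) of fixed per-probe affinity effects.
#' @param noise_sd_log2 SD (log2) of per-measurement noise.
#' @param fold_changes List of named numeric vectors (condition ->
#'   multiplicative effect); `NULL` entries mean all conditions at 1.
#' @param truth_label Planted label: `stable`, `sensitive`, `high_variance`
#'   or `too_few_probes`.
#' @return A tibble of gene specifications (`fold_changes` is a
#'   list-column).
#' @export
gene_specs <- function(gene_symbol, baseline_fi, n_probes,
                       probe_affinity_sd = 0.25, noise_sd_log2 = 0.15,
                       fold_changes = NULL, truth_label = "stable") {
  n <- length(gene_symbol)
  if (is.null(fold_changes)) fold_changes <- vector("list", n)
  specs <- tibble::tibble(
    gene_symbol = gene_symbol,
    baseline_fi = rep_len(baseline_fi, n),
    n_probes = as.integer(rep_len(n_probes, n)),
    probe_affinity_sd = rep_len(probe_affinity_sd, n),
    noise_sd_log2 = rep_len(noise_sd_log2, n),
    fold_changes = fold_changes,
    truth_label = rep_len(truth_label, n)
  )
  if (any(specs$baseline_fi <= 0)) stop("baseline_fi must be positive",
                                        call. = FALSE)
  if (any(specs$probe_affinity_sd < 0) || any(specs$noise_sd_log2 < 0)) {
    stop("spread parameters must be non-negative", call. = FALSE)
  }
  bad_fc <- vapply(specs$fold_changes,
                   function(fc) !is.null(fc) && any(fc <= 0), logical(1))
  if (any(bad_fc)) stop("fold changes must be positive", call. = FALSE)
  specs
}

#' Simulate a probe-level flight expression study
#'
#' Draws a full probe x array linear-scale expression table under the
#' lognormal generative model of [gene_specs()], for a given study design.
#' Probe affinity effects are drawn once per probe; measurement noise is
#' drawn per probe x array. The same seed reproduces the study exactly.
#'
#' @param design A `refstab_design` (e.g. [flight_design()]).
#' @param specs Gene specifications from [gene_specs()].
#' @param seed Integer RNG seed (R's default Mersenne-Twister stream).
#' @return A list of class `simulated_study` with `expr` (linear expression
#'   table), `design`, `truth` (the specs), and `seed`.
#' @export
simulate_study <- function(design, specs, seed = 1L) {
  stopifnot(inherits(design, "refstab_design"))
  conditions <- design$condition
  n_arrays <- nrow(design)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  rows <- withr_seed({
    purrr::pmap_dfr(specs, function(gene_symbol, baseline_fi, n_probes,
                                    probe_affinity_sd, noise_sd_log2,
                                    fold_changes, truth_label) {
      pe <- stats::rnorm(n_probes, 0, probe_affinity_sd)
      fc_log2 <- rep(0, n_arrays)
      if (!is.null(fold_changes)) {
        hit <- conditions %in% names(fold_changes)
        fc_log2[hit] <- log2(fold_changes[conditions[hit]])
      }
      eps <- matrix(stats::rnorm(n_probes * n_arrays, 0, noise_sd_log2),
                    n_probes, n_arrays)
      vals <- baseline_fi *
        2^(outer(pe, fc_log2, `+`) + eps)
      colnames(vals) <- design$array_id
      dplyr::bind_cols(
        tibble::tibble(
          probe_id = sprintf("%s_probe%02d", gene_symbol,
                             seq_len(n_probes)),
          gene_symbol = gene_symbol),
        tibble::as_tibble(vals))
    })
  })
  structure(list(expr = expression_table(rows, scale = "linear"),
                 design = design, truth = specs, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("# Simulated study: %d genes, %d probes, %d arrays (seed %d)\n",
              nrow(x$truth), nrow(x$expr), nrow(x$design), x$seed))
  invisible(x)
}

#' Flight-study-mimic gene specification preset
#'
#' A 99-gene panel shaped like the flight screening study: 20
#' reference-gene-like candidates, 47 ABC-transporter-like genes and 32
#' tRNA-synthetase-like genes, with planted low-probe genes (2 probes),
#' high-inter-probe-variance genes, g-sensitive genes (20-40% fold changes
#' in the altered-gravity conditions) and stable genes. Baselines span the
#' observed linear dynamic range (~2 to ~25,000 FI). The planted partition
#' is 8 stable, 9 sensitive, 82 unassignable (low probe count or high
#' variance).
#'
#' @param campaign Campaign whose conditions the fold changes target.
#' @param fold_change Multiplicative effect for sensitive genes
#'   (default 0.7, a 30% drop).
#' @param seed Seed for drawing baselines.
#' @return A gene-spec tibble, see [gene_specs()].
#' @export
paper_mimic_specs <- function(campaign = c("PFC", "TEXUS"),
                              fold_change = 0.7, seed = 1L) {
  campaign <- match.arg(campaign)
  hyper <- if (campaign == "PFC") "1.8g" else "BL"
  micro <- "ug"
  mk_names <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  plan <- rbind(
    data.frame(prefix = "REF", stable = 5, sensitive = 2, high_var = 2,
               low_probe = 11),
    data.frame(prefix = "ABC", stable = 3, sensitive = 6, high_var = 8,
               low_probe = 30),
    data.frame(prefix = "TRS", stable = 0, sensitive = 1, high_var = 3,
               low_probe = 28)
  )
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  specs <- purrr::pmap_dfr(plan, function(prefix, stable, sensitive,
                                          high_var, low_probe) {
    n <- stable + sensitive + high_var + low_probe
    label <- rep(c("stable", "sensitive", "high_variance", "too_few_probes"),
                 c(stable, sensitive, high_var, low_probe))
    baseline <- 2^stats::runif(n, 1, log2(25000))
    n_probes <- ifelse(label == "too_few_probes", 2L,
                       sample(3:6, n, replace = TRUE))
    affinity <- ifelse(label == "high_variance", 2, 0.25)
    fc <- purrr::map(label, function(l) {
      if (l == "sensitive") {
        stats::setNames(c(fold_change, fold_change), c(hyper, micro))
      } else NULL
    })
    gene_specs(mk_names(prefix, n), baseline, n_probes,
               probe_affinity_sd = affinity, noise_sd_log2 = 0.15,
               fold_changes = fc, truth_label = label)
  })
  specs
}

#' Compare pipeline verdicts with planted truth
#'
#' Cross-tabulates the generator's planted labels against the overall
#' verdicts of a pipeline run on the simulated study.
#'
#' @param study A `simulated_study`.
#' @param verdicts Output of [classify_genes()] on that study's pipeline
#'   results.
#' @return A list with `confusion` (tibble `truth_label`, `overall`, `n`)
#'   and `by_gene` (one row per gene).
#' @export
recovery_report <- function(study, verdicts) {
  by_gene <- study$truth |>
    dplyr::select(dplyr::all_of(c("gene_symbol", "truth_label"))) |>
    dplyr::left_join(dplyr::distinct(verdicts, .data$gene_symbol,
                                     .data$overall),
                     by = "gene_symbol") |>
    dplyr::mutate(overall = ifelse(is.na(.data$overall), "unassigned",
                                   .data$overall))
  confusion <- dplyr::count(by_gene, .data$truth_label, .data$overall,
                            name = "n")
  list(confusion = confusion, by_gene = by_gene)
}
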