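#' Candidate gene x sample log2 matrix
#'
#' Builds the input for the stability-ranking algorithms from a linear-scale
#' expression table: per array, each candidate gene's value is the log2 of
#' the mean linear FI over its probes.
#'
#' @param x A linear-scale expression table.
#' @param genes Optional candidate gene subset (default: all genes).
#' @return A numeric matrix, genes in rows, arrays in columns, log2 scale.
#' @export
candidate_matrix <- function(x, genes = NULL) {
  if (fi_scale(x) != "linear") x <- to_linear(x)
  tb <- tibble::as_tibble(x)
  if (!is.null(genes)) tb <- dplyr::filter(tb, .data$gene_symbol %in% genes)
  m <- tb |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(array_ids(x)), mean),
                     .groups = "drop")
  out <- log2(as.matrix(m[-1]))
  rownames(out) <- m$gene_symbol
  out
}

check_candidate <- function(mat, min_genes = 2L) {
  if (!is.matrix(mat) || is.null(rownames(mat))) {
    stop("candidate matrix must be a matrix with gene rownames",
         call. = FALSE)
  }
  if (nrow(mat) < min_genes) {
    stop("need at least ", min_genes, " candidate genes", call. = FALSE)
  }
  if (ncol(mat) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (any(!is.finite(mat))) stop("candidate matrix has non-finite values",
                                 call. = FALSE)
  invisible(mat)
}

# Mean, over all other genes, of the SD across samples of the pairwise
# log2 ratio. This single formula is both the geNorm M value and the
# comparative delta-Ct stability score.
pairwise_ratio_score <- function(mat) {
  g <- nrow(mat)
  sds <- vapply(seq_len(g), function(j) {
    mean(vapply(seq_len(g)[-j], function(k) {
      stats::sd(mat[j, ] - mat[k, ])
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(sds, rownames(mat))
}

#' geNorm expression stability
#'
#' Computes each candidate's M value (mean SD of its pairwise log2 ratios
#' with every other candidate), then iteratively removes the least stable
#' gene (highest M; ties removed in reverse lexicographic order) and
#' recomputes until two genes remain. Also returns the pairwise variation
#' V(n/n+1): the SD across samples of the log2 ratio of normalization
#' factors built from the n versus n+1 most stable genes, used to judge how
#' many reference genes suffice.
#'
#' @param mat Candidate matrix (genes x samples, log2), see
#'   [candidate_matrix()].
#' @return A list with `m` (initial M per gene), `ranking` (most to least
#'   stable; the final two genes are ordered by initial M), `rank` (named
#'   integer vector), and `pairwise_variation` (tibble `n`, `v`).
#' @export
genorm <- function(mat) {
  check_candidate(mat, min_genes = 3L)
  m0 <- pairwise_ratio_score(mat)
  remaining <- rownames(mat)
  removed <- character(0)
  while (length(remaining) > 2L) {
    m <- pairwise_ratio_score(mat[remaining, , drop = FALSE])
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]   # tie: drop lexicographically larger
    removed <- c(worst, removed)
    remaining <- setdiff(remaining, worst)
  }
  final_two <- remaining[order(m0[remaining], remaining)]
  ranking <- c(final_two, removed)
  v <- genorm_pairwise_variation(mat, ranking)
  list(m = m0, ranking = ranking,
       rank = stats::setNames(seq_along(ranking), ranking),
       pairwise_variation = v)
}

genorm_pairwise_variation <- function(mat, ranking) {
  g <- length(ranking)
  if (g < 3L) return(tibble::tibble(n = integer(0), v = numeric(0)))
  # log2 NF_k per sample = mean log2 value of the k most stable genes
  nf <- vapply(seq_len(g), function(k) {
    colMeans(mat[ranking[seq_len(k)], , drop = FALSE])
  }, numeric(ncol(mat)))
  tibble::tibble(
    n = 2:(g - 1),
    v = vapply(2:(g - 1), function(k) stats::sd(nf[, k] - nf[, k + 1]),
               numeric(1))
  )
}

#' Comparative delta-Ct stability score
#'
#' Mean, over all other candidates, of the SD across samples of the pairwise
#' log2 expression difference. On log2 input this is by construction
#' identical to the initial (pre-exclusion) geNorm M value; the method is
#' kept as a separately callable scorer because its ranking enters the
#' composite independently.
#'
#' @inheritParams genorm
#' @return Named numeric vector of scores (lower = more stable).
#' @export
delta_ct_score <- function(mat) {
  check_candidate(mat, min_genes = 3L)
  pairwise_ratio_score(mat)
}

#' NormFinder stability estimate
#'
#' Model-based decomposition of each candidate's variation on the
#' gene-centered, sample-centered log2 matrix. With group labels, the
#' per-group intergroup bias d (the gene-by-group interaction term) and the
#' intragroup SD sigma are estimated per gene and combined as
#' `rho = mean over groups of (|d| + sigma / sqrt(n_group))`, so a gene is
#' penalized both for shifting between groups and for scattering within
#' them. Without groups, rho is the SD across samples of the
#' sample-centered values.
#'
#' @inheritParams genorm
#' @param groups Optional factor/character vector of sample group labels
#'   (length `ncol(mat)`); every group needs at least 2 samples.
#' @return Named numeric vector `rho` (lower = more stable).
#' @export
normfinder <- function(mat, groups = NULL) {
  check_candidate(mat)
  z <- sweep(mat, 2L, colMeans(mat))      # remove per-sample (array) effects
  z <- sweep(z, 1L, rowMeans(z))          # remove per-gene overall level
  if (is.null(groups)) {
    rho <- apply(z, 1L, stats::sd)
    return(rho)
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 samples", call. = FALSE)
  }
  per_group <- vapply(names(sizes), function(g) {
    zg <- z[, groups == g, drop = FALSE]
    d <- rowMeans(zg)                     # intergroup bias per gene
    sigma <- apply(sweep(zg, 1L, d), 1L, stats::sd)
    abs(d) + sigma / sqrt(ncol(zg))
  }, numeric(nrow(mat)))
  rowMeans(per_group)
}

#' BestKeeper descriptive stability
#'
#' Per candidate: SD and CV of its log2 values across samples, and the
#' Pearson correlation with the BestKeeper index (the per-sample geometric
#' mean over all candidates, i.e. the per-sample mean on the log2 scale).
#' BestKeeper was formulated for qPCR crossing-point values; applying it to
#' log2 fluorescence is a documented adaptation. A zero-variance gene or
#' index yields `NA` correlation, flagged rather than erroring.
#'
#' @inheritParams genorm
#' @return A tibble with `gene_symbol`, `sd_log2`, `cv_log2`, `pearson_r`.
#' @export
bestkeeper <- function(mat) {
  check_candidate(mat)
  idx <- colMeans(mat)
  sd_log2 <- apply(mat, 1L, stats::sd)
  r <- if (stats::sd(idx) == 0) {
    rep(NA_real_, nrow(mat))
  } else {
    apply(mat, 1L, function(v) {
      if (stats::sd(v) == 0) NA_real_ else stats::cor(v, idx)
    })
  }
  tibble::tibble(gene_symbol = rownames(mat), sd_log2 = unname(sd_log2),
                 cv_log2 = unname(100 * sd_log2 / rowMeans(mat)),
                 pearson_r = unname(r))
}

rank_with_ties <- function(score, genes) {
  # lower score = better; ties broken lexicographically by gene symbol
  stats::setNames(order(order(score, genes)), genes)
}

#' Rank candidate reference genes by four stability algorithms
#'
#' Runs geNorm, NormFinder, BestKeeper (ranked by SD of log2 values) and the
#' comparative delta-Ct method on a candidate matrix, ranks genes per method
#' (rank 1 = most stable; ties broken lexicographically) and combines them
#' into an overall ordering by the geometric mean of per-method ranks, the
#' convention of the RefFinder-style integration of the four algorithms.
#'
#' @inheritParams normfinder
#' @param methods Subset of `c("genorm", "normfinder", "bestkeeper",
#'   "delta_ct")`.
#' @return An object of class `stability_ranking`; see [tidy()] /
#'   [glance()] methods. Contains `scores` (per-gene tibble with per-method
#'   scores, ranks, `composite` and `overall_rank`) and, when geNorm ran,
#'   `pairwise_variation`.
#' @export
rank_stability <- function(mat, groups = NULL,
                           methods = c("genorm", "normfinder",
                                       "bestkeeper", "delta_ct")) {
  methods <- match.arg(methods, several.ok = TRUE)
  check_candidate(mat, min_genes = if (any(c("genorm", "delta_ct") %in%
                                             methods)) 3L else 2L)
  genes <- rownames(mat)
  scores <- tibble::tibble(gene_symbol = genes)
  ranks <- list()
  pv <- NULL
  if ("genorm" %in% methods) {
    gn <- genorm(mat)
    scores$genorm_m <- unname(gn$m[genes])
    ranks$genorm <- unname(gn$rank[genes])
    pv <- gn$pairwise_variation
  }
  if ("normfinder" %in% methods) {
    rho <- normfinder(mat, groups)
    scores$normfinder_rho <- unname(rho[genes])
    ranks$normfinder <- unname(rank_with_ties(rho[genes], genes))
  }
  if ("bestkeeper" %in% methods) {
    bk <- bestkeeper(mat)
    scores$bestkeeper_sd <- bk$sd_log2
    scores$bestkeeper_cv <- bk$cv_log2
    scores$bestkeeper_r <- bk$pearson_r
    ranks$bestkeeper <- unname(rank_with_ties(bk$sd_log2, genes))
  }
  if ("delta_ct" %in% methods) {
    dc <- delta_ct_score(mat)
    scores$delta_ct <- unname(dc[genes])
    ranks$delta_ct <- unname(rank_with_ties(dc[genes], genes))
  }
  rk <- tibble::as_tibble(ranks)
  names(rk) <- paste0("rank_", names(rk))
  scores <- dplyr::bind_cols(scores, rk)
  scores$composite <- exp(rowMeans(log(as.matrix(rk))))
  scores$overall_rank <- unname(rank_with_ties(scores$composite, genes))
  scores <- dplyr::arrange(scores, .data$overall_rank)
  structure(list(scores = scores, pairwise_variation = pv,
                 methods = methods, n_samples = ncol(mat),
                 groups = groups),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat(sprintf("# Reference-gene stability ranking (%s; %d genes, %d samples)\n",
              paste(x$methods, collapse = ", "), nrow(x$scores), x$n_samples))
  print(x$scores)
  invisible(x)
}

#' Tidy a stability ranking
#'
#' @param x A `stability_ranking` from [rank_stability()].
#' @param ... Unused.
#' @return The per-gene score/rank tibble, most stable gene first.
#' @method tidy stability_ranking
#' @export
tidy.stability_ranking <- function(x, ...) x$scores

#' One-row summary of a stability ranking
#'
#' @inheritParams tidy.stability_ranking
#' @return A tibble with `n_genes`, `n_samples`, `n_methods`, `best_gene`,
#'   and `v_2_3` (geNorm pairwise variation V(2/3), `NA` if geNorm did not
#'   run).
#' @method glance stability_ranking
#' @export
glance.stability_ranking <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$scores),
    n_samples = x$n_samples,
    n_methods = length(x$methods),
    best_gene = x$scores$gene_symbol[1L],
    v_2_3 = if (!is.null(x$pairwise_variation) &&
                nrow(x$pairwise_variation) > 0)
      x$pairwise_variation$v[x$pairwise_variation$n == 2L] else NA_real_
  )
}
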