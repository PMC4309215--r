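# Small builders shared across test files.

toy_expr <- function(values, scale = "linear", genes = NULL) {
  # values: matrix probes x arrays
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  np <- nrow(values)
  if (is.null(genes)) genes <- rep("G1", np)
  tb <- tibble::tibble(probe_id = sprintf("P%02d", seq_len(np)),
                       gene_symbol = genes)
  cols <- sprintf("A%02d", seq_len(ncol(values)))
  tb[cols] <- tibble::as_tibble(`colnames<-`(values, cols))
  expression_table(tb, scale = scale)
}

toy_design <- function(conditions_per_array, campaign = "PFC",
                       conditions = NULL, contrasts = NULL) {
  n <- length(conditions_per_array)
  study_design(
    tibble::tibble(array_id = sprintf("A%02d", seq_len(n)),
                   campaign = campaign,
                   condition = conditions_per_array),
    conditions = conditions, contrasts = contrasts)
}

# Brute-force type-7 percentile: sort and linearly interpolate ranks.
manual_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
}

# Step-up false-discovery-rate adjustment written out longhand.
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Random candidate log2 matrix.
random_candidate <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 10, 1), n_genes, n_samples)
  rownames(m) <- sprintf("G%02d", seq_len(n_genes))
  colnames(m) <- sprintf("S%02d", seq_len(n_samples))
  m
}
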