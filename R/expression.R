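#' Construct an expression table
#'
#' An expression table holds probe-level fluorescence intensities (FI): one
#' row per probe, identified by `probe_id` (accession) and annotated with a
#' `gene_symbol`, followed by one numeric column per array. The measurement
#' scale (`"log2"` or `"linear"`) travels with the object so that scale
#' transforms are explicit and can never be applied twice silently.
#'
#' @param x A data frame with columns `probe_id`, `gene_symbol`, then one
#'   numeric column per array.
#' @param scale Measurement scale of the values, `"log2"` or `"linear"`.
#' @return A tibble of class `refstab_expr` with attribute `fi_scale`.
#' @examples
#' expression_table(
#'   tibble::tibble(probe_id = c("P1", "P2"), gene_symbol = "G1",
#'                  A1 = c(10, 11), A2 = c(10.5, 11.2)),
#'   scale = "log2"
#' )
#' @export
expression_table <- function(x, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0L) {
    stop("expression table is empty", call. = FALSE)
  }
  required <- c("probe_id", "gene_symbol")
  if (!all(required %in% names(x))) {
    stop("expression table needs columns 'probe_id' and 'gene_symbol'",
         call. = FALSE)
  }
  arrays <- setdiff(names(x), required)
  if (length(arrays) == 0L) {
    stop("expression table has no array columns", call. = FALSE)
  }
  dup <- unique(x$probe_id[duplicated(x$probe_id)])
  if (length(dup) > 0L) {
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (a in arrays) {
    if (!is.numeric(x[[a]])) {
      stop("non-numeric values in array column '", a, "'", call. = FALSE)
    }
  }
  vals <- as.matrix(x[arrays])
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop("non-finite value at probe '", x$probe_id[bad[1L]], "', array '",
         arrays[bad[2L]], "'", call. = FALSE)
  }
  if (scale == "linear" && any(vals <= 0)) {
    stop("linear-scale values must be positive", call. = FALSE)
  }
  structure(x, class = c("refstab_expr", class(tibble::tibble())),
            fi_scale = scale)
}

#' Measurement scale of an expression table
#' @param x An expression table created by [expression_table()].
#' @return `"log2"` or `"linear"`.
#' @export
fi_scale <- function(x) {
  s <- attr(x, "fi_scale")
  if (is.null(s)) stop("not an expression table (no scale attribute)",
                       call. = FALSE)
  s
}

#' Array identifiers of an expression table
#' @inheritParams fi_scale
#' @return Character vector of array column names.
#' @export
array_ids <- function(x) setdiff(names(x), c("probe_id", "gene_symbol"))

#' @export
print.refstab_expr <- function(x, ...) {
  cat(sprintf("# Expression table: %d probes x %d arrays (%s scale)\n",
              nrow(x), length(array_ids(x)), fi_scale(x)))
  NextMethod()
}

expr_values <- function(x) {
  m <- as.matrix(x[array_ids(x)])
  rownames(m) <- x$probe_id
  m
}

replace_values <- function(x, m, scale) {
  out <- x
  out[array_ids(x)] <- tibble::as_tibble(m)
  attr(out, "fi_scale") <- scale
  out
}

#' Read / write delimited expression tables
#'
#' Tab-separated text with a header row; the first two columns are
#' `probe_id` and `gene_symbol`, remaining columns are arrays. Values use
#' `.` as decimal separator.
#'
#' @param path File to read or write.
#' @param scale Declared scale of the stored values.
#' @return `read_expression_table()` returns an expression table;
#'   `write_expression_table()` returns `path` invisibly.
#' @export
read_expression_table <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0L) stop("expression table is empty", call. = FALSE)
  for (a in setdiff(names(raw), c("probe_id", "gene_symbol"))) {
    v <- suppressWarnings(as.numeric(raw[[a]]))
    if (any(is.na(v) & !is.na(raw[[a]]))) {
      row <- which(is.na(v) & !is.na(raw[[a]]))[1L]
      stop("non-numeric cell at row ", row, ", column '", a, "'",
           call. = FALSE)
    }
    raw[[a]] <- v
  }
  expression_table(raw, scale = scale)
}

#' @param x An expression table.
#' @rdname read_expression_table
#' @export
write_expression_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Transform an expression table between log2 and linear scale
#'
#' Microarray pipelines report log2 fluorescence; per-gene summary
#' statistics here are computed on the linear scale, so values are
#' back-transformed first. Transforming an already-linear table is an error
#' rather than a silent no-op or double transform.
#'
#' @param x An expression table.
#' @return The transformed expression table.
#' @export
to_linear <- function(x) {
  if (fi_scale(x) != "log2") {
    stop("expression table is already on the linear scale", call. = FALSE)
  }
  replace_values(x, 2^expr_values(x), "linear")
}

#' @rdname to_linear
#' @export
to_log2 <- function(x) {
  if (fi_scale(x) != "linear") {
    stop("expression table is already on the log2 scale", call. = FALSE)
  }
  replace_values(x, log2(expr_values(x)), "log2")
}

#' Quantile-normalize an expression table
#'
#' Forces every array to share the same value distribution: the across-array
#' mean of sorted value vectors. Within-array rank order is preserved. Tied
#' values within an array receive the mean of the reference values at the
#' ranks the tie group occupies, so the map from value to normalized value
#' is well defined.
#'
#' @param x An expression table with at least two arrays and no missing
#'   values.
#' @return The normalized expression table, same scale flag as the input.
#' @export
quantile_normalize <- function(x) {
  m <- expr_values(x)
  if (ncol(m) < 2L) {
    stop("quantile normalization needs at least 2 arrays", call. = FALSE)
  }
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) {
    nv <- numeric(length(col))
    nv[order(col)] <- ref
    # tie groups share the mean reference value of their occupied ranks
    stats::ave(nv, factor(col), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  replace_values(x, out, fi_scale(x))
}

#' Five-number boxplot summary with 9th/91st percentile whiskers
#'
#' The QC display used for flight microarray sets draws, per array, the
#' median, the quartiles, and whiskers at the 9th and 91st percentile.
#' Percentiles use linear interpolation between closest ranks
#' (`stats::quantile()` type 7).
#'
#' @param x A numeric vector of array values, or an expression table (one
#'   summary row per array).
#' @return A tibble with columns `p09`, `p25`, `p50`, `p75`, `p91` (and
#'   `array_id` when `x` is an expression table).
#' @export
boxplot_summary <- function(x) {
  if (inherits(x, "refstab_expr")) {
    m <- expr_values(x)
    out <- purrr::map_dfr(array_ids(x), function(a) {
      dplyr::bind_cols(tibble::tibble(array_id = a),
                       boxplot_summary(m[, a]))
    })
    return(out)
  }
  x <- as.numeric(x)
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("boxplot_summary needs >= 2 finite values", call. = FALSE)
  }
  q <- stats::quantile(x, probs = c(0.09, 0.25, 0.5, 0.75, 0.91),
                       type = 7, names = FALSE)
  tibble::tibble(p09 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p91 = q[5])
}
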