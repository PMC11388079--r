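#' Normalize counts to log counts-per-10K
#'
#' The single preprocessing convention used by every expression-based stage:
#' each cell's counts are scaled to sum to 10,000 and transformed with
#' `log1p` (natural log). Cells with zero total counts are kept as all-zero
#' rows (so per-sample denominators are unchanged) and reported via a
#' message; downstream scoring excludes them where a denominator matters.
#'
#' @param ds A [cell_dataset].
#' @param scale_factor Library-size target, default 1e4.
#' @return An object of class `normalized_matrix`: list with `values` (dense
#'   cells x genes matrix of log-scale expression), `norm_method` and
#'   `scale_factor`.
#' @export
normalize_log_cp10k <- function(ds, scale_factor = 1e4) {
  counts <- as.matrix(ds$counts)
  totals <- rowSums(counts)
  if (!any(totals > 0)) stop("all cells have zero total counts")
  zero_cells <- sum(totals == 0)
  if (zero_cells > 0) {
    message(sprintf("%d cell(s) with zero total counts kept as all-zero rows", zero_cells))
  }
  scale <- ifelse(totals > 0, scale_factor / totals, 0)
  values <- log1p(counts * scale)
  structure(
    list(values = values, norm_method = "log_cp10k", scale_factor = scale_factor),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "<normalized_matrix> %d cells x %d genes (%s, scale %g)\n",
    nrow(x$values), ncol(x$values), x$norm_method, x$scale_factor
  ))
  invisible(x)
}

# Top-n most variable genes of a cells/pseudobulks x genes value matrix.
variable_genes <- function(values, n = 2000) {
  v <- apply(values, 2, stats::var)
  names(utils::head(sort(v, decreasing = TRUE), n))
}
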