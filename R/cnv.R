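#' Infer reference-centred, window-smoothed CNV profiles
#'
#' Expression-based copy-number surrogate: genes are put in genome order
#' (chromosome, then start), each gene is centred by subtracting its mean
#' over the reference cells, centred values are clipped to
#' `clip` x (reference per-gene standard deviation, floored at `sd_floor`),
#' a moving average over `window` genes is taken within each chromosome
#' (window shrinking symmetrically at chromosome edges), each cell is
#' median-centred across genes (removing the genome-wide library/composition
#' offset that would otherwise masquerade as a uniform gain or loss), and
#' the result is re-centred so the reference-cell mean per gene is exactly
#' zero.
#'
#' @param norm A [normalize_log_cp10k] result.
#' @param gene_pos Gene-position table (`gene_id`, `chrom`, `start`, `end`).
#' @param reference_mask Logical or integer index of reference cells
#'   (normal epithelial plus endothelial cells).
#' @param window Genes per moving window, default 101 (odd recommended).
#' @param clip Symmetric clip bound in reference standard deviations,
#'   default 3; `Inf` disables clipping.
#' @param sd_floor Lower bound for the per-gene reference SD used in the
#'   clip radius.
#' @param cell_center Median-centre each cell across genes after smoothing
#'   (default `TRUE`); disable to obtain the pure centred-and-smoothed
#'   limit.
#' @return An object of class `cnv_profile`: list with `residuals` (cells x
#'   ordered genes), `gene_order` tibble, `window`, `clip`,
#'   `reference_cells`.
#' @export
infer_cnv_profile <- function(norm, gene_pos, reference_mask, window = 101,
                              clip = 3, sd_floor = 0.1, cell_center = TRUE) {
  ref_idx <- to_index(reference_mask, nrow(norm$values))
  if (!length(ref_idx)) stop("reference_mask selects no cells")
  gene_pos <- tibble::as_tibble(gene_pos)
  covered <- intersect(colnames(norm$values), gene_pos$gene_id)
  if (length(covered) < 0.5 * ncol(norm$values)) {
    stop("gene positions missing for more than half of the genes")
  }
  gp <- gene_pos[gene_pos$gene_id %in% covered, , drop = FALSE]
  gp <- gp[order_chromosomes(gp$chrom), , drop = FALSE]
  gp <- gp[order(match(gp$chrom, unique(gp$chrom)), gp$start), , drop = FALSE]

  x <- norm$values[, gp$gene_id, drop = FALSE]
  ref_mean <- colMeans(x[ref_idx, , drop = FALSE])
  centred <- sweep(x, 2, ref_mean)
  if (is.finite(clip)) {
    ref_sd <- pmax(apply(x[ref_idx, , drop = FALSE], 2, stats::sd), sd_floor)
    bound <- clip * ref_sd
    centred <- pmin(pmax(sweep(centred, 2, bound, "/"), -1), 1)
    centred <- sweep(centred, 2, bound, "*")
  }

  smoothed <- centred
  for (ch in unique(gp$chrom)) {
    cols <- which(gp$chrom == ch)
    w <- window
    if (length(cols) < window) {
      warning(sprintf(
        "chromosome %s has %d genes < window %d; using full-chromosome window",
        ch, length(cols), window
      ))
      w <- length(cols)
    }
    smoothed[, cols] <- running_mean_rows(centred[, cols, drop = FALSE], w)
  }
  if (cell_center) smoothed <- smoothed - apply(smoothed, 1, stats::median)
  smoothed <- sweep(smoothed, 2, colMeans(smoothed[ref_idx, , drop = FALSE]))

  structure(
    list(
      residuals = smoothed,
      gene_order = gp,
      window = window,
      clip = clip,
      reference_cells = ref_idx
    ),
    class = "cnv_profile"
  )
}

# Moving average along columns of a matrix with half-window w%/%2, window
# shrinking symmetrically near the edges. O(n) per row via cumulative sums.
running_mean_rows <- function(m, window) {
  g <- ncol(m)
  if (window <= 1 || g == 1) return(m)
  half <- (window - 1) %/% 2
  lo <- pmax(seq_len(g) - half, 1L)
  hi <- pmin(seq_len(g) + half, g)
  cs <- m
  for (j in seq_len(g)[-1]) cs[, j] <- cs[, j - 1] + m[, j]
  zero <- matrix(0, nrow(m), 1)
  left <- cbind(zero, cs)[, lo, drop = FALSE]
  sweep(cs[, hi, drop = FALSE] - left, 2, hi - lo + 1, "/")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf(
    "<cnv_profile> %d cells x %d genes (window %d, clip %g, %d reference cells)\n",
    nrow(x$residuals), ncol(x$residuals), x$window, x$clip,
    length(x$reference_cells)
  ))
  invisible(x)
}

#' Per-cell CNV score
#'
#' Default `"mad"` mode scores each cell by the mean absolute residual over
#' genes (mean absolute deviation from the reference baseline); `"raw-mean"`
#' is the literal mean of the residuals, kept selectable because centring
#' makes it nearly constant across cells and therefore uninformative.
#'
#' @param profile A [infer_cnv_profile] result.
#' @param mode `"mad"` (default) or `"raw-mean"`.
#' @return Named numeric vector of per-cell scores (non-negative in `"mad"`
#'   mode).
#' @export
cnv_score <- function(profile, mode = c("mad", "raw-mean")) {
  mode <- match.arg(mode)
  if (mode == "mad") {
    rowMeans(abs(profile$residuals))
  } else {
    rowMeans(profile$residuals)
  }
}

#' Call cluster-level malignancy against the reference cells
#'
#' Candidate clusters (those not dominated by reference cells) are compared
#' to the pooled reference scores with a two-sided Wilcoxon rank-sum test,
#' BH-adjusted across clusters. A cluster is malignant when its median
#' score exceeds the reference median by more than `min_effect` AND the
#' adjusted p-value is at most `alpha`.
#'
#' @param scores Named per-cell CNV scores from [cnv_score].
#' @param clusters Cluster labels, one per cell (same order as `scores`).
#' @param reference_mask Logical or integer index of reference cells.
#' @param min_effect Minimum difference of medians.
#' @param alpha Adjusted p-value cutoff, default 0.01.
#' @return An object of class `malignancy_call`: tibble with one row per
#'   candidate cluster (`cluster`, `n_cells`, `cnv_score_median`,
#'   `reference_median`, `effect`, `p`, `p_adjusted`, `is_malignant`).
#' @export
classify_malignant <- function(scores, clusters, reference_mask, min_effect,
                               alpha = 0.01) {
  stopifnot(length(scores) == length(clusters))
  ref_idx <- to_index(reference_mask, length(scores))
  ref_scores <- scores[ref_idx]
  ref_median <- stats::median(ref_scores)
  is_ref <- seq_along(scores) %in% ref_idx
  cand <- tapply(is_ref, clusters, mean) < 0.5
  candidates <- names(cand)[cand]
  if (!length(candidates)) stop("no candidate clusters outside the reference")

  rows <- purrr::map_dfr(candidates, function(cl) {
    s <- scores[clusters == cl]
    if (length(s) == 1) warning(sprintf("cluster %s has a single cell; test degenerate", cl))
    p <- suppressWarnings(stats::wilcox.test(s, ref_scores, exact = FALSE)$p.value)
    tibble::tibble(
      cluster = cl,
      n_cells = length(s),
      cnv_score_median = stats::median(s),
      reference_median = ref_median,
      effect = stats::median(s) - ref_median,
      p = p
    )
  })
  rows$p_adjusted <- stats::p.adjust(rows$p, method = "BH")
  rows$is_malignant <- rows$effect > min_effect & rows$p_adjusted <= alpha
  class(rows) <- c("malignancy_call", class(rows))
  attr(rows, "min_effect") <- min_effect
  attr(rows, "alpha") <- alpha
  rows
}
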