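#' Control-binned oncofetal score per cell
#'
#' Module score with expression-matched controls: genes with nonzero total
#' expression are ranked by average expression across cells and split into
#' `n_bins` equal-size bins; for each signature gene, `n_ctrl` control genes
#' are drawn uniformly from its bin (without replacement, or with
#' replacement when the bin holds fewer than `n_ctrl` other genes). The raw
#' score of a cell is the mean over signature genes of
#' (gene value - mean of its control genes).
#'
#' Control draws consume the RNG seeded with `seed`: one `sample()` call per
#' signature gene, genes visited in signature order, the gene itself
#' excluded from its own control pool. This protocol is fixed so scores are
#' reproducible across platforms.
#'
#' @param norm A [normalize_log_cp10k] result.
#' @param sig An `oncofetal_signature` or a character vector of genes.
#' @param n_bins Number of expression bins, default 25.
#' @param n_ctrl Control genes per signature gene, default 50.
#' @param seed Integer seed for the control draws.
#' @return Named numeric vector of raw per-cell scores, with attributes
#'   `params` (list) and `controls` (list of control genes per signature
#'   gene).
#' @export
score_cells <- function(norm, sig, n_bins = 25, n_ctrl = 50, seed = 1L) {
  genes <- signature_genes(sig)
  present <- intersect(genes, colnames(norm$values))
  missing <- setdiff(genes, colnames(norm$values))
  if (!length(present)) {
    stop("no signature gene present in the matrix; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  if (length(missing)) {
    message(sprintf("%d signature gene(s) absent from the matrix", length(missing)))
  }
  avg <- colMeans(norm$values)
  expressed <- names(avg)[avg > 0]
  if (!all(present %in% expressed)) {
    present <- intersect(present, expressed)
    if (!length(present)) stop("all present signature genes have zero total expression")
  }
  bins <- expression_bins(avg[expressed], n_bins)

  controls <- withr::with_seed(seed, {
    lapply(present, function(g) {
      pool <- setdiff(names(bins)[bins == bins[g]], g)
      if (!length(pool)) return(g) # degenerate singleton bin: self-control
      if (length(pool) >= n_ctrl) {
        sample(pool, n_ctrl)
      } else {
        sample(pool, n_ctrl, replace = TRUE)
      }
    })
  })
  names(controls) <- present

  sig_mat <- norm$values[, present, drop = FALSE]
  ctrl_mat <- vapply(
    controls,
    function(cg) rowMeans(norm$values[, cg, drop = FALSE]),
    numeric(nrow(norm$values))
  )
  raw <- rowMeans(sig_mat - ctrl_mat)
  names(raw) <- rownames(norm$values)
  attr(raw, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  attr(raw, "controls") <- controls
  raw
}

# Equal-frequency bins by average expression; ties broken by rank order so
# bins are balanced and deterministic.
expression_bins <- function(avg, n_bins) {
  r <- rank(avg, ties.method = "first")
  bins <- ceiling(r / length(r) * n_bins)
  names(bins) <- names(avg)
  bins
}

signature_genes <- function(sig) {
  if (inherits(sig, "oncofetal_signature")) sig$genes else as.character(sig)
}

#' Zero scores below a normal-cell percentile threshold
#'
#' The threshold is the `pct`-th percentile (linear interpolation) of raw
#' scores over the normal reference cells; every cell's adjusted score is
#' its raw score if strictly above the threshold, else 0. Cells at exactly
#' the threshold are zeroed.
#'
#' @param raw Named numeric vector of raw scores from [score_cells].
#' @param normal_mask Logical or integer index of normal reference cells.
#' @param pct Percentile in `[0, 100]`, default 95.
#' @return Tibble with `cell_id`, `raw`, `adjusted`; the threshold is
#'   carried in attribute `threshold`.
#' @export
zero_below_normal_percentile <- function(raw, normal_mask, pct = 95) {
  idx <- to_index(normal_mask, length(raw))
  if (!length(idx)) stop("normal_mask selects no cells")
  threshold <- percentile_interp(raw[idx], pct)
  adjusted <- ifelse(raw > threshold, raw, 0)
  out <- tibble::tibble(cell_id = names(raw), raw = unname(raw), adjusted = unname(adjusted))
  attr(out, "threshold") <- threshold
  attr(out, "pct") <- pct
  out
}

# pct-th percentile with linear interpolation between order statistics
# (position 1 + p*(n-1), the common definition for continuous samples).
percentile_interp <- function(x, pct) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- 1 + (pct / 100) * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  unname(x[lo] + (h - lo) * (x[hi] - x[lo]))
}

#' Classify fetal-like cells and tabulate per-sample proportions
#'
#' A cell is fetal-like when its adjusted oncofetal score is positive and it
#' is epithelial; non-epithelial cells are scored but never classified.
#' Proportions are percentages over epithelial cells per sample; samples
#' with no epithelial cells are excluded with a message.
#'
#' @param adjusted Tibble from [zero_below_normal_percentile].
#' @param cell_meta Cell metadata with `cell_id`, `sample_id`, `phenotype`,
#'   `cell_type`.
#' @param epithelial_label Value of `cell_type` treated as epithelial.
#' @return An object of class `fetal_like_result`: list with `cells`
#'   (per-cell tibble adding `is_fetal_like`) and `samples` (per-sample
#'   tibble with `n_cells`, `n_fetal_like`, `proportion` in percent and
#'   `contains_fetal_like`).
#' @export
classify_fetal_like <- function(adjusted, cell_meta, epithelial_label = "epithelial") {
  cells <- dplyr::left_join(adjusted, tibble::as_tibble(cell_meta), by = "cell_id")
  cells$is_fetal_like <- cells$adjusted > 0 & cells$cell_type == epithelial_label
  epi <- dplyr::filter(cells, .data$cell_type == epithelial_label)
  no_epi <- setdiff(unique(cells$sample_id), unique(epi$sample_id))
  if (length(no_epi)) {
    message(sprintf("%d sample(s) without epithelial cells excluded", length(no_epi)))
  }
  samples <- epi |>
    dplyr::group_by(.data$sample_id, .data$phenotype) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_fetal_like = sum(.data$is_fetal_like),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      proportion = 100 * .data$n_fetal_like / .data$n_cells,
      contains_fetal_like = .data$n_fetal_like >= 1
    )
  structure(
    list(
      cells = cells, samples = samples,
      threshold = attr(adjusted, "threshold"), pct = attr(adjusted, "pct")
    ),
    class = "fetal_like_result"
  )
}

#' @export
print.fetal_like_result <- function(x, ...) {
  cat(sprintf(
    "<fetal_like_result> %d cells; %d/%d sample(s) contain fetal-like cells (threshold %.4g)\n",
    nrow(x$cells), sum(x$samples$contains_fetal_like), nrow(x$samples),
    x$threshold
  ))
  invisible(x)
}

#' Differentiation-potential surrogate
#'
#' Counts detected genes per cell (values > 0), smooths the counts by
#' averaging over each cell's `smooth_k` nearest neighbours (Euclidean
#' distance in the space of the top `n_variable` variable genes), and
#' min-max rescales to `[0, 1]`. Higher values mark less differentiated,
#' transcriptionally broader cells; this is a declared surrogate for
#' gene-count-based developmental-potential estimators, not a
#' reimplementation of any of them.
#'
#' @param norm A [normalize_log_cp10k] result.
#' @param smooth_k Neighbours averaged per cell (0 disables smoothing);
#'   clamped to `n_cells - 1` with a warning.
#' @param n_variable Variable-gene subspace size for the neighbour search.
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
differentiation_potential <- function(norm, smooth_k = 30, n_variable = 2000) {
  n <- nrow(norm$values)
  if (n < 2) stop("need at least 2 cells")
  if (smooth_k >= n) {
    warning(sprintf("smooth_k clamped from %d to %d", smooth_k, n - 1))
    smooth_k <- n - 1
  }
  detected <- rowSums(norm$values > 0)
  if (smooth_k > 0) {
    vg <- variable_genes(norm$values, n_variable)
    d <- as.matrix(stats::dist(norm$values[, vg, drop = FALSE]))
    smoothed <- vapply(seq_len(n), function(i) {
      nb <- order(d[i, ])[seq_len(smooth_k + 1)] # self plus k nearest
      mean(detected[nb])
    }, numeric(1))
  } else {
    smoothed <- detected
  }
  rng <- range(smoothed)
  out <- if (rng[1] == rng[2]) rep(0.5, n) else (smoothed - rng[1]) / diff(rng)
  names(out) <- rownames(norm$values)
  out
}
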