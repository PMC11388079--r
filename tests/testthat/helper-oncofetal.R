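# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles deliberately use naive loops / external routines so they stay
# independent of the implementation paths they check.

# small single-cell config: ~310 cells x 800 genes, defaults otherwise
small_sc_config <- function(...) {
  plan <- dplyr::bind_rows(
    tibble::tibble(sample_id = "FET1", phenotype = "fetal",
                   cell_type = c("epithelial", "immune"), n_cells = c(40L, 15L)),
    tibble::tibble(sample_id = "NOR1", phenotype = "normal",
                   cell_type = c("epithelial", "endothelial"), n_cells = c(40L, 20L)),
    tibble::tibble(sample_id = "ADJ1", phenotype = "adjacent",
                   cell_type = "epithelial", n_cells = 30L),
    tibble::tibble(sample_id = "HCC1", phenotype = "tumor_HCC",
                   cell_type = c("epithelial", "endothelial"), n_cells = c(60L, 15L)),
    tibble::tibble(sample_id = "HB1", phenotype = "tumor_HB",
                   cell_type = "epithelial", n_cells = 50L)
  )
  args <- utils::modifyList(
    list(
      n_genes = 800, samples = plan, module_genes = 60, adult_genes = 60,
      marker_genes = 50,
      fetal_like_fraction = c(HCC1 = 0.7, HB1 = 0.7)
    ),
    list(...)
  )
  do.call(synth_config, args)
}

# tiny hand-sized normalized matrix from explicit values
norm_from_values <- function(values) {
  structure(
    list(values = values, norm_method = "log_cp10k", scale_factor = 1e4),
    class = "normalized_matrix"
  )
}

make_norm <- function(counts) normalize_log_cp10k(make_cell_dataset(counts))

make_cell_dataset <- function(counts, phenotype = "normal", cell_type = "epithelial") {
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("c%03d", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  cell_dataset(
    counts,
    tibble::tibble(
      cell_id = rownames(counts), sample_id = "S1",
      phenotype = phenotype, cell_type = cell_type
    )
  )
}

# brute-force Pearson from the textbook formula
naive_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# naive control-binned module score: explicit loops, same sampling protocol
naive_score_cells <- function(values, sig_genes, n_bins, n_ctrl, seed) {
  avg <- colMeans(values)
  expressed <- names(avg)[avg > 0]
  r <- rank(avg[expressed], ties.method = "first")
  bins <- ceiling(r / length(r) * n_bins)
  names(bins) <- expressed
  sig_genes <- intersect(sig_genes, expressed)
  set.seed(seed)
  ctrl <- list()
  for (g in sig_genes) {
    pool <- setdiff(expressed[bins == bins[g]], g)
    ctrl[[g]] <- if (!length(pool)) g
      else if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
      else sample(pool, n_ctrl, replace = TRUE)
  }
  out <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    diffs <- vapply(sig_genes, function(g) {
      values[i, g] - mean(values[i, ctrl[[g]]])
    }, numeric(1))
    out[i] <- mean(diffs)
  }
  out
}
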