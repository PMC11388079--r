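test_that("pseudobulk rows are group means and small groups are filtered", {
  counts <- matrix(0L, 4, 2, dimnames = list(paste0("c", 1:4), c("gA", "gB")))
  meta <- tibble::tibble(
    cell_id = paste0("c", 1:4), sample_id = c("S1", "S1", "S2", "S2"),
    phenotype = "normal", cell_type = "epithelial"
  )
  ds <- cell_dataset(counts, meta)
  norm <- norm_from_values(matrix(
    c(1, 3, 3, 1, 5, 5, 7, 7), nrow = 4, byrow = TRUE,
    dimnames = dimnames(counts)
  ))
  pb <- build_pseudobulks(ds, norm, group_keys = "sample_id", min_cells = 1)
  expect_equal(unname(pb$values["S1", ]), c(2, 2))
  expect_equal(pb$pb_meta$n_cells, c(2L, 2L))

  # groups below min_cells vanish; all below => error
  counts5 <- rbind(counts, c5 = c(0L, 0L))
  meta5 <- dplyr::bind_rows(meta, tibble::tibble(
    cell_id = "c5", sample_id = "S3", phenotype = "normal", cell_type = "epithelial"
  ))
  ds5 <- cell_dataset(counts5, meta5)
  norm5 <- norm_from_values(rbind(norm$values, c5 = c(9, 9)))
  expect_message(
    pb5 <- build_pseudobulks(ds5, norm5, group_keys = "sample_id", min_cells = 2),
    "dropped 1"
  )
  expect_false("S3" %in% pb5$pb_meta$sample_id)
  expect_error(
    suppressMessages(build_pseudobulks(ds5, norm5, group_keys = "sample_id", min_cells = 10)),
    "no pseudobulks"
  )
})

test_that("pseudobulk means match a naive per-group loop on synthetic data", {
  cfg <- small_sc_config()
  sc <- generate_single_cell(cfg, seed = 3)
  norm <- normalize_log_cp10k(sc$dataset)
  pb <- suppressMessages(build_pseudobulks(sc$dataset, norm, min_cells = 5))
  meta <- sc$dataset$cell_meta
  for (i in seq_len(nrow(pb$pb_meta))) {
    idx <- meta$sample_id == pb$pb_meta$sample_id[i] &
      meta$cell_type == pb$pb_meta$cell_type[i]
    expect_equal(unname(pb$values[i, ]), unname(colMeans(norm$values[idx, , drop = FALSE])))
  }
})

test_that("pseudobulk correlations equal the brute-force Pearson formula", {
  cfg <- small_sc_config()
  sc <- generate_single_cell(cfg, seed = 5)
  norm <- normalize_log_cp10k(sc$dataset)
  pb <- suppressMessages(build_pseudobulks(sc$dataset, norm, min_cells = 5))
  vg <- utils::head(names(sort(apply(pb$values, 2, var), decreasing = TRUE)), 100)
  cc <- correlate_pseudobulks(pb, gene_subset = vg)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, nrow(cc)))
  for (i in c(1, 3)) {
    for (j in c(2, nrow(cc))) {
      expect_equal(cc[i, j], naive_pearson(pb$values[i, vg], pb$values[j, vg]),
                   tolerance = 1e-10)
    }
  }
  # anti-correlated rows and zero-variance handling
  vals2 <- rbind(a = c(1, 2, 5), b = c(5, 4, 1), flat = c(2, 2, 2))
  colnames(vals2) <- c("g1", "g2", "g3")
  pb2 <- structure(
    list(values = vals2, pb_meta = tibble::tibble(pseudobulk_id = c("a", "b", "flat"))),
    class = "pseudobulk_matrix"
  )
  expect_warning(cc2 <- correlate_pseudobulks(pb2, gene_subset = colnames(pb2$values)),
                 "zero-variance")
  expect_equal(cc2["a", "b"], -1, tolerance = 1e-12)
  expect_equal(cc2["a", "flat"], 0)
  expect_equal(cc2["flat", "flat"], 1)
})

test_that("correlation and pseudobulks are invariant to cell order", {
  cfg <- small_sc_config()
  sc <- generate_single_cell(cfg, seed = 6)
  norm <- normalize_log_cp10k(sc$dataset)
  perm <- withr::with_seed(1, sample(nrow(norm$values)))
  ds_p <- cell_dataset(sc$dataset$counts[perm, ], sc$dataset$cell_meta[perm, ],
                       sc$dataset$gene_pos)
  norm_p <- norm_from_values(norm$values[perm, ])
  pb <- suppressMessages(build_pseudobulks(sc$dataset, norm, min_cells = 5))
  pb_p <- suppressMessages(build_pseudobulks(ds_p, norm_p, min_cells = 5))
  expect_equal(pb_p$values[rownames(pb$values), ], pb$values)
  expect_equal(correlate_pseudobulks(pb_p)[rownames(pb$values), rownames(pb$values)],
               correlate_pseudobulks(pb))
})

test_that("comodule selection follows the fetal-fraction x tumor-gate rule", {
  blk <- function(ids, r) {
    m <- matrix(r, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    m
  }
  ids <- c("f1", "f2", "t1", "n1", "n2")
  cc <- matrix(0.1, 5, 5, dimnames = list(ids, ids))
  cc[1:3, 1:3] <- 0.9
  cc[4:5, 4:5] <- 0.9
  diag(cc) <- 1
  meta <- tibble::tibble(
    pseudobulk_id = ids,
    phenotype = c("fetal", "fetal", "tumor_HCC", "adjacent", "normal")
  )
  mod <- detect_comodule(cc, meta, n_clusters = 2)
  expect_setequal(mod$module_members, c("f1", "f2", "t1"))

  # fetal split across clusters; only one cluster holds a tumor -> tumor gate
  cc2 <- cc
  meta2 <- tibble::tibble(
    pseudobulk_id = ids,
    phenotype = c("fetal", "fetal", "tumor_HB", "fetal", "fetal")
  )
  mod2 <- detect_comodule(cc2, meta2, n_clusters = 2)
  expect_true("t1" %in% mod2$module_members)

  expect_error(
    detect_comodule(cc, dplyr::mutate(meta, phenotype = "normal"), 2),
    "no fetal"
  )
})

test_that("comodule detection recovers the planted fetal/tumor module and ignores row order", {
  for (seed in c(2, 9)) {
    cfg <- small_sc_config()
    sc <- generate_single_cell(cfg, seed = seed)
    norm <- normalize_log_cp10k(sc$dataset)
    pb <- suppressMessages(build_pseudobulks(sc$dataset, norm, min_cells = 5))
    cc <- correlate_pseudobulks(pb)
    mod <- detect_comodule(cc, pb$pb_meta, n_clusters = 4)
    got <- sort(unique(pb$pb_meta$sample_id[match(mod$module_members, pb$pb_meta$pseudobulk_id)]))
    expect_equal(got, sort(sc$truth$module_samples), info = paste("seed", seed))
    # epithelial pseudobulks only in the module
    expect_true(all(grepl("epithelial", mod$module_members)))

    perm <- withr::with_seed(seed, sample(nrow(cc)))
    mod_p <- detect_comodule(cc[perm, perm], pb$pb_meta[perm, ], n_clusters = 4)
    expect_setequal(mod_p$module_members, mod$module_members)
  }
})

test_that("signature derivation excludes null genes and captures full separation", {
  set.seed(42)
  n <- 30
  vals <- cbind(
    null_gene = rep(2, 2 * n),
    sep_gene = c(rep(1.5, n), rep(0, n)),
    noise = runif(2 * n)
  )
  rownames(vals) <- sprintf("c%02d", seq_len(2 * n))
  norm <- norm_from_values(vals)
  sig <- suppressWarnings(
    derive_signature(norm, seq_len(n), n + seq_len(n), n_top = 10)
  )
  expect_false("null_gene" %in% sig$genes)
  expect_true("sep_gene" %in% sig$genes)
  expect_equal(sig$genes[1], "sep_gene") # maximal LFC among qualifiers
  expect_error(derive_signature(norm, seq_len(n), c(n, n + 1)), "disjoint")
})

test_that("signature recovers planted program genes with high recall", {
  cfg <- small_sc_config()
  sc <- generate_single_cell(cfg, seed = 4)
  norm <- normalize_log_cp10k(sc$dataset)
  meta <- sc$dataset$cell_meta
  is_epi <- meta$cell_type == "epithelial"
  in_mod <- is_epi & sc$truth$is_fetal_like
  sig <- suppressWarnings(derive_signature(norm, in_mod, is_epi & !in_mod, n_top = 60))
  recall <- mean(sc$truth$module_genes %in% sig$genes)
  expect_gte(recall, 0.9)
  # stats tibble invariants
  td <- tidy(sig, signature_only = TRUE)
  expect_equal(td$gene, sig$genes)
  expect_true(all(diff(td$log2_fc) <= 0))
  expect_true(all(td$p_adjusted <= sig$alpha))
  expect_true(all(td$log2_fc > 0))
})

test_that("label-permuted signature derivation stays at the nominal false-positive level", {
  # global null: one homogeneous population, random group labels
  alpha <- 0.05
  n_genes <- 250
  counts_cfg <- synth_config(
    n_genes = n_genes, module_genes = 10, module_log2fc = 0, adult_genes = 0,
    marker_genes = 0, tumor_benign_fraction = 0,
    cnv_segments = tibble::tibble(chrom = character(), start_gene = integer(),
                                  length = integer(), fold_change = numeric()),
    samples = tibble::tibble(sample_id = "N1", phenotype = "normal",
                             cell_type = "epithelial", n_cells = 60L)
  )
  n_qual <- vapply(1:20, function(seed) {
    sc <- generate_single_cell(counts_cfg, seed = seed)
    norm <- normalize_log_cp10k(sc$dataset)
    grp <- withr::with_seed(seed + 100, sample(rep(c(TRUE, FALSE), each = 30)))
    sig <- suppressWarnings(derive_signature(norm, grp, !grp, n_top = n_genes, alpha = alpha))
    sum(sig$stats$qualifies, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(n_qual), 2 * alpha * n_genes)
})
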