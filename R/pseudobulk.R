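#' Aggregate cells into pseudobulk expression profiles
#'
#' One pseudobulk per combination of the grouping keys (typically
#' `sample_id` x `cell_type`), equal to the arithmetic mean of the member
#' cells' normalized expression rows. Combinations with fewer than
#' `min_cells` cells are dropped and counted in a message.
#'
#' @param ds A [cell_dataset].
#' @param norm The matching [normalize_log_cp10k] result.
#' @param group_keys Character vector of metadata columns to group by.
#' @param min_cells Minimum cells per retained pseudobulk.
#' @return An object of class `pseudobulk_matrix`: list with `values`
#'   (pseudobulks x genes mean expression) and `pb_meta` (tibble with the
#'   grouping keys, `phenotype` and `n_cells` per pseudobulk).
#' @export
build_pseudobulks <- function(ds, norm, group_keys = c("sample_id", "cell_type"),
                              min_cells = 10) {
  stopifnot(min_cells >= 1)
  missing_keys <- setdiff(group_keys, names(ds$cell_meta))
  if (length(missing_keys)) {
    stop("group_keys absent from cell metadata: ", paste(missing_keys, collapse = ", "))
  }
  meta <- ds$cell_meta
  grp <- interaction(meta[group_keys], drop = TRUE, sep = "|", lex.order = TRUE)
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= min_cells]
  dropped <- length(sizes) - length(keep)
  if (dropped > 0) {
    message(sprintf("dropped %d group(s) below min_cells = %d", dropped, min_cells))
  }
  if (!length(keep)) stop("no pseudobulks: every group falls below min_cells")

  rows <- t(vapply(
    keep,
    function(g) colMeans(norm$values[grp == g, , drop = FALSE]),
    numeric(ncol(norm$values))
  ))
  colnames(rows) <- colnames(norm$values)

  pb_meta <- purrr::map_dfr(keep, function(g) {
    idx <- which(grp == g)
    key_vals <- meta[idx[1], group_keys, drop = FALSE]
    extra <- setdiff(c("phenotype"), group_keys)
    extra <- extra[extra %in% names(meta)]
    dplyr::bind_cols(
      tibble::tibble(pseudobulk_id = g),
      key_vals,
      meta[idx[1], extra, drop = FALSE],
      tibble::tibble(n_cells = length(idx))
    )
  })
  rownames(rows) <- pb_meta$pseudobulk_id
  structure(list(values = rows, pb_meta = pb_meta), class = "pseudobulk_matrix")
}

#' @export
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf(
    "<pseudobulk_matrix> %d pseudobulks x %d genes\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Pairwise Pearson correlation of pseudobulk profiles
#'
#' Correlates pseudobulk rows over a gene subset (the 2,000 most variable
#' genes across pseudobulks by default). Zero-variance pseudobulks get
#' correlation 0 against everything (flagged by a warning); the diagonal is
#' set to exactly 1.
#'
#' @param pb A [build_pseudobulks] result.
#' @param gene_subset Optional character vector of genes; `NULL` selects the
#'   `n_variable` most variable genes.
#' @param n_variable Size of the default variable-gene subset.
#' @return Symmetric correlation matrix with pseudobulk ids as dimnames.
#' @export
correlate_pseudobulks <- function(pb, gene_subset = NULL, n_variable = 2000) {
  if (nrow(pb$values) < 2) stop("need at least 2 pseudobulks")
  if (is.null(gene_subset)) gene_subset <- variable_genes(pb$values, n_variable)
  gene_subset <- intersect(gene_subset, colnames(pb$values))
  if (!length(gene_subset)) stop("gene_subset shares no genes with the pseudobulks")
  m <- pb$values[, gene_subset, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(m)))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance pseudobulk(s): correlations set to 0", sum(sds == 0)))
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Detect the fetal/tumor co-clustering pseudobulk module
#'
#' Hierarchically clusters pseudobulks with distance `1 - correlation` and
#' average linkage, cuts the tree into `n_clusters`, and selects the cluster
#' maximizing (fraction of members with fetal phenotype) x (1 if the cluster
#' also contains at least one tumor pseudobulk, else 0). Ties break toward
#' the larger cluster, then the lowest cluster id.
#'
#' @param corr Correlation matrix from [correlate_pseudobulks].
#' @param pb_meta Pseudobulk metadata with `pseudobulk_id` and `phenotype`.
#' @param n_clusters Number of clusters to cut, default 4.
#' @return An object of class `module_assignment`: list with `labels`
#'   (named integer cluster per pseudobulk), `module_id`, `module_members`,
#'   `selection_scores` (per-cluster tibble) and `linkage_summary` (merge
#'   heights).
#' @export
detect_comodule <- function(corr, pb_meta, n_clusters = 4) {
  stopifnot(n_clusters >= 2, nrow(corr) == nrow(pb_meta))
  phen <- pb_meta$phenotype[match(rownames(corr), pb_meta$pseudobulk_id)]
  if (!any(phen == "fetal")) stop("no oncofetal module: no fetal pseudobulk present")
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  labels <- stats::cutree(hc, k = min(n_clusters, nrow(corr)))
  tumor_phen <- c("tumor_HCC", "tumor_HB", "tumor_ICC")
  per_cluster <- purrr::map_dfr(sort(unique(labels)), function(k) {
    members <- names(labels)[labels == k]
    ph <- phen[labels == k]
    tibble::tibble(
      cluster = k,
      size = length(members),
      fetal_fraction = mean(ph == "fetal"),
      has_tumor = any(ph %in% tumor_phen),
      score = mean(ph == "fetal") * as.numeric(any(ph %in% tumor_phen))
    )
  })
  if (all(per_cluster$score == 0)) {
    stop("no oncofetal module: no cluster joins fetal and tumor pseudobulks")
  }
  ord <- order(-per_cluster$score, -per_cluster$size, per_cluster$cluster)
  module_id <- per_cluster$cluster[ord[1]]
  structure(
    list(
      labels = labels,
      module_id = module_id,
      module_members = names(labels)[labels == module_id],
      selection_scores = per_cluster,
      linkage_summary = hc$height
    ),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf(
    "<module_assignment> %d clusters; oncofetal module = cluster %d (%d pseudobulks)\n",
    length(unique(x$labels)), x$module_id, length(x$module_members)
  ))
  invisible(x)
}

#' Derive the oncofetal signature by differential expression
#'
#' Two-sided Wilcoxon rank-sum per gene between module epithelial cells and
#' the remaining epithelial cells on normalized values, Benjamini-Hochberg
#' adjusted. Qualifying genes (adjusted p <= `alpha`, positive log2 fold
#' change) are ranked by descending log2 fold change and the top `n_top`
#' kept. The fold change contrasts group means on the CP10K scale:
#' `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`.
#'
#' @param norm A [normalize_log_cp10k] result.
#' @param module_cells Logical or integer index of module cells.
#' @param other_epithelial Logical or integer index of the contrast cells;
#'   must be disjoint from `module_cells`.
#' @param n_top Signature size cap, default 200.
#' @param alpha BH-adjusted p-value cutoff, default 0.05.
#' @return An object of class `oncofetal_signature`: list with `genes`
#'   (ordered character vector) and `stats` (per-gene tibble with `log2_fc`,
#'   `p_value`, `p_adjusted`, `qualifies`, `rank`).
#' @export
derive_signature <- function(norm, module_cells, other_epithelial,
                             n_top = 200, alpha = 0.05) {
  in_idx <- to_index(module_cells, nrow(norm$values))
  out_idx <- to_index(other_epithelial, nrow(norm$values))
  if (!length(in_idx) || !length(out_idx)) stop("both cell groups must be nonempty")
  if (length(intersect(in_idx, out_idx))) stop("cell groups must be disjoint")

  x_in <- norm$values[in_idx, , drop = FALSE]
  x_out <- norm$values[out_idx, , drop = FALSE]
  p <- vapply(seq_len(ncol(x_in)), function(j) {
    a <- x_in[, j]
    b <- x_out[, j]
    if (all(a == a[1]) && all(b == a[1])) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  lfc <- log2((colMeans(expm1(x_in)) + 1) / (colMeans(expm1(x_out)) + 1))
  p_adj <- stats::p.adjust(p, method = "BH")
  stats_tbl <- tibble::tibble(
    gene = colnames(norm$values),
    log2_fc = lfc,
    p_value = p,
    p_adjusted = p_adj,
    qualifies = !is.na(p_adj) & p_adj <= alpha & lfc > 0
  )
  qual <- dplyr::arrange(dplyr::filter(stats_tbl, .data$qualifies), dplyr::desc(.data$log2_fc))
  if (nrow(qual) < n_top) {
    warning(sprintf("only %d genes qualify (requested %d)", nrow(qual), n_top))
  }
  top <- utils::head(qual, n_top)
  stats_tbl$rank <- match(stats_tbl$gene, top$gene)
  structure(
    list(genes = top$gene, stats = stats_tbl, n_top = n_top, alpha = alpha),
    class = "oncofetal_signature"
  )
}

#' @export
print.oncofetal_signature <- function(x, ...) {
  cat(sprintf(
    "<oncofetal_signature> %d genes (cap %d, alpha %g); top: %s\n",
    length(x$genes), x$n_top, x$alpha,
    paste(utils::head(x$genes, 5), collapse = ", ")
  ))
  invisible(x)
}

#' Write a signature as a two-column TSV or a GMT set
#'
#' @param sig An [derive_signature] result.
#' @param path Output file.
#' @param format `"tsv"` (columns gene, rank) or `"gmt"` (single set named
#'   `oncofetal_signature`).
#' @export
write_signature <- function(sig, path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(
      tibble::tibble(gene = sig$genes, rank = seq_along(sig$genes)), path
    )
  } else {
    write_gmt(list(oncofetal_signature = sig$genes), path)
  }
  invisible(path)
}

to_index <- function(x, n) {
  if (is.logical(x)) {
    stopifnot(length(x) == n)
    which(x)
  } else {
    as.integer(x)
  }
}
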