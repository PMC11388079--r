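#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Correlation heatmap of pseudobulks
#'
#' Tile heatmap of a pseudobulk correlation matrix, rows/columns in
#' hierarchical-clustering order (average linkage on 1 - correlation) so a
#' fetal/tumor co-clustering module shows up as a block.
#'
#' @param corr Matrix from [correlate_pseudobulks].
#' @param pb_meta Optional pseudobulk metadata used to annotate phenotypes
#'   in the axis labels.
#' @return A ggplot object.
#' @export
plot_pseudobulk_corr <- function(corr, pb_meta = NULL) {
  ord <- stats::hclust(stats::as.dist(1 - corr), method = "average")$order
  labs <- rownames(corr)[ord]
  if (!is.null(pb_meta)) {
    phen <- pb_meta$phenotype[match(labs, pb_meta$pseudobulk_id)]
    labs_show <- paste0(labs, " [", phen, "]")
  } else {
    labs_show <- labs
  }
  df <- tidyr::expand_grid(row = labs, col = labs)
  df$correlation <- corr[cbind(df$row, df$col)]
  df$row <- factor(df$row, levels = labs, labels = labs_show)
  df$col <- factor(df$col, levels = labs, labels = labs_show)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  midpoint = 0, limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' @export
autoplot.fetal_like_result <- function(object, ...) {
  ggplot2::ggplot(
    object$samples,
    ggplot2::aes(stats::reorder(.data$sample_id, -.data$proportion),
                 .data$proportion, fill = .data$phenotype)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "sample", y = "fetal-like cells (% of epithelial)",
      title = sprintf("Fetal-like fraction per sample (threshold %.3g)", object$threshold)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' @export
autoplot.cnv_profile <- function(object, max_cells = 400, ...) {
  res <- object$residuals
  if (nrow(res) > max_cells) {
    res <- res[seq(1, nrow(res), length.out = max_cells), , drop = FALSE]
  }
  df <- tidyr::expand_grid(
    cell = factor(rownames(res), levels = rownames(res)),
    gene_index = seq_len(ncol(res))
  )
  df$residual <- as.vector(t(res))
  chrom_bounds <- cumsum(table(factor(object$gene_order$chrom,
                                      levels = unique(object$gene_order$chrom))))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_index, .data$cell, fill = .data$residual)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  midpoint = 0) +
    ggplot2::geom_vline(xintercept = utils::head(unname(chrom_bounds), -1) + 0.5,
                        linewidth = 0.3) +
    ggplot2::labs(x = "genes in genome order", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.regulator_table <- function(object, label_top = 10, ...) {
  df <- dplyr::filter(object, .data$has_dependency)
  top <- dplyr::filter(df, !is.na(.data$rank), .data$rank <= label_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_oncofetal, .data$mean_dependency)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$passes_filter,
                                     shape = .data$is_rbp), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = attr(object, "dep_max"), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "r_min"), linetype = "dashed") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "correlation with oncofetal score",
      y = "mean dependency (gene effect; lower = more essential)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.logrank_km <- function(object, ...) {
  # prepend the (0, 1) anchor per group so curves start at full survival
  anchors <- tibble::tibble(
    group = unique(object$curves$group), time = 0, survival = 1
  )
  df <- dplyr::bind_rows(anchors, object$curves[, c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = factor(.data$group))) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (months)", y = "survival probability", colour = "group",
      subtitle = sprintf("log-rank chi-square = %.3g, p = %.3g", object$chisq, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cutpoint_split <- function(object, ...) {
  scan <- attr(object, "scan")
  if (is.null(scan)) stop("no candidate scan attached to this split")
  ggplot2::ggplot(scan, ggplot2::aes(.data$cutoff, abs(.data$logrank_z))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(
      x = "candidate cutoff", y = "|standardized log-rank statistic|",
      subtitle = sprintf(
        "selected cutoff %.3g (%d%% high), permutation p = %.3g",
        object$cutoff, object$pct_high, object$p
      )
    ) +
    ggplot2::theme_minimal()
}
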