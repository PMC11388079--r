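#' Cell-line panel carrier
#'
#' @param expression Non-negative matrix, cell lines x genes, TPM units.
#' @param dependency Matrix, cell lines x genes, CRISPR gene-effect scores
#'   (more negative = more essential for proliferation). `NA` marks lines
#'   not screened for a gene.
#' @param line_meta Data frame with `line_id` and `lineage`.
#' @return An object of class `cell_line_panel`.
#' @export
cell_line_panel <- function(expression, dependency, line_meta) {
  stopifnot(is.matrix(expression), is.matrix(dependency))
  if (min(expression, na.rm = TRUE) < 0) stop("TPM expression must be non-negative")
  line_meta <- tibble::as_tibble(line_meta)
  stopifnot(all(c("line_id", "lineage") %in% names(line_meta)))
  common_lines <- intersect(rownames(expression), rownames(dependency))
  if (!length(common_lines)) stop("expression and dependency share no cell lines")
  structure(
    list(
      expression = expression,
      dependency = dependency,
      line_meta = line_meta[match(rownames(expression), line_meta$line_id), , drop = FALSE]
    ),
    class = "cell_line_panel"
  )
}

#' Subset a cell-line panel by line or lineage
#'
#' @param panel A [cell_line_panel].
#' @param lines Character vector of line ids, or `NULL`.
#' @param lineage Character vector of lineages to keep, or `NULL`.
#' @return A [cell_line_panel] restricted to the selected lines. The
#'   regulator association analysis runs on the liver lineage subset;
#'   lineage specificity runs on the full pan-cancer panel.
#' @export
subset_panel <- function(panel, lines = NULL, lineage = NULL) {
  keep <- rownames(panel$expression)
  if (!is.null(lineage)) {
    keep <- intersect(keep, panel$line_meta$line_id[panel$line_meta$lineage %in% lineage])
  }
  if (!is.null(lines)) keep <- intersect(keep, lines)
  if (!length(keep)) stop("no cell lines left after subsetting")
  cell_line_panel(
    panel$expression[keep, , drop = FALSE],
    panel$dependency[intersect(keep, rownames(panel$dependency)), , drop = FALSE],
    panel$line_meta[panel$line_meta$line_id %in% keep, , drop = FALSE]
  )
}

#' @export
print.cell_line_panel <- function(x, ...) {
  cat(sprintf(
    "<cell_line_panel> %d lines x %d genes (expression), %d x %d (dependency)\n",
    nrow(x$expression), ncol(x$expression),
    nrow(x$dependency), ncol(x$dependency)
  ))
  invisible(x)
}

#' Oncofetal score per cell line
#'
#' Per-line mean z-score over the signature genes: expression is
#' log2(TPM + 1) transformed, each gene standardized across lines, then
#' averaged over signature genes. Zero-variance genes are excluded with a
#' warning.
#'
#' @param panel A [cell_line_panel].
#' @param sig An `oncofetal_signature` or character vector of genes.
#' @return Named numeric vector of per-line scores.
#' @export
score_cell_lines <- function(panel, sig) {
  genes <- intersect(signature_genes(sig), colnames(panel$expression))
  if (!length(genes)) stop("no signature gene present in the panel")
  lx <- log2(panel$expression[, genes, drop = FALSE] + 1)
  sds <- apply(lx, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance signature gene(s) excluded", sum(sds == 0)))
    lx <- lx[, sds > 0, drop = FALSE]
    if (!ncol(lx)) stop("all signature genes have zero variance across lines")
  }
  z <- scale(lx)
  out <- rowMeans(z)
  names(out) <- rownames(panel$expression)
  out
}

#' Associate genes with the oncofetal score and proliferative dependency
#'
#' For every gene: Pearson correlation of log2(TPM + 1) with the per-line
#' oncofetal score (`r_oncofetal`, 0 for zero-variance genes), and mean
#' dependency over lines with a non-missing gene effect. A gene passes the
#' filter when `r_oncofetal >= r_min` and `mean_dependency <= dep_max`;
#' passing genes are ranked by the sum of the two standardized criteria
#' (z of `r_oncofetal` plus z of `|mean_dependency|`, both across passing
#' genes, descending). Genes with dependency missing in every line are kept
#' in the table, flagged, and excluded from filtering and ranking.
#'
#' @param panel A [cell_line_panel].
#' @param line_scores Named per-line scores from [score_cell_lines].
#' @param rbp_set,tf_set Character vectors of RNA-binding-protein and
#'   transcription-factor gene ids (annotation flags only).
#' @param r_min Minimum Pearson correlation with the oncofetal score.
#' @param dep_max Maximum mean gene effect (more negative = more
#'   essential), default -0.4.
#' @return An object of class `regulator_table`: tibble with one row per
#'   gene (`gene`, `r_oncofetal`, `mean_dependency`, `n_dep_lines`,
#'   `is_rbp`, `is_tf`, `has_dependency`, `passes_filter`, `rank`).
#' @export
associate_regulators <- function(panel, line_scores, rbp_set = character(),
                                 tf_set = character(), r_min = 0.3,
                                 dep_max = -0.4) {
  if (nrow(panel$expression) < 3) stop("need at least 3 cell lines")
  lx <- log2(panel$expression + 1)
  sc <- line_scores[rownames(lx)]
  r <- suppressWarnings(as.vector(stats::cor(lx, sc)))
  r[is.na(r)] <- 0

  genes <- colnames(panel$expression)
  dep <- panel$dependency[rownames(lx), , drop = FALSE]
  mean_dep <- vapply(genes, function(g) {
    if (!g %in% colnames(dep)) return(NA_real_)
    mean(dep[, g], na.rm = TRUE)
  }, numeric(1))
  n_dep <- vapply(genes, function(g) {
    if (!g %in% colnames(dep)) return(0L)
    sum(!is.na(dep[, g]))
  }, integer(1))

  tbl <- tibble::tibble(
    gene = genes,
    r_oncofetal = r,
    mean_dependency = ifelse(n_dep > 0, mean_dep, NA_real_),
    n_dep_lines = n_dep,
    is_rbp = genes %in% rbp_set,
    is_tf = genes %in% tf_set,
    has_dependency = n_dep > 0
  )
  tbl$passes_filter <- tbl$has_dependency &
    tbl$r_oncofetal >= r_min & tbl$mean_dependency <= dep_max

  tbl$rank <- NA_integer_
  pass <- which(tbl$passes_filter)
  if (length(pass)) {
    combined <- zscore(tbl$r_oncofetal[pass]) + zscore(abs(tbl$mean_dependency[pass]))
    tbl$rank[pass[order(-combined)]] <- seq_along(pass)
  }
  tbl <- dplyr::arrange(tbl, !is.na(.data$rank) * -1, .data$rank, dplyr::desc(.data$r_oncofetal))
  class(tbl) <- c("regulator_table", class(tbl))
  attr(tbl, "r_min") <- r_min
  attr(tbl, "dep_max") <- dep_max
  tbl
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Lineage composition of the most dependent expressing lines
#'
#' Among cell lines expressing `gene` above `tpm_min`, ranks lines by
#' ascending dependency (most essential first), keeps the top `k`, and
#' counts lineages.
#'
#' @param panel A [cell_line_panel].
#' @param gene Gene id present in both matrices.
#' @param tpm_min Expression gate (TPM), default 1.
#' @param dep_max Reference essentiality threshold carried into the output
#'   for plotting, default -0.4 (gene-effect convention, lower = more
#'   essential).
#' @param k Lines kept, default 10; clamped to the number of qualifying
#'   lines with a warning.
#' @return An object of class `lineage_specificity`: list with `counts`
#'   (tibble lineage/n, descending), `top_lines` (tibble of the retained
#'   lines with expression and dependency) and `most_dependent_line`.
#' @export
lineage_specificity <- function(panel, gene, tpm_min = 1, dep_max = -0.4, k = 10) {
  if (!gene %in% colnames(panel$expression) || !gene %in% colnames(panel$dependency)) {
    stop("gene absent from the expression or dependency matrix: ", gene)
  }
  tbl <- tibble::tibble(
    line_id = rownames(panel$expression),
    lineage = panel$line_meta$lineage,
    tpm = panel$expression[, gene],
    dependency = panel$dependency[rownames(panel$expression), gene]
  )
  qual <- dplyr::filter(tbl, .data$tpm > tpm_min, !is.na(.data$dependency))
  if (!nrow(qual)) {
    warning(sprintf("no line passes TPM > %g for %s", tpm_min, gene))
    return(structure(
      list(
        counts = tibble::tibble(lineage = character(), n = integer()),
        top_lines = qual, most_dependent_line = NA_character_,
        gene = gene, tpm_min = tpm_min, dep_max = dep_max, k = k
      ),
      class = "lineage_specificity"
    ))
  }
  if (nrow(qual) < k) {
    warning(sprintf("only %d qualifying line(s) for top-%d", nrow(qual), k))
  }
  top <- utils::head(dplyr::arrange(qual, .data$dependency), k)
  counts <- top |>
    dplyr::count(.data$lineage, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$lineage)
  structure(
    list(
      counts = counts,
      top_lines = top,
      most_dependent_line = top$line_id[1],
      gene = gene, tpm_min = tpm_min, dep_max = dep_max, k = k
    ),
    class = "lineage_specificity"
  )
}

#' @export
print.lineage_specificity <- function(x, ...) {
  cat(sprintf(
    "<lineage_specificity> %s: top-%d lines by dependency (TPM > %g); most dependent: %s\n",
    x$gene, nrow(x$top_lines), x$tpm_min, x$most_dependent_line
  ))
  print(x$counts)
  invisible(x)
}
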