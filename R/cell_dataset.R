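#' Single-cell dataset carrier
#'
#' Bundles a UMI count matrix (cells x genes) with per-cell metadata and an
#' optional per-gene genomic position table. This is the universal carrier
#' every downstream stage (pseudobulking, signature scoring, CNV inference)
#' consumes.
#'
#' @param counts Non-negative integer matrix, cells in rows, genes in columns.
#'   Dimnames are taken as cell and gene identifiers; both must be unique.
#'   Sparse [Matrix::Matrix] input is kept sparse.
#' @param cell_meta Data frame with one row per cell: columns `cell_id`,
#'   `sample_id`, `phenotype` (one of `fetal`, `normal`, `adjacent`,
#'   `tumor_HCC`, `tumor_HB`, `tumor_ICC`), `cell_type` and optionally
#'   `cluster`.
#' @param gene_pos Optional data frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (1-based inclusive base-pair coordinates).
#'
#' @return An object of class `cell_dataset`: a list with elements `counts`,
#'   `cell_meta` (tibble, ordered as the matrix rows) and `gene_pos`
#'   (tibble or `NULL`).
#' @export
cell_dataset <- function(counts, cell_meta, gene_pos = NULL) {
  stopifnot(is.matrix(counts) || methods::is(counts, "Matrix"))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry cell ids as rownames and gene ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids in counts")
  if (min(counts) < 0) stop("`counts` has negative entries")

  cell_meta <- tibble::as_tibble(cell_meta)
  required <- c("cell_id", "sample_id", "phenotype", "cell_type")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols)) {
    stop("cell_meta missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cell_meta$cell_id)) stop("duplicate cell ids in cell_meta")

  orphans <- setdiff(rownames(counts), cell_meta$cell_id)
  if (length(orphans)) {
    stop(
      "cells present in the matrix but absent from metadata: ",
      paste(utils::head(orphans, 5), collapse = ", "),
      if (length(orphans) > 5) sprintf(" (and %d more)", length(orphans) - 5)
    )
  }
  extra <- setdiff(cell_meta$cell_id, rownames(counts))
  if (length(extra)) {
    message(sprintf("dropping %d metadata row(s) without a matrix cell", length(extra)))
    cell_meta <- cell_meta[cell_meta$cell_id %in% rownames(counts), , drop = FALSE]
  }
  cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), , drop = FALSE]

  if (!is.null(gene_pos)) {
    gene_pos <- tibble::as_tibble(gene_pos)
    pos_cols <- c("gene_id", "chrom", "start", "end")
    if (!all(pos_cols %in% names(gene_pos))) {
      stop("gene_pos must have columns: ", paste(pos_cols, collapse = ", "))
    }
    gene_pos <- gene_pos[gene_pos$gene_id %in% colnames(counts), , drop = FALSE]
    gene_pos <- gene_pos[order_chromosomes(gene_pos$chrom), , drop = FALSE]
    gene_pos <- gene_pos[order(match(gene_pos$chrom, unique(gene_pos$chrom)), gene_pos$start), ,
      drop = FALSE
    ]
  }

  structure(
    list(counts = counts, cell_meta = cell_meta, gene_pos = gene_pos),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf(
    "<cell_dataset> %d cells x %d genes; %d sample(s); gene positions: %s\n",
    nrow(x$counts), ncol(x$counts),
    dplyr::n_distinct(x$cell_meta$sample_id),
    if (is.null(x$gene_pos)) "absent" else sprintf("%d genes", nrow(x$gene_pos))
  ))
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

# Deterministic total chromosome order: natural-numeric where the name has a
# numeric core (chr1 < chr2 < chr10), then lexicographic for the rest (chrX...).
order_chromosomes <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  key <- order(is.na(num), num, u)
  order(match(chrom, u[key]))
}

#' Read a single-cell dataset from standard on-disk formats
#'
#' Accepts either a 10x-style MatrixMarket triplet directory (`matrix.mtx`,
#' `barcodes.tsv`, `features.tsv`; the MTX is stored genes x cells as 10x
#' writes it) or a dense TSV with cells in rows and a header of gene ids.
#' Cell metadata comes from a tab-delimited table with a `cell_id` column;
#' matrix cells missing from the metadata are an error, metadata rows missing
#' from the matrix are dropped with a message.
#'
#' @param matrix_path Path to an MTX triplet directory or a dense TSV file.
#' @param meta_path Path to the cell metadata TSV.
#' @param gene_pos_path Optional path to a gene-position TSV with columns
#'   `gene_id`, `chrom`, `start`, `end`.
#' @return A [cell_dataset].
#' @export
read_cell_dataset <- function(matrix_path, meta_path, gene_pos_path = NULL) {
  if (dir.exists(matrix_path)) {
    mtx_file <- file.path(matrix_path, "matrix.mtx")
    bc_file <- file.path(matrix_path, "barcodes.tsv")
    ft_file <- file.path(matrix_path, "features.tsv")
    for (f in c(mtx_file, bc_file, ft_file)) {
      if (!file.exists(f)) stop("MTX triplet incomplete, missing ", basename(f))
    }
    counts <- tryCatch(Matrix::readMM(mtx_file), error = function(e) {
      stop("malformed MTX file: ", conditionMessage(e))
    })
    barcodes <- readr::read_tsv(bc_file, col_names = "cell_id", show_col_types = FALSE)
    features <- readr::read_tsv(ft_file, col_names = FALSE, show_col_types = FALSE)
    if (nrow(counts) != nrow(features) || ncol(counts) != nrow(barcodes)) {
      stop("malformed MTX triplet: dimensions disagree with barcodes/features")
    }
    counts <- Matrix::t(counts) # stored genes x cells, carrier is cells x genes
    dimnames(counts) <- list(barcodes$cell_id, features[[1]])
  } else {
    tab <- readr::read_tsv(matrix_path, show_col_types = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1]])
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  if (!"cell_id" %in% names(meta)) stop("metadata TSV lacks a cell_id column")
  gene_pos <- if (!is.null(gene_pos_path)) {
    readr::read_tsv(gene_pos_path, show_col_types = FALSE)
  }
  cell_dataset(counts, meta, gene_pos)
}

#' Write a single-cell dataset to disk
#'
#' @param ds A [cell_dataset].
#' @param dir Output directory (created if needed).
#' @param dialect `"mtx"` for a 10x-style triplet (genes x cells MatrixMarket
#'   plus `barcodes.tsv`/`features.tsv`) or `"tsv"` for a dense cells x genes
#'   table with a `cell_id` first column.
#' @return `dir`, invisibly. Writes `cell_meta.tsv` and, when present,
#'   `gene_pos.tsv` alongside the matrix.
#' @export
write_cell_dataset <- function(ds, dir, dialect = c("mtx", "tsv")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (dialect == "mtx") {
    m <- methods::as(
      methods::as(Matrix::t(Matrix::Matrix(ds$counts, sparse = TRUE)), "generalMatrix"),
      "CsparseMatrix"
    )
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    readr::write_tsv(tibble::tibble(x = rownames(ds$counts)),
      file.path(dir, "barcodes.tsv"),
      col_names = FALSE
    )
    readr::write_tsv(tibble::tibble(x = colnames(ds$counts)),
      file.path(dir, "features.tsv"),
      col_names = FALSE
    )
  } else {
    tab <- tibble::as_tibble(as.matrix(ds$counts))
    tab <- dplyr::bind_cols(tibble::tibble(cell_id = rownames(ds$counts)), tab)
    readr::write_tsv(tab, file.path(dir, "matrix.tsv"))
  }
  readr::write_tsv(ds$cell_meta, file.path(dir, "cell_meta.tsv"))
  if (!is.null(ds$gene_pos)) readr::write_tsv(ds$gene_pos, file.path(dir, "gene_pos.tsv"))
  invisible(dir)
}

#' Read and write GMT gene-set files
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Second-column description written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(
    names(sets),
    function(nm) paste(c(nm, description, sets[[nm]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}
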