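#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-gene statistics behind a signature
#'
#' @param x An `oncofetal_signature`.
#' @param signature_only Keep only the selected signature genes.
#' @param ... Unused.
#' @return A tibble with one row per gene.
#' @export
tidy.oncofetal_signature <- function(x, signature_only = FALSE, ...) {
  out <- x$stats
  if (signature_only) {
    out <- dplyr::arrange(dplyr::filter(out, !is.na(.data$rank)), .data$rank)
  }
  out
}

#' @rdname tidy.oncofetal_signature
#' @export
glance.oncofetal_signature <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_top = x$n_top,
    alpha = x$alpha,
    n_qualifying = sum(x$stats$qualifies, na.rm = TRUE),
    max_log2_fc = if (length(x$genes)) x$stats$log2_fc[match(x$genes[1], x$stats$gene)] else NA_real_
  )
}

#' Tidy a module assignment into one row per pseudobulk
#'
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @export
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(
    pseudobulk_id = names(x$labels),
    cluster = unname(x$labels),
    in_module = unname(x$labels) == x$module_id
  )
}

#' @rdname tidy.module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(unique(x$labels)),
    module_id = x$module_id,
    module_size = length(x$module_members),
    max_merge_height = max(x$linkage_summary)
  )
}

#' Tidy fetal-like classification results
#'
#' `tidy()` returns the per-cell table, `glance()` the cohort-level summary
#' (samples containing fetal-like cells, proportion range).
#'
#' @param x A `fetal_like_result`.
#' @param ... Unused.
#' @export
tidy.fetal_like_result <- function(x, ...) x$cells

#' @rdname tidy.fetal_like_result
#' @export
glance.fetal_like_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_with_fetal_like = sum(x$samples$contains_fetal_like),
    min_proportion = min(x$samples$proportion),
    max_proportion = max(x$samples$proportion),
    threshold = x$threshold,
    pct = x$pct
  )
}

#' Tidy a log-rank/KM result
#'
#' `tidy()` returns the KM step functions, `glance()` the test statistic.
#'
#' @param x A `logrank_km`.
#' @param ... Unused.
#' @export
tidy.logrank_km <- function(x, ...) x$curves

#' @rdname tidy.logrank_km
#' @export
glance.logrank_km <- function(x, ...) {
  tibble::tibble(
    chisq = x$chisq, df = x$df, p_value = x$p,
    observed_1 = x$observed[1], observed_2 = x$observed[2],
    expected_1 = x$expected[1], expected_2 = x$expected[2]
  )
}

#' Tidy a cutpoint split
#'
#' `tidy()` returns the candidate scan (when attached), `glance()` the
#' selected split.
#'
#' @param x A `cutpoint_split`.
#' @param ... Unused.
#' @export
tidy.cutpoint_split <- function(x, ...) {
  scan <- attr(x, "scan")
  if (is.null(scan)) {
    tibble::tibble(cutoff = x$cutoff, n_high = x$n_high, logrank_z = x$logrank_stat)
  } else {
    scan
  }
}

#' @rdname tidy.cutpoint_split
#' @export
glance.cutpoint_split <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, n_high = x$n_high, n_low = x$n_low,
    pct_high = x$pct_high, logrank_stat = x$logrank_stat, p_value = x$p
  )
}

#' Tidy a lineage-specificity result
#'
#' @param x A `lineage_specificity`.
#' @param ... Unused.
#' @export
tidy.lineage_specificity <- function(x, ...) x$counts

#' @rdname tidy.lineage_specificity
#' @export
glance.lineage_specificity <- function(x, ...) {
  tibble::tibble(
    gene = x$gene, k = x$k, n_top = nrow(x$top_lines),
    most_dependent_line = x$most_dependent_line,
    top_lineage = if (nrow(x$counts)) x$counts$lineage[1] else NA_character_,
    top_lineage_n = if (nrow(x$counts)) x$counts$n[1] else 0L
  )
}
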