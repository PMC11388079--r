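#' Configuration for the synthetic-data generators
#'
#' Pins every study condition the generators emulate: a multi-sample
#' single-cell cohort whose fetal epithelial cells and a planted fraction of
#' tumor epithelial cells share an up-regulated gene program, segmental CNVs
#' in malignant cells, a cell-line panel in which planted drivers track the
#' program and are strongly dependent, and a bulk survival cohort whose
#' hazard rises with the planted score.
#'
#' @param n_genes Number of genes; split evenly over two synthetic
#'   chromosomes so CNV windows meet a chromosome boundary.
#' @param samples Tibble describing the single-cell cohort: one row per
#'   sample x cell type with `sample_id`, `phenotype`, `cell_type`,
#'   `n_cells`. `NULL` uses the default plan (2 fetal, 2 normal, 1
#'   adjacent, 3 HCC, 1 HB samples with epithelial, endothelial and immune
#'   compartments).
#' @param module_genes Planted signature size, default 150.
#' @param module_log2fc Planted log2 fold change of the module in fetal and
#'   fetal-like cells, default 2 (4-fold).
#' @param fetal_like_fraction Fraction of malignant tumor epithelial cells
#'   carrying the module: a scalar applied to every tumor sample, or a
#'   named vector keyed by `sample_id`. The default gives each tumor
#'   sample its own high fraction (0.5-0.8), the regime in which tumor
#'   pseudobulks genuinely co-cluster with fetal ones.
#' @param tumor_benign_fraction Fraction of each tumor sample's epithelial
#'   cells that are benign admixture (no CNV, no module; own cluster
#'   label), default 0.2.
#' @param cnv_segments Tibble with `chrom`, `start_gene`, `length`,
#'   `fold_change` describing segmental CNVs planted in malignant cells;
#'   `NULL` plants four segments (gains of 2.0 and 1.5, one 0.5 loss, 500
#'   genes total) clear of the module and marker blocks. Pass a 0-row
#'   tibble for no CNVs.
#' @param marker_genes Genes per cell-type identity program planted in each
#'   non-epithelial cell type, default 100.
#' @param marker_log2fc Log2 fold change of the identity programs,
#'   default 2.
#' @param adult_genes Size of the adult hepatocyte maturation program,
#'   default 150: expressed by differentiated epithelium (normal and
#'   adjacent samples, and the benign admixture inside tumors) and lost by
#'   fetal and malignant cells — the dedifferentiation axis that makes
#'   tumors resemble fetal rather than adult liver.
#' @param adult_log2fc Log2 fold change of the maturation program,
#'   default 2.
#' @param nb_size Negative-binomial size (inverse dispersion), default 2.
#' @param mean_log_mu,mean_log_sd Log-normal parameters of per-gene baseline
#'   means, defaults -0.5 and 1.
#' @param libsize_log_sd Log-normal spread of per-cell size factors,
#'   default 0.3.
#' @param dropout Independent zero-inflation probability, default 0.1.
#' @param panel_lineages Named integer vector: cell lines per lineage.
#' @param liver_score_shift Mean shift of the liver-lineage oncofetal score
#'   above the pan-cancer baseline, default 1.5 standard deviations.
#' @param panel_genes Genes in the cell-line panel, default 500.
#' @param n_drivers Planted driver genes, default 3.
#' @param driver_dependency_mean Mean gene effect of drivers in
#'   high-score lines, default -0.8.
#' @param cohort_datasets Named integer vector: bulk samples per dataset.
#' @param cohort_genes Genes in the bulk cohort, default 500.
#' @param log_hr Log hazard ratio per unit of the true score, default 0.8.
#' @param baseline_hazard Baseline exponential hazard per month,
#'   default 0.02.
#' @param censor_rate Independent exponential censoring hazard per month,
#'   default 0.015.
#' @param covariate_effects Named numeric vector: additive effect on the
#'   true score per unit of each generated clinical covariate.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         samples = NULL,
                         module_genes = 150,
                         module_log2fc = 2,
                         fetal_like_fraction = c(HCC1 = 0.8, HCC2 = 0.6,
                                                 HCC3 = 0.5, HB1 = 0.7),
                         tumor_benign_fraction = 0.2,
                         cnv_segments = NULL,
                         marker_genes = 100,
                         marker_log2fc = 2,
                         adult_genes = 150,
                         adult_log2fc = 2,
                         nb_size = 2,
                         mean_log_mu = -0.5,
                         mean_log_sd = 1,
                         libsize_log_sd = 0.3,
                         dropout = 0.1,
                         panel_lineages = c(liver = 20, lung = 15, breast = 15, colon = 10),
                         liver_score_shift = 1.5,
                         panel_genes = 500,
                         n_drivers = 3,
                         driver_dependency_mean = -0.8,
                         cohort_datasets = c(dsA = 180, dsB = 120),
                         cohort_genes = 500,
                         log_hr = 0.8,
                         baseline_hazard = 0.02,
                         censor_rate = 0.015,
                         covariate_effects = c(grade = 0.5, stage = 0.3,
                                               fibrosis = 0.4, hbv = 0.3)) {
  if (is.null(samples)) samples <- default_sample_plan()
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "phenotype", "cell_type", "n_cells") %in% names(samples)))
  if (module_genes > n_genes) stop("module_genes exceeds n_genes")
  if (any(fetal_like_fraction < 0 | fetal_like_fraction > 1)) {
    stop("fetal_like_fraction in [0,1]")
  }
  if (tumor_benign_fraction < 0 || tumor_benign_fraction >= 1) {
    stop("tumor_benign_fraction in [0,1)")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout in [0,1)")
  if (is.null(cnv_segments)) {
    # placed clear of the module block (gene 1..module_genes on chr1) and of
    # the marker blocks (second half of chr2); scaled down for small genomes
    half <- n_genes %/% 2
    s <- function(x) as.integer(max(1, round(x * half / 1000)))
    cnv_segments <- tibble::tibble(
      chrom = c("chr1", "chr1", "chr2", "chr2"),
      start_gene = c(s(351), s(701), s(201), s(401)),
      length = c(s(150), s(100), s(150), s(100)),
      fold_change = c(2.0, 1.5, 0.5, 1.5)
    )
  }
  cnv_segments <- tibble::as_tibble(cnv_segments)
  if (any(cnv_segments$fold_change <= 0)) stop("fold changes must be positive")
  structure(
    list(
      n_genes = n_genes, samples = samples, module_genes = module_genes,
      module_log2fc = module_log2fc, fetal_like_fraction = fetal_like_fraction,
      tumor_benign_fraction = tumor_benign_fraction,
      marker_genes = marker_genes, marker_log2fc = marker_log2fc,
      adult_genes = adult_genes, adult_log2fc = adult_log2fc,
      cnv_segments = cnv_segments, nb_size = nb_size,
      mean_log_mu = mean_log_mu, mean_log_sd = mean_log_sd,
      libsize_log_sd = libsize_log_sd, dropout = dropout,
      panel_lineages = panel_lineages, liver_score_shift = liver_score_shift,
      panel_genes = panel_genes,
      n_drivers = n_drivers, driver_dependency_mean = driver_dependency_mean,
      cohort_datasets = cohort_datasets, cohort_genes = cohort_genes,
      log_hr = log_hr, baseline_hazard = baseline_hazard,
      censor_rate = censor_rate, covariate_effects = covariate_effects
    ),
    class = "synth_config"
  )
}

default_sample_plan <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(
      sample_id = c("FET1", "FET2"), phenotype = "fetal",
      tibble::tibble(cell_type = c("epithelial", "immune"), n_cells = c(80L, 20L))
    ),
    tidyr::expand_grid(
      sample_id = c("NOR1", "NOR2"), phenotype = "normal",
      tibble::tibble(
        cell_type = c("epithelial", "endothelial", "immune"),
        n_cells = c(80L, 30L, 20L)
      )
    ),
    tibble::tibble(
      sample_id = "ADJ1", phenotype = "adjacent",
      cell_type = "epithelial", n_cells = 60L
    ),
    tidyr::expand_grid(
      sample_id = c("HCC1", "HCC2", "HCC3"), phenotype = "tumor_HCC",
      tibble::tibble(
        cell_type = c("epithelial", "endothelial"), n_cells = c(100L, 20L)
      )
    ),
    tibble::tibble(
      sample_id = "HB1", phenotype = "tumor_HB",
      cell_type = "epithelial", n_cells = 60L
    )
  )
}

#' Generate a synthetic single-cell cohort with known ground truth
#'
#' Counts are negative binomial per gene with log-normal per-cell size
#' factors and independent zero-inflation, over two synthetic chromosomes
#' of equal gene count. Planted structure:
#'
#' * the first `module_genes` genes (start of chr1) form the oncofetal
#'   program, multiplied by `2^module_log2fc` in fetal epithelial cells and
#'   in the per-sample `fetal_like_fraction` of malignant tumor epithelial
#'   cells;
#' * the next `adult_genes` genes form the adult maturation program,
#'   expressed (`2^adult_log2fc`) by normal/adjacent epithelium and the
#'   benign admixture but not by fetal or malignant cells, so malignancy
#'   reads as dedifferentiation the way it does in real liver data;
#' * each non-epithelial cell type gets its own `marker_genes`-gene
#'   identity program (blocks in the second half of chr2) at
#'   `2^marker_log2fc`, so pseudobulk panels resolve by cell type the way
#'   real ones do;
#' * malignant cells carry the configured segmental CNVs (segment means
#'   scaled by the fold change before sampling); a `tumor_benign_fraction`
#'   of each tumor sample's epithelial cells is benign admixture with
#'   neither CNVs nor the program, carrying its own cluster label.
#'
#' Cluster labels are `sample_cellType`, with tumor epithelial cells split
#' into `_malignant` / `_benign`, so malignancy calling has planted
#' candidate units. The generator is a pure function of (config, seed).
#'
#' @param config A [synth_config].
#' @param seed Integer seed.
#' @return List with `dataset` (a [cell_dataset]) and `truth` (list:
#'   `module_genes`, `marker_genes` per cell type, per-cell
#'   `is_fetal_like` / `is_malignant` / `is_reference`,
#'   `cnv_segment_genes`, `cnv_segments`, `module_samples`, `sample_plan`).
#' @export
generate_single_cell <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(seed, {
    g <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    half <- g %/% 2
    chrom <- rep(c("chr1", "chr2"), times = c(half, g - half))
    within_idx <- c(seq_len(half), seq_len(g - half))
    gene_pos <- tibble::tibble(
      gene_id = gene_ids, chrom = chrom,
      start = within_idx * 1000L, end = within_idx * 1000L + 500L
    )

    plan <- config$samples
    cells <- plan[rep(seq_len(nrow(plan)), plan$n_cells), , drop = FALSE]
    n <- nrow(cells)
    cell_ids <- sprintf("c%05d", seq_len(n))
    tumor_phen <- c("tumor_HCC", "tumor_HB", "tumor_ICC")
    is_epi <- cells$cell_type == "epithelial"
    is_tumor_epi <- is_epi & cells$phenotype %in% tumor_phen

    # benign admixture inside tumor epithelium
    benign <- is_tumor_epi & stats::runif(n) < config$tumor_benign_fraction
    malignant <- is_tumor_epi & !benign

    frac <- config$fetal_like_fraction
    cell_frac <- if (is.null(names(frac))) {
      rep(frac[1], n)
    } else {
      out <- rep(0, n)
      hit <- cells$sample_id %in% names(frac)
      out[hit] <- frac[cells$sample_id[hit]]
      out
    }
    fetal_like <- (is_epi & cells$phenotype == "fetal") |
      (malignant & stats::runif(n) < cell_frac)

    cluster <- paste(cells$sample_id, cells$cell_type, sep = "_")
    cluster[malignant] <- paste0(cluster[malignant], "_malignant")
    cluster[benign] <- paste0(cluster[benign], "_benign")
    meta <- tibble::tibble(
      cell_id = cell_ids,
      sample_id = cells$sample_id,
      phenotype = cells$phenotype,
      cell_type = cells$cell_type,
      cluster = cluster
    )

    base_mu <- stats::rlnorm(g, config$mean_log_mu, config$mean_log_sd)
    size_factor <- stats::rlnorm(n, 0, config$libsize_log_sd)
    module <- gene_ids[seq_len(config$module_genes)]

    # cell-type identity blocks in the second half of chr2
    other_types <- setdiff(unique(cells$cell_type), "epithelial")
    marker_map <- list()
    marker_start <- half + (g - half) %/% 2
    for (k in seq_along(other_types)) {
      lo <- marker_start + (k - 1) * config$marker_genes + 1
      hi <- min(lo + config$marker_genes - 1, g)
      marker_map[[other_types[k]]] <-
        if (config$marker_genes == 0 || lo > g) character(0) else gene_ids[seq(lo, hi)]
    }

    # per-gene CNV multiplier for malignant cells
    cnv_mult <- rep(1, g)
    seg_genes <- character(0)
    for (i in seq_len(nrow(config$cnv_segments))) {
      seg <- config$cnv_segments[i, ]
      idx <- which(gene_pos$chrom == seg$chrom)
      idx <- idx[seq(seg$start_gene, min(seg$start_gene + seg$length - 1, length(idx)))]
      cnv_mult[idx] <- seg$fold_change
      seg_genes <- c(seg_genes, gene_ids[idx])
    }

    mu <- outer(size_factor, base_mu)
    mod_cols <- seq_len(config$module_genes)
    mu[fetal_like, mod_cols] <- mu[fetal_like, mod_cols] * 2^config$module_log2fc
    adult_cols <- integer(0)
    if (config$adult_genes > 0) {
      adult_cols <- config$module_genes + seq_len(config$adult_genes)
      stopifnot(max(adult_cols) <= g)
      mature <- (is_epi & cells$phenotype %in% c("normal", "adjacent")) | benign
      mu[mature, adult_cols] <- mu[mature, adult_cols] * 2^config$adult_log2fc
    }
    for (ct in names(marker_map)) {
      colsx <- match(marker_map[[ct]], gene_ids)
      if (!length(colsx)) next
      rows <- cells$cell_type == ct
      mu[rows, colsx] <- mu[rows, colsx] * 2^config$marker_log2fc
    }
    mu[malignant, ] <- sweep(mu[malignant, , drop = FALSE], 2, cnv_mult, "*")

    counts <- matrix(
      stats::rnbinom(n * g, mu = as.vector(mu), size = config$nb_size),
      nrow = n, ncol = g
    )
    if (config$dropout > 0) {
      counts[matrix(stats::runif(n * g) < config$dropout, n, g)] <- 0L
    }
    dimnames(counts) <- list(cell_ids, gene_ids)

    truth <- list(
      module_genes = module,
      adult_genes = gene_ids[adult_cols],
      marker_genes = marker_map,
      is_fetal_like = stats::setNames(fetal_like, cell_ids),
      is_malignant = stats::setNames(malignant, cell_ids),
      is_reference = stats::setNames(
        (is_epi & cells$phenotype == "normal") | cells$cell_type == "endothelial",
        cell_ids
      ),
      cnv_segment_genes = seg_genes,
      cnv_segments = config$cnv_segments,
      module_samples = unique(cells$sample_id[
        (is_epi & cells$phenotype == "fetal") | (is_tumor_epi & cell_frac > 0)
      ]),
      sample_plan = plan
    )
    list(dataset = cell_dataset(counts, meta, gene_pos), truth = truth)
  })
}

#' Generate a synthetic cell-line panel with planted drivers
#'
#' Per-line oncofetal scores are normal with the liver lineage shifted up
#' by `liver_score_shift`. The first `n_drivers` panel genes are drivers:
#' their log2-TPM is an affine function of the line score plus noise, and
#' their dependency is `Normal(driver_dependency_mean, 0.1)` in high-score
#' lines (score above 0, the non-liver baseline mean) and `Normal(0, 0.1)`
#' elsewhere. Non-driver expression and dependency are independent of the
#' score.
#'
#' @param config A [synth_config].
#' @param seed Integer seed.
#' @param driver_noise_sd Noise SD on driver log2 expression, default 0.3.
#' @return List with `panel` (a [cell_line_panel]), `line_scores` (planted
#'   per-line score) and `truth` (`driver_genes`).
#' @export
generate_cell_line_panel <- function(config, seed = 1L, driver_noise_sd = 0.3) {
  stopifnot(inherits(config, "synth_config"), config$n_drivers >= 1)
  withr::with_seed(seed, {
    lineages <- rep(names(config$panel_lineages), config$panel_lineages)
    n <- length(lineages)
    line_ids <- sprintf("%s_%02d", toupper(lineages), stats::ave(
      seq_len(n), lineages, FUN = seq_along
    ))
    score <- stats::rnorm(n) + ifelse(lineages == "liver", config$liver_score_shift, 0)
    g <- config$panel_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    drivers <- gene_ids[seq_len(config$n_drivers)]

    log_expr <- matrix(stats::rnorm(n * g, mean = 2, sd = 1), n, g)
    for (j in seq_len(config$n_drivers)) {
      log_expr[, j] <- 2 + score + stats::rnorm(n, 0, driver_noise_sd)
    }
    expression <- pmax(2^log_expr - 1, 0)
    dimnames(expression) <- list(line_ids, gene_ids)

    dependency <- matrix(stats::rnorm(n * g, 0, 0.1), n, g)
    high <- score > 0
    for (j in seq_len(config$n_drivers)) {
      dependency[high, j] <- stats::rnorm(sum(high), config$driver_dependency_mean, 0.1)
    }
    dimnames(dependency) <- list(line_ids, gene_ids)

    panel <- cell_line_panel(
      expression, dependency,
      tibble::tibble(line_id = line_ids, lineage = lineages)
    )
    list(
      panel = panel,
      line_scores = stats::setNames(score, line_ids),
      truth = list(driver_genes = drivers)
    )
  })
}

#' Generate a synthetic bulk survival cohort
#'
#' Per-sample true scores are standard normal; each dataset adds its own
#' global shift to the expression values (exercising the within-dataset
#' standardization and the dataset covariate). Clinical covariates are
#' drawn first (grade 1-4, stage 1-3, fibrosis and HBV 0/1) and contribute
#' `covariate_effects` to the true score. Expression of the first
#' `module_genes` cohort genes equals the true score plus noise; other
#' genes are independent noise. Survival is exponential with log-hazard
#' `log(baseline_hazard) + log_hr * true_score`, censored by an independent
#' exponential at `censor_rate` truncated at 120 months.
#'
#' @param config A [synth_config].
#' @param seed Integer seed.
#' @param expr_noise_sd Noise SD on signature-gene expression, default 0.5.
#' @return List with `cohort` (a [bulk_cohort]) and `truth`
#'   (`signature_genes`, per-sample `true_score`, `log_hr`).
#' @export
generate_bulk_cohort <- function(config, seed = 1L, expr_noise_sd = 0.5) {
  stopifnot(inherits(config, "synth_config"), length(config$cohort_datasets) >= 2)
  withr::with_seed(seed, {
    datasets <- rep(names(config$cohort_datasets), config$cohort_datasets)
    n <- length(datasets)
    sample_ids <- sprintf("s%04d", seq_len(n))
    ds_shift <- stats::setNames(
      seq_along(config$cohort_datasets) - 1,
      names(config$cohort_datasets)
    )

    grade <- sample(1:4, n, replace = TRUE)
    stage <- sample(1:3, n, replace = TRUE)
    fibrosis <- stats::rbinom(n, 1, 0.5)
    hbv <- stats::rbinom(n, 1, 0.5)
    eff <- config$covariate_effects
    true_score <- stats::rnorm(n) +
      eff[["grade"]] * (grade - mean(grade)) +
      eff[["stage"]] * (stage - mean(stage)) +
      eff[["fibrosis"]] * (fibrosis - mean(fibrosis)) +
      eff[["hbv"]] * (hbv - mean(hbv))

    g <- config$cohort_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    n_sig <- min(config$module_genes, g)
    expr <- matrix(stats::rnorm(n * g), n, g)
    expr[, seq_len(n_sig)] <- true_score +
      matrix(stats::rnorm(n * n_sig, 0, expr_noise_sd), n, n_sig)
    expr <- expr + ds_shift[datasets]
    dimnames(expr) <- list(sample_ids, gene_ids)

    hazard <- config$baseline_hazard * exp(config$log_hr * scale(true_score)[, 1])
    event_time <- stats::rexp(n, rate = hazard)
    censor_time <- if (config$censor_rate > 0) {
      pmin(stats::rexp(n, rate = config$censor_rate), 120)
    } else {
      rep(120, n)
    }
    time <- pmin(event_time, censor_time)
    event <- as.integer(event_time <= censor_time)

    cohort <- bulk_cohort(
      expr,
      tibble::tibble(
        sample_id = sample_ids, dataset = datasets,
        grade = grade, stage = stage, fibrosis = fibrosis, hbv = hbv
      ),
      tibble::tibble(sample_id = sample_ids, time = time, event = event)
    )
    list(
      cohort = cohort,
      truth = list(
        signature_genes = gene_ids[seq_len(n_sig)],
        true_score = stats::setNames(true_score, sample_ids),
        log_hr = config$log_hr
      )
    )
  })
}
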