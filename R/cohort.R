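#' Bulk cohort carrier
#'
#' @param expression Matrix, samples x genes, log-scale expression.
#' @param clinical Data frame with `sample_id`, `dataset` (source label) and
#'   clinical covariates (ordinal covariates coded as integers, binary as
#'   0/1).
#' @param survival Data frame with `sample_id`, `time` (months, > 0) and
#'   `event` (0/1).
#' @return An object of class `bulk_cohort`.
#' @export
bulk_cohort <- function(expression, clinical, survival) {
  stopifnot(is.matrix(expression))
  clinical <- tibble::as_tibble(clinical)
  survival <- tibble::as_tibble(survival)
  stopifnot(all(c("sample_id", "dataset") %in% names(clinical)))
  stopifnot(all(c("sample_id", "time", "event") %in% names(survival)))
  if (any(is.na(clinical$dataset)) || any(clinical$dataset == "")) {
    stop("every sample needs a nonempty dataset label")
  }
  if (any(survival$time <= 0)) stop("survival times must be positive")
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0/1")
  if (!setequal(rownames(expression), clinical$sample_id)) {
    stop("expression rownames and clinical sample_id must match")
  }
  clinical <- clinical[match(rownames(expression), clinical$sample_id), , drop = FALSE]
  survival <- survival[match(rownames(expression), survival$sample_id), , drop = FALSE]
  structure(
    list(expression = expression, clinical = clinical, survival = survival),
    class = "bulk_cohort"
  )
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf(
    "<bulk_cohort> %d samples x %d genes; datasets: %s; %d events\n",
    nrow(x$expression), ncol(x$expression),
    paste(unique(x$clinical$dataset), collapse = ", "),
    sum(x$survival$event)
  ))
  invisible(x)
}

#' Oncofetal score per bulk sample
#'
#' Mean z-score over signature genes, standardized per gene WITHIN each
#' dataset and then concatenated, which removes additive source shifts at
#' the scoring stage (the dataset covariate in [clinical_association]
#' guards the regression stage as well). Genes with zero variance within a
#' dataset are excluded there with a warning.
#'
#' @param cohort A [bulk_cohort].
#' @param sig An `oncofetal_signature` or character vector of genes.
#' @return Tibble with `sample_id`, `dataset`, `score`.
#' @export
score_bulk_samples <- function(cohort, sig) {
  genes <- intersect(signature_genes(sig), colnames(cohort$expression))
  if (!length(genes)) stop("no signature gene present in the cohort")
  out <- purrr::map_dfr(unique(cohort$clinical$dataset), function(ds) {
    idx <- which(cohort$clinical$dataset == ds)
    m <- cohort$expression[idx, genes, drop = FALSE]
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("%d zero-variance gene(s) excluded in dataset %s", sum(sds == 0), ds))
      m <- m[, sds > 0, drop = FALSE]
    }
    tibble::tibble(
      sample_id = rownames(m),
      dataset = ds,
      score = unname(rowMeans(scale(m)))
    )
  })
  out[match(rownames(cohort$expression), out$sample_id), , drop = FALSE]
}

#' Covariate association of the oncofetal score, adjusted for data source
#'
#' Ordinary least squares of the per-sample score on each clinical
#' parameter with dataset indicator covariates; one row per parameter with
#' the parameter coefficient, its 95% confidence interval (exact t-based
#' under the Gaussian error model, as `confint()` reports), two-sided
#' p-value, and BH adjustment across the requested parameters.
#' Parameters constant within every dataset are inestimable and returned
#' flagged with `NA` statistics.
#'
#' @param scores Tibble from [score_bulk_samples] (or any tibble with
#'   `sample_id` and `score`).
#' @param cohort A [bulk_cohort].
#' @param parameters Character vector of clinical column names; ordinal
#'   covariates must be integer-coded, binary 0/1.
#' @param conf_level Confidence level, default 0.95.
#' @return Tibble with `parameter`, `n`, `estimate`, `conf_low`,
#'   `conf_high`, `p_value`, `p_adjusted`, `estimable`.
#' @export
clinical_association <- function(scores, cohort, parameters, conf_level = 0.95) {
  dat <- dplyr::left_join(scores, cohort$clinical, by = c("sample_id", "dataset"))
  multi_ds <- dplyr::n_distinct(dat$dataset) > 1
  rows <- purrr::map_dfr(parameters, function(p) {
    if (!p %in% names(dat)) stop("unknown clinical parameter: ", p)
    d <- dat[!is.na(dat[[p]]), , drop = FALSE]
    if (dplyr::n_distinct(d[[p]]) < 2 ||
        all(tapply(d[[p]], d$dataset, function(v) dplyr::n_distinct(v)) < 2)) {
      return(tibble::tibble(
        parameter = p, n = nrow(d), estimate = NA_real_, conf_low = NA_real_,
        conf_high = NA_real_, p_value = NA_real_, estimable = FALSE
      ))
    }
    form <- if (multi_ds) {
      stats::as.formula(sprintf("score ~ `%s` + factor(dataset)", p))
    } else {
      stats::as.formula(sprintf("score ~ `%s`", p))
    }
    fit <- stats::lm(form, data = d)
    est <- summary(fit)$coefficients[2, ]
    zq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
    tibble::tibble(
      parameter = p, n = nrow(d), estimate = est[["Estimate"]],
      conf_low = est[["Estimate"]] - zq * est[["Std. Error"]],
      conf_high = est[["Estimate"]] + zq * est[["Std. Error"]],
      p_value = est[["Pr(>|t|)"]], estimable = TRUE
    )
  })
  rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "BH")
  rows
}

# ---- log-rank / Kaplan-Meier kernel -----------------------------------------

# Precompute the parts of the two-group log-rank statistic that do not
# depend on group membership; logrank_stat_z then costs a few vectorized
# passes per evaluation, which the cutpoint scan and its permutation null
# rely on.
logrank_precompute <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- as.integer(event[ord])
  n <- length(time)
  # tie groups over sorted times
  grp_start <- which(c(TRUE, time[-1] != time[-n]))
  grp_end <- c(grp_start[-1] - 1L, n)
  ev_cum <- cumsum(event)
  d <- ev_cum[grp_end] - c(0L, ev_cum[grp_end])[seq_along(grp_end)]
  keep <- d > 0 # only event times contribute
  list(
    ord = ord, n = n, event = event,
    grp_start = grp_start[keep], grp_end = grp_end[keep],
    d = d[keep],
    n_risk = n - grp_start[keep] + 1L
  )
}

# Standardized two-group log-rank statistic U/sqrt(V) for group indicator z
# (TRUE = group 1), ties handled by the simultaneous-event convention.
logrank_stat_z <- function(z, pc) {
  zs <- as.integer(z[pc$ord])
  rc <- rev(cumsum(rev(zs))) # group-1 at risk from each sorted position
  n1 <- rc[pc$grp_start]
  cz <- cumsum(zs * pc$event)
  d1 <- cz[pc$grp_end] - c(0L, cz)[pc$grp_start]
  frac <- n1 / pc$n_risk
  U <- sum(d1 - pc$d * frac)
  ok <- pc$n_risk > 1
  V <- sum((pc$d * frac * (1 - frac) * (pc$n_risk - pc$d) / (pc$n_risk - 1))[ok])
  if (V <= 0) return(c(U = U, V = V, z = 0))
  c(U = U, V = V, z = U / sqrt(V))
}

#' Two-group log-rank test and Kaplan-Meier curves
#'
#' Standard two-group log-rank chi-square statistic (1 df, ties handled by
#' the simultaneous-event convention) with the right-censored Kaplan-Meier
#' estimator per group, emitted as step-function tables.
#'
#' @param groups Binary labels, one per sample (logical, or any
#'   two-level vector).
#' @param time Positive follow-up times.
#' @param event Event indicator, 0 censored / 1 event.
#' @return An object of class `logrank_km`: list with `chisq`, `df`, `p`,
#'   `observed`/`expected` per group, and `curves` (tibble with `group`,
#'   `time`, `n_risk`, `n_event`, `survival`).
#' @export
logrank_km <- function(groups, time, event) {
  stopifnot(length(groups) == length(time), length(time) == length(event))
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two nonempty groups required")
  z <- groups == lev[2]
  if (sum(event) == 0) {
    warning("no events in either group; statistic is 0")
  } else if (any(tapply(event, groups, sum) == 0)) {
    warning("a group has zero events")
  }
  pc <- logrank_precompute(time, event)
  st <- logrank_stat_z(z, pc)
  chisq <- unname(st["z"]^2)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  curves <- purrr::map_dfr(lev, function(g) {
    km <- km_curve(time[groups == g], event[groups == g])
    dplyr::bind_cols(tibble::tibble(group = g), km)
  })
  o1 <- sum(event[z])
  e1 <- o1 - unname(st["U"])
  structure(
    list(
      chisq = chisq, df = 1L, p = p,
      groups = lev,
      observed = c(sum(event[!z]), o1),
      expected = c(sum(event) - e1, e1),
      curves = curves
    ),
    class = "logrank_km"
  )
}

#' @export
print.logrank_km <- function(x, ...) {
  cat(sprintf(
    "<logrank_km> chisq = %.4g on %d df, p = %.3g (groups %s vs %s)\n",
    x$chisq, x$df, x$p, x$groups[1], x$groups[2]
  ))
  invisible(x)
}

#' Kaplan-Meier estimator for one group
#'
#' @param time Positive follow-up times.
#' @param event Event indicator, 0/1.
#' @return Tibble of the step function at distinct event times (`time`,
#'   `n_risk`, `n_event`, `survival`), survival 1 before the first event.
#' @export
km_curve <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  n <- length(time)
  ut <- unique(time[event == 1])
  if (!length(ut)) {
    return(tibble::tibble(
      time = numeric(), n_risk = integer(), n_event = integer(), survival = numeric()
    ))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), integer(1))
  tibble::tibble(
    time = ut, n_risk = n_risk, n_event = n_event,
    survival = cumprod(1 - n_event / n_risk)
  )
}

# ---- optimal cutpoint -------------------------------------------------------

#' Cutpoint split summary
#'
#' Constructor for the result of a high/low split of a scored cohort; used
#' by [optimal_cutpoint] and directly when group sizes come from an
#' external report.
#'
#' @param cutoff Score threshold (samples strictly above are "high").
#' @param n_high,n_low Group sizes.
#' @param logrank_stat Standardized log-rank statistic at the split
#'   (optional).
#' @param p P-value for the split (optional).
#' @return An object of class `cutpoint_split` with `pct_high`
#'   (= `round(100 * n_high / (n_high + n_low))`).
#' @export
cutpoint_split <- function(cutoff = NA_real_, n_high, n_low,
                           logrank_stat = NA_real_, p = NA_real_) {
  stopifnot(n_high >= 0, n_low >= 0, n_high + n_low > 0)
  structure(
    list(
      cutoff = cutoff, n_high = as.integer(n_high), n_low = as.integer(n_low),
      pct_high = as.integer(round(100 * n_high / (n_high + n_low))),
      logrank_stat = logrank_stat, p = p
    ),
    class = "cutpoint_split"
  )
}

#' @export
print.cutpoint_split <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_split> cutoff %.4g: %d high (%d%%) vs %d low; |log-rank z| = %.4g, p = %.3g\n",
    x$cutoff, x$n_high, x$pct_high, x$n_low, x$logrank_stat, x$p
  ))
  invisible(x)
}

#' Maximally selected survival cutpoint with a permutation p-value
#'
#' Scans every distinct score value as a candidate cutoff (samples strictly
#' above the cutoff form the high group) subject to both groups holding at
#' least `min_prop` of the samples, computes the standardized two-group
#' log-rank statistic at each, and returns the cutoff maximizing the
#' absolute statistic (ties broken toward the lower cutoff). Because the
#' maximum over cutoffs inflates the naive log-rank p-value, significance
#' is assessed by permuting scores against the fixed survival data
#' (`n_perm` permutations, seed-controlled) and comparing the observed
#' maximal statistic with the permutation maxima.
#'
#' @param scores Per-sample scores: a numeric vector or the tibble from
#'   [score_bulk_samples].
#' @param time,event Survival outcome aligned with `scores`.
#' @param min_prop Minimum group fraction, default 0.1.
#' @param n_perm Permutations for the p-value, default 1000.
#' @param seed Seed for the permutation draw.
#' @return A [cutpoint_split] with the permutation `p` and an extra
#'   `scan` tibble (cutoff, n_high, logrank z) attached.
#' @export
optimal_cutpoint <- function(scores, time, event, min_prop = 0.1,
                             n_perm = 1000, seed = 1L) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$sample_id)
  stopifnot(min_prop > 0, min_prop < 0.5)
  if (sum(event) < 2) stop("need at least 2 events")
  n <- length(scores)
  pc <- logrank_precompute(time, event)
  min_n <- ceiling(min_prop * n)

  scan_stats <- function(s) {
    cand <- sort(unique(s))
    n_high <- vapply(cand, function(cc) sum(s > cc), integer(1))
    keep <- n_high >= min_n & (n - n_high) >= min_n
    cand <- cand[keep]
    if (!length(cand)) return(NULL)
    zst <- vapply(cand, function(cc) logrank_stat_z(s > cc, pc)["z"], numeric(1))
    list(cutoff = cand, n_high = n_high[keep], z = zst)
  }

  obs <- scan_stats(scores)
  if (is.null(obs)) stop("no candidate cutoff satisfies min_prop = ", min_prop)
  best <- which.max(abs(obs$z)) # ties: which.max takes the first = lowest cutoff
  obs_max <- abs(obs$z[best])

  perm_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      sb <- scan_stats(sample(scores))
      if (is.null(sb)) return(0) # cannot happen: same multiset of scores
      max(abs(sb$z))
    }, numeric(1))
  })
  p <- (1 + sum(perm_max >= obs_max)) / (1 + n_perm)

  out <- cutpoint_split(
    cutoff = obs$cutoff[best],
    n_high = obs$n_high[best],
    n_low = n - obs$n_high[best],
    logrank_stat = obs$z[best],
    p = p
  )
  attr(out, "scan") <- tibble::tibble(
    cutoff = obs$cutoff, n_high = obs$n_high, logrank_z = obs$z
  )
  attr(out, "n_perm") <- n_perm
  out
}
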