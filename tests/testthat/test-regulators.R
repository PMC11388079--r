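toy_panel <- function() {
  expr <- rbind(
    L1 = c(10, 1, 3), L2 = c(2, 1, 3), L3 = c(6, 1, 3), L4 = c(4, 1, 3)
  )
  colnames(expr) <- c("gA", "gFlat", "gB")
  dep <- matrix(rnorm(12, 0, 0.05), 4, 3, dimnames = dimnames(expr))
  cell_line_panel(expr, dep, tibble::tibble(
    line_id = rownames(expr), lineage = c("liver", "liver", "lung", "lung")
  ))
}

test_that("cell-line scores are per-gene z-means with degenerate genes excluded", {
  set.seed(1)
  panel <- toy_panel()
  expect_warning(s <- score_cell_lines(panel, c("gA", "gFlat")), "zero-variance")
  lx <- log2(panel$expression[, "gA"] + 1)
  expect_equal(unname(s), unname((lx - mean(lx)) / sd(lx)))

  # two lines, one uniformly 1 SD above the mean -> scores (+1, -1) x (1/sqrt(2))...
  # with n=2 the sample z-scores are +-1/sqrt(2)*sqrt(2) = +-0.707*...: check symmetry
  expr2 <- rbind(hi = c(3, 7), lo = c(1, 3))
  colnames(expr2) <- c("g1", "g2")
  dep2 <- expr2 * 0
  p2 <- cell_line_panel(expr2, dep2, tibble::tibble(line_id = c("hi", "lo"), lineage = "liver"))
  s2 <- score_cell_lines(p2, c("g1", "g2"))
  expect_equal(unname(s2["hi"]), -unname(s2["lo"]))
  expect_gt(s2[["hi"]], 0)

  # oracle: naive per-gene z then mean
  cfg <- synth_config(panel_genes = 60)
  pan <- generate_cell_line_panel(cfg, seed = 2)
  genes <- sprintf("g%04d", 5:20)
  s3 <- score_cell_lines(pan$panel, genes)
  lx3 <- log2(pan$panel$expression[, genes] + 1)
  oracle <- rowMeans(apply(lx3, 2, function(v) (v - mean(v)) / sd(v)))
  expect_equal(unname(s3), unname(oracle), tolerance = 1e-10)
})

test_that("regulator filtering and ranking follow the joint criteria", {
  set.seed(3)
  n <- 12
  score <- rnorm(n)
  expr <- cbind(
    driver = 2^(2 + score) - 1,
    flat = rep(3, n),
    noise = runif(n, 0, 5)
  )
  rownames(expr) <- sprintf("L%02d", 1:n)
  dep <- cbind(driver = rnorm(n, -0.8, 0.05), flat = rnorm(n, 0, 0.05),
               noise = rnorm(n, 0, 0.05))
  rownames(dep) <- rownames(expr)
  panel <- cell_line_panel(expr, dep, tibble::tibble(
    line_id = rownames(expr), lineage = "liver"
  ))
  rt <- associate_regulators(panel, stats::setNames(score, rownames(expr)),
                             rbp_set = "driver", r_min = 0.5, dep_max = -0.4)
  expect_true(rt$passes_filter[rt$gene == "driver"])
  expect_equal(rt$rank[rt$gene == "driver"], 1L)
  expect_true(rt$is_rbp[rt$gene == "driver"])
  # flat expression: r undefined -> 0, cannot pass
  expect_equal(rt$r_oncofetal[rt$gene == "flat"], 0)
  expect_false(rt$passes_filter[rt$gene == "flat"])
  expect_error(associate_regulators(
    cell_line_panel(expr[1:2, ], dep[1:2, ], tibble::tibble(
      line_id = rownames(expr)[1:2], lineage = "liver"
    )), score[1:2]
  ), "at least 3")
})

test_that("genes without dependency data are kept but unranked", {
  set.seed(4)
  panel <- toy_panel()
  panel$dependency[, "gB"] <- NA_real_
  rt <- associate_regulators(panel, stats::setNames(rnorm(4), rownames(panel$expression)))
  row <- rt[rt$gene == "gB", ]
  expect_false(row$has_dependency)
  expect_true(is.na(row$rank))
  expect_false(row$passes_filter)
})

test_that("planted drivers rank at the top of the liver-line table across seeds", {
  cfg <- synth_config()
  for (seed in c(61, 62, 63)) {
    pan <- generate_cell_line_panel(cfg, seed = seed)
    liver <- subset_panel(pan$panel, lineage = "liver")
    rt <- associate_regulators(liver, pan$line_scores[rownames(liver$expression)])
    top5 <- rt$gene[!is.na(rt$rank) & rt$rank <= 5]
    expect_true(all(pan$truth$driver_genes %in% top5), info = paste("seed", seed))
  }
})

test_that("regulator ranking is invariant to gene and line order", {
  cfg <- synth_config(panel_genes = 80)
  pan <- generate_cell_line_panel(cfg, seed = 6)
  rt <- associate_regulators(pan$panel, pan$line_scores)
  gperm <- withr::with_seed(1, sample(ncol(pan$panel$expression)))
  lperm <- withr::with_seed(2, sample(nrow(pan$panel$expression)))
  panel_p <- cell_line_panel(
    pan$panel$expression[lperm, gperm],
    pan$panel$dependency[lperm, gperm],
    pan$panel$line_meta[lperm, ]
  )
  rt_p <- associate_regulators(panel_p, pan$line_scores[rownames(panel_p$expression)])
  merged <- dplyr::left_join(rt, rt_p, by = "gene", suffix = c("", "_p"))
  expect_equal(merged$r_oncofetal, merged$r_oncofetal_p, tolerance = 1e-12)
  expect_equal(merged$rank, merged$rank_p)
})

test_that("null panels pass the filter at no more than the Pearson null tail", {
  r_min <- 0.5
  hits <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 20
      g <- 150
      expr <- matrix(2^rnorm(n * g, 2, 1), n, g,
                     dimnames = list(sprintf("L%02d", 1:n), sprintf("g%03d", 1:g)))
      panel <- cell_line_panel(expr, expr * 0, tibble::tibble(
        line_id = rownames(expr), lineage = "liver"
      ))
      rt <- associate_regulators(panel, stats::setNames(rnorm(n), rownames(expr)),
                                 r_min = r_min)
      mean(abs(rt$r_oncofetal) >= r_min)
    })
  }, numeric(1))
  # two-sided Pearson tail for n = 20 from the exact t transform
  r_null <- 2 * stats::pt(r_min * sqrt(18) / sqrt(1 - r_min^2), df = 18, lower.tail = FALSE)
  expect_lte(mean(hits), 2 * r_null)
})

test_that("lineage specificity counts the most dependent expressing lines", {
  # 4 liver lines hold the most negative dependencies among 12 qualifiers,
  # mirroring a 4-of-10 top composition
  expr <- matrix(5, 14, 2, dimnames = list(sprintf("L%02d", 1:14), c("gX", "gY")))
  expr[13:14, "gX"] <- 0.5 # fail the TPM gate
  dep <- matrix(0, 14, 2, dimnames = dimnames(expr))
  dep[1:4, "gX"] <- c(-0.9, -0.85, -0.8, -0.75)
  dep[5:12, "gX"] <- seq(-0.6, -0.1, length.out = 8)
  dep[13:14, "gX"] <- -2 # most dependent but not expressed
  meta <- tibble::tibble(
    line_id = rownames(expr),
    lineage = c(rep("liver", 4), rep("other", 10))
  )
  panel <- cell_line_panel(expr, dep, meta)
  ls <- lineage_specificity(panel, "gX", tpm_min = 1, k = 10)
  expect_equal(ls$counts$n[ls$counts$lineage == "liver"], 4L)
  expect_equal(sum(ls$counts$n), 10L)
  expect_equal(ls$most_dependent_line, "L01")

  # k larger than qualifiers -> clamp with warning
  expect_warning(ls2 <- lineage_specificity(panel, "gX", k = 13), "qualifying")
  expect_equal(sum(ls2$counts$n), 12L)
  expect_warning(ls3 <- lineage_specificity(panel, "gX", tpm_min = 100), "no line")
  expect_equal(nrow(ls3$counts), 0L)
})

test_that("lineage counts match a brute-force sort on a random panel", {
  cfg <- synth_config()
  pan <- generate_cell_line_panel(cfg, seed = 8)
  g <- pan$truth$driver_genes[2]
  ls <- lineage_specificity(pan$panel, g, tpm_min = 1, k = 10)
  expr <- pan$panel$expression[, g]
  dep <- pan$panel$dependency[, g]
  qual <- names(expr)[expr > 1 & !is.na(dep)]
  top <- qual[order(dep[qual])][1:min(10, length(qual))]
  lin <- pan$panel$line_meta$lineage[match(top, pan$panel$line_meta$line_id)]
  oracle <- sort(table(lin), decreasing = TRUE)
  got <- stats::setNames(ls$counts$n, ls$counts$lineage)
  expect_equal(got[order(names(got))], c(oracle)[order(names(oracle))],
               ignore_attr = TRUE)
  expect_equal(sum(ls$counts$n), min(10, length(qual)))
})
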