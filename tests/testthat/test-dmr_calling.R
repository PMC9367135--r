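test_that("cell-effect ANOVA reproduces the hand-computed worked example", {
  s <- sample_sheet(c("c1", "c2", "c3"), c("a1", "a2"))
  rates <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.8, 0.7), s$sample_id)
  res <- cell_effect_anova(rates, s)
  expect_equal(res$F_cell, 28, tolerance = 1e-10)
  expect_equal(res$df_num, 2L)
  expect_equal(res$df_den, 2L)
  expect_equal(res$p_cell, 1 / 29, tolerance = 1e-6)

  # constant response
  res0 <- cell_effect_anova(setNames(rep(0.5, 6), s$sample_id), s)
  expect_equal(res0$F_cell, 0)
  expect_equal(res0$p_cell, 1)

  # exactly additive cell + animal structure: SSE = 0, exact fit
  add <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), s$sample_id)
  resa <- cell_effect_anova(add, s)
  expect_true(resa$exact_fit)
  expect_equal(resa$p_cell, 1e-300)
})

test_that("extra-sum-of-squares F equals the classical balanced ANOVA F", {
  set.seed(31)
  s <- sample_sheet(pig_immune_cells(), c("A1", "A2"))
  for (rep in 1:20) {
    y <- setNames(runif(18), s$sample_id)
    got <- cell_effect_anova(y, s)
    want <- oracle_balanced_anova_F(unname(y), s$cell_type, s$animal)
    expect_lt(abs(got$F_cell - want), 1e-8)
    expect_equal(got$df_num, 8L)
    expect_equal(got$df_den, 8L)
  }
})

test_that("ANOVA handles missing cells and degenerate designs", {
  s <- sample_sheet(c("c1", "c2", "c3"), c("a1", "a2"))
  y <- setNames(c(0.1, 0.25, 0.3, 0.4, NA, NA), s$sample_id)
  res <- cell_effect_anova(y, s)
  expect_equal(res$df_num, 1L)
  expect_false(res$untestable)
  # cross-check against lm on the same data
  keep <- !is.na(y)
  full <- lm(y[keep] ~ factor(s$cell_type[keep]) + factor(s$animal[keep]))
  red <- lm(y[keep] ~ factor(s$animal[keep]))
  want <- anova(red, full)
  expect_equal(res$F_cell, want$F[2], tolerance = 1e-10)
  expect_equal(res$p_cell, want$`Pr(>F)`[2], tolerance = 1e-10)

  # a single animal's worth of data is untestable
  y1 <- setNames(c(0.1, NA, 0.3, NA, 0.5, NA), s$sample_id)
  expect_true(cell_effect_anova(y1, s)$untestable)
})

test_that("BH adjustment matches the step-up formula and handles NAs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.05), 0.05)

  set.seed(8)
  p <- runif(50)
  expect_equal(bh_fdr(p), oracle_bh(p))

  # q is monotone in p after adjustment
  q <- bh_fdr(sort(p))
  expect_true(!is.unsorted(q))

  pn <- c(0.01, NA, 0.04)
  qn <- bh_fdr(pn)
  expect_true(is.na(qn[2]))
  expect_equal(qn[c(1, 3)], oracle_bh(c(0.01, 0.04)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cDMR calling flags everything at threshold 1 and nothing on empty input", {
  set.seed(13)
  cfg <- tiny_sim_config()
  sim <- simulate_methylomes(cfg)
  tiles <- apply_coverage_filter(tile_counts(sim$reports), sim$samples)
  dmrs <- call_cdmrs(tiles, sim$samples, fdr_threshold = 1.0)
  expect_true(all(dmrs$is_cdmr[!dmrs$untestable]))

  empty <- subset_tiles(tiles, integer(0))
  expect_equal(nrow(call_cdmrs(empty, sim$samples)), 0L)
})

test_that("cLMR z-scores follow the sample-level standardization", {
  cells <- paste0("c", 1:9)
  samples <- sample_sheet(cells, "A1")
  regions <- data.frame(region_id = "r1", chrom = "chr1", start = 0L,
                        end = 1000L, n_cpg = 5L, stringsAsFactors = FALSE)
  mk <- function(rates) {
    r <- matrix(rates, 1, dimnames = list("r1", samples$sample_id))
    structure(list(regions = regions, meth = r, total = r, rate = r,
                   samples = samples$sample_id), class = "tile_matrix")
  }
  dmrs <- data.frame(region_id = "r1", is_cdmr = TRUE)

  # eight cells at 0.9, one at 0.1: z = -2.667 and rate < 0.75 -> cLMR
  cl <- classify_clmrs(dmrs, mk(c(rep(0.9, 8), 0.1)), samples)
  low <- cl[cl$cell_type == "c9", ]
  expect_equal(low$avg_z, -2.6666667, tolerance = 1e-6)
  expect_equal(low$mean_rate, 0.1)
  expect_true(low$is_clmr)
  expect_false(any(cl$is_clmr[cl$cell_type != "c9"]))

  # z below -1 but mean rate above 75%: the methylation bound binds
  cl2 <- classify_clmrs(dmrs, mk(c(rep(0.95, 8), 0.80)), samples)
  low2 <- cl2[cl2$cell_type == "c9", ]
  expect_lt(low2$avg_z, -1)
  expect_false(low2$is_clmr)

  # z-scores of any region sum to zero across samples
  set.seed(4)
  cl3 <- classify_clmrs(dmrs, mk(runif(9)), samples)
  expect_equal(sum(cl3$avg_z), 0, tolerance = 1e-12)

  # constant region: zero SD -> no cLMRs
  cl4 <- classify_clmrs(dmrs, mk(rep(0.5, 9)), samples)
  expect_false(any(cl4$is_clmr))
})

test_that("cLMR flags are invariant to sample order and animal relabeling", {
  set.seed(17)
  cfg <- tiny_sim_config(n_dmr_planted = 6L)
  sim <- simulate_methylomes(cfg)
  tiles <- apply_coverage_filter(tile_counts(sim$reports), sim$samples)
  dmrs <- call_cdmrs(tiles, sim$samples)
  cl <- classify_clmrs(dmrs, tiles, sim$samples)

  perm <- sample(length(tiles$samples))
  tiles2 <- tiles
  tiles2$meth <- tiles2$meth[, perm]
  tiles2$total <- tiles2$total[, perm]
  tiles2$rate <- tiles2$rate[, perm]
  tiles2$samples <- tiles2$samples[perm]
  cl2 <- classify_clmrs(dmrs, tiles2, sim$samples)
  key <- function(d) d[order(d$region_id, d$cell_type), ]
  expect_equal(key(cl)$is_clmr, key(cl2)$is_clmr)
  expect_equal(key(cl)$avg_z, key(cl2)$avg_z)

  swapped <- sim$samples
  swapped$animal <- ifelse(swapped$animal == "A1", "A2", "A1")
  dmrs_sw <- call_cdmrs(tiles, swapped)
  expect_equal(dmrs_sw$F_cell, dmrs$F_cell, tolerance = 1e-10)
  cl3 <- classify_clmrs(dmrs_sw, tiles, swapped)
  expect_equal(key(cl)$is_clmr, key(cl3)$is_clmr)
})

test_that("cLMR uniqueness summary reproduces the published-ratio layout", {
  # (total, unique) pairs with their rounded percentages, per cell type
  rows <- list(CD21nB = c(1196, 174, 14.5), CD21pB = c(13701, 9398, 68.6),
               Myeloid = c(7959, 4640, 58.3), Neut = c(2837, 666, 23.5),
               NK = c(4894, 2410, 49.2), CD4T = c(1785, 450, 25.2),
               CD8T = c(1493, 375, 25.1), CD4CD8T = c(7873, 3598, 45.7),
               SWC6gdT = c(1655, 907, 54.8))
  for (ct in names(rows)) {
    total <- rows[[ct]][1]; uniq <- rows[[ct]][2]; pct <- rows[[ct]][3]
    shared <- total - uniq
    calls <- rbind(
      data.frame(region_id = paste0("u", seq_len(uniq)), cell_type = ct,
                 is_clmr = TRUE),
      data.frame(region_id = paste0("s", seq_len(shared)), cell_type = ct,
                 is_clmr = TRUE),
      data.frame(region_id = paste0("s", seq_len(shared)),
                 cell_type = "other", is_clmr = TRUE))
    out <- summarize_clmr_uniqueness(calls)
    row <- out[out$cell_type == ct, ]
    expect_equal(row$n_clmrs, total)
    expect_equal(row$n_unique, uniq)
    expect_equal(row$pct_unique, pct)
  }

  # gene-level uniqueness: the one-cell-only case is 100%
  calls <- data.frame(region_id = c("r1", "r2"), cell_type = "CD4T",
                      is_clmr = TRUE)
  gmap <- data.frame(region_id = c("r1", "r2"), gene_id = c("g1", "g2"))
  out <- summarize_clmr_uniqueness(calls, gmap)
  expect_equal(out$pct_unique, 100)
  expect_equal(out$n_genes, 2L)
  expect_equal(out$pct_unique_genes, 100)
})
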