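test_that("methylation-expression correlations behave on hand inputs", {
  cells <- paste0("c", 1:3)
  samples <- sample_sheet(cells, "A1")
  regions <- data.frame(region_id = "r1", chrom = "chr1", start = 0L,
                        end = 1000L, n_cpg = 3L, stringsAsFactors = FALSE)
  r <- matrix(c(0.1, 0.5, 0.9), 1,
              dimnames = list("r1", samples$sample_id))
  tiles <- structure(list(regions = regions, meth = r, total = r, rate = r,
                          samples = samples$sample_id),
                     class = "tile_matrix")
  ann <- data.frame(region_id = "r1", feature_class = "promoter",
                    cgi_class = "non_cgi", overlapping_gene_ids = "g1",
                    nearest_gene_id = NA, nearest_tss_distance = NA,
                    stringsAsFactors = FALSE)
  tpm <- matrix(c(9, 5, 1), 1, dimnames = list("g1", cells))

  out <- correlate_methylation_expression("r1", tiles, samples, ann, tpm,
                                          log2_transform = FALSE)
  expect_equal(out$r, -1, tolerance = 1e-12)
  expect_equal(out$stratum, "promoter")
  expect_equal(out$n, 3L)

  # constant TPM: undefined correlation, excluded from tests
  tpm2 <- matrix(c(5, 5, 5), 1, dimnames = list("g1", cells))
  out2 <- correlate_methylation_expression("r1", tiles, samples, ann, tpm2,
                                           log2_transform = FALSE)
  expect_true(is.na(out2$r))
  expect_true(is.na(out2$p))
})

test_that("reported Pearson r matches the closed-form covariance formula", {
  cells <- paste0("c", 1:3)
  samples <- sample_sheet(cells, "A1")
  regions <- data.frame(region_id = "r1", chrom = "chr1", start = 0L,
                        end = 1000L, n_cpg = 3L, stringsAsFactors = FALSE)
  ann <- data.frame(region_id = "r1", feature_class = "promoter",
                    cgi_class = "non_cgi", overlapping_gene_ids = "g1",
                    nearest_gene_id = NA, nearest_tss_distance = NA,
                    stringsAsFactors = FALSE)
  set.seed(14)
  for (i in 1:20) {
    x <- runif(3); y <- runif(3)
    r <- matrix(x, 1, dimnames = list("r1", samples$sample_id))
    tiles <- structure(list(regions = regions, meth = r, total = r,
                            rate = r, samples = samples$sample_id),
                       class = "tile_matrix")
    tpm <- matrix(y, 1, dimnames = list("g1", cells))
    got <- correlate_methylation_expression("r1", tiles, samples, ann,
                                            tpm, log2_transform = FALSE)$r
    closed <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(got - closed), 1e-12)
  }
})

test_that("the left-shift Wilcoxon test matches exact enumeration", {
  # all foreground below all background, n = m = 3: p = 1/20
  p <- wilcoxon_left_shift(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p, 1 / 20, tolerance = 1e-12)
  expect_equal(p, oracle_wilcox_less(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  set.seed(6)
  for (i in 1:15) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    v <- sample(1000, n + m)  # distinct -> no ties
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_lt(abs(wilcoxon_left_shift(x, y) - oracle_wilcox_less(x, y)),
              1e-12)
  }
})

test_that("sign enrichment Fisher tests match enumeration", {
  # table [[2,0],[0,2]] one-sided: p = 1/6
  p <- fisher.test(matrix(c(2, 0, 0, 2), 2, byrow = TRUE),
                   alternative = "greater")$p.value
  expect_equal(p, 1 / 6, tolerance = 1e-12)
  expect_equal(p, oracle_fisher_greater(2, 0, 0, 2), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(sample(0:4, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    got <- fisher.test(tab, alternative = "greater")$p.value
    want <- oracle_fisher_greater(tab[1, 1], tab[1, 2], tab[2, 1],
                                  tab[2, 2])
    expect_lt(abs(got - want), 1e-12)
  }

  # identical proportions -> no enrichment signal
  fg <- data.frame(region_id = paste0("a", 1:4), gene_id = "g",
                   stratum = "promoter", r = c(-0.99, -0.98, 0.5, 0.4),
                   p = c(0.001, 0.002, 0.5, 0.6), n = 9L)
  bg <- fg
  bg$region_id <- paste0("b", 1:4)
  se <- sign_enrichment_test(fg, bg)
  neg <- se[se$sign == "neg", ]
  expect_equal(neg$odds_ratio, 1, tolerance = 1e-6)
  expect_gte(neg$p, 0.5)

  # zero significant regions anywhere -> degenerate, p = 1
  fg0 <- fg; fg0$p <- 0.9; bg0 <- bg; bg0$p <- 0.9
  se0 <- sign_enrichment_test(fg0, bg0)
  expect_true(all(se0$p == 1))
  expect_true(all(se0$degenerate))
})

test_that("gene-set enrichment reproduces the enumeration example", {
  universe <- paste0("g", 1:20)
  enriched <- data.frame(gene_id = paste0("g", 1:5), cell_type = "NK",
                         log2fc = 2, fdr = 0.01)
  clmr <- data.frame(cell_type = "NK", stratum = "promoter",
                     gene_id = paste0("g", 1:4))
  out <- clmr_gene_set_enrichment(clmr, enriched, universe)
  expect_equal(out$p, 5 / 4845, tolerance = 1e-12)
  expect_equal(out$p, oracle_hyper_upper(20, 5, 4, 4), tolerance = 1e-12)

  # zero overlap: upper tail at 0 is 1
  clmr0 <- data.frame(cell_type = "NK", stratum = "promoter",
                      gene_id = paste0("g", 10:13))
  out0 <- clmr_gene_set_enrichment(clmr0, enriched, universe)
  expect_equal(out0$p, 1)

  # forced complete overlap in a saturated universe
  out1 <- clmr_gene_set_enrichment(
    data.frame(cell_type = "NK", stratum = "promoter",
               gene_id = paste0("g", 1:5)),
    enriched, paste0("g", 1:5))
  expect_equal(out1$p, 1)

  expect_error(clmr_gene_set_enrichment(
    data.frame(cell_type = "NK", stratum = "promoter", gene_id = "gX"),
    enriched, universe), "outside universe: gX")
})

test_that("GWAS SNP enrichment counts overlaps within half-open tiles", {
  cdmrs <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                      end = c(2000L, 6000L))
  snps <- data.frame(
    snp_id = paste0("rs", 1:8), chrom = "chr1",
    pos = c(1001L, 1500L, 2000L, 2001L, 5500L, 7000L, 8000L, 9000L),
    trait_class = c(rep("immune capacity", 5), rep("growth", 3)),
    trait = "t")
  out <- gwas_snp_enrichment(snps, cdmrs)
  imm <- out[out$trait_class == "immune capacity", ]
  # pos 1001, 1500, 2000 and 5500 are inside; 2001 is not (end exclusive)
  expect_equal(imm$observed, 4)
  expect_equal(imm$category_n, 4)
  expect_equal(imm$draw_n, 5)
  expect_equal(imm$p, oracle_hyper_upper(8, 4, 5, 4), tolerance = 1e-12)

  gro <- out[out$trait_class == "growth", ]
  expect_equal(gro$observed, 0)
  expect_equal(gro$p, 1)

  # unknown chromosomes excluded with a count
  snps2 <- rbind(snps, data.frame(snp_id = "rsX", chrom = "chrUn",
                                  pos = 1L, trait_class = "growth",
                                  trait = "t"))
  out2 <- gwas_snp_enrichment(snps2, cdmrs, known_chroms = "chr1")
  expect_equal(attr(out2, "n_excluded"), 1L)
  expect_equal(out2[out2$trait_class == "growth", "observed"], 0)
})

test_that("background draws are seeded, reproducible and exclude cDMRs", {
  set.seed(19)
  cfg <- sim_config(n_chroms = 1L, chrom_length_bp = 500000L,
                    n_genes = 30L, n_dmr_planted = 0L,
                    frac_genes_correlated = 0.4, expr_noise_sd = 0.1,
                    seed = 5L)
  sim <- simulate_study(cfg)
  tiles <- apply_coverage_filter(tile_counts(sim$reports), sim$samples)
  dmrs <- call_cdmrs(tiles, sim$samples)
  ann <- annotate_regions(tiles$regions, sim$genes, sim$cgis)
  cors <- correlate_methylation_expression(
    dmrs$region_id[dmrs$is_cdmr], tiles, sim$samples, ann, sim$tpm,
    sim$tpm_meta)
  expect_gt(nrow(cors), 5)

  b1 <- background_correlation_test(cors, dmrs, tiles, sim$samples, ann,
                                    sim$tpm, sim$tpm_meta, seed = 11)
  b2 <- background_correlation_test(cors, dmrs, tiles, sim$samples, ann,
                                    sim$tpm, sim$tpm_meta, seed = 11)
  expect_identical(b1$background, b2$background)
  expect_false(any(b1$background$region_id %in%
                     dmrs$region_id[dmrs$is_cdmr]))

  # identical foreground and background: no left shift
  fg <- cors$r[cors$stratum == "promoter" & !is.na(cors$p)]
  expect_gte(round(wilcoxon_left_shift(fg, fg), 6), 0.5)
})
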