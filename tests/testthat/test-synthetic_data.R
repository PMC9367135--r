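test_that("sim_config validates the study design", {
  expect_error(sim_config(n_animals = 1), "unidentifiable")
  expect_error(sim_config(dmr_effect = 0), "\\(0, 1\\]")
  expect_error(sim_config(dmr_effect = 1.2), "\\(0, 1\\]")
  expect_error(sim_config(dmr_effect = 0.97), "leaves no room")
  cfg <- sim_config()
  expect_equal(length(cfg$cell_types), 9L)
  expect_equal(cfg$n_animals, 2L)
})

test_that("null configuration gives equal expected rates across samples", {
  cfg <- tiny_sim_config(n_dmr_planted = 0L, animal_effect_sd = 0)
  sim <- simulate_methylomes(cfg)
  expect_equal(nrow(sim$truth$planted_dmrs), 0L)
  # all cells share the baseline rate at every tile
  expect_true(all(abs(sim$truth$cell_rates -
                        sim$truth$tiles$baseline) < 1e-12))
})

test_that("planted cDMRs depress exactly the target cell by dmr_effect", {
  cfg <- tiny_sim_config(dmr_effect = 0.5, n_dmr_planted = 3L)
  sim <- simulate_methylomes(cfg)
  pl <- sim$truth$planted_dmrs
  expect_equal(nrow(pl), 3L)
  for (i in seq_len(nrow(pl))) {
    rates <- sim$truth$cell_rates[pl$region_id[i], ]
    others <- rates[setdiff(names(rates), pl$cell_type[i])]
    expect_true(all(abs(others - pl$baseline[i]) < 1e-12))
    expect_equal(unname(rates[pl$cell_type[i]]), pl$baseline[i] - 0.5,
                 tolerance = 1e-12)
  }
})

test_that("the same seed reproduces files byte-identically, a new seed does not", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_study(tiny_sim_config(), d1)
  simulate_study(tiny_sim_config(), d2)
  simulate_study(tiny_sim_config(seed = 43L), d3)
  files <- list.files(d1)
  expect_true(length(files) > 18)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
  f1 <- file.path(d1, "CD4T_A1.CpG_report.txt")
  f3 <- file.path(d3, "CD4T_A1.CpG_report.txt")
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(f3))))
})

test_that("per-CpG counts are binomial draws consistent with the truth", {
  cfg <- tiny_sim_config(animal_effect_sd = 0, n_dmr_planted = 4L)
  sim <- simulate_methylomes(cfg)
  rec <- sim$reports[[1]]
  expect_true(all(rec$n_meth >= 0 & rec$n_unmeth >= 0))

  # empirical rate difference at planted cDMRs within 3 binomial SEs
  tiles <- tile_counts(sim$reports)
  pl <- sim$truth$planted_dmrs
  meta <- sim$samples
  for (i in seq_len(nrow(pl))) {
    ridx <- match(pl$region_id[i], tiles$regions$region_id)
    tgt <- meta$sample_id[meta$cell_type == pl$cell_type[i]]
    oth <- setdiff(meta$sample_id, tgt)
    m_t <- sum(tiles$meth[ridx, tgt]) / sum(tiles$total[ridx, tgt])
    m_o <- sum(tiles$meth[ridx, oth]) / sum(tiles$total[ridx, oth])
    se <- sqrt(m_o * (1 - m_o) / sum(tiles$total[ridx, oth]) +
                 m_t * (1 - m_t) / sum(tiles$total[ridx, tgt]))
    expect_lt(abs((m_o - m_t) - cfg$dmr_effect), 3 * se + 1e-3)
  }
})

test_that("noise-free linked genes are exactly monotone in methylation", {
  cfg <- tiny_sim_config(frac_genes_correlated = 0.5, expr_noise_sd = 0,
                         n_dmr_planted = 0L)
  sim <- simulate_methylomes(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  links <- sim$truth$gene_region_links
  expect_gt(nrow(links), 0)
  cells <- cfg$cell_types
  cellmeans <- sapply(cells, function(ct) {
    rowMeans(expr$tpm[, paste0(ct, c("_A1", "_A2")), drop = FALSE])
  })
  for (i in seq_len(nrow(links))) {
    meth <- sim$truth$cell_rates[links$region_id[i], cells]
    tpm <- cellmeans[links$gene_id[i], cells]
    # strictly monotone map of methylation (ties in meth give ties in TPM)
    if (links$sign[i] == -1) {
      expect_equal(rank(-tpm, ties.method = "average"),
                   rank(meth, ties.method = "average"))
    } else {
      expect_equal(rank(tpm, ties.method = "average"),
                   rank(meth, ties.method = "average"))
    }
  }
})

test_that("unlinked genes have near-zero mean correlation with any region", {
  cfg <- sim_config(n_chroms = 4L, chrom_length_bp = 1e6,
                    n_genes = 200L, n_dmr_planted = 10L,
                    frac_genes_correlated = 0, n_cgis_per_chrom = 2L,
                    seed = 3L)
  sim <- simulate_methylomes(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  cells <- cfg$cell_types
  cellmeans <- sapply(cells, function(ct) {
    rowMeans(expr$tpm[, paste0(ct, c("_A1", "_A2")), drop = FALSE])
  })
  # a planted region has non-constant true rates across cells
  region <- sim$truth$cell_rates[sim$truth$planted_dmrs$region_id[1],
                                 cells]
  r <- apply(log2(cellmeans + 1), 1, function(e) {
    suppressWarnings(cor(e, region))
  })
  r <- r[!is.na(r)]
  expect_gt(length(r), 150)
  expect_lt(abs(mean(r)), 0.1)
})

test_that("enriched-gene tables are reproducible and satisfy their bounds", {
  cfg <- tiny_sim_config(frac_genes_correlated = 0.3)
  sim <- simulate_methylomes(cfg)
  e1 <- simulate_expression(cfg, sim$truth)
  e2 <- simulate_expression(cfg, sim$truth)
  expect_identical(e1$enriched, e2$enriched)
  expect_true(all(e1$enriched$log2fc > 1))
  expect_true(all(e1$enriched$fdr < 0.05))
  expect_true(all(e1$tpm >= 0))

  bad_truth <- sim$truth
  bad_truth$gene_region_links$gene_id[1] <- "nonexistent"
  expect_error(simulate_expression(cfg, bad_truth), "unknown gene id")
})

test_that("simulated annotation layout satisfies its guarantees", {
  cfg <- tiny_sim_config(n_genes = 10L, snp_in_dmr_frac = 1.0)
  sim <- simulate_methylomes(cfg)
  ann <- simulate_annotation_and_snps(cfg, sim$truth)

  # genes non-overlapping with TSS < TTS on the + strand
  g <- ann$genes
  ord <- order(g$chrom, g$start)
  g <- g[ord, ]
  expect_true(all(diff(g$start) > 0))
  expect_true(all(g$end[-nrow(g)] <= g$start[-1] |
                    g$chrom[-nrow(g)] != g$chrom[-1]))
  plus <- g[g$strand == "+", ]
  expect_true(all(plus$tss < plus$tts))

  # all immune-capacity SNPs inside planted cDMR tiles
  imm <- ann$snps[ann$snps$trait_class == "immune capacity", ]
  tiles <- sim$truth$tiles[match(sim$truth$planted_dmrs$region_id,
                                 sim$truth$tiles$region_id), ]
  inside <- vapply(seq_len(nrow(imm)), function(i) {
    any(tiles$chrom == imm$chrom[i] & tiles$start < imm$pos[i] &
          imm$pos[i] <= tiles$end)
  }, logical(1))
  expect_true(all(inside))

  # the all-probability-1 planted consensus is present in every carrier
  cons <- ann$truth$planted_motif$consensus
  for (rid in ann$truth$planted_motif$carrier_ids) {
    expect_true(grepl(cons, ann$positive_seqs[[rid]], fixed = TRUE))
  }

  # CGIs are CpG-dense: observed/expected CpG ratio above 0.6 given a
  # uniform base composition
  sites <- do.call(rbind, lapply(unique(sim$reports[[1]]$chrom),
                                 function(ch) sim$reports[[1]]))
  cg <- sim$truth$cgis
  rec <- sim$reports[[1]]
  for (i in seq_len(nrow(cg))) {
    n_in <- sum(rec$chrom == cg$chrom[i] & rec$pos > cg$start[i] &
                  rec$pos <= cg$end[i])
    w <- cg$end[i] - cg$start[i]
    # obs/exp = n_cpg / (w * 0.25 * 0.25)
    expect_gt(n_in / (w * 0.0625), 0.6)
  }

  expect_error(simulate_methylomes(tiny_sim_config(n_genes = 500L)),
               "genome too small")
})
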