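#' Configuration for the synthetic WGBS study generator
#'
#' Defines the simulated study: nine sorted immune cell populations from two
#' animals, per-CpG binomial counts over per-tile methylation rates, planted
#' cell differentially methylated regions, promoter-linked
#' methylation-expression correlations, trait-class SNPs and a planted
#' binding motif. Defaults mirror the design the package targets (9 cell
#' types x 2 animals, ~30x CpG depth, 1 kb tiles).
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome.
#' @param cpg_spacing_mean_bp Mean CpG spacing outside CpG islands; inside
#'   CGIs spacing is 10x denser.
#' @param cell_types Cell-type labels (default the nine porcine immune
#'   populations).
#' @param n_animals Number of animals (>= 2; the animal term is otherwise
#'   unidentifiable).
#' @param mean_depth Mean per-CpG read depth (Poisson).
#' @param baseline_meth_alpha,baseline_meth_beta Beta shape parameters of
#'   the per-tile baseline methylation rate (defaults give mean 0.8,
#'   matching the 80-84% global methylation typical of mammalian immune
#'   cells).
#' @param n_dmr_planted Number of randomly placed planted cDMRs.
#' @param dmr_effect Methylation depression in the target cell type, in
#'   (0, 1]; planted baselines are drawn so the depressed rate stays in
#'   [0, 1].
#' @param animal_effect_sd SD of the additive per-animal offset on the
#'   logit of the rate.
#' @param frac_genes_correlated Fraction of genes given a planted
#'   methylation-expression link through their promoter tile (each such
#'   promoter tile becomes an additional planted cDMR).
#' @param link_sign_neg_frac Fraction of planted links with negative sign.
#' @param n_genes Total number of gene models.
#' @param n_cgis_per_chrom CpG islands per chromosome.
#' @param cgi_length_bp CGI length.
#' @param n_snps Total GWAS SNPs across trait classes.
#' @param snp_trait_classes Trait-class labels; the first is the immune
#'   class whose SNPs are preferentially planted inside cDMRs.
#' @param snp_in_dmr_frac Fraction of immune-class SNPs placed inside
#'   planted cDMRs.
#' @param n_decoy_pwms Decoy PWMs accompanying the planted motif.
#' @param motif_width Planted motif width.
#' @param motif_carrier_frac Fraction of positive sequences carrying the
#'   planted consensus.
#' @param expr_noise_sd SD of the per-cell log2 expression noise around a
#'   planted link.
#' @param expr_link_slope log2-TPM units per unit methylation for planted
#'   links.
#' @param tile_size Tile width in bp.
#' @param seed Integer seed; the same seed reproduces every output
#'   byte-identically.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length_bp = 1e6,
                       cpg_spacing_mean_bp = 100,
                       cell_types = pig_immune_cells(), n_animals = 2L,
                       mean_depth = 30, baseline_meth_alpha = 8,
                       baseline_meth_beta = 2, n_dmr_planted = 20L,
                       dmr_effect = 0.3, animal_effect_sd = 0.1,
                       frac_genes_correlated = 0, link_sign_neg_frac = 0.9,
                       n_genes = 60L, n_cgis_per_chrom = 8L,
                       cgi_length_bp = 800L, n_snps = 400L,
                       snp_trait_classes = c("immune capacity", "growth",
                                             "reproduction", "behavior"),
                       snp_in_dmr_frac = 0.6, n_decoy_pwms = 10L,
                       motif_width = 8L, motif_carrier_frac = 0.6,
                       expr_noise_sd = 0.25, expr_link_slope = 10,
                       tile_size = 1000L, seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.integer(chrom_length_bp),
              cpg_spacing_mean_bp = cpg_spacing_mean_bp,
              cell_types = cell_types, n_animals = as.integer(n_animals),
              mean_depth = mean_depth,
              baseline_meth_alpha = baseline_meth_alpha,
              baseline_meth_beta = baseline_meth_beta,
              n_dmr_planted = as.integer(n_dmr_planted),
              dmr_effect = dmr_effect, animal_effect_sd = animal_effect_sd,
              frac_genes_correlated = frac_genes_correlated,
              link_sign_neg_frac = link_sign_neg_frac,
              n_genes = as.integer(n_genes),
              n_cgis_per_chrom = as.integer(n_cgis_per_chrom),
              cgi_length_bp = as.integer(cgi_length_bp),
              n_snps = as.integer(n_snps),
              snp_trait_classes = snp_trait_classes,
              snp_in_dmr_frac = snp_in_dmr_frac,
              n_decoy_pwms = as.integer(n_decoy_pwms),
              motif_width = as.integer(motif_width),
              motif_carrier_frac = motif_carrier_frac,
              expr_noise_sd = expr_noise_sd,
              expr_link_slope = expr_link_slope,
              tile_size = as.integer(tile_size), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chroms >= 1L, chrom_length_bp >= tile_size,
              cpg_spacing_mean_bp > 0, mean_depth > 0,
              baseline_meth_alpha > 0, baseline_meth_beta > 0,
              n_dmr_planted >= 0L, animal_effect_sd >= 0,
              frac_genes_correlated >= 0, frac_genes_correlated <= 1,
              link_sign_neg_frac >= 0, link_sign_neg_frac <= 1,
              n_genes >= 0L, tile_size > 0L, length(cell_types) >= 2L)
  })
  if (cfg$n_animals < 2L) {
    stop("n_animals must be >= 2: with a single animal the animal effect ",
         "is unidentifiable")
  }
  if (cfg$dmr_effect <= 0 || cfg$dmr_effect > 1) {
    stop("dmr_effect must lie in (0, 1]")
  }
  if (cfg$dmr_effect > 0.96) {
    stop("dmr_effect = ", cfg$dmr_effect, " leaves no room for baseline ",
         "rates within [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

# Non-overlapping CGI intervals, evenly spaced with jitter
sim_cgis <- function(config) {
  out <- lapply(sim_chrom_names(config), function(ch) {
    n <- config$n_cgis_per_chrom
    if (n == 0L) return(NULL)
    span <- config$chrom_length_bp - 2L * config$cgi_length_bp
    anchor <- round(seq(config$cgi_length_bp, span, length.out = n))
    start <- anchor + sample(-2000:2000, n, replace = TRUE)
    start <- pmin(pmax(start, 0L),
                  config$chrom_length_bp - config$cgi_length_bp)
    data.frame(chrom = ch, start = as.integer(start),
               end = as.integer(start + config$cgi_length_bp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# CpG positions: exponential spacing outside CGIs, 10x denser inside
sim_cpg_positions <- function(config, cgis) {
  out <- lapply(sim_chrom_names(config), function(ch) {
    len <- config$chrom_length_bp
    n_draw <- ceiling(len / config$cpg_spacing_mean_bp * 1.4) + 10L
    pos <- cumsum(stats::rexp(n_draw, 1 / config$cpg_spacing_mean_bp))
    pos <- pos[pos < len]
    cg <- cgis[cgis$chrom == ch, , drop = FALSE]
    if (nrow(cg)) {
      in_cgi <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(cg))) {
        in_cgi <- in_cgi | (pos >= cg$start[i] & pos < cg$end[i])
      }
      pos <- pos[!in_cgi]
      dense <- unlist(lapply(seq_len(nrow(cg)), function(i) {
        w <- cg$end[i] - cg$start[i]
        nd <- ceiling(w / (config$cpg_spacing_mean_bp / 10) * 1.4) + 5L
        p <- cumsum(stats::rexp(nd, 10 / config$cpg_spacing_mean_bp))
        cg$start[i] + p[p < w]
      }))
      pos <- c(pos, dense)
    }
    pos <- sort(unique(pmax(1L, as.integer(ceiling(pos)))))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sequentially laid-out, non-overlapping gene models
sim_genes <- function(config) {
  if (config$n_genes == 0L) {
    return(gene_models(character(), character(), character(), integer(),
                       integer()))
  }
  chroms <- sim_chrom_names(config)
  per_chrom <- table(factor(rep(chroms, length.out = config$n_genes),
                            levels = chroms))
  rows <- list()
  gid <- 0L
  for (ch in chroms) {
    cursor <- 15000L + sample(0:5000, 1L)
    for (k in seq_len(per_chrom[[ch]])) {
      g_len <- sample(3000:8000, 1L)
      if (cursor + g_len > config$chrom_length_bp - 10000L) {
        stop("genome too small for requested feature counts (",
             config$n_genes, " genes on ", config$n_chroms, " x ",
             config$chrom_length_bp, " bp)")
      }
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(2:4, 1L)
      # alternate exon/intron segments; first and last are exons
      cuts <- sort(sample(seq(200L, g_len - 200L, by = 100L),
                          2L * n_ex - 2L))
      bounds <- c(0L, cuts, g_len)
      seg_start <- bounds[-length(bounds)]
      seg_end <- bounds[-1L]
      exon_idx <- seq(1L, 2L * n_ex - 1L, by = 2L)
      rows[[gid]] <- list(gene_id = sprintf("gene%03d", gid), chrom = ch,
                          strand = strand, start = cursor,
                          end = cursor + g_len,
                          exon_starts = cursor + seg_start[exon_idx],
                          exon_ends = cursor + seg_end[exon_idx])
      cursor <- cursor + g_len + sample(2000:8000, 1L)
    }
  }
  gene_models(gene_id = vapply(rows, `[[`, "", "gene_id"),
              chrom = vapply(rows, `[[`, "", "chrom"),
              strand = vapply(rows, `[[`, "", "strand"),
              start = vapply(rows, function(r) r$start, 0L),
              end = vapply(rows, function(r) r$end, 0L),
              exon_starts = lapply(rows, `[[`, "exon_starts"),
              exon_ends = lapply(rows, `[[`, "exon_ends"))
}

rbeta_between <- function(n, alpha, beta, lo, hi) {
  out <- numeric(0)
  for (i in 1:10000) {
    draw <- stats::rbeta(n * 2L + 10L, alpha, beta)
    out <- c(out, draw[draw >= lo & draw <= hi])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("could not draw baseline rates in [", lo, ", ", hi, "]")
}

#' Simulate per-sample CpG methylation reports with known ground truth
#'
#' Draws the genome layout (CpG islands, CpG sites, gene models), per-tile
#' baseline methylation rates from a Beta distribution, plants cDMRs by
#' depressing the target cell type's rate by `dmr_effect` (random tiles
#' plus, when `frac_genes_correlated > 0`, the promoter tiles of the linked
#' genes), adds a per-animal offset on the logit of the rate, and generates
#' per-CpG counts as `Binomial(Poisson(mean_depth), rate)`. One report per
#' cell type x animal sample.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, one
#'   `<sample_id>.CpG_report.txt` per sample is written there.
#' @return List with `reports` (named list of CpG record data.frames),
#'   `samples` (the sample sheet) and `truth` (ground-truth list: `tiles`
#'   with baselines, `cell_rates` matrix of true per-cell rates, planted
#'   DMR table, gene/CGI layout, gene-region links, and the config).
#' @export
simulate_methylomes <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cgis <- sim_cgis(config)
  sites <- sim_cpg_positions(config, cgis)
  genes <- sim_genes(config)

  ts <- config$tile_size
  tiles <- do.call(rbind, lapply(sim_chrom_names(config), function(ch) {
    start <- as.integer(seq(0L, config$chrom_length_bp - ts, by = ts))
    data.frame(chrom = ch, start = start, end = start + ts,
               stringsAsFactors = FALSE)
  }))
  tiles$region_id <- paste0(tiles$chrom, ":", tiles$start, "-", tiles$end)
  n_tiles <- nrow(tiles)
  baseline <- stats::rbeta(n_tiles, config$baseline_meth_alpha,
                           config$baseline_meth_beta)

  tile_of <- function(chrom, pos0) {
    match(paste0(chrom, ":", (pos0 %/% ts) * ts, "-",
                 (pos0 %/% ts) * ts + ts), tiles$region_id)
  }

  # planted links through gene promoter tiles
  links <- data.frame(gene_id = character(), region_id = character(),
                      sign = integer(), stringsAsFactors = FALSE)
  planted <- data.frame(region_id = character(), cell_type = character(),
                        via = character(), stringsAsFactors = FALSE)
  n_linked <- round(config$frac_genes_correlated * nrow(genes))
  if (n_linked > 0L) {
    ord <- sample(nrow(genes))
    used <- character(0)
    for (i in ord) {
      if (length(used) >= n_linked) break
      rid <- tiles$region_id[tile_of(genes$chrom[i], genes$tss[i])]
      if (rid %in% used) next
      used <- c(used, rid)
      sign <- if (stats::runif(1) < config$link_sign_neg_frac) -1L else 1L
      links <- rbind(links, data.frame(gene_id = genes$gene_id[i],
                                       region_id = rid, sign = sign,
                                       stringsAsFactors = FALSE))
      planted <- rbind(planted, data.frame(
        region_id = rid,
        cell_type = sample(config$cell_types, 1L), via = "promoter",
        stringsAsFactors = FALSE))
    }
    if (nrow(links) < n_linked) {
      stop("genome too small to place ", n_linked,
           " distinct promoter-linked regions")
    }
  }
  if (config$n_dmr_planted > 0L) {
    free <- setdiff(tiles$region_id, planted$region_id)
    if (length(free) < config$n_dmr_planted) {
      stop("genome too small for ", config$n_dmr_planted, " planted cDMRs")
    }
    rnd <- sample(free, config$n_dmr_planted)
    planted <- rbind(planted, data.frame(
      region_id = rnd,
      cell_type = sample(config$cell_types, length(rnd), replace = TRUE),
      via = "random", stringsAsFactors = FALSE))
  }
  if (nrow(planted)) {
    idx <- match(planted$region_id, tiles$region_id)
    baseline[idx] <- rbeta_between(length(idx), config$baseline_meth_alpha,
                                   config$baseline_meth_beta,
                                   config$dmr_effect + 0.02, 0.98)
  }

  cell_rates <- matrix(baseline, n_tiles, length(config$cell_types),
                       dimnames = list(tiles$region_id, config$cell_types))
  if (nrow(planted)) {
    idx <- cbind(match(planted$region_id, tiles$region_id),
                 match(planted$cell_type, config$cell_types))
    cell_rates[idx] <- cell_rates[idx] - config$dmr_effect
    if (any(cell_rates[idx] < -1e-9)) {
      stop("dmr_effect produces methylation rates outside [0, 1]")
    }
    cell_rates[idx] <- pmax(cell_rates[idx], 0)
    planted$baseline <- baseline[idx[, 1L]]
    planted$depressed_rate <- cell_rates[idx]
  }

  animals <- paste0("A", seq_len(config$n_animals))
  offsets <- matrix(stats::rnorm(n_tiles * config$n_animals, 0,
                                 config$animal_effect_sd),
                    n_tiles, config$n_animals,
                    dimnames = list(NULL, animals))

  samples <- sample_sheet(config$cell_types, animals)
  site_tile <- tile_of(sites$chrom, sites$pos - 1L)
  n_sites <- nrow(sites)

  reports <- stats::setNames(vector("list", nrow(samples)),
                             samples$sample_id)
  for (i in seq_len(nrow(samples))) {
    ct <- samples$cell_type[i]
    an <- samples$animal[i]
    base_r <- pmin(pmax(cell_rates[, ct], 1e-6), 1 - 1e-6)
    rate_tile <- stats::plogis(stats::qlogis(base_r) + offsets[, an])
    rate_cpg <- rate_tile[site_tile]
    depth <- stats::rpois(n_sites, config$mean_depth)
    meth <- stats::rbinom(n_sites, depth, rate_cpg)
    reports[[i]] <- data.frame(chrom = sites$chrom, pos = sites$pos,
                               strand = "+", n_meth = meth,
                               n_unmeth = depth - meth,
                               stringsAsFactors = FALSE)
  }

  truth <- list(config = config,
                tiles = cbind(tiles[, c("region_id", "chrom", "start",
                                        "end")],
                              baseline = baseline),
                cell_rates = cell_rates, planted_dmrs = planted,
                gene_region_links = links, genes = genes, cgis = cgis)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(reports), function(sid) {
      p <- file.path(dir, paste0(sid, ".CpG_report.txt"))
      write_cpg_report(reports[[sid]], p)
      p
    }, character(1))
  }
  list(reports = reports, samples = samples, truth = truth, paths = paths)
}

#' Simulate expression (TPM) and expression-enriched gene tables
#'
#' Unlinked genes get cell-level `log2 TPM` drawn independently of
#' methylation. Genes linked in the ground truth get cell-level expression
#' as a monotone function of their linked region's true methylation rate
#' (`log2 TPM = b + sign * slope * (meth - mean(meth)) + noise`), so a
#' negative-sign link yields a negative methylation-expression correlation.
#' Per-sample replicates add small lognormal noise around the cell-level
#' value. The enriched-gene table lists each gene's top cell where its true
#' cell-level log2 fold change versus the mean of the other cells exceeds
#' 1, with a sub-0.05 FDR; a further 10% of unlinked genes receive an
#' expression boost in a random cell so the table is not exclusively
#' methylation-driven.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_methylomes()].
#' @param dir Optional output directory (`tpm.tsv`, `enriched_genes.tsv`).
#' @return List with `tpm` (genes x samples matrix), `tpm_meta`
#'   (`sample_id`, `cell_type`), and `enriched` (`gene_id`, `cell_type`,
#'   `log2fc`, `fdr`).
#' @export
simulate_expression <- function(config, truth, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- truth$genes
  links <- truth$gene_region_links
  if (nrow(links) && !all(links$gene_id %in% genes$gene_id)) {
    stop("link to unknown gene id: ",
         setdiff(links$gene_id, genes$gene_id)[1L])
  }
  cells <- config$cell_types
  n_g <- nrow(genes)
  b <- stats::rnorm(n_g, 4, 1.5)
  l2 <- matrix(NA_real_, n_g, length(cells),
               dimnames = list(genes$gene_id, cells))
  linked <- genes$gene_id %in% links$gene_id
  for (i in seq_len(n_g)) {
    if (linked[i]) {
      lk <- links[links$gene_id == genes$gene_id[i], ]
      meth <- truth$cell_rates[lk$region_id, ]
      l2[i, ] <- b[i] + lk$sign * config$expr_link_slope *
        (meth - mean(meth)) +
        stats::rnorm(length(cells), 0, config$expr_noise_sd)
    } else {
      l2[i, ] <- b[i] + stats::rnorm(length(cells), 0, 0.5)
    }
  }
  boost_pool <- which(!linked)
  n_boost <- min(length(boost_pool), max(0L, round(0.1 * n_g)))
  if (n_boost > 0L) {
    bi <- sample(boost_pool, n_boost)
    bc <- sample(cells, n_boost, replace = TRUE)
    l2[cbind(bi, match(bc, cells))] <- l2[cbind(bi, match(bc, cells))] + 2.5
  }

  samples <- sample_sheet(cells, paste0("A", seq_len(config$n_animals)))
  tpm <- matrix(NA_real_, n_g, nrow(samples),
                dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    # replicate-level lognormal noise, scaled with the link noise so a
    # noise-free configuration stays exactly monotone
    rep_noise <- stats::rnorm(n_g, 0, 0.4 * config$expr_noise_sd)
    tpm[, j] <- 2^(l2[, samples$cell_type[j]] + rep_noise)
  }

  fc <- l2  # log2 fold change of each cell versus the mean of the others
  for (ct in cells) {
    others <- rowMeans(l2[, setdiff(cells, ct), drop = FALSE])
    fc[, ct] <- l2[, ct] - others
  }
  top_cell <- cells[max.col(fc)]
  top_fc <- fc[cbind(seq_len(n_g), max.col(fc))]
  keep <- top_fc > 1
  enriched <- data.frame(gene_id = genes$gene_id[keep],
                         cell_type = top_cell[keep],
                         log2fc = top_fc[keep],
                         fdr = stats::runif(sum(keep), 0, 0.049),
                         stringsAsFactors = FALSE)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tpm_table(tpm, file.path(dir, "tpm.tsv"))
    utils::write.table(enriched, file.path(dir, "enriched_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(tpm = tpm,
       tpm_meta = samples[, c("sample_id", "cell_type")],
       enriched = enriched)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

#' Simulate annotation files, GWAS SNPs, region sequences and PWMs
#'
#' Serializes the gene and CGI layout drawn by [simulate_methylomes()],
#' places trait-class SNPs (a configurable fraction of the immune class
#' inside planted cDMRs, the rest uniformly), builds a planted
#' consensus-probability-1 PWM plus random decoys, and generates tile
#' sequences: positives are the planted cDMR tiles with the consensus
#' embedded in a `motif_carrier_frac` fraction of them, controls an equal
#' number of unplanted tiles.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_methylomes()].
#' @param dir Optional output directory (`genes.bed`, `cgis.bed`,
#'   `snps.tsv`, `motifs.meme`, `positive_sequences.fa`,
#'   `control_sequences.fa`, `ground_truth.json`).
#' @return List with `genes`, `cgis`, `snps`, `pwms`, `positive_seqs`,
#'   `control_seqs` and `truth` (augmented with `planted_motif` and
#'   `planted_snps_in_dmrs`).
#' @export
simulate_annotation_and_snps <- function(config, truth, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  chroms <- sim_chrom_names(config)
  planted <- truth$planted_dmrs

  # SNP table
  classes <- config$snp_trait_classes
  n_per <- diff(round(seq(0, config$n_snps, length.out =
                            length(classes) + 1L)))
  snp_rows <- list()
  sid <- 0L
  planted_snp_ids <- character(0)
  for (ci in seq_along(classes)) {
    n_cl <- n_per[ci]
    n_in <- 0L
    if (ci == 1L) {
      n_in <- round(config$snp_in_dmr_frac * n_cl)
      if (n_in > 0L && nrow(planted) == 0L) {
        warning("no planted cDMRs: immune-class SNPs placed uniformly")
        n_in <- 0L
      }
    }
    for (k in seq_len(n_cl)) {
      sid <- sid + 1L
      id <- sprintf("rs%06d", sid)
      if (k <= n_in) {
        row <- planted[sample(nrow(planted), 1L), ]
        tl <- truth$tiles[match(row$region_id, truth$tiles$region_id), ]
        pos <- tl$start + sample.int(tl$end - tl$start, 1L)  # 1-based in tile
        chrom <- tl$chrom
        planted_snp_ids <- c(planted_snp_ids, id)
      } else {
        chrom <- sample(chroms, 1L)
        pos <- sample.int(config$chrom_length_bp, 1L)
      }
      snp_rows[[sid]] <- data.frame(snp_id = id, chrom = chrom,
                                    pos = as.integer(pos),
                                    trait_class = classes[ci],
                                    trait = classes[ci],
                                    stringsAsFactors = FALSE)
    }
  }
  snps <- do.call(rbind, snp_rows)

  # PWMs: planted consensus motif + random decoys
  consensus <- sample(BASES, config$motif_width, replace = TRUE)
  planted_pwm <- matrix(0, config$motif_width, 4L,
                        dimnames = list(NULL, BASES))
  planted_pwm[cbind(seq_len(config$motif_width),
                    match(consensus, BASES))] <- 1
  pwms <- list(planted_motif = planted_pwm)
  for (d in seq_len(config$n_decoy_pwms)) {
    m <- matrix(stats::rexp(config$motif_width * 4L), config$motif_width,
                4L, dimnames = list(NULL, BASES))
    pwms[[sprintf("decoy%02d", d)]] <- m / rowSums(m)
  }

  # Tile sequences: positives are planted cDMR tiles, controls unplanted
  pos_ids <- unique(planted$region_id)
  if (!length(pos_ids)) {
    pos_ids <- sample(truth$tiles$region_id,
                      min(20L, nrow(truth$tiles)))
  }
  ctrl_ids <- sample(setdiff(truth$tiles$region_id, pos_ids),
                     length(pos_ids))
  seq_len_bp <- config$tile_size
  positive_seqs <- stats::setNames(
    vapply(pos_ids, function(x) random_dna(seq_len_bp), character(1)),
    pos_ids)
  carriers <- sample(pos_ids,
                     round(config$motif_carrier_frac * length(pos_ids)))
  cons_str <- paste(consensus, collapse = "")
  for (rid in carriers) {
    at <- sample.int(seq_len_bp - config$motif_width + 1L, 1L)
    s <- positive_seqs[[rid]]
    substr(s, at, at + config$motif_width - 1L) <- cons_str
    positive_seqs[[rid]] <- s
  }
  control_seqs <- stats::setNames(
    vapply(ctrl_ids, function(x) random_dna(seq_len_bp), character(1)),
    ctrl_ids)

  truth$planted_motif <- list(motif_id = "planted_motif",
                              consensus = cons_str, carrier_ids = carriers)
  truth$planted_snps_in_dmrs <- planted_snp_ids

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_gene_bed12(truth$genes, file.path(dir, "genes.bed"))
    write_cgi_bed(truth$cgis, file.path(dir, "cgis.bed"))
    write_snp_table(snps, file.path(dir, "snps.tsv"))
    write_meme_pwms(pwms, file.path(dir, "motifs.meme"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(positive_seqs),
      file.path(dir, "positive_sequences.fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(control_seqs),
      file.path(dir, "control_sequences.fa"))
    manifest <- list(
      seed = config$seed,
      planted_dmrs = truth$planted_dmrs,
      gene_region_links = truth$gene_region_links,
      planted_motif = truth$planted_motif,
      planted_snps_in_dmrs = truth$planted_snps_in_dmrs)
    jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(genes = truth$genes, cgis = truth$cgis, snps = snps, pwms = pwms,
       positive_seqs = positive_seqs, control_seqs = control_seqs,
       truth = truth)
}

#' Run all three simulation stages
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory passed to each stage.
#' @return List combining the outputs of [simulate_methylomes()],
#'   [simulate_expression()] and [simulate_annotation_and_snps()]; `truth`
#'   is the fully augmented ground truth.
#' @export
simulate_study <- function(config, dir = NULL) {
  meth <- simulate_methylomes(config, dir)
  expr <- simulate_expression(config, meth$truth, dir)
  ann <- simulate_annotation_and_snps(config, meth$truth, dir)
  list(reports = meth$reports, samples = meth$samples, tpm = expr$tpm,
       tpm_meta = expr$tpm_meta, enriched = expr$enriched,
       genes = ann$genes, cgis = ann$cgis, snps = ann$snps,
       pwms = ann$pwms, positive_seqs = ann$positive_seqs,
       control_seqs = ann$control_seqs, truth = ann$truth)
}
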