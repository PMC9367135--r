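map_stratum <- function(feature_class) {
  c(promoter = "promoter", exon = "intragenic", intron = "intragenic",
    tts = "tts", intergenic = "intergenic")[feature_class]
}

# genes x cells matrix of cell-mean expression, optionally log2(TPM + 1)
expression_cell_means <- function(tpm, tpm_meta = NULL, log2_transform = TRUE) {
  if (log2_transform) tpm <- log2(tpm + 1)
  if (is.null(tpm_meta)) return(tpm)  # columns already one per cell type
  cellf <- factor(tpm_meta$cell_type[match(colnames(tpm),
                                           tpm_meta$sample_id)])
  out <- do.call(cbind, lapply(levels(cellf), function(ct) {
    rowMeans(tpm[, cellf == ct, drop = FALSE])
  }))
  dimnames(out) <- list(rownames(tpm), levels(cellf))
  out
}

# regions x cells matrix of cell-mean methylation rates
methylation_cell_means <- function(tiles, samples) {
  meta <- samples[match(tiles$samples, samples$sample_id), ]
  cells <- unique(meta$cell_type)
  out <- do.call(cbind, lapply(cells, function(ct) {
    rowMeans(tiles$rate[, meta$cell_type == ct, drop = FALSE],
             na.rm = TRUE)
  }))
  dimnames(out) <- list(tiles$regions$region_id, cells)
  out
}

pearson_row <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(c(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlate region methylation with transcript abundance
#'
#' For each region in `region_ids` and each gene its annotation pairs it
#' with (overlapping genes for genic regions, the nearest-TSS gene for
#' intergenic ones), the Pearson correlation between per-cell mean
#' methylation rates and per-cell mean transcript abundance across cell
#' populations, stratified by feature: promoter, intragenic (exon or
#' intron), tts, intergenic. Expression is `log2(TPM + 1)` transformed by
#' default. Pairs with fewer than three cells or a constant vector get an
#' undefined `r`/`p` and are excluded from downstream tests.
#'
#' @param region_ids Regions to correlate (typically the cDMR ids).
#' @param tiles The `tile_matrix`.
#' @param samples Sample sheet for the methylation samples.
#' @param annotations Output of [annotate_regions()].
#' @param tpm Numeric TPM matrix, genes x expression samples.
#' @param tpm_meta Optional data.frame `sample_id`, `cell_type` mapping TPM
#'   columns to cell types; omit when the columns are already per cell
#'   type.
#' @param log2_transform Transform TPM as `log2(TPM + 1)` (default TRUE).
#' @return data.frame `region_id`, `gene_id`, `stratum`, `r`, `p`, `n`.
#' @export
correlate_methylation_expression <- function(region_ids, tiles, samples,
                                             annotations, tpm,
                                             tpm_meta = NULL,
                                             log2_transform = TRUE) {
  meth <- methylation_cell_means(tiles, samples)
  expr <- expression_cell_means(tpm, tpm_meta, log2_transform)
  common <- intersect(colnames(meth), colnames(expr))
  if (length(common) < 3L) {
    stop("fewer than 3 cell populations shared between methylation and ",
         "expression data")
  }
  meth <- meth[, common, drop = FALSE]
  expr <- expr[, common, drop = FALSE]
  ann <- annotations[match(region_ids, annotations$region_id), ]
  if (anyNA(ann$region_id)) stop("annotations must cover all regions")

  rows <- list()
  for (i in seq_along(region_ids)) {
    rid <- region_ids[i]
    if (!rid %in% rownames(meth)) next
    stratum <- unname(map_stratum(ann$feature_class[i]))
    gids <- if (ann$feature_class[i] == "intergenic") {
      ann$nearest_gene_id[i]
    } else {
      strsplit(ann$overlapping_gene_ids[i], ",")[[1L]]
    }
    gids <- gids[!is.na(gids) & nzchar(gids) & gids %in% rownames(expr)]
    for (g in gids) {
      st <- pearson_row(meth[rid, ], expr[g, ])
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = rid, gene_id = g, stratum = stratum, r = st[["r"]],
        p = st[["p"]], n = as.integer(st[["n"]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(region_id = character(), gene_id = character(),
                      stratum = character(), r = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided Wilcoxon rank-sum test for a left shift
#'
#' Tests whether `x` is stochastically smaller than `y` (alternative
#' "less"). Exact p-values are used when both groups have fewer than 25
#' observations and there are no ties; otherwise the normal approximation
#' with continuity correction.
#'
#' @param x,y Numeric vectors.
#' @return The one-sided p-value.
#' @export
wilcoxon_left_shift <- function(x, y) {
  exact <- length(x) < 25 && length(y) < 25
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = exact,
                       correct = TRUE)$p.value)
}

#' Compare cDMR correlations against a seeded random background
#'
#' Per feature stratum, draws (without replacement) a background set of
#' equally many non-cDMR retained tiles annotated with the same stratum,
#' computes the same methylation-expression correlations, and reports the
#' one-sided Wilcoxon rank-sum p-value for the cDMR correlation
#' distribution being shifted left of the background. Exact p-values are
#' used below 25 observations per group (no ties), the normal approximation
#' with continuity correction above.
#'
#' @param cdmr_cor Correlations of the cDMR set (from
#'   [correlate_methylation_expression()]).
#' @param dmrs DMR results (to exclude cDMRs from the background pool).
#' @param tiles,samples,annotations,tpm,tpm_meta,log2_transform As in
#'   [correlate_methylation_expression()].
#' @param n_draws Number of background draws pooled together (default 1).
#' @param seed Integer seed for the background draw.
#' @return List with `comparison` (data.frame `stratum`, `n_cdmr`, `n_bg`,
#'   `wilcoxon_p`) and `background` (the background correlation
#'   data.frame).
#' @export
background_correlation_test <- function(cdmr_cor, dmrs, tiles, samples,
                                        annotations, tpm, tpm_meta = NULL,
                                        log2_transform = TRUE, n_draws = 1,
                                        seed = 1) {
  set.seed(seed)
  cdmr_ids <- dmrs$region_id[dmrs$is_cdmr]
  pool_ids <- setdiff(tiles$regions$region_id, cdmr_ids)
  ann <- annotations[match(pool_ids, annotations$region_id), ]
  pool_stratum <- unname(map_stratum(ann$feature_class))

  bg_list <- list()
  comp <- list()
  for (st in unique(cdmr_cor$stratum)) {
    fg <- cdmr_cor$r[cdmr_cor$stratum == st & !is.na(cdmr_cor$p)]
    n_target <- sum(cdmr_cor$stratum == st)
    cand <- pool_ids[pool_stratum == st]
    if (!length(cand)) {
      warning("no background tiles for stratum ", st, "; skipped")
      next
    }
    bg_cor <- NULL
    for (d in seq_len(n_draws)) {
      draw <- sample(cand, min(n_target, length(cand)))
      bc <- correlate_methylation_expression(draw, tiles, samples,
                                             annotations, tpm, tpm_meta,
                                             log2_transform)
      bg_cor <- rbind(bg_cor, bc)
    }
    bg_list[[st]] <- bg_cor
    bg <- bg_cor$r[!is.na(bg_cor$p)]
    p <- if (length(fg) && length(bg)) wilcoxon_left_shift(fg, bg)
         else NA_real_
    comp[[length(comp) + 1L]] <- data.frame(
      stratum = st, n_cdmr = length(fg), n_bg = length(bg), wilcoxon_p = p,
      stringsAsFactors = FALSE)
  }
  background <- do.call(rbind, bg_list)
  rownames(background) <- NULL
  list(comparison = do.call(rbind, comp), background = background)
}

#' Enrichment of significantly signed correlations among cDMRs
#'
#' Classifies each region as significantly positively correlated (`r > 0`,
#' `p < alpha`), significantly negatively correlated, or neither, and per
#' stratum and sign runs a one-sided Fisher's exact test of cDMRs versus
#' background on the 2x2 table (significant-with-that-sign / not).
#'
#' @param cdmr_cor,bg_cor Correlation data.frames for the cDMR and
#'   background sets.
#' @param alpha Nominal significance threshold for calling a correlation
#'   (default 0.05).
#' @return data.frame `stratum`, `sign`, `n_cdmr_sig`, `n_cdmr`,
#'   `n_bg_sig`, `n_bg`, `odds_ratio`, `p`, `degenerate`.
#' @export
sign_enrichment_test <- function(cdmr_cor, bg_cor, alpha = 0.05) {
  if (is.null(bg_cor)) bg_cor <- cdmr_cor[0, , drop = FALSE]
  classify <- function(d, s) {
    ok <- !is.na(d$p)
    if (s == "pos") ok & d$p < alpha & d$r > 0 else ok & d$p < alpha & d$r < 0
  }
  out <- list()
  for (st in unique(cdmr_cor$stratum)) {
    fg <- cdmr_cor[cdmr_cor$stratum == st, , drop = FALSE]
    bg <- bg_cor[bg_cor$stratum == st, , drop = FALSE]
    for (s in c("pos", "neg")) {
      a <- sum(classify(fg, s)); b <- sum(classify(bg, s))
      tab <- matrix(c(a, nrow(fg) - a, b, nrow(bg) - b), nrow = 2,
                    byrow = TRUE)
      degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
      if (degenerate) {
        p <- 1
        orr <- NA_real_
      } else {
        ft <- stats::fisher.test(tab, alternative = "greater")
        p <- ft$p.value
        orr <- unname(ft$estimate)
      }
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, sign = s, n_cdmr_sig = a, n_cdmr = nrow(fg),
        n_bg_sig = b, n_bg = nrow(bg), odds_ratio = orr, p = p,
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric enrichment of cLMR genes in expression-enriched gene sets
#'
#' For every combination of cLMR cell type (and stratum) and
#' expression-enriched cell type: an upper-tail hypergeometric test of the
#' overlap between the genes carrying a cLMR of cell A (in that stratum)
#' and the genes with enriched expression in cell B, within the supplied
#' gene universe.
#'
#' @param clmr_genes data.frame `cell_type`, `stratum`, `gene_id`.
#' @param enriched data.frame `gene_id`, `cell_type`, `log2fc`, `fdr`
#'   (members must satisfy log2FC > 1 and FDR < 0.05).
#' @param universe Character vector of all gene ids under consideration.
#' @return data.frame with one row per (cLMR cell, enriched cell, stratum).
#' @export
clmr_gene_set_enrichment <- function(clmr_genes, enriched, universe) {
  bad <- setdiff(unique(c(clmr_genes$gene_id, enriched$gene_id)), universe)
  if (length(bad)) stop("gene outside universe: ", bad[1L])
  if (any(enriched$log2fc <= 1 | enriched$fdr >= 0.05)) {
    stop("enriched-gene table must satisfy log2FC > 1 and FDR < 0.05")
  }
  N <- length(unique(universe))
  out <- list()
  for (cb in unique(enriched$cell_type)) {
    eg <- unique(enriched$gene_id[enriched$cell_type == cb])
    for (ca in unique(clmr_genes$cell_type)) {
      for (st in unique(clmr_genes$stratum)) {
        cg <- unique(clmr_genes$gene_id[clmr_genes$cell_type == ca &
                                        clmr_genes$stratum == st])
        row <- hypergeom_enrichment(length(intersect(cg, eg)), length(eg),
                                    length(cg), N)
        out[[length(out) + 1L]] <- cbind(
          data.frame(clmr_cell = ca, enriched_cell = cb, stratum = st,
                     stringsAsFactors = FALSE), row)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' GWAS SNP enrichment within cDMRs per trait class
#'
#' The universe is every SNP in the table (all trait classes); the category
#' is the SNPs falling inside any cDMR (1-based SNP position within the
#' 0-based half-open region, i.e. `start < pos <= end`); the draws are the
#' SNPs of the tested class. Upper-tail hypergeometric p per class. SNPs on
#' chromosomes absent from `known_chroms` (when given) are excluded with a
#' count.
#'
#' @param snps SNP data.frame from [read_snp_table()].
#' @param cdmr_regions data.frame `chrom`, `start`, `end` of the cDMRs
#'   (0-based half-open).
#' @param known_chroms Optional chromosome whitelist.
#' @return data.frame with one row per trait class, plus attribute
#'   `n_excluded`.
#' @export
gwas_snp_enrichment <- function(snps, cdmr_regions, known_chroms = NULL) {
  n_excluded <- 0L
  if (!is.null(known_chroms)) {
    drop <- !(snps$chrom %in% known_chroms)
    n_excluded <- sum(drop)
    snps <- snps[!drop, , drop = FALSE]
  }
  in_dmr <- rep(FALSE, nrow(snps))
  if (nrow(cdmr_regions) && nrow(snps)) {
    sgr <- GenomicRanges::GRanges(snps$chrom,
                                  IRanges::IRanges(snps$pos, snps$pos))
    dgr <- regions_gr(cdmr_regions)
    in_dmr[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(sgr, dgr)))] <- TRUE
  }
  N <- nrow(snps)
  K <- sum(in_dmr)
  out <- do.call(rbind, lapply(sort(unique(snps$trait_class)),
                               function(cl) {
    sel <- snps$trait_class == cl
    row <- hypergeom_enrichment(sum(in_dmr & sel), K, sum(sel), N)
    cbind(data.frame(trait_class = cl, stringsAsFactors = FALSE), row)
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
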