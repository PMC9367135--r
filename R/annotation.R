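#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# regions data.frame (chrom, start, end in 0-based half-open) -> GRanges
regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

# 0-based inclusive base window [lo, hi] -> GRanges, clipped at base 0
window_gr <- function(chrom, lo, hi) {
  lo <- pmax(lo, 0L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(lo + 1L, hi + 1L))
}

#' Annotate regions with gene-feature and CpG-island classes
#'
#' Feature classes follow the precedence promoter > tts > exon > intron >
#' intergenic; any overlap of at least 1 bp qualifies. The promoter is the
#' strand-aware window `promoter_bp` upstream of the TSS through the TSS;
#' the TTS window extends `tts_bp` either side of the TTS. CGI classes
#' follow the precedence cgi > shore > non_cgi, where a shore is within
#' `shore_bp` of a CGI edge. Intergenic regions carry the nearest TSS gene
#' and its distance (see [nearest_tss()]).
#'
#' @param regions data.frame `region_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes Gene-model data.frame (see [gene_models()]).
#' @param cgis CpG-island intervals (`chrom`, `start`, `end`).
#' @param promoter_bp Promoter window size upstream of the TSS (default
#'   2000).
#' @param tts_bp TTS flank on either side (default 1000).
#' @param shore_bp CGI shore flank (default 2000).
#' @return data.frame `region_id`, `feature_class`, `cgi_class`,
#'   `overlapping_gene_ids` (comma-joined ids of the genes conferring the
#'   assigned class), `nearest_gene_id`, `nearest_tss_distance` (intergenic
#'   regions only).
#' @export
annotate_regions <- function(regions, genes, cgis, promoter_bp = 2000L,
                             tts_bp = 1000L, shore_bp = 2000L) {
  n <- nrow(regions)
  rgr <- regions_gr(regions)

  prom <- window_gr(genes$chrom,
                    ifelse(genes$strand == "+", genes$tss - promoter_bp,
                           genes$tss),
                    ifelse(genes$strand == "+", genes$tss,
                           genes$tss + promoter_bp))
  ttsw <- window_gr(genes$chrom, genes$tts - tts_bp, genes$tts + tts_bp)
  exon_gene <- rep(seq_len(nrow(genes)), lengths(genes$exon_starts))
  exons <- GenomicRanges::GRanges(
    genes$chrom[exon_gene],
    IRanges::IRanges(unlist(genes$exon_starts) + 1L,
                     unlist(genes$exon_ends)))
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))

  hit_genes <- function(target, gene_of = NULL) {
    ov <- GenomicRanges::findOverlaps(rgr, target)
    gi <- if (is.null(gene_of)) S4Vectors::subjectHits(ov)
          else gene_of[S4Vectors::subjectHits(ov)]
    split(genes$gene_id[gi], factor(S4Vectors::queryHits(ov),
                                    levels = seq_len(n)))
  }
  g_prom <- hit_genes(prom)
  g_tts <- hit_genes(ttsw)
  g_exon <- hit_genes(exons, exon_gene)
  g_body <- hit_genes(body)

  feature <- character(n)
  glist <- vector("list", n)
  for (i in seq_len(n)) {
    if (length(g_prom[[i]])) {
      feature[i] <- "promoter"; glist[[i]] <- g_prom[[i]]
    } else if (length(g_tts[[i]])) {
      feature[i] <- "tts"; glist[[i]] <- g_tts[[i]]
    } else if (length(g_exon[[i]])) {
      feature[i] <- "exon"; glist[[i]] <- g_exon[[i]]
    } else if (length(g_body[[i]])) {
      feature[i] <- "intron"; glist[[i]] <- g_body[[i]]
    } else {
      feature[i] <- "intergenic"
    }
  }

  cgi_class <- rep("non_cgi", n)
  if (nrow(cgis)) {
    cgr <- regions_gr(cgis)
    shores <- c(window_gr(cgis$chrom, cgis$start - shore_bp,
                          cgis$start - 1L),
                window_gr(cgis$chrom, cgis$end, cgis$end + shore_bp - 1L))
    in_shore <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(rgr, shores)))
    cgi_class[in_shore] <- "shore"
    in_cgi <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(rgr, cgr)))
    cgi_class[in_cgi] <- "cgi"
  }

  out <- data.frame(
    region_id = regions$region_id, feature_class = feature,
    cgi_class = cgi_class,
    overlapping_gene_ids = vapply(glist, function(g) {
      paste(sort(unique(g)), collapse = ",")
    }, character(1)),
    nearest_gene_id = NA_character_, nearest_tss_distance = NA_real_,
    stringsAsFactors = FALSE)

  inter <- which(feature == "intergenic")
  if (length(inter)) {
    nt <- nearest_tss(regions[inter, , drop = FALSE], genes)
    out$nearest_gene_id[inter] <- nt$gene_id
    out$nearest_tss_distance[inter] <- nt$distance
  }
  out
}

#' Nearest transcription start site to each region
#'
#' Distance convention (0-based region coordinates, `end` exclusive): 0 when
#' the TSS lies inside the region; `start - tss + 1` when the TSS is
#' upstream of the region start; `tss - end + 1` when it is at or beyond the
#' region end. Ties are broken by the lexicographically smallest gene id.
#' Regions on chromosomes without genes get `NA` with a warning.
#'
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param genes Gene-model data.frame.
#' @return data.frame `gene_id`, `distance`, one row per input region.
#' @export
nearest_tss <- function(regions, genes) {
  out <- data.frame(gene_id = rep(NA_character_, nrow(regions)),
                    distance = rep(NA_real_, nrow(regions)),
                    stringsAsFactors = FALSE)
  for (ch in unique(regions$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ri <- which(regions$chrom == ch)
    if (!nrow(g)) next
    g <- g[order(g$gene_id), , drop = FALSE]
    for (i in ri) {
      s <- regions$start[i]; e <- regions$end[i]
      d <- ifelse(g$tss < s, s - g$tss + 1,
                  ifelse(g$tss >= e, g$tss - e + 1, 0))
      best <- which.min(d)  # first minimum = smallest gene_id on ties
      out$gene_id[i] <- g$gene_id[best]
      out$distance[i] <- d[best]
    }
  }
  if (anyNA(out$gene_id)) {
    warning(sum(is.na(out$gene_id)),
            " region(s) on chromosomes without genes left unassigned")
  }
  out
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= observed)` for `X ~ Hypergeometric(universe_n, category_n,
#' draw_n)`, with `expected = draw_n * category_n / universe_n` and
#' `score = log2(observed / expected)` (`NA` when the expectation is zero).
#'
#' @param observed Overlap count.
#' @param category_n Category size within the universe.
#' @param draw_n Number of draws.
#' @param universe_n Universe size.
#' @return One-row data.frame `observed`, `expected`, `score`, `p`,
#'   `universe_n`, `category_n`, `draw_n`.
#' @export
hypergeom_enrichment <- function(observed, category_n, draw_n, universe_n) {
  stopifnot(observed <= min(category_n, draw_n))
  expected <- draw_n * category_n / universe_n
  data.frame(observed = observed, expected = expected,
             score = if (expected > 0) log2(observed / expected)
                     else NA_real_,
             p = stats::phyper(observed - 1, category_n,
                               universe_n - category_n, draw_n,
                               lower.tail = FALSE),
             universe_n = universe_n, category_n = category_n,
             draw_n = draw_n)
}

#' Genomic-feature enrichment of per-cell cLMR sets
#'
#' Hypergeometric enrichment over tiles as sampling units: the universe is
#' all retained tiles, the category the tiles of a given feature (or CGI)
#' class, and the draws one cell type's cLMR tiles.
#'
#' @param clmrs cLMR call data.frame from [classify_clmrs()].
#' @param universe_ids Region ids of all retained (tested) tiles.
#' @param annotations Output of [annotate_regions()] covering the universe.
#' @param what `"feature"` (default) or `"cgi"`: which annotation layer to
#'   enrich over.
#' @return data.frame with one row per (cell type, class).
#' @export
feature_enrichment <- function(clmrs, universe_ids, annotations,
                               what = c("feature", "cgi")) {
  what <- match.arg(what)
  ann <- annotations[match(universe_ids, annotations$region_id), ]
  if (anyNA(ann$region_id)) stop("annotations must cover all tested regions")
  cls <- if (what == "feature") ann$feature_class else ann$cgi_class
  N <- length(universe_ids)
  hits <- clmrs[clmrs$is_clmr, , drop = FALSE]
  out <- list()
  for (ct in unique(clmrs$cell_type)) {
    draw_ids <- unique(hits$region_id[hits$cell_type == ct])
    draw_cls <- cls[match(draw_ids, universe_ids)]
    for (cl in sort(unique(cls))) {
      K <- sum(cls == cl)
      row <- hypergeom_enrichment(sum(draw_cls == cl, na.rm = TRUE), K,
                                  length(draw_ids), N)
      row <- cbind(data.frame(cell_type = ct, class = cl,
                              stringsAsFactors = FALSE), row)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
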