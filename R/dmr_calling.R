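#' Per-region cell-effect ANOVA
#'
#' Fits the additive two-factor model `rate ~ cell_type + animal` by least
#' squares for one region and tests the cell effect by the extra sum of
#' squares: the full model is compared against the animal-only reduced
#' model, `F = ((RSS_reduced - RSS_full) / df_num) / (RSS_full / df_den)`
#' with `df_num` the rank difference and `df_den` the residual df of the
#' full model. With one observation per cell x animal a random animal
#' intercept is not separable from its fixed-effect counterpart, so the
#' animal term enters as a fixed additive effect; the resulting F is the
#' classical balanced two-way ANOVA F on complete designs.
#'
#' @param rates Numeric vector of per-sample methylation rates, named by
#'   sample id (or in `samples` order). `NA`s (missing cells) are allowed.
#' @param samples Sample sheet (`sample_id`, `cell_type`, `animal`).
#' @return List with `F_cell`, `df_num`, `df_den`, `p_cell`, `untestable`,
#'   `exact_fit`.
#' @export
cell_effect_anova <- function(rates, samples) {
  if (!is.null(names(rates))) {
    samples <- samples[match(names(rates), samples$sample_id), ]
  } else if (length(rates) != nrow(samples)) {
    stop("rates must be named by sample id or match samples row order")
  }
  res <- anova_batch(matrix(rates, nrow = 1), samples$cell_type,
                     samples$animal)
  lapply(res, `[`, 1L)
}

# Vectorised extra-sum-of-squares two-factor ANOVA over the rows of Y.
# Rows are grouped by missingness pattern so each distinct design is QR
# decomposed once.
anova_batch <- function(Y, cell, animal) {
  n <- nrow(Y)
  out <- list(F_cell = rep(NA_real_, n), df_num = rep(NA_integer_, n),
              df_den = rep(NA_integer_, n), p_cell = rep(NA_real_, n),
              untestable = rep(TRUE, n), exact_fit = rep(FALSE, n))
  cell <- as.character(cell)
  animal <- as.character(animal)
  pat <- apply(!is.na(Y), 1L, function(r) paste(as.integer(r),
                                                collapse = ""))
  for (p in unique(pat)) {
    rows <- which(pat == p)
    obs <- which(strsplit(p, "")[[1L]] == "1")
    if (length(obs) < 3L) next
    ce <- factor(cell[obs])
    an <- factor(animal[obs])
    if (nlevels(ce) < 2L || nlevels(an) < 2L) next
    X_full <- stats::model.matrix(~ ce + an)
    X_red <- stats::model.matrix(~ an)
    qf <- qr(X_full)
    qr_ <- qr(X_red)
    df_num <- qf$rank - qr_$rank
    df_den <- length(obs) - qf$rank
    if (df_num < 1L || df_den < 1L) next
    Qf <- qr.Q(qf)[, seq_len(qf$rank), drop = FALSE]
    Qr <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
    Ys <- Y[rows, obs, drop = FALSE]
    rss_full <- rowSums((Ys - (Ys %*% Qf) %*% t(Qf))^2)
    rss_red <- rowSums((Ys - (Ys %*% Qr) %*% t(Qr))^2)
    tot <- rowSums((Ys - rowMeans(Ys))^2)

    Fv <- ((rss_red - rss_full) / df_num) / (rss_full / df_den)
    pv <- stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
    constant <- tot < 1e-20
    Fv[constant] <- 0
    pv[constant] <- 1
    exact <- !constant & rss_full < 1e-20
    Fv[exact] <- Inf
    pv[exact] <- 1e-300
    pv <- pmax(pv, 1e-300)

    out$F_cell[rows] <- Fv
    out$df_num[rows] <- df_num
    out$df_den[rows] <- df_den
    out$p_cell[rows] <- pv
    out$untestable[rows] <- FALSE
    out$exact_fit[rows] <- exact
  }
  out
}

#' Benjamini-Hochberg FDR adjustment with NA passthrough
#'
#' Step-up BH adjustment of a single batch of p-values. `NA` entries
#' (untestable regions) are excluded from the batch size and returned as
#' `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Call cell differentially methylated regions (cDMRs)
#'
#' Runs the cell-effect ANOVA on every retained tile, applies BH correction
#' across all testable tiles in one genome-wide batch, and flags tiles with
#' `q < fdr_threshold` as cDMRs.
#'
#' @param tiles A filtered `tile_matrix`.
#' @param samples Sample sheet.
#' @param fdr_threshold cDMR FDR cut-off (default 0.01).
#' @return data.frame with one row per tile: `region_id`, `F_cell`,
#'   `df_num`, `df_den`, `p_cell`, `q_cell`, `is_cdmr`, `untestable`,
#'   `exact_fit`.
#' @export
call_cdmrs <- function(tiles, samples, fdr_threshold = 0.01) {
  stopifnot(inherits(tiles, "tile_matrix"))
  if (nrow(tiles$regions) == 0L) {
    return(data.frame(region_id = character(), F_cell = numeric(),
                      df_num = integer(), df_den = integer(),
                      p_cell = numeric(), q_cell = numeric(),
                      is_cdmr = logical(), untestable = logical(),
                      exact_fit = logical(), stringsAsFactors = FALSE))
  }
  meta <- samples[match(tiles$samples, samples$sample_id), ]
  res <- anova_batch(tiles$rate, meta$cell_type, meta$animal)
  q <- bh_fdr(res$p_cell)
  data.frame(region_id = tiles$regions$region_id, F_cell = res$F_cell,
             df_num = res$df_num, df_den = res$df_den, p_cell = res$p_cell,
             q_cell = q, is_cdmr = !is.na(q) & q < fdr_threshold,
             untestable = res$untestable, exact_fit = res$exact_fit,
             stringsAsFactors = FALSE)
}

#' Classify cell lowly methylated regions (cLMRs)
#'
#' For every cDMR, each sample's methylation rate is standardized using the
#' mean and sample (n-1 denominator) standard deviation across all of the
#' region's samples; the per-cell average z-score is the mean of that cell's
#' samples' z-scores and the per-cell mean rate the mean of its samples'
#' rates. A (region, cell) pair is a cLMR iff the region is a cDMR, the
#' average z-score is below `z_cut` and the mean rate is below `meth_cut`.
#' Regions with zero rate SD yield no cLMRs. With `z_level = "cell"` the
#' z-scores are computed across the nine cell-type means instead of the
#' individual samples.
#'
#' @param dmrs Output of [call_cdmrs()].
#' @param tiles The `tile_matrix` the calls were made on.
#' @param samples Sample sheet.
#' @param z_cut Average z-score threshold (default -1).
#' @param meth_cut Mean methylation threshold as a fraction (default 0.75).
#' @param z_level `"sample"` (default) or `"cell"`.
#' @return data.frame with one row per (cDMR, cell type): `region_id`,
#'   `cell_type`, `mean_rate`, `avg_z`, `is_clmr`.
#' @export
classify_clmrs <- function(dmrs, tiles, samples, z_cut = -1,
                           meth_cut = 0.75, z_level = c("sample", "cell")) {
  z_level <- match.arg(z_level)
  stopifnot(inherits(tiles, "tile_matrix"))
  cdmr_ids <- dmrs$region_id[dmrs$is_cdmr]
  cells <- unique(samples$cell_type[match(tiles$samples,
                                          samples$sample_id)])
  if (!length(cdmr_ids)) {
    return(data.frame(region_id = character(), cell_type = character(),
                      mean_rate = numeric(), avg_z = numeric(),
                      is_clmr = logical(), stringsAsFactors = FALSE))
  }
  idx <- match(cdmr_ids, tiles$regions$region_id)
  Y <- tiles$rate[idx, , drop = FALSE]
  meta <- samples[match(tiles$samples, samples$sample_id), ]
  cf <- factor(meta$cell_type, levels = cells)
  memb <- stats::model.matrix(~ cf - 1)  # samples x cells indicator
  colnames(memb) <- cells

  obs <- !is.na(Y)
  Y0 <- ifelse(obs, Y, 0)
  n_cell <- obs %*% memb
  mean_rate <- (Y0 %*% memb) / ifelse(n_cell > 0, n_cell, NA)

  if (z_level == "sample") {
    n <- rowSums(obs)
    mu <- rowSums(Y0) / n
    ss <- rowSums((ifelse(obs, Y - mu, 0))^2)
    sdv <- sqrt(ss / pmax(n - 1, 1))
    Z <- (Y - mu) / ifelse(sdv > 0, sdv, NA)
    Z0 <- ifelse(obs & !is.na(Z), Z, 0)
    avg_z <- (Z0 %*% memb) / ifelse(n_cell > 0, n_cell, NA)
    avg_z[sdv == 0, ] <- NA
  } else {
    M <- mean_rate
    mu <- rowMeans(M, na.rm = TRUE)
    sdv <- apply(M, 1L, stats::sd, na.rm = TRUE)
    avg_z <- (M - mu) / ifelse(sdv > 0, sdv, NA)
  }

  out <- data.frame(
    region_id = rep(cdmr_ids, times = length(cells)),
    cell_type = rep(cells, each = length(cdmr_ids)),
    mean_rate = as.vector(mean_rate), avg_z = as.vector(avg_z),
    stringsAsFactors = FALSE)
  out$is_clmr <- !is.na(out$avg_z) & !is.na(out$mean_rate) &
    out$avg_z < z_cut & out$mean_rate < meth_cut
  rownames(out) <- NULL
  out
}

#' Per-cell summary of cLMR counts, uniqueness and overlapped genes
#'
#' For each cell type: the number of cLMRs, how many of those are unique to
#' that cell (the region is a cLMR in no other cell), and, when a
#' region-to-gene map is supplied, the number of distinct genes its cLMRs
#' overlap and how many of those genes carry a cLMR in that cell type only.
#' Percentages are `100 * unique / total` rounded to one decimal.
#'
#' @param calls cLMR call data.frame from [classify_clmrs()].
#' @param gene_map Optional data.frame `region_id`, `gene_id` (a region may
#'   map to several genes).
#' @return data.frame with one row per cell type.
#' @export
summarize_clmr_uniqueness <- function(calls, gene_map = NULL) {
  hits <- calls[calls$is_clmr, , drop = FALSE]
  cells <- unique(calls$cell_type)
  # region -> number of distinct cell types flagging it
  reg_cells <- tapply(hits$cell_type, hits$region_id,
                      function(x) length(unique(x)))
  uniq_region <- names(reg_cells)[reg_cells == 1L]

  gene_cells <- NULL
  if (!is.null(gene_map) && nrow(hits)) {
    gm <- merge(hits[, c("region_id", "cell_type")], gene_map,
                by = "region_id")
    gene_cells <- tapply(gm$cell_type, gm$gene_id,
                         function(x) length(unique(x)))
  }

  out <- do.call(rbind, lapply(cells, function(ct) {
    mine <- hits[hits$cell_type == ct, , drop = FALSE]
    n <- nrow(mine)
    u <- sum(mine$region_id %in% uniq_region)
    row <- data.frame(cell_type = ct, n_clmrs = n, n_unique = u,
                      pct_unique = if (n > 0) round(100 * u / n, 1)
                                   else NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(gene_cells)) {
      gm <- gene_map[gene_map$region_id %in% mine$region_id, , drop = FALSE]
      genes <- unique(gm$gene_id)
      ng <- length(genes)
      ug <- sum(gene_cells[genes] == 1L)
      row$n_genes <- ng
      row$n_unique_genes <- ug
      row$pct_unique_genes <- if (ng > 0) round(100 * ug / ng, 1)
                              else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  out
}
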