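#' Aggregate per-CpG counts into fixed non-overlapping genome tiles
#'
#' Tiles are anchored at coordinate 0 and cover the genome in `tile_size`
#' steps (default 1 kb, the regional unit used throughout the package). A
#' CpG at 1-based position `p` falls in tile `floor((p - 1) / tile_size)`.
#' Per tile and sample, methylated and total counts are pooled over member
#' CpGs and the rate is the pooled (coverage-weighted) ratio
#' `n_meth / n_total` -- not the mean of per-CpG rates. Tiles with no CpG in
#' any sample are not represented; the final partial tile of a chromosome is
#' kept if it contains CpGs.
#'
#' @param reports Named list of CpG record data.frames (one per sample; see
#'   [read_cpg_report()]).
#' @param tile_size Tile width in bp (default 1000).
#' @param chrom_lengths Optional named vector; records beyond the declared
#'   chromosome length raise an error.
#' @return A `tile_matrix`: list with `regions` (data.frame `region_id`,
#'   `chrom`, `start`, `end` in BED 0-based half-open coordinates, `n_cpg`),
#'   matrices `meth`, `total`, `rate` (regions x samples; `rate` is `NA`
#'   where `n_total` is 0), and `samples` (sample ids).
#' @export
tile_counts <- function(reports, tile_size = 1000L, chrom_lengths = NULL) {
  stopifnot(is.list(reports), length(reports) > 0)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    stop("reports must be a named list (sample ids)")
  }
  tile_size <- as.integer(tile_size)
  if (tile_size <= 0L) stop("tile_size must be positive")

  per_sample <- lapply(reports, function(rec) {
    if (!nrow(rec)) {
      return(data.frame(key = character(), chrom = character(),
                        start = integer(), meth = integer(),
                        total = integer(), stringsAsFactors = FALSE))
    }
    if (!is.null(chrom_lengths)) {
      lim <- chrom_lengths[rec$chrom]
      if (anyNA(lim) || any(rec$pos > lim)) {
        stop("CpG record beyond declared chromosome length")
      }
    }
    bin <- (rec$pos - 1L) %/% tile_size
    key <- paste0(rec$chrom, ":", bin)
    grp <- match(key, unique(key))
    first <- !duplicated(grp)
    data.frame(key = key[first], chrom = rec$chrom[first],
               start = bin[first] * tile_size,
               meth = as.integer(rowsum(rec$n_meth, grp)[, 1L]),
               total = as.integer(rowsum(rec$n_meth + rec$n_unmeth,
                                         grp)[, 1L]),
               stringsAsFactors = FALSE)
  })

  all_keys <- unique(unlist(lapply(per_sample, `[[`, "key")))
  if (!length(all_keys)) stop("no CpG records in any sample")
  meta <- do.call(rbind, lapply(per_sample, function(d) {
    d[, c("key", "chrom", "start")]
  }))
  meta <- meta[!duplicated(meta$key), ]
  ord <- order(meta$chrom, meta$start)
  meta <- meta[ord, ]

  n <- nrow(meta)
  samples <- names(reports)
  meth <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  total <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  for (s in samples) {
    d <- per_sample[[s]]
    i <- match(d$key, meta$key)
    meth[i, s] <- d$meth
    total[i, s] <- d$total
  }

  # distinct CpG sites per tile across the union of samples
  site <- unique(do.call(rbind, lapply(reports, function(rec) {
    rec[, c("chrom", "pos"), drop = FALSE]
  })))
  skey <- paste0(site$chrom, ":", (site$pos - 1L) %/% tile_size)
  n_cpg <- as.integer(table(factor(skey, levels = meta$key)))

  regions <- data.frame(
    region_id = paste0(meta$chrom, ":", meta$start, "-",
                       meta$start + tile_size),
    chrom = meta$chrom, start = meta$start,
    end = meta$start + tile_size, n_cpg = n_cpg, stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  rate <- ifelse(total > 0L, meth / total, NA_real_)
  rownames(meth) <- rownames(total) <- rownames(rate) <- regions$region_id
  structure(list(regions = regions, meth = meth, total = total, rate = rate,
                 samples = samples), class = "tile_matrix")
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat("tile_matrix:", nrow(x$regions), "regions x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Subset a tile_matrix by region
#' @param tiles A `tile_matrix`.
#' @param keep Logical or integer index over regions.
#' @return The subsetted `tile_matrix`.
#' @export
subset_tiles <- function(tiles, keep) {
  tiles$regions <- tiles$regions[keep, , drop = FALSE]
  rownames(tiles$regions) <- NULL
  tiles$meth <- tiles$meth[keep, , drop = FALSE]
  tiles$total <- tiles$total[keep, , drop = FALSE]
  tiles$rate <- tiles$rate[keep, , drop = FALSE]
  if (!is.null(tiles$low_coverage)) {
    tiles$low_coverage <- tiles$low_coverage[keep, , drop = FALSE]
  }
  tiles
}

#' Construct the sample sheet for a cell-by-animal design
#'
#' @param cell_types Character vector of cell-type labels.
#' @param animals Character or integer vector of animal identifiers.
#' @return data.frame `sample_id`, `cell_type`, `animal` with one sample per
#'   cell x animal combination (`sample_id = "<cell>_<animal>"`).
#' @export
sample_sheet <- function(cell_types = pig_immune_cells(), animals = 1:2) {
  grid <- expand.grid(animal = as.character(animals),
                      cell_type = cell_types, stringsAsFactors = FALSE)
  data.frame(sample_id = paste0(grid$cell_type, "_", grid$animal),
             cell_type = grid$cell_type, animal = grid$animal,
             stringsAsFactors = FALSE)
}

#' The nine sorted porcine immune cell populations
#' @return Character vector of cell-type labels.
#' @export
pig_immune_cells <- function() {
  c("CD4T", "SWC6gdT", "Myeloid", "CD8T", "Neut", "CD21nB", "CD21pB", "NK",
    "CD4CD8T")
}

#' Apply the per-animal coverage filter to a tile matrix
#'
#' A tile is retained iff, for every animal, the number of cell types whose
#' pooled tile coverage exceeds `min_coverage` (strictly) is at least
#' `min_cell_types`. The study design has one sample per cell x animal, so a
#' cell type's coverage within an animal is that single sample's pooled
#' total. Rates of surviving cells that individually fail the coverage bound
#' remain defined but are flagged in the `low_coverage` matrix.
#'
#' @param tiles A `tile_matrix`.
#' @param samples Sample sheet (`sample_id`, `cell_type`, `animal`).
#' @param min_coverage Coverage bound, strict `>` (default 25).
#' @param min_cell_types Minimum qualifying cell types per animal (default
#'   7).
#' @param coverage Either `"pooled"` (pooled read count over the tile's
#'   CpGs; default) or `"mean_cpg"` (mean per-CpG depth, pooled total
#'   divided by the tile's CpG count).
#' @return The filtered `tile_matrix` (possibly with zero regions), with a
#'   `low_coverage` logical matrix attached.
#' @export
apply_coverage_filter <- function(tiles, samples, min_coverage = 25,
                                  min_cell_types = 7,
                                  coverage = c("pooled", "mean_cpg")) {
  coverage <- match.arg(coverage)
  stopifnot(inherits(tiles, "tile_matrix"))
  if (!all(tiles$samples %in% samples$sample_id)) {
    stop("every tile sample must map to a (cell_type, animal) pair")
  }
  meta <- samples[match(tiles$samples, samples$sample_id), ]
  if (min_cell_types > length(unique(meta$cell_type))) {
    stop("min_cell_types exceeds the number of cell types")
  }
  cov <- tiles$total
  if (coverage == "mean_cpg") cov <- cov / pmax(tiles$regions$n_cpg, 1L)
  ok_sample <- cov > min_coverage
  keep <- rep(TRUE, nrow(tiles$regions))
  for (an in unique(meta$animal)) {
    cols <- which(meta$animal == an)
    # qualifying distinct cell types per tile within this animal
    n_cells <- rowSums(ok_sample[, cols, drop = FALSE])
    keep <- keep & (n_cells >= min_cell_types)
  }
  tiles$low_coverage <- !ok_sample
  subset_tiles(tiles, keep)
}

#' Global CpG methylation percentage per sample
#'
#' `100 * sum(n_meth) / sum(n_meth + n_unmeth)` over all CpGs of each
#' sample's report.
#'
#' @param reports Named list of CpG record data.frames.
#' @return Named numeric vector of percentages.
#' @export
global_methylation <- function(reports) {
  vapply(reports, function(rec) {
    tot <- sum(rec$n_meth) + sum(rec$n_unmeth)
    if (tot <= 0) stop("global_methylation: sample with zero coverage")
    100 * sum(rec$n_meth) / tot
  }, numeric(1))
}

#' Cell-type global methylation as the mean over that cell's animals
#'
#' @param sample_pct Named vector from [global_methylation()].
#' @param samples Sample sheet.
#' @return Named numeric vector, one value per cell type.
#' @export
cell_global_methylation <- function(sample_pct, samples) {
  meta <- samples[match(names(sample_pct), samples$sample_id), ]
  tapply(sample_pct, meta$cell_type, mean)[unique(meta$cell_type)]
}

#' Serialize a tile_matrix to TSV
#' @param tiles A `tile_matrix`.
#' @param path Output path.
#' @export
write_tile_matrix <- function(tiles, path) {
  df <- tiles$regions
  for (s in tiles$samples) {
    df[[paste0("n_meth.", s)]] <- tiles$meth[, s]
    df[[paste0("n_total.", s)]] <- tiles$total[, s]
    df[[paste0("rate.", s)]] <- sprintf("%.17g", tiles$rate[, s])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
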