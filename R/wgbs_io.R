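#' Read a Bismark-style per-CpG cytosine report
#'
#' Parses the tab-separated CpG-report dialect: `chrom`, 1-based `pos`,
#' `strand`, `count_methylated`, `count_unmethylated`, `context`. Lines whose
#' context is not `"CpG"` are skipped with a counted warning so genome-wide
#' cytosine reports can be fed in unchanged. Reading is gzip-transparent.
#'
#' With `strand_policy = "merge"` (the default), records on the minus strand
#' are shifted to the plus-strand position of their CpG dinucleotide
#' (`pos - 1`) and their counts summed with any plus-strand record there, so
#' each CpG site appears once. Tiling pools both strands anyway, and the two
#' strands of a CpG carry the same methylation state in somatic cells.
#'
#' @param path File path (optionally gzipped).
#' @param strand_policy `"merge"` (default) or `"keep"`.
#' @return A data.frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `n_meth`, `n_unmeth`.
#' @export
read_cpg_report <- function(path, strand_policy = c("merge", "keep")) {
  strand_policy <- match.arg(strand_policy)
  if (!file.exists(path)) stop("CpG report not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_meth = integer(),
                      n_unmeth = integer(), stringsAsFactors = FALSE))
  }
  keep <- nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed CpG report line ", lineno[which(nf < 6L)[1L]],
         " in ", path, ": expected >= 6 fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  n_meth <- suppressWarnings(as.integer(m[, 4L]))
  n_unmeth <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(pos) | is.na(n_meth) | is.na(n_unmeth) |
    !(m[, 3L] %in% c("+", "-"))
  if (any(bad)) {
    stop("malformed CpG report line ", lineno[which(bad)[1L]], " in ", path)
  }
  if (any(n_meth < 0L | n_unmeth < 0L)) {
    stop("negative count at CpG report line ",
         lineno[which(n_meth < 0L | n_unmeth < 0L)[1L]], " in ", path)
  }
  if (any(pos < 1L)) {
    stop("position < 1 at CpG report line ", lineno[which(pos < 1L)[1L]],
         " in ", path)
  }
  ctx <- m[, 6L]
  non_cpg <- ctx != "CpG"
  if (any(non_cpg)) {
    warning(sum(non_cpg), " non-CpG context record(s) skipped in ", path)
  }
  rec <- data.frame(chrom = m[, 1L], pos = pos, strand = m[, 3L],
                    n_meth = n_meth, n_unmeth = n_unmeth,
                    stringsAsFactors = FALSE)[!non_cpg, , drop = FALSE]
  rownames(rec) <- NULL
  if (strand_policy == "merge" && nrow(rec)) rec <- merge_cpg_strands(rec)
  rec
}

#' Merge plus/minus strand records of each CpG dinucleotide
#'
#' Minus-strand records are moved to `pos - 1` (the plus-strand C of the CpG)
#' and counts are summed per site. Total methylated and unmethylated counts
#' per chromosome are conserved.
#'
#' @param records data.frame as returned by [read_cpg_report()].
#' @return data.frame with one plus-strand record per CpG site.
#' @export
merge_cpg_strands <- function(records) {
  pos <- ifelse(records$strand == "-", records$pos - 1L, records$pos)
  key <- paste0(records$chrom, "\r", pos)
  grp <- match(key, unique(key))
  out <- data.frame(
    chrom = records$chrom[!duplicated(grp)],
    pos = pos[!duplicated(grp)],
    strand = "+",
    n_meth = as.integer(rowsum(records$n_meth, grp)[, 1L]),
    n_unmeth = as.integer(rowsum(records$n_unmeth, grp)[, 1L]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-CpG report in the Bismark cytosine-report dialect
#'
#' @param records data.frame with `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`.
#' @param path Output path.
#' @export
write_cpg_report <- function(records, path) {
  df <- data.frame(records$chrom, records$pos, records$strand,
                   records$n_meth, records$n_unmeth, "CpG")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bisulfite conversion efficiency from unmethylated spike-in counts
#'
#' The lambda phage genome is unmethylated, so any methylated call on
#' lambda-derived reads reflects incomplete conversion. Efficiency is
#' `100 - 100 * sum(n_meth) / sum(n_meth + n_unmeth)`, in percent.
#'
#' @param lambda_records CpG records from reads aligned to the spike-in
#'   genome.
#' @return Percentage in `[0, 100]`.
#' @export
conversion_efficiency <- function(lambda_records) {
  tot <- sum(lambda_records$n_meth) + sum(lambda_records$n_unmeth)
  if (!is.finite(tot) || tot <= 0) {
    stop("conversion_efficiency: zero total spike-in coverage")
  }
  100 - 100 * sum(lambda_records$n_meth) / tot
}

#' Read gene models from a BED12 file
#'
#' Coordinates are BED 0-based half-open. The TSS is the 5' end respecting
#' strand: `chromStart` on `+`, `chromEnd - 1` on `-` (both as 0-based base
#' coordinates); the TTS is the opposite end. `thickStart`/`thickEnd` are
#' ignored. Exons come from the block fields.
#'
#' @param path BED12 file.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `tts` and list columns `exon_starts`, `exon_ends` (0-based
#'   half-open).
#' @export
read_gene_bed12 <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric", "character",
                                          "integer", "integer", "character",
                                          "integer", "character", "character"))
  if (ncol(tab) < 12L) stop("BED12 requires 12 columns, got ", ncol(tab))
  if (anyDuplicated(tab[[4L]])) {
    stop("duplicate gene id in ", path, ": ",
         tab[[4L]][anyDuplicated(tab[[4L]])])
  }
  if (any(tab[[2L]] < 0L) || any(tab[[3L]] <= tab[[2L]])) {
    stop("BED12 coordinate out of range in ", path)
  }
  if (!all(tab[[6L]] %in% c("+", "-"))) stop("BED12 strand must be + or -")
  split_ints <- function(x) lapply(strsplit(sub(",$", "", x), ","), as.integer)
  sizes <- split_ints(tab[[11L]])
  offs <- split_ints(tab[[12L]])
  exon_starts <- Map(function(s, o, st) st + o, sizes, offs, tab[[2L]])
  exon_ends <- Map(`+`, exon_starts, sizes)
  gene_models(gene_id = tab[[4L]], chrom = tab[[1L]], strand = tab[[6L]],
              start = tab[[2L]], end = tab[[3L]],
              exon_starts = exon_starts, exon_ends = exon_ends)
}

#' Construct a validated gene-model table
#'
#' @param gene_id,chrom,strand,start,end Vectors of equal length; `start`/
#'   `end` are 0-based half-open gene spans.
#' @param exon_starts,exon_ends Lists of integer vectors (0-based half-open),
#'   one per gene; default one exon spanning the gene.
#' @return Gene-model data.frame (see [read_gene_bed12()]).
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        exon_starts = NULL, exon_ends = NULL) {
  if (is.null(exon_starts)) exon_starts <- as.list(start)
  if (is.null(exon_ends)) exon_ends <- as.list(end)
  ok <- mapply(function(es, ee, s, e) {
    length(es) == length(ee) && all(ee > es) && all(es >= s) && all(ee <= e) &&
      !is.unsorted(es, strictly = TRUE) && all(es[-1] >= ee[-length(ee)])
  }, exon_starts, exon_ends, start, end)
  if (!all(ok)) {
    stop("invalid exon structure for gene ", gene_id[which(!ok)[1L]])
  }
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  strand = as.character(strand), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tts <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g$exon_starts <- exon_starts
  g$exon_ends <- exon_ends
  g
}

#' Write gene models as BED12
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @export
write_gene_bed12 <- function(genes, path) {
  sizes <- vapply(seq_len(nrow(genes)), function(i) {
    paste0(paste(genes$exon_ends[[i]] - genes$exon_starts[[i]],
                 collapse = ","), ",")
  }, character(1))
  offs <- vapply(seq_len(nrow(genes)), function(i) {
    paste0(paste(genes$exon_starts[[i]] - genes$start[i], collapse = ","), ",")
  }, character(1))
  df <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0,
                   genes$strand, genes$start, genes$end, "0",
                   lengths(genes$exon_starts), sizes, offs)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CpG-island intervals from a BED3 file
#' @param path BED3 file (0-based half-open).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_cgi_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED3 requires >= 3 columns")
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]), stringsAsFactors = FALSE)
  if (any(out$start < 0L) || any(out$end <= out$start)) {
    stop("BED coordinate out of range in ", path)
  }
  out
}

#' Write BED3 intervals
#' @param intervals data.frame `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_cgi_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a GWAS SNP table
#'
#' Tab-separated with header: `snp_id`, `chrom`, `pos` (1-based),
#' `trait_class` and optionally `trait`.
#'
#' @param path TSV file.
#' @return data.frame of SNP records.
#' @export
read_snp_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "trait_class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("SNP table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$pos <- as.integer(tab$pos)
  if (any(is.na(tab$pos)) || any(tab$pos < 1L)) {
    stop("SNP position must be a 1-based positive integer")
  }
  if (is.null(tab$trait)) tab$trait <- tab$trait_class
  tab[, c("snp_id", "chrom", "pos", "trait_class", "trait")]
}

#' Write a GWAS SNP table
#' @param snps SNP data.frame.
#' @param path Output path.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TPM expression table
#'
#' Tab-separated with header; first column gene ids, remaining columns one
#' per sample. Any missing cell is an error naming the offending sample.
#'
#' @param path TSV file.
#' @return Numeric matrix, genes x samples.
#' @export
read_tpm_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene id in TPM table: ",
                               ids[anyDuplicated(ids)])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0][1L]
    stop("TPM table has missing value(s) in sample ", bad)
  }
  m
}

#' Write a TPM expression table
#' @param tpm Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_tpm_table <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read position weight matrices in MEME minimal motif format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' Each PWM is a `width x 4` matrix of base probabilities in A, C, G, T
#' order; every row must sum to 1 within 1e-6.
#'
#' @param path MEME minimal motif format file.
#' @return Named list of PWMs (matrices with columns A, C, G, T).
#' @export
read_meme_pwms <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  pwms <- list()
  for (i in motif_at) {
    id <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]][2L]
    j <- i + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("motif ", id, " has no probability matrix")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    vals <- lapply(strsplit(trimws(rows), "[\t ]+"), as.numeric)
    if (any(lengths(vals) != 4L) || anyNA(unlist(vals))) {
      stop("motif ", id, ": malformed probability row")
    }
    pwm <- do.call(rbind, vals)
    colnames(pwm) <- c("A", "C", "G", "T")
    validate_pwm(pwm, id)
    pwms[[id]] <- pwm
  }
  pwms
}

validate_pwm <- function(pwm, id = "PWM") {
  if (!is.matrix(pwm) || ncol(pwm) != 4L || nrow(pwm) < 1L) {
    stop(id, ": PWM must be a width x 4 matrix")
  }
  if (any(pwm < 0)) stop(id, ": PWM probabilities must be non-negative")
  if (any(abs(rowSums(pwm) - 1) > 1e-6)) {
    stop(id, ": PWM column probabilities must sum to 1 (tolerance 1e-6)")
  }
  invisible(pwm)
}

#' Write PWMs in MEME minimal motif format
#' @param pwms Named list of `width x 4` probability matrices.
#' @param path Output path.
#' @export
write_meme_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (id in names(pwms)) {
    pwm <- pwms[[id]]
    writeLines(sprintf("MOTIF %s", id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(pwm)), con)
    writeLines(apply(pwm, 1L, function(r) paste(sprintf("%.10f", r),
                                                collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write region-level call tables (BED6 + TSV)
#'
#' Emits `<prefix>.bed` with one line per region (name = region id, score =
#' `-10 * log10(q)` capped at 1000) and `<prefix>.tsv` with per-cell mean
#' methylation, the F statistic, p, q, cDMR flag and per-cell cLMR flags.
#' Numeric columns are written at full precision so
#' [read_region_results()] round-trips the call set exactly.
#'
#' @param dmrs DMR result data.frame from [call_cdmrs()].
#' @param clmrs cLMR call data.frame from [classify_clmrs()] (may be `NULL`).
#' @param tiles The [tile_matrix] the calls were made on.
#' @param path_prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_region_tables <- function(dmrs, clmrs, tiles, path_prefix) {
  reg <- tiles$regions[match(dmrs$region_id, tiles$regions$region_id), ]
  score <- ifelse(is.na(dmrs$q_cell), 0,
                  pmin(1000, round(-10 * log10(pmax(dmrs$q_cell, 1e-100)))))
  score[!is.na(dmrs$q_cell) & dmrs$q_cell == 0] <- 1000
  bed <- data.frame(reg$chrom, reg$start, reg$end, dmrs$region_id, score, ".")
  bed_path <- paste0(path_prefix, ".bed")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  num <- function(x) sprintf("%.17g", x)
  tsv <- data.frame(region_id = dmrs$region_id, chrom = reg$chrom,
                    start = reg$start, end = reg$end,
                    F_cell = num(dmrs$F_cell), df_num = dmrs$df_num,
                    df_den = dmrs$df_den, p_cell = num(dmrs$p_cell),
                    q_cell = num(dmrs$q_cell), is_cdmr = dmrs$is_cdmr,
                    stringsAsFactors = FALSE)
  if (!is.null(clmrs) && nrow(clmrs)) {
    for (ct in unique(clmrs$cell_type)) {
      sub <- clmrs[clmrs$cell_type == ct, ]
      i <- match(dmrs$region_id, sub$region_id)
      tsv[[paste0("mean_rate.", ct)]] <- num(sub$mean_rate[i])
      tsv[[paste0("avg_z.", ct)]] <- num(sub$avg_z[i])
      tsv[[paste0("is_clmr.", ct)]] <- sub$is_clmr[i]
    }
  }
  tsv_path <- paste0(path_prefix, ".tsv")
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read back region-level calls written by [write_region_tables()]
#'
#' @param path The `.tsv` path produced by [write_region_tables()].
#' @return List with `dmrs` and `clmrs` data.frames matching the written
#'   call set.
#' @export
read_region_results <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  dmrs <- data.frame(region_id = tab$region_id,
                     F_cell = as.numeric(tab$F_cell),
                     df_num = tab$df_num, df_den = tab$df_den,
                     p_cell = as.numeric(tab$p_cell),
                     q_cell = as.numeric(tab$q_cell),
                     is_cdmr = as.logical(tab$is_cdmr),
                     stringsAsFactors = FALSE)
  clmr_cols <- grep("^is_clmr\\.", names(tab), value = TRUE)
  clmrs <- NULL
  if (length(clmr_cols)) {
    cells <- sub("^is_clmr\\.", "", clmr_cols)
    clmrs <- do.call(rbind, lapply(cells, function(ct) {
      data.frame(region_id = tab$region_id, cell_type = ct,
                 mean_rate = as.numeric(tab[[paste0("mean_rate.", ct)]]),
                 avg_z = as.numeric(tab[[paste0("avg_z.", ct)]]),
                 is_clmr = as.logical(tab[[paste0("is_clmr.", ct)]]),
                 stringsAsFactors = FALSE)
    }))
    rownames(clmrs) <- NULL
  }
  list(dmrs = dmrs, clmrs = clmrs)
}
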