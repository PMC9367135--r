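#' Build a pipeline configuration
#'
#' Collects every input path, output directory and analysis parameter for
#' [run_pipeline()]. All thresholds default to the study parameters the
#' package targets: 1 kb tiles, coverage > 25 in at least 7 cell types per
#' animal, cDMR FDR < 0.01, cLMR z-score < -1 and mean methylation < 75%,
#' promoter < 2 kb from the TSS.
#'
#' @param sample_sheet_path TSV with columns `sample_id`, `cell_type`,
#'   `animal`, `path` (per-sample CpG report paths).
#' @param out_dir Output directory.
#' @param genes_path,cgis_path BED12 gene models and BED3 CGIs (optional:
#'   annotation stage skipped when missing).
#' @param tpm_path,tpm_meta_path,enriched_path Expression inputs
#'   (integration stage; `tpm_meta_path` maps TPM columns to cell types).
#' @param snps_path GWAS SNP table (enrichment stage).
#' @param meme_path,positive_fasta,control_fasta Motif stage inputs.
#' @param tile_size,min_coverage,min_cell_types Tiling and coverage-filter
#'   parameters.
#' @param fdr_threshold,z_cut,meth_cut cDMR/cLMR calling thresholds.
#' @param promoter_bp,tts_bp,shore_bp Annotation window sizes.
#' @param alpha Correlation significance threshold for the sign test.
#' @param n_background_draws Background draws for the correlation test.
#' @param seed Seed for all randomized stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet_path, out_dir,
                            genes_path = NULL, cgis_path = NULL,
                            tpm_path = NULL, tpm_meta_path = NULL,
                            enriched_path = NULL, snps_path = NULL,
                            meme_path = NULL, positive_fasta = NULL,
                            control_fasta = NULL, tile_size = 1000L,
                            min_coverage = 25, min_cell_types = 7,
                            fdr_threshold = 0.01, z_cut = -1,
                            meth_cut = 0.75, promoter_bp = 2000L,
                            tts_bp = 1000L, shore_bp = 2000L,
                            alpha = 0.05, n_background_draws = 1L,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys are the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges and that every referenced input path resolves.
#' Never mutates state.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (cond) v <<- c(v, msg)
  chk(config$tile_size <= 0, "tile_size must be positive")
  chk(config$min_coverage < 0, "min_coverage must be non-negative")
  chk(config$fdr_threshold <= 0 || config$fdr_threshold > 1,
      "fdr_threshold must lie in (0, 1]")
  chk(config$meth_cut < 0 || config$meth_cut > 1,
      "meth_cut must lie in [0, 1]")
  chk(config$alpha <= 0 || config$alpha >= 1, "alpha must lie in (0, 1)")
  chk(config$promoter_bp < 0, "promoter_bp must be non-negative")
  chk(config$tts_bp < 0, "tts_bp must be non-negative")
  chk(config$shore_bp < 0, "shore_bp must be non-negative")
  chk(config$n_background_draws < 1, "n_background_draws must be >= 1")

  if (!file.exists(config$sample_sheet_path)) {
    v <- c(v, paste0("sample sheet not found: ", config$sample_sheet_path))
  } else {
    ss <- utils::read.table(config$sample_sheet_path, sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    need <- c("sample_id", "cell_type", "animal", "path")
    if (!all(need %in% names(ss))) {
      v <- c(v, "sample sheet must have sample_id, cell_type, animal, path")
    } else {
      chk(anyDuplicated(paste(ss$cell_type, ss$animal)) > 0,
          "(cell_type, animal) pairs must be unique")
      chk(config$min_cell_types > length(unique(ss$cell_type)),
          "min_cell_types exceeds the number of cell types")
      missing <- ss$path[!file.exists(ss$path)]
      if (length(missing)) {
        v <- c(v, paste0("CpG report not found: ", missing[1L]))
      }
    }
  }
  for (key in c("genes_path", "cgis_path", "tpm_path", "tpm_meta_path",
                "enriched_path", "snps_path", "meme_path",
                "positive_fasta", "control_fasta")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      v <- c(v, paste0(key, " not found: ", p))
    }
  }
  if (!is.null(config$tpm_path) && is.null(config$genes_path)) {
    v <- c(v, "integration requires genes_path for annotation")
  }
  v
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Run the full tiling / cDMR / cLMR / annotation / integration pipeline
#'
#' Executes tiling, coverage filtering, cDMR calling, cLMR classification,
#' then -- for each optional input group present in the config --
#' annotation with feature enrichment, methylation-expression integration,
#' motif enrichment and GWAS SNP enrichment, writing every stage table plus
#' a JSON run manifest (parameters, per-stage counts, seed) under
#' `config$out_dir`. Identical config and inputs produce identical
#' outputs.
#'
#' @param config A validated `pipeline_config`.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid pipeline config:\n  ", paste(violations,
                                               collapse = "\n  "))
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("methylcell")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("out_dir"))])

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ss <- utils::read.table(config$sample_sheet_path, sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  stage_log("load", nrow(ss), " samples")
  reports <- run_stage("load", {
    stats::setNames(lapply(ss$path, read_cpg_report), ss$sample_id)
  })

  tiles <- run_stage("tiling", tile_counts(reports, config$tile_size))
  manifest$n_tiles <- nrow(tiles$regions)
  stage_log("tiling", manifest$n_tiles, " tiles")

  tiles <- run_stage("filter", apply_coverage_filter(
    tiles, ss, config$min_coverage, config$min_cell_types))
  manifest$n_tested <- nrow(tiles$regions)
  stage_log("filter", manifest$n_tested, " tiles retained")

  dmrs <- run_stage("call-dmrs", call_cdmrs(tiles, ss,
                                            config$fdr_threshold))
  manifest$n_cdmrs <- sum(dmrs$is_cdmr)
  stage_log("call-dmrs", manifest$n_cdmrs, " cDMRs")

  clmrs <- run_stage("classify-clmrs", classify_clmrs(
    dmrs, tiles, ss, config$z_cut, config$meth_cut))
  manifest$n_clmrs <- sum(clmrs$is_clmr)
  manifest$n_clmr_regions <- length(unique(
    clmrs$region_id[clmrs$is_clmr]))
  stage_log("classify-clmrs", manifest$n_clmrs, " cLMR flags over ",
            manifest$n_clmr_regions, " regions")
  write_region_tables(dmrs, clmrs, tiles, file.path(out_dir, "regions"))
  gm <- global_methylation(reports)
  utils::write.table(
    data.frame(sample_id = names(gm), global_methylation_pct = gm),
    file.path(out_dir, "global_methylation.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  annotations <- NULL
  if (!is.null(config$genes_path)) {
    genes <- run_stage("annotate", read_gene_bed12(config$genes_path))
    cgis <- if (!is.null(config$cgis_path)) {
      read_cgi_bed(config$cgis_path)
    } else {
      data.frame(chrom = character(), start = integer(), end = integer())
    }
    annotations <- run_stage("annotate", annotate_regions(
      tiles$regions, genes, cgis, config$promoter_bp, config$tts_bp,
      config$shore_bp))
    utils::write.table(annotations, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fe <- run_stage("annotate", rbind(
      feature_enrichment(clmrs, tiles$regions$region_id, annotations,
                         "feature"),
      feature_enrichment(clmrs, tiles$regions$region_id, annotations,
                         "cgi")))
    utils::write.table(fe, file.path(out_dir, "feature_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_annotated <- nrow(annotations)
    stage_log("annotate", nrow(annotations), " regions annotated")
  }

  if (!is.null(config$tpm_path)) {
    tpm <- run_stage("integrate", read_tpm_table(config$tpm_path))
    tpm_meta <- if (!is.null(config$tpm_meta_path)) {
      utils::read.table(config$tpm_meta_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    } else NULL
    cdmr_ids <- dmrs$region_id[dmrs$is_cdmr]
    cors <- run_stage("integrate", correlate_methylation_expression(
      cdmr_ids, tiles, ss, annotations, tpm, tpm_meta))
    utils::write.table(cors, file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bg <- run_stage("integrate", background_correlation_test(
      cors, dmrs, tiles, ss, annotations, tpm, tpm_meta,
      n_draws = config$n_background_draws, seed = config$seed))
    utils::write.table(bg$comparison,
                       file.path(out_dir, "background_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    se <- run_stage("integrate", sign_enrichment_test(cors, bg$background,
                                                      config$alpha))
    utils::write.table(se, file.path(out_dir, "sign_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_correlations <- nrow(cors)
    stage_log("integrate", nrow(cors), " methylation-expression pairs")

    if (!is.null(config$enriched_path)) {
      enr_tab <- utils::read.table(config$enriched_path, sep = "\t",
                                   header = TRUE, stringsAsFactors = FALSE)
      ann_idx <- match(clmrs$region_id, annotations$region_id)
      hits <- clmrs[clmrs$is_clmr, ]
      hidx <- match(hits$region_id, annotations$region_id)
      gid <- ifelse(annotations$feature_class[hidx] == "intergenic",
                    annotations$nearest_gene_id[hidx],
                    annotations$overlapping_gene_ids[hidx])
      cg <- do.call(rbind, lapply(which(nzchar(gid) & !is.na(gid)),
                                  function(i) {
        data.frame(cell_type = hits$cell_type[i],
                   stratum = unname(map_stratum(
                     annotations$feature_class[hidx[i]])),
                   gene_id = strsplit(gid[i], ",")[[1L]],
                   stringsAsFactors = FALSE)
      }))
      universe <- unique(rownames(tpm))
      cg <- cg[cg$gene_id %in% universe, , drop = FALSE]
      enr_tab <- enr_tab[enr_tab$gene_id %in% universe, , drop = FALSE]
      gse <- run_stage("integrate", clmr_gene_set_enrichment(
        cg, enr_tab, universe))
      utils::write.table(gse,
                         file.path(out_dir, "gene_set_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(config$meme_path) && !is.null(config$positive_fasta) &&
      !is.null(config$control_fasta)) {
    pwms <- run_stage("motif-enrich", read_meme_pwms(config$meme_path))
    pos <- Biostrings::readDNAStringSet(config$positive_fasta)
    ctl <- Biostrings::readDNAStringSet(config$control_fasta)
    me <- run_stage("motif-enrich",
                    motif_enrichment_test(pos, ctl, pwms))
    utils::write.table(me, file.path(out_dir, "motif_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_motifs <- length(pwms)
    stage_log("motif-enrich", length(pwms), " motifs tested")
  }

  if (!is.null(config$snps_path)) {
    snps <- run_stage("gwas-enrich", read_snp_table(config$snps_path))
    cdmr_reg <- tiles$regions[tiles$regions$region_id %in%
                                dmrs$region_id[dmrs$is_cdmr], ]
    ge <- run_stage("gwas-enrich", gwas_snp_enrichment(snps, cdmr_reg))
    utils::write.table(ge, file.path(out_dir, "gwas_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_snps <- nrow(snps)
    stage_log("gwas-enrich", nrow(snps), " SNPs tested")
  }

  stopifnot(manifest$n_clmr_regions <= manifest$n_cdmrs,
            manifest$n_cdmrs <= manifest$n_tested,
            manifest$n_tested <= manifest$n_tiles)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
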