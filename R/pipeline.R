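# End-to-end orchestration: read inputs, build loci, link, compute
# statistics, write the output bundle and a run manifest.

#' Validate a pipeline configuration
#'
#' The config is a nested list (usually read from YAML):
#'
#' ```yaml
#' inputs:
#'   loops:                      # one entry per sample
#'     - {path: loops_a.bedpe, sample_id: kc_unstim}
#'   peaks:
#'     - {path: peaks_a.narrowPeak, sample_id: kc_unstim}
#'   gtf: genes.gtf
#'   expression: expression.tsv
#'   snps: gwas_snps.tsv
#'   tads: tads.bed              # optional
#'   eqtl: eqtl.tsv              # optional
#'   background_snps: bg.tsv     # optional
#' params:                       # optional; any link_config() field,
#'   loop_window: 5000           # plus r2_threshold / r2_strict
#' seed: 1
#' ```
#'
#' Validation happens before any computation; a violation is a
#' configuration error.
#'
#' @param config a list, or a path to a YAML file.
#' @return the validated config list (paths untouched), invisibly a fixed
#'   point of parse -> serialize -> parse.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      lg_config_error(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$inputs)) {
    lg_config_error("config must be a list with an 'inputs' section")
  }
  ins <- config$inputs
  for (req in c("loops", "peaks", "gtf", "expression", "snps")) {
    if (is.null(ins[[req]])) {
      lg_config_error(sprintf("config inputs missing required entry '%s'", req))
    }
  }
  for (grp in c("loops", "peaks")) {
    for (e in ins[[grp]]) {
      if (is.null(e$path) || is.null(e$sample_id)) {
        lg_config_error(sprintf(
          "each '%s' entry needs 'path' and 'sample_id'", grp))
      }
    }
  }
  paths <- c(vapply(ins$loops, `[[`, "", "path"),
             vapply(ins$peaks, `[[`, "", "path"),
             ins$gtf, ins$expression, ins$snps,
             ins$tads, ins$eqtl, ins$background_snps)
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing)) {
    lg_config_error(paste("input file(s) not found:",
                          paste(unlist(missing), collapse = ", ")))
  }
  known <- names(formals(link_config))
  extra <- setdiff(names(config$params),
                   c(known, "r2_threshold", "r2_strict", "n_perm"))
  if (length(extra)) {
    lg_config_error(paste("unknown params in config:",
                          paste(extra, collapse = ", ")))
  }
  invisible(config)
}

#' Run the full locus-to-gene pipeline
#'
#' Executes ingest, locus construction, loop- and promoter-evidence
#' linking, the expression filter, and every applicable statistic, then
#' writes the output bundle to `out_dir`:
#' `link_table.tsv` (all evidence rows, audited expression flags),
#' `genes_per_locus.tsv`, `per_disease_summary.tsv`,
#' `closest_gene_report.tsv`, `gene_desert_loci.tsv`, `stats.json`, and
#' `manifest.json` (config snapshot, input digests, warnings). Analytic
#' outputs are deterministic: rerunning with identical inputs and config
#' reproduces digest-identical TSVs.
#'
#' @param config pipeline config (list or YAML path); see
#'   [validate_pipeline_config()].
#' @param out_dir output directory.
#' @return list with the in-memory results (`loci`, `tss`, `link_table`,
#'   `stats`, `outputs` = named file paths), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_pipeline_config(config)
  ins <- config$inputs
  params <- config$params %||% list()
  cfg <- do.call(link_config,
                 params[intersect(names(params), names(formals(link_config)))])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  withCallingHandlers({
    loops <- rbindlist(lapply(ins$loops, function(e)
      read_bedpe_loops(e$path, sample_id = e$sample_id,
                       score_column = e$score_column,
                       score_threshold = e$score_threshold)))
    peaks <- rbindlist(lapply(ins$peaks, function(e)
      read_narrowpeak(e$path, sample_id = e$sample_id)))
    tss <- extract_tss(ins$gtf)
    expr <- read_expression(ins$expression)
    loci <- build_loci(ins$snps,
                       r2_threshold = params$r2_threshold %||% 0.8,
                       strict = isTRUE(params$r2_strict))

    loop_links <- link_by_loop(loci, loops, tss, cfg)
    prom_links <- link_by_promoter(loci, peaks, tss, cfg)
    digests <- as.list(tools::md5sum(unlist(c(
      lapply(ins$loops, `[[`, "path"), lapply(ins$peaks, `[[`, "path"),
      ins$gtf, ins$expression, ins$snps, ins$tads, ins$eqtl,
      ins$background_snps))))
    lt <- assemble_links(loop_links, prom_links, expr, cfg,
                         provenance = list(inputs = digests,
                                           params = unclass(cfg)))

    gpl <- genes_per_locus(lt, loci)
    cg <- closest_gene_report(loci, tss, lt, cfg)
    desert <- gene_desert_loci(loci, tss, cfg)
    dist_stats <- loop_distance_stats(loops)
    per_disease <- disease_gene_counts(lt, loci)

    stats <- list(
      n_loops = nrow(loops),
      n_loci = nrow(loci$loci),
      n_linked_genes = uniqueN(linked_gene_sets(lt)$gene_id),
      genes_per_locus = list(mean_linked_loci = gpl$mean_linked_loci,
                             mean_all_loci = gpl$mean_all_loci),
      loop_distance = list(median = dist_stats$median,
                           mean = dist_stats$mean),
      closest_gene_classes = as.list(table(cg$class)),
      n_gene_desert_loci = length(desert)
    )
    if (!is.null(ins$tads)) {
      tstats <- tad_overlap_stats(loops, read_bed(ins$tads))
      stats$tad <- tstats[c("n_within", "n_crossing", "fraction_within")]
    }
    if (!is.null(ins$eqtl)) {
      val <- eqtl_validation(linked_gene_sets(lt), read_eqtl(ins$eqtl))
      stats$eqtl <- unclass(val)
    }
    if (!is.null(ins$background_snps)) {
      bg <- build_loci(ins$background_snps, r2_threshold = 0)
      enr <- snp_peak_enrichment(loci$variants, peaks, bg$variants,
                                 n_perm = params$n_perm %||% 1000,
                                 seed = config$seed %||% 1)
      stats$snp_peak_enrichment <- enr
    }
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) {
    warnings_log <<- c(warnings_log, trimws(conditionMessage(m)))
    invokeRestart("muffleMessage")
  })

  outputs <- c(
    link_table = file.path(out_dir, "link_table.tsv"),
    genes_per_locus = file.path(out_dir, "genes_per_locus.tsv"),
    per_disease = file.path(out_dir, "per_disease_summary.tsv"),
    closest_gene = file.path(out_dir, "closest_gene_report.tsv"),
    gene_desert = file.path(out_dir, "gene_desert_loci.tsv"),
    stats = file.path(out_dir, "stats.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  fwrite(format_link_table(lt), outputs[["link_table"]], sep = "\t")
  fwrite(gpl$counts, outputs[["genes_per_locus"]], sep = "\t")
  fwrite(per_disease, outputs[["per_disease"]], sep = "\t")
  fwrite(cg, outputs[["closest_gene"]], sep = "\t")
  fwrite(data.table(locus_id = desert), outputs[["gene_desert"]], sep = "\t")
  jsonlite::write_json(stats, outputs[["stats"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  manifest <- list(
    tool = "loopgene",
    version = as.character(utils::packageVersion("loopgene")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = lt$provenance$inputs,
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, outputs[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(loci = loci, tss = tss, link_table = lt, stats = stats,
                 closest_gene = cg, gene_desert = desert,
                 genes_per_locus = gpl, outputs = outputs,
                 warnings = warnings_log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: the on-disk LinkTable dialect (1-based positions for humans).
format_link_table <- function(lt) {
  rows <- copy(lt$links)
  rows[, `:=`(snp_pos_1based = snp_pos + 1,
              tss_pos_1based = tss + 1,
              expressed = as.integer(expressed))]
  lead <- rows$locus_id
  rows[, lead_snp := lead]
  rows[, .(locus_id, lead_snp, snp_id, snp_chrom, snp_pos_1based,
           gene_id, gene_name, evidence, sample_id,
           loop_anchor1, loop_anchor2, tss_pos_1based, distance_bp,
           expressed, tpm)]
}
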