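#' Build GWAS loci from a SNP table
#'
#' Groups variants by lead SNP (locus), applies the LD threshold, and
#' derives each locus's LD-block span. A locus is a lead SNP plus the proxy
#' SNPs in linkage disequilibrium with it at `r2 >= r2_threshold` (or
#' strictly `>` with `strict = TRUE`; GWAS figure legends often print
#' "r2 > 0.8" but catalog conventions vary, so both are supported).
#'
#' Input positions are 1-based (GWAS-catalog/VCF convention) and converted
#' to the package's internal 0-based coordinates. The LD block is the
#' half-open interval from the smallest variant position to the largest
#' plus one, so a single-SNP locus has block width 1.
#'
#' @param x path to a SNP TSV (see [read_snp_table()]) or an equivalent
#'   data.frame.
#' @param r2_threshold minimum r2 with the lead (default 0.8).
#' @param strict logical; apply the threshold strictly (`>`), default
#'   inclusive (`>=`).
#' @return an object of class `locus_set`: a list with
#'   * `variants`: `data.table` of retained variants (`snp_id`, `chrom`,
#'     `pos` 0-based, `r2`, `locus_id`, `disease`);
#'   * `loci`: one row per locus (`locus_id`, `chrom`, `block_start`,
#'     `block_end`, `width`, `n_variants`, `disease`).
#' @export
build_loci <- function(x, r2_threshold = 0.8, strict = FALSE) {
  if (r2_threshold < 0 || r2_threshold > 1) {
    lg_config_error("r2_threshold must be in [0, 1]")
  }
  dt <- if (is.character(x)) read_snp_table(x) else as.data.table(x)
  need <- c("snp_id", "chrom", "pos_1based", "locus_id", "r2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    lg_data_error(paste("SNP table missing columns:",
                        paste(miss, collapse = ", ")))
  }
  if (!"disease" %in% names(dt)) dt <- copy(dt)[, disease := NA_character_]
  dt <- as.data.table(dt)
  if (any(dt$r2 < 0 | dt$r2 > 1, na.rm = TRUE)) {
    lg_data_error("r2 values outside [0, 1]")
  }
  if (any(dt$pos_1based < 1)) lg_data_error("1-based SNP position < 1")
  # chromosome consistency against the lead, checked before filtering
  chk <- dt[, .(n_chrom = uniqueN(norm_chrom(chrom))), by = locus_id]
  if (any(chk$n_chrom > 1)) {
    lg_data_error(sprintf(
      "variants on different chromosomes within locus: %s",
      paste(chk[n_chrom > 1, locus_id], collapse = ", ")))
  }
  if (!all(dt$locus_id %in% dt$snp_id)) {
    bad <- setdiff(unique(dt$locus_id), dt$snp_id)
    lg_data_error(paste("locus without its lead SNP row:",
                        paste(bad, collapse = ", ")))
  }
  ndup <- sum(duplicated(dt[, .(locus_id, snp_id)]))
  if (ndup > 0) {
    warning(sprintf("build_loci: deduplicated %d repeated variant row(s)", ndup))
    dt <- dt[!duplicated(dt[, .(locus_id, snp_id)])]
  }
  keep <- if (strict) dt$r2 > r2_threshold else dt$r2 >= r2_threshold
  dropped_loci <- setdiff(unique(dt$locus_id), unique(dt$locus_id[keep]))
  if (length(dropped_loci)) {
    warning(sprintf("build_loci: dropped %d locus/loci with no variant at r2 %s %.3g",
                    length(dropped_loci), if (strict) ">" else ">=", r2_threshold))
  }
  variants <- dt[keep, .(snp_id, chrom, pos = pos_1based - 1, r2,
                         locus_id, disease)]
  setorder(variants, locus_id, pos, snp_id)
  loci <- variants[, .(
    chrom = chrom[1],
    block_start = min(pos),
    block_end = max(pos) + 1,
    n_variants = .N,
    disease = disease[1]
  ), by = locus_id]
  loci[, width := block_end - block_start]
  setcolorder(loci, c("locus_id", "chrom", "block_start", "block_end",
                      "width", "n_variants", "disease"))
  setorder(loci, locus_id)
  structure(list(variants = variants, loci = loci), class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d loci, %d variants\n",
              nrow(x$loci), nrow(x$variants)))
  invisible(x)
}

#' Classify loci by LD-block width
#'
#' A locus is `small` when its LD block is strictly narrower than
#' `width_cutoff` ("smaller than 100 kb" by default), otherwise `large`.
#' The closest-gene report is restricted to small loci, where "the closest
#' gene" is a meaningful notion.
#'
#' @param loci a `locus_set` (or its `loci` table).
#' @param width_cutoff width cutoff in bp (default 100,000; strict `<`).
#' @return character vector (`"small"`/`"large"`) along the loci table rows.
#' @export
block_width_class <- function(loci, width_cutoff = 100000) {
  if (width_cutoff <= 0) lg_config_error("width_cutoff must be > 0")
  tab <- if (inherits(loci, "locus_set")) loci$loci else as.data.table(loci)
  ifelse(tab$block_end - tab$block_start < width_cutoff, "small", "large")
}
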