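#' Extract transcription start sites from a GTF annotation
#'
#' Reads `transcript` features from a Gencode/Ensembl-style GTF (gzip
#' accepted) and emits one TSS record per transcript whose biotype is in
#' `biotypes` (default: protein-coding transcripts only). The TSS is the
#' strand-dependent first transcribed base, converted to a 0-based
#' coordinate: feature start − 1 on the `+` strand, feature end − 1 on the
#' `-` strand. The biotype attribute key is looked up in order
#' `gene_type`, `gene_biotype`, `transcript_type`, `transcript_biotype`
#' (Gencode vs Ensembl dialect drift).
#'
#' Transcripts with unknown strand (`.`/`*`) are skipped; their count is
#' reported as a warning. A transcript missing `gene_id` or `transcript_id`
#' is a parse error naming the feature.
#'
#' @param path path to a GTF file.
#' @param biotypes character vector of biotypes to keep.
#' @return a `data.table` with columns `gene_id`, `gene_name`,
#'   `transcript_id`, `chrom`, `tss` (0-based), `strand`, `biotype`, sorted
#'   by (`chrom`, `tss`, `transcript_id`) so the result is independent of
#'   GTF line order.
#' @export
extract_tss <- function(path, biotypes = "protein_coding") {
  if (!file.exists(path)) lg_config_error(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "transcript"]
  if (!length(gr)) {
    lg_data_error(sprintf("no transcript features in %s", path))
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  getcol <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]]) else
    rep(NA_character_, nrow(mc))
  gene_id <- getcol("gene_id")
  transcript_id <- getcol("transcript_id")
  gene_name <- getcol("gene_name")
  if (anyNA(gene_id) || anyNA(transcript_id)) {
    bad <- which(is.na(gene_id) | is.na(transcript_id))[1]
    lg_parse_error(sprintf(
      "transcript feature #%d (%s:%d-%d) missing gene_id/transcript_id",
      bad, as.character(GenomicRanges::seqnames(gr))[bad],
      GenomicRanges::start(gr)[bad], GenomicRanges::end(gr)[bad]))
  }
  biotype <- rep(NA_character_, length(gr))
  for (key in c("gene_type", "gene_biotype", "transcript_type",
                "transcript_biotype")) {
    v <- getcol(key)
    fill <- is.na(biotype) & !is.na(v)
    biotype[fill] <- v[fill]
  }
  strand <- as.character(GenomicRanges::strand(gr))
  known <- strand %in% c("+", "-")
  if (any(!known)) {
    warning(sprintf("extract_tss: skipped %d transcript(s) with unknown strand",
                    sum(!known)))
  }
  dt <- data.table(
    gene_id = gene_id,
    gene_name = fifelse(is.na(gene_name), gene_id, gene_name),
    transcript_id = transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = fifelse(strand == "+",
                  as.numeric(GenomicRanges::start(gr)) - 1,
                  as.numeric(GenomicRanges::end(gr)) - 1),
    strand = strand,
    biotype = biotype
  )[known & biotype %in% biotypes]
  dt <- unique(dt)
  if (anyDuplicated(dt$transcript_id)) {
    lg_data_error("conflicting duplicate transcript_id records in annotation")
  }
  setorder(dt, chrom, tss, transcript_id)
  dt[]
}

#' Test gene expression against a TPM threshold
#'
#' A gene counts as expressed in a sample when its TPM in that sample is at
#' least `threshold` (inclusive: TPM 1.0 passes the default 1 TPM filter).
#' Genes absent from the table are treated as not expressed.
#'
#' @param gene_id character vector of gene identifiers.
#' @param sample_id a single sample identifier (a column of `expr`).
#' @param expr expression table from [read_expression()].
#' @param threshold minimum TPM (default 1.0, inclusive).
#' @return logical vector along `gene_id`.
#' @export
is_expressed <- function(gene_id, sample_id, expr, threshold = 1.0) {
  if (threshold < 0) lg_config_error("threshold must be >= 0")
  tpm <- expression_tpm(gene_id, sample_id, expr)
  !is.na(tpm) & tpm >= threshold
}

#' Look up TPM values for genes in one sample
#'
#' @inheritParams is_expressed
#' @return numeric vector of TPM along `gene_id`; `NA` for genes absent
#'   from the table.
#' @export
expression_tpm <- function(gene_id, sample_id, expr) {
  stopifnot(length(sample_id) == 1)
  samples <- setdiff(names(expr), "gene_id")
  if (!sample_id %in% samples) {
    lg_config_error(sprintf(
      "unknown sample_id '%s'; expression table has samples: %s",
      sample_id, paste(samples, collapse = ", ")))
  }
  expr[[sample_id]][match(gene_id, expr$gene_id)]
}
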