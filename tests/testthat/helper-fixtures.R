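# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

library(data.table)

# A compact simulation the full pipeline can chew through in ~a second.
quick_sim_cfg <- function(seed = 42, ...) {
  args <- utils::modifyList(list(
    seed = seed, n_chroms = 2, chrom_length = 2e6, n_tads_per_chrom = 4,
    n_genes = 60, n_noncoding_genes = 6, gene_free_tad_period = 4,
    n_enhancers = 24, n_truth_loops = 80, n_noise_loops = 0,
    n_gwas_loci = 10, n_desert_loci = 2, proxies_per_locus = 4,
    eqtl_dropout = 0, eqtl_spurious_rate = 0,
    n_background_snps = 400, n_background_peaks = 30), list(...))
  do.call(simulation_config, args)
}

# Pipeline config pointing at a simulated bundle.
pipeline_config_for <- function(ds, params = list(), seed = 1) {
  samples <- ds$config$samples
  list(
    inputs = list(
      loops = lapply(samples, function(s)
        list(path = unname(ds$files[[paste0("loops_", s)]]), sample_id = s)),
      peaks = lapply(samples, function(s)
        list(path = unname(ds$files[[paste0("peaks_", s)]]), sample_id = s)),
      gtf = unname(ds$files[["gtf"]]),
      expression = unname(ds$files[["expression"]]),
      snps = unname(ds$files[["gwas_snps"]]),
      tads = unname(ds$files[["tads"]]),
      eqtl = unname(ds$files[["eqtl"]]),
      background_snps = unname(ds$files[["background_snps"]])),
    params = params,
    seed = seed)
}

# Random feature tables for oracle-equivalence checks (caller seeds RNG).
rand_loops_dt <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                          anchor = 2000, samples = c("sa", "sb")) {
  c1 <- sample(chroms, n, replace = TRUE)
  s1 <- sample.int(max_pos, n, replace = TRUE)
  s2 <- sample.int(max_pos, n, replace = TRUE)
  data.table(chrom1 = c1, start1 = s1, end1 = s1 + anchor,
             chrom2 = c1, start2 = s2, end2 = s2 + anchor,
             score = NA_real_,
             sample_id = sample(samples, n, replace = TRUE))
}

rand_tss_dt <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                        n_genes = max(2, n %/% 2)) {
  gid <- sprintf("G%03d", sample.int(n_genes, n, replace = TRUE))
  data.table(gene_id = gid, gene_name = gid,
             transcript_id = sprintf("T%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             tss = sample.int(max_pos, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = "protein_coding")
}

rand_locus_set <- function(n_loci, vars_per_locus = 3,
                           chroms = c("chr1", "chr2"), max_pos = 1e6) {
  rows <- lapply(seq_len(n_loci), function(i) {
    lid <- sprintf("L%03d", i)
    ch <- sample(chroms, 1)
    lead_pos <- sample.int(max_pos, 1)
    prox <- pmax(1, lead_pos + sample(-20000:20000, vars_per_locus))
    data.table(
      snp_id = c(lid, sprintf("%s_p%d", lid, seq_len(vars_per_locus))),
      chrom = ch,
      pos_1based = c(lead_pos, prox),
      locus_id = lid,
      r2 = c(1, round(runif(vars_per_locus, 0.8, 1), 3)),
      disease = "t")
  })
  build_loci(rbindlist(rows))
}

rand_peaks_dt <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                          width = 1500, samples = c("sa", "sb")) {
  s <- sample.int(max_pos, n, replace = TRUE)
  data.table(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + width, signal = 1,
             sample_id = sample(samples, n, replace = TRUE))
}

# A tiny deterministic GTF written to a temp file; returns the path.
write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_tx_line <- function(chrom, start, end, strand, gene, tx,
                        biotype = "protein_coding",
                        type = "transcript", name = gene) {
  sprintf(
    '%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_type "%s";',
    chrom, type, start, end, strand, gene, tx, name, biotype)
}
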