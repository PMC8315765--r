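# Seeded generator producing a coherent toy genome -- TADs, genes, H3K27ac
# peaks, enhancer-promoter loops, GWAS loci with LD proxies, expression,
# eQTL sets -- with emitted ground truth, so every pipeline stage is
# testable without external downloads.
#
# Layout per TAD (width W): slots every 20 kb across [0.05 W, 0.95 W),
# alternating gene slot / enhancer slot, so short enhancer-promoter
# distances are realizable while loop-rule and promoter-rule evidence stay
# separable: the 20 kb pitch exceeds anchor half-width + loop window and
# proxy spread + promoter window, so a variant in an enhancer can only
# reach a gene through a loop, and on noise-free data the pipeline's links
# equal the emitted truth exactly. Every `gene_free_tad_period`-th TAD of
# each chromosome carries enhancer slots only: GWAS loci landing there are
# gene deserts (no TSS within tens of kb).
#
# Randomness: each component draws from its own substream (set.seed on a
# seed derived from cfg$seed + a fixed offset), in the documented order
# genes, enhancers, truth loops, GWAS loci, expression, noise loops,
# background SNPs, eQTL, peaks. Adding an output never perturbs earlier
# draws; the same config yields byte-identical files.

SLOT_SPACING <- 20000

#' Simulation configuration
#'
#' Parameters of the synthetic toy genome. Defaults describe a compact but
#' realistic instance: 2 chromosomes of 10 Mb tiled by 1 Mb TADs, 300
#' protein-coding genes, 200 enhancers, 1,000 loops of which 90% stay
#' within a TAD (the fraction observed for H3K27ac HiChIP interactions
#' against matched Hi-C TADs), anchor-midpoint distances drawn from a
#' gamma distribution with median near 250 kb (the typical median
#' significant-interaction distance), and eQTL sets that echo the truth
#' with realistic dropout and spurious additions.
#'
#' @param seed master RNG seed; every component derives its own substream
#'   from it.
#' @param n_chroms,chrom_length chromosome count and length (bp).
#' @param n_tads_per_chrom TADs per chromosome, tiled edge to edge.
#' @param n_genes protein-coding gene count.
#' @param n_noncoding_genes additional lncRNA genes (exercise the biotype
#'   filter; never truth targets).
#' @param expressed_fraction probability a non-target gene is expressed
#'   (TPM >= 1) in a given sample.
#' @param tpm_meanlog,tpm_sdlog lognormal parameters for expressed TPM
#'   (shifted by +1 so expressed genes always pass the 1 TPM filter).
#' @param gene_free_tad_period every k-th TAD of each chromosome carries
#'   no genes (default 5; 0 disables), creating gene-desert territory.
#' @param n_enhancers enhancer count, assigned round-robin over TADs so
#'   every TAD hosts at least one.
#' @param n_truth_loops,n_noise_loops enhancer-promoter truth loops and
#'   unanchored noise loops.
#' @param fraction_within_tads probability a loop stays inside one TAD.
#' @param loop_dist_shape,loop_dist_scale gamma parameters of the target
#'   anchor distance (bp); defaults give median ~250 kb.
#' @param n_gwas_loci GWAS loci; each lead SNP sits at the center of an
#'   enhancer that anchors at least one truth loop.
#' @param n_desert_loci of the `n_gwas_loci`, how many have their lead
#'   enhancer in a gene-free TAD (default 3). These loci reach their
#'   target genes through TAD-crossing loops (`desert_loops_per_locus`
#'   each) and have no protein-coding TSS nearby.
#' @param desert_loops_per_locus truth loops per gene-desert locus.
#' @param proxies_per_locus,proxy_spread LD proxies per locus, scattered
#'   uniformly within +/- `proxy_spread` bp of the lead; r2 drawn in
#'   [0.65, 1] so some proxies fall below the 0.8 threshold.
#' @param eqtl_dropout probability a truth target gene is missing from the
#'   eQTL set of its locus.
#' @param eqtl_spurious_rate,eqtl_spurious_pool each locus gains
#'   `Binomial(pool, rate)` spurious non-target genes in its eQTL set.
#' @param n_background_snps,n_background_peaks background variant pool and
#'   scattered background peaks per sample.
#' @param samples sample (cell type / condition) labels.
#' @param diseases trait labels, assigned to loci round-robin.
#' @param anchor_width loop anchor width (bp, a fixed-size bin).
#' @param enhancer_width,promoter_peak_width H3K27ac peak widths (bp).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chroms = 2,
                              chrom_length = 10e6,
                              n_tads_per_chrom = 10,
                              n_genes = 300,
                              n_noncoding_genes = 20,
                              gene_free_tad_period = 5,
                              expressed_fraction = 0.7,
                              tpm_meanlog = 1.5,
                              tpm_sdlog = 1.0,
                              n_enhancers = 200,
                              n_truth_loops = 900,
                              n_noise_loops = 100,
                              fraction_within_tads = 0.9,
                              loop_dist_shape = 2,
                              loop_dist_scale = 149000,
                              n_gwas_loci = 40,
                              n_desert_loci = 3,
                              desert_loops_per_locus = 2,
                              proxies_per_locus = 5,
                              proxy_spread = 4000,
                              eqtl_dropout = 0.3,
                              eqtl_spurious_rate = 0.25,
                              eqtl_spurious_pool = 4,
                              n_background_snps = 3000,
                              n_background_peaks = 100,
                              samples = c("kc_unstim", "kc_stim"),
                              diseases = c("trait_a", "trait_b"),
                              anchor_width = 5000,
                              enhancer_width = 1000,
                              promoter_peak_width = 1500) {
  cfg <- as.list(environment())
  fracs <- c("expressed_fraction", "fraction_within_tads", "eqtl_dropout",
             "eqtl_spurious_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      lg_config_error(sprintf("%s must be in [0, 1]", f))
    }
  }
  validate_geometry(cfg)
  structure(cfg, class = "simulation_config")
}

# Internal: TAD tiling plus alternating gene/enhancer slot tables.
sim_layout <- function(cfg) {
  W <- floor(cfg$chrom_length / cfg$n_tads_per_chrom)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  tads <- CJ(chrom = chroms, k = seq_len(cfg$n_tads_per_chrom) - 1)
  tads[, `:=`(start = k * W,
              end = fifelse(k == cfg$n_tads_per_chrom - 1,
                            cfg$chrom_length, (k + 1) * W))]
  tads[, tad_id := paste0(chrom, "_tad", k + 1)]
  per <- cfg$gene_free_tad_period
  tads[, gene_free := per > 0 & (k + 1) %% per == 0]
  slots <- tads[, {
    n_slots <- floor(0.90 * W / SLOT_SPACING)
    pos <- start + round(0.05 * W) + (seq_len(n_slots) - 1) * SLOT_SPACING
    .(pos = pos, kind = rep_len(c("gene", "enhancer"), n_slots),
      gene_free = gene_free)
  }, by = .(chrom, tad_id)]
  list(W = W, chroms = chroms, tads = tads,
       gene_slots = slots[kind == "gene" & !gene_free, .(chrom, tad_id, pos)],
       enh_slots = slots[kind == "enhancer", .(chrom, tad_id, pos)])
}

# Internal: feasibility of the slot layout.
validate_geometry <- function(cfg) {
  n_tads <- cfg$n_chroms * cfg$n_tads_per_chrom
  lay <- sim_layout(cfg)
  if (lay$W < 10 * cfg$anchor_width) {
    lg_config_error(sprintf(
      "infeasible geometry: %d TADs of width %d bp cannot host %d bp anchors",
      n_tads, lay$W, cfg$anchor_width))
  }
  if (cfg$n_genes + cfg$n_noncoding_genes > nrow(lay$gene_slots)) {
    lg_config_error(sprintf(
      "infeasible geometry: %d genes requested but only %d gene slots",
      cfg$n_genes + cfg$n_noncoding_genes, nrow(lay$gene_slots)))
  }
  if (cfg$n_enhancers < n_tads) {
    lg_config_error("n_enhancers must be >= total TAD count (one per TAD)")
  }
  if (cfg$n_enhancers > nrow(lay$enh_slots)) {
    lg_config_error(sprintf(
      "infeasible geometry: %d enhancers requested but only %d slots",
      cfg$n_enhancers, nrow(lay$enh_slots)))
  }
  gene_tads <- unique(lay$gene_slots$tad_id)
  if (!length(gene_tads)) {
    lg_config_error("every TAD is gene-free; no gene placement possible")
  }
  if (cfg$fraction_within_tads < 1 && cfg$n_tads_per_chrom < 2) {
    lg_config_error("TAD-crossing loops need >= 2 TADs per chromosome")
  }
  if (cfg$n_desert_loci > 0) {
    if (cfg$gene_free_tad_period == 0) {
      lg_config_error("n_desert_loci > 0 requires gene_free_tad_period > 0")
    }
    if (cfg$n_desert_loci >= cfg$n_gwas_loci) {
      lg_config_error("n_desert_loci must be smaller than n_gwas_loci")
    }
  }
  invisible(cfg)
}

# Internal: derived sub-seed, kept inside 32-bit integer range.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647)
}

#' Simulate a full input bundle with ground truth
#'
#' Writes every input the linking pipeline consumes -- gene annotation
#' (GTF), expression table, TAD BED, per-sample loop BEDPE and H3K27ac
#' narrowPeak files, GWAS SNP table with LD proxies, background SNP table,
#' eQTL table -- plus `truth.tsv` (the generator's locus-to-gene map) and a
#' manifest of file digests. A pure function of its config: the same
#' config produces byte-identical files.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @return an object of class `synthetic_dataset`: list with `files`
#'   (named paths), `truth` (list: `locus_genes`, `loop_labels`,
#'   `expression_status`), `tables` (the in-memory generated tables) and
#'   `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), out_dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  validate_geometry(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lay <- sim_layout(cfg)
  W <- lay$W
  chroms <- lay$chroms
  tads <- lay$tads

  # --- genes (substream 1) ------------------------------------------------
  set.seed(sub_seed(cfg$seed, 1))
  n_all_genes <- cfg$n_genes + cfg$n_noncoding_genes
  pick <- sort(sample.int(nrow(lay$gene_slots), n_all_genes))
  genes <- lay$gene_slots[pick]
  genes[, `:=`(
    gene_id = sprintf("GENE%04d", seq_len(n_all_genes)),
    gene_name = sprintf("Gn%04d", seq_len(n_all_genes)),
    strand = sample(c("+", "-"), n_all_genes, replace = TRUE),
    biotype = rep(c("protein_coding", "lncRNA"),
                  c(cfg$n_genes, cfg$n_noncoding_genes)),
    n_tx = sample(1:3, n_all_genes, replace = TRUE)
  )]
  setnames(genes, "pos", "tss")  # 0-based

  # --- enhancers (substream 2): round-robin over TADs ---------------------
  set.seed(sub_seed(cfg$seed, 2))
  enh_slots <- lay$enh_slots
  tad_ids <- tads$tad_id
  assign_tad <- tad_ids[(seq_len(cfg$n_enhancers) - 1) %% length(tad_ids) + 1]
  enh_rows <- integer(cfg$n_enhancers)
  for (tid in unique(assign_tad)) {
    idx <- which(assign_tad == tid)
    avail <- which(enh_slots$tad_id == tid)
    enh_rows[idx] <- sample(avail, length(idx), replace = FALSE)
  }
  enhancers <- enh_slots[enh_rows]
  enhancers[, enh_id := sprintf("ENH%04d", seq_len(cfg$n_enhancers))]
  setnames(enhancers, "pos", "center")

  # --- truth loops (substream 3) ------------------------------------------
  set.seed(sub_seed(cfg$seed, 3))
  coding <- genes[biotype == "protein_coding"]
  gene_tad <- coding$tad_id
  n_t <- cfg$n_truth_loops
  g_idx <- sample.int(nrow(coding), n_t, replace = TRUE)
  within <- runif(n_t) < cfg$fraction_within_tads
  target_d <- rgamma(n_t, shape = cfg$loop_dist_shape,
                     scale = cfg$loop_dist_scale)
  e_idx <- integer(n_t)
  for (i in seq_len(n_t)) {
    g <- g_idx[i]
    if (within[i]) {
      elig <- which(enhancers$tad_id == gene_tad[g])
    } else {
      elig <- which(enhancers$chrom == coding$chrom[g] &
                      enhancers$tad_id != gene_tad[g])
    }
    d <- abs(enhancers$center[elig] - coding$tss[g])
    e_idx[i] <- elig[which.min(abs(d - target_d[i]))]
  }
  truth_loops <- data.table(
    loop_name = sprintf("truth_%04d", seq_len(n_t)),
    sample_id = sample(cfg$samples, n_t, replace = TRUE),
    enh_id = enhancers$enh_id[e_idx],
    gene_id = coding$gene_id[g_idx],
    chrom = coding$chrom[g_idx],
    enh_center = enhancers$center[e_idx],
    prom_center = coding$tss[g_idx],
    label = "truth"
  )

  # gene-desert loci: lead enhancers in gene-free TADs, reached by
  # TAD-crossing loops only (there is no gene in their own TAD)
  desert_enh <- character(0)
  if (cfg$n_desert_loci > 0) {
    free_tads <- tads[gene_free == TRUE, tad_id]
    cand <- which(enhancers$tad_id %in% free_tads)
    if (cfg$n_desert_loci > length(cand)) {
      lg_config_error(sprintf(
        "n_desert_loci (%d) exceeds enhancers in gene-free TADs (%d)",
        cfg$n_desert_loci, length(cand)))
    }
    de_idx <- sample(cand, cfg$n_desert_loci, replace = FALSE)
    desert_enh <- enhancers$enh_id[de_idx]
    n_d <- cfg$n_desert_loci * cfg$desert_loops_per_locus
    de_rep <- rep(de_idx, each = cfg$desert_loops_per_locus)
    dg_idx <- integer(n_d)
    d_target <- rgamma(n_d, shape = cfg$loop_dist_shape,
                       scale = cfg$loop_dist_scale)
    for (i in seq_len(n_d)) {
      elig <- which(coding$chrom == enhancers$chrom[de_rep[i]])
      d <- abs(coding$tss[elig] - enhancers$center[de_rep[i]])
      dg_idx[i] <- elig[which.min(abs(d - d_target[i]))]
    }
    desert_loops <- data.table(
      loop_name = sprintf("truth_desert_%04d", seq_len(n_d)),
      sample_id = sample(cfg$samples, n_d, replace = TRUE),
      enh_id = enhancers$enh_id[de_rep],
      gene_id = coding$gene_id[dg_idx],
      chrom = coding$chrom[dg_idx],
      enh_center = enhancers$center[de_rep],
      prom_center = coding$tss[dg_idx],
      label = "truth")
    truth_loops <- rbindlist(list(truth_loops, desert_loops))
  }

  # --- GWAS loci (substream 4) --------------------------------------------
  set.seed(sub_seed(cfg$seed, 4))
  used_enh <- setdiff(unique(truth_loops$enh_id), desert_enh)
  n_regular <- cfg$n_gwas_loci - length(desert_enh)
  if (n_regular > length(used_enh)) {
    lg_config_error(sprintf(
      "n_gwas_loci (%d) exceeds enhancers with truth loops (%d)",
      cfg$n_gwas_loci, length(used_enh) + length(desert_enh)))
  }
  locus_enh <- c(sample(used_enh, n_regular, replace = FALSE), desert_enh)
  enh_lookup <- setNames(seq_len(nrow(enhancers)), enhancers$enh_id)
  lead_pos <- enhancers$center[enh_lookup[locus_enh]]
  lead_chrom <- enhancers$chrom[enh_lookup[locus_enh]]
  locus_ids <- sprintf("rs_sim_%03d", seq_len(cfg$n_gwas_loci))
  locus_disease <- cfg$diseases[(seq_len(cfg$n_gwas_loci) - 1) %%
                                  length(cfg$diseases) + 1]
  snp_rows <- vector("list", cfg$n_gwas_loci)
  for (i in seq_len(cfg$n_gwas_loci)) {
    np <- cfg$proxies_per_locus
    off <- round(runif(np, -cfg$proxy_spread, cfg$proxy_spread))
    ppos <- pmax(0, lead_pos[i] + off)
    snp_rows[[i]] <- data.table(
      snp_id = c(locus_ids[i], sprintf("%s_p%d", locus_ids[i], seq_len(np))),
      chrom = sub("^chr", "", lead_chrom[i]),  # bare dialect on purpose
      pos_1based = c(lead_pos[i], ppos) + 1,
      locus_id = locus_ids[i],
      r2 = c(1, round(runif(np, 0.65, 1), 3)),
      disease = locus_disease[i]
    )
  }
  gwas_snps <- rbindlist(snp_rows)
  truth_map <- unique(merge(
    data.table(locus_id = locus_ids, enh_id = locus_enh),
    truth_loops[, .(enh_id, gene_id)],
    by = "enh_id", allow.cartesian = TRUE)[, .(locus_id, gene_id)])
  setorder(truth_map, locus_id, gene_id)

  # --- expression (substream 5) -------------------------------------------
  set.seed(sub_seed(cfg$seed, 5))
  truth_genes <- unique(truth_map$gene_id)
  expr_long <- CJ(gene_id = genes$gene_id, sample_id = cfg$samples,
                  sorted = TRUE)
  expr_long[, expressed := runif(.N) < cfg$expressed_fraction]
  expr_long[gene_id %in% truth_genes, expressed := TRUE]
  expr_long[, tpm := fifelse(
    expressed,
    round(1 + rlnorm(.N, cfg$tpm_meanlog, cfg$tpm_sdlog), 3),
    round(runif(.N, 0, 0.9), 3))]
  expression <- dcast(expr_long, gene_id ~ sample_id, value.var = "tpm")

  # --- noise loops (substream 6) ------------------------------------------
  set.seed(sub_seed(cfg$seed, 6))
  aw2 <- floor(cfg$anchor_width / 2)
  n_n <- cfg$n_noise_loops
  noise_loops <- if (n_n > 0) {
    nwithin <- runif(n_n) < cfg$fraction_within_tads
    rows <- vector("list", n_n)
    for (i in seq_len(n_n)) {
      if (nwithin[i]) {
        trow <- tads[sample.int(nrow(tads), 1)]
        repeat {
          cs <- sort(round(runif(2, trow$start + aw2, trow$end - aw2 - 1)))
          if (cs[2] - cs[1] >= cfg$anchor_width) break
        }
        rows[[i]] <- data.table(chrom = trow$chrom, c1 = cs[1], c2 = cs[2])
      } else {
        ch <- sample(chroms, 1)
        tt <- tads[chrom == ch][sample.int(cfg$n_tads_per_chrom, 2)]
        c1 <- round(runif(1, tt$start[1] + aw2, tt$end[1] - aw2 - 1))
        c2 <- round(runif(1, tt$start[2] + aw2, tt$end[2] - aw2 - 1))
        rows[[i]] <- data.table(chrom = ch, c1 = min(c1, c2), c2 = max(c1, c2))
      }
    }
    nl <- rbindlist(rows)
    nl[, `:=`(loop_name = sprintf("noise_%04d", seq_len(n_n)),
              sample_id = sample(cfg$samples, n_n, replace = TRUE),
              label = "noise")]
    nl
  } else {
    data.table(chrom = character(), c1 = numeric(), c2 = numeric(),
               loop_name = character(), sample_id = character(),
               label = character())
  }

  # --- background SNPs (substream 7) --------------------------------------
  set.seed(sub_seed(cfg$seed, 7))
  bg_chrom <- sample(chroms, cfg$n_background_snps, replace = TRUE)
  bg_pos <- floor(runif(cfg$n_background_snps, 0, cfg$chrom_length))
  bg_ids <- sprintf("bg_sim_%05d", seq_len(cfg$n_background_snps))
  background_snps <- data.table(
    snp_id = bg_ids, chrom = sub("^chr", "", bg_chrom),
    pos_1based = bg_pos + 1, locus_id = bg_ids, r2 = 1,
    disease = "background")

  # --- eQTL sets (substream 8) --------------------------------------------
  set.seed(sub_seed(cfg$seed, 8))
  coding_ids <- coding$gene_id
  eqtl_rows <- vector("list", cfg$n_gwas_loci)
  for (i in seq_len(cfg$n_gwas_loci)) {
    lid <- locus_ids[i]
    tg <- truth_map[locus_id == lid, gene_id]
    kept <- tg[runif(length(tg)) >= cfg$eqtl_dropout]
    n_sp <- rbinom(1, cfg$eqtl_spurious_pool, cfg$eqtl_spurious_rate)
    decoys <- setdiff(coding_ids, tg)
    spurious <- if (n_sp > 0) sample(decoys, n_sp, replace = FALSE)
                else character(0)
    gg <- c(kept, spurious)
    eqtl_rows[[i]] <- if (length(gg)) data.table(locus_id = lid, gene_id = gg)
                      else NULL
  }
  eqtl <- rbindlist(eqtl_rows)
  if (nrow(eqtl)) setorder(eqtl, locus_id, gene_id)

  # --- peaks (substream 9) ------------------------------------------------
  set.seed(sub_seed(cfg$seed, 9))
  pw2 <- floor(cfg$promoter_peak_width / 2)
  ew2 <- floor(cfg$enhancer_width / 2)
  peak_tabs <- list()
  for (s in cfg$samples) {
    expressed_genes <- expr_long[sample_id == s & tpm >= 1, gene_id]
    prom <- genes[gene_id %in% expressed_genes,
                  .(chrom, start = tss - pw2, end = tss + pw2)]
    enh <- enhancers[, .(chrom, start = center - ew2, end = center + ew2)]
    bgp_center <- floor(runif(cfg$n_background_peaks,
                              5000, cfg$chrom_length - 5000))
    bgp <- data.table(chrom = sample(chroms, cfg$n_background_peaks,
                                     replace = TRUE),
                      start = bgp_center - 500, end = bgp_center + 500)
    pk <- rbindlist(list(prom, enh, bgp))
    pk[, signal := round(runif(.N, 5, 50), 2)]
    setorder(pk, chrom, start, end)
    peak_tabs[[s]] <- pk
  }

  # --- assemble loop tables and write files -------------------------------
  all_loops <- rbindlist(list(
    truth_loops[, .(chrom1 = chrom, start1 = enh_center - aw2,
                    end1 = enh_center + aw2,
                    chrom2 = chrom, start2 = prom_center - aw2,
                    end2 = prom_center + aw2,
                    name = loop_name, sample_id, label)],
    noise_loops[, .(chrom1 = chrom, start1 = c1 - aw2, end1 = c1 + aw2,
                    chrom2 = chrom, start2 = c2 - aw2, end2 = c2 + aw2,
                    name = loop_name, sample_id, label)]))
  all_loops <- sort_loop_anchors(all_loops)

  files <- c(
    gtf = file.path(out_dir, "genes.gtf"),
    expression = file.path(out_dir, "expression.tsv"),
    tads = file.path(out_dir, "tads.bed"),
    gwas_snps = file.path(out_dir, "gwas_snps.tsv"),
    background_snps = file.path(out_dir, "background_snps.tsv"),
    eqtl = file.path(out_dir, "eqtl.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  for (s in cfg$samples) {
    files[paste0("loops_", s)] <- file.path(out_dir,
                                            sprintf("loops_%s.bedpe", s))
    files[paste0("peaks_", s)] <- file.path(out_dir,
                                            sprintf("peaks_%s.narrowPeak", s))
  }

  write_sim_gtf(genes, files[["gtf"]])
  fwrite(expression, files[["expression"]], sep = "\t")
  write_bed(tads[, .(chrom, start, end)], files[["tads"]])
  fwrite(gwas_snps, files[["gwas_snps"]], sep = "\t")
  fwrite(background_snps, files[["background_snps"]], sep = "\t")
  fwrite(eqtl, files[["eqtl"]], sep = "\t")
  fwrite(truth_map, files[["truth"]], sep = "\t")
  for (s in cfg$samples) {
    write_bedpe(all_loops[sample_id == s],
                files[[paste0("loops_", s)]])
    np <- peak_tabs[[s]][, .(chrom, start, end,
                             name = sprintf("peak_%d", .I), score = 0,
                             strand = ".", signal,
                             pValue = -1, qValue = -1, peak = -1)]
    fwrite(np, files[[paste0("peaks_", s)]], sep = "\t", col.names = FALSE)
  }
  manifest <- list(
    tool = "loopgene",
    version = as.character(utils::packageVersion("loopgene")),
    config = unclass(cfg),
    digests = as.list(tools::md5sum(files[names(files) != "manifest"]))
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(
    files = files,
    truth = list(locus_genes = truth_map,
                 loop_labels = all_loops[, .(name, sample_id, label)],
                 expression_status = expr_long[, .(gene_id, sample_id,
                                                   tpm, expressed)]),
    tables = list(genes = genes, enhancers = enhancers, tads = tads,
                  loops = all_loops, gwas_snps = gwas_snps,
                  background_snps = background_snps, eqtl = eqtl,
                  expression = expression, peaks = peak_tabs),
    config = cfg
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d loci -> %d truth genes; %d loops; files in %s\n",
    uniqueN(x$truth$locus_genes$locus_id),
    uniqueN(x$truth$locus_genes$gene_id),
    nrow(x$tables$loops), dirname(x$files[["gtf"]])))
  invisible(x)
}

# Internal: write the gene table as a minimal Gencode-style GTF.
write_sim_gtf <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    tx_len <- 2000 + 4000 * seq_len(g$n_tx)  # deterministic per transcript
    if (g$strand == "+") {
      starts <- rep(g$tss + 1, g$n_tx)
      ends <- g$tss + tx_len
    } else {
      starts <- pmax(1, g$tss + 2 - tx_len)
      ends <- rep(g$tss + 1, g$n_tx)
    }
    gene_attr <- sprintf(
      'gene_id "%s"; gene_name "%s"; gene_type "%s";',
      g$gene_id, g$gene_name, g$biotype)
    lines <- c(lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
      g$chrom, min(starts), max(ends), g$strand, gene_attr))
    for (k in seq_len(g$n_tx)) {
      tx_attr <- sprintf(
        'gene_id "%s"; transcript_id "%s.t%d"; gene_name "%s"; gene_type "%s";',
        g$gene_id, g$gene_id, k, g$gene_name, g$biotype)
      lines <- c(lines, sprintf(
        "%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        g$chrom, starts[k], ends[k], g$strand, tx_attr))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
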