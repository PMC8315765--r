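# Dataset- and result-level statistics: eQTL concordance, TAD crossing,
# loop distance distributions, interactions per gene, SNP-in-peak
# enrichment, replicate loop concordance.

# Internal: intra-chromosomal subset of a loop table.
intra_loops <- function(loops) {
  dt <- as.data.table(loops)
  dt[norm_chrom(chrom1) == norm_chrom(chrom2)]
}

#' eQTL concordance of linked genes
#'
#' Compares the pipeline's per-locus linked gene sets with per-locus eQTL
#' gene sets used as orthogonal validation. With per-locus matching
#' (default), a gene counts as concordant when the same (locus, gene) pair
#' appears on both sides; loci present on only one side contribute their
#' genes to that side's denominator only. With `per_locus = FALSE`, the
#' gene sets are unioned over loci before matching.
#'
#' `recall` is the fraction of eQTL genes recovered by the linker;
#' `precision` — the quantity some reports label "specificity" — is the
#' fraction of linked genes supported by eQTL evidence.
#'
#' @param linked_genes `data.table`/data.frame of (`locus_id`, `gene_id`)
#'   pairs, e.g. from [linked_gene_sets()].
#' @param eqtl_genes `data.table`/data.frame of (`locus_id`, `gene_id`)
#'   pairs, e.g. from [read_eqtl()].
#' @param per_locus match pairs per locus (default) or on global gene
#'   unions.
#' @return an object of class `validation_result`: list with
#'   `n_eqtl_genes`, `n_linked_genes`, `n_intersection`, `recall`,
#'   `precision`.
#' @export
eqtl_validation <- function(linked_genes, eqtl_genes, per_locus = TRUE) {
  linked <- unique(as.data.table(linked_genes)[, .(locus_id, gene_id)])
  eqtl <- unique(as.data.table(eqtl_genes)[, .(locus_id, gene_id)])
  if (!nrow(eqtl)) {
    lg_data_error("eqtl_validation: empty eQTL mapping; recall undefined")
  }
  if (!per_locus) {
    linked <- unique(linked[, .(gene_id)])[, locus_id := "all"]
    eqtl <- unique(eqtl[, .(gene_id)])[, locus_id := "all"]
  }
  inter <- merge(linked, eqtl, by = c("locus_id", "gene_id"))
  res <- list(n_eqtl_genes = nrow(eqtl),
              n_linked_genes = nrow(linked),
              n_intersection = nrow(inter),
              recall = nrow(inter) / nrow(eqtl),
              precision = if (nrow(linked)) nrow(inter) / nrow(linked)
                          else NA_real_)
  structure(res, class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "<validation_result> recall %.3f (%d/%d), precision ('specificity') %.3f (%d/%d)\n",
    x$recall, x$n_intersection, x$n_eqtl_genes,
    x$precision, x$n_intersection, x$n_linked_genes))
  invisible(x)
}

#' TAD containment of loops
#'
#' Classifies every intra-chromosomal loop as *within* a TAD — some single
#' TAD fully contains both anchors — or as *crossing* a TAD boundary
#' (everything else, including loops in gaps between TADs). TADs must be
#' non-overlapping per chromosome; overlapping TADs are a data error.
#'
#' @param loops a loop table (see [read_bedpe_loops()]).
#' @param tads a `data.table`/data.frame of TAD intervals (`chrom`,
#'   `start`, `end`), e.g. from [read_bed()].
#' @return list with `n_within`, `n_crossing`, `fraction_within`.
#' @export
tad_overlap_stats <- function(loops, tads) {
  tads <- as.data.table(tads)
  check_intervals(tads, "TAD")
  tads <- copy(tads)[, key := norm_chrom(chrom)]
  setorder(tads, key, start)
  overl <- tads[, any(start[-1] < head(end, -1)), by = key]
  if (any(overl$V1)) {
    lg_data_error(sprintf("overlapping TADs on chromosome(s): %s",
                          paste(overl[V1 == TRUE, key], collapse = ", ")))
  }
  dt <- intra_loops(loops)
  if (!nrow(dt)) return(list(n_within = 0L, n_crossing = 0L,
                             fraction_within = NaN))
  # anchors are stored sorted, but recompute the span defensively
  dt <- copy(dt)[, `:=`(key = norm_chrom(chrom1),
                        span_lo = pmin(start1, start2),
                        span_hi = pmax(end1, end2))]
  hit <- tads[dt, on = .(key, start <= span_lo, end >= span_hi),
              nomatch = NA, mult = "first", which = TRUE]
  n_within <- sum(!is.na(hit))
  list(n_within = as.integer(n_within),
       n_crossing = as.integer(nrow(dt) - n_within),
       fraction_within = n_within / nrow(dt))
}

#' Loop distance statistics
#'
#' Anchor-midpoint distances of intra-chromosomal loops: the distance of a
#' loop is `|midpoint(anchor2) - midpoint(anchor1)|` with
#' `midpoint = floor((start + end) / 2)`. The median is the lower median
#' for even counts (a realized loop distance, not an interpolation).
#'
#' @param loops a loop table.
#' @param probs quantiles to report.
#' @return list with `n`, `median`, `mean`, `quantiles`, and the raw
#'   `distances`.
#' @export
loop_distance_stats <- function(loops, probs = c(0.25, 0.5, 0.75, 0.9)) {
  dt <- intra_loops(loops)
  if (!nrow(dt)) {
    lg_data_error("loop_distance_stats: no intra-chromosomal loops")
  }
  d <- abs(floor((dt$start2 + dt$end2) / 2) - floor((dt$start1 + dt$end1) / 2))
  ds <- sort(d)
  lower_median <- ds[ceiling(length(ds) / 2)]
  list(n = length(d),
       median = lower_median,
       mean = mean(d),
       quantiles = quantile(d, probs = probs, type = 1),
       distances = d)
}

#' Mean chromatin interactions per gene
#'
#' For each gene in `gene_set`, counts the loops having at least one anchor
#' within `window` bp of any of the gene's TSSs (each loop counted at most
#' once per gene); reports the mean over the gene set, including genes with
#' zero nearby loops.
#'
#' @param loops a loop table.
#' @param tss TSS table from [extract_tss()].
#' @param gene_set character vector of gene ids to evaluate.
#' @param window bp window around each anchor (default 5,000).
#' @return list with `mean`, and `counts` (`gene_id`, `n_loops`).
#' @export
interactions_per_gene <- function(loops, tss, gene_set, window = 5000) {
  if (!length(gene_set)) {
    lg_config_error("interactions_per_gene: empty gene_set")
  }
  tss <- as.data.table(tss)[gene_id %in% gene_set]
  anchors <- loop_anchor_table(as.data.table(loops))
  counts <- data.table(gene_id = gene_set, n_loops = 0L)
  if (nrow(tss) && nrow(anchors)) {
    anchors[, `:=`(key = norm_chrom(a_chrom),
                   t_lo = a_start - window, t_hi = a_end - 1 + window)]
    tt <- copy(tss)[, `:=`(key = norm_chrom(chrom), tpos = tss)]
    hits <- anchors[tt, on = .(key, t_lo <= tpos, t_hi >= tpos),
                    nomatch = NULL, allow.cartesian = TRUE,
                    .(gene_id = i.gene_id, loop_id = x.loop_id)]
    if (nrow(hits)) {
      per_gene <- unique(hits)[, .(n = .N), by = gene_id]
      counts[per_gene, n_loops := i.n, on = "gene_id"]
    }
  }
  list(mean = mean(counts$n_loops), counts = counts[])
}

#' Permutation test for GWAS-SNP enrichment in peaks
#'
#' Tests whether a SNP set falls inside H3K27ac peaks more often than
#' background variants. The observed statistic is the fraction of `snps`
#' inside any peak; the null distribution resamples `|snps|` variants from
#' `background_snps` without replacement `n_perm` times. Fold enrichment is
#' observed over the null mean; the p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (n_perm + 1)`, which can never be zero.
#' Fully reproducible given `seed`.
#'
#' @param snps variant table with `chrom` and 0-based `pos` (e.g. the
#'   `variants` table of a `locus_set`).
#' @param peaks peak table from [read_narrowpeak()].
#' @param background_snps background variant pool, same columns as `snps`;
#'   must be at least as large as `snps`.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `observed_fraction`, `null_mean`, `fold`, `p_value`,
#'   `n_perm`, `degenerate` (TRUE when the null mean is zero and `fold` is
#'   infinite).
#' @export
snp_peak_enrichment <- function(snps, peaks, background_snps,
                                n_perm = 1000, seed = 1) {
  if (n_perm < 100) lg_config_error("n_perm must be >= 100")
  snps <- as.data.table(snps)
  bg <- as.data.table(background_snps)
  if (nrow(bg) < nrow(snps)) {
    lg_config_error("background pool smaller than the SNP set")
  }
  in_peak <- function(v) {
    p <- copy(as.data.table(peaks))[, `:=`(key = norm_chrom(chrom),
                                           p_lo = start, p_hi = end - 1)]
    vv <- copy(v)[, `:=`(key = norm_chrom(chrom), vpos = pos, row = .I)]
    hit <- p[vv, on = .(key, p_lo <= vpos, p_hi >= vpos),
             nomatch = NULL, allow.cartesian = TRUE, .(row = i.row)]
    seq_len(nrow(v)) %in% hit$row
  }
  obs_flags <- in_peak(snps)
  bg_flags <- in_peak(bg)
  observed <- mean(obs_flags)
  n <- nrow(snps)
  null_frac <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) mean(sample(bg_flags, n, replace = FALSE)),
           numeric(1))
  })
  null_mean <- mean(null_frac)
  degenerate <- null_mean == 0
  list(observed_fraction = observed,
       null_mean = null_mean,
       fold = if (degenerate) Inf else observed / null_mean,
       p_value = (1 + sum(null_frac >= observed)) / (n_perm + 1),
       n_perm = n_perm,
       degenerate = degenerate)
}

#' Concordance of two loop sets
#'
#' Replicate-agreement statistic: loops are snapped to a fixed bin grid
#' (anchor midpoints, default 5 kb bins) and two loops match when both
#' binned anchor pairs coincide (with `slack > 0`, when both anchor
#' midpoints differ by at most `slack` bp). Reports the Jaccard index over
#' the binned loop sets.
#'
#' @param loops_a,loops_b loop tables.
#' @param bin_size grid size in bp (default 5,000).
#' @param slack matching tolerance in bp (default 0: exact bin identity).
#' @return list with `jaccard`, `shared`, `a_only`, `b_only`.
#' @export
loop_set_concordance <- function(loops_a, loops_b, bin_size = 5000,
                                 slack = 0) {
  if (slack < 0) lg_config_error("slack must be >= 0")
  keyed <- function(dt) {
    dt <- as.data.table(dt)
    if (!nrow(dt)) return(data.table(k1 = character(), m1 = numeric(),
                                     k2 = character(), m2 = numeric()))
    unique(data.table(k1 = norm_chrom(dt$chrom1),
                      m1 = floor((dt$start1 + dt$end1) / 2),
                      k2 = norm_chrom(dt$chrom2),
                      m2 = floor((dt$start2 + dt$end2) / 2)))
  }
  a <- keyed(loops_a); b <- keyed(loops_b)
  if (slack == 0) {
    a[, `:=`(b1 = floor(m1 / bin_size), b2 = floor(m2 / bin_size))]
    b[, `:=`(b1 = floor(m1 / bin_size), b2 = floor(m2 / bin_size))]
    ua <- unique(a[, .(k1, b1, k2, b2)])
    ub <- unique(b[, .(k1, b1, k2, b2)])
    shared <- nrow(merge(ua, ub, by = c("k1", "b1", "k2", "b2")))
    a_only <- nrow(ua) - shared
    b_only <- nrow(ub) - shared
  } else {
    match_a <- logical(nrow(a)); match_b <- logical(nrow(b))
    for (i in seq_len(nrow(a))) {
      hit <- b$k1 == a$k1[i] & b$k2 == a$k2[i] &
        abs(b$m1 - a$m1[i]) <= slack & abs(b$m2 - a$m2[i]) <= slack
      if (any(hit)) {
        match_a[i] <- TRUE
        match_b[hit] <- TRUE
      }
    }
    shared <- sum(match_a)
    a_only <- sum(!match_a)
    b_only <- sum(!match_b)
  }
  denom <- shared + a_only + b_only
  list(jaccard = if (denom > 0) shared / denom else NaN,
       shared = as.integer(shared), a_only = as.integer(a_only),
       b_only = as.integer(b_only))
}
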