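pairs_dt <- function(lid, genes) data.table(locus_id = lid, gene_id = genes)

test_that("eqtl_validation does per-locus set arithmetic", {
  v <- eqtl_validation(pairs_dt("L1", c("A", "B", "C")),
                       pairs_dt("L1", c("B", "C", "D")))
  expect_equal(v$recall, 2 / 3)
  expect_equal(v$precision, 2 / 3)
  expect_equal(v$n_intersection, 2)

  same <- pairs_dt("L1", c("A", "B"))
  id <- eqtl_validation(same, same)
  expect_equal(id$recall, 1)
  expect_equal(id$precision, 1)

  expect_error(eqtl_validation(same, same[0]), class = "loopgene_data_error")
})

test_that("per-locus matching distinguishes gene reuse across loci", {
  linked <- rbind(pairs_dt("L1", "A"), pairs_dt("L2", "B"))
  eqtl <- rbind(pairs_dt("L1", "B"), pairs_dt("L2", "A"))
  v <- eqtl_validation(linked, eqtl)
  expect_equal(v$n_intersection, 0)   # right genes, wrong loci
  g <- eqtl_validation(linked, eqtl, per_locus = FALSE)
  expect_equal(g$n_intersection, 2)   # global union matching
})

test_that("validation identities hold on random inputs", {
  set.seed(501)
  for (rep in 1:20) {
    linked <- unique(data.table(locus_id = sample(sprintf("L%d", 1:6), 40, TRUE),
                                gene_id = sample(sprintf("G%d", 1:12), 40, TRUE)))
    eqtl <- unique(data.table(locus_id = sample(sprintf("L%d", 1:6), 40, TRUE),
                              gene_id = sample(sprintf("G%d", 1:12), 40, TRUE)))
    v <- eqtl_validation(linked, eqtl)
    expect_equal(v$recall, v$n_intersection / v$n_eqtl_genes)
    expect_equal(v$precision, v$n_intersection / v$n_linked_genes)
    expect_lte(v$n_intersection, min(v$n_eqtl_genes, v$n_linked_genes))
  }
})

test_that("TAD classification: within iff one TAD contains both anchors", {
  tads <- data.table(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6))
  loops <- rbind(
    data.table(chrom1 = "chr1", start1 = 1e5, end1 = 1.05e5,
               chrom2 = "chr1", start2 = 8e5, end2 = 8.05e5,
               sample_id = "s"),                       # within TAD 1
    data.table(chrom1 = "chr1", start1 = 9e5, end1 = 9.05e5,
               chrom2 = "chr1", start2 = 1.2e6, end2 = 1.205e6,
               sample_id = "s"),                       # adjacent TADs
    data.table(chrom1 = "chr1", start1 = 1e5, end1 = 1.05e5,
               chrom2 = "chr2", start2 = 1e5, end2 = 1.05e5,
               sample_id = "s"))                       # inter-chromosomal
  st <- tad_overlap_stats(loops, tads)
  expect_equal(st$n_within, 1)
  expect_equal(st$n_crossing, 1)      # inter-chromosomal loop excluded
  expect_equal(st$fraction_within, 0.5)

  bad <- data.table(chrom = "chr1", start = c(0, 5e5), end = c(1e6, 1.5e6))
  expect_error(tad_overlap_stats(loops, bad), class = "loopgene_data_error")
})

test_that("TAD within-counts match the brute-force oracle and sum up", {
  set.seed(502)
  for (rep in 1:15) {
    tads <- rbindlist(lapply(c("chr1", "chr2"), function(ch) {
      cuts <- sort(sample.int(1e6, 5))
      data.table(chrom = ch, start = c(0, cuts), end = c(cuts, 1.1e6))
    }))
    loops <- rand_loops_dt(60, max_pos = 1e6, anchor = 3000)
    st <- tad_overlap_stats(loops, tads)
    expect_equal(st$n_within, oracle_tad_within(loops, tads))
    n_intra <- sum(o_norm(loops$chrom1) == o_norm(loops$chrom2))
    expect_equal(st$n_within + st$n_crossing, n_intra)
  }
})

test_that("loop distances use anchor midpoints and the lower median", {
  loops <- data.table(
    chrom1 = "chr1", start1 = 0, end1 = 10000,
    chrom2 = "chr1", start2 = 245000, end2 = 255000, sample_id = "s")
  st <- loop_distance_stats(loops)
  expect_equal(st$median, 245000)

  mk <- function(d) data.table(chrom1 = "chr1", start1 = 0, end1 = 2,
                               chrom2 = "chr1", start2 = d, end2 = d + 2,
                               sample_id = "s")
  st3 <- loop_distance_stats(rbind(mk(100), mk(200), mk(300)))
  expect_equal(st3$median, 200)
  st4 <- loop_distance_stats(rbind(mk(100), mk(200), mk(300), mk(400)))
  expect_equal(st4$median, 200)  # lower median for even n

  expect_error(loop_distance_stats(mk(100)[0]), class = "loopgene_data_error")
})

test_that("distance stats match a sort-and-pick oracle and ignore order", {
  set.seed(503)
  for (rep in 1:20) {
    loops <- rand_loops_dt(41)
    st <- loop_distance_stats(loops)
    d <- sort(abs(floor((loops$start2 + loops$end2) / 2) -
                    floor((loops$start1 + loops$end1) / 2)))
    expect_equal(st$median, d[ceiling(length(d) / 2)])
    expect_equal(st$mean, mean(d))
    perm <- loop_distance_stats(loops[sample(.N)])
    expect_equal(perm$median, st$median)
  }
})

test_that("interactions_per_gene averages loop counts incl. zero genes", {
  tss <- rbind(
    data.table(gene_id = "G1", gene_name = "G1", transcript_id = "t1",
               chrom = "chr1", tss = 10000, strand = "+",
               biotype = "protein_coding"),
    data.table(gene_id = "G2", gene_name = "G2", transcript_id = "t2",
               chrom = "chr1", tss = 500000, strand = "+",
               biotype = "protein_coding"))
  near <- function(p) data.table(chrom1 = "chr1", start1 = p, end1 = p + 1000,
                                 chrom2 = "chr1", start2 = p + 2e5,
                                 end2 = p + 2e5 + 1000, sample_id = "s")
  loops <- rbind(near(9000), near(9500), near(10100),  # 3 at G1
                 near(499000))                          # 1 at G2
  res <- interactions_per_gene(loops, tss, c("G1", "G2"))
  expect_equal(res$mean, 2.0)
  res3 <- interactions_per_gene(loops, tss, c("G1", "G2", "G3"))
  expect_equal(res3$counts[gene_id == "G3", n_loops], 0L)
  expect_equal(res3$mean, 4 / 3)
  expect_error(interactions_per_gene(loops, tss, character(0)),
               class = "loopgene_config_error")
})

test_that("interactions_per_gene matches the brute-force double loop", {
  set.seed(504)
  for (rep in 1:15) {
    loops <- rand_loops_dt(40)
    tss <- rand_tss_dt(25, n_genes = 8)
    genes <- sprintf("G%03d", 1:8)
    got <- interactions_per_gene(loops, tss, genes)
    want <- oracle_interactions_per_gene(loops, tss, genes)
    expect_equal(setNames(got$counts$n_loops, got$counts$gene_id),
                 want)
  }
})

test_that("snp_peak_enrichment contracts: degenerate, null, determinism", {
  peaks <- data.table(chrom = "chr1", start = 0, end = 1000,
                      signal = 1, sample_id = "s")
  snps <- data.table(snp_id = sprintf("s%d", 1:20), chrom = "chr1",
                     pos = sample(0:999, 20), locus_id = "x", r2 = 1)
  bg <- data.table(snp_id = sprintf("b%d", 1:200), chrom = "chr1",
                   pos = sample(5000:50000, 200), locus_id = "x", r2 = 1)
  res <- snp_peak_enrichment(snps, peaks, bg, n_perm = 199, seed = 5)
  expect_true(res$degenerate)
  expect_equal(res$fold, Inf)
  expect_equal(res$p_value, 1 / 200)

  # snps drawn from the background itself: fold near 1
  set.seed(505)
  bg2 <- data.table(snp_id = sprintf("b%d", 1:2000), chrom = "chr1",
                    pos = sample.int(2e5, 2000), locus_id = "x", r2 = 1)
  peaks2 <- data.table(chrom = "chr1",
                       start = seq(0, 1.9e5, by = 10000),
                       end = seq(0, 1.9e5, by = 10000) + 3000,
                       signal = 1, sample_id = "s")
  snps2 <- bg2[sample(.N, 100)]
  res2 <- snp_peak_enrichment(snps2, peaks2, bg2, n_perm = 499, seed = 6)
  expect_gt(res2$fold, 0.5)
  expect_lt(res2$fold, 2)
  expect_gt(res2$p_value, 0.001)

  # bit-identical across runs with the same seed
  rerun <- snp_peak_enrichment(snps2, peaks2, bg2, n_perm = 499, seed = 6)
  expect_identical(res2, rerun)

  expect_error(snp_peak_enrichment(bg2, peaks2, snps2, n_perm = 199),
               class = "loopgene_config_error")  # background too small
  expect_error(snp_peak_enrichment(snps2, peaks2, bg2, n_perm = 10),
               class = "loopgene_config_error")
})

test_that("loop_set_concordance handles identity, disjoint and random sets", {
  set.seed(506)
  a <- rand_loops_dt(30)
  expect_equal(loop_set_concordance(a, a)$jaccard, 1)
  b <- copy(a)[, `:=`(start1 = start1 + 1e6, end1 = end1 + 1e6,
                      start2 = start2 + 2e6, end2 = end2 + 2e6)]
  expect_equal(loop_set_concordance(a, b)$jaccard, 0)
  for (rep in 1:15) {
    x <- rand_loops_dt(25); y <- rbind(x[sample(.N, 10)], rand_loops_dt(15))
    got <- loop_set_concordance(x, y)
    want <- oracle_concordance(x, y)
    expect_equal(got$jaccard, want$jaccard)
    expect_equal(got$shared, want$shared)
    expect_equal(got$a_only, want$a_only)
    expect_equal(got$b_only, want$b_only)
  }
})
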