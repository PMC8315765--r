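one_locus <- function(pos0, chrom = "chr1", lid = "rsX") {
  build_loci(data.table(snp_id = lid, chrom = chrom, pos_1based = pos0 + 1,
                        locus_id = lid, r2 = 1, disease = "t"))
}

tss_row <- function(gene, chrom, tss, tx = paste0(gene, ".t1")) {
  data.table(gene_id = gene, gene_name = gene, transcript_id = tx,
             chrom = chrom, tss = tss, strand = "+",
             biotype = "protein_coding")
}

loop_row <- function(s1, e1, s2, e2, chrom = "chr1", sample = "s1") {
  data.table(chrom1 = chrom, start1 = s1, end1 = e1,
             chrom2 = chrom, start2 = s2, end2 = e2,
             score = NA_real_, sample_id = sample)
}

test_that("loop rule: SNP in one anchor, TSS within 5 kb of the other", {
  loci <- one_locus(10500)
  loops <- loop_row(10000, 15000, 200000, 205000)
  hit <- link_by_loop(loci, loops, tss_row("G1", "chr1", 204000))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance_bp, 0)   # TSS inside the other anchor
  expect_equal(hit$evidence, "loop")

  # 5,001 bp past the anchor end: not linked at the 5 kb window
  miss <- link_by_loop(loci, loops, tss_row("G1", "chr1", 210000))
  expect_equal(nrow(miss), 0)
  # exactly 5,000: linked (inclusive window)
  edge <- link_by_loop(loci, loops, tss_row("G1", "chr1", 209999))
  expect_equal(nrow(edge), 1)
  expect_equal(edge$distance_bp, 5000)
})

test_that("loop rule requires the SNP inside an anchor by default", {
  loci <- one_locus(9999)  # one bp left of anchor1
  loops <- loop_row(10000, 15000, 200000, 205000)
  tss <- tss_row("G1", "chr1", 204000)
  expect_equal(nrow(link_by_loop(loci, loops, tss)), 0)
  # a 1 bp variant-side tolerance rescues it
  cfg <- link_config(snp_anchor_window = 1)
  expect_equal(nrow(link_by_loop(loci, loops, tss, cfg)), 1)
})

test_that("promoter rule: SNP in a peak, TSS within 1 kb of the SNP", {
  loci <- one_locus(1000)
  peaks <- data.table(chrom = "chr1", start = 900, end = 1100,
                      signal = 1, sample_id = "s1")
  hit <- link_by_promoter(loci, peaks, tss_row("G1", "chr1", 1500))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance_bp, 500)
  expect_equal(hit$evidence, "promoter")

  # no peak over the SNP: no link even with the TSS at the SNP itself
  nopeak <- data.table(chrom = "chr1", start = 5000, end = 5100,
                       signal = 1, sample_id = "s1")
  expect_equal(nrow(link_by_promoter(loci, nopeak, tss_row("G1", "chr1", 1000))),
               0)
  # TSS exactly 1,000 bp away: linked (inclusive); 1,001: not
  expect_equal(nrow(link_by_promoter(loci, peaks, tss_row("G1", "chr1", 2000))), 1)
  expect_equal(nrow(link_by_promoter(loci, peaks, tss_row("G1", "chr1", 2001))), 0)
})

test_that("empty TSS annotation is a configuration error, not zero links", {
  loci <- one_locus(1000)
  loops <- loop_row(500, 1500, 5000, 6000)
  empty <- tss_row("G1", "chr1", 1)[0]
  expect_error(link_by_loop(loci, loops, empty),
               class = "loopgene_config_error")
  expect_error(link_by_promoter(loci, loops[, .(chrom = chrom1,
                                                start = start1, end = end1,
                                                signal = 1, sample_id)],
                                empty),
               class = "loopgene_config_error")
})

test_that("link_by_loop matches the exhaustive oracle on random instances", {
  set.seed(401)
  for (rep in 1:30) {
    loci <- rand_locus_set(4, vars_per_locus = 3)
    loops <- rand_loops_dt(40, anchor = 5000)
    tss <- rand_tss_dt(30)
    got <- link_by_loop(loci, loops, tss)
    got_set <- unique(got[, .(locus_id, gene_id, sample_id, loop_id)])
    setorder(got_set, locus_id, gene_id, sample_id, loop_id)
    want <- oracle_link_by_loop(loci$variants, loops, tss)
    expect_identical(as.data.frame(got_set), as.data.frame(want),
                     info = sprintf("rep %d", rep))
  }
})

test_that("link_by_promoter matches the exhaustive oracle", {
  set.seed(402)
  for (rep in 1:30) {
    loci <- rand_locus_set(4, vars_per_locus = 3, max_pos = 2e5)
    peaks <- rand_peaks_dt(40, max_pos = 2e5)
    tss <- rand_tss_dt(30, max_pos = 2e5)
    got <- link_by_promoter(loci, peaks, tss)
    got_set <- unique(got[, .(locus_id, gene_id, sample_id)])
    setorder(got_set, locus_id, gene_id, sample_id)
    want <- oracle_link_by_promoter(loci$variants, peaks, tss)
    expect_identical(as.data.frame(got_set), as.data.frame(want),
                     info = sprintf("rep %d", rep))
  }
})

test_that("every reported distance respects its window bound", {
  set.seed(403)
  cfg <- link_config(loop_window = 3000, promoter_window = 800)
  loci <- rand_locus_set(6, vars_per_locus = 4, max_pos = 3e5)
  ll <- link_by_loop(loci, rand_loops_dt(80, max_pos = 3e5),
                     rand_tss_dt(60, max_pos = 3e5), cfg)
  pl <- link_by_promoter(loci, rand_peaks_dt(60, max_pos = 3e5),
                         rand_tss_dt(60, max_pos = 3e5), cfg)
  expect_true(all(ll$distance_bp <= 3000))
  expect_true(all(pl$distance_bp <= 800))
})

test_that("enlarging windows never removes a link (monotonicity)", {
  set.seed(404)
  loci <- rand_locus_set(5, vars_per_locus = 3)
  loops <- rand_loops_dt(60)
  tss <- rand_tss_dt(40)
  key <- function(x) paste(x$locus_id, x$gene_id, x$sample_id, x$loop_id)
  small <- link_by_loop(loci, loops, tss, link_config(loop_window = 2000))
  big <- link_by_loop(loci, loops, tss, link_config(loop_window = 8000))
  expect_true(all(key(small) %in% key(big)))
})

test_that("assemble_links groups transcripts by gene and flags expression", {
  loci <- one_locus(10500)
  loops <- loop_row(10000, 15000, 200000, 205000)
  # two transcripts of G1 reached by the same loop -> one gene-level row
  tss <- rbind(tss_row("G1", "chr1", 204000, "G1.t1"),
               tss_row("G1", "chr1", 204100, "G1.t2"),
               tss_row("G2", "chr1", 204500))
  ll <- link_by_loop(loci, loops, tss)
  expect_equal(nrow(ll[gene_id == "G1"]), 1)
  expr <- data.table(gene_id = c("G1", "G2"), s1 = c(2.0, 0.5))
  lt <- assemble_links(ll, ll[0], expr)
  expect_equal(sort(lt$links$gene_id), c("G1", "G2"))
  expect_equal(lt$links[gene_id == "G1", expressed], TRUE)
  expect_equal(lt$links[gene_id == "G2", expressed], FALSE)
  # reported sets keep only expressed genes; unexpressed rows are audited
  expect_equal(linked_gene_sets(lt)$gene_id, "G1")
  expect_equal(nrow(lt$links), 2)
})

test_that("adding a duplicate transcript changes nothing (dedup invariance)", {
  loci <- one_locus(10500)
  loops <- loop_row(10000, 15000, 200000, 205000)
  tss <- rbind(tss_row("G1", "chr1", 204000, "G1.t1"),
               tss_row("G2", "chr1", 201000, "G2.t1"))
  expr <- data.table(gene_id = c("G1", "G2"), s1 = c(2, 2))
  base <- assemble_links(link_by_loop(loci, loops, tss), NULL, expr)
  dup_tss <- rbind(tss, tss_row("G1", "chr1", 204000, "G1.t99"))
  with_dup <- assemble_links(link_by_loop(loci, loops, dup_tss), NULL, expr)
  expect_identical(as.data.frame(linked_gene_sets(base)),
                   as.data.frame(linked_gene_sets(with_dup)))
})

test_that("genes_per_locus counts unique genes and both means", {
  lt <- structure(list(links = data.table(
    locus_id = c("L1", "L1", "L1", "L2"),
    gene_id = c("A", "B", "A", "C"),
    sample_id = c("s1", "s1", "s2", "s1"),
    evidence = "loop", expressed = TRUE)), class = "link_table")
  gpl <- genes_per_locus(lt)
  expect_equal(gpl$counts[order(locus_id), n_genes], c(2, 1))
  expect_equal(gpl$mean_linked_loci, 1.5)
  # a third locus with no genes pulls down only the all-loci mean
  loci3 <- build_loci(data.table(
    snp_id = c("L1", "L2", "L3"), chrom = "chr1",
    pos_1based = c(100, 200, 300), locus_id = c("L1", "L2", "L3"), r2 = 1))
  gpl3 <- genes_per_locus(lt, loci3)
  expect_equal(gpl3$counts[order(locus_id), n_genes], c(2, 1, 0))
  expect_equal(gpl3$mean_linked_loci, 1.5)
  expect_equal(gpl3$mean_all_loci, 1)
})

test_that("genes_per_locus matches brute-force set counting on random tables", {
  set.seed(405)
  for (rep in 1:20) {
    n <- 50
    links <- data.table(
      locus_id = sample(sprintf("L%d", 1:8), n, TRUE),
      gene_id = sample(sprintf("G%d", 1:15), n, TRUE),
      sample_id = sample(c("s1", "s2"), n, TRUE),
      evidence = "loop",
      expressed = sample(c(TRUE, FALSE), n, TRUE))
    lt <- structure(list(links = links), class = "link_table")
    gpl <- genes_per_locus(lt)
    for (i in seq_len(nrow(gpl$counts))) {
      lid <- gpl$counts$locus_id[i]
      brute <- length(unique(links[locus_id == lid & expressed, gene_id]))
      expect_equal(gpl$counts$n_genes[i], brute)
    }
  }
})

test_that("closest-gene classification covers all three categories", {
  # locus at 1,000; G_near at 1,200 is closest; G_far at 90,000
  loci <- one_locus(1000)
  tss <- rbind(tss_row("G_near", "chr1", 1200),
               tss_row("G_far", "chr1", 90000))
  mk_lt <- function(genes) structure(list(links = data.table(
    locus_id = rep("rsX", length(genes)), gene_id = genes,
    sample_id = "s1", evidence = "loop",
    expressed = rep(TRUE, length(genes)))), class = "link_table")
  expect_equal(closest_gene_report(loci, tss, mk_lt("G_near"))$class,
               "all_closest_linked")
  expect_equal(closest_gene_report(loci, tss, mk_lt("G_far"))$class,
               "no_closest_linked")
  # tie: two genes equidistant, only one linked -> some_closest_linked
  tie <- rbind(tss_row("G_a", "chr1", 900), tss_row("G_b", "chr1", 1100))
  expect_equal(closest_gene_report(loci, tie, mk_lt("G_a"))$class,
               "some_closest_linked")
})

test_that("closest-gene sets match the brute-force nearest-TSS oracle", {
  set.seed(406)
  for (rep in 1:20) {
    loci <- rand_locus_set(5, vars_per_locus = 3, max_pos = 2e5)
    tss <- rand_tss_dt(30, max_pos = 2e5)
    lt <- structure(list(links = data.table(
      locus_id = character(), gene_id = character(), sample_id = character(),
      evidence = character(), expressed = logical())), class = "link_table")
    rep_out <- closest_gene_report(loci, tss, lt,
                                   link_config(block_width_cutoff = 1e9))
    want <- oracle_closest_sets(loci, tss)
    for (i in seq_len(nrow(rep_out))) {
      got <- sort(strsplit(rep_out$closest_genes[i], ",")[[1]])
      expect_equal(got, want[[rep_out$locus_id[i]]])
    }
  }
})

test_that("closest-gene report is restricted to narrow LD blocks", {
  wide <- build_loci(data.table(
    snp_id = c("L1", "L1_p"), chrom = "chr1",
    pos_1based = c(1000, 250000), locus_id = "L1", r2 = 1))
  tss <- tss_row("G1", "chr1", 500)
  lt <- structure(list(links = data.table(
    locus_id = "L1", gene_id = "G1", sample_id = "s1",
    evidence = "loop", expressed = TRUE)), class = "link_table")
  expect_equal(nrow(closest_gene_report(wide, tss, lt)), 0)
})

test_that("gene-desert calls respect the 50 kb boundary exactly", {
  loci <- build_loci(data.table(
    snp_id = c("L1", "L1_p"), chrom = "chr1", pos_1based = c(1, 1000),
    locus_id = "L1", r2 = 1))
  # block is [0, 1000); TSS at 60,000 -> distance 59,001 -> desert
  expect_equal(gene_desert_loci(loci, tss_row("G1", "chr1", 60000)), "L1")
  # TSS at 50,999 -> distance 50,000 -> not a desert (boundary inclusive)
  expect_equal(length(gene_desert_loci(loci, tss_row("G1", "chr1", 50999))), 0)
  expect_equal(gene_desert_loci(loci, tss_row("G1", "chr1", 51000)), "L1")
})

test_that("gene-desert calls match the brute-force oracle", {
  set.seed(407)
  for (rep in 1:20) {
    loci <- rand_locus_set(6, vars_per_locus = 2, max_pos = 5e5)
    tss <- rand_tss_dt(15, max_pos = 5e5)
    got <- gene_desert_loci(loci, tss)
    expect_equal(sort(got), sort(oracle_desert(loci, tss)))
  }
})
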