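# Brute-force reference implementations, written independently of the
# package's join-based code paths: plain nested loops over every
# combination, with the point-to-interval distance restated inline.

o_dist <- function(pos, s, e) {
  if (pos >= s && pos < e) return(0)
  if (pos < s) return(s - pos)
  pos - e + 1
}

o_norm <- function(x) sub("^chr", "", x)

# exhaustive triple loop over (variant, loop, tss); returns sorted unique
# (locus, gene, sample, loop index) tuples
oracle_link_by_loop <- function(variants, loops, tss, loop_window = 5000,
                                snp_anchor_window = 0) {
  out <- list()
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi]
    for (li in seq_len(nrow(loops))) {
      L <- loops[li]
      for (side in 1:2) {
        ac <- if (side == 1) c(L$chrom1, L$start1, L$end1)
              else c(L$chrom2, L$start2, L$end2)
        oc <- if (side == 1) c(L$chrom2, L$start2, L$end2)
              else c(L$chrom1, L$start1, L$end1)
        if (o_norm(v$chrom) != o_norm(ac[1])) next
        if (o_dist(v$pos, as.numeric(ac[2]), as.numeric(ac[3])) >
              snp_anchor_window) next
        for (ti in seq_len(nrow(tss))) {
          tr <- tss[ti]
          if (o_norm(tr$chrom) != o_norm(oc[1])) next
          if (o_dist(tr$tss, as.numeric(oc[2]), as.numeric(oc[3])) <=
                loop_window) {
            out[[length(out) + 1]] <- data.table(
              locus_id = v$locus_id, gene_id = tr$gene_id,
              sample_id = L$sample_id, loop_id = li)
          }
        }
      }
    }
  }
  if (!length(out)) return(data.table(locus_id = character(),
                                      gene_id = character(),
                                      sample_id = character(),
                                      loop_id = integer()))
  res <- unique(rbindlist(out))
  setorder(res, locus_id, gene_id, sample_id, loop_id)
  res
}

oracle_link_by_promoter <- function(variants, peaks, tss,
                                    promoter_window = 1000) {
  out <- list()
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi]
    for (pi in seq_len(nrow(peaks))) {
      p <- peaks[pi]
      if (o_norm(v$chrom) != o_norm(p$chrom)) next
      if (o_dist(v$pos, p$start, p$end) != 0) next
      for (ti in seq_len(nrow(tss))) {
        tr <- tss[ti]
        if (o_norm(tr$chrom) != o_norm(v$chrom)) next
        if (abs(tr$tss - v$pos) <= promoter_window) {
          out[[length(out) + 1]] <- data.table(
            locus_id = v$locus_id, gene_id = tr$gene_id,
            sample_id = p$sample_id)
        }
      }
    }
  }
  if (!length(out)) return(data.table(locus_id = character(),
                                      gene_id = character(),
                                      sample_id = character()))
  res <- unique(rbindlist(out))
  setorder(res, locus_id, gene_id, sample_id)
  res
}

# nearest-TSS search per locus over its variants, ties included
oracle_closest_sets <- function(loci, tss) {
  res <- list()
  for (i in seq_len(nrow(loci$loci))) {
    lid <- loci$loci$locus_id[i]
    vv <- loci$variants[locus_id == lid]
    cand <- tss[o_norm(chrom) == o_norm(vv$chrom[1]) &
                  biotype == "protein_coding"]
    closest <- character(0)
    if (nrow(cand)) {
      for (p in vv$pos) {
        dmin <- Inf; best <- character(0)
        for (ti in seq_len(nrow(cand))) {
          d <- abs(cand$tss[ti] - p)
          if (d < dmin) { dmin <- d; best <- cand$gene_id[ti] }
          else if (d == dmin) best <- c(best, cand$gene_id[ti])
        }
        closest <- union(closest, unique(best))
      }
    }
    res[[lid]] <- sort(closest)
  }
  res
}

oracle_desert <- function(loci, tss, window = 50000) {
  out <- character(0)
  for (i in seq_len(nrow(loci$loci))) {
    row <- loci$loci[i]
    cand <- tss[o_norm(chrom) == o_norm(row$chrom) &
                  biotype == "protein_coding"]
    if (!nrow(cand)) { out <- c(out, row$locus_id); next }
    dmin <- Inf
    for (ti in seq_len(nrow(cand))) {
      dmin <- min(dmin, o_dist(cand$tss[ti], row$block_start, row$block_end))
    }
    if (dmin > window) out <- c(out, row$locus_id)
  }
  out
}

oracle_interactions_per_gene <- function(loops, tss, gene_set,
                                         window = 5000) {
  counts <- setNames(integer(length(gene_set)), gene_set)
  for (g in gene_set) {
    gt <- tss[gene_id == g]
    for (li in seq_len(nrow(loops))) {
      L <- loops[li]
      hit <- FALSE
      for (ti in seq_len(nrow(gt))) {
        tr <- gt[ti]
        if (o_norm(tr$chrom) == o_norm(L$chrom1) &&
              o_dist(tr$tss, L$start1, L$end1) <= window) hit <- TRUE
        if (o_norm(tr$chrom) == o_norm(L$chrom2) &&
              o_dist(tr$tss, L$start2, L$end2) <= window) hit <- TRUE
      }
      if (hit) counts[g] <- counts[g] + 1L
    }
  }
  counts
}

# all-pairs matching of binned loops
oracle_concordance <- function(a, b, bin = 5000) {
  key <- function(dt) {
    unique(apply(dt, 1, function(r) {
      m1 <- floor((as.numeric(r["start1"]) + as.numeric(r["end1"])) / 2)
      m2 <- floor((as.numeric(r["start2"]) + as.numeric(r["end2"])) / 2)
      paste(o_norm(r["chrom1"]), floor(m1 / bin),
            o_norm(r["chrom2"]), floor(m2 / bin), sep = "|")
    }))
  }
  ka <- key(a); kb <- key(b)
  shared <- length(intersect(ka, kb))
  list(jaccard = shared / length(union(ka, kb)),
       shared = shared, a_only = length(setdiff(ka, kb)),
       b_only = length(setdiff(kb, ka)))
}

oracle_tad_within <- function(loops, tads) {
  n_within <- 0L
  for (li in seq_len(nrow(loops))) {
    L <- loops[li]
    if (o_norm(L$chrom1) != o_norm(L$chrom2)) next
    lo <- min(L$start1, L$start2); hi <- max(L$end1, L$end2)
    inside <- FALSE
    for (ti in seq_len(nrow(tads))) {
      td <- tads[ti]
      if (o_norm(td$chrom) == o_norm(L$chrom1) &&
            td$start <= lo && td$end >= hi) inside <- TRUE
    }
    if (inside) n_within <- n_within + 1L
  }
  n_within
}
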