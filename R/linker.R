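#' Linker configuration
#'
#' Window and threshold parameters for the SNP-to-gene linking rules.
#'
#' @param loop_window bp window around the TSS-side loop anchor (default
#'   5,000): a TSS "within 5 kb of a loop" means
#'   [point_interval_distance()] from the TSS to the anchor opposite the
#'   variant is at most this value (inclusive).
#' @param promoter_window bp window for the promoter rule (default 1,000):
#'   a TSS within this distance of a peak-overlapping variant.
#' @param tpm_threshold minimum TPM for the expressed-gene filter
#'   (default 1.0, inclusive).
#' @param gene_desert_window bp window for gene-desert classification
#'   (default 50,000): a locus is a gene desert when no protein-coding TSS
#'   lies within this distance of its LD block.
#' @param block_width_cutoff bp cutoff for the closest-gene report
#'   (default 100,000; loci with LD block strictly narrower qualify).
#' @param snp_anchor_window bp tolerance for the variant-side anchor test
#'   (default 0: the variant must lie inside the anchor).
#' @return an object of class `link_config`.
#' @export
link_config <- function(loop_window = 5000, promoter_window = 1000,
                        tpm_threshold = 1.0, gene_desert_window = 50000,
                        block_width_cutoff = 100000, snp_anchor_window = 0) {
  cfg <- list(loop_window = loop_window, promoter_window = promoter_window,
              tpm_threshold = tpm_threshold,
              gene_desert_window = gene_desert_window,
              block_width_cutoff = block_width_cutoff,
              snp_anchor_window = snp_anchor_window)
  bad <- names(cfg)[!vapply(cfg, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v) && v >= 0, logical(1))]
  if (length(bad)) {
    lg_config_error(paste("link_config: non-negative scalar required for:",
                          paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "link_config")
}

# Internal: long anchor table — one row per loop per side, with the
# opposite anchor carried along. Inter-chromosomal loops are kept (the
# evidence rule does not require both anchors on one chromosome).
loop_anchor_table <- function(loops) {
  dt <- as.data.table(loops)
  dt[, loop_id := .I]
  a1 <- dt[, .(loop_id, sample_id,
               a_chrom = chrom1, a_start = start1, a_end = end1,
               o_chrom = chrom2, o_start = start2, o_end = end2)]
  a2 <- dt[, .(loop_id, sample_id,
               a_chrom = chrom2, a_start = start2, a_end = end2,
               o_chrom = chrom1, o_start = start1, o_end = end1)]
  rbindlist(list(a1, a2))
}

# Internal: format an anchor as chrom:start-end for the output table.
fmt_anchor <- function(chrom, start, end) sprintf("%s:%d-%d", chrom,
                                                  as.integer(start),
                                                  as.integer(end))

empty_gene_links <- function() {
  data.table(locus_id = character(), snp_id = character(),
             snp_chrom = character(), snp_pos = numeric(),
             gene_id = character(), gene_name = character(),
             evidence = character(), sample_id = character(),
             loop_anchor1 = character(), loop_anchor2 = character(),
             loop_id = integer(), tss = numeric(), distance_bp = numeric())
}

#' Link loci to genes through chromatin loops
#'
#' The loop evidence rule: a variant supports a gene when the variant lies
#' inside one loop anchor (within `snp_anchor_window`, default 0 = strict
#' containment) and one of the gene's TSSs lies within `loop_window`
#' (default 5 kb) of the *other* anchor. Both anchors are tried; a variant
#' sitting in both anchors is evaluated in both directions. Transcript-level
#' hits are deduplicated to one row per (locus, gene, sample, loop),
#' keeping the representative variant/transcript with the smallest
#' TSS-to-anchor distance.
#'
#' @param loci a `locus_set` from [build_loci()].
#' @param loops a loop table from [read_bedpe_loops()] (rows may pool
#'   several `sample_id`s).
#' @param tss a TSS table from [extract_tss()].
#' @param cfg a [link_config()].
#' @return a `data.table` of gene links with `evidence = "loop"`; columns
#'   `locus_id`, `snp_id`, `snp_chrom`, `snp_pos` (0-based), `gene_id`,
#'   `gene_name`, `evidence`, `sample_id`, `loop_anchor1`, `loop_anchor2`,
#'   `loop_id`, `tss` (0-based), `distance_bp`.
#' @export
link_by_loop <- function(loci, loops, tss, cfg = link_config()) {
  stopifnot(inherits(loci, "locus_set"))
  tss <- as.data.table(tss)
  if (!nrow(tss)) {
    lg_config_error("link_by_loop: empty TSS annotation")
  }
  loops <- as.data.table(loops)
  variants <- loci$variants
  if (!nrow(loops) || !nrow(variants)) return(empty_gene_links())

  anchors <- loop_anchor_table(loops)
  w0 <- cfg$snp_anchor_window
  anchors[, `:=`(key = norm_chrom(a_chrom),
                 v_lo = a_start - w0, v_hi = a_end - 1 + w0)]
  v <- copy(variants)[, `:=`(key = norm_chrom(chrom), vpos = pos)]
  hits <- anchors[v, on = .(key, v_lo <= vpos, v_hi >= vpos),
                  nomatch = NULL, allow.cartesian = TRUE,
                  .(locus_id = i.locus_id, snp_id = i.snp_id,
                    snp_chrom = i.chrom, snp_pos = i.pos,
                    sample_id = x.sample_id, loop_id = x.loop_id,
                    a_chrom = x.a_chrom, a_start = x.a_start, a_end = x.a_end,
                    o_chrom = x.o_chrom, o_start = x.o_start, o_end = x.o_end)]
  if (!nrow(hits)) return(empty_gene_links())

  w <- cfg$loop_window
  hits[, `:=`(okey = norm_chrom(o_chrom),
              t_lo = o_start - w, t_hi = o_end - 1 + w)]
  t <- copy(tss)[, `:=`(okey = norm_chrom(chrom), tpos = tss)]
  links <- hits[t, on = .(okey, t_lo <= tpos, t_hi >= tpos),
                nomatch = NULL, allow.cartesian = TRUE,
                .(locus_id = x.locus_id, snp_id = x.snp_id,
                  snp_chrom = x.snp_chrom, snp_pos = x.snp_pos,
                  gene_id = i.gene_id, gene_name = i.gene_name,
                  sample_id = x.sample_id, loop_id = x.loop_id,
                  a_chrom = x.a_chrom, a_start = x.a_start, a_end = x.a_end,
                  o_chrom = x.o_chrom, o_start = x.o_start, o_end = x.o_end,
                  tss = i.tss)]
  if (!nrow(links)) return(empty_gene_links())
  links[, distance_bp := point_interval_distance(tss, o_start, o_end)]
  # dedup transcript-level hits to (locus, gene, sample, loop)
  setorder(links, locus_id, gene_id, sample_id, loop_id, distance_bp,
           snp_id, tss)
  links <- links[!duplicated(links[, .(locus_id, gene_id, sample_id, loop_id)])]
  links[, `:=`(evidence = "loop",
               loop_anchor1 = fmt_anchor(a_chrom, a_start, a_end),
               loop_anchor2 = fmt_anchor(o_chrom, o_start, o_end))]
  links[, .(locus_id, snp_id, snp_chrom, snp_pos, gene_id, gene_name,
            evidence, sample_id, loop_anchor1, loop_anchor2, loop_id,
            tss, distance_bp)]
}

#' Link loci to genes through promoter-proximal peak overlap
#'
#' The promoter evidence rule: a variant supports a gene when the variant
#' overlaps an H3K27ac peak and one of the gene's TSSs lies within
#' `promoter_window` (default 1 kb) of the variant position itself
#' (`distance_bp = |tss - pos|`). The peak must belong to the sample whose
#' evidence is being scored; peaks from several samples may be pooled in
#' the input.
#'
#' @inheritParams link_by_loop
#' @param peaks a peak table from [read_narrowpeak()].
#' @return a `data.table` of gene links with `evidence = "promoter"` (loop
#'   columns NA), deduplicated to one row per (locus, gene, sample).
#' @export
link_by_promoter <- function(loci, peaks, tss, cfg = link_config()) {
  stopifnot(inherits(loci, "locus_set"))
  tss <- as.data.table(tss)
  if (!nrow(tss)) {
    lg_config_error("link_by_promoter: empty TSS annotation")
  }
  peaks <- as.data.table(peaks)
  variants <- loci$variants
  if (!nrow(peaks) || !nrow(variants)) return(empty_gene_links())

  p <- copy(peaks)[, `:=`(key = norm_chrom(chrom), p_lo = start, p_hi = end - 1)]
  v <- copy(variants)[, `:=`(key = norm_chrom(chrom), vpos = pos)]
  inpeak <- p[v, on = .(key, p_lo <= vpos, p_hi >= vpos),
              nomatch = NULL, allow.cartesian = TRUE,
              .(locus_id = i.locus_id, snp_id = i.snp_id,
                snp_chrom = i.chrom, snp_pos = i.pos,
                sample_id = x.sample_id)]
  if (!nrow(inpeak)) return(empty_gene_links())
  # one peak hit per (variant, sample) is enough
  inpeak <- unique(inpeak)

  w <- cfg$promoter_window
  inpeak[, `:=`(key = norm_chrom(snp_chrom),
                t_lo = snp_pos - w, t_hi = snp_pos + w)]
  t <- copy(tss)[, `:=`(key = norm_chrom(chrom), tpos = tss)]
  links <- inpeak[t, on = .(key, t_lo <= tpos, t_hi >= tpos),
                  nomatch = NULL, allow.cartesian = TRUE,
                  .(locus_id = x.locus_id, snp_id = x.snp_id,
                    snp_chrom = x.snp_chrom, snp_pos = x.snp_pos,
                    gene_id = i.gene_id, gene_name = i.gene_name,
                    sample_id = x.sample_id, tss = i.tss)]
  if (!nrow(links)) return(empty_gene_links())
  links[, distance_bp := abs(tss - snp_pos)]
  setorder(links, locus_id, gene_id, sample_id, distance_bp, snp_id, tss)
  links <- links[!duplicated(links[, .(locus_id, gene_id, sample_id)])]
  links[, `:=`(evidence = "promoter",
               loop_anchor1 = NA_character_, loop_anchor2 = NA_character_,
               loop_id = NA_integer_)]
  links[, .(locus_id, snp_id, snp_chrom, snp_pos, gene_id, gene_name,
            evidence, sample_id, loop_anchor1, loop_anchor2, loop_id,
            tss, distance_bp)]
}

#' Assemble a link table with the expressed-gene filter
#'
#' Combines loop-mediated and promoter-overlap gene links, annotates each
#' row with the gene's TPM in the evidence row's sample and an `expressed`
#' flag (TPM at least `tpm_threshold`, inclusive; genes absent from the
#' expression table count as not expressed, with a reported count).
#' Unexpressed rows are retained with `expressed = FALSE` so the filter's
#' effect is auditable; reported gene sets use `expressed = TRUE` rows only.
#'
#' @param loop_links,promoter_links outputs of [link_by_loop()] and
#'   [link_by_promoter()] (either may be empty).
#' @param expr expression table from [read_expression()].
#' @param cfg a [link_config()].
#' @param provenance optional named list recorded alongside the table
#'   (e.g. input paths and digests).
#' @return an object of class `link_table`: list with `links` (the
#'   annotated rows), `config`, `provenance` and `log` (dropped/absent-gene
#'   counts).
#' @export
assemble_links <- function(loop_links, promoter_links, expr,
                           cfg = link_config(), provenance = list()) {
  links <- rbindlist(list(as.data.table(loop_links),
                          as.data.table(promoter_links)),
                     use.names = TRUE, fill = TRUE)
  if (nrow(links)) {
    links[, tpm := NA_real_]
    for (s in unique(links$sample_id)) {
      idx <- which(links$sample_id == s)
      links[idx, tpm := expression_tpm(gene_id, s, expr)]
    }
    links[, expressed := !is.na(tpm) & tpm >= cfg$tpm_threshold]
    setorder(links, locus_id, gene_id, evidence, sample_id, loop_id,
             na.last = TRUE)
  } else {
    links <- empty_gene_links()[, `:=`(tpm = numeric(0),
                                       expressed = logical(0))]
  }
  n_absent <- length(unique(links$gene_id[is.na(links$tpm)]))
  if (n_absent > 0) {
    message(sprintf(
      "assemble_links: %d linked gene(s) absent from the expression table (treated as not expressed)",
      n_absent))
  }
  structure(list(links = links[], config = cfg, provenance = provenance,
                 log = list(n_genes_absent_from_expression = n_absent,
                            n_rows = nrow(links),
                            n_rows_expressed = sum(links$expressed))),
            class = "link_table")
}

#' @export
print.link_table <- function(x, ...) {
  cat(sprintf(
    "<link_table> %d evidence rows (%d expressed), %d loci, %d genes\n",
    nrow(x$links), sum(x$links$expressed),
    uniqueN(x$links$locus_id), uniqueN(x$links$gene_id)))
  invisible(x)
}

#' Per-locus sets of linked, expressed genes
#'
#' @param table a `link_table`.
#' @param expressed_only use only `expressed = TRUE` rows (default TRUE).
#' @return a `data.table` of unique (`locus_id`, `gene_id`) pairs.
#' @export
linked_gene_sets <- function(table, expressed_only = TRUE) {
  stopifnot(inherits(table, "link_table"))
  rows <- table$links
  if (expressed_only) rows <- rows[expressed == TRUE]
  unique(rows[, .(locus_id, gene_id)])
}

#' Per-disease unique gene counts
#'
#' The headline output shape: the number of unique expressed genes linked
#' to each disease's loci, unioned across all samples and loci.
#'
#' @param table a `link_table`.
#' @param loci the `locus_set` the table was built from (supplies the
#'   locus-to-disease mapping).
#' @return a `data.table` with columns `disease`, `n_genes`.
#' @export
disease_gene_counts <- function(table, loci) {
  stopifnot(inherits(loci, "locus_set"))
  sets <- linked_gene_sets(table)
  m <- merge(sets, loci$loci[, .(locus_id, disease)], by = "locus_id")
  m[, .(n_genes = uniqueN(gene_id)), by = disease][order(disease)]
}

#' Genes per locus
#'
#' Counts unique expressed genes per locus across all samples, and reports
#' two means: over loci with at least one linked gene, and over all loci in
#' the supplied locus set (loci with zero genes contribute zeros).
#'
#' @param table a `link_table`.
#' @param loci optional `locus_set`; when given, loci with no links appear
#'   with count 0 and enter the all-loci mean.
#' @return list with `counts` (`locus_id`, `n_genes`), `mean_linked_loci`,
#'   `mean_all_loci`.
#' @export
genes_per_locus <- function(table, loci = NULL) {
  sets <- linked_gene_sets(table)
  counts <- sets[, .(n_genes = uniqueN(gene_id)), by = locus_id]
  if (!is.null(loci)) {
    stopifnot(inherits(loci, "locus_set"))
    all_ids <- loci$loci$locus_id
    counts <- merge(data.table(locus_id = all_ids), counts,
                    by = "locus_id", all.x = TRUE)
    counts[is.na(n_genes), n_genes := 0]
  }
  setorder(counts, locus_id)
  list(counts = counts[],
       mean_linked_loci = if (any(counts$n_genes > 0))
         mean(counts$n_genes[counts$n_genes > 0]) else NA_real_,
       mean_all_loci = mean(counts$n_genes))
}

# Internal: protein-coding subset of a TSS table (all rows if no biotype).
# Always returns a copy so callers can add work columns by reference.
coding_tss <- function(tss) {
  tss <- copy(as.data.table(tss))
  if ("biotype" %in% names(tss)) tss[biotype == "protein_coding"] else tss
}

#' Closest-gene classification for narrow loci
#'
#' For every locus whose LD block is strictly narrower than
#' `cfg$block_width_cutoff`, computes the locus's closest-gene set — the
#' union over its variants of the protein-coding gene(s) whose TSS
#' minimizes the distance to that variant, ties included (an LD block can
#' have multiple closest genes) — and classifies the locus by how that set
#' intersects its linked expressed genes: `all_closest_linked`,
#' `some_closest_linked`, or `no_closest_linked`.
#'
#' @param loci a `locus_set`.
#' @param tss TSS table (protein-coding rows are used).
#' @param table a `link_table`.
#' @param cfg a [link_config()].
#' @return a `data.table` with one row per tested locus: `locus_id`,
#'   `class`, `closest_genes` (comma-joined), `n_closest`,
#'   `n_closest_linked`.
#' @export
closest_gene_report <- function(loci, tss, table, cfg = link_config()) {
  stopifnot(inherits(loci, "locus_set"))
  tss <- coding_tss(tss)
  small <- loci$loci[block_end - block_start < cfg$block_width_cutoff]
  if (!nrow(small)) {
    return(data.table(locus_id = character(), class = character(),
                      closest_genes = character(), n_closest = integer(),
                      n_closest_linked = integer()))
  }
  variants <- loci$variants[locus_id %in% small$locus_id]
  linked <- linked_gene_sets(table)
  tss[, key := norm_chrom(chrom)]
  res <- vector("list", nrow(small))
  for (i in seq_len(nrow(small))) {
    lid <- small$locus_id[i]
    vv <- variants[locus_id == lid]
    cand <- tss[key == norm_chrom(vv$chrom[1])]
    if (!nrow(cand)) {
      warning(sprintf(
        "closest_gene_report: locus %s on a chromosome with no protein-coding TSS",
        lid))
      res[[i]] <- data.table(locus_id = lid, class = "no_closest_linked",
                             closest_genes = "", n_closest = 0L,
                             n_closest_linked = 0L)
      next
    }
    closest <- character(0)
    for (p in vv$pos) {
      d <- abs(cand$tss - p)
      closest <- union(closest, unique(cand$gene_id[d == min(d)]))
    }
    lg <- linked[locus_id == lid, gene_id]
    n_hit <- length(intersect(closest, lg))
    cls <- if (n_hit == length(closest) && length(closest) > 0) {
      "all_closest_linked"
    } else if (n_hit > 0) "some_closest_linked" else "no_closest_linked"
    res[[i]] <- data.table(locus_id = lid, class = cls,
                           closest_genes = paste(sort(closest), collapse = ","),
                           n_closest = length(closest),
                           n_closest_linked = n_hit)
  }
  rbindlist(res)
}

#' Gene-desert loci
#'
#' Loci with no protein-coding TSS within `cfg$gene_desert_window`
#' (default 50 kb) of the LD block: the minimum over all protein-coding
#' TSSs of [point_interval_distance()] from the TSS to the block exceeds
#' the window.
#'
#' @inheritParams closest_gene_report
#' @return character vector of gene-desert `locus_id`s.
#' @export
gene_desert_loci <- function(loci, tss, cfg = link_config()) {
  stopifnot(inherits(loci, "locus_set"))
  tss <- coding_tss(tss)
  tss[, key := norm_chrom(chrom)]
  out <- character(0)
  for (i in seq_len(nrow(loci$loci))) {
    row <- loci$loci[i]
    cand <- tss[key == norm_chrom(row$chrom)]
    if (!nrow(cand)) {
      out <- c(out, row$locus_id)
      next
    }
    dmin <- min(point_interval_distance(cand$tss, row$block_start,
                                        row$block_end))
    if (dmin > cfg$gene_desert_window) out <- c(out, row$locus_id)
  }
  out
}
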