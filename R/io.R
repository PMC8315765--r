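# Readers and writers for the tab-separated formats the pipeline touches.
# All parsed coordinates are 0-based half-open as in the BED standard; SNP
# tables (1-based, GWAS-catalog convention) are converted in build_loci().
# Parsers are line-based so malformed input can be reported by line number.

# Internal: read a tab-separated file, dropping comment/track/browser and
# blank lines. Returns list(fields = list of character vectors, lineno).
read_tab_lines <- function(path, skip_prefixes = c("#", "track", "browser")) {
  if (!file.exists(path)) lg_config_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  for (p in skip_prefixes) keep <- keep & !startsWith(lines, p)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = lineno[keep])
}

# Internal: strict integer coercion; NA on failure.
as_coord <- function(x) suppressWarnings(as.numeric(x))

is_coord <- function(x) {
  y <- as_coord(x)
  !is.na(y) & y == floor(y)
}

#' Read a BED file of genomic intervals
#'
#' Parses BED3+ (tab-separated, 0-based half-open). Track, browser and
#' `#`-comment lines are skipped. Only the first three columns are kept.
#'
#' @param path path to a BED file.
#' @return a `data.table` with columns `chrom`, `start`, `end` (one row per
#'   data line, in file order). Chromosome names are kept verbatim.
#' @seealso [write_bed()], [read_narrowpeak()]
#' @export
read_bed <- function(path) {
  tl <- read_tab_lines(path)
  parse_bed3 <- function(f, ln) {
    if (length(f) < 3) {
      lg_parse_error("BED line with fewer than 3 columns", path, ln)
    }
    if (!is_coord(f[2]) || !is_coord(f[3])) {
      lg_parse_error(sprintf("non-integer BED coordinates '%s', '%s'",
                             f[2], f[3]), path, ln)
    }
    s <- as_coord(f[2]); e <- as_coord(f[3])
    if (s < 0 || s >= e) {
      lg_parse_error(sprintf("invalid BED interval [%s, %s)", f[2], f[3]),
                     path, ln)
    }
    list(chrom = f[1], start = s, end = e)
  }
  rows <- Map(parse_bed3, tl$fields, tl$lineno)
  if (!length(rows)) return(data.table(chrom = character(),
                                       start = numeric(), end = numeric()))
  rbindlist(rows)
}

#' Write intervals as BED3
#'
#' @param intervals a data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  fwrite(as.data.table(intervals)[, .(chrom, start, end)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read chromatin loops from a BEDPE file
#'
#' Parses FitHiChIP-style significant-interaction files: at least six
#' tab-separated columns `chrom1 start1 end1 chrom2 start2 end2`, optionally
#' followed by further columns (name, counts, q-value, ...). Header lines
#' starting with `#`, and column-name header rows (non-numeric start
#' fields), are skipped. Anchors are stored in sorted genomic order
#' (`start1 <= start2` on the same chromosome), so a loop written with its
#' anchors reversed parses to the identical record.
#'
#' Inputs are assumed to be pre-filtered significant interactions; when
#' `score_column` is given, that column (1-based index over all columns) is
#' read as a significance value (q-value dialect) and, if `score_threshold`
#' is also given, rows with `score > score_threshold` are dropped.
#'
#' @param path path to a BEDPE file.
#' @param sample_id sample/cell-type label attached to every loop.
#' @param score_column optional 1-based column index of the significance
#'   (q-value) column.
#' @param score_threshold optional maximum score; rows above it are dropped.
#'   Requires `score_column`.
#' @return a `data.table` with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `score` (NA when no `score_column`), `sample_id`.
#' @export
read_bedpe_loops <- function(path, sample_id = NA_character_,
                             score_column = NULL, score_threshold = NULL) {
  if (!is.null(score_threshold) && is.null(score_column)) {
    lg_config_error("score_threshold given without score_column")
  }
  tl <- read_tab_lines(path)
  # drop column-name header rows (non-numeric start fields)
  is_header <- vapply(tl$fields, function(f) {
    length(f) >= 6 && !(is_coord(f[2]) && is_coord(f[3]))
  }, logical(1))
  tl$fields <- tl$fields[!is_header]
  tl$lineno <- tl$lineno[!is_header]
  parse_row <- function(f, ln) {
    if (length(f) < 6) {
      lg_parse_error("BEDPE line with fewer than 6 columns", path, ln)
    }
    co <- f[c(2, 3, 5, 6)]
    if (!all(is_coord(co))) {
      lg_parse_error("non-integer BEDPE coordinates", path, ln)
    }
    s1 <- as_coord(f[2]); e1 <- as_coord(f[3])
    s2 <- as_coord(f[5]); e2 <- as_coord(f[6])
    if (s1 < 0 || s1 >= e1 || s2 < 0 || s2 >= e2) {
      lg_parse_error("invalid BEDPE anchor interval", path, ln)
    }
    score <- NA_real_
    if (!is.null(score_column)) {
      if (score_column > length(f) || score_column < 1) {
        lg_config_error(sprintf(
          "score_column %d out of range for %d-column BEDPE row (line %d)",
          score_column, length(f), ln))
      }
      score <- as_coord(f[score_column])
    }
    list(chrom1 = f[1], start1 = s1, end1 = e1,
         chrom2 = f[4], start2 = s2, end2 = e2, score = score)
  }
  rows <- Map(parse_row, tl$fields, tl$lineno)
  dt <- if (length(rows)) rbindlist(rows) else {
    data.table(chrom1 = character(), start1 = numeric(), end1 = numeric(),
               chrom2 = character(), start2 = numeric(), end2 = numeric(),
               score = numeric())
  }
  dt <- sort_loop_anchors(dt)
  if (!is.null(score_threshold)) dt <- dt[!is.na(score) & score <= score_threshold]
  dt[, sample_id := sample_id]
  dt[]
}

# Internal: canonicalize anchor order (by normalized chrom, then start).
sort_loop_anchors <- function(dt) {
  if (!nrow(dt)) return(dt)
  k1 <- norm_chrom(dt$chrom1); k2 <- norm_chrom(dt$chrom2)
  swap <- (k1 == k2 & dt$start2 < dt$start1) | (k2 < k1)
  if (any(swap)) {
    tmp <- dt[swap, .(chrom1, start1, end1)]
    dt[swap, `:=`(chrom1 = chrom2, start1 = start2, end1 = end2)]
    dt[swap, `:=`(chrom2 = tmp$chrom1, start2 = tmp$start1, end2 = tmp$end1)]
  }
  dt
}

#' Write loops as BEDPE
#'
#' Writes the six anchor columns plus any of `name` and `score` present.
#'
#' @param loops a loop `data.table` (see [read_bedpe_loops()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  dt <- as.data.table(loops)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            intersect(c("name", "score"), names(dt)))
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read H3K27ac peaks from a narrowPeak or BED file
#'
#' Accepts the 6–10 column narrowPeak dialect as well as plain BED3/BED6;
#' the enrichment signal is taken from column 7 (`signalValue`) when
#' present, otherwise left `NA`. Files may mix row widths.
#'
#' @param path path to a narrowPeak/BED file.
#' @param sample_id sample/cell-type label attached to every peak.
#' @return a `data.table` with columns `chrom`, `start`, `end`, `signal`,
#'   `sample_id`.
#' @export
read_narrowpeak <- function(path, sample_id = NA_character_) {
  tl <- read_tab_lines(path)
  parse_row <- function(f, ln) {
    if (length(f) < 3) {
      lg_parse_error("peak line with fewer than 3 columns", path, ln)
    }
    if (!is_coord(f[2]) || !is_coord(f[3])) {
      lg_parse_error("non-integer peak coordinates", path, ln)
    }
    s <- as_coord(f[2]); e <- as_coord(f[3])
    if (s < 0 || s >= e) lg_parse_error("invalid peak interval", path, ln)
    signal <- if (length(f) >= 7) as_coord(f[7]) else NA_real_
    list(chrom = f[1], start = s, end = e, signal = signal)
  }
  rows <- Map(parse_row, tl$fields, tl$lineno)
  dt <- if (length(rows)) rbindlist(rows) else {
    data.table(chrom = character(), start = numeric(), end = numeric(),
               signal = numeric())
  }
  dt[, sample_id := sample_id]
  dt[]
}

#' Read a gene expression table (TPM)
#'
#' Expects a tab-separated file whose first column is `gene_id` and whose
#' remaining columns are one per sample, holding TPM values.
#'
#' @param path path to the expression TSV.
#' @return a wide `data.table` (`gene_id` + one numeric column per sample).
#' @seealso [is_expressed()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) lg_config_error(sprintf("file not found: %s", path))
  dt <- fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "gene_id") setnames(dt, 1, "gene_id")
  if (ncol(dt) < 2) lg_data_error("expression table has no sample columns")
  num <- dt[, -1]
  if (any(vapply(num, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    lg_data_error("negative TPM values in expression table")
  }
  dt
}

#' Read a GWAS SNP table
#'
#' Tab-separated with header columns `snp_id`, `chrom`, `pos_1based`,
#' `locus_id`, `r2` and optionally `disease`. One row per variant; the lead
#' SNP of a locus has `snp_id == locus_id` and `r2 = 1`.
#'
#' @param path path to the SNP TSV.
#' @return a `data.table` with the columns above (`disease` added as NA when
#'   absent).
#' @seealso [build_loci()]
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) lg_config_error(sprintf("file not found: %s", path))
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("snp_id", "chrom", "pos_1based", "locus_id", "r2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    lg_data_error(sprintf("SNP table %s missing columns: %s", path,
                          paste(miss, collapse = ", ")))
  }
  if (!"disease" %in% names(dt)) dt[, disease := NA_character_]
  dt
}

#' Read an eQTL SNP–gene support table
#'
#' Tab-separated with header columns `locus_id`, `gene_id`; one row per
#' locus–gene pair supported by eQTL evidence.
#'
#' @param path path to the eQTL TSV.
#' @return a `data.table` with columns `locus_id`, `gene_id`.
#' @export
read_eqtl <- function(path) {
  if (!file.exists(path)) lg_config_error(sprintf("file not found: %s", path))
  dt <- fread(path, sep = "\t", header = TRUE)
  miss <- setdiff(c("locus_id", "gene_id"), names(dt))
  if (length(miss)) {
    lg_data_error(sprintf("eQTL table %s missing columns: %s", path,
                          paste(miss, collapse = ", ")))
  }
  unique(dt[, .(locus_id, gene_id)])
}
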