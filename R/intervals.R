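#' Normalize chromosome names
#'
#' Maps the two common chromosome-name dialects onto one key by stripping a
#' leading `"chr"` prefix, so that `"chr1"` and `"1"` compare equal.
#' Mitochondrial and haplotype/contig names are passed through otherwise
#' unchanged (no `"MT"`/`"M"` unification). Normalization is idempotent.
#'
#' Readers keep the chromosome names exactly as found in the file (so
#' write-after-read round-trips); every analysis function calls
#' `norm_chrom()` when building join keys.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @examples
#' norm_chrom(c("chr1", "1", "chrX", "MT"))
#' @export
norm_chrom <- function(x) {
  x <- as.character(x)
  if (any(is.na(x) | x == "")) lg_data_error("empty chromosome name")
  sub("^chr", "", x)
}

#' Distance from a point to a genomic interval
#'
#' Base-pair distance between a position and a 0-based half-open interval
#' `[start, end)`: 0 when the position lies inside the interval,
#' `start - pos` when the position is to the left, and `pos - end + 1` when
#' at or beyond `end` (the distance to the last base of the interval). This
#' is the primitive behind every "within N kb" rule in the linker:
#' "within N kb" means `point_interval_distance(...) <= N * 1000`.
#'
#' @param pos integer vector of 0-based positions.
#' @param start,end integer vectors, 0-based half-open interval bounds
#'   (recycled against `pos`).
#' @return integer vector of non-negative distances.
#' @examples
#' point_interval_distance(150, 100, 200)  # 0: inside
#' point_interval_distance(205, 100, 200)  # 6: past the end
#' point_interval_distance(95, 100, 200)   # 5: before the start
#' @export
point_interval_distance <- function(pos, start, end) {
  n <- max(length(pos), length(start), length(end))
  pos <- rep_len(as.numeric(pos), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (any(start >= end)) lg_data_error("interval with start >= end")
  d <- numeric(n)
  left <- pos < start
  right <- pos >= end
  d[left] <- start[left] - pos[left]
  d[right] <- pos[right] - end[right] + 1
  d
}

# Internal: validate a chrom/start/end table (0-based half-open).
check_intervals <- function(dt, what = "interval") {
  if (any(!is.finite(dt$start) | !is.finite(dt$end))) {
    lg_data_error(sprintf("%s with non-finite coordinates", what))
  }
  if (any(dt$start < 0)) lg_data_error(sprintf("%s with negative start", what))
  if (any(dt$start >= dt$end)) {
    lg_data_error(sprintf("%s with start >= end", what))
  }
  invisible(dt)
}
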