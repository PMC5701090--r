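# Repeat-length genotyping from amplicon reads: quality trimming, exact
# flank anchoring, allele-length histograms, and stutter/depth filtering.

#' Read a FASTQ file of amplicon reads
#'
#' Thin wrapper around [Biostrings::readQualityScaledDNAStringSet()]
#' (gzip-aware). Reads with sequence/quality length mismatch are rejected
#' by the parser.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq_reads <- function(path) {
  d <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- Biostrings::PhredQuality(S4Vectors::mcols(d)$qualities)
  S4Vectors::mcols(d) <- NULL
  Biostrings::QualityScaledDNAStringSet(d, q)
}

#' Write amplicon reads to FASTQ
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(reads, path) {
  Biostrings::writeXStringSet(
    methods::as(reads, "DNAStringSet"), path, format = "fastq",
    qualities = methods::as(Biostrings::quality(reads), "BStringSet"))
  invisible(path)
}

# Truncation point of one read under the sliding-window rule: scan 5'->3';
# at the first length-`window` window whose mean quality < min_q, cut at the
# first below-threshold base at/after the window start (bases before it are
# kept). Returns the number of bases kept.
trim_point <- function(q, window, min_q) {
  n <- length(q)
  if (n == 0L) return(0L)
  w <- min(window, n)
  means <- (cumsum(q)[w:n] - c(0, cumsum(q))[1:(n - w + 1L)]) / w
  bad <- which(means < min_q)
  if (!length(bad)) return(n)
  i <- bad[1]                       # window starts at position i
  j <- which(q[i:n] < min_q)
  if (!length(j)) return(n)         # cannot happen for a failing window
  i + j[1] - 2L
}

#' Quality-trim reads with a sliding window
#'
#' Deterministic 3' quality trimmer: each read is scanned 5' to 3' and cut
#' at the first base below `min_q` inside the first length-`window` window
#' whose mean quality falls below `min_q`; reads shorter than `min_len`
#' (before or after trimming) are dropped.
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param window Sliding-window width in bases.
#' @param min_q Minimum mean window quality (Phred).
#' @param min_len Minimum surviving read length in bases.
#' @return Trimmed `QualityScaledDNAStringSet`.
#' @export
trim_reads <- function(reads, window = 4L, min_q = 20L, min_len = 36L) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  if (!length(reads)) return(reads)
  qints <- methods::as(Biostrings::quality(reads), "IntegerList")
  lows <- min(qints)                      # vectorized per-read minimum
  keep_len <- Biostrings::width(reads)
  need <- which(lows < min_q)
  for (k in need)
    keep_len[k] <- trim_point(qints[[k]], window, min_q)
  out <- IRanges::narrow(reads, start = 1L, end = pmax(keep_len, 1L))
  out[keep_len >= min_len]
}

#' Measure the repeat-tract length spanned by one read
#'
#' Anchors the locus by exact, unique matches of its left and right flank
#' sequences and returns the number of bases strictly between them,
#' provided that segment is a pure run of the locus motif (any rotation).
#' Returns `NA` (no measurement) when either flank is absent or matches
#' more than once, or the spanned segment is impure.
#'
#' @param read_seq A single read sequence (character).
#' @param motif Canonical repeat motif of the locus.
#' @param left_flank,right_flank Flank sequences adjacent to the reference
#'   tract (each at least 6 bp).
#' @return Integer tract length in bp, or `NA_integer_`.
#' @export
extract_repeat_length <- function(read_seq, motif, left_flank, right_flank) {
  if (nchar(left_flank) < 6L || nchar(right_flank) < 6L)
    stop("flanks shorter than 6 bp anchor unreliably")
  lm <- gregexpr(left_flank, read_seq, fixed = TRUE)[[1]]
  rm_ <- gregexpr(right_flank, read_seq, fixed = TRUE)[[1]]
  if (lm[1] == -1L || rm_[1] == -1L ||
      length(lm) != 1L || length(rm_) != 1L) return(NA_integer_)
  seg_start <- lm + nchar(left_flank)
  seg_len <- rm_ - seg_start
  if (seg_len < 0L) return(NA_integer_)
  seg <- substr(read_seq, seg_start, rm_ - 1L)
  if (!segment_is_pure(seg, motif)) return(NA_integer_)
  as.integer(seg_len)
}

# TRUE where each segment is a (possibly truncated / phase-shifted) pure run
# of `motif`. Vectorized over segments.
segment_is_pure <- function(segments, motif) {
  ok <- rep(FALSE, length(segments))
  lens <- nchar(segments)
  ok[lens == 0L] <- TRUE
  for (rot in rotations(motif)) {
    todo <- which(!ok)
    if (!length(todo)) break
    full <- strrep(rot, ceiling(max(lens[todo], 1) / nchar(rot)) + 1L)
    ok[todo] <- segments[todo] == substr(rep(full, length(todo)),
                                         1L, lens[todo])
  }
  ok
}

#' Build an allele-length histogram
#'
#' @param lengths Integer vector of per-read tract-length measurements
#'   (`NA`s are dropped).
#' @param locus_id Locus identifier recorded on the histogram.
#' @return List of class `allele_histogram`: `locus_id`, `counts` (named
#'   integer, names = tract length in bp), `total_reads`.
#' @export
allele_histogram <- function(lengths, locus_id = "locus") {
  lengths <- lengths[!is.na(lengths)]
  counts <- table(lengths)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(locus_id = locus_id, counts = counts,
                 total_reads = sum(counts)),
            class = "allele_histogram")
}

#' Call a diploid genotype from an allele-length histogram
#'
#' Alleles supported by fewer than `min_allele_frac` of the locus reads are
#' treated as PCR stutter and discarded. Of the retained alleles the two
#' highest-count lengths form the genotype (count ties resolved toward the
#' shorter length); a single retained allele is called homozygous. The call
#' is missing when total depth is below `min_depth` or no allele survives.
#'
#' @param hist An `allele_histogram`, or a named count vector
#'   (names = tract lengths in bp).
#' @param min_depth Minimum total read depth for a non-missing call.
#' @param min_allele_frac Minimum fraction of locus reads supporting a real
#'   allele.
#' @return Named integer vector `c(a1, a2, depth)` with `a1 <= a2`, or
#'   `NULL` for a missing call.
#' @examples
#' call_genotype(c("13" = 40, "12" = 5, "15" = 35))  # (13, 15), depth 80
#' @export
call_genotype <- function(hist, min_depth = 10L, min_allele_frac = 0.25) {
  counts <- if (inherits(hist, "allele_histogram")) hist$counts else hist
  if (!length(counts)) return(NULL)
  total <- sum(counts)
  if (total < min_depth) return(NULL)
  lens <- as.integer(names(counts))
  keep <- counts / total >= min_allele_frac
  if (!any(keep)) return(NULL)
  lens <- lens[keep]; cnt <- counts[keep]
  ord <- order(-cnt, lens)            # highest count first, shorter wins ties
  top <- lens[ord][seq_len(min(2L, length(ord)))]
  if (length(top) == 1L) top <- c(top, top)
  c(a1 = min(top), a2 = max(top), depth = as.integer(total))
}
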