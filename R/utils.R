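# Small shared helpers: genotype encoding, motif canonicalization, regions.

#' Encode a diploid repeat-length genotype as a string
#'
#' Genotypes are unordered pairs of repeat-tract lengths in bp; the canonical
#' string form is `"a1/a2"` with `a1 <= a2`, which makes genotype equality a
#' plain string comparison throughout the screening and classification code.
#'
#' @param a1,a2 Integer allele lengths in bp (order irrelevant).
#' @return Character vector of `"a1/a2"` genotype strings.
#' @examples
#' gt_string(15, 13)  # "13/15"
#' @export
gt_string <- function(a1, a2) {
  stopifnot(length(a1) == length(a2), all(a1 >= 0), all(a2 >= 0))
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

#' Decode genotype strings into allele lengths
#'
#' @param g Character vector of `"a1/a2"` strings (NA allowed).
#' @return Integer matrix with columns `a1`, `a2` (`a1 <= a2`).
#' @export
gt_alleles <- function(g) {
  out <- matrix(NA_integer_, nrow = length(g), ncol = 2,
                dimnames = list(NULL, c("a1", "a2")))
  ok <- !is.na(g)
  if (any(ok)) {
    parts <- strsplit(g[ok], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed genotype string: ", g[ok][bad][1])
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    if (anyNA(m)) stop("non-integer allele in genotype string")
    out[ok, 1] <- pmin(m[, 1], m[, 2])
    out[ok, 2] <- pmax(m[, 1], m[, 2])
  }
  out
}

# All rotations of a single motif string.
rotations <- function(motif) {
  n <- nchar(motif)
  if (n <= 1L) return(motif)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(motif, k + 1L, n), substr(motif, 1L, k))
  }, character(1))
}

#' Canonical rotation of a repeat motif
#'
#' The lexicographically minimal rotation, so that e.g. `"CA"`, `"AC"` and
#' `"TG"`, `"GT"` do not create duplicate catalog entries for the same tract.
#' (Strand is ignored; repeats are treated as strand-symmetric.)
#'
#' @param motif Character vector of repeat units (ACGT, 1-6 bp).
#' @return Character vector of canonical motifs.
#' @examples
#' canonical_motif(c("CA", "TTG"))  # "AC" "GTT"
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) min(rotations(m)), character(1), USE.NAMES = FALSE)
}

# TRUE if motif is primitive (not a repetition of a shorter unit).
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n == 1L) return(TRUE)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L &&
          strrep(substr(m, 1L, d), n %/% d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# A string of `len` bases made of `motif` repeated (possibly truncated).
repeat_string <- function(motif, len) {
  u <- nchar(motif)
  substr(strrep(motif, ceiling(len / u) + 1L), 1L, len)
}

#' Parse 1-based inclusive region strings
#'
#' Converts `"chrN:a-b"` (1-based, inclusive, as printed in marker tables)
#' to internal 0-based half-open coordinates.
#'
#' @param x Character vector like `"chr2:60918364-60918376"`.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive).
#' @examples
#' parse_region("chr2:60918364-60918376")  # start 60918363, end 60918376
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^(\\S+):([0-9]+)-([0-9]+)$", x))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed region string: ", x[bad][1])
  chrom <- vapply(m, `[`, character(1), 2L)
  a <- as.numeric(vapply(m, `[`, character(1), 3L))
  b <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(b < a)) stop("region end before start: ", x[b < a][1])
  data.frame(chrom = chrom, start = a - 1, end = b,
             stringsAsFactors = FALSE)
}

#' Format internal coordinates as 1-based inclusive region strings
#'
#' @param chrom Chromosome / contig names.
#' @param start 0-based starts.
#' @param end Exclusive ends.
#' @return Character vector `"chrom:start1-end"` (1-based inclusive).
#' @export
format_region <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start) + 1L, as.integer(end))
}
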