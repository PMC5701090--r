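# Cohort-level genotyping: the genotype-matrix container, read-based cohort
# genotyping against a marker panel, coverage summaries, and TSV I/O.

#' Construct a genotype matrix
#'
#' Samples x loci container of diploid repeat-length genotype calls with
#' per-call depth and case/control labels.
#'
#' @param calls Character matrix (`"a1/a2"` strings, `NA` = missing) with
#'   sample rownames and locus colnames.
#' @param depth Integer matrix of supporting read depths, same shape
#'   (0 where missing).
#' @param labels Named character vector mapping every sample to `"case"` or
#'   `"control"`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, depth, labels) {
  stopifnot(is.matrix(calls), is.matrix(depth),
            identical(dim(calls), dim(depth)),
            !is.null(rownames(calls)), !is.null(colnames(calls)))
  labels <- labels[rownames(calls)]
  if (anyNA(labels) || !all(labels %in% c("case", "control")))
    stop("labels must cover all samples with values 'case'/'control'")
  storage.mode(depth) <- "integer"
  dimnames(depth) <- dimnames(calls)
  structure(list(calls = calls, depth = depth,
                 sample_ids = rownames(calls),
                 locus_ids = colnames(calls),
                 labels = labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$locus_ids), "loci (",
      sum(x$labels == "case"), "cases /",
      sum(x$labels == "control"), "controls );",
      sprintf("call rate %.3f\n", mean(!is.na(x$calls))))
  invisible(x)
}

# Extract anchoring flanks for each panel locus from the reference.
# Returns data.frame with left/right flank strings and a `callable` flag.
locus_flanks <- function(panel, reference, flank_len = 10L) {
  loci <- if (inherits(panel, "mst_panel")) panel$loci else panel
  refn <- names(reference)
  out <- data.frame(locus_id = loci$locus_id, motif = loci$motif,
                    left = NA_character_, right = NA_character_,
                    callable = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(loci))) {
    chrom <- loci$chrom[k]
    if (!chrom %in% refn) next
    contig <- as.character(reference[[chrom]])
    s <- loci$start[k]; e <- loci$end[k]
    if (s < flank_len || e + flank_len > nchar(contig)) next
    left <- substr(contig, s - flank_len + 1L, s)
    right <- substr(contig, e + 1L, e + flank_len)
    # anchors must be unique in the contig for unambiguous placement
    n_left <- length(gregexpr(left, contig, fixed = TRUE)[[1]])
    n_right <- length(gregexpr(right, contig, fixed = TRUE)[[1]])
    if (n_left != 1L || n_right != 1L) next
    out$left[k] <- left; out$right[k] <- right; out$callable[k] <- TRUE
  }
  out
}

# Measure tract lengths for all reads of one sample at one locus.
# reads_chr: character vector of read sequences.
measure_locus <- function(reads_chr, motif, left, right) {
  cand <- which(grepl(left, reads_chr, fixed = TRUE) &
                  grepl(right, reads_chr, fixed = TRUE))
  if (!length(cand)) return(integer(0))
  res <- rep(NA_integer_, length(cand))
  lm <- gregexpr(left, reads_chr[cand], fixed = TRUE)
  rm_ <- gregexpr(right, reads_chr[cand], fixed = TRUE)
  lpos <- vapply(lm, function(m) if (length(m) == 1L) m[1] else -2L, integer(1))
  rpos <- vapply(rm_, function(m) if (length(m) == 1L) m[1] else -2L, integer(1))
  ok <- lpos > 0L & rpos > 0L
  seg_start <- lpos + nchar(left)
  seg_len <- rpos - seg_start
  ok <- ok & seg_len >= 0L
  if (any(ok)) {
    segs <- substr(reads_chr[cand][ok], seg_start[ok], rpos[ok] - 1L)
    pure <- segment_is_pure(segs, motif)
    res[ok][pure] <- seg_len[ok][pure]
  }
  res[!is.na(res)]
}

#' Genotype a cohort of samples against a marker panel
#'
#' For every sample and panel locus, reads spanning the locus are found by
#' exact, unique matches of both anchoring flanks (reads are treated as
#' unaligned), tract lengths are histogrammed, and [call_genotype()] applies
#' depth and stutter-fraction filters. Loci whose flanks cannot be extracted
#' from the reference (or are not unique in their contig) are flagged
#' uncallable, not fatal.
#'
#' @param samples Named character vector of FASTQ paths, or a named list of
#'   `QualityScaledDNAStringSet` objects (names = sample ids).
#' @param panel An `mst_panel` or `mst_catalog`.
#' @param reference Reference sequences: `DNAStringSet` or FASTA path.
#' @param labels Named character vector (`"case"`/`"control"`) per sample.
#' @param flank_len Anchor length in bp (>= 6).
#' @param min_depth,min_allele_frac Passed to [call_genotype()].
#' @param trim Quality-trim reads before genotyping (see [trim_reads()]).
#' @return A `genotype_matrix`; uncallable loci are recorded in
#'   `attr(, "uncallable")`.
#' @export
genotype_cohort <- function(samples, panel, reference, labels,
                            flank_len = 10L, min_depth = 10L,
                            min_allele_frac = 0.25, trim = TRUE) {
  if (flank_len < 6L) stop("flank_len < 6 anchors unreliably")
  if (is.character(reference) && length(reference) == 1L)
    reference <- Biostrings::readDNAStringSet(reference)
  loci <- if (inherits(panel, "mst_panel")) panel$loci else panel
  fl <- locus_flanks(loci, reference, flank_len)
  sample_ids <- names(samples)
  stopifnot(!is.null(sample_ids))
  calls <- matrix(NA_character_, length(sample_ids), nrow(loci),
                  dimnames = list(sample_ids, loci$locus_id))
  depth <- matrix(0L, length(sample_ids), nrow(loci),
                  dimnames = dimnames(calls))
  for (si in seq_along(samples)) {
    reads <- samples[[si]]
    if (is.character(reads)) reads <- read_fastq_reads(reads)
    if (trim) reads <- trim_reads(reads)
    reads_chr <- as.character(reads)
    names(reads_chr) <- NULL
    for (k in which(fl$callable)) {
      lens <- measure_locus(reads_chr, fl$motif[k], fl$left[k], fl$right[k])
      g <- call_genotype(allele_histogram(lens, fl$locus_id[k]),
                         min_depth = min_depth,
                         min_allele_frac = min_allele_frac)
      if (!is.null(g)) {
        calls[si, k] <- gt_string(g[["a1"]], g[["a2"]])
        depth[si, k] <- g[["depth"]]
      }
    }
  }
  gm <- genotype_matrix(calls, depth, labels)
  attr(gm, "uncallable") <- fl$locus_id[!fl$callable]
  gm
}

#' Per-locus call-rate and depth summary
#'
#' @param matrix A `genotype_matrix`.
#' @param call_rate_threshold Loci with call rate below this are flagged.
#' @return data.frame with per-locus `n_called`, `call_rate`, `depth_mean`,
#'   `depth_sd`, `depth_min` (over non-missing calls) and `flagged`.
#' @export
coverage_summary <- function(matrix, call_rate_threshold = 0.93) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  called <- !is.na(matrix$calls)
  if (!length(matrix$locus_ids)) stop("empty genotype matrix")
  n <- nrow(matrix$calls)
  stat1 <- function(f, default = NA_real_) {
    vapply(seq_along(matrix$locus_ids), function(j) {
      d <- matrix$depth[called[, j], j]
      if (!length(d)) default else f(as.numeric(d))
    }, numeric(1))
  }
  out <- data.frame(
    locus_id = matrix$locus_ids,
    n_called = colSums(called),
    call_rate = colSums(called) / n,
    depth_mean = stat1(mean),
    depth_sd = stat1(stats::sd),
    depth_min = stat1(min),
    stringsAsFactors = FALSE)
  out$flagged <- out$call_rate < call_rate_threshold
  rownames(out) <- NULL
  out
}

#' Write / read a genotype matrix as TSV
#'
#' Rows are samples, columns loci; cells are `"a1/a2:depth"` with `"."` for
#' missing. Labels go to a 2-column TSV (`sample_id`, `label`).
#'
#' @param matrix A `genotype_matrix`.
#' @param path Matrix TSV path.
#' @param labels_path Labels TSV path (default: `path` + `".labels"`).
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(matrix, path,
                                  labels_path = paste0(path, ".labels")) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  cells <- ifelse(is.na(matrix$calls), ".",
                  paste0(matrix$calls, ":", matrix$depth))
  dim(cells) <- dim(matrix$calls)
  hdr <- paste(c("sample_id", matrix$locus_ids), collapse = "\t")
  rows <- vapply(seq_along(matrix$sample_ids), function(i) {
    paste(c(matrix$sample_ids[i], cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  writeLines(c("sample_id\tlabel",
               paste(matrix$sample_ids, matrix$labels, sep = "\t")),
             labels_path)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path, labels_path = paste0(path, ".labels")) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  lab <- utils::read.delim(labels_path, colClasses = "character")
  cells <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cells) <- tab$sample_id
  calls <- ifelse(cells == ".", NA_character_, sub(":.*$", "", cells))
  depth <- ifelse(cells == ".", 0L,
                  suppressWarnings(as.integer(sub("^.*:", "", cells))))
  dim(calls) <- dim(cells); dimnames(calls) <- dimnames(cells)
  dim(depth) <- dim(cells); dimnames(depth) <- dimnames(cells)
  genotype_matrix(calls, depth,
                  stats::setNames(lab$label, lab$sample_id))
}
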