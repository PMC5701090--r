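# Tandem-repeat cataloging: detection of perfect tandem tracts in reference
# sequence, catalog validation, and marker-panel assembly.

#' Build / validate a repeat-locus catalog
#'
#' A catalog is a data.frame with one row per microsatellite locus:
#' `locus_id`, `chrom`, `start` (0-based), `end` (exclusive), `motif`
#' (canonical rotation), `unit_len`, `ref_tract_len`, `source_tag`.
#' The constructor checks coordinate arithmetic, canonicalizes motifs,
#' sorts by (chrom, start) and rejects overlapping loci.
#'
#' @param df data.frame with at least `chrom`, `start`, `end`, `motif`;
#'   `locus_id` and `source_tag` are filled in when absent.
#' @return The validated catalog (class `mst_catalog`, still a data.frame).
#' @export
as_catalog <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "motif")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df)) {
    if (any(df$end <= df$start)) stop("catalog has end <= start")
    if (any(!grepl("^[ACGT]{1,6}$", df$motif)))
      stop("motif must be 1-6 uppercase ACGT bases")
    df$motif <- canonical_motif(df$motif)
  }
  df$unit_len <- nchar(df$motif)
  df$ref_tract_len <- df$end - df$start
  if (nrow(df) && any(df$ref_tract_len < df$unit_len * 2L & df$unit_len >= 2L))
    stop("tract shorter than two repeat units")
  if (is.null(df$locus_id))
    df$locus_id <- format_region(df$chrom, df$start, df$end)
  if (is.null(df$source_tag)) df$source_tag <- rep("unspecified", nrow(df))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1] < df$end[-nrow(df)]))
      stop("catalog contains overlapping loci")
  }
  if (anyDuplicated(df$locus_id)) stop("duplicate locus_id in catalog")
  rownames(df) <- NULL
  cols <- c("locus_id", "chrom", "start", "end", "motif", "unit_len",
            "ref_tract_len", "source_tag")
  df <- df[, cols]
  class(df) <- c("mst_catalog", "data.frame")
  df
}

# Candidate maximal perfect tracts of one unit size in a character vector of
# bases. Returns start (1-based, within seq) and tract length.
tracts_of_unit <- function(bases, u, min_tract_bp) {
  n <- length(bases)
  if (n < u + 1L) return(NULL)
  i <- seq_len(n - u)
  eq <- bases[i] == bases[i + u] & bases[i] != "N" & bases[i + u] != "N"
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + u) >= min_tract_bp
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], tract_len = r$lengths[keep] + u)
}

#' Scan a sequence for perfect tandem repeats
#'
#' Detects maximal perfect (ungapped, mismatch-free) tandem tracts with unit
#' sizes `min_unit..max_unit` and tract length at least `min_tract_bp`.
#' Where tracts of different unit sizes overlap, the smallest unit that
#' explains a tract wins; remaining ties go to the leftmost, then longest
#' tract. Tracts whose length is not a whole number of units are truncated
#' to whole copies. Loci never contain N.
#'
#' @param seq A single nucleotide string (ACGTN only).
#' @param chrom Name recorded in the resulting catalog (default "seq").
#' @param min_unit,max_unit Unit-size range, 1-6 bp.
#' @param min_tract_bp Minimum tract length in bp (must allow two copies of
#'   the smallest unit; larger units additionally require tract >= 2 units).
#' @param source_tag Source tag stored on the returned loci.
#' @return An `mst_catalog` of detected loci (possibly empty).
#' @examples
#' scan_tandem_repeats(paste0("GACGT", strrep("T", 13), "GCAGC"))
#' @export
scan_tandem_repeats <- function(seq, chrom = "seq", min_unit = 1L,
                                max_unit = 6L, min_tract_bp = 10L,
                                source_tag = "scan") {
  stopifnot(length(seq) == 1L, is.character(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters other than ACGTN")
  if (!(1L <= min_unit && min_unit <= max_unit && max_unit <= 6L))
    stop("need 1 <= min_unit <= max_unit <= 6")
  if (min_tract_bp < 2L * min_unit)
    stop("min_tract_bp must allow at least two copies of the smallest unit")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- list()
  for (u in seq.int(min_unit, max_unit)) {
    tr <- tracts_of_unit(bases, u, min_tract_bp)
    if (is.null(tr)) next
    # truncate to whole copies of the unit
    tr$tract_len <- (tr$tract_len %/% u) * u
    tr <- tr[tr$tract_len >= min_tract_bp & tr$tract_len >= 2L * u, , drop = FALSE]
    if (!nrow(tr)) next
    tr$unit <- substr(rep(seq, nrow(tr)), tr$start, tr$start + u - 1L)
    tr <- tr[is_primitive_motif(tr$unit) & !grepl("N", tr$unit), , drop = FALSE]
    if (!nrow(tr)) next
    tr$unit_len <- u
    cand[[length(cand) + 1L]] <- tr
  }
  if (!length(cand)) return(empty_catalog())
  cand <- do.call(rbind, cand)
  # smallest unit first, then leftmost, then longest
  cand <- cand[order(cand$unit_len, cand$start, -cand$tract_len), , drop = FALSE]
  taken_end <- integer(0)  # parallel vectors of accepted intervals
  taken_start <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    s <- cand$start[k]; e <- cand$start[k] + cand$tract_len[k] - 1L
    if (!length(taken_start) || all(e < taken_start | s > taken_end)) {
      keep[k] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_catalog())
  as_catalog(data.frame(
    chrom = chrom,
    start = cand$start - 1L,             # to 0-based
    end = cand$start - 1L + cand$tract_len,
    motif = cand$unit,
    source_tag = source_tag,
    stringsAsFactors = FALSE))
}

empty_catalog <- function() {
  as_catalog(data.frame(chrom = character(), start = integer(),
                        end = integer(), motif = character(),
                        stringsAsFactors = FALSE))
}

#' Assemble a marker panel from source catalogs
#'
#' Takes the lung-signature, other-cancer and control locus lists, forms
#' their union with exact-coordinate de-duplication, and reports unique
#' locus counts per source. A locus present in several sources keeps all
#' source tags (comma-joined). Identical coordinates with conflicting
#' canonical motifs raise a catalog-inconsistency error.
#'
#' @param lung,other_cancer,control Catalogs (each an `mst_catalog` or a
#'   data.frame acceptable to [as_catalog()]); duplicates within and across
#'   inputs are allowed and merged.
#' @return An object of class `mst_panel`: list with `loci` (an
#'   `mst_catalog`) and `counts_by_source` (named integer).
#' @export
assemble_panel <- function(lung = empty_catalog(),
                           other_cancer = empty_catalog(),
                           control = empty_catalog()) {
  # normalize columns without the catalog-level overlap/duplicate checks:
  # duplicates within and across the inputs are allowed here and merged.
  tag_one <- function(df, tag) {
    df <- as.data.frame(df)
    need <- c("chrom", "start", "end", "motif")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("catalog missing columns: ",
                           paste(miss, collapse = ", "))
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    if (nrow(df)) {
      if (any(df$end <= df$start)) stop("catalog has end <= start")
      df$motif <- canonical_motif(df$motif)
    }
    if (is.null(df$locus_id))
      df$locus_id <- format_region(df$chrom, df$start, df$end)
    df$source_tag <- rep(tag, nrow(df))
    df[, c("locus_id", "chrom", "start", "end", "motif", "source_tag")]
  }
  parts <- rbind(tag_one(lung, "lung_signature"),
                 tag_one(other_cancer, "other_cancer"),
                 tag_one(control, "control_panel"))
  if (!nrow(parts)) {
    panel <- list(loci = empty_catalog(),
                  counts_by_source = c(lung_signature = 0L,
                                       other_cancer = 0L,
                                       control_panel = 0L))
    class(panel) <- "mst_panel"
    return(panel)
  }
  parts$motif <- canonical_motif(parts$motif)
  key <- paste(parts$chrom, parts$start, parts$end, sep = "\r")
  counts <- vapply(c("lung_signature", "other_cancer", "control_panel"),
                   function(tag) length(unique(key[parts$source_tag == tag])),
                   integer(1))
  first <- !duplicated(key)
  merged <- parts[first, , drop = FALSE]
  motif_by_key <- split(parts$motif, key)
  tags_by_key <- split(parts$source_tag, key)
  mk <- key[first]
  conflict <- vapply(motif_by_key[mk], function(m) length(unique(m)) > 1L,
                     logical(1))
  if (any(conflict))
    stop("catalog inconsistency: conflicting motifs at identical coordinates (",
         merged$chrom[conflict][1], ":", merged$start[conflict][1], ")")
  merged$source_tag <- vapply(tags_by_key[mk], function(tg) {
    paste(unique(tg)[order(match(unique(tg),
      c("lung_signature", "other_cancer", "control_panel")))], collapse = ",")
  }, character(1))
  loci <- as_catalog(merged[, c("locus_id", "chrom", "start", "end",
                                "motif", "source_tag")])
  panel <- list(loci = loci, counts_by_source = counts)
  class(panel) <- "mst_panel"
  panel
}

#' @export
print.mst_panel <- function(x, ...) {
  cat("mst_panel:", nrow(x$loci), "unique loci\n")
  for (tag in names(x$counts_by_source))
    cat(sprintf("  %-15s %d\n", tag, x$counts_by_source[[tag]]))
  invisible(x)
}

#' Panel size
#' @param panel An `mst_panel`.
#' @return Number of unique loci in the panel.
#' @export
panel_size <- function(panel) nrow(panel$loci)
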