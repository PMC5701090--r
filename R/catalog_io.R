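# Catalog file I/O: BED-like 6-column format and 1-based region-string format.

#' Read a repeat-locus catalog
#'
#' Two tab-separated layouts are accepted ('#' lines are comments):
#' * BED-like: `chrom  start(0-based)  end(exclusive)  locus_id  motif
#'   source_tag`
#' * region-style: `chrN:a-b  locus_id  motif  source_tag` with 1-based
#'   inclusive coordinates as printed in marker tables.
#' The layout is detected from the first data line.
#'
#' @param path File path.
#' @return An `mst_catalog`.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(empty_catalog())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  region_style <- grepl("^\\S+:[0-9]+-[0-9]+$", fields[[1]][1])
  ncol_need <- if (region_style) 4L else 6L
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    f <- fields[[k]]
    if (length(f) != ncol_need)
      stop("line ", idx[k], ": expected ", ncol_need, " tab-separated fields")
    if (region_style) {
      reg <- tryCatch(parse_region(f[1]),
                      error = function(e) stop("line ", idx[k], ": ",
                                               conditionMessage(e)))
      rows[[k]] <- data.frame(chrom = reg$chrom, start = reg$start,
                              end = reg$end, locus_id = f[2], motif = f[3],
                              source_tag = f[4], stringsAsFactors = FALSE)
    } else {
      s <- suppressWarnings(as.integer(f[2]))
      e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e))
        stop("line ", idx[k], ": non-integer coordinates")
      if (e <= s)
        stop("line ", idx[k], ": end <= start")
      rows[[k]] <- data.frame(chrom = f[1], start = s, end = e,
                              locus_id = f[4], motif = f[5],
                              source_tag = f[6], stringsAsFactors = FALSE)
    }
  }
  as_catalog(do.call(rbind, rows))
}

#' Write a repeat-locus catalog
#'
#' @param loci An `mst_catalog` (or coercible data.frame).
#' @param path Output file path.
#' @param style `"bed"` (0-based 6-column, default) or `"regions"`
#'   (1-based inclusive `chr:a-b` strings).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(loci, path, style = c("bed", "regions")) {
  style <- match.arg(style)
  loci <- as_catalog(as.data.frame(loci))
  hdr <- if (style == "bed") {
    "# chrom\tstart\tend\tlocus_id\tmotif\tsource_tag"
  } else {
    "# region(1-based incl)\tlocus_id\tmotif\tsource_tag"
  }
  body <- if (!nrow(loci)) {
    character(0)
  } else if (style == "bed") {
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", loci$chrom, loci$start, loci$end,
            loci$locus_id, loci$motif, loci$source_tag)
  } else {
    sprintf("%s\t%s\t%s\t%s", format_region(loci$chrom, loci$start, loci$end),
            loci$locus_id, loci$motif, loci$source_tag)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
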