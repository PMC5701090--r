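# Synthetic-data generation: references with planted microsatellite loci,
# cohort genotype matrices with planted informative loci, stutter-noised
# amplicon reads, and a machine-readable truth manifest.

MANIFEST_VERSION <- "mstrisk-manifest-1"

#' Simulation configuration
#'
#' Defaults describe the study conditions the package targets: a 347-locus
#' enrichment panel carrying 13 informative markers, a 30-case / 89-control
#' cohort, mono/di-nucleotide tracts of 12-26 bp, and per-locus read depth
#' with mean 579, s.d. 315 and floor 83. The control genotype distribution
#' at each locus puts `control_modal_freq` on one modal genotype and spreads
#' the rest over genotypes built from alleles within `allele_spread` repeat
#' units of the reference; at informative loci cases put `case_shift_freq`
#' on a different top genotype.
#'
#' @param seed Integer master seed (all outputs are deterministic in it).
#' @param n_loci Panel size.
#' @param n_informative Number of planted informative loci.
#' @param unit_len_weights Named sampling weights for motif unit sizes 1-6.
#' @param tract_len_range Reference tract length range in bp.
#' @param flank_len Anchoring flank length in bp (base errors are excluded
#'   from these bases next to the tract unless `errors_in_flanks`).
#' @param contig_flank Flanking sequence per side of each planted tract, bp.
#' @param n_cases,n_controls Cohort sizes.
#' @param control_modal_freq Frequency of the control modal genotype.
#' @param case_shift_freq Frequency of the shifted case genotype at
#'   informative loci (a value <= 0.5 warns: planted loci may fail the
#'   >50% predominance rule).
#' @param allele_spread Alternative alleles span this many repeat units on
#'   each side of the reference length.
#' @param depth_mean,depth_sd,depth_min Per-locus read-depth model: normal
#'   draw, rounded, floored at `depth_min`.
#' @param stutter_rate Per-read probability of a +/- 1 unit stutter slip.
#' @param base_error_rate Per-base substitution error rate.
#' @param errors_in_flanks Allow substitution errors inside the anchoring
#'   flanks (off by default; see the methods vignette).
#' @param read_len Read length budget in bp.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_loci = 347L,
                              n_informative = 13L,
                              unit_len_weights = c("1" = 0.9, "2" = 0.1),
                              tract_len_range = c(12L, 26L),
                              flank_len = 10L,
                              contig_flank = 60L,
                              n_cases = 30L,
                              n_controls = 89L,
                              control_modal_freq = 0.8,
                              case_shift_freq = 0.7,
                              allele_spread = 2L,
                              depth_mean = 579,
                              depth_sd = 315,
                              depth_min = 83L,
                              stutter_rate = 0.05,
                              base_error_rate = 0.001,
                              errors_in_flanks = FALSE,
                              read_len = 150L) {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              n_informative = as.integer(n_informative),
              unit_len_weights = unit_len_weights,
              tract_len_range = as.integer(tract_len_range),
              flank_len = as.integer(flank_len),
              contig_flank = as.integer(contig_flank),
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              control_modal_freq = control_modal_freq,
              case_shift_freq = case_shift_freq,
              allele_spread = as.integer(allele_spread),
              depth_mean = depth_mean, depth_sd = depth_sd,
              depth_min = as.integer(depth_min),
              stutter_rate = stutter_rate,
              base_error_rate = base_error_rate,
              errors_in_flanks = isTRUE(errors_in_flanks),
              read_len = as.integer(read_len))
  if (cfg$n_informative > cfg$n_loci)
    stop("n_informative must not exceed n_loci")
  if (cfg$control_modal_freq <= 0 || cfg$control_modal_freq > 1 ||
      cfg$case_shift_freq <= 0 || cfg$case_shift_freq > 1)
    stop("frequencies must be in (0, 1]")
  if (cfg$case_shift_freq <= 0.5)
    warning("case_shift_freq <= 0.5: planted loci may not satisfy the ",
            ">50% predominance rule")
  if (cfg$depth_min < 1L) stop("depth_min must be >= 1")
  if (length(cfg$tract_len_range) != 2L ||
      cfg$tract_len_range[1] > cfg$tract_len_range[2] ||
      cfg$tract_len_range[1] < 2L * max(as.integer(names(unit_len_weights))))
    stop("invalid tract_len_range")
  max_tract <- cfg$tract_len_range[2] +
    cfg$allele_spread * max(as.integer(names(unit_len_weights)))
  if (max_tract + 2L * cfg$flank_len > cfg$read_len)
    stop("tract plus flanks exceeds read length: reads cannot span loci")
  if (!all(names(unit_len_weights) %in% as.character(1:6)) ||
      any(unit_len_weights < 0) || sum(unit_len_weights) <= 0)
    stop("unit_len_weights must be named '1'..'6' with non-negative weights")
  class(cfg) <- "simulation_config"
  cfg
}

# Random primitive motif of a given unit length.
random_motif <- function(u) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE), collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

# Random flank sequence with no base repeated more than twice in a row
# (keeps spurious homopolymer tracts out by construction; full contigs are
# additionally verified by rescanning).
random_flank <- function(len) {
  b <- character(len)
  b[1] <- sample(c("A", "C", "G", "T"), 1)
  for (i in seq_len(len)[-1]) {
    avoid <- if (i >= 3 && b[i - 1] == b[i - 2]) b[i - 1] else ""
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
  }
  paste(b, collapse = "")
}

#' Simulate a reference with planted microsatellite loci
#'
#' One contig per locus: random non-repetitive flanks around a planted
#' perfect tandem tract. Each contig is verified by rescanning with
#' [scan_tandem_repeats()]: the planted locus must be recovered at exact
#' coordinates with its canonical motif and the anchoring flanks must be
#' unique within the contig; flanks are re-drawn otherwise. Deterministic
#' given `config$seed`.
#'
#' @param config A `simulation_config`.
#' @return List with `reference` (named `DNAStringSet`) and `catalog`
#'   (an `mst_catalog`; `chrom` = contig = locus id).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n <- config$n_loci
    if (n == 0L) {
      return(list(reference = Biostrings::DNAStringSet(),
                  catalog = empty_catalog()))
    }
    units <- as.integer(names(config$unit_len_weights))
    seqs <- character(n)
    rows <- vector("list", n)
    for (j in seq_len(n)) {
      id <- sprintf("MST%04d", j)
      u <- if (length(units) == 1L) units else
        sample(units, 1, prob = config$unit_len_weights)
      tl_range <- config$tract_len_range
      for (attempt in seq_len(200L)) {
        tract_len <- (sample(seq(tl_range[1], tl_range[2]), 1) %/% u) * u
        if (tract_len < max(tl_range[1], 2L * u)) next
        motif <- random_motif(u)
        tract <- repeat_string(motif, tract_len)
        left <- random_flank(config$contig_flank)
        right <- random_flank(config$contig_flank)
        contig <- paste0(left, tract, right)
        found <- scan_tandem_repeats(contig, chrom = id,
                                     min_tract_bp = 10L)
        ok <- nrow(found) == 1L &&
          found$start == config$contig_flank &&
          found$end == config$contig_flank + tract_len &&
          found$motif == canonical_motif(motif)
        if (ok) {
          fl <- config$flank_len
          s <- config$contig_flank; e <- s + tract_len
          la <- substr(contig, s - fl + 1L, s)
          ra <- substr(contig, e + 1L, e + fl)
          ok <- length(gregexpr(la, contig, fixed = TRUE)[[1]]) == 1L &&
            length(gregexpr(ra, contig, fixed = TRUE)[[1]]) == 1L
        }
        if (ok) break
        if (attempt == 200L) stop("could not plant locus ", id)
      }
      seqs[j] <- contig
      rows[[j]] <- data.frame(locus_id = id, chrom = id,
                              start = config$contig_flank,
                              end = config$contig_flank + tract_len,
                              motif = motif, source_tag = "simulated",
                              stringsAsFactors = FALSE)
    }
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- sprintf("MST%04d", seq_len(n))
    list(reference = reference, catalog = as_catalog(do.call(rbind, rows)))
  })
}

# Depth draws: normal, rounded, floored at depth_min.
draw_depths <- function(n, config) {
  pmax(config$depth_min,
       as.integer(round(stats::rnorm(n, config$depth_mean, config$depth_sd))))
}

#' Simulate cohort genotypes with planted informative loci
#'
#' Controls draw genotypes per locus from a distribution whose top (modal)
#' genotype has frequency `control_modal_freq`, the remainder spread over
#' four alternative genotypes built from alleles within `allele_spread`
#' units. At `n_informative` randomly chosen loci, cases put
#' `case_shift_freq` on one of those alternative genotypes; elsewhere cases
#' follow the control distribution. Deterministic given `config$seed`.
#'
#' @param config A `simulation_config`.
#' @param catalog Catalog from [simulate_reference()].
#' @param dropout_rate Per-call missingness probability (default 0).
#' @return List with `matrix` (a truth `genotype_matrix` with simulated
#'   depths) and `manifest` (truth manifest; see
#'   [write_truth_manifest()]).
#' @export
simulate_cohort_genotypes <- function(config, catalog, dropout_rate = 0) {
  stopifnot(inherits(config, "simulation_config"),
            nrow(catalog) >= config$n_informative)
  withr::with_seed(config$seed + 1L, {
    n_loci <- nrow(catalog)
    sample_ids <- c(sprintf("case%03d", seq_len(config$n_cases)),
                    sprintf("ctrl%03d", seq_len(config$n_controls)))
    labels <- stats::setNames(rep(c("case", "control"),
                                  c(config$n_cases, config$n_controls)),
                              sample_ids)
    informative <- sort(sample(n_loci, config$n_informative))
    control_dist <- vector("list", n_loci)
    case_dist <- vector("list", n_loci)
    names(control_dist) <- names(case_dist) <- catalog$locus_id
    truth <- matrix(NA_character_, length(sample_ids), n_loci,
                    dimnames = list(sample_ids, catalog$locus_id))
    for (j in seq_len(n_loci)) {
      u <- catalog$unit_len[j]
      L <- catalog$ref_tract_len[j]
      alleles <- L + u * seq.int(-config$allele_spread, config$allele_spread)
      alleles <- alleles[alleles >= max(u, 1L)]
      pairs <- expand.grid(a1 = alleles, a2 = alleles)
      pairs <- pairs[pairs$a1 <= pairs$a2, ]
      gts <- gt_string(pairs$a1, pairs$a2)
      modal <- gt_string(L, L)
      alts <- sample(setdiff(gts, modal), 4L)
      p_ctrl <- stats::setNames(
        c(config$control_modal_freq,
          rep((1 - config$control_modal_freq) / 4, 4)),
        c(modal, alts))
      control_dist[[j]] <- p_ctrl
      if (j %in% informative) {
        shift <- sample(alts, 1L)
        rest <- setdiff(names(p_ctrl), shift)
        w <- p_ctrl[rest] / sum(p_ctrl[rest])
        case_dist[[j]] <- stats::setNames(
          c(config$case_shift_freq, (1 - config$case_shift_freq) * w),
          c(shift, rest))
      } else {
        case_dist[[j]] <- p_ctrl
      }
      is_case <- labels == "case"
      truth[is_case, j] <- sample(names(case_dist[[j]]), sum(is_case),
                                  replace = TRUE, prob = case_dist[[j]])
      truth[!is_case, j] <- sample(names(control_dist[[j]]), sum(!is_case),
                                   replace = TRUE, prob = control_dist[[j]])
    }
    depth <- matrix(draw_depths(length(truth), config),
                    nrow(truth), ncol(truth), dimnames = dimnames(truth))
    calls <- truth
    if (dropout_rate > 0) {
      drop <- matrix(stats::runif(length(calls)) < dropout_rate,
                     nrow(calls), ncol(calls))
      calls[drop] <- NA_character_
      depth[drop] <- 0L
    }
    manifest <- list(
      version = MANIFEST_VERSION,
      seed = config$seed,
      loci = data.frame(
        locus_id = catalog$locus_id,
        informative = seq_len(n_loci) %in% informative,
        control_modal = vapply(control_dist, function(p)
          names(p)[which.max(p)], character(1), USE.NAMES = FALSE),
        case_top = vapply(case_dist, function(p)
          names(p)[which.max(p)], character(1), USE.NAMES = FALSE),
        stringsAsFactors = FALSE),
      control_dist = control_dist,
      case_dist = case_dist,
      labels = labels,
      truth = truth)
    list(matrix = genotype_matrix(calls, depth, labels), manifest = manifest)
  })
}

# Substitute k random different bases at eligible positions of one read.
mutate_read <- function(seq, positions) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions)
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}

#' Simulate amplicon reads for a cohort
#'
#' Per sample and locus, the read count is the simulated call depth; each
#' read draws one of the sample's two true alleles with equal probability,
#' a +/- 1 repeat-unit stutter slip with probability `stutter_rate`, and
#' per-base substitution errors at `base_error_rate` (excluded from the
#' `flank_len` anchoring bases next to the tract unless
#' `config$errors_in_flanks`). Reads span tract plus flanking context up to
#' `read_len`; names encode `sample:locus:true_allele:index`. Deterministic
#' given `config$seed`.
#'
#' @param matrix Truth `genotype_matrix` from
#'   [simulate_cohort_genotypes()].
#' @param catalog,reference From [simulate_reference()].
#' @param config The `simulation_config`.
#' @param outdir Directory for per-sample FASTQ files (created if needed).
#' @return Named character vector of FASTQ paths (one per sample).
#' @export
simulate_reads <- function(matrix, catalog, reference, config,
                           outdir = tempfile("reads")) {
  stopifnot(inherits(matrix, "genotype_matrix"),
            inherits(config, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed + 2L, {
    paths <- stats::setNames(
      file.path(outdir, paste0(matrix$sample_ids, ".fastq")),
      matrix$sample_ids)
    contigs <- stats::setNames(as.character(reference), names(reference))
    for (i in seq_along(matrix$sample_ids)) {
      sid <- matrix$sample_ids[i]
      seqs <- list(); nms <- list()
      for (j in seq_len(nrow(catalog))) {
        g <- matrix$calls[i, j]
        if (is.na(g)) next
        d <- matrix$depth[i, j]
        if (d < 1L) next
        u <- catalog$unit_len[j]
        contig <- contigs[[catalog$chrom[j]]]
        s <- catalog$start[j]; e <- catalog$end[j]
        start_unit <- substr(contig, s + 1L, s + u)
        al <- gt_alleles(g)
        true_allele <- sample(c(al[1, "a1"], al[1, "a2"]), d, replace = TRUE)
        slip <- stats::runif(d) < config$stutter_rate
        dir_ <- sample(c(-1L, 1L), d, replace = TRUE)
        obs <- pmax(u, true_allele + ifelse(slip, dir_ * u, 0L))
        ctx_l <- pmin(s, (config$read_len - obs) %/% 2L)
        ctx_r <- pmin(nchar(contig) - e, config$read_len - obs - ctx_l)
        tracts <- vapply(obs, function(len) repeat_string(start_unit, len),
                         character(1))
        reads <- paste0(substr(rep(contig, d), s - ctx_l + 1L, s),
                        tracts,
                        substr(rep(contig, d), e + 1L, e + ctx_r))
        if (config$base_error_rate > 0) {
          rl <- nchar(reads)
          fl <- if (config$errors_in_flanks) 0L else config$flank_len
          n_elig <- pmax(0L, rl - 2L * fl)
          k <- stats::rbinom(d, n_elig, config$base_error_rate)
          for (r in which(k > 0L)) {
            # eligible: outside the fl anchoring bases on each side of the
            # tract (tract itself is eligible)
            elig <- setdiff(seq_len(rl[r]),
                            c(seq(ctx_l[r] - fl + 1L, length.out = fl),
                              seq(ctx_l[r] + obs[r] + 1L, length.out = fl)))
            pos <- sample(elig, min(k[r], length(elig)))
            reads[r] <- mutate_read(reads[r], pos)
          }
        }
        seqs[[length(seqs) + 1L]] <- reads
        nms[[length(nms) + 1L]] <-
          sprintf("%s:%s:%d:%d", sid, catalog$locus_id[j], true_allele,
                  seq_len(d))
      }
      seqs <- unlist(seqs) %||% character(0)
      nms <- unlist(nms) %||% character(0)
      dna <- Biostrings::DNAStringSet(seqs)
      names(dna) <- nms
      Biostrings::writeXStringSet(
        dna, paths[i], format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
    }
    paths
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the truth manifest
#'
#' The manifest is serialized as JSON with a version field; reading a file
#' with a different version is an explicit error.
#'
#' @param manifest Manifest list from [simulate_cohort_genotypes()].
#' @param path JSON file path.
#' @return `path` invisibly (write) or the manifest list (read).
#' @export
write_truth_manifest <- function(manifest, path) {
  m <- manifest
  m$labels <- as.list(m$labels)
  truth_df <- data.frame(sample_id = rownames(manifest$truth),
                         as.data.frame(manifest$truth),
                         check.names = FALSE, stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  m$truth <- truth_df
  m$control_dist <- lapply(m$control_dist, as.list)
  m$case_dist <- lapply(m$case_dist, as.list)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  if (!identical(m$version, MANIFEST_VERSION))
    stop("truth manifest version mismatch: found ",
         m$version %||% "<none>", ", expected ", MANIFEST_VERSION)
  loci <- do.call(rbind, lapply(m$loci, function(r)
    data.frame(locus_id = r$locus_id, informative = r$informative,
               control_modal = r$control_modal, case_top = r$case_top,
               stringsAsFactors = FALSE)))
  to_dist <- function(lst) lapply(lst, function(p) unlist(p))
  truth_rows <- lapply(m$truth, function(r)
    unlist(r[!names(r) %in% c("sample_id", "_row")]))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- vapply(m$truth, function(r) r$sample_id, character(1))
  list(version = m$version, seed = m$seed, loci = loci,
       control_dist = to_dist(m$control_dist),
       case_dist = to_dist(m$case_dist),
       labels = unlist(m$labels),
       truth = truth)
}

#' Run the full simulation and write every pipeline input
#'
#' Convenience wrapper producing reference FASTA, locus catalog, per-sample
#' FASTQ files, a labels TSV, the truth genotype matrix and the truth
#' manifest under one directory.
#'
#' @param config A `simulation_config`.
#' @param outdir Output directory.
#' @return Named list of the paths written.
#' @export
simulate_all <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  sim <- simulate_cohort_genotypes(config, ref$catalog)
  fasta <- file.path(outdir, "reference.fasta")
  Biostrings::writeXStringSet(ref$reference, fasta)
  catalog_path <- file.path(outdir, "catalog.bed")
  write_catalog(ref$catalog, catalog_path)
  matrix_path <- file.path(outdir, "truth_genotypes.tsv")
  write_genotype_matrix(sim$matrix, matrix_path,
                        file.path(outdir, "labels.tsv"))
  manifest_path <- file.path(outdir, "truth_manifest.json")
  write_truth_manifest(sim$manifest, manifest_path)
  fastqs <- simulate_reads(sim$matrix, ref$catalog, ref$reference, config,
                           file.path(outdir, "reads"))
  list(reference = fasta, catalog = catalog_path, matrix = matrix_path,
       labels = file.path(outdir, "labels.tsv"), manifest = manifest_path,
       fastq = fastqs)
}
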