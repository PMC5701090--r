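# Synthetic-data generator: determinism, planted-locus recovery, depth and
# stutter models, truth-manifest round trip and conservation.

test_that("simulation_config validates its parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_loci = 5, n_informative = 6),
               "n_informative")
  expect_error(simulation_config(control_modal_freq = 0), "frequencies")
  expect_error(simulation_config(depth_min = 0), "depth_min")
  expect_error(simulation_config(read_len = 40), "read length")
  expect_warning(simulation_config(case_shift_freq = 0.4), "predominance")
})

test_that("simulated references are deterministic and rediscovered exactly", {
  cfg <- simulation_config(seed = 7, n_loci = 25, n_informative = 5)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  expect_identical(as.character(ref1$reference), as.character(ref2$reference))
  expect_identical(as.data.frame(ref1$catalog), as.data.frame(ref2$catalog))
  # every planted locus is recovered at identical coordinates and motif
  for (j in seq_len(nrow(ref1$catalog))) {
    hit <- scan_tandem_repeats(as.character(ref1$reference[[j]]),
                               chrom = ref1$catalog$chrom[j])
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, ref1$catalog$start[j])
    expect_equal(hit$end, ref1$catalog$end[j])
    expect_equal(hit$motif, ref1$catalog$motif[j])
  }
  # n_loci 0 gives empty outputs
  empty <- simulate_reference(simulation_config(n_loci = 0, n_informative = 0))
  expect_equal(length(empty$reference), 0L)
  expect_equal(nrow(empty$catalog), 0L)
})

test_that("cohort genotypes and reads are byte-deterministic in the seed", {
  cfg <- simulation_config(seed = 17, n_loci = 3, n_informative = 1,
                           n_cases = 3, n_controls = 3,
                           depth_mean = 50, depth_sd = 10, depth_min = 20)
  ref <- simulate_reference(cfg)
  s1 <- simulate_cohort_genotypes(cfg, ref$catalog)
  s2 <- simulate_cohort_genotypes(cfg, ref$catalog)
  expect_identical(s1$matrix$calls, s2$matrix$calls)
  expect_identical(s1$manifest, s2$manifest)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_reads(s1$matrix, ref$catalog, ref$reference, cfg, d1)
  f2 <- simulate_reads(s2$matrix, ref$catalog, ref$reference, cfg, d2)
  for (s in names(f1))
    expect_identical(readLines(f1[[s]]), readLines(f2[[s]]))
})

test_that("manifest structure matches the planted design", {
  cfg <- simulation_config(seed = 1, n_loci = 50, n_informative = 13)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort_genotypes(cfg, ref$catalog)
  man <- sim$manifest
  expect_equal(sum(man$loci$informative), 13L)
  # informative loci have a shifted case top genotype, others match control
  inf <- man$loci$informative
  expect_true(all(man$loci$case_top[inf] != man$loci$control_modal[inf]))
  expect_true(all(man$loci$case_top[!inf] == man$loci$control_modal[!inf]))
  # all 119 samples labeled
  expect_equal(sum(man$labels == "case"), 30L)
  expect_equal(sum(man$labels == "control"), 89L)
  # matrix equals the manifest truth when dropout is zero
  expect_identical(sim$matrix$calls, man$truth)
})

test_that("depth model honours the floor and the target mean", {
  cfg <- simulation_config(seed = 29, n_loci = 50, n_informative = 5)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort_genotypes(cfg, ref$catalog)
  d <- as.vector(sim$matrix$depth)       # 50 loci x 119 samples draws
  expect_gte(min(d), 83)
  expect_lt(abs(mean(d) - 579) / 579, 0.05)
})

test_that("stutter appears at the configured per-read rate", {
  cfg <- simulation_config(seed = 37, n_loci = 2, n_informative = 0,
                           n_cases = 5, n_controls = 25,
                           depth_mean = 200, depth_sd = 0, depth_min = 100,
                           stutter_rate = 0.05, base_error_rate = 0,
                           control_modal_freq = 1, allele_spread = 2)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort_genotypes(cfg, ref$catalog)
  fq <- simulate_reads(sim$matrix, ref$catalog, ref$reference, cfg,
                       withr::local_tempdir())
  off <- 0L; total <- 0L
  for (s in names(fq)) {
    reads <- read_fastq_reads(fq[[s]])
    info <- strsplit(names(reads), ":", fixed = TRUE)
    true_allele <- as.integer(vapply(info, `[`, character(1), 3))
    locus <- vapply(info, `[`, character(1), 2)
    k <- match(locus, ref$catalog$locus_id)
    fl <- locus_flanks(ref$catalog, ref$reference, 10L)
    for (j in unique(k)) {
      sel <- which(k == j)
      lens <- vapply(as.character(reads)[sel], function(r)
        extract_repeat_length(r, fl$motif[j], fl$left[j], fl$right[j]),
        integer(1), USE.NAMES = FALSE)
      off <- off + sum(lens != true_allele[sel], na.rm = TRUE)
      total <- total + sum(!is.na(lens))
    }
  }
  rate <- off / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("truth manifest round-trips losslessly through JSON", {
  cfg <- simulation_config(seed = 43, n_loci = 6, n_informative = 2,
                           n_cases = 4, n_controls = 5)
  ref <- simulate_reference(cfg)
  man <- simulate_cohort_genotypes(cfg, ref$catalog)$manifest
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(man, path)
  back <- read_truth_manifest(path)
  expect_equal(back$loci, man$loci)
  expect_equal(back$control_dist, man$control_dist)
  expect_equal(back$case_dist, man$case_dist)
  expect_equal(back$labels, man$labels)
  expect_equal(back$truth, man$truth)
  expect_equal(back$seed, man$seed)
  # version mismatch is an explicit error
  m2 <- man; m2$version <- "other-0"
  write_truth_manifest(m2, path)
  expect_error(read_truth_manifest(path), "version mismatch")
})

test_that("manifest/matrix cross-check catches an injected mismatch", {
  cfg <- simulation_config(seed = 47, n_loci = 4, n_informative = 1,
                           n_cases = 3, n_controls = 3)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort_genotypes(cfg, ref$catalog)
  tampered <- sim$matrix$calls
  al <- gt_alleles(tampered[2, 2])
  tampered[2, 2] <- gt_string(al[1] + 1L, al[2] + 1L)
  expect_false(identical(tampered, sim$manifest$truth))
  expect_identical(sim$matrix$calls, sim$manifest$truth)
})

test_that("sampled genotype frequencies conserve the generating distributions", {
  cfg <- simulation_config(seed = 53, n_loci = 12, n_informative = 3,
                           n_cases = 250, n_controls = 250)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort_genotypes(cfg, ref$catalog)
  is_ctrl <- sim$matrix$labels == "control"
  for (j in seq_len(12)) {
    p <- sim$manifest$control_dist[[j]]
    emp <- table(factor(sim$matrix$calls[is_ctrl, j], levels = names(p))) / 250
    # binomial sampling error: 4 SE per category
    tol <- 4 * sqrt(p * (1 - p) / 250)
    expect_true(all(abs(as.numeric(emp) - p) <= tol + 1e-9))
  }
})

test_that("simulate_all writes a complete, reloadable input set", {
  cfg <- simulation_config(seed = 59, n_loci = 3, n_informative = 1,
                           n_cases = 2, n_controls = 3,
                           depth_mean = 40, depth_sd = 5, depth_min = 20,
                           stutter_rate = 0, base_error_rate = 0)
  out <- withr::local_tempdir()
  paths <- simulate_all(cfg, out)
  expect_true(all(file.exists(unlist(paths))))
  catalog <- read_catalog(paths$catalog)
  expect_equal(nrow(catalog), 3L)
  gm <- read_genotype_matrix(paths$matrix, paths$labels)
  man <- read_truth_manifest(paths$manifest)
  expect_identical(gm$calls, man$truth)
  regen <- genotype_cohort(paths$fastq, catalog,
                           Biostrings::readDNAStringSet(paths$reference),
                           gm$labels)
  expect_identical(regen$calls, gm$calls)
})
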