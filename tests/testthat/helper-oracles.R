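# Independent oracles used to verify package computations, written as naive
# reference implementations (loops / enumeration / closed forms), plus small
# fixture builders. They deliberately avoid the package's code paths.

# Naive maximal-perfect-tandem-repeat scanner: for every start position and
# unit size, extend a perfect run base by base; keep left-maximal, primitive,
# N-free tracts truncated to whole copies; then apply the same resolution
# rule (smallest unit, then leftmost, then longest; non-overlapping).
oracle_scan <- function(seq, min_unit = 1, max_unit = 6, min_tract = 10) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  rows <- list()
  for (u in min_unit:max_unit) {
    for (i in seq_len(n)) {
      if (i + 2 * u - 1 > n) next
      unit <- paste(b[i:(i + u - 1)], collapse = "")
      if (grepl("N", unit)) next
      len <- u
      while (i + len <= n && b[i + len] != "N" &&
             b[i + len] == b[i + len - u]) len <- len + 1
      left_max <- i == 1 ||
        !(b[i - 1] != "N" && i - 1 + u <= n && b[i - 1] == b[i - 1 + u])
      if (!left_max) next
      len <- (len %/% u) * u
      if (len < max(min_tract, 2 * u)) next
      prim <- TRUE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 && strrep(substr(unit, 1, d), u / d) == unit)
          prim <- FALSE
      }
      if (!prim) next
      rows[[length(rows) + 1]] <- data.frame(start = i, len = len, u = u,
                                             unit = unit)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character()))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$u, cand$start, -cand$len), ]
  acc <- list()
  for (k in seq_len(nrow(cand))) {
    s <- cand$start[k]; e <- cand$start[k] + cand$len[k] - 1
    clash <- FALSE
    for (iv in acc) if (s <= iv[2] && e >= iv[1]) clash <- TRUE
    if (clash) next
    acc[[length(acc) + 1]] <- c(s, e, k)
  }
  kept <- cand[vapply(acc, `[`, numeric(1), 3), , drop = FALSE]
  out <- data.frame(start = kept$start - 1L,
                    end = kept$start - 1L + kept$len,
                    motif = vapply(kept$unit, function(m) {
                      n <- nchar(m)
                      rots <- vapply(seq_len(n) - 1, function(j)
                        paste0(substr(m, j + 1, n), substr(m, 1, j)), "")
                      min(rots)
                    }, character(1), USE.NAMES = FALSE))
  out[order(out$start), , drop = FALSE]
}

# Two-sided Fisher exact p by direct enumeration of all tables at fixed
# margins, probabilities from log-binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c; N <- n1 + n2
  sup <- max(0, k - n2):min(k, n1)
  p <- exp(lchoose(n1, sup) + lchoose(n2, k - sup) - lchoose(N, k))
  obs <- p[sup == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# AUC as the Mann-Whitney pairwise concordance probability (0.5 for ties).
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  total <- 0
  for (x in cs) for (y in ct)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(cs) * length(ct))
}

# Hand-rolled BH step-up adjustment, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  res <- numeric(m)
  res[o] <- pmin(1, adj)
  res
}

# Monte-Carlo power of the pooled two-sample t-test (vectorized).
oracle_mc_power <- function(n1, n2, diff, sd, alpha, nsim) {
  x <- matrix(stats::rnorm(n1 * nsim, diff, sd), nrow = n1)
  y <- matrix(stats::rnorm(n2 * nsim, 0, sd), nrow = n2)
  m1 <- colMeans(x); m2 <- colMeans(y)
  ss1 <- colSums(sweep(x, 2, m1)^2)
  ss2 <- colSums(sweep(y, 2, m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  mean(abs(tstat) > stats::qt(1 - alpha / 2, n1 + n2 - 2))
}

# Random ACGT sequence.
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small simulated cohort (genotype level) for screening/classifier tests.
quick_cohort <- function(seed, n_loci = 40, n_informative = 8, ...) {
  cfg <- simulation_config(seed = seed, n_loci = n_loci,
                           n_informative = n_informative, ...)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort_genotypes(cfg, ref$catalog)
  list(config = cfg, reference = ref$reference, catalog = ref$catalog,
       matrix = sim$matrix, manifest = sim$manifest)
}

# Genotype matrix built directly from per-cohort genotype string vectors
# (one locus), for targeted screening tests.
matrix_one_locus <- function(case_calls, control_calls, locus = "L1") {
  calls <- matrix(c(case_calls, control_calls), ncol = 1,
                  dimnames = list(c(sprintf("ca%02d", seq_along(case_calls)),
                                    sprintf("co%02d", seq_along(control_calls))),
                                  locus))
  depth <- matrix(100L, nrow(calls), 1, dimnames = dimnames(calls))
  depth[is.na(calls)] <- 0L
  labels <- stats::setNames(rep(c("case", "control"),
                                c(length(case_calls), length(control_calls))),
                            rownames(calls))
  genotype_matrix(calls, depth, labels)
}
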