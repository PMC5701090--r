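# Informative-locus screening: modal/predominant genotypes, per-locus 2x2
# Fisher exact tests on modal vs non-modal counts, Benjamini-Hochberg FDR,
# and per-locus odds ratios.

# Most frequent genotype among non-missing calls; ties broken to the
# lexicographically smaller (a1, a2) pair. Ties never satisfy predominance.
top_genotype <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NULL)
  tab <- table(calls)
  al <- gt_alleles(names(tab))
  ord <- order(-as.integer(tab), al[, 1], al[, 2])
  best <- names(tab)[ord[1]]
  n_best <- as.integer(tab[ord[1]])
  tied <- sum(tab == n_best) > 1L
  freq <- n_best / length(calls)
  list(genotype = best, freq = freq,
       predominant = freq > 0.5 && !tied, n = length(calls))
}

#' Modal genotype of the control cohort at one locus
#'
#' The modal genotype is the most frequent genotype among non-missing
#' control calls; the predominance flag records whether it covers more than
#' half of the called controls (required for validation-mode
#' informativeness). Frequency denominators are called samples only.
#'
#' @param control_calls Character vector of `"a1/a2"` genotype strings with
#'   `NA` for missing calls.
#' @return List with `genotype`, `freq`, `predominant`, `n` (called count).
#' @export
modal_genotype <- function(control_calls) {
  res <- top_genotype(control_calls)
  if (is.null(res)) stop("all calls missing: locus is unscreenable")
  res
}

#' Predominant genotype of the case cohort at one locus
#'
#' Same computation as [modal_genotype()] over case samples: the genotype
#' found in more than 50% of called cases, when one exists.
#'
#' @param case_calls Character vector of `"a1/a2"` strings with `NA`s.
#' @return List with `genotype`, `freq`, `predominant`, `n`.
#' @export
predominant_genotype <- function(case_calls) {
  res <- top_genotype(case_calls)
  if (is.null(res)) stop("all calls missing: locus is unscreenable")
  res
}

#' Two-sided Fisher exact test on modal vs non-modal counts
#'
#' Exact p-value for a 2x2 table by summing, at fixed margins, the
#' hypergeometric probabilities of all tables at most as probable as the
#' observed one (the conventional minimum-likelihood two-sided definition,
#' with the standard 1 + 1e-7 relative tolerance on the comparison so the
#' result is reproducible bit-for-bit). A zero margin yields p = 1.
#'
#' @param case_modal,case_nonmodal Counts of case samples with / without
#'   the control-modal genotype.
#' @param control_modal,control_nonmodal Same for control samples.
#' @return Two-sided p-value.
#' @examples
#' fisher_modal_test(0, 5, 5, 0)  # 2/252
#' @export
fisher_modal_test <- function(case_modal, case_nonmodal,
                              control_modal, control_nonmodal) {
  cnt <- c(case_modal, case_nonmodal, control_modal, control_nonmodal)
  if (any(cnt < 0) || anyNA(cnt)) stop("counts must be non-negative")
  n1 <- case_modal + case_nonmodal
  n2 <- control_modal + control_nonmodal
  if (n1 < 1 || n2 < 1) stop("both cohort totals must be >= 1")
  k <- case_modal + control_modal
  support <- max(0, k - n2):min(k, n1)
  d <- stats::dhyper(support, n1, n2, k)
  d_obs <- d[support == case_modal]
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (via [stats::p.adjust()], i.e. `p * m / rank`
#' with running-minimum monotonization) and the significance calls at a
#' given adjusted-p cutoff. Input order is preserved.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @param q_cutoff Adjusted-p cutoff; significant where `adjusted < q_cutoff`.
#' @return List with `adjusted` and logical `significant`, both in input
#'   order.
#' @export
bh_fdr <- function(pvalues, q_cutoff = 1e-4) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  if (!length(pvalues))
    return(list(adjusted = numeric(0), significant = logical(0)))
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, significant = !is.na(adjusted) & adjusted < q_cutoff)
}

#' Per-locus odds ratio
#'
#' `OR = (case_risk / case_nonrisk) / (control_risk / control_nonrisk)`,
#' the risk category in the numerator for cases. When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied.
#'
#' @param counts2x2 Length-4 vector `(case_risk, case_nonrisk,
#'   control_risk, control_nonrisk)` or a 2x2 matrix with rows case/control
#'   and columns risk/non-risk.
#' @return Positive odds ratio.
#' @examples
#' locus_odds_ratio(c(20, 10, 10, 20))  # 4
#' @export
locus_odds_ratio <- function(counts2x2) {
  x <- if (is.matrix(counts2x2)) as.numeric(t(counts2x2)) else as.numeric(counts2x2)
  stopifnot(length(x) == 4, all(x >= 0))
  if (any(x == 0)) x <- x + 0.5
  (x[1] / x[2]) / (x[3] / x[4])
}

#' Screen a cohort for informative loci
#'
#' Computes, per locus, the control modal genotype, the case predominant
#' genotype, 2x2 modal/non-modal counts, the Fisher exact p, BH-adjusted q
#' and the per-locus odds ratio, then flags informative loci:
#' * `discovery`: loci whose Fisher p passes the BH cutoff (risk category =
#'   non-modal genotype);
#' * `validation`: loci where the control modal and case predominant
#'   genotypes are each held by >50% of their cohort and differ (risk
#'   category = the predominant cancer genotype).
#' Loci below `min_call_rate` and loci with an entirely missing cohort are
#' excluded before testing and listed in `attr(, "excluded")`.
#'
#' @param matrix A `genotype_matrix` containing both cases and controls.
#' @param mode `"validation"` or `"discovery"`.
#' @param q_cutoff BH adjusted-p cutoff for discovery mode.
#' @param min_call_rate Minimum overall per-locus call rate.
#' @return data.frame (one row per screened locus): `locus_id`,
#'   `modal_genotype`, `modal_freq_controls`, `modal_predominant`,
#'   `predominant_cancer_genotype`, `predominant_freq_cases`,
#'   `case_predominant`, `case_modal`, `case_nonmodal`, `control_modal`,
#'   `control_nonmodal`, `fisher_p`, `bh_q`, `informative`, `odds_ratio`.
#' @export
select_informative_loci <- function(matrix,
                                    mode = c("validation", "discovery"),
                                    q_cutoff = 1e-4, min_call_rate = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "genotype_matrix"))
  is_case <- matrix$labels == "case"
  if (!any(is_case) || all(is_case))
    stop("matrix must contain both cases and controls")
  case_calls <- matrix$calls[is_case, , drop = FALSE]
  ctrl_calls <- matrix$calls[!is_case, , drop = FALSE]
  n_samples <- nrow(matrix$calls)

  n_loci <- length(matrix$locus_ids)
  reason <- rep(NA_character_, n_loci)
  modal_gt <- pred_gt <- rep(NA_character_, n_loci)
  modal_fr <- pred_fr <- rep(NA_real_, n_loci)
  modal_pr <- pred_pr <- rep(NA, n_loci)
  cm <- cn <- tm <- tn <- crisk <- trisk <- rep(NA_integer_, n_loci)
  for (j in seq_len(n_loci)) {
    cc <- case_calls[, j]; tc <- ctrl_calls[, j]
    n_cc <- sum(!is.na(cc)); n_tc <- sum(!is.na(tc))
    if ((n_cc + n_tc) / n_samples < min_call_rate) {
      reason[j] <- "low_call_rate"
      next
    }
    if (n_tc == 0L || n_cc == 0L) {
      reason[j] <- "unscreenable"
      next
    }
    modal <- top_genotype(tc)
    pred <- top_genotype(cc)
    modal_gt[j] <- modal$genotype; modal_fr[j] <- modal$freq
    modal_pr[j] <- modal$predominant
    pred_gt[j] <- pred$genotype; pred_fr[j] <- pred$freq
    pred_pr[j] <- pred$predominant
    cm[j] <- sum(cc == modal$genotype, na.rm = TRUE)
    tm[j] <- sum(tc == modal$genotype, na.rm = TRUE)
    cn[j] <- n_cc - cm[j]; tn[j] <- n_tc - tm[j]
    crisk[j] <- sum(cc == pred$genotype, na.rm = TRUE)
    trisk[j] <- sum(tc == pred$genotype, na.rm = TRUE)
  }
  keep <- is.na(reason)
  excluded <- data.frame(locus_id = matrix$locus_ids[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (!any(keep))
    stop("no screenable loci after call-rate filtering")
  stats_df <- data.frame(
    locus_id = matrix$locus_ids[keep],
    modal_genotype = modal_gt[keep],
    modal_freq_controls = modal_fr[keep],
    modal_predominant = modal_pr[keep],
    predominant_cancer_genotype = pred_gt[keep],
    predominant_freq_cases = pred_fr[keep],
    case_predominant = pred_pr[keep],
    case_modal = cm[keep],
    case_nonmodal = cn[keep],
    control_modal = tm[keep],
    control_nonmodal = tn[keep],
    case_risk = crisk[keep],
    control_risk = trisk[keep],
    stringsAsFactors = FALSE)
  stats_df$fisher_p <- mapply(fisher_modal_test,
                              stats_df$case_modal, stats_df$case_nonmodal,
                              stats_df$control_modal, stats_df$control_nonmodal)
  bh <- bh_fdr(stats_df$fisher_p, q_cutoff = q_cutoff)
  stats_df$bh_q <- bh$adjusted
  if (mode == "discovery") {
    stats_df$informative <- bh$significant
    stats_df$odds_ratio <- vapply(seq_len(nrow(stats_df)), function(i) {
      locus_odds_ratio(c(stats_df$case_nonmodal[i], stats_df$case_modal[i],
                         stats_df$control_nonmodal[i], stats_df$control_modal[i]))
    }, numeric(1))
  } else {
    stats_df$informative <- stats_df$modal_predominant &
      stats_df$case_predominant &
      stats_df$modal_genotype != stats_df$predominant_cancer_genotype
    case_n <- stats_df$case_modal + stats_df$case_nonmodal
    ctrl_n <- stats_df$control_modal + stats_df$control_nonmodal
    stats_df$odds_ratio <- vapply(seq_len(nrow(stats_df)), function(i) {
      locus_odds_ratio(c(stats_df$case_risk[i],
                         case_n[i] - stats_df$case_risk[i],
                         stats_df$control_risk[i],
                         ctrl_n[i] - stats_df$control_risk[i]))
    }, numeric(1))
  }
  stats_df$case_risk <- NULL
  stats_df$control_risk <- NULL
  rownames(stats_df) <- NULL
  attr(stats_df, "excluded") <- excluded
  attr(stats_df, "mode") <- mode
  stats_df
}

#' Write a locus-statistics table as TSV
#'
#' @param stats data.frame from [select_informative_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
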