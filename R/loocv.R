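# Leave-one-out cross-validation of the risk classifier.

#' Leave-one-out cross-validation
#'
#' One fold per sample: the locus screen, signature and accuracy-optimal
#' cutoff are refit on the remaining samples and the held-out sample is
#' scored and classified. The number of iterations therefore equals the
#' total sample count. Folds whose refit yields an empty signature (or an
#' unscorable held-out sample) are recorded as unpredictable and surfaced
#' in the output rather than silently dropped.
#'
#' Pooled sensitivity/specificity are computed over the held-out
#' predictions; per-fold training metrics are also reported, since a
#' "per-fold sensitivity" of a single held-out sample is not well defined.
#'
#' @param matrix A `genotype_matrix` with at least 2 samples per class.
#' @param mode,q_cutoff,min_call_rate Passed to
#'   [select_informative_loci()] at each refit.
#' @param fixed_signature If `TRUE`, the signature is fit once on the full
#'   cohort and only the cutoff is refit per fold (the optimistic variant);
#'   default refits everything.
#' @return List with `predictions` (per held-out sample: `sample_id`,
#'   `label`, `score`, `predicted`, `n_signature`, `fold_cutoff`,
#'   `predictable`), `n_folds`, pooled `sensitivity`, `specificity`,
#'   `accuracy`, `confusion`, and `per_fold` training metrics
#'   (`train_sensitivity`, `train_specificity`, `train_accuracy`).
#' @export
loocv <- function(matrix, mode = c("validation", "discovery"),
                  q_cutoff = 1e-4, min_call_rate = 0.5,
                  fixed_signature = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "genotype_matrix"))
  lab <- matrix$labels
  if (sum(lab == "case") < 2L || sum(lab == "control") < 2L)
    stop("need at least 2 samples per class")
  n <- length(matrix$sample_ids)
  full_model <- if (fixed_signature) {
    fit_classifier(matrix, mode = mode, q_cutoff = q_cutoff,
                   min_call_rate = min_call_rate)
  } else NULL

  preds <- data.frame(sample_id = matrix$sample_ids,
                      label = unname(lab),
                      score = NA_real_, predicted = NA_character_,
                      n_signature = 0L, fold_cutoff = NA_real_,
                      predictable = FALSE, stringsAsFactors = FALSE)
  fold_metrics <- data.frame(train_sensitivity = rep(NA_real_, n),
                             train_specificity = NA_real_,
                             train_accuracy = NA_real_)
  for (i in seq_len(n)) {
    train <- subset_matrix(matrix, -i)
    model <- tryCatch({
      if (fixed_signature) {
        m <- full_model
        sc <- score_cohort(train, m)
        oc <- optimal_cutoff(sc$score, sc$label)
        m$cutoff <- oc$cutoff
        m
      } else {
        fit_classifier(train, mode = mode, q_cutoff = q_cutoff,
                       min_call_rate = min_call_rate)
      }
    }, error = function(e) NULL)
    if (is.null(model)) next                      # unpredictable fold
    sc <- score_cohort(train, model)
    ev <- evaluate(sc$score, sc$label, model$cutoff)
    fold_metrics$train_sensitivity[i] <- ev$sensitivity
    fold_metrics$train_specificity[i] <- ev$specificity
    fold_metrics$train_accuracy[i] <- ev$accuracy
    s <- score_sample(stats::setNames(matrix$calls[i, ],
                                      colnames(matrix$calls)), model)
    preds$n_signature[i] <- nrow(model$signature)
    preds$fold_cutoff[i] <- model$cutoff
    if (is.na(s)) next                            # unscorable held-out sample
    preds$score[i] <- s
    preds$predicted[i] <- if (s >= model$cutoff) "at_risk" else "healthy"
    preds$predictable[i] <- TRUE
  }
  ok <- preds$predictable
  TP <- sum(ok & preds$label == "case" & preds$predicted == "at_risk")
  FN <- sum(ok & preds$label == "case" & preds$predicted == "healthy")
  TN <- sum(ok & preds$label == "control" & preds$predicted == "healthy")
  FP <- sum(ok & preds$label == "control" & preds$predicted == "at_risk")
  list(predictions = preds,
       n_folds = n,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       accuracy = if (sum(ok) > 0) (TP + TN) / sum(ok) else NA_real_,
       confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
       per_fold = fold_metrics,
       n_unpredictable = sum(!ok))
}

# Row-subset a genotype_matrix (keeps class and labels consistent).
subset_matrix <- function(matrix, idx) {
  genotype_matrix(matrix$calls[idx, , drop = FALSE],
                  matrix$depth[idx, , drop = FALSE],
                  matrix$labels[rownames(matrix$calls[idx, , drop = FALSE])])
}
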