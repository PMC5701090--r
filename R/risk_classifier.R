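# Fraction-of-risk-genotype classification: sample scoring, ROC/AUC,
# accuracy-optimal cutoff, confusion-matrix metrics and model I/O.

#' Build a classifier model from a locus-statistics table
#'
#' The signature is the set of informative loci. In validation mode the
#' risk genotype of a locus is its predominant cancer genotype and a sample
#' scores by the fraction of called signature loci carrying it; in
#' discovery mode the reference genotype is the control modal genotype and
#' a sample scores by the fraction of called signature loci that are
#' non-modal.
#'
#' @param stats data.frame from [select_informative_loci()].
#' @param cutoff Score cutoff in \[0, 1\]; a sample is called at-risk when
#'   `score >= cutoff`. May be `NA` while unfitted (see [fit_classifier()]).
#' @param mode `"validation"` or `"discovery"` (defaults to the mode the
#'   stats table was screened under).
#' @return Object of class `classifier_model` with `signature`
#'   (data.frame: `locus_id`, `risk_genotype`, `reference_genotype`),
#'   `cutoff`, `mode`.
#' @export
build_classifier <- function(stats, cutoff = NA_real_,
                             mode = attr(stats, "mode")) {
  mode <- match.arg(mode, c("validation", "discovery"))
  sig <- stats[stats$informative, , drop = FALSE]
  if (!nrow(sig)) stop("empty signature: no informative loci")
  signature <- data.frame(
    locus_id = sig$locus_id,
    risk_genotype = if (mode == "validation")
      sig$predominant_cancer_genotype else NA_character_,
    reference_genotype = sig$modal_genotype,
    stringsAsFactors = FALSE)
  if (!is.na(cutoff)) stopifnot(cutoff >= 0, cutoff <= 1)
  structure(list(signature = signature, cutoff = cutoff, mode = mode),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("classifier_model (", x$mode, " mode): ", nrow(x$signature),
      " signature loci, cutoff ",
      if (is.na(x$cutoff)) "unfitted" else sprintf("%.4f", x$cutoff),
      "\n", sep = "")
  invisible(x)
}

#' Score one sample against a classifier signature
#'
#' Score = (signature loci whose call matches the risk category) /
#' (signature loci with a non-missing call). Missing calls drop out of
#' both numerator and denominator; a sample with no called signature locus
#' is unscorable and returns `NA`.
#'
#' @param calls Named character vector of `"a1/a2"` calls (`NA` missing),
#'   names = locus ids.
#' @param model A `classifier_model`.
#' @return Fraction in \[0, 1\], or `NA_real_` if unscorable.
#' @export
score_sample <- function(calls, model) {
  sig <- model$signature
  g <- calls[sig$locus_id]
  called <- !is.na(g)
  if (!any(called)) return(NA_real_)
  hit <- if (model$mode == "validation") {
    g[called] == sig$risk_genotype[called]
  } else {
    g[called] != sig$reference_genotype[called]
  }
  sum(hit) / sum(called)
}

#' Score every sample of a genotype matrix
#'
#' @param matrix A `genotype_matrix`.
#' @param model A `classifier_model`.
#' @param min_called_frac Samples with fewer than this fraction of
#'   signature loci called are flagged low-confidence.
#' @return data.frame: `sample_id`, `label`, `score`, `n_loci_used`,
#'   `low_confidence`.
#' @export
score_cohort <- function(matrix, model, min_called_frac = 0.5) {
  sig_ids <- model$signature$locus_id
  missing_loci <- setdiff(sig_ids, matrix$locus_ids)
  if (length(missing_loci))
    stop("signature loci absent from matrix: ",
         paste(utils::head(missing_loci, 3), collapse = ", "))
  sub <- matrix$calls[, sig_ids, drop = FALSE]
  n_used <- rowSums(!is.na(sub))
  score <- vapply(seq_len(nrow(sub)), function(i) {
    score_sample(stats::setNames(sub[i, ], colnames(sub)), model)
  }, numeric(1))
  data.frame(sample_id = matrix$sample_ids,
             label = unname(matrix$labels),
             score = score,
             n_loci_used = n_used,
             low_confidence = n_used < min_called_frac * length(sig_ids),
             stringsAsFactors = FALSE)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("both cases and controls are required")
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case'/'control'")
}

#' ROC curve and AUC for risk scores
#'
#' Threshold sweep over the distinct observed scores (plus a sentinel above
#' the maximum) under the rule `score >= threshold` = at-risk. AUC is
#' computed by trapezoidal integration of the ROC step curve, which equals
#' the Mann-Whitney concordance probability with 0.5 credit for ties.
#'
#' @param scores Numeric scores (NA scores are dropped with their labels).
#' @param labels `"case"`/`"control"` per score.
#' @return Object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `optimal_cutoff`, `accuracy_at_cutoff`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  check_two_classes(labels)
  pos <- labels == "case"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  oc <- optimal_cutoff(scores, labels)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 optimal_cutoff = oc$cutoff,
                 accuracy_at_cutoff = oc$accuracy),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f; optimal cutoff %.4f (accuracy %.4f)\n",
              x$auc, x$optimal_cutoff, x$accuracy_at_cutoff))
  invisible(x)
}

#' Accuracy-optimal score cutoff
#'
#' Maximizes accuracy (TP+TN)/n over the distinct observed scores as cutoff
#' candidates under `score >= cutoff` = at-risk; accuracy ties are broken
#' toward the larger cutoff (higher specificity).
#'
#' @inheritParams roc_auc
#' @return List with `cutoff` and `accuracy`.
#' @export
optimal_cutoff <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  check_two_classes(labels)
  cand <- sort(unique(scores), decreasing = TRUE)   # larger cutoff wins ties
  pos <- labels == "case"
  acc <- vapply(cand, function(t) {
    mean((scores >= t) == pos)
  }, numeric(1))
  best <- which.max(acc)                            # first = largest cutoff
  list(cutoff = cand[best], accuracy = acc[best])
}

#' Confusion matrix, sensitivity, specificity and odds ratio at a cutoff
#'
#' At-risk = `score >= cutoff`. The classifier odds ratio is
#' `(TP/FP)/(FN/TN)`, with the Haldane-Anscombe +0.5 correction applied to
#' every cell when any cell is zero.
#'
#' @inheritParams roc_auc
#' @param cutoff Score cutoff in \[0, 1\].
#' @return List with `confusion` (named `TP`, `FP`, `FN`, `TN`),
#'   `sensitivity`, `specificity`, `accuracy`, `odds_ratio`.
#' @export
evaluate <- function(scores, labels, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- labels == "case"
  pred <- scores >= cutoff
  TP <- sum(pred & pos); FP <- sum(pred & !pos)
  FN <- sum(!pred & pos); TN <- sum(!pred & !pos)
  cells <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  or_cells <- if (any(cells == 0)) cells + 0.5 else cells
  list(confusion = cells,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       accuracy = (TP + TN) / length(scores),
       odds_ratio = (or_cells[["TP"]] / or_cells[["FP"]]) /
         (or_cells[["FN"]] / or_cells[["TN"]]))
}

#' Fit a classifier on a genotype matrix
#'
#' Screens the matrix with [select_informative_loci()], builds the
#' signature, scores the training samples and sets the accuracy-optimal
#' cutoff.
#'
#' @param matrix A `genotype_matrix`.
#' @param mode,q_cutoff,min_call_rate Passed to
#'   [select_informative_loci()].
#' @return A fitted `classifier_model` (with `training_roc` attached as an
#'   attribute).
#' @export
fit_classifier <- function(matrix, mode = c("validation", "discovery"),
                           q_cutoff = 1e-4, min_call_rate = 0.5) {
  mode <- match.arg(mode)
  stats <- select_informative_loci(matrix, mode = mode, q_cutoff = q_cutoff,
                                   min_call_rate = min_call_rate)
  model <- build_classifier(stats, mode = mode)
  sc <- score_cohort(matrix, model)
  roc <- roc_auc(sc$score, sc$label)
  model$cutoff <- roc$optimal_cutoff
  attr(model, "training_roc") <- roc
  model
}

#' Predict risk calls for a cohort
#'
#' @param matrix A `genotype_matrix`.
#' @param model A fitted `classifier_model` (cutoff set).
#' @return data.frame: `sample_id`, `label`, `score`, `call`
#'   (`"at_risk"`/`"healthy"`, `NA` if unscorable), `n_loci_used`,
#'   `low_confidence`.
#' @export
predict_risk <- function(matrix, model) {
  if (is.na(model$cutoff)) stop("model cutoff is unfitted")
  sc <- score_cohort(matrix, model)
  sc$call <- ifelse(is.na(sc$score), NA_character_,
                    ifelse(sc$score >= model$cutoff, "at_risk", "healthy"))
  sc[, c("sample_id", "label", "score", "call", "n_loci_used",
         "low_confidence")]
}

#' Write / read a classifier model as structured text
#'
#' Header lines carry `mode` and `cutoff`; the body is a tab-separated
#' table of signature loci with their risk and reference genotypes.
#'
#' @param model A `classifier_model`.
#' @param path Output path.
#' @return `path` invisibly (write) or a `classifier_model` (read).
#' @export
write_classifier <- function(model, path) {
  lines <- c("#mstrisk-classifier-1",
             paste0("#mode\t", model$mode),
             paste0("#cutoff\t", format(model$cutoff, digits = 17)),
             "locus_id\trisk_genotype\treference_genotype",
             sprintf("%s\t%s\t%s", model$signature$locus_id,
                     ifelse(is.na(model$signature$risk_genotype), ".",
                            model$signature$risk_genotype),
                     model$signature$reference_genotype))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#mstrisk-classifier-1")
    stop("not a mstrisk classifier file (version header missing)")
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(ln) != 1L) stop("missing header field: ", key)
    sub("^#[^\t]+\t", "", ln)
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = "character")
  signature <- data.frame(
    locus_id = tab$locus_id,
    risk_genotype = ifelse(tab$risk_genotype == ".", NA_character_,
                           tab$risk_genotype),
    reference_genotype = tab$reference_genotype,
    stringsAsFactors = FALSE)
  structure(list(signature = signature,
                 cutoff = as.numeric(get("cutoff")),
                 mode = get("mode")),
            class = "classifier_model")
}
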