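# Risk scoring, ROC/AUC, optimal cutoff, evaluation and cross-validation.

toy_model <- function(n_loci, mode = "validation", cutoff = NA_real_) {
  structure(list(
    signature = data.frame(
      locus_id = sprintf("L%02d", seq_len(n_loci)),
      risk_genotype = if (mode == "validation") rep("12/12", n_loci)
                      else NA_character_,
      reference_genotype = rep("13/13", n_loci),
      stringsAsFactors = FALSE),
    cutoff = cutoff, mode = mode), class = "classifier_model")
}

calls_with_hits <- function(model, n_hit, n_missing = 0) {
  n <- nrow(model$signature)
  calls <- rep("13/13", n)                   # reference genotype
  calls[seq_len(n_hit)] <- "12/12"           # risk genotype
  if (n_missing > 0) calls[(n - n_missing + 1):n] <- NA_character_
  stats::setNames(calls, model$signature$locus_id)
}

test_that("score_sample computes the fraction of risk genotypes", {
  m13 <- toy_model(13)
  # 8 of 13 risk genotypes: at-risk under the 0.61 cutoff
  expect_equal(score_sample(calls_with_hits(m13, 8), m13), 8 / 13,
               tolerance = 1e-12)
  expect_gte(score_sample(calls_with_hits(m13, 8), m13), 0.61)
  expect_lt(score_sample(calls_with_hits(m13, 7), m13), 0.61)
  expect_equal(score_sample(calls_with_hits(m13, 0), m13), 0)
  # 12 of 21: at-risk under the 0.57 cutoff
  m21 <- toy_model(21)
  expect_equal(score_sample(calls_with_hits(m21, 12), m21), 12 / 21,
               tolerance = 1e-12)
  expect_gte(score_sample(calls_with_hits(m21, 12), m21), 0.57)
  # discovery mode counts non-modal calls
  d <- toy_model(10, mode = "discovery")
  expect_equal(score_sample(calls_with_hits(d, 4), d), 0.4)
})

test_that("score_sample handles missingness and is permutation invariant", {
  m <- toy_model(13)
  # missing calls leave the denominator
  calls <- calls_with_hits(m, 4, n_missing = 3)
  expect_equal(score_sample(calls, m), 4 / 10)
  # an extra missing-call locus never changes the score
  calls2 <- c(calls, stats::setNames(NA_character_, "L99"))
  expect_equal(score_sample(calls2, m), 4 / 10)
  # permuting locus order changes nothing
  withr::with_seed(3, {
    for (k in 1:10)
      expect_equal(score_sample(sample(calls), m), 4 / 10)
  })
  # all signature loci missing -> unscorable
  none <- stats::setNames(rep(NA_character_, 13), m$signature$locus_id)
  expect_true(is.na(score_sample(none, m)))
})

test_that("roc_auc matches hand-counted concordance and handles ties", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
               c("case", "case", "control", "control"))
  expect_equal(r$auc, 1)
  r2 <- roc_auc(c(0.8, 0.4, 0.6, 0.2),
                c("case", "case", "control", "control"))
  expect_equal(r2$auc, 0.75)   # 3 concordant of 4 pairs
  r3 <- roc_auc(rep(0.5, 6), rep(c("case", "control"), 3))
  expect_equal(r3$auc, 0.5)    # all tied
  expect_error(roc_auc(c(0.1, 0.2), c("case", "case")), "both")
  # curve endpoints and monotonicity
  expect_equal(r2$tpr[1], 0); expect_equal(r2$fpr[1], 0)
  expect_equal(r2$tpr[length(r2$tpr)], 1)
  expect_true(all(diff(r2$tpr) >= 0) && all(diff(r2$fpr) >= 0))
})

test_that("roc_auc equals the pairwise-concordance oracle on random inputs", {
  withr::with_seed(19, {
    for (k in 1:200) {
      n <- sample(4:12, 1)
      labels <- c("case", "control",
                  sample(c("case", "control"), n - 2, replace = TRUE))
      scores <- round(runif(n), sample(1:2, 1))   # coarse grid forces ties
      expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC flips with labels for tie-free scores", {
  withr::with_seed(23, {
    for (k in 1:20) {
      n <- sample(4:10, 1)
      labels <- c("case", "control",
                  sample(c("case", "control"), n - 2, replace = TRUE))
      scores <- sample(seq(0.01, 0.99, by = 0.013), n)   # distinct
      flipped <- ifelse(labels == "case", "control", "case")
      expect_equal(roc_auc(scores, labels)$auc +
                     roc_auc(scores, flipped)$auc, 1, tolerance = 1e-12)
    }
  })
})

test_that("optimal_cutoff maximizes accuracy and breaks ties upward", {
  oc <- optimal_cutoff(c(0.9, 0.8, 0.2, 0.1),
                       c("case", "case", "control", "control"))
  expect_equal(oc$cutoff, 0.8)
  expect_equal(oc$accuracy, 1)
  oc2 <- optimal_cutoff(c(0.7, 0.3, 0.6, 0.2),
                        c("case", "case", "control", "control"))
  expect_equal(oc2$cutoff, 0.7)      # tie with 0.3 resolved upward
  expect_equal(oc2$accuracy, 0.75)
  oc3 <- optimal_cutoff(rep(0.4, 5), c(rep("control", 3), rep("case", 2)))
  expect_equal(oc3$accuracy, 0.4)    # all one score: majority-class accuracy
})

test_that("optimal_cutoff accuracy equals the exhaustive evaluate() maximum", {
  withr::with_seed(29, {
    for (k in 1:50) {
      n <- sample(4:15, 1)
      labels <- c("case", "control",
                  sample(c("case", "control"), n - 2, replace = TRUE))
      scores <- round(runif(n), 1)
      oc <- optimal_cutoff(scores, labels)
      accs <- vapply(unique(scores), function(t)
        evaluate(scores, labels, t)$accuracy, numeric(1))
      expect_equal(oc$accuracy, max(accs), tolerance = 1e-12)
    }
  })
})

test_that("evaluate reproduces the published confusion-matrix arithmetic", {
  # 27/30 cases and 84/89 controls correct
  scores <- c(rep(1, 27), rep(0, 3), rep(1, 5), rep(0, 84))
  labels <- c(rep("case", 30), rep("control", 89))
  ev <- evaluate(scores, labels, cutoff = 0.5)
  expect_equal(unname(ev$confusion), c(27, 5, 3, 84))
  expect_equal(ev$sensitivity, 0.90)
  expect_equal(ev$specificity, 84 / 89)
  expect_equal(round(ev$specificity, 4), 0.9438)
  expect_equal(ev$odds_ratio, (27 / 5) / (3 / 84))
  expect_equal(ev$odds_ratio, 151.2)
  # perfect classification stays finite through the Haldane correction
  ev2 <- evaluate(c(rep(1, 30), rep(0, 89)), labels, 0.5)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 1)
  expect_true(is.finite(ev2$odds_ratio))
  # cutoff 0 calls everything at-risk
  ev3 <- evaluate(runif(119), labels, 0)
  expect_equal(ev3$sensitivity, 1)
  expect_equal(ev3$specificity, 0)
})

test_that("fit/predict pipeline separates a planted cohort", {
  sim <- quick_cohort(111, n_loci = 40, n_informative = 13)
  model <- fit_classifier(sim$matrix, "validation")
  expect_equal(nrow(model$signature),
               sum(sim$manifest$loci$informative))
  pred <- predict_risk(sim$matrix, model)
  roc <- attr(model, "training_roc")
  expect_gte(roc$auc, 0.95)
  expect_true(all(pred$call[pred$score >= model$cutoff] == "at_risk"))
})

test_that("classifier model round-trips through its text serialization", {
  sim <- quick_cohort(121, n_loci = 20, n_informative = 5)
  model <- fit_classifier(sim$matrix, "validation")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classifier(model, path)
  back <- read_classifier(path)
  expect_equal(back$signature, model$signature)
  expect_equal(back$cutoff, model$cutoff)
  expect_equal(back$mode, model$mode)
  writeLines("#not-a-classifier", path)
  expect_error(read_classifier(path), "version")
})

test_that("loocv runs one fold per sample and pools held-out predictions", {
  sim <- quick_cohort(131, n_loci = 30, n_informative = 10,
                      n_cases = 12, n_controls = 20)
  cv <- loocv(sim$matrix, "validation")
  expect_equal(cv$n_folds, 32L)
  expect_equal(nrow(cv$predictions), 32L)
  expect_equal(sum(cv$confusion) + cv$n_unpredictable, 32L)
  expect_true(all(cv$per_fold$train_accuracy >= 0.5, na.rm = TRUE))
  # fixed-signature variant also runs and reports every fold
  cv2 <- loocv(sim$matrix, "validation", fixed_signature = TRUE)
  expect_equal(cv2$n_folds, 32L)
  expect_gte(cv2$sensitivity, cv$sensitivity - 0.25)
})

test_that("a perfectly separable cohort is classified without error in loocv", {
  # deterministic: all cases carry the risk genotype at every signature
  # locus, all controls the modal genotype
  n_loci <- 6
  calls <- rbind(matrix("12/12", 5, n_loci), matrix("13/13", 8, n_loci))
  dimnames(calls) <- list(c(sprintf("ca%d", 1:5), sprintf("co%d", 1:8)),
                          sprintf("L%02d", seq_len(n_loci)))
  depth <- matrix(100L, nrow(calls), n_loci, dimnames = dimnames(calls))
  labels <- stats::setNames(rep(c("case", "control"), c(5, 8)),
                            rownames(calls))
  gm <- genotype_matrix(calls, depth, labels)
  cv <- loocv(gm, "validation")
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$n_unpredictable, 0L)
})

test_that("loocv at study-default effect sizes keeps pooled metrics high", {
  sens <- spec <- numeric(0)
  for (seed in 1:5) {
    sim <- quick_cohort(6000 + seed, n_loci = 30, n_informative = 13)
    cv <- loocv(sim$matrix, "validation")
    sens <- c(sens, cv$sensitivity)
    spec <- c(spec, cv$specificity)
  }
  expect_gte(mean(sens), 0.9)
  expect_gte(mean(spec), 0.9)
})

test_that("AUC agrees with the pROC reference implementation", {
  withr::with_seed(31, {
    for (k in 1:20) {
      n <- sample(6:20, 1)
      labels <- c("case", "control",
                  sample(c("case", "control"), n - 2, replace = TRUE))
      scores <- round(runif(n), 1)
      ref <- suppressMessages(as.numeric(pROC::auc(
        pROC::roc(labels == "case", scores, direction = "<", quiet = TRUE))))
      expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
    }
  })
})
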