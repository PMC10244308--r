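test_that("the ROC AUC equals the Mann-Whitney pair-count statistic", {
  expect_equal(rocCurve(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(rocCurve(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  set.seed(101)
  for (i in 1:25) {
    inst <- randomInstance(sample(6:60, 1), tie = i %% 2 == 0)
    roc <- rocCurve(inst$scores, inst$labels)
    expect_equal(roc$auc, oracleAucPairCount(inst$scores, inst$labels))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  }
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("the Youden threshold equals exhaustive search with high-threshold ties", {
  # perfect separation: midpoint of the separating gap
  roc <- rocCurve(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  yt <- youdenThreshold(roc)
  expect_equal(yt$threshold, 0.5)
  expect_equal(yt$sensitivity + yt$specificity - 1, 1)
  # all tied: J = 0
  rocT <- rocCurve(rep(2, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(youdenThreshold(rocT)$youden, 0)
  set.seed(202)
  for (i in 1:25) {
    inst <- randomInstance(sample(6:50, 1), tie = i %% 3 == 0)
    roc <- rocCurve(inst$scores, inst$labels)
    yt <- youdenThreshold(roc)
    or <- oracleYouden(inst$scores, inst$labels)
    expect_equal(yt$threshold, or$threshold)
    expect_equal(yt$sensitivity + yt$specificity - 1, or$youden)
    # reported metrics recompute at the returned threshold
    expect_equal(yt$sensitivity, mean(inst$scores[inst$labels] > yt$threshold))
    expect_equal(yt$fpr, 1 - yt$specificity)
  }
})

test_that("bootstrap ROC replication is deterministic with percentile intervals", {
  set.seed(7)
  pos <- rnorm(200, 1); neg <- rnorm(300)
  b1 <- bootstrapRoc(pos, neg, nPerGroup = 64, nReplicates = 10, seed = 5)
  b2 <- bootstrapRoc(pos, neg, nPerGroup = 64, nReplicates = 10, seed = 5)
  expect_identical(b1$metrics, b2$metrics)
  expect_false(identical(
    b1$metrics, bootstrapRoc(pos, neg, 64, 10, seed = 6)$metrics))
  expect_equal(nrow(b1$metrics), 10)
  expect_false(any(b1$with_replacement))
  expect_true(all(b1$ci["lower", ] <= b1$ci["upper", ]))
  expect_true(all(b1$metrics$auc >= 0 & b1$metrics$auc <= 1))
  # single replicate: degenerate interval at the observed value
  b3 <- bootstrapRoc(pos, neg, nPerGroup = 32, nReplicates = 1, seed = 9)
  expect_equal(b3$ci["lower", "auc"], b3$metrics$auc[1])
  expect_equal(b3$ci["upper", "auc"], b3$metrics$auc[1])
  # small pools fall back to sampling with replacement, and say so
  b4 <- bootstrapRoc(pos[1:10], neg, nPerGroup = 64, nReplicates = 3, seed = 2)
  expect_true(b4$with_replacement["pos"])
  expect_false(b4$with_replacement["neg"])
  expect_error(bootstrapRoc(numeric(0), neg), "empty")
})

test_that("the logistic fit matches an independent likelihood maximizer", {
  set.seed(303)
  for (i in 1:5) {
    n <- 40
    score <- runif(n)
    scanner <- rbinom(n, 1, 0.3)
    eta <- -1 + 2 * score + 0.8 * scanner
    y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    if (length(unique(y)) < 2) next
    fit <- fitExamLogistic(score, y, scanner)
    ref <- oracleLogistic(y, score, scanner)
    expect_lt(max(abs(fit$coefficients - ref)), 1e-6)
    expect_true(all(fit$p_values > 0 & fit$p_values <= 1))
    # Wald p consistent with its own z statistic
    expect_equal(unname(fit$p_values["score"]),
                 unname(2 * pnorm(-abs(fit$z["score"]))))
    expect_true(all(fit$ci[, "lower"] <= fit$coefficients &
                      fit$coefficients <= fit$ci[, "upper"]))
  }
})

test_that("logistic degeneracies are flagged rather than silently fitted", {
  # label-symmetric paired design: score coefficient must vanish
  score <- rep(runif(10), 2)
  y <- c(rep(0, 10), rep(1, 10))
  fit <- fitExamLogistic(score, y, rep(0, 20))
  expect_lt(abs(fit$coefficients["score"]), 1e-8)
  # zero-variance predictor
  expect_error(fitExamLogistic(rep(0.4, 10), rep(c(0, 1), 5), rep(0, 10)),
               "degenerate predictor")
  expect_error(fitExamLogistic(runif(6), rep(1, 6), rep(0, 6)), "both outcome")
  # complete separation
  sep <- fitExamLogistic(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                         c(0, 0, 0, 1, 1, 1), rep(0, 6))
  expect_false(sep$converged)
  expect_false(sep$significant)
  expect_match(sep$diagnostic, "separation")
})

test_that("the exam-threshold sweep reproduces hand-counted confusion tables", {
  scores <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 0.95)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1, 0, 1)
  sw <- thresholdSweep(scores, labels)
  expect_equal(nrow(sw), 9)
  # at T = 0.5: positives above = scores .55,.65,.75,.85,.95 -> labels 0,1,1,0,1
  row <- sw[sw$threshold == 0.5, ]
  expect_equal(c(row$tp, row$fp, row$tn, row$fn), c(3, 2, 3, 2))
  expect_equal(row$sensitivity, 3 / 5)
  expect_equal(row$specificity, 3 / 5)
  expect_equal(row$ppv, 3 / 5)
  expect_equal(row$npv, 3 / 5)
  # extremes
  swLo <- thresholdSweep(scores, labels, thresholds = 0)
  expect_equal(swLo$sensitivity, 1)
  expect_equal(swLo$specificity, 0)
  swHi <- thresholdSweep(scores, labels, thresholds = 1)
  expect_equal(swHi$sensitivity, 0)
  expect_equal(swHi$specificity, 1)
  # exhaustive recount across all thresholds
  for (r in seq_len(nrow(sw))) {
    t <- sw$threshold[r]
    expect_equal(sw$tp[r], sum(scores > t & labels == 1))
    expect_equal(sw$fp[r], sum(scores > t & labels == 0))
    expect_equal(sw$tn[r], sum(scores <= t & labels == 0))
    expect_equal(sw$fn[r], sum(scores <= t & labels == 1))
  }
})

test_that("malignancy-stratified evaluation regroups grades correctly", {
  set.seed(11)
  scores <- runif(20)
  grades <- c(rep(1, 10), 2, 2, 2, 3, 3, 4, 4, 5, 5, 5)
  strat <- malignancyStratifiedEval(scores, grades)
  # any-lesion table equals a direct sweep with grade > 1
  expect_equal(strat$any_lesion, thresholdSweep(scores, grades > 1))
  # malignant table counts grades 1-2 as negative
  expect_equal(strat$malignant, thresholdSweep(scores, grades >= 3))
  expect_equal(strat$malignant$tp + strat$malignant$fn,
               rep(sum(grades >= 3), 9))
  # grades all >= 3: both groupings coincide
  strat2 <- malignancyStratifiedEval(scores, ifelse(grades > 1, 4, 1))
  expect_equal(strat2$any_lesion, strat2$malignant)
  # empty stratum yields NA performance cells
  strat3 <- malignancyStratifiedEval(scores[1:13], grades[1:13])  # no grade >= 3
  expect_true(all(is.na(strat3$malignant$sensitivity)))
  expect_false(any(is.na(strat3$malignant$threshold)))
})
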