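#' Empirical ROC curve
#'
#' Computes the empirical ROC over all distinct-score thresholds, with the
#' classification rule "positive iff score > t". Candidate thresholds are the
#' midpoints between adjacent distinct scores plus one threshold below the
#' minimum (everything positive) and the maximum itself (nothing positive), so
#' tied scores enter and leave the curve together; the trapezoidal AUC then
#' equals the Mann-Whitney statistic with half credit for ties.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) true class per score.
#' @return list of class `"rocResult"`: `thresholds` (decreasing), `fpr`,
#'   `tpr`, `auc`, `youden_threshold`, `sensitivity`, `specificity`,
#'   `fpr_at_threshold`, `n_pos`, `n_neg`, plus the input `scores`/`labels`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present to compute a ROC curve")
  v <- sort(unique(scores))
  cand <- if (length(v) == 1) numeric(0) else (v[-1] + v[-length(v)]) / 2
  cand <- c(v[1] - 1, cand, v[length(v)])
  cand <- sort(cand, decreasing = TRUE)          # (0,0) -> (1,1)
  tpr <- vapply(cand, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(cand, function(t) mean(neg > t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  res <- list(thresholds = cand, fpr = fpr, tpr = tpr, auc = auc,
              n_pos = length(pos), n_neg = length(neg),
              scores = scores, labels = labels)
  class(res) <- "rocResult"
  yt <- youdenThreshold(res)
  res$youden_threshold <- yt$threshold
  res$sensitivity <- yt$sensitivity
  res$specificity <- yt$specificity
  res$fpr_at_threshold <- yt$fpr
  res
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (%d pos / %d neg); Youden threshold %.4g, sens %.3f, spec %.3f\n",
              x$auc, x$n_pos, x$n_neg, x$youden_threshold, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Returns the threshold maximizing Youden's J = sensitivity + specificity - 1
#' over the curve's candidate thresholds; ties are broken toward the higher
#' (more specific) threshold. In the perfectly separated case this is the
#' midpoint of the separating gap.
#'
#' @param roc a `"rocResult"` from [rocCurve()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `fpr`,
#'   `youden` (the attained J).
#' @export
youdenThreshold <- function(roc) {
  J <- roc$tpr - roc$fpr
  best <- which(J >= max(J) - 1e-12)
  # thresholds are sorted decreasing; the first maximal index is the highest t
  i <- best[1]
  list(threshold = roc$thresholds[i], sensitivity = roc$tpr[i],
       specificity = 1 - roc$fpr[i], fpr = roc$fpr[i], youden = J[i])
}

#' Bootstrap distribution of ROC curves
#'
#' Repeats the ROC analysis on random subsamples of the patch pools: each
#' replicate draws `nPerGroup` scores from the positive pool and `nPerGroup`
#' from the negative pool (without replacement; pools smaller than
#' `nPerGroup` fall back to sampling with replacement, recorded in the
#' result), computes a ROC curve with its Youden operating point, and
#' percentile 95% confidence intervals are formed over the replicates.
#'
#' @param posScores,negScores score pools of the two classes.
#' @param nPerGroup patches drawn per cohort per replicate (default 128).
#' @param nReplicates number of replicates (default 10).
#' @param seed integer seed; the replicate draws are deterministic given it.
#' @return list of class `"bootstrapSummary"`: `replicates` (list of
#'   `"rocResult"`), `metrics` (data.frame of per-replicate auc, threshold,
#'   sensitivity, specificity, fpr), `ci` (2 x k matrix of percentile 95%
#'   bounds), `mean_youden_threshold`, `n_per_group`, `n_replicates`,
#'   `with_replacement`.
#' @export
bootstrapRoc <- function(posScores, negScores, nPerGroup = 128,
                         nReplicates = 10, seed = 1L) {
  if (length(posScores) == 0 || length(negScores) == 0)
    stop("empty score pool")
  set.seed(seed)
  withRepl <- c(pos = length(posScores) < nPerGroup,
                neg = length(negScores) < nPerGroup)
  reps <- vector("list", nReplicates)
  rows <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    ps <- posScores[sample.int(length(posScores), nPerGroup, replace = withRepl["pos"])]
    ns <- negScores[sample.int(length(negScores), nPerGroup, replace = withRepl["neg"])]
    roc <- rocCurve(c(ps, ns), c(rep(TRUE, nPerGroup), rep(FALSE, nPerGroup)))
    reps[[r]] <- roc
    rows[[r]] <- data.frame(replicate = r, auc = roc$auc,
                            threshold = roc$youden_threshold,
                            sensitivity = roc$sensitivity,
                            specificity = roc$specificity,
                            fpr = roc$fpr_at_threshold)
  }
  metrics <- do.call(rbind, rows)
  ci <- vapply(c("auc", "sensitivity", "specificity", "fpr", "threshold"),
               function(col) stats::quantile(metrics[[col]], c(0.025, 0.975),
                                             names = FALSE, type = 7),
               numeric(2))
  rownames(ci) <- c("lower", "upper")
  res <- list(replicates = reps, metrics = metrics, ci = ci,
              mean_youden_threshold = mean(metrics$threshold),
              n_per_group = nPerGroup, n_replicates = nReplicates,
              with_replacement = withRepl)
  class(res) <- "bootstrapSummary"
  res
}

#' @export
print.bootstrapSummary <- function(x, ...) {
  cat(sprintf("Bootstrap ROC: %d replicates of %d patches per cohort\n",
              x$n_replicates, x$n_per_group))
  cat(sprintf("  AUC mean %.3f, 95%% CI [%.3f, %.3f]\n", mean(x$metrics$auc),
              x$ci["lower", "auc"], x$ci["upper", "auc"]))
  cat(sprintf("  sensitivity CI [%.3f, %.3f], specificity CI [%.3f, %.3f]\n",
              x$ci["lower", "sensitivity"], x$ci["upper", "sensitivity"],
              x$ci["lower", "specificity"], x$ci["upper", "specificity"]))
  invisible(x)
}

#' Logistic regression of future lesion presence on the exam score
#'
#' Maximum-likelihood logistic fit of
#' `label ~ intercept + exam_score + scanner_indicator`, with a two-sided Wald
#' test (z = coefficient / SE against the normal reference) on the score
#' coefficient at significance level `alpha`. The scanner indicator controls
#' for the acquisition-period confound on difference-image intensity.
#' Complete or quasi-complete separation is flagged as non-convergent; the
#' coefficients are still returned but `converged` is `FALSE` and no
#' significance claim is made.
#'
#' @param examScores numeric exam-level scores in \[0, 1\].
#' @param labels future lesion presence per exam (logical or 0/1).
#' @param scanner scanner indicator per exam (e.g., any period-1 visit in the
#'   difference pair).
#' @param alpha Wald significance level (default 0.05).
#' @return list of class `"logisticFit"`: `coefficients`, `se`, `z`,
#'   `p_values`, `ci` (Wald 95%), `converged`, `significant`, `alpha`,
#'   `diagnostic`.
#' @export
fitExamLogistic <- function(examScores, labels, scanner, alpha = 0.05) {
  labels <- as.numeric(as.logical(labels))
  scanner <- as.numeric(scanner)
  if (anyNA(examScores) || anyNA(labels) || anyNA(scanner))
    stop("missing values are not allowed")
  if (length(unique(labels)) < 2) stop("both outcome classes must be present")
  if (stats::var(examScores) == 0)
    stop("degenerate predictor: exam score has zero variance")
  dat <- data.frame(y = labels, score = examScores, scanner = scanner)
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ score + scanner, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  coefs <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  z <- sm[, "z value"]
  p <- sm[, "Pr(>|z|)"]
  converged <- fit$converged && !sepWarn && all(abs(coefs) < 50)
  ci <- cbind(lower = coefs - stats::qnorm(0.975) * se,
              upper = coefs + stats::qnorm(0.975) * se)
  res <- list(coefficients = coefs, se = se, z = z, p_values = p, ci = ci,
              converged = converged,
              significant = converged && p["score"] < alpha,
              alpha = alpha,
              diagnostic = if (converged) NA_character_ else
                "possible complete or quasi-complete separation; coefficients unreliable")
  class(res) <- "logisticFit"
  res
}

#' @export
print.logisticFit <- function(x, ...) {
  cat("Logistic fit: label ~ score + scanner\n")
  print(data.frame(coef = x$coefficients, se = x$se, z = x$z, p = x$p_values))
  if (!x$converged) cat("  WARNING:", x$diagnostic, "\n")
  else cat(sprintf("  score coefficient %ssignificant at alpha = %.2f\n",
                   if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Performance sweep over examination-level thresholds
#'
#' For each threshold T_exam an exam is called positive iff its score is
#' strictly greater than T_exam; sensitivity, specificity, PPV, NPV and the
#' confusion counts are tabulated.
#'
#' @param examScores numeric exam scores.
#' @param labels true exam labels (logical or 0/1).
#' @param thresholds candidate thresholds (default 0.1 to 0.9 in steps of
#'   0.1).
#' @return `data.frame` with one row per threshold: `threshold`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
thresholdSweep <- function(examScores, labels,
                           thresholds = seq(0.1, 0.9, by = 0.1)) {
  labels <- as.logical(labels)
  rows <- lapply(thresholds, function(t) {
    call <- examScores > t
    tp <- sum(call & labels); fp <- sum(call & !labels)
    tn <- sum(!call & !labels); fn <- sum(!call & labels)
    sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
    data.frame(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = sdiv(tp, tp + fn), specificity = sdiv(tn, tn + fp),
               ppv = sdiv(tp, tp + fp), npv = sdiv(tn, tn + fn))
  })
  do.call(rbind, rows)
}

#' Exam-level evaluation stratified by lesion malignancy grade
#'
#' Recomputes the threshold sweep under two groupings of the final-visit
#' grade: the standard grouping (positive iff grade > 1, i.e., any lesion)
#' and the malignancy-weighted grouping (positive iff grade in 3-5, grades 1-2
#' counted as negative). A grouping with an empty class yields a table of
#' `NA` performance cells.
#'
#' @param examScores numeric exam scores.
#' @param grades final grade associated with each exam (1 for exams of
#'   negative-cohort subjects).
#' @param thresholds thresholds for the sweep.
#' @return list with `any_lesion` and `malignant` sweep tables.
#' @export
malignancyStratifiedEval <- function(examScores, grades,
                                     thresholds = seq(0.1, 0.9, by = 0.1)) {
  sweepOrNA <- function(lab) {
    if (length(unique(lab)) < 2) {
      out <- thresholdSweep(examScores, rep(c(TRUE, FALSE), length.out = length(examScores)),
                            thresholds)
      out[, setdiff(names(out), "threshold")] <- NA
      return(out)
    }
    thresholdSweep(examScores, lab, thresholds)
  }
  list(any_lesion = sweepOrNA(grades > 1),
       malignant = sweepOrNA(grades >= 3))
}
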