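#' Assemble a full pipeline run configuration
#'
#' Bundles the cohort generator settings with the preprocessing, model and
#' evaluation parameters of a reproducible end-to-end run. Defaults follow the
#' analysis design the package implements: 64-pixel patches, a background
#' limit of 50 pixels, sliding-window stride 16, bootstrap ROCs from 128
#' patches per cohort repeated 10 times, Wald tests at alpha = 0.05 and an
#' exam-threshold sweep from 0.1 to 0.9.
#'
#' @param cohort a [CohortConfig-class].
#' @param patchSide patch/window side in pixels.
#' @param stride sliding-window stride in voxels.
#' @param backgroundLimit maximum background pixels tolerated per patch.
#' @param register register follow-up visits to the first visit before
#'   differencing.
#' @param registrationFloor minimum acceptable registration NCC.
#' @param segmentation `"passthrough"` (use generator masks; synthetic mode
#'   default) or `"otsu"` (automated segmentation).
#' @param patchesPerDiff normal training/evaluation patches sampled per
#'   difference volume.
#' @param lesionPatchesPerSubject lesion-location patches retained per
#'   positive subject.
#' @param gan a [ganConfig()] list.
#' @param nPerGroup,nReplicates bootstrap ROC design (128 and 10).
#' @param examThresholds exam-level threshold grid.
#' @param alpha Wald significance level.
#' @param examsPerSubject `"all"` consecutive grade-1 pairs per subject or
#'   only the `"last"` one.
#' @param seed global run seed; all stage seeds derive from it.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(cohort = cohortConfig(),
                      patchSide = 64, stride = 16, backgroundLimit = 50,
                      register = TRUE, registrationFloor = 0.85,
                      segmentation = c("passthrough", "otsu"),
                      patchesPerDiff = 60, lesionPatchesPerSubject = 30,
                      gan = ganConfig(), nPerGroup = 128, nReplicates = 10,
                      examThresholds = seq(0.1, 0.9, by = 0.1), alpha = 0.05,
                      examsPerSubject = c("all", "last"), seed = 1L) {
  structure(list(cohort = cohort, patchSide = patchSide, stride = stride,
                 backgroundLimit = backgroundLimit, register = register,
                 registrationFloor = registrationFloor,
                 segmentation = match.arg(segmentation),
                 patchesPerDiff = patchesPerDiff,
                 lesionPatchesPerSubject = lesionPatchesPerSubject,
                 gan = gan, nPerGroup = nPerGroup, nReplicates = nReplicates,
                 examThresholds = examThresholds, alpha = alpha,
                 examsPerSubject = match.arg(examsPerSubject), seed = seed),
            class = "runConfig")
}

#' Validate a run configuration
#'
#' Checks every invariant of the configuration and returns all violations,
#' not only the first; an empty character vector means the configuration is
#' valid.
#'
#' @param config a [runConfig()] list.
#' @return character vector of violations (empty if valid).
#' @export
validateConfig <- function(config) {
  msgs <- character(0)
  msgs <- c(msgs, cohortConfigViolations(config$cohort))
  shape <- config$cohort@volumeShape
  if (config$patchSide < 2) msgs <- c(msgs, "patchSide: must be at least 2")
  if (length(shape) == 3 && (config$patchSide > shape[2] || config$patchSide > shape[3]))
    msgs <- c(msgs, sprintf("patchSide: %d exceeds in-plane volume extent %dx%d",
                            config$patchSide, shape[2], shape[3]))
  if (config$stride < 1) msgs <- c(msgs, "stride: must be at least 1")
  if (config$backgroundLimit < 0) msgs <- c(msgs, "backgroundLimit: must be non-negative")
  if (config$registrationFloor < -1 || config$registrationFloor > 1)
    msgs <- c(msgs, "registrationFloor: must be a correlation in [-1, 1]")
  if (config$patchesPerDiff < 1) msgs <- c(msgs, "patchesPerDiff: must be positive")
  if (config$lesionPatchesPerSubject < 1)
    msgs <- c(msgs, "lesionPatchesPerSubject: must be positive")
  if (config$nPerGroup < 1) msgs <- c(msgs, "nPerGroup: must be positive")
  if (config$nReplicates < 1) msgs <- c(msgs, "nReplicates: must be positive")
  if (any(config$examThresholds <= 0 | config$examThresholds >= 1))
    msgs <- c(msgs, "examThresholds: must lie strictly between 0 and 1")
  if (config$alpha <= 0 || config$alpha >= 1)
    msgs <- c(msgs, "alpha: must lie strictly between 0 and 1")
  if (config$gan$batchSize < 1) msgs <- c(msgs, "gan$batchSize: must be positive")
  msgs
}

runConfigAsList <- function(config) {
  out <- unclass(config)
  out$cohort <- cohortConfigAsList(config$cohort)
  out$gan <- unclass(config$gan)
  out
}

## Preprocess one subject: segmentation, registration to visit 1, consecutive
## grade-1 differences. Returns list(series=, diffs=, excluded=, reason=).
preprocessSubject <- function(series, config) {
  visits <- series@visits
  for (v in seq_along(visits)) {
    seg <- if (config$segmentation == "passthrough")
      segmentBreast(visits[[v]]$volume, passthroughMask = visits[[v]]$mask)
    else segmentBreast(visits[[v]]$volume)
    if (seg$excluded)
      return(list(series = series, diffs = list(), excluded = TRUE,
                  reason = seg$reason))
    visits[[v]]$mask <- seg$mask
  }
  if (config$register && length(visits) > 1) {
    fixed <- visits[[1]]
    for (v in 2:length(visits)) {
      reg <- registerFollowup(visits[[v]]$volume, fixed$volume,
                              visits[[v]]$mask, fixed$mask,
                              qualityFloor = config$registrationFloor)
      if (reg$excluded)
        return(list(series = series, diffs = list(), excluded = TRUE,
                    reason = reg$reason))
      visits[[v]]$volume <- reg$volume
      visits[[v]]$mask <- reg$mask
    }
  }
  series@visits <- visits
  list(series = series, diffs = subjectDifferences(series),
       excluded = FALSE, reason = NA_character_)
}

collectNormalPatches <- function(prep, config, seedTag) {
  sets <- list()
  for (dv in prep$diffs) {
    ps <- extractRandomPatches(dv, n = config$patchesPerDiff,
                               p = config$patchSide,
                               seed = deriveSeed(config$seed, seedTag,
                                                 dv@subjectId, dv@visitPair),
                               backgroundLimit = config$backgroundLimit)
    sets[[length(sets) + 1]] <- ps
  }
  sets
}

lastGradeOnePair <- function(diffs) {
  if (length(diffs) == 0) return(NULL)
  diffs[[length(diffs)]]
}

## Exam-level rows (score, label, scanner indicator, grade) for one
## preprocessed subject. The last consecutive grade-1 difference of a positive
## subject carries label TRUE (a lesion is confirmed at the following visit);
## all other exams are label FALSE.
subjectExamRows <- function(p, cohort, finalGrade, model, patchThreshold, config) {
  diffs <- p$diffs
  if (config$examsPerSubject == "last") diffs <- utils::tail(diffs, 1)
  lastPair <- lastGradeOnePair(p$diffs)@visitPair
  rows <- list()
  for (dv in diffs) {
    map <- slidingWindowMap(dv, model, stride = config$stride)
    calls <- classifyVoxels(map, patchThreshold)
    es <- examLevelScore(calls, map, patchThreshold, scannerPair = dv@scannerPair)
    lab <- cohort == "positive" && identical(dv@visitPair, lastPair)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = p$series@subjectId,
      visit_i = dv@visitPair[1], visit_j = dv@visitPair[2],
      score = es@score, n_voxels = es@nVoxels,
      patch_threshold = patchThreshold,
      scanner_period1 = any(dv@scannerPair == 1),
      label = lab,
      grade = if (lab) finalGrade else 1)
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes generate, preprocess, train, score and evaluate
#' as one reproducible run: synthetic cohort generation to disk, segmentation
#' and registration, difference volumes of consecutive grade-1 visits, patch
#' extraction with the background-exclusion rule, WGAN + encoder training on
#' normal training patches, patch-level bootstrap ROC evaluation (validation
#' Youden thresholds set the deployed patch threshold), sliding-window exam
#' scores with logistic-regression evaluation, the exam-threshold sweep, the
#' malignancy-stratified tables and the lesion-level detection calls. Every
#' subject exclusion is recorded with a reason code; all artifacts and a JSON
#' report (with a content hash) are written under `outDir`.
#'
#' @param config a [runConfig()] list.
#' @param outDir run directory to create.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the report, invisibly (a list; also at `outDir/report.json`).
#' @export
runPipeline <- function(config, outDir, overwrite = FALSE) {
  viol <- validateConfig(config)
  if (length(viol) > 0)
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  if (dir.exists(outDir) && length(list.files(outDir)) > 0 && !overwrite)
    stop("output directory exists and is non-empty; pass overwrite = TRUE")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  exclusions <- list()
  note <- function(subject, stage, reason) {
    exclusions[[length(exclusions) + 1]] <<- list(subject_id = subject,
                                                  stage = stage, reason = reason)
  }

  ## stage 1: generate
  cohortDir <- file.path(outDir, "cohort")
  cfg <- config$cohort
  cfg@seed <- deriveSeed(config$seed, "cohort")
  manifest <- generateCohort(cfg, cohortDir, overwrite = TRUE)
  yaml::write_yaml(runConfigAsList(config), file.path(outDir, "run_config.yaml"))

  ## stage 2: preprocess
  subjects <- unique(manifest$subject_id)
  prep <- list()
  for (sid in subjects) {
    series <- loadSubjectSeries(manifest, sid, cohortDir)
    pr <- preprocessSubject(series, config)
    if (pr$excluded) note(sid, "preprocess", pr$reason)
    prep[[sid]] <- pr
  }
  meta <- manifest[!duplicated(manifest$subject_id),
                   c("subject_id", "cohort", "split")]
  finalGrade <- vapply(subjects, function(sid) {
    g <- manifest$grade[manifest$subject_id == sid]
    g[length(g)]
  }, numeric(1))
  names(finalGrade) <- subjects
  usable <- vapply(prep, function(p) !p$excluded && length(p$diffs) > 0, logical(1))

  splitOf <- stats::setNames(meta$split, meta$subject_id)
  cohortOf <- stats::setNames(meta$cohort, meta$subject_id)

  ## stage 3: patches + normalization statistics
  trainSets <- list()
  for (sid in subjects[usable[subjects] & splitOf[subjects] == "train" &
                       cohortOf[subjects] == "negative"]) {
    sets <- collectNormalPatches(prep[[sid]], config, "trainpatch")
    for (ps in sets) {
      if (length(ps@reason) > 0) note(sid, "patch_extraction", ps@reason)
      else trainSets[[length(trainSets) + 1]] <- ps
    }
  }
  if (length(trainSets) == 0) stop("stage patches: no usable training subjects")
  stats <- patchNormStats(trainSets)
  trainX <- do.call(rbind, lapply(trainSets, patchMatrix))
  trainX <- normalizePatch(trainX, stats)

  ## stage 4: train
  gan <- trainWGAN(trainX, config$gan, seed = deriveSeed(config$seed, "wgan"))
  enc <- trainEncoder(trainX, gan$G, gan$D, config$gan,
                      seed = deriveSeed(config$seed, "encoder"))
  model <- anomalyModel(gan$G, gan$D, enc$E, patchSide = config$patchSide,
                        normStats = stats, k = config$gan$k,
                        trainingConfig = c(unclass(config$gan),
                                           list(seed = config$seed)),
                        trainingLog = merge(gan$log, enc$log, by = "step",
                                            all = TRUE))
  saveAnomalyModel(model, file.path(outDir, "model.rds"))

  ## stage 5: patch-level scores per evaluation split
  scoreRows <- list()
  scorePool <- function(split) {
    normal <- numeric(0); lesion <- numeric(0)
    lesionBySubject <- list()
    keep <- function(sid, label, L) {
      scoreRows[[length(scoreRows) + 1]] <<- data.frame(
        split = split, subject_id = sid, label = label, L = L)
    }
    for (sid in subjects[usable[subjects] & splitOf[subjects] == split]) {
      p <- prep[[sid]]
      if (cohortOf[sid] == "negative") {
        for (ps in collectNormalPatches(p, config, paste0(split, "patch"))) {
          if (length(ps@reason) > 0) { note(sid, "patch_extraction", ps@reason); next }
          sc <- anomalyScore(normalizePatch(patchMatrix(ps), stats), model)
          normal <- c(normal, sc$L)
          keep(sid, "normal", sc$L)
        }
      } else {
        dv <- lastGradeOnePair(p$diffs)
        if (is.null(dv)) next
        ps <- extractLesionPatches(dv, p$series@lesionMask, p = config$patchSide,
                                   nPerLesion = config$lesionPatchesPerSubject,
                                   seed = deriveSeed(config$seed, "lesionpatch", sid),
                                   backgroundLimit = config$backgroundLimit)
        if (length(ps@reason) > 0) { note(sid, "patch_extraction", ps@reason); next }
        sc <- anomalyScore(normalizePatch(patchMatrix(ps), stats), model)
        lesion <- c(lesion, sc$L)
        lesionBySubject[[sid]] <- sc$L
        keep(sid, "future_lesion", sc$L)
      }
    }
    list(normal = normal, lesion = lesion, lesionBySubject = lesionBySubject)
  }
  valPool <- scorePool("validation")
  testPool <- scorePool("test")
  utils::write.csv(do.call(rbind, scoreRows),
                   file.path(outDir, "patch_scores.csv"), row.names = FALSE)
  if (length(valPool$lesion) == 0 || length(valPool$normal) == 0)
    stop("stage score: validation pools are empty")
  if (length(testPool$lesion) == 0 || length(testPool$normal) == 0)
    stop("stage score: test pools are empty")

  valBoot <- bootstrapRoc(valPool$lesion, valPool$normal,
                          nPerGroup = config$nPerGroup,
                          nReplicates = config$nReplicates,
                          seed = deriveSeed(config$seed, "valboot"))
  patchThreshold <- valBoot$mean_youden_threshold
  testBoot <- bootstrapRoc(testPool$lesion, testPool$normal,
                           nPerGroup = config$nPerGroup,
                           nReplicates = config$nReplicates,
                           seed = deriveSeed(config$seed, "testboot"))
  utils::write.csv(testBoot$metrics, file.path(outDir, "roc_replicates.csv"),
                   row.names = FALSE)

  detection <- lapply(names(testPool$lesionBySubject), function(sid) {
    det <- lesionLevelDetection(testPool$lesionBySubject[[sid]], patchThreshold)
    data.frame(subject_id = sid, fraction = det$fraction, detected = det$detected)
  })
  detection <- if (length(detection) > 0) do.call(rbind, detection) else
    data.frame(subject_id = character(0), fraction = numeric(0),
               detected = logical(0))
  utils::write.csv(detection, file.path(outDir, "lesion_detection.csv"),
                   row.names = FALSE)

  ## stage 6: exam-level evaluation on validation + test subjects
  examRows <- list()
  for (sid in subjects[usable[subjects] & splitOf[subjects] %in% c("validation", "test")]) {
    rows <- subjectExamRows(prep[[sid]], cohortOf[sid], finalGrade[sid],
                            model, patchThreshold, config)
    rows$split <- splitOf[sid]
    examRows[[length(examRows) + 1]] <- rows
  }
  exams <- do.call(rbind, examRows)
  utils::write.csv(exams, file.path(outDir, "exam_scores.csv"), row.names = FALSE)

  logi <- fitExamLogistic(exams$score, exams$label, exams$scanner_period1,
                          alpha = config$alpha)
  sweep <- thresholdSweep(exams$score, exams$label, config$examThresholds)
  utils::write.csv(sweep, file.path(outDir, "threshold_sweep.csv"), row.names = FALSE)
  strat <- malignancyStratifiedEval(exams$score, exams$grade, config$examThresholds)
  utils::write.csv(strat$malignant, file.path(outDir, "threshold_sweep_malignant.csv"),
                   row.names = FALSE)

  writeLines(vapply(exclusions, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
    file.path(outDir, "exclusions.jsonl"))

  report <- list(
    config_hash = md5OfObject(runConfigAsList(config)),
    seed = config$seed,
    n_subjects = length(subjects),
    n_excluded = sum(!usable),
    exclusion_reasons = table(vapply(exclusions, `[[`, character(1), "reason")),
    n_training_patches = nrow(trainX),
    norm_stats = stats[c("lower", "upper")],
    patch_threshold = patchThreshold,
    validation = list(auc_mean = mean(valBoot$metrics$auc),
                      auc_ci = as.numeric(valBoot$ci[, "auc"])),
    test = list(auc_mean = mean(testBoot$metrics$auc),
                auc_ci = as.numeric(testBoot$ci[, "auc"]),
                sensitivity_mean = mean(testBoot$metrics$sensitivity),
                sensitivity_ci = as.numeric(testBoot$ci[, "sensitivity"]),
                specificity_mean = mean(testBoot$metrics$specificity),
                specificity_ci = as.numeric(testBoot$ci[, "specificity"]),
                fpr_ci = as.numeric(testBoot$ci[, "fpr"]),
                n_pos_pool = length(testPool$lesion),
                n_neg_pool = length(testPool$normal)),
    lesion_detection = list(n_lesions = nrow(detection),
                            n_detected = sum(detection$detected),
                            fractions = detection$fraction),
    exam = list(n_exams = nrow(exams),
                n_positive = sum(exams$label),
                mean_score_positive = mean(exams$score[exams$label]),
                mean_score_negative = mean(exams$score[!exams$label]),
                coefficients = as.list(logi$coefficients),
                p_values = as.list(logi$p_values),
                score_ci = as.numeric(logi$ci["score", ]),
                converged = logi$converged,
                significant = logi$significant),
    threshold_sweep = sweep)
  report$exclusion_reasons <- as.list(report$exclusion_reasons)
  report$report_hash <- md5OfObject(report)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(outDir, "report.json"))
  invisible(report)
}

#' Exam-level scores for an in-memory synthetic cohort
#'
#' Generates a cohort in memory (no disk artifacts), preprocesses every
#' subject and returns the examination-level score table scored against an
#' already-trained model. This is the building block for calibration studies
#' that need many simulated cohorts, e.g. estimating the type-I error of the
#' exam-level Wald test under a null configuration.
#'
#' @param cohortCfg a [CohortConfig-class]; its `seed` drives all subjects.
#' @param model a trained [AnomalyModel-class].
#' @param patchThreshold deployed patch threshold for voxel classification.
#' @param stride sliding-window stride.
#' @param examsPerSubject `"last"` or `"all"` consecutive grade-1 pairs.
#' @param register run registration before differencing (defaults off: the
#'   generator's volumes share a grid, and calibration studies favor speed).
#' @return `data.frame` with one row per exam: `subject_id`, `visit_i`,
#'   `visit_j`, `score`, `n_voxels`, `patch_threshold`, `scanner_period1`,
#'   `label`, `grade`.
#' @export
simulateExamScores <- function(cohortCfg, model, patchThreshold,
                               stride = 16, examsPerSubject = "last",
                               register = FALSE) {
  cfgLite <- list(segmentation = "passthrough", register = register,
                  registrationFloor = 0.85, stride = stride,
                  examsPerSubject = examsPerSubject)
  ids <- c(sprintf("neg%03d", seq_len(cohortCfg@nNegative)),
           sprintf("pos%03d", seq_len(cohortCfg@nPositive)))
  cohorts <- c(rep("negative", cohortCfg@nNegative),
               rep("positive", cohortCfg@nPositive))
  rows <- list()
  for (s in seq_along(ids)) {
    series <- generateSubject(cohortCfg, cohorts[s],
                              subjectSeed = deriveSeed(cohortCfg@seed, "subject", ids[s]),
                              subjectId = ids[s])
    pr <- preprocessSubject(series, cfgLite)
    if (pr$excluded || length(pr$diffs) == 0) next
    grades <- vapply(series@visits, `[[`, numeric(1), "grade")
    rows[[length(rows) + 1]] <- subjectExamRows(pr, cohorts[s],
                                                grades[length(grades)],
                                                model, patchThreshold, cfgLite)
  }
  do.call(rbind, rows)
}

#' Desk-scale demonstration run configuration
#'
#' The calibrated small-scale study conditions used throughout the package's
#' examples and validation: a 22 + 10 subject cohort on a 2 x 40 x 40 grid
#' with 16-pixel patches, a precursor contrast of 0.5 (ten times the noise
#' level), a period-1 scanner-shift probability of 0.3, and a compact
#' adversarial model (latent dimension 16, width 64) trained for 150 generator
#' steps. The full analysis completes in minutes on one CPU while preserving
#' every stage of the method at realistic effect sizes.
#'
#' @param seed global run seed.
#' @return a [runConfig()] list.
#' @export
demoRunConfig <- function(seed = 1L) {
  runConfig(
    cohort = cohortConfig(nNegative = 22, nPositive = 10, nVisits = 3,
                          volumeShape = c(2, 40, 40), textureCorr = 3,
                          deformAmp = 0.6, lesionRadiusVox = 3,
                          precursorContrast = 0.5, lesionContrast = 1.0,
                          scannerShiftProb = 0.3, seed = seed),
    patchSide = 16, stride = 8, registrationFloor = 0.8,
    patchesPerDiff = 40, lesionPatchesPerSubject = 25,
    gan = ganConfig(latentDim = 16, hidden = 64, batchSize = 64,
                    ganSteps = 150, criticSteps = 5, encoderSteps = 300,
                    lr = 1e-3),
    seed = seed)
}
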