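#' @include network.R evaluate.R phantom.R
NULL

#' Desk-scale experiment configuration
#'
#' The package's reference configuration for CPU-scale end-to-end runs:
#' 64 x 64 x 44 phantoms at 1.5 x 1.5 x 2.0 mm resampled to 1.5 mm
#' isotropic, a depth-6 dual-pathway network (filters 8-8-12-12, hidden
#' 16, patch 17^3 / context 11^3, output 9^3), and a compressed training
#' schedule (10 epochs x 5 sub-epochs x 8 batches of 10, learning rate
#' 0.001 halved over the last five epochs). One training takes on the
#' order of 1-2 minutes on a single CPU. The published full-scale
#' settings remain available through \code{\link{experimentConfig}}.
#'
#' @param seed global experiment seed.
#' @param ... overrides passed on to \code{\link{experimentConfig}}.
#' @return an \code{ExperimentConfig}.
#' @export
deskExperimentConfig <- function(seed = 1L, ...) {
  experimentConfig(
    nTrainA = 4L, nTrainB = 4L, nTestA = 4L, nTestB = 4L,
    phantom = PhantomSpec(gridShape = c(64L, 64L, 44L),
                          spacingMm = c(1.5, 1.5, 2.0)),
    preprocess = preprocessConfig(targetSpacingMm = 1.5,
                                  maxMetricPoints = 8000L),
    network = networkConfig(convFilters = c(8, 8, 12, 12),
                            hiddenFilters = 16),
    training = trainingConfig(nEpochs = 10L, subepochsPerEpoch = 5L,
                              batchesPerSubepoch = 8L,
                              lrHalvingEpochs = c(6, 7, 8, 9, 10),
                              initialLr = 0.001),
    seed = seed, ...)
}

#' Channels of a feature set
#'
#' The three input-feature experiments: CTA alone, CTA plus the
#' hemispheric comparison channel, and those two plus NCCT.
#'
#' @param featureSet one of \code{"cta"}, \code{"cta+flip"},
#'   \code{"cta+flip+ncct"}.
#' @return character vector of channel names.
#' @export
featureSetChannels <- function(featureSet) {
  switch(featureSet,
         "cta" = "cta",
         "cta+flip" = c("cta", "flip"),
         "cta+flip+ncct" = c("cta", "flip", "ncct"),
         stop("unknown feature set: ", featureSet))
}

#' Create an ExperimentConfig
#'
#' Describes one end-to-end experiment: cohort sizes and train/test split,
#' phantom parameters and randomization ranges, preprocessing, network and
#' training settings, the input feature set, and the global seed from
#' which all stage seeds are derived. The default is the desk-scale
#' smoke cohort (4+4 train, 4+4 test) with a small dual-pathway network;
#' the full-scale 15+15/15+15 design is reachable through the size
#' arguments.
#'
#' @param nTrainA,nTrainB,nTestA,nTestB cases per group and split.
#' @param phantom base \code{\link{PhantomSpec}}.
#' @param ranges cohort randomization ranges (see
#'   \code{\link{generateCohort}}).
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param network a \code{\link{networkConfig}}; its channel count is
#'   overridden per feature set.
#' @param training a \code{\link{trainingConfig}}.
#' @param featureSet see \code{\link{featureSetChannels}}.
#' @param outputDir directory for report files, or \code{NULL} to skip
#'   writing.
#' @param seed global experiment seed.
#' @return object of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(nTrainA = 4L, nTrainB = 4L, nTestA = 4L,
                             nTestB = 4L, phantom = PhantomSpec(),
                             ranges = list(),
                             preprocess = preprocessConfig(),
                             network = networkConfig(),
                             training = trainingConfig(),
                             featureSet = "cta+flip",
                             outputDir = NULL, seed = 1L) {
  featureSetChannels(featureSet)  # validates
  structure(list(nTrainA = as.integer(nTrainA), nTrainB = as.integer(nTrainB),
                 nTestA = as.integer(nTestA), nTestB = as.integer(nTestB),
                 phantom = phantom, ranges = ranges, preprocess = preprocess,
                 network = network, training = training,
                 featureSet = featureSet, outputDir = outputDir,
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

# Generate and preprocess the cohort, and split case ids into train/test
# (random partition, seed-derived).
.buildCohort <- function(config) {
  cohortSeed <- .caseSeed(config$seed, 101L)
  splitSeed <- .caseSeed(config$seed, 202L)
  nA <- config$nTrainA + config$nTestA
  nB <- config$nTrainB + config$nTestB
  cases <- generateCohort(nA, nB, config$phantom, cohortSeed, config$ranges)
  ids <- vapply(cases, function(x) x@id, "")
  groups <- vapply(cases, function(x) x@group, "")
  split <- .withSeed(splitSeed, {
    trainA <- sample(ids[groups == "A"], config$nTrainA)
    trainB <- sample(ids[groups == "B"], config$nTrainB)
    list(train = c(trainA, trainB),
         test = setdiff(ids, c(trainA, trainB)))
  })
  pp <- lapply(cases, preprocessCase, config = config$preprocess)
  names(pp) <- ids
  list(cases = cases, pp = pp, split = split)
}

# Train one network on the training split and evaluate it on the test
# split; the per-stage seeds derive from trainSeed.
.fitAndEvaluate <- function(pp, split, config, channels, trainSeed) {
  netCfg <- config$network
  netCfg <- networkConfig(nInputChannels = length(channels),
                          convFilters = netCfg$convFilters,
                          hiddenFilters = netCfg$hiddenFilters,
                          outputSize = netCfg$outputSize,
                          downsampleFactor = netCfg$downsampleFactor,
                          kernelSize = netCfg$kernelSize)
  trainCfg <- config$training
  trainCfg$seed <- .caseSeed(trainSeed, 7L)
  model <- buildNetwork(netCfg, seed = .caseSeed(trainSeed, 11L))
  model <- trainNetwork(model, pp[split$train], trainCfg, channels)
  perCase <- list()
  scoresPool <- list(); truthPool <- list()
  predReg <- list(); truthReg <- list()
  for (id in split$test) {
    cs <- pp[[id]]
    prob <- predictVolume(model, cs[channels], cs$brainMask)
    ev <- evaluateCase(prob, cs$lesionMask, cs$brainMask, cs$atlas)
    inm <- cs$brainMask@values == 1
    scoresPool[[id]] <- prob@values[inm]
    truthPool[[id]] <- cs$lesionMask@values[inm] == 1
    predReg[[id]] <- ev$predRegions
    truthReg[[id]] <- ev$truthRegions
    perCase[[id]] <- data.frame(
      id = id, group = cs$group,
      sensitivity = as.numeric(ev$voxel$sensitivity),
      specificity = as.numeric(ev$voxel$specificity),
      dsc = ev$voxel$dsc, aspects_pred = ev$aspectsPred,
      aspects_truth = ev$aspectsTruth, volume_cm3 = ev$volumeCm3,
      truth_volume_cm3 = largestComponentVolume(cs$lesionMask))
  }
  perCase <- do.call(rbind, perCase)
  s <- unlist(scoresPool, use.names = FALSE)
  g <- unlist(truthPool, use.names = FALSE)
  pred05 <- s >= 0.5
  tp <- sum(pred05 & g); fp <- sum(pred05 & !g)
  fn <- sum(!pred05 & g); tn <- sum(!pred05 & !g)
  pm <- ProbabilityMap(array(s, c(length(s), 1, 1)))
  tm <- BinaryMask(array(as.numeric(g), c(length(g), 1, 1)))
  allm <- BinaryMask(array(1, c(length(g), 1, 1)))
  auc <- if (any(g) && !all(g)) rocCurve(pm, tm, allm)$auc else NA_real_
  groupsTest <- vapply(split$test, function(id) pp[[id]]$group, "")
  aIds <- split$test[groupsTest == "A"]
  bIds <- split$test[groupsTest == "B"]
  contA <- regionContingency(predReg[aIds], truthReg[aIds])
  fpB <- sum(unlist(predReg[bIds]))
  tnB <- 20 * length(bIds) - fpB
  regA <- metricsFromContingency(contA)
  comb <- combinedDsc(contA, fpB)
  specAll <- (contA@tn + tnB) / (contA@tn + contA@fp + tnB + fpB)
  list(model = model, perCase = perCase, specificityAllRegions = specAll,
       voxel = list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
                    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
                    dsc = if (2 * tp + fp + fn > 0)
                      2 * tp / (2 * tp + fp + fn) else NaN,
                    auc = auc),
       contingencyA = contA, fpGroupB = fpB, region = regA,
       combinedDsc = comb$dsc,
       predRegions = predReg, truthRegions = truthReg)
}

#' Run one end-to-end experiment
#'
#' Generates the phantom cohort, preprocesses every case, trains the
#' network for the configured feature set on the training split only,
#' predicts the test split, and evaluates at both levels (voxel-wise and
#' ASPECTS regions). Identical config and seed reproduce identical
#' reports. When \code{outputDir} is set, writes
#' \code{per_case_metrics.tsv}, \code{summary.tsv},
#' \code{training_log.txt} and \code{preprocess_log.txt}.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @return report bundle: \code{split}, \code{model}, \code{perCase}
#'   data.frame, pooled \code{voxel} metrics (sensitivity, specificity,
#'   DSC at 0.5 and ROC AUC), region-level \code{contingencyA},
#'   \code{fpGroupB}, \code{region} metrics and \code{combinedDsc}.
#' @export
runExperiment <- function(config = experimentConfig()) {
  channels <- featureSetChannels(config$featureSet)
  stage <- "cohort generation"
  bundle <- tryCatch({
    t0 <- Sys.time()
    co <- .buildCohort(config)
    t1 <- Sys.time()
    stage <- "training/evaluation"
    fit <- .fitAndEvaluate(co$pp, co$split, config, channels,
                           trainSeed = .caseSeed(config$seed, 303L))
    t2 <- Sys.time()
    timings <- sprintf(
      "stage=%s seconds=%.1f",
      c("generate+preprocess", "train+evaluate"),
      c(as.numeric(t1 - t0, units = "secs"),
        as.numeric(t2 - t1, units = "secs")))
    c(fit, list(split = co$split, featureSet = config$featureSet,
                stageTimings = timings,
                preprocessLog = unlist(lapply(co$pp, `[[`, "log"),
                                       use.names = FALSE)))
  }, error = function(e)
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(bundle$perCase,
                       file.path(config$outputDir, "per_case_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cnt <- contingencyCounts(bundle$contingencyA)
    summ <- data.frame(
      feature_set = config$featureSet,
      voxel_sensitivity = bundle$voxel$sensitivity,
      voxel_specificity = bundle$voxel$specificity,
      voxel_dsc = bundle$voxel$dsc, voxel_auc = bundle$voxel$auc,
      region_tn = cnt["tn"], region_tp = cnt["tp"], region_fn = cnt["fn"],
      region_fp = cnt["fp"], region_fp_groupB = bundle$fpGroupB,
      region_sensitivity = as.numeric(bundle$region$sensitivity),
      region_specificity = as.numeric(bundle$region$specificity),
      region_dsc = as.numeric(bundle$region$dsc),
      combined_dsc = bundle$combinedDsc)
    utils::write.table(summ, file.path(config$outputDir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(sprintf("train_ids: %s",
                         paste(bundle$split$train, collapse = ",")),
                 bundle$stageTimings,
                 trainingLog(bundle$model)),
               file.path(config$outputDir, "training_log.txt"))
    writeLines(bundle$preprocessLog,
               file.path(config$outputDir, "preprocess_log.txt"))
  }
  invisible(bundle)
}

#' Compare the three input-feature sets on a shared test cohort
#'
#' Generates and preprocesses one cohort, then trains and evaluates one
#' network per requested feature set (optionally over several training
#' seeds) on the same train/test split and threshold. Returns the
#' per-run comparison table and, when several seeds are used, the
#' per-feature-set medians.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param featureSets feature sets to compare.
#' @param seeds training seeds; default the config's own seed.
#' @return list with \code{table} (one row per feature set x seed) and
#'   \code{median} (per-feature-set medians over seeds).
#' @export
runAblation <- function(config = experimentConfig(),
                        featureSets = c("cta", "cta+flip",
                                        "cta+flip+ncct"),
                        seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed
  co <- .buildCohort(config)
  rows <- list()
  for (fs in featureSets) {
    channels <- featureSetChannels(fs)
    for (sd in seeds) {
      fit <- .fitAndEvaluate(co$pp, co$split, config, channels,
                             trainSeed = .caseSeed(sd, 303L))
      cnt <- contingencyCounts(fit$contingencyA)
      rows[[paste(fs, sd)]] <- data.frame(
        feature_set = fs, seed = sd,
        voxel_sensitivity = fit$voxel$sensitivity,
        voxel_specificity = fit$voxel$specificity,
        voxel_dsc = fit$voxel$dsc, voxel_auc = fit$voxel$auc,
        region_tn = cnt["tn"], region_tp = cnt["tp"],
        region_fn = cnt["fn"], region_fp = cnt["fp"],
        region_fp_groupB = fit$fpGroupB,
        region_sensitivity = as.numeric(fit$region$sensitivity),
        region_specificity = as.numeric(fit$region$specificity),
        region_specificity_all = fit$specificityAllRegions,
        region_dsc = as.numeric(fit$region$dsc),
        combined_dsc = fit$combinedDsc)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  med <- do.call(rbind, lapply(split(tab, tab$feature_set), function(d)
    data.frame(feature_set = d$feature_set[1],
               voxel_auc = stats::median(d$voxel_auc),
               region_specificity = stats::median(d$region_specificity),
               region_specificity_all = stats::median(d$region_specificity_all),
               region_sensitivity = stats::median(d$region_sensitivity),
               combined_dsc = stats::median(d$combined_dsc))))
  rownames(med) <- NULL
  list(table = tab, median = med, split = co$split)
}

#' Verify printed region-contingency metrics
#'
#' Reads a tab-separated counts file (columns \code{features}, \code{tn},
#' \code{tp}, \code{fn}, \code{fp}, \code{fp_groupB}, \code{sensitivity},
#' \code{specificity}, \code{dsc}, \code{dsc_combined}), recomputes every
#' metric from the counts, and compares with the printed value after
#' half-up rounding to 2 decimals. The packaged reference counts are in
#' \code{system.file("extdata", "table2_counts.tsv", package =
#' "ctastroke")}.
#'
#' @param file path to the counts file.
#' @return data.frame with one row per feature-set x metric: the expected
#'   and recomputed values and a \code{pass} flag; overall success in
#'   attribute \code{"pass"}.
#' @export
table2Check <- function(file = system.file("extdata", "table2_counts.tsv",
                                           package = "ctastroke")) {
  lines <- readLines(file)
  if (!length(lines)) stop("parse error at line 1: empty counts file")
  need <- c("features", "tn", "tp", "fn", "fp", "fp_groupB", "sensitivity",
            "specificity", "dsc", "dsc_combined")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, need))
    stop("parse error at line 1: expected columns ",
         paste(need, collapse = ", "))
  if (length(lines) < 2) stop("parse error at line 2: no count rows")
  out <- list()
  for (i in 2:length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(need))
      stop(sprintf("parse error at line %d: expected %d fields, found %d",
                   i, length(need), length(f)))
    num <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(num)))
      stop(sprintf("parse error at line %d: non-numeric field", i))
    cnt <- new("RegionContingency", tn = num[1], tp = num[2], fn = num[3],
               fp = num[4])
    met <- metricsFromContingency(cnt)
    comb <- combinedDsc(cnt, num[5])
    computed <- c(sensitivity = unname(met$rounded["sensitivity"]),
                  specificity = unname(met$rounded["specificity"]),
                  dsc = unname(met$rounded["dsc"]),
                  dsc_combined = comb$rounded)
    expected <- c(sensitivity = num[6], specificity = num[7], dsc = num[8],
                  dsc_combined = num[9])
    out[[i - 1]] <- data.frame(
      features = f[1], check = names(expected), expected = expected,
      computed = computed, pass = abs(computed - expected) < 1e-9)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pass") <- all(res$pass)
  res
}
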