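#' Pipeline run configuration
#'
#' Gathers every stage's settings for the end-to-end workflow
#' (augment -> extract -> train/tune -> evaluate). Read from a YAML file
#' with [readRunConfig()]; every seed is recorded in the run manifest so
#' two runs with identical configurations produce identical outputs.
#'
#' @param manifest path to the input image manifest CSV.
#' @param outputDir directory all stage outputs are written to.
#' @param pglcm a [pglcmConfig()].
#' @param san a [sanConfig()], or NULL to disable attention.
#' @param forest a [forestConfig()].
#' @param augment list: `targetPerClass` (NULL = max class size),
#'   `spec` (an [augmentationSpec()]).
#' @param tuning list: `depthRange`, `treesRange`, `nFolds`.
#' @param splitFraction training fraction of the stratified split.
#' @param splitSeed,seed seeds for the split and the global run.
#' @return List of class `"RunConfig"`.
#' @export
runConfig <- function(manifest = NULL, outputDir = tempfile("sarfrun"),
                      pglcm = pglcmConfig(), san = sanConfig(),
                      forest = forestConfig(),
                      augment = list(targetPerClass = NULL,
                                     spec = augmentationSpec()),
                      tuning = list(depthRange = 10:30,
                                    treesRange = 190:230, nFolds = 5L),
                      splitFraction = 0.7, splitSeed = 1L, seed = 1L) {
  if (splitFraction <= 0 || splitFraction >= 1)
    stopf("splitFraction must lie in (0, 1)")
  structure(list(manifest = manifest, outputDir = outputDir, pglcm = pglcm,
                 san = san, forest = forest, augment = augment,
                 tuning = tuning, splitFraction = splitFraction,
                 splitSeed = as.integer(splitSeed), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `manifest`, `output_dir`, `pglcm`
#' (`n_levels`, `quant_levels`, `distances`, `angles`, `symmetric`),
#' `san` (`n_heads`, `hidden_size`, `epochs`, `batch_size`,
#' `learning_rate`, `dropout_rate`, `seed`, or `enabled: false`),
#' `forest` (`n_trees`, `max_depth`, `seed`), `augment`
#' (`target_per_class`), `tuning` (`depth_range`, `trees_range`,
#' `n_folds` — ranges as `[lo, hi]`), `split_fraction`, `split_seed`,
#' `seed`.
#'
#' @param path YAML file path.
#' @return A [runConfig()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  pick <- function(lst, key, default) if (is.null(lst[[key]])) default else lst[[key]]
  rangeOf <- function(v, default) if (is.null(v)) default else v[1]:v[2]
  p <- y$pglcm
  pg <- pglcmConfig(nLevels = pick(p, "n_levels", 3L),
                    quantLevels = pick(p, "quant_levels", 16L),
                    distances = pick(p, "distances", c(1L, 2L, 4L)),
                    angles = pick(p, "angles", c(0L, 45L, 90L, 135L)),
                    symmetric = pick(p, "symmetric", TRUE))
  s <- y$san
  sanCfg <- if (identical(pick(s, "enabled", TRUE), FALSE)) NULL else
    sanConfig(nHeads = pick(s, "n_heads", 1L),
              hiddenSize = s$hidden_size,
              epochs = pick(s, "epochs", 20L),
              batchSize = pick(s, "batch_size", 16L),
              learningRate = pick(s, "learning_rate", 0.001),
              dropoutRate = pick(s, "dropout_rate", 0.2),
              seed = pick(s, "seed", pick(y, "seed", 1L)))
  f <- y$forest
  fCfg <- forestConfig(nTrees = pick(f, "n_trees", 200L),
                       maxDepth = pick(f, "max_depth", 20L),
                       seed = pick(f, "seed", pick(y, "seed", 1L)))
  runConfig(manifest = y$manifest,
            outputDir = pick(y, "output_dir", tempfile("sarfrun")),
            pglcm = pg, san = sanCfg, forest = fCfg,
            augment = list(targetPerClass = y$augment$target_per_class,
                           spec = augmentationSpec()),
            tuning = list(
              depthRange = rangeOf(y$tuning$depth_range, 10:30),
              treesRange = rangeOf(y$tuning$trees_range, 190:230),
              nFolds = pick(y$tuning, "n_folds", 5L)),
            splitFraction = pick(y, "split_fraction", 0.7),
            splitSeed = pick(y, "split_seed", pick(y, "seed", 1L)),
            seed = pick(y, "seed", 1L))
}

logMsg <- function(logFile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(logFile)) cat(msg, "\n", file = logFile, append = TRUE)
}

writeRunManifest <- function(config, outputDir, stage, extra = list()) {
  obj <- c(list(stage = stage,
                package = "SARFtex",
                version = as.character(utils::packageVersion("SARFtex")),
                seed = config$seed, splitSeed = config$splitSeed,
                splitFraction = config$splitFraction,
                pglcm = unclass(config$pglcm),
                san = if (is.null(config$san)) NULL else unclass(config$san),
                forest = unclass(config$forest)),
           extra)
  jsonlite::write_json(obj, file.path(outputDir, sprintf("run_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

prepareStage <- function(config, stage) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$outputDir, sprintf("%s.log", stage))
}

#' Stage 1: augment and balance the dataset
#'
#' Balances every class of the input manifest to the configured target
#' (default: the largest class size) and writes the augmented manifest
#' plus per-class before/after counts to the log.
#'
#' @param config a [runConfig()].
#' @return Path of the augmented manifest CSV.
#' @export
cmdAugment <- function(config) {
  logFile <- prepareStage(config, "augment")
  manifest <- readManifest(config$manifest)
  before <- table(manifest$label)
  target <- config$augment$targetPerClass
  if (is.null(target)) target <- max(before)
  aug <- balanceDataset(manifest, config$augment$spec, target,
                        seed = config$seed,
                        outputDir = file.path(config$outputDir, "augmented"))
  after <- table(aug$label)
  for (cls in names(before))
    logMsg(logFile, "class %s: %d -> %d images", cls, before[[cls]],
           after[[cls]])
  out <- file.path(config$outputDir, "manifest_augmented.csv")
  writeManifest(aug, out)
  writeRunManifest(config, config$outputDir, "augment",
                   list(targetPerClass = target))
  out
}

#' Stage 2: extract PGLCM features
#'
#' @param config a [runConfig()]; uses the augmented manifest when
#'   present, else the input manifest.
#' @return Path of the feature CSV.
#' @export
cmdExtract <- function(config) {
  logFile <- prepareStage(config, "extract")
  mpath <- file.path(config$outputDir, "manifest_augmented.csv")
  if (!file.exists(mpath)) mpath <- config$manifest
  manifest <- readManifest(mpath)
  logMsg(logFile, "extracting %d features from %d images",
         2L * 4L * length(config$pglcm$distances) * length(config$pglcm$angles),
         nrow(manifest))
  tab <- extractDataset(manifest, config$pglcm)
  out <- file.path(config$outputDir, "features.csv")
  writeFeatureTable(tab, out, config$pglcm)
  writeRunManifest(config, config$outputDir, "extract",
                   list(nImages = nrow(tab)))
  out
}

stratifiedSplit <- function(labels, fraction, seed) {
  set.seed(childSeed(seed, 71L))
  train <- logical(length(labels))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    nTrain <- max(1L, round(length(idx) * fraction))
    train[sample(idx, nTrain)] <- TRUE
  }
  train
}

#' Stage 3: train SARF and evaluate on the held-out split
#'
#' Splits the feature table stratified by class (70/30 by default),
#' fits the SARF composite on the training part, and writes the model
#' artifact, held-out metric report (JSON), attention weights and
#' out-of-bag importance (CSV).
#'
#' @param config a [runConfig()].
#' @param featurePath feature CSV (default: the extract stage output).
#' @return List: `modelPath`, `metricsPath`, `report` (the held-out
#'   [metricReport()]), `model`.
#' @export
cmdTrain <- function(config,
                     featurePath = file.path(config$outputDir, "features.csv")) {
  logFile <- prepareStage(config, "train")
  tab <- readFeatureTable(featurePath)
  X <- tab[, setdiff(names(tab), "label"), drop = FALSE]
  y <- tab$label
  train <- stratifiedSplit(y, config$splitFraction, config$splitSeed)
  logMsg(logFile, "training on %d samples, testing on %d", sum(train),
         sum(!train))
  model <- fitSARF(X[train, , drop = FALSE], y[train],
                   sanCfg = config$san, forestCfg = config$forest)
  pred <- predict(model, X[!train, , drop = FALSE])
  report <- metricReport(confusionMatrix(y[!train], pred,
                                         classNames = model@classLevels))
  logMsg(logFile, "held-out accuracy: %.2f%%", report$accuracy)
  modelPath <- file.path(config$outputDir, "sarf_model.rds")
  writeSARFModel(model, modelPath)
  metricsPath <- file.path(config$outputDir, "metrics.json")
  writeMetricsJSON(report, metricsPath)
  rg <- globalAttention(model)$rg
  utils::write.csv(data.frame(feature = names(rg), rg = unname(rg)),
                   file.path(config$outputDir, "attention.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  if (isTRUE(config$forest$oob)) {
    imp <- importanceReport(model, X[train, , drop = FALSE], y[train],
                            seed = config$seed)
    utils::write.csv(imp, file.path(config$outputDir, "importance.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  writeRunManifest(config, config$outputDir, "train",
                   list(nTrain = sum(train), nTest = sum(!train),
                        accuracy = report$accuracy))
  list(modelPath = modelPath, metricsPath = metricsPath, report = report,
       model = model)
}

#' Stage 3b: grid-search tuning, then train at the best setting
#'
#' Runs the depth/size grid search by stratified cross-validation on the
#' training split only, writes the per-candidate report CSV, and refits
#' the SARF at the best `(maxDepth, nTrees)`.
#'
#' @param config a [runConfig()].
#' @param featurePath feature CSV path.
#' @return List: `gridResult`, plus the [cmdTrain()] outputs of the
#'   refit.
#' @export
cmdTune <- function(config,
                    featurePath = file.path(config$outputDir, "features.csv")) {
  logFile <- prepareStage(config, "tune")
  tab <- readFeatureTable(featurePath)
  X <- tab[, setdiff(names(tab), "label"), drop = FALSE]
  y <- tab$label
  train <- stratifiedSplit(y, config$splitFraction, config$splitSeed)
  gs <- gridSearchForest(X[train, , drop = FALSE], y[train],
                         depthRange = config$tuning$depthRange,
                         treesRange = config$tuning$treesRange,
                         nFolds = config$tuning$nFolds, seed = config$seed)
  logMsg(logFile, "best (d, n) = (%d, %d), CV accuracy %.2f%%",
         gs$best[["maxDepth"]], gs$best[["nTrees"]], 100 * gs$bestAccuracy)
  utils::write.csv(gs$grid, file.path(config$outputDir, "grid_search.csv"),
                   row.names = FALSE)
  tuned <- config
  tuned$forest <- forestConfig(nTrees = gs$best[["nTrees"]],
                               maxDepth = gs$best[["maxDepth"]],
                               seed = config$forest$seed,
                               oob = config$forest$oob)
  c(list(gridResult = gs), cmdTrain(tuned, featurePath))
}

#' Stage 4: evaluate a stored model on a feature table
#'
#' @param modelPath path to a model artifact from [cmdTrain()].
#' @param featurePath feature CSV with the training columns plus `label`.
#' @param outputDir directory for `metrics_eval.json`.
#' @return The [metricReport()] of the evaluation.
#' @export
cmdEvaluate <- function(modelPath, featurePath,
                        outputDir = dirname(modelPath)) {
  model <- readSARFModel(modelPath)
  tab <- readFeatureTable(featurePath)
  X <- tab[, setdiff(names(tab), "label"), drop = FALSE]
  pred <- predict(model, X)
  report <- metricReport(confusionMatrix(tab$label, pred,
                                         classNames = model@classLevels))
  writeMetricsJSON(report, file.path(outputDir, "metrics_eval.json"))
  report
}
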