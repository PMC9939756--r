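#' Random-forest configuration
#'
#' Defaults follow the published setting: 200 trees of depth at most 20,
#' Gini splitting, sqrt(|F|) candidate features per split, bootstrap
#' samples of the training-set size with in-bag records kept for
#' out-of-bag analysis.
#'
#' @param nTrees number of trees n (>= 1).
#' @param maxDepth maximum tree depth d (>= 1).
#' @param seed integer seed.
#' @param oob keep per-tree in-bag counts (needed by [oobImportance()]).
#' @return List of class `"ForestConfig"`.
#' @export
forestConfig <- function(nTrees = 200L, maxDepth = 20L, seed = 1L,
                         oob = TRUE) {
  if (nTrees < 1L || maxDepth < 1L) stopf("nTrees and maxDepth must be >= 1")
  structure(list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
                 seed = as.integer(seed), oob = isTRUE(oob)),
            class = "ForestConfig")
}

# ranger chokes on non-syntactic column names; fit on sanitized names and
# keep the originals for the user-facing contract.
sanitizeCols <- function(nms) sprintf("x%03d", seq_along(nms))

#' Fit a bootstrap-aggregated forest of depth-bounded trees
#'
#' Grows `nTrees` classification trees, each on a bootstrap sample of the
#' training-set size, and predicts by majority vote. The ensemble is
#' fitted with \pkg{ranger} (single-threaded, seeded, in-bag counts
#' kept), wrapped in a [SARFModel-class] with uniform attention.
#'
#' @param features data.frame or matrix of predictors.
#' @param labels class labels (>= 2 classes).
#' @param config a [forestConfig()].
#' @return A [SARFModel-class] (attention slot empty).
#' @export
fitForest <- function(features, labels, config = forestConfig()) {
  stopifnot(inherits(config, "ForestConfig"))
  X <- as.data.frame(features, check.names = FALSE)
  origNames <- colnames(X)
  labels <- as.character(labels)
  classLevels <- sort(unique(labels))
  if (length(classLevels) < 2L)
    stopf("forest training requires at least 2 classes")
  dat <- X
  colnames(dat) <- sanitizeCols(origNames)
  dat$.label <- factor(labels, levels = classLevels)
  rf <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = config$nTrees, max.depth = config$maxDepth,
    keep.inbag = config$oob, seed = config$seed, num.threads = 1,
    respect.unordered.factors = "order")
  nf <- length(origNames)
  new("SARFModel", attention = list(), forest = rf,
      rg = rep(1 / nf, nf), featureNames = origNames,
      classLevels = classLevels, forestConfig = unclass(config),
      fusionRescale = TRUE, applyFusion = FALSE)
}

checkPredictColumns <- function(model, features) {
  nms <- colnames(features)
  if (is.null(nms)) {
    if (ncol(features) != length(model@featureNames))
      stopf("feature count mismatch: expected %d, got %d",
            length(model@featureNames), ncol(features))
    return(invisible(NULL))
  }
  missing <- setdiff(model@featureNames, nms)
  extra <- setdiff(nms, model@featureNames)
  if (length(missing) || length(extra))
    stopf("feature columns do not match training columns%s%s",
          if (length(missing)) paste0("; missing: ",
                                      paste(missing, collapse = ", ")) else "",
          if (length(extra)) paste0("; extra: ",
                                    paste(extra, collapse = ", ")) else "")
  invisible(NULL)
}

# Vote fractions of the forest on already-fused features.
forestVotes <- function(model, fused) {
  dat <- as.data.frame(fused, check.names = FALSE)
  colnames(dat) <- sanitizeCols(model@featureNames)
  pred <- stats::predict(model@forest, data = dat, predict.all = TRUE,
                         num.threads = 1)$predictions
  nc <- length(model@classLevels)
  votes <- t(apply(pred, 1, tabulate, nbins = nc)) / ncol(pred)
  colnames(votes) <- model@classLevels
  votes
}

#' Predict classes or vote fractions from a SARF model
#'
#' Features are fused with the model's stored attention weights, each
#' tree votes, and the majority class wins; ties break to the
#' lexicographically first class. `type = "prob"` returns the vote
#' fractions (rows sum to 1).
#'
#' @param object a [SARFModel-class].
#' @param features data.frame/matrix with the training feature columns.
#' @param type `"response"` (labels) or `"prob"` (vote fractions).
#' @param ... ignored.
#' @return Character vector of labels, or a numeric matrix of vote
#'   fractions with one column per class.
#' @export
setMethod("predict", "SARFModel",
  function(object, features, type = c("response", "prob"), ...) {
    type <- match.arg(type)
    checkPredictColumns(object, features)
    X <- asFeatureMatrix(features, object@featureNames)
    fused <- if (object@applyFusion)
      fuseFeatures(X, object@rg, rescale = object@fusionRescale) else X
    votes <- forestVotes(object, fused)
    if (type == "prob") return(votes)
    # deterministic tie-break: first (lexicographic) class with max votes
    object@classLevels[apply(votes, 1, which.max)]
  })

#' Out-of-bag permutation importance
#'
#' For every tree k with a non-empty out-of-bag set B_k and every
#' feature x_j, feature j is permuted (seeded) within B_k, the tree's
#' predictions with and without permutation are compared against the
#' labels, and the misclassification-count difference is normalized by
#' `1/|B_k|` within trees and `1/T` across trees:
#' `J(x_j) = (1/T) sum_k (1/|B_k|) (err_k(perm j) - err_k)`.
#' Negative values (permutation helping) are not clipped. Trees whose
#' out-of-bag set is empty are skipped with a warning.
#'
#' @param model a [SARFModel-class] fitted with `oob = TRUE` on these
#'   (raw) features.
#' @param features the training features (raw; fused internally exactly
#'   as during training).
#' @param labels the training labels.
#' @param seed integer seed for the permutations.
#' @param nRepeats permutations per (tree, feature); default 1.
#' @return Named numeric vector of importances J, one per feature.
#' @export
oobImportance <- function(model, features, labels, seed = 1L, nRepeats = 1L) {
  stopifnot(is(model, "SARFModel"))
  rf <- model@forest
  if (is.null(rf$inbag.counts))
    stopf("forest was fitted without in-bag records (oob = FALSE)")
  checkPredictColumns(model, features)
  X <- asFeatureMatrix(features, model@featureNames)
  fused <- if (model@applyFusion)
    fuseFeatures(X, model@rg, rescale = model@fusionRescale) else X
  dat <- as.data.frame(fused, check.names = FALSE)
  colnames(dat) <- sanitizeCols(model@featureNames)
  labels <- as.character(labels)
  nT <- rf$num.trees
  nf <- ncol(dat)
  allPred <- stats::predict(rf, data = dat, predict.all = TRUE,
                            num.threads = 1)$predictions
  J <- numeric(nf)
  used <- 0L
  set.seed(childSeed(seed, 37L))
  for (k in seq_len(nT)) {
    oobIdx <- which(rf$inbag.counts[[k]] == 0L)
    if (length(oobIdx) == 0L) {
      warnf("tree %d has an empty out-of-bag set; skipped", k)
      next
    }
    used <- used + 1L
    yk <- labels[oobIdx]
    baseErr <- sum(model@classLevels[allPred[oobIdx, k]] != yk)
    # one batched prediction per tree: all (feature, repeat) permutations
    blocks <- vector("list", nf * nRepeats)
    bi <- 0L
    for (j in seq_len(nf)) for (r in seq_len(nRepeats)) {
      bi <- bi + 1L
      blk <- dat[oobIdx, , drop = FALSE]
      blk[[j]] <- blk[[j]][sample.int(length(oobIdx))]
      blocks[[bi]] <- blk
    }
    permPred <- stats::predict(rf, data = do.call(rbind, blocks),
                               predict.all = TRUE, num.threads = 1)$predictions
    nb <- length(oobIdx)
    bi <- 0L
    for (j in seq_len(nf)) {
      dErr <- 0
      for (r in seq_len(nRepeats)) {
        bi <- bi + 1L
        rows <- ((bi - 1L) * nb + 1L):(bi * nb)
        permErr <- sum(model@classLevels[permPred[rows, k]] != yk)
        dErr <- dErr + (permErr - baseErr)
      }
      J[j] <- J[j] + dErr / (nRepeats * nb)
    }
  }
  if (used == 0L) stopf("every tree had an empty out-of-bag set")
  J <- J / nT
  names(J) <- model@featureNames
  J
}

#' Grid search over forest depth and size
#'
#' Evaluates every `(maxDepth, nTrees)` candidate by stratified k-fold
#' cross-validated accuracy and returns the grid with its scores and the
#' best candidate; ties break to the smallest depth, then the smallest
#' tree count. Reproducible under a fixed seed and invariant to the
#' ordering of the ranges.
#'
#' @param features predictors (data.frame or matrix).
#' @param labels class labels.
#' @param depthRange candidate depths (default 10:30).
#' @param treesRange candidate tree counts (default 190:230).
#' @param nFolds folds (default 5); every fold must contain every class.
#' @param seed integer seed (fold assignment and forest fits).
#' @return List of class `"GridSearchResult"`: `grid` (data.frame with
#'   `maxDepth`, `nTrees`, `meanAccuracy`), `best` (named vector),
#'   `nFolds`.
#' @export
gridSearchForest <- function(features, labels, depthRange = 10:30,
                             treesRange = 190:230, nFolds = 5L, seed = 1L) {
  if (!length(depthRange) || !length(treesRange))
    stopf("depthRange and treesRange must be non-empty")
  if (nFolds < 2L) stopf("nFolds must be >= 2")
  labels <- as.character(labels)
  folds <- stratifiedFolds(labels, nFolds, seed)
  for (f in seq_len(nFolds)) {
    present <- unique(labels[folds == f])
    if (!setequal(present, unique(labels)))
      stopf("fold %d lacks a class; use fewer folds", f)
  }
  grid <- expand.grid(maxDepth = sort(unique(as.integer(depthRange))),
                      nTrees = sort(unique(as.integer(treesRange))),
                      KEEP.OUT.ATTRS = FALSE)
  X <- as.data.frame(features, check.names = FALSE)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    foldAcc <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      test <- folds == f
      cfg <- forestConfig(grid$nTrees[g], grid$maxDepth[g],
                          seed = childSeed(seed, f), oob = FALSE)
      fit <- fitForest(X[!test, , drop = FALSE], labels[!test], cfg)
      pred <- predict(fit, X[test, , drop = FALSE])
      foldAcc[f] <- mean(pred == labels[test])
    }
    acc[g] <- mean(foldAcc)
  }
  grid$meanAccuracy <- acc
  # argmax with ties to smallest depth, then smallest nTrees (grid is
  # sorted that way already)
  best <- grid[order(-grid$meanAccuracy, grid$maxDepth, grid$nTrees)[1], ]
  structure(list(grid = grid,
                 best = c(maxDepth = best$maxDepth, nTrees = best$nTrees),
                 bestAccuracy = best$meanAccuracy, nFolds = as.integer(nFolds)),
            class = "GridSearchResult")
}

# Seeded stratified fold assignment: within each class, shuffled samples
# are dealt round-robin across folds.
stratifiedFolds <- function(labels, nFolds, seed) {
  folds <- integer(length(labels))
  set.seed(childSeed(seed, 53L))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

#' Fit the full SARF composite
#'
#' Trains the self-attention network on the raw features, extracts its
#' global attention distribution, residually fuses the features with it,
#' and fits the depth-bounded random forest on the fused features. Both
#' sub-models and the fusion weights are stored so prediction replays
#' the identical transform.
#'
#' @param features raw predictors (data.frame or matrix).
#' @param labels class labels.
#' @param sanCfg a [sanConfig()]; NULL skips attention (uniform fusion,
#'   i.e. a plain random forest on doubled features).
#' @param forestCfg a [forestConfig()].
#' @param rescale rescale attention by |F| before fusion (default TRUE).
#' @return A [SARFModel-class].
#' @export
fitSARF <- function(features, labels, sanCfg = sanConfig(),
                    forestCfg = forestConfig(), rescale = TRUE) {
  X <- as.data.frame(features, check.names = FALSE)
  labels <- as.character(labels)
  nf <- ncol(X)
  if (is.null(sanCfg)) {
    att <- list()
    rg <- rep(1 / nf, nf)
  } else {
    att <- trainSAN(X, labels, sanCfg)
    rg <- unname(globalAttention(att)$rg)
  }
  fused <- fuseFeatures(X, rg, rescale = rescale)
  base <- fitForest(fused, labels, forestCfg)
  new("SARFModel", attention = att, forest = base@forest, rg = rg,
      featureNames = colnames(X), classLevels = base@classLevels,
      forestConfig = unclass(forestCfg), fusionRescale = rescale,
      applyFusion = TRUE)
}

#' Save / load a SARF model bundle
#'
#' The attention model, forest, fusion weights and configuration are
#' bundled into one portable RDS artifact.
#'
#' @param model a [SARFModel-class].
#' @param path output `.rds` path.
#' @return `path` invisibly; `readSARFModel` returns the model.
#' @export
writeSARFModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname writeSARFModel
#' @export
readSARFModel <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "SARFModel")) stopf("%s does not contain a SARFModel", path)
  obj
}

#' Combined importance report
#'
#' One row per feature with the out-of-bag permutation importance J and
#' the global attention weight r_g.
#'
#' @param model a fitted [SARFModel-class].
#' @param features,labels the training data (for the permutation runs).
#' @param seed permutation seed.
#' @return data.frame with columns `feature`, `J`, `rg`, sorted by
#'   decreasing J.
#' @export
importanceReport <- function(model, features, labels, seed = 1L) {
  J <- oobImportance(model, features, labels, seed = seed)
  rg <- globalAttention(model)$rg
  out <- data.frame(feature = model@featureNames, J = unname(J),
                    rg = unname(rg), stringsAsFactors = FALSE)
  out[order(-out$J), ]
}
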