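#' @include AllGenerics.R
NULL

#' Grayscale image container
#'
#' A quantized 2-D intensity grid. Pixels are stored as an integer-valued
#' numeric matrix in row/column (height x width) orientation; every value
#' lies in `[0, maxLevel]`.
#'
#' @slot pixels numeric matrix of non-negative integer intensities.
#' @slot maxLevel integer, maximum representable intensity (255 for 8-bit).
#'
#' @seealso [loadImage()], [rotateImage()], [flipImage()], [enhanceImage()],
#'   [quantizeImage()], [buildPyramid()]
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", maxLevel = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
    if (length(object@maxLevel) != 1L || object@maxLevel < 1L)
      return("maxLevel must be a single positive integer")
    if (anyNA(p)) return("pixels contain NA")
    if (min(p) < 0 || max(p) > object@maxLevel)
      return(sprintf("pixel values outside [0, %d]", object@maxLevel))
    if (any(p != round(p))) return("pixel values must be integers")
    TRUE
  }
)

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of integer intensities.
#' @param maxLevel maximum representable intensity (default 255).
#' @return A [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(0:3, 2, 2), maxLevel = 255)
#' dim(img)
#' @export
GrayImage <- function(pixels, maxLevel = 255L) {
  new("GrayImage", pixels = structure(as.numeric(pixels), dim = dim(pixels)),
      maxLevel = as.integer(maxLevel))
}

#' @describeIn GrayImage-class pixel matrix accessor
#' @param x a GrayImage.
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @describeIn GrayImage-class maximum intensity accessor
#' @export
setMethod("maxLevel", "GrayImage", function(x) x@maxLevel)

#' @describeIn GrayImage-class image dimensions (height, width)
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage %d x %d, levels [0, %d]\n", d[1], d[2], object@maxLevel))
  cat(sprintf("  intensity range observed: [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

#' Gray-level co-occurrence matrix
#'
#' Joint distribution of gray-level pairs at a fixed pixel offset
#' (distance, angle), optionally symmetric (both pair orders counted) and
#' normalized to sum to one.
#'
#' @slot probs numeric L x L matrix, L = number of quantization levels.
#' @slot distance integer offset magnitude in pixels.
#' @slot angle integer direction in degrees, one of 0, 45, 90, 135.
#' @slot level integer pyramid level index the matrix was computed at
#'   (0 = original resolution; -1 when not applicable).
#' @slot symmetric logical, whether both pair orders were counted.
#' @slot normalized logical, whether entries sum to one.
#' @seealso [computeGLCM()], [haralickStats()]
#' @export
setClass("GLCMMatrix",
  representation(probs = "matrix", distance = "integer", angle = "integer",
                 level = "integer", symmetric = "logical",
                 normalized = "logical"),
  validity = function(object) {
    p <- object@probs
    if (nrow(p) != ncol(p)) return("probs must be square")
    if (anyNA(p) || min(p) < 0) return("probs must be non-negative")
    if (!object@angle %in% c(0L, 45L, 90L, 135L))
      return("angle must be one of 0, 45, 90, 135")
    if (object@normalized && abs(sum(p) - 1) > 1e-9)
      return("normalized GLCM entries must sum to 1")
    if (object@symmetric && !isTRUE(all.equal(p, t(p), tolerance = 1e-12)))
      return("symmetric GLCM must equal its transpose")
    TRUE
  }
)

#' @describeIn GLCMMatrix-class probability matrix accessor
#' @param x a GLCMMatrix.
#' @export
setMethod("glcmProbs", "GLCMMatrix", function(x) x@probs)

setMethod("show", "GLCMMatrix", function(object) {
  cat(sprintf("GLCMMatrix %d levels, d=%d, %d deg%s%s%s\n",
              nrow(object@probs), object@distance, object@angle,
              if (object@symmetric) ", symmetric" else "",
              if (object@normalized) ", normalized" else " (counts)",
              if (object@level >= 0L) sprintf(", pyramid level %d", object@level) else ""))
})

#' Self-attention network model
#'
#' Weights and configuration of the shallow self-attention network (SAN):
#' per-head attention matrices, two SELU/sigmoid dense layers and a softmax
#' classification head, together with the input standardization applied at
#' training time and the training-loss trace.
#'
#' @slot weights list of weight matrices/vectors: `Watt` (list of |F| x |F|
#'   matrices, one per head), `batt` (list of length-|F| vectors), `W1`,
#'   `b1`, `W2`, `b2`, `Wout`, `bout`.
#' @slot config list, see [sanConfig()].
#' @slot featureNames character, column names of the training features.
#' @slot classLevels character, class labels in model order.
#' @slot center,scale numeric, per-feature standardization applied to inputs.
#' @slot lossTrace numeric, mean cross-entropy per epoch.
#' @seealso [trainSAN()], [globalAttention()], [fuseFeatures()]
#' @export
setClass("AttentionModel",
  representation(weights = "list", config = "list", featureNames = "character",
                 classLevels = "character", center = "numeric",
                 scale = "numeric", lossTrace = "numeric"),
  validity = function(object) {
    w <- object@weights
    need <- c("Watt", "batt", "W1", "b1", "W2", "b2", "Wout", "bout")
    if (!all(need %in% names(w))) return("missing weight components")
    nf <- length(object@featureNames)
    if (length(w$Watt) < 1L) return("at least one attention head required")
    for (h in seq_along(w$Watt)) {
      if (!all(dim(w$Watt[[h]]) == c(nf, nf)))
        return("attention weight matrices must be |F| x |F|")
      if (length(w$batt[[h]]) != nf) return("attention bias length mismatch")
    }
    if (ncol(w$W1) != nf) return("first dense layer width mismatch")
    TRUE
  }
)

setMethod("show", "AttentionModel", function(object) {
  cat(sprintf("AttentionModel: |F| = %d features, %d head(s), hidden %d, %d classes\n",
              length(object@featureNames), length(object@weights$Watt),
              nrow(object@weights$W1), length(object@classLevels)))
  if (length(object@lossTrace))
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                length(object@lossTrace), tail(object@lossTrace, 1)))
  rg <- globalAttention(object)$rg
  top <- head(order(rg, decreasing = TRUE), 3)
  cat("  top attention: ",
      paste(sprintf("%s (%.3f)", object@featureNames[top], rg[top]),
            collapse = ", "), "\n", sep = "")
})

#' Self-attention random forest model
#'
#' The SARF composite: a trained [AttentionModel-class], its global
#' attention weights, and a random forest fitted on the residually
#' reweighted (fused) features.
#'
#' @slot attention the trained [AttentionModel-class], or NULL-like empty
#'   list when the forest was fitted on raw features.
#' @slot forest the fitted ensemble (a `ranger` object with in-bag records).
#' @slot rg numeric, global attention distribution used for fusion (sums
#'   to 1; uniform when no attention model is present).
#' @slot featureNames character, training feature columns in order.
#' @slot classLevels character, class labels (lexicographic).
#' @slot forestConfig list, see [forestConfig()].
#' @slot fusionRescale logical, whether attention was rescaled by |F| so
#'   that uniform attention doubles the features.
#' @slot applyFusion logical; TRUE when the forest was trained on fused
#'   features, so prediction must replay the fusion. FALSE for plain
#'   forests fitted directly on the supplied features.
#' @seealso [fitSARF()], [predict,SARFModel-method]
#' @export
setClass("SARFModel",
  representation(attention = "ANY", forest = "ANY", rg = "numeric",
                 featureNames = "character", classLevels = "character",
                 forestConfig = "list", fusionRescale = "logical",
                 applyFusion = "logical"),
  validity = function(object) {
    if (abs(sum(object@rg) - 1) > 1e-6) return("rg must sum to 1")
    if (length(object@rg) != length(object@featureNames))
      return("rg length must match feature count")
    TRUE
  }
)

setMethod("show", "SARFModel", function(object) {
  cat(sprintf("SARFModel: %d features -> %d classes (%s)\n",
              length(object@featureNames), length(object@classLevels),
              paste(object@classLevels, collapse = ", ")))
  cat(sprintf("  forest: %d trees, max depth %d%s\n",
              object@forestConfig$nTrees, object@forestConfig$maxDepth,
              if (isTRUE(object@forestConfig$oob)) ", in-bag records kept" else ""))
  cat(sprintf("  attention: %s\n",
              if (is(object@attention, "AttentionModel")) "trained SAN" else "uniform (none)"))
})

#' @describeIn SARFModel-class class labels accessor
#' @param x a SARFModel.
#' @export
setMethod("classNames", "SARFModel", function(x) x@classLevels)

#' Confusion matrix
#'
#' Ground-truth (rows) by prediction (columns) counts for an n-class
#' problem; the source of all derived accuracy/sensitivity/specificity
#' metrics.
#'
#' @slot counts non-negative integer n x n matrix with identical row and
#'   column names (the class labels).
#' @seealso [confusionMatrix()], [overallAccuracy()], [perClassMetrics()]
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix"),
  validity = function(object) {
    m <- object@counts
    if (nrow(m) != ncol(m)) return("counts must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      return("row and column names must be identical class labels")
    if (anyNA(m) || min(m) < 0 || any(m != round(m)))
      return("counts must be non-negative integers")
    if (sum(m) <= 0) return("confusion matrix must contain at least one count")
    TRUE
  }
)

#' @describeIn ConfusionMatrix-class class labels accessor
#' @param x a ConfusionMatrix.
#' @export
setMethod("classNames", "ConfusionMatrix", function(x) rownames(x@counts))

#' @describeIn ConfusionMatrix-class raw count matrix
#' @param object a ConfusionMatrix.
#' @export
counts <- function(object) object@counts

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (%d classes, %d samples), accuracy %.2f%%\n",
              nrow(object@counts), sum(object@counts),
              overallAccuracy(object)))
  print(object@counts)
})
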