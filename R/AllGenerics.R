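#' @import methods
#' @importFrom stats predict
#' @importFrom utils head tail
#' @importFrom ranger ranger
NULL

#' Pixel matrix of an image
#'
#' @param x a [GrayImage-class] object.
#' @return Integer matrix of intensities (rows = image rows).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Maximum representable intensity
#'
#' @param x a [GrayImage-class] object.
#' @return Scalar integer, e.g. 255 for 8-bit images.
#' @export
setGeneric("maxLevel", function(x) standardGeneric("maxLevel"))

#' Co-occurrence probability matrix
#'
#' @param x a [GLCMMatrix-class] object.
#' @return Numeric L x L matrix of joint probabilities (or raw counts if
#'   the object was built unnormalized).
#' @export
setGeneric("glcmProbs", function(x) standardGeneric("glcmProbs"))

#' Global attention weights
#'
#' Per-feature importance distribution obtained by softmaxing the diagonal
#' of each attention head's weight matrix and averaging across heads.
#'
#' @param model a trained or initialized attention model, or a fitted
#'   SARF model (in which case the stored attention sub-model is used).
#' @return A list with `rg` (length-|F| probability vector, named by
#'   feature) and `perHead` (list of per-head probability vectors).
#' @export
setGeneric("globalAttention", function(model) standardGeneric("globalAttention"))

#' Class names of a confusion matrix or classifier
#'
#' @param x a [ConfusionMatrix-class] or [SARFModel-class] object.
#' @return Character vector of class labels in display order.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
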