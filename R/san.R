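#' Numerically stable softmax
#'
#' `exp(v) / sum(exp(v))` computed after subtracting `max(v)`, so the
#' result is invariant to adding a constant and never overflows.
#'
#' @param v numeric vector with finite entries.
#' @return Positive vector summing to 1.
#' @examples
#' sanSoftmax(c(0, log(3)))  # 0.25 0.75
#' @export
sanSoftmax <- function(v) {
  if (length(v) == 0L) stopf("softmax of an empty vector")
  if (any(!is.finite(v))) stopf("softmax requires finite entries")
  e <- exp(v - max(v))
  e / sum(e)
}

# Row-wise softmax of a matrix.
softmaxRows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for `x > 0` and
#' `lambda * alpha * (exp(x) - 1)` for `x <= 0`; continuous at 0 with
#' lower asymptote `-lambda * alpha`. Defaults are the standard
#' self-normalizing constants.
#'
#' @param x numeric (vectorized).
#' @param lambda,alpha positive hyperparameters.
#' @return `selu(x)`, same shape as `x`.
#' @export
selu <- function(x, lambda = 1.0507, alpha = 1.67326) {
  ifelse(x > 0, lambda * x, lambda * alpha * (exp(x) - 1))
}

seluGrad <- function(x, lambda, alpha) {
  ifelse(x > 0, lambda, lambda * alpha * exp(x))
}

#' SAN training configuration
#'
#' Defaults follow the published training setup: 20 epochs, batch size
#' 16, Adam with learning rate 0.001, dropout 20% after the SELU hidden
#' layer, one attention head, hidden width equal to the number of
#' features.
#'
#' @param nHeads number of attention heads k (>= 1).
#' @param hiddenSize hidden layer width; NULL means |F|.
#' @param epochs training epochs T (>= 1).
#' @param batchSize minibatch size (>= 1).
#' @param learningRate Adam learning rate.
#' @param dropoutRate dropout probability in `[0, 1)`.
#' @param seluLambda,seluAlpha SELU constants.
#' @param standardize min-max scale the inputs to `[0, 1]` before the
#'   attention layer (stored in the model and reapplied at prediction
#'   time); non-negative inputs let the attention matrix diagonal carry
#'   the per-feature importance signal.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return List of class `"SANConfig"`.
#' @export
sanConfig <- function(nHeads = 1L, hiddenSize = NULL, epochs = 20L,
                      batchSize = 16L, learningRate = 0.001,
                      dropoutRate = 0.2, seluLambda = 1.0507,
                      seluAlpha = 1.67326, standardize = TRUE, seed = 1L) {
  if (nHeads < 1L) stopf("nHeads must be >= 1")
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (batchSize < 1L) stopf("batchSize must be >= 1")
  if (dropoutRate < 0 || dropoutRate >= 1)
    stopf("dropoutRate must lie in [0, 1)")
  if (learningRate <= 0 || seluLambda <= 0 || seluAlpha <= 0)
    stopf("learningRate and SELU constants must be positive")
  structure(list(nHeads = as.integer(nHeads), hiddenSize = hiddenSize,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, dropoutRate = dropoutRate,
                 seluLambda = seluLambda, seluAlpha = seluAlpha,
                 standardize = standardize, seed = as.integer(seed)),
            class = "SANConfig")
}

# Build an AttentionModel with seeded small-normal weights.
initAttentionModel <- function(featureNames, classLevels, config,
                               center = NULL, scale = NULL) {
  nf <- length(featureNames)
  nh <- if (is.null(config$hiddenSize)) nf else as.integer(config$hiddenSize)
  nc <- length(classLevels)
  set.seed(childSeed(config$seed, 11L))
  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.05), r, c)
  w <- list(
    Watt = replicate(config$nHeads, rmat(nf, nf), simplify = FALSE),
    batt = replicate(config$nHeads, numeric(nf), simplify = FALSE),
    W1 = rmat(nh, nf), b1 = numeric(nh),
    W2 = rmat(nh, nh), b2 = numeric(nh),
    Wout = rmat(nc, nh), bout = numeric(nc))
  new("AttentionModel", weights = w, config = unclass(config),
      featureNames = featureNames, classLevels = classLevels,
      center = if (is.null(center)) rep(0, nf) else center,
      scale = if (is.null(scale)) rep(1, nf) else scale,
      lossTrace = numeric(0))
}

standardizeInput <- function(X, model) {
  sweep(sweep(X, 2, model@center, "-"), 2, model@scale, "/")
}

asFeatureMatrix <- function(X, featureNames) {
  if (is.data.frame(X)) X <- as.matrix(X[, featureNames, drop = FALSE])
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  if (ncol(X) != length(featureNames))
    stopf("expected %d feature columns, got %d", length(featureNames), ncol(X))
  X
}

#' Attention layer forward pass
#'
#' The first SAN layer: per head, the input is multiplied elementwise
#' (Hadamard product) by the softmax of its attention logits
#' `W_att x + b_att`; head outputs are summed and divided by the number
#' of heads. With zero weights the softmax is uniform and the layer
#' returns `x / |F|` exactly. Inputs are rescaled with the model's
#' stored center/scale (min-max by default) first.
#'
#' @param X numeric vector of length |F|, or a matrix/data.frame with
#'   |F| columns (rows = samples).
#' @param model an [AttentionModel-class].
#' @return Refined matrix of the same row count, |F| columns.
#' @export
omegaForward <- function(X, model) {
  stopifnot(is(model, "AttentionModel"))
  X <- asFeatureMatrix(X, model@featureNames)
  Xs <- standardizeInput(X, model)
  w <- model@weights
  k <- length(w$Watt)
  acc <- 0
  for (h in seq_len(k)) {
    Z <- Xs %*% t(w$Watt[[h]])
    Z <- sweep(Z, 2, w$batt[[h]], "+")
    acc <- acc + Xs * softmaxRows(Z)
  }
  acc / k
}

# Full forward pass; returns intermediate activations for backprop.
sanForwardFull <- function(X, model, train = FALSE, dropMask = NULL) {
  w <- model@weights; cfg <- model@config
  Xs <- standardizeInput(X, model)
  k <- length(w$Watt)
  S <- vector("list", k)
  O <- 0
  for (h in seq_len(k)) {
    Z <- sweep(Xs %*% t(w$Watt[[h]]), 2, w$batt[[h]], "+")
    S[[h]] <- softmaxRows(Z)
    O <- O + Xs * S[[h]]
  }
  O <- O / k
  H1 <- sweep(O %*% t(w$W1), 2, w$b1, "+")
  A <- selu(H1, cfg$seluLambda, cfg$seluAlpha)
  D <- if (train && cfg$dropoutRate > 0) {
    if (is.null(dropMask))
      dropMask <- matrix(stats::runif(length(A)) >= cfg$dropoutRate,
                         nrow(A), ncol(A))
    A * dropMask / (1 - cfg$dropoutRate)
  } else A
  H2 <- sweep(D %*% t(w$W2), 2, w$b2, "+")
  G <- 1 / (1 + exp(-H2))
  logits <- sweep(G %*% t(w$Wout), 2, w$bout, "+")
  P <- softmaxRows(logits)
  list(Xs = Xs, S = S, O = O, H1 = H1, A = A, D = D,
       dropMask = dropMask, H2 = H2, G = G, P = P)
}

#' SAN forward pass (class probabilities)
#'
#' Attention layer, SELU dense layer, sigmoid dense layer, softmax
#' classification head. Dropout is inactive at inference, so repeated
#' calls on the same input are identical.
#'
#' @param X feature vector / matrix / data.frame (columns = features).
#' @param model an [AttentionModel-class].
#' @return Matrix of class probabilities (rows sum to 1), columns named
#'   by class.
#' @export
sanForward <- function(X, model) {
  stopifnot(is(model, "AttentionModel"))
  X <- asFeatureMatrix(X, model@featureNames)
  P <- sanForwardFull(X, model, train = FALSE)$P
  colnames(P) <- model@classLevels
  P
}

#' Train the self-attention network
#'
#' Minimizes categorical cross-entropy with Adam over `epochs` epochs of
#' shuffled minibatches. Initialization, shuffling and dropout are all
#' driven by `config$seed`, so training twice with the same data and
#' seed yields bit-identical weights. The per-epoch mean loss is stored
#' in the returned model's `lossTrace`.
#'
#' @param features data.frame or matrix of predictors (no label column).
#' @param labels factor or character class labels (>= 2 classes, >= 2
#'   samples each).
#' @param config a [sanConfig()].
#' @return A trained [AttentionModel-class].
#' @export
trainSAN <- function(features, labels, config = sanConfig()) {
  stopifnot(inherits(config, "SANConfig"))
  X <- if (is.data.frame(features)) as.matrix(features) else features
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- as.character(labels)
  classLevels <- sort(unique(labels))
  if (length(classLevels) < 2L) stopf("training requires at least 2 classes")
  if (any(table(labels) < 2L)) stopf("every class needs at least 2 samples")
  n <- nrow(X)
  # min-max scale inputs to [0, 1]: keeping the attention-layer inputs
  # non-negative lets the diagonal of W_att accumulate the per-feature
  # importance signal that the global attention reads out.
  center <- if (config$standardize) apply(X, 2, min) else rep(0, ncol(X))
  scl <- if (config$standardize) apply(X, 2, max) - center else rep(1, ncol(X))
  scl[scl == 0 | !is.finite(scl)] <- 1
  model <- initAttentionModel(colnames(X), classLevels, config,
                              center = center, scale = scl)
  w <- model@weights
  Y <- outer(labels, classLevels, "==") * 1
  # Adam state per weight tensor
  mState <- lapply(rapply(w, function(x) x * 0, how = "list"), identity)
  vState <- mState
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  stepCount <- 0
  lossTrace <- numeric(config$epochs)
  set.seed(childSeed(config$seed, 23L))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epochLoss <- 0
    for (b in batches) {
      model@weights <- w
      f <- sanForwardFull(X[b, , drop = FALSE], model, train = TRUE)
      P <- f$P
      loss <- -mean(log(pmax(rowSums(P * Y[b, , drop = FALSE]), 1e-12)))
      if (!is.finite(loss)) stopf("NaN loss at epoch %d", epoch)
      epochLoss <- epochLoss + loss * length(b)
      g <- sanBackward(f, Y[b, , drop = FALSE], w, model@config)
      stepCount <- stepCount + 1
      for (nm in names(g)) {
        if (nm %in% c("Watt", "batt")) {
          for (h in seq_along(g[[nm]])) {
            mState[[nm]][[h]] <- beta1 * mState[[nm]][[h]] + (1 - beta1) * g[[nm]][[h]]
            vState[[nm]][[h]] <- beta2 * vState[[nm]][[h]] + (1 - beta2) * g[[nm]][[h]]^2
            mhat <- mState[[nm]][[h]] / (1 - beta1^stepCount)
            vhat <- vState[[nm]][[h]] / (1 - beta2^stepCount)
            w[[nm]][[h]] <- w[[nm]][[h]] - config$learningRate * mhat / (sqrt(vhat) + eps)
          }
        } else {
          mState[[nm]] <- beta1 * mState[[nm]] + (1 - beta1) * g[[nm]]
          vState[[nm]] <- beta2 * vState[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- mState[[nm]] / (1 - beta1^stepCount)
          vhat <- vState[[nm]] / (1 - beta2^stepCount)
          w[[nm]] <- w[[nm]] - config$learningRate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    lossTrace[epoch] <- epochLoss / n
  }
  model@weights <- w
  model@lossTrace <- lossTrace
  model
}

# Gradients of mean cross-entropy wrt every weight tensor.
sanBackward <- function(f, Yb, w, cfg) {
  nb <- nrow(f$P)
  k <- length(w$Watt)
  dLogits <- (f$P - Yb) / nb
  gWout <- t(dLogits) %*% f$G
  gbout <- colSums(dLogits)
  dG <- dLogits %*% w$Wout
  dH2 <- dG * f$G * (1 - f$G)
  gW2 <- t(dH2) %*% f$D
  gb2 <- colSums(dH2)
  dD <- dH2 %*% w$W2
  dA <- if (!is.null(f$dropMask)) dD * f$dropMask / (1 - cfg$dropoutRate) else dD
  dH1 <- dA * seluGrad(f$H1, cfg$seluLambda, cfg$seluAlpha)
  gW1 <- t(dH1) %*% f$O
  gb1 <- colSums(dH1)
  dO <- dH1 %*% w$W1
  gWatt <- vector("list", k); gbatt <- vector("list", k)
  for (h in seq_len(k)) {
    dS <- (f$Xs * dO) / k
    S <- f$S[[h]]
    dZ <- S * (dS - rowSums(dS * S))
    gWatt[[h]] <- t(dZ) %*% f$Xs
    gbatt[[h]] <- colSums(dZ)
  }
  list(Watt = gWatt, batt = gbatt, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       Wout = gWout, bout = gbout)
}

#' @describeIn globalAttention softmax of each head's attention-matrix
#'   diagonal, averaged over heads.
#' @export
setMethod("globalAttention", "AttentionModel", function(model) {
  w <- model@weights
  perHead <- lapply(w$Watt, function(W) {
    s <- sanSoftmax(diag(W))
    names(s) <- model@featureNames
    s
  })
  rg <- Reduce("+", perHead) / length(perHead)
  list(rg = rg, perHead = perHead)
})

#' @describeIn globalAttention attention weights stored in a fitted SARF
#'   model.
#' @export
setMethod("globalAttention", "SARFModel", function(model) {
  if (is(model@attention, "AttentionModel"))
    return(globalAttention(model@attention))
  rg <- model@rg
  names(rg) <- model@featureNames
  list(rg = rg, perHead = list(rg))
})

#' Residual attention fusion of a feature vector
#'
#' `fused_j = F_j + F_j * (|F| * rg_j)` (with `rescale = TRUE`, the
#' default): attention is rescaled so that a uniform distribution
#' (`rg_j = 1/|F|`) doubles every feature, leaving a scale-invariant
#' classifier unchanged. With `rescale = FALSE` the raw attention is
#' used: `fused_j = F_j + F_j * rg_j`.
#'
#' @param F numeric vector, matrix or data.frame of raw features.
#' @param rg attention distribution (sums to 1), or the list returned by
#'   [globalAttention()].
#' @param rescale multiply attention by |F| before fusing (default TRUE).
#' @return Fused features, same shape/type as the input.
#' @export
fuseFeatures <- function(F, rg, rescale = TRUE) {
  if (is.list(rg) && !is.null(rg$rg)) rg <- rg$rg
  wasDF <- is.data.frame(F)
  M <- if (wasDF) as.matrix(F) else if (is.null(dim(F))) matrix(F, nrow = 1) else F
  if (ncol(M) != length(rg))
    stopf("feature length %d does not match attention length %d",
          ncol(M), length(rg))
  wvec <- if (rescale) length(rg) * rg else rg
  out <- M + sweep(M, 2, wvec, "*")
  if (wasDF) {
    out <- as.data.frame(out, check.names = FALSE)
    names(out) <- names(F)
    out
  } else if (is.null(dim(F))) {
    stats::setNames(drop(out), names(F))
  } else out
}

#' Serialize / restore an attention model
#'
#' The full weight set, configuration, standardization and feature names
#' are stored in a single JSON container.
#'
#' @param model an [AttentionModel-class].
#' @param path output `.json` path.
#' @return `path` invisibly; `readAttentionModel` returns the model.
#' @export
writeAttentionModel <- function(model, path) {
  stopifnot(is(model, "AttentionModel"))
  obj <- list(weights = model@weights, config = model@config,
              featureNames = model@featureNames,
              classLevels = model@classLevels, center = model@center,
              scale = model@scale, lossTrace = model@lossTrace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAttentionModel
#' @export
readAttentionModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  # a list of equal-sized matrices may come back as one 3-D array
  w$Watt <- if (is.array(w$Watt) && length(dim(w$Watt)) == 3L)
    lapply(seq_len(dim(w$Watt)[1]), function(h) w$Watt[h, , ])
  else if (is.list(w$Watt)) lapply(w$Watt, as.matrix) else list(as.matrix(w$Watt))
  w$batt <- if (is.matrix(w$batt))
    lapply(seq_len(nrow(w$batt)), function(h) w$batt[h, ])
  else if (is.list(w$batt)) lapply(w$batt, as.numeric) else list(as.numeric(w$batt))
  for (nm in c("W1", "W2", "Wout")) w[[nm]] <- as.matrix(w[[nm]])
  new("AttentionModel", weights = w, config = as.list(obj$config),
      featureNames = obj$featureNames, classLevels = obj$classLevels,
      center = obj$center, scale = obj$scale,
      lossTrace = as.numeric(obj$lossTrace))
}
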