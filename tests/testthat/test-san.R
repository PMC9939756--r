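zeroAttentionModel <- function(nf = 4L, classes = c("a", "b")) {
  m <- SARFtex:::initAttentionModel(paste0("f", seq_len(nf)), classes,
                          sanConfig(seed = 1))
  for (h in seq_along(m@weights$Watt)) {
    m@weights$Watt[[h]][] <- 0
    m@weights$batt[[h]][] <- 0
  }
  m
}

test_that("softmax matches closed forms and is shift-invariant", {
  expect_equal(sanSoftmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(sanSoftmax(c(0, log(3))), c(0.25, 0.75))
  expect_equal(sanSoftmax(c(1000, 1000)), c(0.5, 0.5))
  set.seed(501)
  for (rep in 1:10) {
    v <- rnorm(sample(2:20, 1), sd = 5)
    s <- sanSoftmax(v)
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_equal(s, sanSoftmax(v + 17.3), tolerance = 1e-12)
    expect_true(all(s > 0))
  }
  expect_error(sanSoftmax(numeric(0)), "empty")
})

test_that("SELU follows its two branches and is continuous at zero", {
  expect_equal(selu(0), 0)
  expect_equal(selu(1), 1.0507)
  expect_equal(selu(-20), -1.0507 * 1.67326, tolerance = 1e-6)
  eps <- 10^-(3:8)
  expect_true(all(abs(selu(eps) - selu(-eps)) < 10^-(2:7)))
  expect_equal(selu(2, lambda = 3, alpha = 1), 6)
})

test_that("attention layer reduces to X/|F| for zero weights and is linear in X", {
  m <- zeroAttentionModel(4)
  x <- c(1, 2, 3, 4)
  expect_equal(drop(omegaForward(x, m)), x / 4)
  expect_equal(drop(omegaForward(rep(0, 4), m)), rep(0, 4))
  set.seed(502)
  for (rep in 1:5) {
    x <- rnorm(4)
    expect_equal(drop(omegaForward(x, m)), x / 4, tolerance = 1e-12)
  }
})

test_that("two identical heads average to the single-head attention output", {
  m1 <- SARFtex:::initAttentionModel(paste0("f", 1:5), c("a", "b"), sanConfig(seed = 3))
  m2 <- SARFtex:::initAttentionModel(paste0("f", 1:5), c("a", "b"),
                           sanConfig(nHeads = 2, seed = 3))
  m2@weights$Watt <- list(m1@weights$Watt[[1]], m1@weights$Watt[[1]])
  m2@weights$batt <- list(m1@weights$batt[[1]], m1@weights$batt[[1]])
  x <- matrix(rnorm(10), 2, 5)
  expect_equal(omegaForward(x, m1), omegaForward(x, m2), tolerance = 1e-12)
})

test_that("forward pass returns proper probabilities, deterministically at inference", {
  m <- SARFtex:::initAttentionModel(paste0("f", 1:6), c("a", "b", "c"),
                          sanConfig(seed = 7))
  X <- matrix(rnorm(30), 5, 6)
  p1 <- sanForward(X, m)
  expect_equal(unname(rowSums(p1)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, sanForward(X, m))
  expect_identical(colnames(p1), c("a", "b", "c"))
  expect_error(sanForward(matrix(1, 2, 4), m), "feature columns")
})

test_that("analytic gradients agree with central finite differences", {
  d <- genTabular(nSamples = 12, nInformative = 2, nNoise = 2,
                  effectSize = 2, seed = 9)
  cfg <- sanConfig(epochs = 1, dropoutRate = 0, seed = 3)
  X <- as.matrix(d$features)
  cl <- sort(unique(d$labels))
  Y <- outer(d$labels, cl, "==") * 1
  m <- SARFtex:::initAttentionModel(colnames(X), cl, cfg,
                          center = apply(X, 2, min),
                          scale = apply(X, 2, max) - apply(X, 2, min))
  f <- SARFtex:::sanForwardFull(X, m, train = FALSE)
  g <- SARFtex:::sanBackward(f, Y, m@weights, m@config)
  lossAt <- function(w) {
    m@weights <- w
    P <- SARFtex:::sanForwardFull(X, m, train = FALSE)$P
    -mean(log(pmax(rowSums(P * Y), 1e-12)))
  }
  eps <- 1e-6
  checks <- list(list("Watt", 1, 2, 3), list("Watt", 1, 1, 1),
                 list("W1", NULL, 2, 4), list("Wout", NULL, 2, 3))
  for (cs in checks) {
    w <- m@weights
    bump <- function(delta) {
      if (cs[[1]] == "Watt") w$Watt[[cs[[2]]]][cs[[3]], cs[[4]]] <-
          w$Watt[[cs[[2]]]][cs[[3]], cs[[4]]] + delta
      else w[[cs[[1]]]][cs[[3]], cs[[4]]] <- w[[cs[[1]]]][cs[[3]], cs[[4]]] + delta
      w
    }
    numeric_g <- (lossAt(bump(eps)) - lossAt(bump(-eps))) / (2 * eps)
    analytic_g <- if (cs[[1]] == "Watt") g$Watt[[cs[[2]]]][cs[[3]], cs[[4]]]
      else g[[cs[[1]]]][cs[[3]], cs[[4]]]
    expect_equal(unname(analytic_g), numeric_g, tolerance = 1e-4)
  }
})

test_that("training is seed-deterministic and solves a separable problem", {
  d <- genTabular(nSamples = 80, nInformative = 2, nNoise = 3,
                  effectSize = 4, seed = 3)
  m1 <- trainSAN(d$features, d$labels, sanConfig(epochs = 30, seed = 5))
  m2 <- trainSAN(d$features, d$labels, sanConfig(epochs = 30, seed = 5))
  expect_identical(m1@weights, m2@weights)
  expect_identical(globalAttention(m1)$rg, globalAttention(m2)$rg)
  p <- sanForward(d$features, m1)
  acc <- mean(colnames(p)[max.col(p, ties.method = "first")] == d$labels)
  expect_gte(acc, 0.95)
  expect_length(m1@lossTrace, 30)
  expect_lt(tail(m1@lossTrace, 1), m1@lossTrace[1])
  expect_error(trainSAN(d$features, rep("one", 80), sanConfig()), "2 classes")
  expect_error(sanConfig(epochs = 0), "epochs")
})

test_that("global attention softmaxes the attention diagonal", {
  m <- zeroAttentionModel(5)
  expect_equal(unname(globalAttention(m)$rg), rep(0.2, 5))
  m2 <- zeroAttentionModel(2)
  diag(m2@weights$Watt[[1]]) <- c(log(3), 0)
  expect_equal(unname(globalAttention(m2)$rg), c(0.75, 0.25))
  m3 <- SARFtex:::initAttentionModel(paste0("f", 1:7), c("a", "b"), sanConfig(seed = 2))
  expect_equal(sum(globalAttention(m3)$rg), 1, tolerance = 1e-9)
})

test_that("residual fusion rescales as documented", {
  F <- c(a = 1, b = 2, c = 4)
  expect_equal(fuseFeatures(F, rep(1 / 3, 3)), 2 * F)
  oneHot <- c(0, 0, 1)
  expect_equal(unname(fuseFeatures(F, oneHot)), c(1, 2, 4 * (1 + 3)))
  expect_equal(unname(fuseFeatures(rep(0, 3), c(0.2, 0.3, 0.5))), rep(0, 3))
  expect_equal(unname(fuseFeatures(F, c(0.5, 0.25, 0.25), rescale = FALSE)),
               c(1.5, 2.5, 5))
  expect_error(fuseFeatures(F, c(0.5, 0.5)), "length")
})

test_that("attention models survive a JSON round trip", {
  d <- genTabular(nSamples = 40, seed = 5)
  for (k in c(1, 2)) {
    m <- trainSAN(d$features, d$labels,
                  sanConfig(epochs = 2, nHeads = k, seed = 9))
    path <- tempfile(fileext = ".json")
    writeAttentionModel(m, path)
    back <- readAttentionModel(path)
    expect_equal(sanForward(d$features, back), sanForward(d$features, m),
                 tolerance = 1e-12)
    expect_equal(globalAttention(back)$rg, globalAttention(m)$rg,
                 tolerance = 1e-12)
  }
})
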