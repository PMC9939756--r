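test_that("a forest separates thresholded data and is seed-reproducible", {
  set.seed(601)
  x <- data.frame(v = c(runif(30, 0, 0.4), runif(30, 0.6, 1)))
  y <- rep(c("lo", "hi"), each = 30)
  m <- fitForest(x, y, forestConfig(nTrees = 25, maxDepth = 4, seed = 2))
  expect_equal(mean(predict(m, x) == y), 1)
  hold <- data.frame(v = c(0.1, 0.9))
  m2 <- fitForest(x, y, forestConfig(nTrees = 25, maxDepth = 4, seed = 2))
  expect_identical(predict(m, hold), predict(m2, hold))
  expect_identical(predict(m, hold), c("lo", "hi"))
  expect_error(fitForest(x, rep("one", 60), forestConfig()), "2 classes")
})

test_that("vote fractions sum to one and labels are their argmax with lexicographic ties", {
  d <- genTabular(nSamples = 90, nInformative = 2, nNoise = 4,
                  nClasses = 3, effectSize = 1, seed = 11)
  m <- fitForest(d$features, d$labels, forestConfig(nTrees = 30, maxDepth = 3,
                                                    seed = 5))
  votes <- predict(m, d$features, type = "prob")
  expect_equal(unname(rowSums(votes)), rep(1, nrow(votes)), tolerance = 1e-12)
  labs <- predict(m, d$features)
  expect_identical(labs,
                   colnames(votes)[max.col(votes, ties.method = "first")])
  # single tree: vote of one, probabilities are 0/1
  m1 <- fitForest(d$features, d$labels, forestConfig(nTrees = 1, maxDepth = 3,
                                                     seed = 5))
  v1 <- predict(m1, d$features, type = "prob")
  expect_true(all(v1 %in% c(0, 1)))
  # column mismatch errors name the offending columns
  bad <- d$features; names(bad)[1] <- "zz"
  expect_error(predict(m, bad), "missing: f1")
})

test_that("out-of-bag permutation importance is zero for constants and ranks a label copy first", {
  set.seed(602)
  n <- 120
  labels <- rep(c("a", "b"), each = n / 2)
  feats <- data.frame(copy = as.integer(labels == "b") + rnorm(n, sd = 0.05),
                      const = rep(1.5, n),
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  m <- fitForest(feats, labels, forestConfig(nTrees = 40, maxDepth = 5,
                                             seed = 3))
  J <- oobImportance(m, feats, labels, seed = 4)
  expect_identical(unname(J["const"]), 0)
  expect_true(all(J["copy"] > J[c("n1", "n2", "n3")]))
  # determinism of the seeded permutations
  expect_identical(J, oobImportance(m, feats, labels, seed = 4))
  noOob <- fitForest(feats, labels, forestConfig(nTrees = 5, maxDepth = 3,
                                                 seed = 1, oob = FALSE))
  expect_error(oobImportance(noOob, feats, labels), "in-bag")
})

test_that("label-copy beats every noise feature across ten seeded runs", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 100
    labels <- rep(c("a", "b"), each = n / 2)
    feats <- data.frame(copy = as.integer(labels == "b") + rnorm(n, sd = 0.1),
                        n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    m <- fitForest(feats, labels, forestConfig(nTrees = 30, maxDepth = 5,
                                               seed = s))
    J <- oobImportance(m, feats, labels, seed = s)
    wins <- wins + all(J["copy"] > J[c("n1", "n2", "n3")])
  }
  expect_gte(wins, 9L)
})

test_that("duplicated informative features share importance but both beat the noise floor", {
  ok <- 0L
  for (s in 1:10) {
    set.seed(720 + s)
    n <- 120
    labels <- rep(c("a", "b"), each = n / 2)
    sig <- as.integer(labels == "b") + rnorm(n, sd = 0.15)
    feats <- data.frame(d1 = sig, d2 = sig, n1 = rnorm(n), n2 = rnorm(n),
                        n3 = rnorm(n))
    m <- fitForest(feats, labels, forestConfig(nTrees = 30, maxDepth = 5,
                                               seed = s))
    J <- oobImportance(m, feats, labels, seed = s)
    ok <- ok + (min(J[c("d1", "d2")]) >= min(J[c("n1", "n2", "n3")]))
  }
  expect_gte(ok, 9L)
})

test_that("grid search scores every candidate and breaks ties deterministically", {
  d <- genTabular(nSamples = 60, nInformative = 2, nNoise = 2,
                  effectSize = 3, seed = 21)
  gs <- gridSearchForest(d$features, d$labels, depthRange = c(2, 3),
                         treesRange = c(10, 15), nFolds = 3, seed = 8)
  expect_equal(nrow(gs$grid), 4)
  expect_equal(gs$bestAccuracy, max(gs$grid$meanAccuracy))
  # invariant to grid ordering
  gs2 <- gridSearchForest(d$features, d$labels, depthRange = c(3, 2),
                          treesRange = c(15, 10), nFolds = 3, seed = 8)
  expect_identical(gs$best, gs2$best)
  expect_identical(gs$grid, gs2$grid)
  one <- gridSearchForest(d$features, d$labels, 4, 12, nFolds = 3, seed = 8)
  expect_identical(unname(one$best), c(4L, 12L))
  # a fold that cannot contain every class is rejected
  idx <- c(1:3, 31)  # three of one class, one of the other
  expect_error(gridSearchForest(d$features[idx, ], d$labels[idx],
                                2, 10, nFolds = 3, seed = 1), "fold")
})

test_that("ties in mean CV accuracy resolve to the smallest depth then tree count", {
  d <- genTabular(nSamples = 40, nInformative = 1, nNoise = 1,
                  effectSize = 8, seed = 33)
  # fully separable: every candidate scores 1, tie-break must pick (2, 5)
  gs <- gridSearchForest(d$features, d$labels, depthRange = c(5, 2),
                         treesRange = c(9, 5), nFolds = 2, seed = 3)
  expect_equal(max(gs$grid$meanAccuracy), 1)
  expect_identical(unname(gs$best), c(2L, 5L))
})

test_that("SARF with uniform attention is prediction-identical to the plain forest", {
  d <- genTabular(nSamples = 120, nInformative = 3, nNoise = 5,
                  effectSize = 2, seed = 7)
  tr <- 1:80; te <- 81:120
  cfgF <- forestConfig(nTrees = 60, maxDepth = 8, seed = 4)
  sarf <- fitSARF(d$features[tr, ], d$labels[tr], sanCfg = NULL,
                  forestCfg = cfgF)
  plain <- fitForest(d$features[tr, ], d$labels[tr], cfgF)
  expect_identical(predict(sarf, d$features[te, ]),
                   predict(plain, d$features[te, ]))
  expect_equal(predict(sarf, d$features[te, ], type = "prob"),
               predict(plain, d$features[te, ], type = "prob"))
})

test_that("the fitted SARF pipeline is deterministic and separates synthetic classes", {
  d <- genTabular(nSamples = 150, nInformative = 3, nNoise = 7,
                  nClasses = 3, effectSize = 3, seed = 13)
  tr <- seq(1, 150, by = 3)
  te <- setdiff(seq_len(150), tr)
  fit1 <- fitSARF(d$features[tr, ], d$labels[tr],
                  sanConfig(epochs = 5, seed = 2),
                  forestConfig(nTrees = 50, maxDepth = 10, seed = 2))
  fit2 <- fitSARF(d$features[tr, ], d$labels[tr],
                  sanConfig(epochs = 5, seed = 2),
                  forestConfig(nTrees = 50, maxDepth = 10, seed = 2))
  expect_identical(predict(fit1, d$features[te, ]),
                   predict(fit2, d$features[te, ]))
  expect_identical(fit1@rg, fit2@rg)
  acc <- mean(predict(fit1, d$features[te, ]) == d$labels[te])
  expect_gt(acc, 0.9)
  # artifact round trip preserves predictions
  path <- tempfile(fileext = ".rds")
  writeSARFModel(fit1, path)
  expect_identical(predict(readSARFModel(path), d$features[te, ]),
                   predict(fit1, d$features[te, ]))
})
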