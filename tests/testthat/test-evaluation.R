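test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(counts(cm), matrix(c(1, 0, 1, 1), 2, 2,
                                  dimnames = list(c("A", "B"), c("A", "B"))))
  perfect <- confusionMatrix(c("x", "y", "z"), c("x", "y", "z"))
  expect_true(all(counts(perfect)[row(counts(perfect)) != col(counts(perfect))] == 0))
  expect_error(confusionMatrix(character(0), character(0)), "empty")
  expect_error(confusionMatrix("A", "C", classNames = c("A", "B")), "not in")
  expect_error(confusionMatrix(c("A", "B"), "A"), "length")
})

test_that("accuracy is the diagonal fraction and is permutation-invariant", {
  ref <- referenceConfusionMatrices()
  expect_equal(overallAccuracy(ref$binary), 100 * 8135 / 8373)
  perm <- counts(ref$eightClass)[8:1, 8:1]
  expect_equal(overallAccuracy(asConfusionMatrix(perm)),
               overallAccuracy(ref$eightClass))
  expect_error(overallAccuracy("x"))
})

test_that("one-vs-rest reductions always partition the total count", {
  ref <- referenceConfusionMatrices()
  for (cm in ref) {
    for (cl in classNames(cm)) {
      v <- perClassMetrics(cm, cl)
      expect_equal(sum(attr(v, "counts")), sum(counts(cm)))
    }
  }
  expect_error(perClassMetrics(ref$binary, "Unknown"), "unknown class")
})

test_that("degenerate denominators yield flagged NA, never 0 or 100", {
  m <- asConfusionMatrix(matrix(c(3, 0, 2, 0), 2, 2,
                                dimnames = list(c("A", "B"), c("A", "B"))))
  v <- perClassMetrics(m, "B")  # row B empty: TP+FN = 0
  expect_true(is.na(v[["sen"]]))
  expect_identical(attr(v, "undefined"), "sen")
  all100 <- perClassMetrics(asConfusionMatrix(diag(c(2, 3))), "C1")
  expect_equal(as.numeric(all100), rep(100, 4))
})

test_that("metric reports serialize to JSON with the full matrix and counts", {
  rep <- metricReport(referenceConfusionMatrices()$threeClass)
  expect_equal(nrow(rep$perClass), 3)
  expect_equal(rep$n, 1412)
  path <- tempfile(fileext = ".json")
  writeMetricsJSON(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$confusion, unname(rep$confusion))
  expect_equal(back$perClass$sen, rep$perClass$sen)
})

test_that("ROC curves match hand-computed and degenerate cases", {
  r <- rocCurve(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3))
  expect_equal(r$auc, 0.75)
  sep <- rocCurve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auc, 1)
  tied <- rocCurve(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$fpr, c(0, 1)); expect_equal(tied$tpr, c(0, 1))
  expect_error(rocCurve(c(1, 1), c(0.2, 0.4)), "both classes")
  # curve is monotone from (0,0) to (1,1)
  set.seed(801)
  rr <- rocCurve(rbinom(30, 1, 0.5) == 1, rnorm(30))
  expect_true(all(diff(rr$fpr) >= 0) && all(diff(rr$tpr) >= 0))
  expect_equal(c(rr$fpr[1], rr$tpr[1]), c(0, 0))
  expect_equal(c(tail(rr$fpr, 1), tail(rr$tpr, 1)), c(1, 1))
})

test_that("trapezoidal AUC equals the Mann-Whitney concordance oracle", {
  set.seed(802)
  for (rep in 1:12) {
    n <- sample(6:50, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    expect_equal(rocCurve(truth, scores)$auc, mannWhitneyAUC(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(803)
  for (rep in 1:5) {
    n <- 40
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    scores <- rnorm(n)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocCurve(truth, scores)$auc, ref, tolerance = 1e-10)
  }
})

test_that("micro-average ROC equals the flattened binary construction", {
  set.seed(804)
  n <- 30; cls <- c("a", "b", "c")
  truth <- sample(cls, n, replace = TRUE)
  raw <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, cls))
  proba <- raw / rowSums(raw)
  micro <- microAverageROC(truth, proba)
  flatTruth <- as.vector(outer(truth, cls, "=="))
  flatScore <- as.vector(proba)
  expect_equal(micro$auc, mannWhitneyAUC(flatTruth, flatScore),
               tolerance = 1e-12)
  # perfect one-hot probabilities give AUC 1; uniform gives 0.5
  onehot <- outer(truth, cls, "==") * 1; colnames(onehot) <- cls
  expect_equal(microAverageROC(truth, onehot)$auc, 1)
  unif <- matrix(1 / 3, n, 3, dimnames = list(NULL, cls))
  expect_equal(microAverageROC(truth, unif)$auc, 0.5)
  expect_error(microAverageROC(truth, proba[, 1:2], classNames = cls), "columns")
})
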