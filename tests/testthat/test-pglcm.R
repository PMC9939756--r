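test_that("pyramid levels follow ceil-halving and preserve constants", {
  pyr <- buildPyramid(randomGrayImage(8, 8, 255L), 3)
  expect_identical(lapply(pyr, dim),
                   list(c(8L, 8L), c(4L, 4L), c(2L, 2L)))
  odd <- buildPyramid(randomGrayImage(11, 7, 255L), 2)
  expect_identical(dim(odd[[2]]), c(6L, 4L))
  img <- randomGrayImage(5, 5)
  expect_identical(buildPyramid(img, 1)[[1]], img)
  flat <- GrayImage(matrix(37, 16, 16))
  for (lvl in buildPyramid(flat, 3))
    expect_true(all(pixels(lvl) == 37))
  expect_error(buildPyramid(randomGrayImage(4, 4), 3), "level")
})

test_that("quantization bins uniformly and preserves order", {
  img8 <- randomGrayImage(4, 4, 255L)
  expect_identical(pixels(quantizeImage(img8, 256)), pixels(img8))
  two <- quantizeImage(GrayImage(matrix(c(0, 255), 1, 2)), 2)
  expect_identical(as.vector(pixels(two)), c(0, 1))
  expect_identical(maxLevel(two), 1L)
  q4 <- quantizeImage(GrayImage(matrix(c(0, 100, 200, 255), 2, 2)), 4)
  expect_identical(sort(as.vector(pixels(q4))), c(0, 1, 3, 3))
  expect_error(quantizeImage(img8, 1), "at least 2")
})

test_that("GLCM matches hand-enumerated small cases", {
  flat <- GrayImage(matrix(2, 4, 4), maxLevel = 3L)
  g <- glcmProbs(computeGLCM(flat, 1, 0))
  expect_equal(g[3, 3], 1)
  expect_equal(sum(g), 1)
  checker <- GrayImage(matrix(c(0, 1, 1, 0), 2, 2), maxLevel = 1L)
  expect_equal(glcmProbs(computeGLCM(checker, 1, 0)),
               matrix(c(0, 0.5, 0.5, 0), 2, 2))
  row <- GrayImage(matrix(c(0, 0, 1), 1, 3), maxLevel = 1L)
  expect_equal(glcmProbs(computeGLCM(row, 1, 0, symmetric = FALSE)),
               matrix(c(0.5, 0, 0.5, 0), 2, 2))
  expect_error(computeGLCM(row, 5, 0), "no pixel pairs")
})

test_that("GLCM equals the brute-force pair enumeration oracle", {
  set.seed(401)
  for (rep in 1:6) {
    img <- randomGrayImage(sample(4:16, 1), sample(4:16, 1),
                           maxLevel = sample(c(3L, 7L), 1))
    for (ang in c(0, 45, 90, 135)) for (d in 1:3) {
      if (d >= min(dim(img))) next
      for (sym in c(TRUE, FALSE)) {
        expect_equal(glcmProbs(computeGLCM(img, d, ang, symmetric = sym)),
                     bruteGLCM(img, d, ang, symmetric = sym),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("normalized GLCMs sum to one and symmetric GLCMs equal their transpose", {
  set.seed(402)
  for (rep in 1:5) {
    img <- randomGrayImage(10, 10, 7L)
    g <- computeGLCM(img, sample(1:3, 1), sample(c(0, 45, 90, 135), 1))
    expect_equal(sum(glcmProbs(g)), 1, tolerance = 1e-9)
    expect_identical(glcmProbs(g), t(glcmProbs(g)))
  }
})

test_that("rotating an image by 90 degrees exchanges the 0- and 90-degree GLCMs", {
  set.seed(403)
  for (rep in 1:4) {
    img <- randomGrayImage(9, 9, 7L)
    rot <- rotateImage(img, 1)
    for (d in 1:2) {
      expect_equal(glcmProbs(computeGLCM(rot, d, 0)),
                   glcmProbs(computeGLCM(img, d, 90)))
      expect_equal(glcmProbs(computeGLCM(rot, d, 90)),
                   glcmProbs(computeGLCM(img, d, 0)))
    }
  }
})

test_that("Haralick statistics match hand-evaluated matrices", {
  diagG <- new("GLCMMatrix", probs = diag(c(0.5, 0.5)), distance = 1L,
               angle = 0L, level = -1L, symmetric = TRUE, normalized = TRUE)
  h <- haralickStats(diagG)
  expect_equal(unname(h), c(0, 1, 0.5, 1))
  single <- new("GLCMMatrix", probs = matrix(c(1, 0, 0, 0), 2, 2),
                distance = 1L, angle = 0L, level = -1L, symmetric = TRUE,
                normalized = TRUE)
  expect_equal(unname(haralickStats(single)), c(0, 1, 1, 1))
  anti <- new("GLCMMatrix", probs = matrix(c(0, 0.5, 0.5, 0), 2, 2),
              distance = 1L, angle = 0L, level = -1L, symmetric = TRUE,
              normalized = TRUE)
  expect_equal(unname(haralickStats(anti)), c(1, -1, 0.5, 0.5))
  raw <- new("GLCMMatrix", probs = matrix(1, 2, 2), distance = 1L,
             angle = 0L, level = -1L, symmetric = TRUE, normalized = FALSE)
  expect_error(haralickStats(raw), "normalized")
})

test_that("Haralick statistics stay within their theoretical ranges", {
  set.seed(404)
  for (rep in 1:20) {
    h <- haralickStats(randomGLCMMatrix(sample(2:8, 1)))
    expect_gte(h[["contrast"]], 0)
    expect_gt(h[["energy"]], 0); expect_lte(h[["energy"]], 1)
    expect_gt(h[["homogeneity"]], 0); expect_lte(h[["homogeneity"]], 1)
    expect_gte(h[["correlation"]], -1); expect_lte(h[["correlation"]], 1)
  }
})

test_that("feature vectors have the documented length, names and degenerate values", {
  cfg <- pglcmConfig(nLevels = 3, distances = c(1, 2), quantLevels = 8)
  f <- extractFeatures(randomGrayImage(16, 16, 255L), cfg)
  expect_length(f, 2 * 4 * 2 * 4)
  expect_identical(names(f), pglcmFeatureNames(cfg))
  expect_true("i=1, 0° std contrast" %in% names(f))
  expect_false(anyDuplicated(names(f)) > 0)
  flat <- extractFeatures(GrayImage(matrix(50, 16, 16)), cfg)
  expect_true(all(flat[grepl("mean contrast", names(flat))] == 0))
  expect_true(all(flat[grepl("std", names(flat))] == 0))
})

test_that("dataset extraction is deterministic and CSV round-trip stable", {
  man <- tinyGratingManifest(nPerClass = 2, seed = 31, size = 16L)
  cfg <- pglcmConfig(nLevels = 2, distances = 1, quantLevels = 8)
  t1 <- extractDataset(man, cfg)
  t2 <- extractDataset(man, cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4)
  expect_identical(names(t1), c(pglcmFeatureNames(cfg), "label"))
  csv <- tempfile(fileext = ".csv")
  writeFeatureTable(t1, csv, cfg)
  back <- readFeatureTable(csv)
  expect_identical(names(back), names(t1))
  expect_equal(back[, 1:8], t1[, 1:8], tolerance = 1e-12)
  expect_true(file.exists(paste0(csv, ".meta")))
  # unreadable images are reported per row, all-failed aborts
  broken <- man; broken$path <- paste0(man$path, ".missing")
  expect_error(extractDataset(broken, cfg), "every image")
  half <- man; half$path[1] <- paste0(half$path[1], ".missing")
  expect_warning(out <- extractDataset(half, cfg), "failed for 1")
  expect_equal(nrow(out), 3)
})
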