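# Independent oracles used to cross-check the implementation.

# Brute-force GLCM: explicit double loop over every pixel and its offset
# neighbor, independent of the vectorized implementation.
bruteGLCM <- function(img, distance, angle, symmetric = TRUE,
                      normalize = TRUE) {
  p <- pixels(img)
  off <- switch(as.character(angle),
    "0" = c(0, distance), "45" = c(-distance, distance),
    "90" = c(-distance, 0), "135" = c(-distance, -distance))
  L <- maxLevel(img) + 1
  m <- matrix(0, L, L)
  for (r in seq_len(nrow(p))) for (cc in seq_len(ncol(p))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(p) && c2 >= 1 && c2 <= ncol(p)) {
      i <- p[r, cc] + 1; j <- p[r2, c2] + 1
      m[i, j] <- m[i, j] + 1
      if (symmetric) m[j, i] <- m[j, i] + 1
    }
  }
  if (normalize) m <- m / sum(m)
  m
}

# Mann-Whitney pairwise-concordance AUC (ties counted 1/2).
mannWhitneyAUC <- function(truth, scores) {
  pos <- scores[truth == 1 | truth == TRUE]
  neg <- scores[truth == 0 | truth == FALSE]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(pos) * length(neg))
}

randomGrayImage <- function(h, w, maxLevel = 7L) {
  GrayImage(matrix(sample(0:maxLevel, h * w, replace = TRUE), h, w),
            maxLevel = as.integer(maxLevel))
}

# Random normalized (optionally symmetric) GLCM for property tests.
randomGLCMMatrix <- function(L, symmetric = TRUE) {
  m <- matrix(stats::runif(L * L), L, L)
  if (symmetric) m <- m + t(m)
  m <- m / sum(m)
  new("GLCMMatrix", probs = m, distance = 1L, angle = 0L, level = -1L,
      symmetric = symmetric, normalized = TRUE)
}

writeTestPGM <- function(img, path, binary = FALSE) {
  if (binary) {
    con <- file(path, "wb")
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(pixels(img)), nrow(pixels(img)),
                      maxLevel(img)), con, eos = NULL)
    writeBin(as.integer(t(pixels(img))), con, size = 1L)
    close(con)
  } else {
    writeLines(c("P2", sprintf("%d %d", ncol(pixels(img)), nrow(pixels(img))),
                 as.character(maxLevel(img)),
                 paste(t(pixels(img)), collapse = " ")), path)
  }
  path
}

tinyGratingManifest <- function(nPerClass = 8, seed = 7, size = 32L) {
  specs <- list(
    textureClassSpec("horiz", "oriented-grating", orientation = 0,
                     nImages = nPerClass, imageSize = c(size, size)),
    textureClassSpec("vert", "oriented-grating", orientation = 90,
                     nImages = nPerClass, imageSize = c(size, size)))
  genTextureDataset(specs, seed = seed)
}
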