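#' Gaussian image pyramid
#'
#' Level 0 is the input; each further level is the Gaussian-smoothed,
#' 2x-downsampled previous level with dimensions `ceiling(previous / 2)`.
#' Smoothing uses a separable Gaussian (sigma = 2/3, the usual choice for
#' a downscale factor of 2) with edge-clamped borders, so constant images
#' stay exactly constant; smoothed values are rounded back to integers.
#'
#' @param img a [GrayImage-class].
#' @param nLevels number of pyramid levels (>= 1).
#' @return List of [GrayImage-class] objects, coarsest last.
#' @examples
#' pyr <- buildPyramid(GrayImage(matrix(0:63, 8, 8)), 3)
#' vapply(pyr, dim, integer(2))  # 8x8, 4x4, 2x2
#' @export
buildPyramid <- function(img, nLevels) {
  stopifnot(is(img, "GrayImage"))
  if (nLevels < 1L) stopf("nLevels must be at least 1")
  out <- vector("list", nLevels)
  out[[1]] <- img
  for (l in seq_len(nLevels - 1L)) {
    prev <- out[[l]]
    if (any(ceiling(dim(prev) / 2) < 2L))
      stopf("image too small for pyramid level %d (would fall below 2 x 2)", l)
    sm <- gaussianSmooth(pixels(prev), sigma = 2 / 3)
    ds <- sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2), drop = FALSE]
    out[[l + 1L]] <- GrayImage(round(clipRange(ds, 0, maxLevel(prev))),
                               maxLevel(prev))
  }
  out
}

# Separable Gaussian convolution with edge clamping (replicated borders).
gaussianSmooth <- function(p, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(( -r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  convolve1 <- function(m, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    acc <- 0
    for (o in -r:r) {
      idx <- clipRange(seq_len(n) + o, 1, n)
      shifted <- if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
      acc <- acc + k[o + r + 1L] * shifted
    }
    acc
  }
  convolve1(convolve1(p, 1), 2)
}

#' Uniform gray-level quantization
#'
#' Bins `[0, maxLevel]` uniformly into `levels` bins
#' (`floor(v * levels / (maxLevel + 1))`); order-preserving, returns a
#' GrayImage with `maxLevel = levels - 1`.
#'
#' @param img a [GrayImage-class].
#' @param levels number of output gray levels (>= 2).
#' @return Quantized [GrayImage-class].
#' @examples
#' q <- quantizeImage(GrayImage(matrix(c(0, 100, 200, 255), 2, 2)), 4)
#' sort(unique(as.vector(pixels(q))))  # 0 1 3
#' @export
quantizeImage <- function(img, levels) {
  stopifnot(is(img, "GrayImage"))
  if (levels < 2L) stopf("quantization levels must be at least 2")
  p <- pixels(img)
  q <- pmin(floor(p * levels / (maxLevel(img) + 1)), levels - 1L)
  GrayImage(q, as.integer(levels - 1L))
}

# Offset convention (row, col displacement) for the four GLCM directions:
#   0 deg -> ( 0, +d)   horizontal neighbor
#  45 deg -> (-d, +d)   up-right diagonal
#  90 deg -> (-d,  0)   vertical neighbor
# 135 deg -> (-d, -d)   up-left diagonal
glcmOffset <- function(distance, angle) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stopf("angle must be one of 0, 45, 90, 135 (got %s)", angle))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of gray-level pairs `(i, j)` between each pixel
#' and its neighbor at the given (distance, angle) offset. With
#' `symmetric = TRUE` both pair orders are counted; with
#' `normalize = TRUE` the counts are scaled to joint probabilities.
#'
#' @param img a quantized [GrayImage-class] (levels = `maxLevel + 1`).
#' @param distance offset magnitude in pixels (>= 1).
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @param symmetric count both pair orders (default TRUE).
#' @param normalize scale entries to sum to 1 (default TRUE).
#' @param level pyramid level tag stored in the result (metadata only).
#' @return A [GLCMMatrix-class].
#' @examples
#' checker <- GrayImage(matrix(c(0, 1, 1, 0), 2, 2), maxLevel = 1)
#' glcmProbs(computeGLCM(checker, 1, 0))  # anti-diagonal 0.5s
#' @export
computeGLCM <- function(img, distance, angle, symmetric = TRUE,
                        normalize = TRUE, level = -1L) {
  stopifnot(is(img, "GrayImage"))
  if (distance < 1L) stopf("distance must be at least 1")
  off <- glcmOffset(as.integer(distance), angle)
  p <- pixels(img)
  h <- nrow(p); w <- ncol(p)
  rows <- seq_len(h); cols <- seq_len(w)
  r2 <- rows + off[1]; c2 <- cols + off[2]
  rok <- rows[r2 >= 1 & r2 <= h]; cok <- cols[c2 >= 1 & c2 <= w]
  if (length(rok) == 0L || length(cok) == 0L)
    stopf("offset (d=%d, %d deg) admits no pixel pairs in a %d x %d image",
          distance, angle, h, w)
  a <- p[rok, cok, drop = FALSE]
  b <- p[rok + off[1], cok + off[2], drop = FALSE]
  L <- maxLevel(img) + 1L
  idx <- a * L + b + 1  # row-major (i = first pixel, j = neighbor)
  cnt <- tabulate(idx, nbins = L * L)
  if (symmetric) cnt <- cnt + tabulate(b * L + a + 1, nbins = L * L)
  m <- matrix(cnt, nrow = L, ncol = L, byrow = TRUE)
  if (normalize) m <- m / sum(m)
  new("GLCMMatrix", probs = m, distance = as.integer(distance),
      angle = as.integer(angle), level = as.integer(level),
      symmetric = symmetric, normalized = normalize)
}

#' Haralick statistics of a normalized GLCM
#'
#' Four scalar texture summaries of a co-occurrence distribution
#' `p(i, j)` over gray levels `i, j = 0, ..., L-1`:
#' \describe{
#'   \item{contrast}{`sum p(i,j) (i-j)^2` — local intensity variation.}
#'   \item{correlation}{`sum p(i,j)(i-mu_x)(j-mu_y) / (sigma_x sigma_y)`,
#'     defined as 1 when either marginal variance is zero (a constant
#'     image is perfectly self-correlated).}
#'   \item{energy}{`sum p(i,j)^2`, the angular second moment (not its
#'     square root).}
#'   \item{homogeneity}{`sum p(i,j) / (1 + (i-j)^2)`.}
#' }
#'
#' @param glcm a normalized [GLCMMatrix-class].
#' @return Named numeric vector `c(contrast, correlation, energy,
#'   homogeneity)`.
#' @export
haralickStats <- function(glcm) {
  stopifnot(is(glcm, "GLCMMatrix"))
  if (!glcm@normalized) stopf("haralickStats requires a normalized GLCM")
  p <- glcmProbs(glcm)
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)          # row index = first gray level
  j <- t(i)
  contrast <- sum(p * (i - j)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + (i - j)^2))
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(L - 1)) * px); muy <- sum((0:(L - 1)) * py)
  vx <- sum((0:(L - 1) - mux)^2 * px); vy <- sum((0:(L - 1) - muy)^2 * py)
  correlation <- if (vx * vy <= 0) 1 else
    sum(p * (i - mux) * (j - muy)) / sqrt(vx * vy)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' PGLCM extraction configuration
#'
#' @param nLevels pyramid levels (default 3).
#' @param quantLevels gray levels after quantization (default 16).
#' @param distances pixel offsets (default `c(1, 2, 4)`).
#' @param angles directions in degrees (default `c(0, 45, 90, 135)`).
#' @param symmetric symmetric GLCMs (default TRUE).
#' @return List of class `"PGLCMConfig"`.
#' @export
pglcmConfig <- function(nLevels = 3L, quantLevels = 16L,
                        distances = c(1L, 2L, 4L),
                        angles = c(0L, 45L, 90L, 135L), symmetric = TRUE) {
  if (nLevels < 1L) stopf("nLevels must be >= 1")
  if (quantLevels < 2L) stopf("quantLevels must be >= 2")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stopf("angles must be drawn from {0, 45, 90, 135}")
  structure(list(nLevels = as.integer(nLevels),
                 quantLevels = as.integer(quantLevels),
                 distances = as.integer(distances),
                 angles = as.integer(angles), symmetric = symmetric),
            class = "PGLCMConfig")
}

#' Feature names for a PGLCM configuration
#'
#' Names follow the `"i=<distance>, <angle>° <aggregate> <statistic>"`
#' template, e.g. `"i=1, 0° std contrast"`: the standard deviation,
#' across pyramid levels, of the contrast at distance 1 in the 0-degree
#' direction. Order: distance (outer), angle, statistic, aggregate
#' (mean before std).
#'
#' @param config a [pglcmConfig()].
#' @return Character vector of length
#'   `2 * 4 * length(distances) * length(angles)`.
#' @export
pglcmFeatureNames <- function(config) {
  stats <- c("contrast", "correlation", "energy", "homogeneity")
  out <- character(0)
  for (d in config$distances)
    for (a in config$angles)
      for (s in stats)
        for (agg in c("mean", "std"))
          out <- c(out, sprintf("i=%d, %d\u00b0 %s %s", d, a, agg, s))
  out
}

#' Multi-scale fusion texture features of one image
#'
#' Builds the Gaussian pyramid, quantizes every level, computes the GLCM
#' and its four Haralick statistics for each (distance, angle) at each
#' level, and fuses across levels by taking the mean and standard
#' deviation of each statistic over the pyramid. Deterministic for a
#' fixed image and configuration.
#'
#' @param img a [GrayImage-class].
#' @param config a [pglcmConfig()].
#' @return Named numeric feature vector (names from
#'   [pglcmFeatureNames()]).
#' @export
extractFeatures <- function(img, config = pglcmConfig()) {
  stopifnot(is(img, "GrayImage"), inherits(config, "PGLCMConfig"))
  pyr <- buildPyramid(img, config$nLevels)
  qlv <- lapply(pyr, quantizeImage, levels = config$quantLevels)
  stats <- c("contrast", "correlation", "energy", "homogeneity")
  vals <- numeric(0)
  for (d in config$distances) {
    for (a in config$angles) {
      perLevel <- vapply(seq_along(qlv), function(l)
        haralickStats(computeGLCM(qlv[[l]], d, a,
                                  symmetric = config$symmetric,
                                  level = l - 1L)),
        numeric(4))
      for (s in seq_along(stats)) {
        x <- perLevel[s, ]
        vals <- c(vals, mean(x), if (length(x) > 1L) stats::sd(x) else 0)
      }
    }
  }
  names(vals) <- pglcmFeatureNames(config)
  vals
}

#' Feature table for a labeled image set
#'
#' Applies [extractFeatures()] to every manifest row. Per-image read or
#' extraction failures are collected and reported together (the run
#' aborts only if every image fails); failed rows are dropped with a
#' warning.
#'
#' @param manifest data.frame with columns `path`, `label`.
#' @param config a [pglcmConfig()].
#' @return data.frame: one row per image, feature columns named as in
#'   [pglcmFeatureNames()], plus a final `label` column.
#' @export
extractDataset <- function(manifest, config = pglcmConfig()) {
  stopifnot(is.data.frame(manifest), all(c("path", "label") %in% names(manifest)))
  feats <- vector("list", nrow(manifest))
  errs <- character(0)
  for (r in seq_len(nrow(manifest))) {
    feats[[r]] <- tryCatch(extractFeatures(loadImage(manifest$path[r]), config),
                           error = function(e) {
                             errs <<- c(errs, sprintf("%s: %s", manifest$path[r],
                                                      conditionMessage(e)))
                             NULL
                           })
  }
  ok <- !vapply(feats, is.null, logical(1))
  if (!any(ok)) stopf("feature extraction failed for every image:\n%s",
                      paste(errs, collapse = "\n"))
  if (length(errs)) warnf("feature extraction failed for %d image(s):\n%s",
                          length(errs), paste(errs, collapse = "\n"))
  tab <- as.data.frame(do.call(rbind, feats[ok]), check.names = FALSE)
  tab$label <- manifest$label[ok]
  tab
}

#' Write / read a feature table as CSV
#'
#' The header keeps the generated feature names verbatim (UTF-8); the
#' final column is `label`. A sidecar `<path>.meta` key-value text file
#' records the extraction configuration.
#'
#' @param table feature data.frame from [extractDataset()].
#' @param path output CSV path.
#' @param config optional [pglcmConfig()] echoed into the sidecar file.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path, config = NULL) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(config)) {
    meta <- c(sprintf("nLevels=%d", config$nLevels),
              sprintf("quantLevels=%d", config$quantLevels),
              sprintf("distances=%s", paste(config$distances, collapse = ",")),
              sprintf("angles=%s", paste(config$angles, collapse = ",")),
              sprintf("symmetric=%s", config$symmetric))
    writeLines(meta, paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}
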