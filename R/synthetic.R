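#' Texture class specification
#'
#' Describes one synthetic texture class for [genTextureDataset()].
#' Generators (all seeded, all with additive Gaussian pixel noise):
#' \describe{
#'   \item{oriented-grating}{sinusoidal grating at a given orientation
#'     and period; its co-occurrence contrast is strongly
#'     direction-dependent, so classes differing in orientation separate
#'     in the angle-specific features.}
#'   \item{gaussian-random-field}{white noise smoothed at a correlation
#'     length, an isotropic texture.}
#'   \item{checker}{square checkerboard of a given period.}
#' }
#'
#' @param name class label.
#' @param kind one of `"oriented-grating"`, `"gaussian-random-field"`,
#'   `"checker"`.
#' @param orientation grating orientation in degrees (0 = horizontal
#'   stripes varying along columns).
#' @param period stripe/checker period or correlation length, pixels.
#' @param amplitude contrast amplitude in gray levels (0..127).
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param nImages images to generate for this class.
#' @param imageSize `c(height, width)`.
#' @return List of class `"TextureClassSpec"`.
#' @export
textureClassSpec <- function(name, kind = c("oriented-grating",
                                            "gaussian-random-field",
                                            "checker"),
                             orientation = 0, period = 8, amplitude = 100,
                             noiseSd = 8, nImages = 10L,
                             imageSize = c(64L, 64L)) {
  kind <- match.arg(kind)
  if (!nzchar(name)) stopf("texture class name must be non-empty")
  if (nImages < 1L) stopf("nImages must be >= 1")
  if (period <= 0) stopf("period must be positive")
  if (amplitude < 0 || amplitude > 127) stopf("amplitude must lie in [0, 127]")
  if (any(imageSize < 8L)) stopf("imageSize must be at least 8 x 8")
  structure(list(name = name, kind = kind, orientation = orientation,
                 period = period, amplitude = amplitude, noiseSd = noiseSd,
                 nImages = as.integer(nImages),
                 imageSize = as.integer(imageSize)),
            class = "TextureClassSpec")
}

genTextureImage <- function(spec) {
  h <- spec$imageSize[1]; w <- spec$imageSize[2]
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  base <- switch(spec$kind,
    "oriented-grating" = {
      th <- spec$orientation * pi / 180
      phase <- stats::runif(1, 0, 2 * pi)
      127.5 + spec$amplitude *
        sin(2 * pi * (c_ * cos(th) + r * sin(th)) / spec$period + phase)
    },
    "gaussian-random-field" = {
      z <- matrix(stats::rnorm(h * w), h, w)
      s <- gaussianSmooth(z, sigma = spec$period / 2)
      127.5 + spec$amplitude * s / max(stats::sd(s), 1e-9) / 3
    },
    "checker" = {
      off <- sample.int(spec$period, 1)
      phase <- (floor((r + off) / spec$period) +
                  floor((c_ + off) / spec$period)) %% 2
      127.5 + spec$amplitude * (2 * phase - 1)
    })
  noisy <- base + stats::rnorm(h * w, sd = spec$noiseSd)
  GrayImage(round(clipRange(noisy, 0, 255)), 255L)
}

#' Generate a labeled synthetic texture dataset
#'
#' Writes seeded synthetic textured images (PNG) for each class spec and
#' a manifest CSV (`path,label`). Identical seeds produce byte-identical
#' images.
#'
#' @param specs list of [textureClassSpec()] objects with distinct names
#'   (>= 2).
#' @param seed integer master seed.
#' @param outputDir directory for the images and `manifest.csv`.
#' @return The manifest data.frame (columns `path`, `label`); the
#'   manifest CSV path is attached as attribute `"manifestPath"`.
#' @export
genTextureDataset <- function(specs, seed,
                              outputDir = tempfile("textures")) {
  if (length(specs) < 2L) stopf("need at least 2 texture class specs")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stopf("texture class names must be distinct")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    set.seed(childSeed(seed, s))
    paths <- character(spec$nImages)
    for (i in seq_len(spec$nImages)) {
      img <- genTextureImage(spec)
      paths[i] <- file.path(outputDir,
                            sprintf("%s_%03d.png", make.names(spec$name), i))
      writeImagePNG(img, paths[i])
    }
    rows[[s]] <- data.frame(path = paths, label = spec$name,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(outputDir, "manifest.csv")
  writeManifest(manifest, mpath)
  attr(manifest, "manifestPath") <- mpath
  manifest
}

#' Generate seeded tabular features with a known informative subset
#'
#' The first `nInformative` features are drawn from class-shifted unit
#' normals (class c mean = `c * effectSize` in sd units, centered across
#' classes); the remaining `nNoise` features are class-independent
#' standard normals. The ground-truth informative index set is returned
#' for attention/importance recovery tests.
#'
#' @param nSamples total samples (split evenly across classes).
#' @param nInformative number of label-linked features m (>= 1).
#' @param nNoise number of pure-noise features.
#' @param nClasses number of classes (>= 2).
#' @param effectSize class-mean separation in sd units.
#' @param seed integer seed.
#' @return List: `features` (data.frame `f1..f<m+n>`), `labels`
#'   (character `"c1"..`), `informative` (integer indices).
#' @export
genTabular <- function(nSamples = 200L, nInformative = 3L, nNoise = 17L,
                       nClasses = 2L, effectSize = 3, seed = 1L) {
  if (nInformative < 1L) stopf("nInformative must be >= 1")
  if (nClasses < 2L) stopf("nClasses must be >= 2")
  if (nSamples < 2L * nClasses) stopf("too few samples for %d classes", nClasses)
  set.seed(childSeed(seed, 2L))
  labels <- sort(rep_len(sprintf("c%d", seq_len(nClasses)), nSamples))
  classIdx <- as.integer(sub("c", "", labels))
  shift <- (classIdx - (nClasses + 1) / 2) * effectSize
  nf <- nInformative + nNoise
  X <- matrix(stats::rnorm(nSamples * nf), nSamples, nf)
  for (j in seq_len(nInformative)) X[, j] <- X[, j] + shift
  colnames(X) <- sprintf("f%d", seq_len(nf))
  list(features = as.data.frame(X), labels = labels,
       informative = seq_len(nInformative))
}

#' Published benchmark confusion matrices
#'
#' The three confusion matrices reported for PGLCM-SARF texture
#' classification of the BreaKHis (binary and eight-subtype
#' histopathology) and MIAS (three-class mammography) benchmarks,
#' bundled as worked examples for the metric suite.
#'
#' @return Named list of [ConfusionMatrix-class] objects:
#'   `binary` (Malignant/Benign), `eightClass` (eight BreaKHis tumor
#'   subtypes), `threeClass` (MIAS Malignant/Benign/Normal).
#' @examples
#' overallAccuracy(referenceConfusionMatrices()$binary)
#' @export
referenceConfusionMatrices <- function() {
  bin <- matrix(c(3944, 186,
                  52, 4191), 2, 2, byrow = TRUE,
                dimnames = list(c("Malignant", "Benign"),
                                c("Malignant", "Benign")))
  cls8 <- c("PC", "MC", "LC", "DC", "TA", "PT", "F", "A")
  eight <- matrix(c(
    973,    0,    0,    2,    0,    0,    0,    0,
      4, 1035,    3,   13,    0,    2,    1,    0,
      0,    0, 1043,   43,    0,    0,    0,    2,
     53,   92,  121,  580,   49,   39,   67,   49,
      0,    0,    0,    3, 1005,    0,    0,    0,
      0,    0,    0,    0,    0, 1109,    0,    0,
      6,   11,    9,   10,    4,    5,  981,    1,
      0,    0,    0,    0,    0,    0,    0, 1058),
    8, 8, byrow = TRUE, dimnames = list(cls8, cls8))
  cls3 <- c("Malignant", "Benign", "Normal")
  three <- matrix(c(490, 0, 0,
                    0, 444, 0,
                    9, 8, 461), 3, 3, byrow = TRUE,
                  dimnames = list(cls3, cls3))
  list(binary = asConfusionMatrix(bin),
       eightClass = asConfusionMatrix(eight),
       threeClass = asConfusionMatrix(three))
}
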