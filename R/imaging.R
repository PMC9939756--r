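#' Read an image file into a GrayImage
#'
#' Reads PNG, PGM (ASCII `P2` or binary `P5`) and JPEG files. RGB inputs
#' are converted to luminance with the ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B, rounded) when `asGray = TRUE`; reading an
#' RGB file with `asGray = FALSE` returns the raw height x width x 3
#' integer array instead of a GrayImage.
#'
#' @param path path to an existing PNG/PGM/JPEG file.
#' @param asGray convert color inputs to grayscale (default TRUE).
#' @param lumaWeights length-3 RGB luminance weights; default BT.601.
#' @return A [GrayImage-class] (or an integer array for `asGray = FALSE`
#'   on color input).
#' @examples
#' p <- tempfile(fileext = ".png")
#' png::writePNG(matrix(c(0, 1, 1, 0), 2, 2), p)
#' loadImage(p)
#' @export
loadImage <- function(path, asGray = TRUE,
                      lumaWeights = c(0.299, 0.587, 0.114)) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stopf("cannot read PNG %s: %s", path,
                                             conditionMessage(e))),
    pgm = return(readPGM(path)),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stopf("JPEG support requires the EBImage package")
      img <- tryCatch(EBImage::readImage(path),
                      error = function(e) stopf("cannot read JPEG %s: %s",
                                                path, conditionMessage(e)))
      a <- EBImage::imageData(img)
      # EBImage stores images width x height; transpose to rows x cols
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stopf("unsupported image format '%s' (expect png/pgm/jpg)", ext)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L && asGray) {
      g <- lumaWeights[1] * arr[, , 1] + lumaWeights[2] * arr[, , 2] +
        lumaWeights[3] * arr[, , 3]
      dim(g) <- dim(arr)[1:2]
      return(GrayImage(round(g * 255), 255L))
    }
    if (dim(arr)[3] >= 3L) return(array(as.integer(round(arr * 255)),
                                        dim = c(dim(arr)[1:2], 3L)))
    d2 <- dim(arr)[1:2]
    arr <- arr[, , 1]  # single-channel stored with a channel axis
    dim(arr) <- d2
  }
  GrayImage(round(arr * 255), 255L)
}

# PGM reader: plain (P2) and raw (P5), maxval up to 65535.
readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || !nzchar(ch)) stopf("truncated PGM header: %s", path)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) return(tok) else next }
      tok <- paste0(tok, ch)
    }
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P5")) stopf("not a PGM file (magic %s): %s", magic, path)
  w <- suppressWarnings(as.integer(readToken()))
  h <- suppressWarnings(as.integer(readToken()))
  maxval <- suppressWarnings(as.integer(readToken()))
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stopf("corrupt PGM header: %s", path)
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxval < 256L) as.integer(readBin(con, "integer", n, size = 1L,
                                          signed = FALSE))
    else readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stopf("truncated PGM pixel data: %s", path)
  GrayImage(matrix(vals, nrow = h, ncol = w, byrow = TRUE),
            maxLevel = maxval)
}

#' Write a GrayImage as PNG
#'
#' @param img a [GrayImage-class].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  stopifnot(is(img, "GrayImage"))
  png::writePNG(pixels(img) / maxLevel(img), path)
  invisible(path)
}

#' Lossless quarter-turn rotation
#'
#' Rotates counter-clockwise by `quarterTurns` x 90 degrees. Only multiples
#' of 90 degrees are supported: they permute pixels without interpolation,
#' so the intensity multiset is preserved exactly.
#'
#' @param img a [GrayImage-class].
#' @param quarterTurns integer in `{0, 1, 2, 3}` (counter-clockwise).
#' @return The rotated [GrayImage-class].
#' @examples
#' img <- GrayImage(matrix(1:4, 2, 2, byrow = TRUE))
#' pixels(rotateImage(img, 1))
#' @export
rotateImage <- function(img, quarterTurns) {
  stopifnot(is(img, "GrayImage"))
  if (length(quarterTurns) != 1L || !quarterTurns %in% 0:3)
    stopf("quarterTurns must be 0, 1, 2 or 3 (only lossless 90-degree rotations are supported)")
  p <- pixels(img)
  q <- switch(as.character(quarterTurns),
    "0" = p,
    "1" = t(p)[rev(seq_len(ncol(p))), , drop = FALSE],        # ccw
    "2" = p[rev(seq_len(nrow(p))), rev(seq_len(ncol(p))), drop = FALSE],
    "3" = t(p)[, rev(seq_len(nrow(p))), drop = FALSE])
  GrayImage(q, maxLevel(img))
}

#' Mirror an image
#'
#' @param img a [GrayImage-class].
#' @param axis `"horizontal"` (left-right mirror) or `"vertical"`
#'   (top-bottom mirror). Applying the same flip twice is the identity.
#' @return The flipped [GrayImage-class].
#' @export
flipImage <- function(img, axis = c("horizontal", "vertical")) {
  stopifnot(is(img, "GrayImage"))
  axis <- match.arg(axis)
  p <- pixels(img)
  q <- if (axis == "horizontal") p[, rev(seq_len(ncol(p))), drop = FALSE]
       else p[rev(seq_len(nrow(p))), , drop = FALSE]
  GrayImage(q, maxLevel(img))
}

#' Photometric enhancement
#'
#' Adjust brightness, color, contrast or sharpness by a positive factor,
#' with factor 1 the exact identity (Pillow-style semantics):
#' \describe{
#'   \item{brightness}{intensities scaled by `factor`, clipped.}
#'   \item{contrast}{interpolation between the image mean and the image:
#'     `mean + factor * (img - mean)`; uniform images are fixed points.}
#'   \item{color}{interpolation between the luminance image and the
#'     original; the identity for grayscale input.}
#'   \item{sharpness}{interpolation between a 3x3 box-smoothed image and
#'     the original: factors above 1 sharpen, below 1 blur.}
#' }
#' Results are rounded and clipped to `[0, maxLevel]`.
#'
#' @param img a [GrayImage-class], or an h x w x 3 integer RGB array
#'   (0..255) for the `color` kind.
#' @param kind one of `"brightness"`, `"color"`, `"contrast"`, `"sharpness"`.
#' @param factor positive real; 1 is the identity for every kind.
#' @return Enhanced image of the same type as the input.
#' @examples
#' img <- GrayImage(matrix(100, 4, 4))
#' pixels(enhanceImage(img, "brightness", 1.2))[1, 1]  # 120
#' @export
enhanceImage <- function(img, kind = c("brightness", "color", "contrast",
                                       "sharpness"), factor = 1.2) {
  kind <- match.arg(kind)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stopf("enhancement factor must be a positive number")
  if (is.array(img) && length(dim(img)) == 3L) {
    return(enhanceRGB(img, kind, factor))
  }
  stopifnot(is(img, "GrayImage"))
  if (factor == 1) return(img)
  p <- pixels(img); mx <- maxLevel(img)
  q <- switch(kind,
    brightness = p * factor,
    contrast = mean(p) + factor * (p - mean(p)),
    color = p,  # chromaticity of a grayscale image is the identity
    sharpness = {
      s <- boxSmooth3(p)
      s + factor * (p - s)
    })
  GrayImage(round(clipRange(q, 0, mx)), mx)
}

enhanceRGB <- function(arr, kind, factor) {
  if (factor == 1) return(arr)
  a <- array(as.numeric(arr), dim = dim(arr))
  out <- switch(kind,
    brightness = a * factor,
    contrast = {
      lum <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      m <- mean(round(lum))
      m + factor * (a - m)
    },
    color = {
      lum <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      g <- array(lum, dim = dim(a))
      g + factor * (a - g)
    },
    sharpness = {
      s <- a
      for (ch in 1:3) s[, , ch] <- boxSmooth3(a[, , ch])
      s + factor * (a - s)
    })
  array(as.integer(round(clipRange(out, 0, 255))), dim = dim(arr))
}

# 3x3 box mean with edge clamping (each pixel averages its in-bounds
# 3x3 neighborhood, replicating borders).
boxSmooth3 <- function(p) {
  h <- nrow(p); w <- ncol(p)
  up <- p[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- p[c(seq_len(h)[-1], h), , drop = FALSE]
  v <- p + up + dn
  lf <- v[, c(1, seq_len(w - 1)), drop = FALSE]
  rt <- v[, c(seq_len(w)[-1], w), drop = FALSE]
  (v + lf + rt) / 9
}

#' Augmentation specification
#'
#' The pool of lossless/photometric operators [balanceDataset()] samples
#' from when synthesizing additional images for under-represented classes.
#'
#' @param rotations integer quarter-turn counts to sample from.
#' @param flips subset of `c("horizontal", "vertical")`.
#' @param enhancements data.frame with columns `kind` and `factor`, one
#'   row per enhancement operator; defaults to the four kinds at
#'   factor 1.2.
#' @return A list of class `"AugmentationSpec"`.
#' @export
augmentationSpec <- function(rotations = 1:3,
                             flips = c("horizontal", "vertical"),
                             enhancements = data.frame(
                               kind = c("brightness", "color", "contrast",
                                        "sharpness"),
                               factor = 1.2)) {
  if (!is.null(enhancements) && nrow(enhancements) > 0) {
    if (any(enhancements$factor <= 0))
      stopf("enhancement factors must be positive")
  }
  ops <- character(0)
  for (r in rotations) ops <- c(ops, sprintf("rot%d", as.integer(r)))
  for (f in flips) ops <- c(ops, sprintf("flip-%s", f))
  if (!is.null(enhancements))
    for (i in seq_len(nrow(enhancements)))
      ops <- c(ops, sprintf("%s%.3g", enhancements$kind[i],
                            enhancements$factor[i]))
  structure(list(rotations = as.integer(rotations), flips = flips,
                 enhancements = enhancements, opNames = ops),
            class = "AugmentationSpec")
}

applyAugmentation <- function(img, op) {
  if (grepl("^rot", op)) return(rotateImage(img, as.integer(sub("rot", "", op))))
  if (grepl("^flip-", op)) return(flipImage(img, sub("flip-", "", op)))
  kind <- sub("[0-9.]+$", "", op)
  factor <- as.numeric(sub("^[a-z]+", "", op))
  enhanceImage(img, kind, factor)
}

#' Balance a labeled image set by augmentation
#'
#' Expands every class of a manifest to exactly `targetPerClass` entries.
#' Originals are always retained; additional entries are augmentations of
#' uniformly sampled (seeded) originals, written as PNG next to
#' `outputDir` and recorded with provenance (`source` path and operator).
#'
#' @param manifest data.frame with columns `path`, `label`.
#' @param spec an [augmentationSpec()].
#' @param targetPerClass target count per class; must be at least the
#'   largest original class size.
#' @param seed integer seed making the sampling reproducible.
#' @param outputDir directory augmented images are written to.
#' @return The augmented manifest: columns `path`, `label`, `provenance`
#'   (`"original"` or `"<source>|<operator>"`).
#' @export
balanceDataset <- function(manifest, spec, targetPerClass, seed,
                           outputDir = tempfile("augmented")) {
  stopifnot(is.data.frame(manifest), all(c("path", "label") %in% names(manifest)))
  tab <- table(manifest$label)
  if (any(tab == 0) || nrow(manifest) == 0) stopf("empty class in manifest")
  if (targetPerClass < max(tab))
    stopf("targetPerClass (%d) below largest class size (%d)",
          targetPerClass, max(tab))
  needsExpansion <- any(tab < targetPerClass)
  if (needsExpansion && length(spec$opNames) == 0)
    stopf("augmentation spec has no operators but expansion is needed")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- data.frame(path = manifest$path, label = manifest$label,
                    provenance = "original", stringsAsFactors = FALSE)
  rows <- list(out)
  set.seed(childSeed(seed, 1L))
  for (cls in names(tab)) {
    deficit <- targetPerClass - tab[[cls]]
    if (deficit <= 0) next
    sources <- manifest$path[manifest$label == cls]
    pick <- sample.int(length(sources), deficit, replace = TRUE)
    ops <- sample(spec$opNames, deficit, replace = TRUE)
    newPaths <- character(deficit)
    for (i in seq_len(deficit)) {
      img <- loadImage(sources[pick[i]])
      aug <- applyAugmentation(img, ops[i])
      newPaths[i] <- file.path(outputDir,
                               sprintf("%s_aug%04d.png", make.names(cls), i))
      writeImagePNG(aug, newPaths[i])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      path = newPaths, label = cls,
      provenance = sprintf("%s|%s", sources[pick], ops),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read / write an image manifest
#'
#' A manifest is a CSV with columns `path,label` and optionally
#' `magnification` and `provenance`.
#'
#' @param path CSV file path.
#' @return `readManifest` returns the manifest data.frame.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stopf("manifest must have columns 'path' and 'label'")
  m
}

#' @rdname readManifest
#' @param manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
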