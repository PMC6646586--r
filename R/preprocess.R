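#' Geometry of the coarse and fine processing scales
#'
#' The coarse scale crops a central 128 px window (36 deg FOV) and reduces it
#' by two Gaussian-pyramid levels to 32 px, 1.125 deg/px; the fine scale
#' crops a central 64 px window (18 deg FOV) kept at full resolution,
#' 0.281 deg/px. Both are cut into 8 px patches with stride 4, giving
#' 49 and 225 patches per image.
#'
#' @param name `"coarse"` or `"fine"`.
#' @return a [ScaleConfig-class].
#' @examples
#' degPerPx(scaleConfig("coarse"))  # 1.125
#' nPatches(scaleConfig("fine"))    # 225
#' @export
scaleConfig <- function(name = c("coarse", "fine")) {
  name <- match.arg(name)
  if (name == "coarse")
    new("ScaleConfig", name = "coarse", windowPx = 128L, windowFovDeg = 36,
      downsampleFactor = 4L, outputPx = 32L, patchPx = 8L, stridePx = 4L)
  else
    new("ScaleConfig", name = "fine", windowPx = 64L, windowFovDeg = 18,
      downsampleFactor = 1L, outputPx = 64L, patchPx = 8L, stridePx = 4L)
}

#' Whitening/low-pass filter in the frequency domain
#'
#' Multiplies the image spectrum by `R(f) = f exp(-(f/f0)^n)` with `f` the
#' radial frequency in cycles per image, measured relative to the image
#' width (for the 320 x 240 camera frames, "96 cycles/image" means 96 cycles
#' per 320 px). The linear ramp removes the 1/f correlation structure of
#' natural input (the DC component maps to zero) while the smooth cutoff at
#' `f0` suppresses pixel noise, emulating the retinal ganglion-cell
#' transfer function.
#'
#' @param image numeric gray matrix.
#' @param f0 cutoff frequency, cycles per image (width); default 96.
#' @param n steepness exponent; default 4.
#' @return real-valued filtered matrix of the same size.
#' @export
whitenImage <- function(image, f0 = 96, n = 4) {
  if (any(!is.finite(image))) stop("non-finite input image")
  if (f0 <= 0 || n < 1) stop("require f0 > 0 and n >= 1")
  key <- paste("wh", nrow(image), ncol(image), f0, n, sep = "_")
  gain <- .renderCache[[key]]
  if (is.null(gain)) {
    f <- radialFreq(nrow(image), ncol(image), relTo = ncol(image))
    gain <- f * exp(-(f / f0)^n)
    .renderCache[[key]] <- gain
  }
  Re(fft(fft(image) * gain, inverse = TRUE)) / length(image)
}

## One Gaussian-pyramid reduction: 5-tap binomial blur [1,4,6,4,1]/16
## (borders replicated), then factor-2 decimation.
pyramidReduce <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad <- function(m) m[c(1, 1, seq_len(nrow(m)), nrow(m), nrow(m)), ]
  conv1 <- function(m) {   # filter along rows dimension
    p <- pad(m)
    k[1] * p[seq_len(nrow(m)), ] + k[2] * p[seq_len(nrow(m)) + 1, ] +
      k[3] * p[seq_len(nrow(m)) + 2, ] + k[4] * p[seq_len(nrow(m)) + 3, ] +
      k[5] * p[seq_len(nrow(m)) + 4, ]
  }
  sm <- t(conv1(t(conv1(img))))
  sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2)]
}

centralCrop <- function(img, side) {
  r0 <- (nrow(img) - side) %/% 2
  c0 <- (ncol(img) - side) %/% 2
  img[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)]
}

#' Extract the coarse and fine scale images from a whitened camera frame
#'
#' @param image a whitened 240 x 320 frame.
#' @return list with `coarse` (32 x 32, two pyramid reductions of the central
#'   128 px window) and `fine` (64 x 64 central crop).
#' @export
extractScales <- function(image) {
  stopifnot(all(dim(image) == c(240L, 320L)))
  coarse <- pyramidReduce(pyramidReduce(centralCrop(image, 128L)))
  fine <- centralCrop(image, 64L)
  list(coarse = coarse, fine = fine)
}

#' Cut normalized patches from a scale image
#'
#' Slides an 8 x 8 window with stride 4 over the image in row-major grid
#' order and normalizes every patch to zero mean and unit norm. Patches that
#' are uniform (norm below `1e-8` after mean subtraction) are kept as all
#' zeros rather than amplifying numerical noise.
#'
#' @param image numeric matrix, side >= `patch`.
#' @param patch patch side, pixels.
#' @param stride grid stride, pixels.
#' @param normalize normalize patches (zero mean, unit norm)?
#' @return numeric matrix `patch^2 x nPatches`, one column-major vectorised
#'   patch per column.
#' @export
cutPatches <- function(image, patch = 8L, stride = 4L, normalize = TRUE) {
  n <- nrow(image)
  stopifnot(n >= patch, ncol(image) >= patch)
  starts <- seq(1L, n - patch + 1L, by = stride)
  cstarts <- seq(1L, ncol(image) - patch + 1L, by = stride)
  out <- matrix(0, patch * patch, length(starts) * length(cstarts))
  k <- 0L
  for (r in starts) for (cc in cstarts) {   # row-major grid order
    k <- k + 1L
    out[, k] <- image[r:(r + patch - 1L), cc:(cc + patch - 1L)]
  }
  if (normalize) {
    out <- sweep(out, 2, colMeans(out))
    nrm <- sqrt(colSums(out^2))
    good <- nrm >= 1e-8
    out[, good] <- sweep(out[, good, drop = FALSE], 2, nrm[good], "/")
    out[, !good] <- 0
  }
  out
}

## Positions of the four 8 x 8 subfields inside a vectorised 16 x 16 patch.
subfieldIndex <- local({
  m <- matrix(seq_len(256), 16, 16)
  list(leftPrev = as.vector(m[1:8, 1:8]), leftT = as.vector(m[1:8, 9:16]),
    rightPrev = as.vector(m[9:16, 1:8]), rightT = as.vector(m[9:16, 9:16]))
})

#' Assemble binocular spatio-temporal patches
#'
#' Combines, per grid position, the four normalized 8 x 8 subfields into one
#' 16 x 16 spatio-temporal binocular patch: rows 1-8 left eye, rows 9-16
#' right eye; columns 1-8 time t-1, columns 9-16 time t. The assembled patch
#' is not re-normalized, so a patch with four non-degenerate subfields has
#' squared norm 4.
#'
#' @param leftT,rightT,leftPrev,rightPrev `64 x N` patch matrices from
#'   [cutPatches()], same grid.
#' @return numeric matrix `256 x N` of vectorised 16 x 16 patches.
#' @export
assemblePatches <- function(leftT, rightT, leftPrev, rightPrev) {
  n <- ncol(leftT)
  if (ncol(rightT) != n || ncol(leftPrev) != n || ncol(rightPrev) != n)
    stop("patch lists must have equal length")
  out <- matrix(0, 256, n)
  out[subfieldIndex$leftPrev, ] <- leftPrev
  out[subfieldIndex$leftT, ] <- leftT
  out[subfieldIndex$rightPrev, ] <- rightPrev
  out[subfieldIndex$rightT, ] <- rightT
  out
}

#' Preprocess two consecutive binocular frames into patch sets
#'
#' Runs the full preprocessing chain: whitening of each 320 x 240 frame,
#' extraction of the coarse and fine scale images, patch cutting with
#' per-subfield normalization and spatio-temporal assembly.
#'
#' @param prev,cur [ImagePair-class] frames at times t-1 and t.
#' @param f0,n whitening parameters, see [whitenImage()].
#' @return list with elements `coarse` (256 x 49) and `fine` (256 x 225).
#' @export
preprocessPair <- function(prev, cur, f0 = 96, n = 4) {
  patchSetsFromScales(framePatches(prev, f0, n), framePatches(cur, f0, n))
}

#' Whiten one binocular frame and cut its normalized per-scale patches
#'
#' The monocular, single-time half of [preprocessPair()]; its results can be
#' cached so that in a running simulation each frame is whitened and cut
#' only once.
#'
#' @param pair an [ImagePair-class].
#' @inheritParams whitenImage
#' @return nested list `[eye][scale]` of `64 x N` normalized patch matrices.
#' @export
framePatches <- function(pair, f0 = 96, n = 4) {
  lapply(list(left = pair@left, right = pair@right), function(im) {
    lapply(extractScales(whitenImage(im, f0, n)), cutPatches)
  })
}

#' @rdname framePatches
#' @param prevPatches,curPatches [framePatches()] results at t-1 and t.
#' @return `patchSetsFromScales()` returns the [preprocessPair()] list.
#' @export
patchSetsFromScales <- function(prevPatches, curPatches) {
  one <- function(scale) assemblePatches(
    leftT = curPatches$left[[scale]], rightT = curPatches$right[[scale]],
    leftPrev = prevPatches$left[[scale]],
    rightPrev = prevPatches$right[[scale]])
  list(coarse = one("coarse"), fine = one("fine"))
}
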