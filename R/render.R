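## Pinhole-camera homography renderer replacing the robot-simulator stage:
## two cameras at (+-baseline/2, 0, 0) with 90 deg horizontal FOV and
## 320 x 240 output, version (pan/tilt) rotations applied to both and the
## vergence angle split symmetrically (each camera toed in by vergence/2).

.renderCache <- new.env(parent = emptyenv())

## Unit-less camera-frame ray directions for every pixel, 3 x (W*H),
## pixels in column-major order of the output matrix (rows vary fastest).
cameraRays <- function(width = 320L, height = 240L, fovDeg = 90) {
  key <- paste(width, height, fovDeg, sep = "x")
  if (!is.null(.renderCache[[key]])) return(.renderCache[[key]])
  f <- (width / 2) / tan(fovDeg / 2 * pi / 180)
  col <- rep(seq_len(width), each = height)
  row <- rep(seq_len(height), times = width)
  x <- (col - 1 - (width - 1) / 2) / f
  y <- -(row - 1 - (height - 1) / 2) / f   # image rows grow downwards
  rays <- rbind(x, y, rep(1, width * height))
  .renderCache[[key]] <- rays
  rays
}

rotYaw <- function(deg) {   # positive yaw turns the gaze towards +x
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rotPitch <- function(deg) { # positive pitch turns the gaze towards +y (up)
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3)
}

## Bilinear texture lookup; u, v in [0, 1] (v = 0 is the top row);
## out-of-range coordinates clamp to the texture edge.
bilinearSample <- function(tex, u, v, clamp = TRUE) {
  n <- nrow(tex); m <- ncol(tex)
  if (clamp) {
    u <- pmin(pmax(u, 0), 1)
    v <- pmin(pmax(v, 0), 1)
  }
  x <- u * (m - 1) + 1
  y <- v * (n - 1) + 1
  x0 <- pmin(floor(x), m - 1); y0 <- pmin(floor(y), n - 1)
  dx <- x - x0; dy <- y - y0
  i00 <- (x0 - 1) * n + y0
  i01 <- i00 + n       # x0+1, y0
  i10 <- i00 + 1       # x0,   y0+1
  i11 <- i01 + 1
  tex[i00] * (1 - dx) * (1 - dy) + tex[i01] * dx * (1 - dy) +
    tex[i10] * (1 - dx) * dy + tex[i11] * dx * dy
}

renderEye <- function(world, eyes, side, width, height, fovDeg) {
  s <- if (side == "left") 1 else -1
  pos <- c(-s * eyes@baseline / 2, 0, 0)
  R <- rotYaw(eyes@pan + s * eyes@vergence / 2) %*% rotPitch(eyes@tilt)
  D <- R %*% cameraRays(width, height, fovDeg)
  dz <- pmax(D[3, ], 1e-9)

  zs <- world@depth
  xs <- zs * tan(world@azimuth * pi / 180)
  ys <- zs * tan(world@elevation * pi / 180)
  t <- (zs - pos[3]) / dz
  X <- pos[1] + t * D[1, ]
  Y <- pos[2] + t * D[2, ]
  half <- world@size / 2
  hit <- t > 0 & abs(X - xs) <= half & abs(Y - ys) <= half

  zb <- world@backgroundDistance
  bgHalf <- 2 * zb      # covers the frustum for all admissible eye poses
  img <- numeric(length(dz))
  miss <- !hit
  if (any(miss)) {
    tb <- (zb - pos[3]) / dz[miss]
    Xb <- pos[1] + tb * D[1, miss]
    Yb <- tb * D[2, miss]
    img[miss] <- bilinearSample(pixels(world@background),
      (Xb + bgHalf) / (2 * bgHalf), (bgHalf - Yb) / (2 * bgHalf))
  }
  if (any(hit))
    img[hit] <- bilinearSample(pixels(world@stimulus),
      (X[hit] - xs + half) / world@size, (ys - Y[hit] + half) / world@size,
      clamp = FALSE)
  list(img = matrix(img, height, width), visible = any(hit))
}

#' Render one binocular frame
#'
#' Projects the stimulus and background planes into both pinhole cameras.
#' Rendering is deterministic: identical world and pose give bit-identical
#' images. If the stimulus is outside both frusta the images show only the
#' background and the `visible` attribute of the result is `FALSE`.
#'
#' @param world a [WorldState-class].
#' @param eyes an [EyePose-class].
#' @param timestamp iteration index stored in the frame.
#' @param width,height,fovDeg camera geometry (320 x 240, 90 deg horizontal).
#' @return an [ImagePair-class]; `attr(, "visible")` reports per-eye
#'   stimulus visibility.
#' @export
renderBinocular <- function(world, eyes, timestamp = 0L, width = 320L,
                            height = 240L, fovDeg = 90) {
  L <- renderEye(world, eyes, "left", width, height, fovDeg)
  R <- renderEye(world, eyes, "right", width, height, fovDeg)
  out <- new("ImagePair", left = L$img, right = R$img,
    timestamp = as.integer(timestamp))
  attr(out, "visible") <- c(left = L$visible, right = R$visible)
  out
}

#' Project the stimulus centre into both cameras
#'
#' Closed-form pinhole projection used as the geometric oracle for disparity:
#' returns the sub-pixel image coordinates (column, row) of the stimulus
#' plane centre in each camera. The horizontal disparity in pixels is
#' `col_left - col_right`.
#'
#' @inheritParams renderBinocular
#' @return list with `left` and `right` numeric(2) `(col, row)` coordinates
#'   and `disparity`, the horizontal disparity in pixels.
#' @export
projectStimulusCenter <- function(world, eyes, width = 320L, height = 240L,
                                  fovDeg = 90) {
  f <- (width / 2) / tan(fovDeg / 2 * pi / 180)
  zs <- world@depth
  P <- c(zs * tan(world@azimuth * pi / 180),
    zs * tan(world@elevation * pi / 180), zs)
  one <- function(side) {
    s <- if (side == "left") 1 else -1
    pos <- c(-s * eyes@baseline / 2, 0, 0)
    R <- rotYaw(eyes@pan + s * eyes@vergence / 2) %*% rotPitch(eyes@tilt)
    q <- crossprod(R, P - pos)   # world -> camera frame
    if (q[3] <= 0) return(c(NA_real_, NA_real_))
    c((width - 1) / 2 + f * q[1] / q[3] + 1,
      (height - 1) / 2 - f * q[2] / q[3] + 1)
  }
  l <- one("left"); r <- one("right")
  list(left = l, right = r, disparity = unname(l[1] - r[1]))
}

#' Measure the central horizontal disparity of a rendered frame pair
#'
#' Cross-correlates a central window of the left image against
#' horizontally shifted windows of the right image and locates the best
#' integer shift, refined to sub-pixel precision by parabolic interpolation.
#' Serves as the measurement half of the rendering disparity oracle.
#'
#' @param pair an [ImagePair-class].
#' @param window side of the central window, pixels.
#' @param maxShift maximum horizontal shift searched, pixels.
#' @return disparity estimate in pixels (positive when the left image's
#'   content sits further right than the right image's).
#' @export
centerDisparity <- function(pair, window = 64L, maxShift = 40L) {
  imL <- pair@left; imR <- pair@right
  h <- nrow(imL); w <- ncol(imL)
  r0 <- (h - window) %/% 2; c0 <- (w - window) %/% 2
  rows <- (r0 + 1):(r0 + window)
  colsL <- (c0 + 1):(c0 + window)
  patchL <- imL[rows, colsL]
  patchL <- patchL - mean(patchL)
  shifts <- -maxShift:maxShift
  score <- vapply(shifts, function(s) {
    cols <- colsL - s
    if (min(cols) < 1 || max(cols) > w) return(-Inf)
    pr <- imR[rows, cols]
    pr <- pr - mean(pr)
    den <- sqrt(sum(patchL^2) * sum(pr^2))
    if (den < 1e-12) return(-Inf)
    sum(patchL * pr) / den
  }, numeric(1))
  i <- which.max(score)
  d <- shifts[i]
  if (i > 1 && i < length(shifts) && is.finite(score[i - 1]) &&
      is.finite(score[i + 1])) {
    denom <- score[i - 1] - 2 * score[i] + score[i + 1]
    if (abs(denom) > 1e-12)
      d <- d + 0.5 * (score[i - 1] - score[i + 1]) / denom
  }
  d
}
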