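#' @importFrom stats rnorm runif fft coef lm median quantile sd optim
NULL

## Evaluate expr with a temporarily seeded RNG, restoring global state after.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Radial frequency map in cycles per image (relative to side n), matrix n x n.
radialFreq <- function(nr, nc = nr, relTo = max(nr, nc)) {
  fy <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr * relTo
  fx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc * relTo
  sqrt(outer(fy^2, fx^2, "+"))
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < 1e-12) return(matrix(0.5, nrow(x), ncol(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Generate a stimulus texture
#'
#' Procedural stand-ins for natural "man made" scene photographs, emulating
#' two robust statistics of such images: an approximately 1/f amplitude
#' spectrum and oriented step edges with horizontal and vertical orientations
#' over-represented relative to obliques.
#'
#' * `pink_noise`: Gaussian noise shaped to a 1/f amplitude spectrum.
#' * `edges`: superposition of smoothed step edges whose orientations favour
#'   0 and 90 degrees (60 percent cardinal, jittered) on a pink-noise bed.
#' * `blocks`: a "Mondrian" of axis-aligned gray rectangles, giving strong
#'   horizontal/vertical edge content.
#' * `file`: read a PGM (P2/P5) image file, gray values scaled to \[0, 1\].
#'
#' @param seed integer seed; generation is fully reproducible and leaves the
#'   global RNG state untouched.
#' @param kind one of `"pink_noise"`, `"edges"`, `"blocks"`, `"file"`.
#' @param side side length in pixels (default 600, the stimulus resolution).
#' @param path file path, for `kind = "file"`.
#' @return a [Texture-class].
#' @examples
#' tx <- makeTexture(1, "pink_noise", side = 256)
#' spectralSlope(tx)  # close to -1
#' @export
makeTexture <- function(seed, kind = c("pink_noise", "edges", "blocks", "file"),
                        side = 600, path = NULL) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  px <- switch(kind,
    pink_noise = withSeed(seed, pinkNoiseField(side)),
    edges = withSeed(seed, edgeField(side)),
    blocks = withSeed(seed, blockField(side)),
    file = readPgm(path))
  new("Texture", pixels = px, kind = kind, seed = seed)
}

pinkNoiseField <- function(side) {
  w <- matrix(rnorm(side^2), side, side)
  f <- radialFreq(side)
  amp <- 1 / pmax(f, 1)
  amp[1, 1] <- 0
  x <- Re(fft(fft(w) * amp, inverse = TRUE)) / side^2
  rescale01(x)
}

edgeField <- function(side, nEdges = 40) {
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  img <- 0.35 * (pinkNoiseField(side) - 0.5)
  for (i in seq_len(nEdges)) {
    th <- if (runif(1) < 0.6) {
      sample(c(0, 90), 1) + rnorm(1, 0, 2)
    } else runif(1, 0, 180)
    thr <- th * pi / 180
    ## signed distance to a line through a random point at orientation th
    cx <- runif(1, 1, side); cy <- runif(1, 1, side)
    d <- (xy$x - cx) * cos(thr) + (xy$y - cy) * sin(thr)
    a <- sample(c(-1, 1), 1) * runif(1, 0.1, 0.5)
    img <- img + a * tanh(d / 1.5)
  }
  rescale01(matrix(img, side, side))
}

blockField <- function(side, nBlocks = 60) {
  img <- matrix(0.5, side, side)
  for (i in seq_len(nBlocks)) {
    w <- round(runif(2, side / 20, side / 3))
    x0 <- round(runif(1, 1, side - w[1])); y0 <- round(runif(1, 1, side - w[2]))
    img[y0:(y0 + w[2] - 1), x0:(x0 + w[1] - 1)] <- runif(1)
  }
  img
}

#' Read a PGM image (binary P5 or ASCII P2)
#'
#' @param path path to a `.pgm` file.
#' @return numeric matrix of gray values in \[0, 1\].
#' @export
readPgm <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("texture file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE))
    stop("PNG input is not supported in this build; convert to PGM")
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  nc <- as.integer(readToken()); nr <- as.integer(readToken())
  maxv <- as.integer(readToken())
  n <- nr * nc
  vals <- if (magic == "P5") {
    if (maxv < 256) as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE))
    else as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
      endian = "big"))
  } else {
    scan(con, what = numeric(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM data")
  matrix(vals / maxv, nr, nc, byrow = TRUE)
}

#' Slope of the radially averaged amplitude spectrum
#'
#' Least-squares slope of log amplitude against log radial frequency over the
#' mid-frequency range (8 cycles/image to a quarter of the side). Natural
#' images and the `pink_noise` generator give slopes near -1.
#'
#' @param texture a [Texture-class] or gray matrix.
#' @return the fitted slope (dimensionless).
#' @export
spectralSlope <- function(texture) {
  px <- if (is(texture, "Texture")) pixels(texture) else texture
  n <- nrow(px)
  a <- Mod(fft(px - mean(px)))
  f <- radialFreq(n)
  keep <- f >= 8 & f <= n / 4
  fb <- round(f[keep])
  amp <- tapply(a[keep], fb, mean)
  fr <- as.numeric(names(amp))
  unname(coef(lm(log(amp) ~ log(fr)))[2])
}

#' Orientation energy histogram of a texture
#'
#' Distributes spectral energy (DC and very low frequencies excluded) over
#' orientation bins. Orientation is that of the image structure: 0 degrees
#' means vertical edges (horizontal frequency content), 90 degrees horizontal
#' edges. Axis-aligned textures such as `blocks` put their largest bins at 0
#' and 90 degrees.
#'
#' @param texture a [Texture-class] or gray matrix.
#' @param nBins number of orientation bins over \[0, 180).
#' @return named numeric vector of energies; names are bin centres in degrees.
#' @export
orientationEnergy <- function(texture, nBins = 8) {
  px <- if (is(texture, "Texture")) pixels(texture) else texture
  n <- nrow(px)
  a2 <- Mod(fft(px - mean(px)))^2
  fy <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  fx <- fy
  FY <- matrix(fy, n, n)     # row frequency (vertical)
  FX <- t(FY)                # column frequency (horizontal)
  f <- sqrt(FX^2 + FY^2)
  keep <- f >= 4 & f <= n / 2
  ## structure orientation = angle of the frequency vector for gratings:
  ## vertical edges modulate along x -> angle 0.
  ang <- (atan2(FY[keep], FX[keep]) * 180 / pi) %% 180
  binw <- 180 / nBins
  bin <- floor(((ang + binw / 2) %% 180) / binw) + 1
  e <- vapply(seq_len(nBins), function(b) sum(a2[keep][bin == b]), numeric(1))
  names(e) <- (seq_len(nBins) - 1) * binw
  e
}
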