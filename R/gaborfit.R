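## Gabor receptive-field fitting. The fit maximizes the squared correlation
## between the (unit-normalized) subfield and a Gabor with analytically
## optimal amplitude, i.e. minimizes the fraction of unexplained energy.
## Multi-start: candidate (lambda, theta) pairs from an FFT peak estimate
## plus a grid, each with a correlation-optimal phase, the best few refined
## by box-bounded quasi-Newton and polished by Nelder-Mead.

.gaborLower <- c(lambda = 2, theta = -360, psi = -720, sigma = 0.5,
  beta = 0.1, xc = -2, yc = -2)
.gaborUpper <- c(lambda = 32, theta = 540, psi = 1080, sigma = 10,
  beta = 6, xc = 10, yc = 10)

gaborResidualFraction <- function(p, y, side = 8L) {
  g <- gaborFunction(p, side)
  gn2 <- sum(g * g)
  if (!is.finite(gn2) || gn2 < 1e-12) return(1)
  v <- 1 - sum(y * g)^2 / gn2
  if (!is.finite(v)) 1 else v
}

## Correlation-optimal phase (deg) for fixed remaining parameters: the
## Gabor is cos(psi) * [env cos(phase)] - sin(psi) * [env sin(phase)], so the
## best psi solves a 2 x 2 generalized eigenproblem.
optimalPhase <- function(p, y, side = 8L) {
  pc <- p; pc["psi"] <- 0
  gc <- gaborFunction(pc, side)
  ps <- p; ps["psi"] <- -90
  gs <- gaborFunction(ps, side)      # env * sin(phase)
  a <- sum(y * gc); b <- sum(y * gs)
  M <- rbind(c(a * a, -a * b), c(-a * b, b * b))
  G <- rbind(c(sum(gc * gc), -sum(gc * gs)), c(-sum(gc * gs), sum(gs * gs)))
  ev <- tryCatch(eigen(solve(G, M)), error = function(e) NULL)
  if (is.null(ev)) return(0)
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  atan2(v[2], v[1]) * 180 / pi
}

## (lambda, theta) start from the peak of the zero-padded 2D spectrum.
fftStart <- function(y, side = 8L, pad = 32L) {
  Y <- matrix(0, pad, pad)
  Y[1:side, 1:side] <- matrix(y, side, side)
  A <- Mod(fft(Y))
  fr <- c(0:(pad / 2), -(pad / 2 - 1):-1) / pad
  FY <- matrix(fr, pad, pad)   # row (y) frequency
  FX <- t(FY)                  # column (x) frequency
  A[FX == 0 & FY == 0] <- 0
  i <- which.max(A)
  f <- sqrt(FX[i]^2 + FY[i]^2)
  c(lambda = min(max(1 / max(f, 1 / pad), 2), 32),
    theta = (atan2(FY[i], FX[i]) * 180 / pi) %% 180)
}

#' Fit a 2D Gabor function to a subfield
#'
#' Nonlinear least squares over (lambda, theta, psi, sigma, beta, xc, yc)
#' with an analytically optimal amplitude, box-bounded to generous supersets
#' of the initialization ranges and multi-started from an FFT frequency
#' estimate plus a (lambda, theta) grid with correlation-optimal phases.
#' The residual `r` is the squared norm of the difference between the
#' unit-normalized subfield and the fitted, optimally scaled Gabor -- the
#' fraction of subfield energy the Gabor leaves unexplained, in \[0, 1\].
#'
#' @param y an 8 x 8 subfield (matrix or length-64 vector); need not be
#'   normalized, but must be non-degenerate.
#' @param side patch side in pixels.
#' @param nRefine number of best candidate starts refined by optimization.
#' @return list with `par` (named parameter vector; theta reduced to
#'   \[0, 180), psi to \[0, 360)), `amplitude` (optimal scale for the input
#'   as given), and `r` (residual fraction).
#' @export
fitGabor <- function(y, side = 8L, nRefine = 6L) {
  y <- as.numeric(y)
  nrm <- sqrt(sum(y^2))
  if (!is.finite(nrm) || nrm < 1e-8) stop("degenerate (zero) subfield")
  yn <- y / nrm

  fs <- fftStart(yn, side)
  lams <- unique(c(fs["lambda"], 3, 4.5, 7, 11, 16))
  ths <- unique(c(fs["theta"], seq(0, 150, by = 30)))
  cands <- list()
  for (lam in lams) for (th in ths) {
    p <- c(lambda = unname(lam), theta = unname(th), psi = 0, sigma = 2.5,
      beta = unname(lam) / 6.4, xc = (side - 1) / 2, yc = (side - 1) / 2)
    p["psi"] <- optimalPhase(p, yn, side)
    cands[[length(cands) + 1]] <- list(par = p,
      val = gaborResidualFraction(p, yn, side))
  }
  ord <- order(vapply(cands, `[[`, numeric(1), "val"))
  best <- list(val = Inf, par = cands[[ord[1]]]$par)
  for (i in ord[seq_len(min(nRefine, length(cands)))]) {
    o <- tryCatch(optim(cands[[i]]$par, gaborResidualFraction, y = yn,
      side = side, method = "L-BFGS-B", lower = .gaborLower,
      upper = .gaborUpper, control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(o) && o$value < best$val)
      best <- list(val = o$value, par = o$par)
    if (best$val < 1e-6) break
  }
  if (best$val >= 1e-6) {
    o <- tryCatch(optim(best$par, function(p)
      gaborResidualFraction(pmin(pmax(p, .gaborLower), .gaborUpper), yn, side),
      method = "Nelder-Mead", control = list(maxit = 400)),
      error = function(e) NULL)
    if (!is.null(o) && o$value < best$val) {
      best$val <- o$value
      best$par <- pmin(pmax(o$par, .gaborLower), .gaborUpper)
    }
  }

  p <- best$par
  ## canonical ranges: theta in [0, 180) with psi flipped when folding
  th <- p["theta"] %% 360
  if (th >= 180) {
    th <- th - 180
    p["psi"] <- -p["psi"]
  }
  p["theta"] <- th
  p["psi"] <- p["psi"] %% 360
  g <- gaborFunction(p, side)
  amp <- sum(y * g) / sum(g * g)
  if (amp < 0) {       # canonical positive amplitude: fold sign into phase
    p["psi"] <- (p["psi"] + 180) %% 360
    g <- gaborFunction(p, side)
    amp <- sum(y * g) / sum(g * g)
  }
  ## phase re-referenced to the patch origin: psi is relative to the fitted
  ## centre, so phase differences across fits are only meaningful after
  ## moving both to a common reference point
  thr <- p[["theta"]] * pi / 180
  psi0 <- (p[["psi"]] - 360 * (p[["xc"]] * cos(thr) + p[["yc"]] * sin(thr)) /
    p[["lambda"]]) %% 360
  list(par = p, amplitude = amp, r = max(0, min(1, best$val)), psi0 = psi0)
}

#' Gabor-fit residual statistics of a dictionary
#'
#' Fits a Gabor to each of the four subfields of every atom and reports the
#' squared residual norm at the scale the subfield has inside the
#' unit-energy atom: `r = ||sub||^2 * fraction`, where `fraction` is the
#' unit-normalized residual from [fitGabor()]. For an atom whose four
#' subfields carry equal energy, each subfield contributes 1/4 of the
#' atom's energy, so a perfectly Gabor-like dictionary has r near 0 and
#' unstructured white-noise atoms have r near 0.19.
#'
#' @param dict a [Dictionary-class].
#' @return list with `r` (numeric vector, one entry per subfield), `mean`
#'   and `sd`, plus `fraction` (the unit-normalized residual fractions).
#' @export
residualStats <- function(dict) {
  A <- atoms(dict)
  nms <- c("leftPrev", "leftT", "rightPrev", "rightT")
  r <- numeric(0)
  fr <- numeric(0)
  for (i in seq_len(ncol(A))) {
    for (nm in nms) {
      sub <- A[subfieldIndex[[nm]], i]
      e <- sum(sub^2)
      if (e < 1e-12) next
      f <- fitGabor(sub)$r
      fr <- c(fr, f)
      r <- c(r, e * f)
    }
  }
  list(r = r, mean = mean(r), sd = sd(r), fraction = fr)
}

#' Gabor-fit residuals of unit-energy white-noise atoms
#'
#' Generates `n` subfields as quarters of unit-energy 16 x 16 Gaussian
#' white-noise basis functions and fits each with [fitGabor()], returning
#' the residuals on the atom energy scale (as in [residualStats()]).
#'
#' @param n number of subfields (a multiple of 4 uses whole atoms).
#' @param seed RNG seed.
#' @return numeric vector of `n` residuals.
#' @export
whiteNoiseResiduals <- function(n = 500L, seed = 1L) {
  nAtoms <- ceiling(n / 4)
  dict <- initDictionary(nAtoms, "coarse", seed = seed, mode = "white_noise")
  residualStats(dict)$r[seq_len(n)]
}
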