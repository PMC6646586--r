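#' Evaluate a 2D Gabor function on the patch grid
#'
#' `g(x, y) = exp(-(x'^2 + beta^2 y'^2) / (2 sigma^2)) cos(2 pi x' / lambda + psi)`
#' with `x', y'` the coordinates rotated by the orientation `theta` about the
#' centre `(xc, yc)`. The grid places pixel centres at integer coordinates
#' `0..side-1`; `x` runs along columns, `y` along rows, so `theta = 0` gives
#' vertical stripes (modulation along x).
#'
#' @param params numeric vector or list with elements `lambda` (px), `theta`
#'   (deg), `psi` (deg), `sigma` (px), `beta` (aspect ratio), `xc`, `yc` (px).
#' @param side patch side in pixels.
#' @return numeric `side x side` matrix (unnormalized).
#' @export
gaborFunction <- function(params, side = 8L) {
  p <- as.list(params)
  key <- paste0("grid", side)
  g <- .renderCache[[key]]
  if (is.null(g)) {
    g <- list(
      x = matrix(rep(0:(side - 1), each = side), side, side),  # column coord
      y = matrix(rep(0:(side - 1), times = side), side, side)) # row coord
    .renderCache[[key]] <- g
  }
  x <- g$x; y <- g$y
  th <- p$theta * pi / 180
  ps <- p$psi * pi / 180
  xp <- (x - p$xc) * cos(th) + (y - p$yc) * sin(th)
  yp <- -(x - p$xc) * sin(th) + (y - p$yc) * cos(th)
  exp(-(xp^2 + p$beta^2 * yp^2) / (2 * p$sigma^2)) *
    cos(2 * pi * xp / p$lambda + ps)
}

#' Sample a unit-norm Gabor subfield
#'
#' Evaluates [gaborFunction()] and scales the result to unit norm. With
#' `zeroMean = TRUE` the mean is removed first (the patch space of the
#' sparse coders is zero-mean); the default keeps the raw Gabor profile,
#' matching the initialization of the basis functions.
#'
#' @param params Gabor parameters, see [gaborFunction()].
#' @param side patch side in pixels.
#' @param zeroMean subtract the mean before normalizing?
#' @return `side x side` matrix with unit Frobenius norm, or `NULL` if the
#'   sampled profile is numerically degenerate (norm < 1e-8).
#' @export
sampleGabor <- function(params, side = 8L, zeroMean = FALSE) {
  g <- gaborFunction(params, side)
  if (zeroMean) g <- g - mean(g)
  nrm <- sqrt(sum(g^2))
  if (!is.finite(nrm) || nrm < 1e-8) return(NULL)
  g / nrm
}

## Draw one set of Gabor parameters from the initialization distributions.
drawGaborParams <- function() {
  lambda <- runif(1, 8 / 3, 16)
  c(lambda = lambda, theta = runif(1, 0, 180), psi = runif(1, 0, 360),
    sigma = 2.5, beta = lambda / (0.8 * 8), xc = runif(1, 8 / 3, 8),
    yc = runif(1, 8 / 3, 8))
}

#' Initialize a sparse-coding dictionary
#'
#' Each atom's four 8 x 8 subfields (left/right eye at times t-1 and t) are
#' drawn independently: in `"gabor"` mode as random Gabor wavelets with
#' `lambda ~ U[8/3, 16] px`, `theta ~ U[0, 180) deg`, `psi ~ U[0, 360) deg`,
#' centre `~ U[8/3, 8] px`, `sigma = 2.5 px`, `beta = lambda / 6.4`, each
#' subfield unit-normalized; in `"white_noise"` mode as standard normal
#' pixels. The assembled 16 x 16 atom is then normalized to unit energy.
#'
#' @param nAtoms dictionary size (600 by default; 100-800 supported).
#' @param scale `"coarse"` or `"fine"` (bookkeeping only).
#' @param seed integer seed; initialization is reproducible.
#' @param mode `"gabor"` or `"white_noise"`.
#' @return a [Dictionary-class]; in Gabor mode `initParams` keeps the drawn
#'   parameters (list per atom of four named vectors: leftPrev, rightPrev,
#'   leftT, rightT).
#' @export
initDictionary <- function(nAtoms = 600L, scale = c("coarse", "fine"),
                           seed = 1L, mode = c("gabor", "white_noise")) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  withSeed(seed, {
    A <- matrix(0, 256, nAtoms)
    params <- vector("list", nAtoms)
    for (i in seq_len(nAtoms)) {
      if (mode == "gabor") {
        sf <- list()
        pp <- list()
        for (nm in c("leftPrev", "leftT", "rightPrev", "rightT")) {
          repeat {
            p <- drawGaborParams()
            g <- sampleGabor(p)
            if (!is.null(g)) break
          }
          sf[[nm]] <- g
          pp[[nm]] <- p
        }
        v <- numeric(256)
        v[subfieldIndex$leftPrev] <- sf$leftPrev
        v[subfieldIndex$leftT] <- sf$leftT
        v[subfieldIndex$rightPrev] <- sf$rightPrev
        v[subfieldIndex$rightT] <- sf$rightT
        params[[i]] <- pp
      } else {
        v <- rnorm(256)
      }
      A[, i] <- v / sqrt(sum(v^2))
    }
    new("Dictionary", scale = scale, atoms = A, mode = mode, seed = seed,
      iteration = 0L, initParams = if (mode == "gabor") params else list())
  })
}

#' Encode patches by matching pursuit
#'
#' Greedy sparse coding: for each patch, `k` iterations each select the atom
#' with the largest absolute inner product with the current residual
#' (ties broken towards the lowest atom index), accumulate that inner
#' product into the atom's coefficient and subtract the projection.
#' Re-selection of an atom is allowed, so a patch has at most `k` non-zero
#' coefficients. All patches are encoded simultaneously.
#'
#' @param patches numeric `256 x N` matrix of spatio-temporal patches.
#' @param dict a [Dictionary-class] (unit-energy atoms).
#' @param k number of matching-pursuit iterations (non-zero budget).
#' @return list with `coef` (`K x N` coefficient matrix) and `residual`
#'   (`256 x N`, equal to `patches - atoms %*% coef`).
#' @export
matchingPursuit <- function(patches, dict, k = 10L) {
  D <- atoms(dict)
  N <- ncol(patches)
  coef <- matrix(0, ncol(D), N)
  Rm <- patches
  active <- colSums(Rm^2) > 0
  for (it in seq_len(k)) {
    if (!any(active)) break
    G <- crossprod(D, Rm[, active, drop = FALSE])   # K x N_active
    idx <- max.col(t(abs(G)), ties.method = "first")
    c0 <- G[cbind(idx, seq_along(idx))]
    keep <- abs(c0) > 1e-12      # exhausted residuals select nothing
    if (!any(keep)) break
    cols <- which(active)[keep]
    idx <- idx[keep]; c0 <- c0[keep]
    coef[cbind(idx, cols)] <- coef[cbind(idx, cols)] + c0
    Rm[, cols] <- Rm[, cols, drop = FALSE] -
      D[, idx, drop = FALSE] * rep(c0, each = 256)
  }
  list(coef = coef, residual = Rm)
}

#' Reconstruction error of a sparse code
#'
#' `E = sum_j ||p_j - phat_j||^2 / ||p_j||^2` over the patches of one scale;
#' degenerate all-zero patches contribute 0. Its negative is the intrinsic
#' reward of the reinforcement learner.
#'
#' @param patches `256 x N` patch matrix the code was computed for.
#' @param code result of [matchingPursuit()].
#' @return scalar reconstruction error.
#' @export
reconstructionError <- function(patches, code) {
  p2 <- colSums(patches^2)
  r2 <- colSums(code$residual^2)
  sum(ifelse(p2 > 0, r2 / p2, 0))
}

#' Gradient update of the dictionary
#'
#' Gradient descent on the reconstruction error:
#' `delta_phi_i = eta / N * sum_j kappa_ij (p_j - phat_j)`, applied to every
#' atom, followed by renormalization of each atom to unit energy.
#'
#' @param dict a [Dictionary-class].
#' @param patches `256 x N` patch matrix.
#' @param code matching [matchingPursuit()] result.
#' @param eta learning rate (0.5 for both scales).
#' @return the updated [Dictionary-class].
#' @export
updateDictionary <- function(dict, patches, code, eta = 0.5) {
  A <- atoms(dict)
  A <- A + (eta / ncol(patches)) * tcrossprod(code$residual, code$coef)
  nrm <- sqrt(colSums(A^2))
  bad <- nrm < 1e-12
  if (any(bad)) {           # keep the previous atom if an update nulled it
    A[, bad] <- atoms(dict)[, bad]
    nrm[bad] <- 1
  }
  dict@atoms <- sweep(A, 2, nrm, "/")
  dict@iteration <- dict@iteration + 1L
  dict
}

#' Sensory state vector from the sparse codes
#'
#' Entry `i` of each block is the mean squared coefficient of atom `i` over
#' all patches of the scale (a complex-cell-like pooling of squared
#' simple-cell responses); the coarse block precedes the fine block.
#'
#' @param codeCoarse,codeFine [matchingPursuit()] results; pass `NULL` for
#'   `codeFine` in the no-fine-scale (NFS) configuration.
#' @return non-negative numeric vector of length `2 K` (or `K` under NFS).
#' @export
stateVector <- function(codeCoarse, codeFine = NULL) {
  s <- rowMeans(codeCoarse$coef^2)
  if (!is.null(codeFine)) s <- c(s, rowMeans(codeFine$coef^2))
  s
}
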