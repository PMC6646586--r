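#' Fit Gabor functions to all subfields of a dictionary
#'
#' @param dict a [Dictionary-class].
#' @return data.frame with one row per (atom, subfield): columns `atom`,
#'   `eye`, `time`, the fitted parameters, `amplitude` and the residual
#'   fraction `r` (see [fitGabor()]).
#' @export
fitDictionary <- function(dict) {
  A <- atoms(dict)
  map <- list(leftPrev = c("left", "t-1"), leftT = c("left", "t"),
    rightPrev = c("right", "t-1"), rightT = c("right", "t"))
  rows <- list()
  for (i in seq_len(ncol(A))) {
    for (nm in names(map)) {
      sub <- A[subfieldIndex[[nm]], i]
      if (sum(sub^2) < 1e-12) next
      ft <- fitGabor(sub)
      rows[[length(rows) + 1]] <- data.frame(atom = i, eye = map[[nm]][1],
        time = map[[nm]][2], lambda = ft$par[["lambda"]],
        theta = ft$par[["theta"]], psi = ft$par[["psi"]],
        psi0 = ft$psi0, sigma = ft$par[["sigma"]], beta = ft$par[["beta"]],
        xc = ft$par[["xc"]], yc = ft$par[["yc"]],
        amplitude = ft$amplitude, r = ft$r)
    }
  }
  do.call(rbind, rows)
}

## Wrap an angle difference (radians) to (-pi, pi].
wrapPhase <- function(dpsi) {
  w <- (dpsi + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

#' Disparity preference of one left/right fit pair
#'
#' `dhat = lambda (psi_left - psi_right) / (2 pi cos theta)` in pixels,
#' converted to degrees with the scale's angular resolution. The phase
#' difference is wrapped to (-pi, pi\]. `lambda` and `theta` are averaged
#' over the two eyes; the preference is flagged `NA` when the orientation is
#' near-horizontal (`|cos theta| < 0.1`, horizontal disparity ill-defined)
#' or when the eyes' `lambda`/`theta` disagree by more than `lambdaTol`
#' (relative) / `thetaTol` degrees.
#'
#' @param fitLeft,fitRight named vectors (or one-row data.frames) with
#'   `lambda`, `theta`, `psi` of the two eyes' fits at the same time slice.
#'   The phases must share a reference point: use the origin-referenced
#'   `psi0` of [fitGabor()] when comparing independent fits (phases relative
#'   to each fit's own centre are not comparable).
#' @param degPerPx angular resolution of the scale, deg/px.
#' @param lambdaTol,thetaTol agreement tolerances between the eyes.
#' @return disparity preference in degrees, or `NA` if flagged.
#' @export
disparityPreference <- function(fitLeft, fitRight, degPerPx = 1.125,
                                lambdaTol = 0.1, thetaTol = 10) {
  fl <- as.list(fitLeft); fr <- as.list(fitRight)
  ## orientations folded to [0, 180) can sit on opposite carrier
  ## directions; align the second fit before differencing phases
  if (abs(fl$theta - fr$theta) > 90) {
    fr$theta <- fr$theta - 180 * sign(fr$theta - fl$theta)
    fr$psi <- -fr$psi
  }
  dth <- abs(fl$theta - fr$theta) %% 180
  dth <- min(dth, 180 - dth)
  if (dth > thetaTol) return(NA_real_)
  if (abs(fl$lambda - fr$lambda) > lambdaTol * max(fl$lambda, fr$lambda))
    return(NA_real_)
  lambda <- (fl$lambda + fr$lambda) / 2
  theta <- ((fl$theta + fr$theta) / 2) * pi / 180
  if (abs(cos(theta)) < 0.1) return(NA_real_)
  dpsi <- wrapPhase((fl$psi - fr$psi) * pi / 180)
  lambda * dpsi / (2 * pi * cos(theta)) * degPerPx
}

#' Velocity preference of one eye
#'
#' `vhat = lambda |psi_t - psi_{t-1}| / (2 pi)` in px/iteration, converted to
#' deg/iteration; phase difference wrapped to (-pi, pi\]. Always >= 0.
#'
#' @param fitT,fitPrev named vectors (or one-row data.frames) with `lambda`,
#'   `theta`, `psi` of the eye's fits at times t and t-1 (phases sharing a
#'   reference point, see [disparityPreference()]).
#' @inheritParams disparityPreference
#' @return velocity preference in deg/iteration, or `NA` if the two time
#'   slices' `lambda`/`theta` disagree beyond tolerance.
#' @export
velocityPreference <- function(fitT, fitPrev, degPerPx = 1.125,
                               lambdaTol = 0.1, thetaTol = 10) {
  ft <- as.list(fitT); fp <- as.list(fitPrev)
  if (abs(ft$theta - fp$theta) > 90) {
    fp$theta <- fp$theta - 180 * sign(fp$theta - ft$theta)
    fp$psi <- -fp$psi
  }
  dth <- abs(ft$theta - fp$theta) %% 180
  dth <- min(dth, 180 - dth)
  if (dth > thetaTol) return(NA_real_)
  if (abs(ft$lambda - fp$lambda) > lambdaTol * max(ft$lambda, fp$lambda))
    return(NA_real_)
  lambda <- (ft$lambda + fp$lambda) / 2
  dpsi <- wrapPhase((ft$psi - fp$psi) * pi / 180)
  lambda * abs(dpsi) / (2 * pi) * degPerPx
}

#' Tuning table of a dictionary
#'
#' Aggregates per-atom stimulus preferences from the subfield Gabor fits:
#' orientation `theta` (of the time-t left subfield), disparity preferences
#' at t and t-1 (degrees) and velocity preferences of the left and right eye
#' (deg/iteration). Atoms are included only if all four subfield fits have
#' residual fraction `r <= maxResidual`; disparity/velocity entries are `NA`
#' where the paired fits disagree or the orientation makes the quantity
#' ill-defined (see [disparityPreference()]).
#'
#' @param fits result of [fitDictionary()] (computed if a
#'   [Dictionary-class] is passed).
#' @param scale a [ScaleConfig-class] or scale name, for the deg/px
#'   conversion.
#' @param maxResidual residual-fraction threshold for a usable fit.
#' @return data.frame with columns `atom`, `theta`, `dT`, `dPrev`, `vLeft`,
#'   `vRight`; attribute `excluded` counts atoms dropped by the residual
#'   threshold.
#' @export
tuningTable <- function(fits, scale = "coarse", maxResidual = 0.5) {
  if (is(fits, "Dictionary")) {
    scale <- fits@scale
    fits <- fitDictionary(fits)
  }
  cfg <- if (is(scale, "ScaleConfig")) scale else scaleConfig(scale)
  dpp <- degPerPx(cfg)
  rows <- list()
  excluded <- 0L
  pick <- function(df, eye, time) df[df$eye == eye & df$time == time, ]
  for (a in unique(fits$atom)) {
    af <- fits[fits$atom == a, ]
    if (nrow(af) < 4 || any(af$r > maxResidual)) {
      excluded <- excluded + 1L
      next
    }
    lt <- pick(af, "left", "t"); lp <- pick(af, "left", "t-1")
    rt <- pick(af, "right", "t"); rp <- pick(af, "right", "t-1")
    ## compare origin-referenced phases across fits
    ref <- function(f) c(lambda = f$lambda, theta = f$theta, psi = f$psi0)
    rows[[length(rows) + 1]] <- data.frame(atom = a, theta = lt$theta,
      dT = disparityPreference(ref(lt), ref(rt), dpp),
      dPrev = disparityPreference(ref(lp), ref(rp), dpp),
      vLeft = velocityPreference(ref(lt), ref(lp), dpp),
      vRight = velocityPreference(ref(rt), ref(rp), dpp))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(atom = integer(), theta = numeric(), dT = numeric(),
      dPrev = numeric(), vLeft = numeric(), vRight = numeric())
  attr(out, "excluded") <- excluded
  out
}

#' Histogram of orientation preferences
#'
#' Bins the fitted orientation of the time-t left subfield over \[0, 180).
#' 0 degrees means vertical stripes (horizontal modulation), 90 horizontal.
#'
#' @param table a [tuningTable()] data.frame (or anything with a `theta`
#'   column).
#' @param bins number of bins over \[0, 180).
#' @return named numeric vector of counts; names are bin centres in degrees.
#' @export
orientationHistogram <- function(table, bins = 9L) {
  th <- table$theta %% 180
  binw <- 180 / bins
  b <- pmin(floor(th / binw), bins - 1) + 1
  counts <- tabulate(b, nbins = bins)
  names(counts) <- binw * (seq_len(bins) - 0.5)
  counts
}

#' Joint tuning scatter data and correlations
#'
#' Emits the three scatter relations of the tuning analysis with their
#' Pearson correlations: disparity at t vs t-1, velocity left vs right eye,
#' and mean velocity vs mean absolute disparity; plus the fraction of atoms
#' preferring disparities within one pixel (`|dhat| <= degPerPx`).
#'
#' @param table a [tuningTable()] data.frame.
#' @param degPerPx angular resolution used for the one-pixel criterion.
#' @return list with data.frames `disparity`, `velocity`, `velocityDisparity`
#'   (NA rows removed), correlations `rhoDisparity`, `rhoVelocity`,
#'   `rhoVelDisp`, and `fracWithinOnePx`.
#' @export
tuningScatter <- function(table, degPerPx = 1.125) {
  dd <- table[is.finite(table$dT) & is.finite(table$dPrev),
    c("atom", "dT", "dPrev")]
  vv <- table[is.finite(table$vLeft) & is.finite(table$vRight),
    c("atom", "vLeft", "vRight")]
  meanV <- rowMeans(cbind(table$vLeft, table$vRight))
  meanD <- rowMeans(abs(cbind(table$dT, table$dPrev)))
  vd <- data.frame(atom = table$atom, meanV = meanV, meanD = meanD)
  vd <- vd[is.finite(vd$meanV) & is.finite(vd$meanD), ]
  corOr <- function(x, y) if (length(x) > 2 && sd(x) > 0 && sd(y) > 0)
    stats::cor(x, y) else NA_real_
  list(disparity = dd, velocity = vv, velocityDisparity = vd,
    rhoDisparity = corOr(dd$dT, dd$dPrev),
    rhoVelocity = corOr(vv$vLeft, vv$vRight),
    rhoVelDisp = corOr(vd$meanV, vd$meanD),
    fracWithinOnePx = mean(abs(table$dT) <= degPerPx, na.rm = TRUE))
}
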