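test_that("the Gabor fitter recovers known parameters", {
  set.seed(41)
  nOK <- 0; thErr <- c(); lamErr <- c()
  for (i in 1:40) {
    p <- randomGaborParams()
    g <- sampleGabor(p)
    if (is.null(g)) next
    ft <- fitGabor(g)
    if (ft$r <= 0.01) {
      nOK <- nOK + 1
      dth <- abs(ft$par[["theta"]] - p[["theta"]]) %% 180
      thErr <- c(thErr, min(dth, 180 - dth))
      ## the wavelength is only identified when the 8 px window holds at
      ## least one full period
      if (p[["lambda"]] <= 8)
        lamErr <- c(lamErr, abs(ft$par[["lambda"]] - p[["lambda"]]) /
          p[["lambda"]])
    }
  }
  expect_gte(nOK, 36)                        # >= 90 % well fit
  expect_gte(mean(thErr <= 5), 0.9)          # orientation within 5 deg
  expect_gte(mean(lamErr <= 0.1), 0.85)      # wavelength within 10 %
  ## an exact Gabor is fit essentially perfectly
  gex <- sampleGabor(c(lambda = 6, theta = 40, psi = 110, sigma = 2.5,
    beta = 1.2, xc = 4, yc = 4))
  expect_lt(fitGabor(gex)$r, 1e-4)
})

test_that("residual statistics separate Gabor and white-noise dictionaries", {
  dG <- initDictionary(25, "coarse", seed = 43)
  rsG <- residualStats(dG)                   # 100 subfield fits
  expect_length(rsG$r, 100L)
  expect_gte(rsG$mean, -0.003)
  expect_lte(rsG$mean, 0.009)                # 0.003 +- 0.006 band
  rN <- whiteNoiseResiduals(60, seed = 44)
  expect_gte(mean(rN), 0.188 - 3 * 0.022)
  expect_lte(mean(rN), 0.188 + 3 * 0.022)
  ## deterministic given seeds
  expect_identical(whiteNoiseResiduals(8, seed = 44),
    whiteNoiseResiduals(8, seed = 44))
})

test_that("disparity preference implements the phase-shift relation", {
  fl <- c(lambda = 8, theta = 0, psi = 90)
  fr <- c(lambda = 8, theta = 0, psi = 0)
  ## 90 deg phase shift at lambda 8 -> 2 px -> 2.25 deg at coarse scale
  expect_equal(disparityPreference(fl, fr, degPerPx = 1.125), 2.25)
  expect_equal(disparityPreference(fl, fl, degPerPx = 1.125), 0)
  ## antisymmetry under swapping the eyes
  expect_equal(disparityPreference(fr, fl, degPerPx = 1.125), -2.25)
  ## phase differences wrap to (-pi, pi]
  f3 <- c(lambda = 8, theta = 0, psi = 270)
  expect_equal(disparityPreference(f3, fr, degPerPx = 1.125), -2.25)
  ## near-horizontal orientations and mismatched fits are flagged
  fh <- c(lambda = 8, theta = 88, psi = 90)
  expect_true(is.na(disparityPreference(fh, fh + c(0, 0, -90), 1.125)))
  fm <- c(lambda = 12, theta = 0, psi = 0)
  expect_true(is.na(disparityPreference(fl, fm, 1.125)))
})

test_that("velocity preference implements the temporal phase relation", {
  ft <- c(lambda = 8, theta = 0, psi = 180)
  fp <- c(lambda = 8, theta = 0, psi = 0)
  ## |dpsi| = pi at lambda 8 -> 4 px/iteration -> 4.5 deg at coarse scale
  expect_equal(velocityPreference(ft, fp, degPerPx = 1.125), 4 * 1.125)
  expect_equal(velocityPreference(fp, fp, degPerPx = 1.125), 0)
  ## symmetric in time order and always non-negative
  expect_equal(velocityPreference(fp, ft, degPerPx = 1.125), 4.5)
  f2 <- c(lambda = 8, theta = 0, psi = 300)
  expect_equal(velocityPreference(f2, fp, degPerPx = 1.125),
    8 * (pi / 3) / (2 * pi) * 1.125)
})

test_that("phase-based preferences agree with cross-correlation shifts", {
  ## left/right Gabor pair with a known phase offset: the fitted-phase
  ## disparity must match the horizontal shift of the left subfield that
  ## maximises its correlation with the right subfield
  shiftCorrelation <- function(left, right) {
    score <- function(s) {   # left(x - s) vs right(x), interior columns
      ls <- t(apply(left, 1, function(row)
        stats::spline(0:7, row, xout = (0:7) - s)$y))
      keep <- 2:7
      sum(ls[, keep] * right[, keep]) /
        sqrt(sum(ls[, keep]^2) * sum(right[, keep]^2))
    }
    stats::optimize(score, c(-3, 3), maximum = TRUE)$maximum
  }
  for (case in list(c(th = 0, dpsi = 90), c(th = 20, dpsi = 60),
      c(th = 150, dpsi = -80))) {
    pL <- c(lambda = 6, theta = case[["th"]], psi = 120, sigma = 2.5,
      beta = 1, xc = 3.5, yc = 3.5)
    pR <- pL; pR[["psi"]] <- pL[["psi"]] - case[["dpsi"]]
    gL <- sampleGabor(pL); gR <- sampleGabor(pR)
    fL <- fitGabor(gL); fR <- fitGabor(gR)
    dhatPx <- disparityPreference(
      c(lambda = fL$par[["lambda"]], theta = fL$par[["theta"]],
        psi = fL$psi0),
      c(lambda = fR$par[["lambda"]], theta = fR$par[["theta"]],
        psi = fR$psi0), degPerPx = 1)
    expect_lt(abs(dhatPx - shiftCorrelation(gL, gR)), 0.5)
  }
})

test_that("orientation histograms and tuning tables are consistent", {
  ## identical vertical Gabors end in a single bin
  tab <- data.frame(theta = rep(0.5, 40))
  h <- orientationHistogram(tab, bins = 9)
  expect_equal(sum(h > 0), 1L)
  expect_equal(sum(h), 40)
  ## uniform orientations give a flat histogram (chi-square at 1 %)
  set.seed(46)
  hu <- orientationHistogram(data.frame(theta = runif(3000, 0, 180)), 9)
  expect_gt(stats::chisq.test(hu)$p.value, 0.01)
  expect_equal(sum(hu), 3000)

  ## tuning table on a tiny dictionary: structure and exclusion counting
  d <- initDictionary(8, "coarse", seed = 47)
  tt <- tuningTable(d, maxResidual = 0.5)
  expect_true(all(c("atom", "theta", "dT", "dPrev", "vLeft", "vRight")
    %in% names(tt)))
  expect_equal(nrow(tt) + attr(tt, "excluded"), 8L)
  expect_true(all(tt$vLeft >= 0 | is.na(tt$vLeft)))
})

test_that("tuning scatter reports correlations and pixel fractions", {
  set.seed(48)
  v <- rnorm(600)
  tab <- data.frame(atom = 1:600, theta = runif(600, 0, 180),
    dT = v, dPrev = v, vLeft = abs(v), vRight = abs(v))
  sc <- tuningScatter(tab, degPerPx = 1.125)
  expect_equal(sc$rhoDisparity, 1)
  expect_equal(sc$rhoVelocity, 1)
  ind <- data.frame(atom = 1:600, theta = runif(600, 0, 180),
    dT = rnorm(600), dPrev = rnorm(600), vLeft = abs(rnorm(600)),
    vRight = abs(rnorm(600)))
  expect_lt(abs(tuningScatter(ind, 1.125)$rhoDisparity), 0.1)
  ## exact fraction on a hand-built table
  hand <- data.frame(atom = 1:4, theta = 0, dT = c(0.5, -1.0, 2.0, 1.2),
    dPrev = 0, vLeft = 1, vRight = 1)
  expect_equal(tuningScatter(hand, degPerPx = 1.125)$fracWithinOnePx, 2 / 4)
})
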