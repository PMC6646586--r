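test_that("textures are reproducible and in range", {
  a <- makeTexture(1, "pink_noise", side = 256)
  b <- makeTexture(1, "pink_noise", side = 256)
  expect_identical(pixels(a), pixels(b))
  expect_false(identical(pixels(a), pixels(makeTexture(2, "pink_noise",
    side = 256))))
  for (kind in c("pink_noise", "edges", "blocks")) {
    px <- pixels(makeTexture(3, kind, side = 256))
    expect_true(all(is.finite(px)))
    expect_gte(min(px), 0)
    expect_lte(max(px), 1)
  }
})

test_that("pink noise has an approximately 1/f amplitude spectrum", {
  slopes <- vapply(1:3, function(s)
    spectralSlope(makeTexture(s, "pink_noise", side = 256)), numeric(1))
  expect_true(all(slopes > -1.4 & slopes < -0.6))
})

test_that("edge-bearing textures over-represent cardinal orientations", {
  for (kind in c("blocks", "edges")) {
    e <- orientationEnergy(testTexture(kind), nBins = 8)
    top2 <- names(sort(e, decreasing = TRUE))[1:2]
    expect_setequal(top2, c("0", "90"))
  }
})

test_that("stimulus placement respects the stated distributions", {
  set.seed(1)
  w <- testWorld()
  draws <- t(replicate(10000, {
    w2 <- placeStimulus(w)
    c(w2@depth, w2@velocity, w2@azimuth, w2@elevation)
  }))
  expect_gte(min(draws[, 1]), 1)
  expect_lte(max(draws[, 1]), 2.5)
  expect_lte(max(abs(draws[, 2])), 7.5)
  expect_lte(max(abs(draws[, 3])), 7.5)
  expect_lte(max(abs(draws[, 4])), 0.375)
  expect_true(all(draws[, 5:6] == 0))   # centred in the field of view
  ## reproducible under a fixed seed
  set.seed(42); p1 <- placeStimulus(w)
  set.seed(42); p2 <- placeStimulus(w)
  expect_equal(p1, p2)
})

test_that("world stepping integrates angular and depth motion exactly", {
  w <- testWorld(depth = 2, velocity = c(0, 0, 0))
  expect_equal(stepWorld(w), w)
  w@velocity <- c(0, 0, -0.375)
  expect_equal(stepWorld(w)@depth, 2 - 0.0375)
  w@velocity <- c(7.5, -3, 0)
  for (i in 1:10) w <- stepWorld(w)
  expect_equal(w@azimuth, 7.5)
  expect_equal(w@elevation, -3)
  w@depth <- 0.08; w@velocity <- c(0, 0, -0.375)
  expect_error(stepWorld(w), class = "episodeAbort")
})

test_that("eye commands integrate semi-implicitly", {
  e <- eyePose(vergence = 3)
  expect_equal(applyEyeCommand(e, 0, 0, 0), e)
  expect_equal(applyEyeCommand(e, 0, 0, 1)@vergence, 4)
  e2 <- eyePose()
  for (i in 1:5) e2 <- applyEyeCommand(e2, 16, 0, 0)
  expect_equal(e2@panVel, 8)                     # 5 * 16 * 0.1
  expect_equal(e2@pan, sum((1:5) * 1.6 * 0.1))   # velocity-first integration
})

test_that("joint limits are inclusive and detect violations", {
  expect_false(checkLimits(eyePose(vergence = 2)))
  expect_true(checkLimits(eyePose(vergence = 0.19)))
  expect_true(checkLimits(eyePose(vergence = 16.31)))
  expect_false(checkLimits(eyePose(pan = 15, vergence = 2)))
  expect_false(checkLimits(eyePose(vergence = 0.2)))
  expect_true(checkLimits(eyePose(pan = -15.01, vergence = 2)))
  expect_true(checkLimits(eyePose(tilt = 16, vergence = 2)))
})

test_that("gaze reset fixates straight ahead within the vergence range", {
  set.seed(5)
  e <- eyePose(pan = 4, tilt = -3, panVel = 2, tiltVel = 1, vergence = 10)
  for (i in 1:50) {
    e2 <- resetGaze(e)
    expect_equal(c(e2@pan, e2@tilt, e2@panVel, e2@tiltVel), rep(0, 4))
    expect_gte(e2@vergence, 0.2)
    expect_lte(e2@vergence, vergenceTarget(0.3))
  }
  set.seed(9); a <- resetGaze(e)
  set.seed(9); b <- resetGaze(e)
  expect_equal(a, b)
})

test_that("rendering is deterministic and zero-disparity at fixation", {
  w <- testWorld()
  e <- fixatingEyes()
  p1 <- renderBinocular(w, e)
  p2 <- renderBinocular(w, e)
  expect_identical(p1@left, p2@left)
  expect_identical(p1@right, p2@right)
  ## symmetric vergence on the fixated plane: central regions coincide
  ctr <- function(m) m[117:124, 157:164]
  expect_lt(mean(abs(ctr(p1@left) - ctr(p1@right))), 0.05)
  expect_lt(abs(centerDisparity(p1)), 0.5)
})

test_that("measured disparity matches the analytic pinhole prediction", {
  set.seed(11)
  w <- testWorld()
  for (i in 1:10) {
    d <- runif(1, 1, 2.5)
    w@depth <- d
    verg <- vergenceTarget(d) + runif(1, -2, 2)
    e <- eyePose(vergence = max(verg, 0.2))
    pair <- renderBinocular(w, e)
    expect_lt(abs(centerDisparity(pair) -
      projectStimulusCenter(w, e)$disparity), 0.5)
  }
})

test_that("perfect pursuit stabilises the central retinal image", {
  set.seed(13)
  for (i in 1:5) {
    w <- testWorld(depth = runif(1, 1, 2.5))
    w@velocity <- c(runif(1, -7.5, 7.5), runif(1, -7.5, 7.5), 0)
    e <- eyePose(panVel = w@velocity[1], tiltVel = w@velocity[2],
      vergence = vergenceTarget(w@depth))
    f1 <- renderBinocular(w, e)
    w2 <- stepWorld(w)
    e2 <- applyEyeCommand(e, 0, 0, 0)
    f2 <- renderBinocular(w2, e2)
    fine <- function(m) m[89:152, 129:192]   # stimulus-covered fine window
    expect_lt(mean(abs(fine(f2@left) - fine(f1@left))), 0.01)
    expect_lt(mean(abs(fine(f2@right) - fine(f1@right))), 0.01)
  }
})

test_that("stimulus outside the frusta is flagged and background shown", {
  w <- testWorld()
  w@azimuth <- 80   # far outside the +-45 deg horizontal half-FOV
  pair <- renderBinocular(w, fixatingEyes())
  expect_false(any(attr(pair, "visible")))
  expect_true(all(is.finite(pair@left)))
})
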