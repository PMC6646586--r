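test_that("critic, TD error and average-reward updates follow their forms", {
  agent <- newAgent(4)
  s <- c(0, 3, 0, 0)
  expect_equal(criticValue(agent, s), 0)
  agent@thetaV <- c(0, 1, 0, 0)
  expect_equal(criticValue(agent, s), 3)
  expect_equal(criticValue(agent, 2 * s), 2 * criticValue(agent, s))
  expect_error(criticValue(agent, c(1, 2)), "dimension")

  expect_equal(tdError(0, 0, 0, 0), 0)
  expect_equal(tdError(1, 1, 0, 0), 0)
  expect_equal(tdError(0, 0, 1, 0, gamma = 0.3), 0.3)
  expect_equal(tdError(2, 0.5, 1, 0.25, gamma = 0.3), 2 - 0.5 + 0.3 - 0.25)

  expect_equal(updateAvgReward(0, 1), 0.01)
  expect_equal(updateAvgReward(0.5, 0.5), 0.5)
  expect_equal(updateAvgReward(3, 7, xi = 1), 7)

  a2 <- updateCritic(agent, 0, s)
  expect_equal(a2@thetaV, agent@thetaV)
  a3 <- updateCritic(agent, 1, c(1, 0, 0, 0))
  expect_equal(a3@thetaV[1], agent@thetaV[1] + 0.4)
  a4 <- updateCritic(agent, 2, c(1, 0, 0, 0))
  expect_equal(a4@thetaV[1] - agent@thetaV[1],
    2 * (a3@thetaV[1] - agent@thetaV[1]))
})

test_that("softmax policy is normalized, uniform at start, greedy at T -> 0", {
  agent <- newAgent(6)
  s <- runif(6)
  p <- policyProbs(agent, s, "pan")
  expect_equal(p, rep(1 / 13, 13))
  set.seed(2)
  agent@actors$vergence$thetaA <- matrix(rnorm(13 * 6), 13, 6)
  p2 <- policyProbs(agent, s, "vergence")
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  expect_true(all(p2 > 0))
  ## tiny temperature concentrates on the argmax activation
  z <- as.vector(agent@actors$vergence$thetaA %*% s)
  p3 <- policyProbs(agent, s, "vergence", temperature = 1e-6)
  expect_equal(which.max(p3), which.max(z))
  expect_gt(max(p3), 1 - 1e-6)
})

test_that("the NAC score matches a finite-difference gradient of log pi", {
  set.seed(3)
  nA <- 13; nS <- 5
  agent <- newAgent(nS)
  agent@actors$pan$thetaA <- matrix(rnorm(nA * nS, sd = 0.3), nA, nS)
  agent@actors$pan$w <- matrix(rnorm(nA * nS, sd = 0.1), nA, nS)
  s <- rnorm(nS)
  aIdx <- 4L
  delta <- 0.7

  logPi <- function(theta) {
    z <- as.vector(theta %*% s)
    z[aIdx] - max(z) - log(sum(exp(z - max(z))))
  }
  eps <- 1e-6
  zetaNum <- matrix(0, nA, nS)
  for (i in seq_len(nA)) for (j in seq_len(nS)) {
    tp <- agent@actors$pan$thetaA; tp[i, j] <- tp[i, j] + eps
    tm <- agent@actors$pan$thetaA; tm[i, j] <- tm[i, j] - eps
    zetaNum[i, j] <- (logPi(tp) - logPi(tm)) / (2 * eps)
  }
  ## zeta from the closed form used by nacUpdate
  pi0 <- policyProbs(agent, s, "pan")
  ind <- numeric(nA); ind[aIdx] <- 1
  zeta <- tcrossprod(ind - pi0, s)
  expect_equal(zeta, zetaNum, tolerance = 1e-5)
  ## softmax score identity: the policy-weighted score vanishes
  zsum <- Reduce(`+`, lapply(seq_len(nA), function(a) {
    ia <- numeric(nA); ia[a] <- 1
    pi0[a] * tcrossprod(ia - pi0, s)
  }))
  expect_lt(max(abs(zsum)), 1e-12)

  ## one nacUpdate step equals the brute-force advantage-parameter update
  w0 <- agent@actors$pan$w
  wExp <- w0 + 0.16 * (delta * zeta - zeta * sum(zeta * w0))
  thExp <- agent@actors$pan$thetaA + 0.4 * wExp
  a2 <- nacUpdate(agent, "pan", delta, s, aIdx)
  expect_equal(a2@actors$pan$w, wExp, tolerance = 1e-12)
  expect_equal(a2@actors$pan$thetaA, thExp, tolerance = 1e-12)
  ## delta = 0 with w = 0: no change
  agent@actors$pan$w <- matrix(0, nA, nS)
  a3 <- nacUpdate(agent, "pan", 0, s, aIdx)
  expect_equal(a3@actors$pan$thetaA, agent@actors$pan$thetaA)
})

test_that("action selection: tie-breaking, sampling frequencies, determinism", {
  agent <- newAgent(3)
  s <- c(1, 1, 1)
  g <- chooseActions(agent, s, "greedy")
  expect_equal(unname(g$actions), c(0, 0, 0))  # ties go to magnitude 0
  set.seed(4)
  agent@actors$pan$thetaA[, 1] <- seq(-0.6, 0.6, length.out = 13)
  p <- policyProbs(agent, c(1, 0, 0), "pan")
  draws <- replicate(10000,
    chooseActions(agent, c(1, 0, 0), "sample")$index[["pan"]])
  obs <- tabulate(draws, 13)
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.001)
  set.seed(11); a <- chooseActions(agent, s, "sample")
  set.seed(11); b <- chooseActions(agent, s, "sample")
  expect_identical(a, b)
})

test_that("updates consume exactly the two-step delayed transition", {
  set.seed(6)
  agent <- newAgent(3)
  buffer <- newTransitionBuffer()
  expect_false(bufferReady(buffer))
  consumed <- integer(0)
  for (t in 1:6) {
    s <- rnorm(3)
    upd <- agentUpdate(agent, buffer, s, rnorm(1))
    agent <- upd$agent
    if (!is.na(upd$usedTag)) consumed <- c(consumed, upd$usedTag)
    idx <- chooseActions(agent, s, "sample")$index
    buffer <- pushTransition(buffer, s, idx, tag = t)
  }
  ## the update at iteration t consumes the transition pushed at t - 2
  expect_equal(consumed, c(1L, 2L, 3L, 4L))
  ## no updates for the first two iterations after a reset
  expect_length(consumed, 4L)
})

test_that("advantage parameters settle at the natural-gradient fixed point", {
  ## on fixed (s, delta) statistics the w update has fixed point
  ## E[zeta (zeta^T w)] = E[delta zeta]
  set.seed(7)
  nA <- 5; nS <- 3
  ## eta = 0 freezes the policy so zeta is constant across updates
  agent <- newAgent(nS, actions = c(-2, -1, 0, 1, 2), eta = 0)
  agent@actors$pan$thetaA <- matrix(rnorm(nA * nS, sd = 0.2), nA, nS)
  sFix <- c(1, -0.5, 0.25)
  aFix <- 2L
  deltaFix <- 0.8
  for (i in 1:500) agent <- nacUpdate(agent, "pan", deltaFix, sFix, aFix)
  pi0 <- policyProbs(agent, sFix, "pan")
  ind <- numeric(nA); ind[aFix] <- 1
  zeta <- tcrossprod(ind - pi0, sFix)
  ## fixed point of Eq 13: zeta (zeta^T w) = delta zeta, i.e. <zeta, w> = delta
  expect_equal(sum(zeta * agent@actors$pan$w), deltaFix, tolerance = 1e-3)
})

test_that("the actor-critic solves the error-cancelling bandit", {
  b <- nacBandit(4000, seed = 3)
  expect_gte(b$accuracy, 0.6)   # partial convergence early in training
})
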