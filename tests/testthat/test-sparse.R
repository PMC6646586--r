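test_that("sampled Gabor subfields behave like Gabor functions", {
  p <- c(lambda = 6, theta = 30, psi = 45, sigma = 2.5, beta = 1,
    xc = 4, yc = 5)
  g <- sampleGabor(p)
  expect_equal(sum(g^2), 1)
  p2 <- p; p2["psi"] <- p["psi"] + 360
  expect_equal(sampleGabor(p2), g)
  ## with a symmetric centre, rotating by 90 deg transposes the pattern
  pv <- c(lambda = 5, theta = 0, psi = 20, sigma = 2.5, beta = 1,
    xc = 3.5, yc = 3.5)
  ph <- pv; ph["theta"] <- 90
  expect_equal(sampleGabor(ph), t(sampleGabor(pv)), tolerance = 1e-12)
})

test_that("dictionary initialization is reproducible with unit-energy atoms", {
  d <- initDictionary(120, "coarse", seed = 21)
  expect_equal(nAtoms(d), 120L)
  expect_equal(colSums(atoms(d)^2), rep(1, 120), tolerance = 1e-12)
  d2 <- initDictionary(120, "coarse", seed = 21)
  expect_identical(atoms(d), atoms(d2))
  lambdas <- unlist(lapply(d@initParams, function(pp)
    vapply(pp, `[[`, numeric(1), "lambda")))
  expect_gte(min(lambdas), 8 / 3)
  expect_lte(max(lambdas), 16)
  dn <- initDictionary(60, "fine", seed = 22, mode = "white_noise")
  expect_equal(colSums(atoms(dn)^2), rep(1, 60), tolerance = 1e-12)
  expect_length(dn@initParams, 0)
})

test_that("matching pursuit recovers atoms and shrinks the residual", {
  d <- initDictionary(80, "coarse", seed = 23)
  patch <- atoms(d)[, 12, drop = FALSE] * 1.7
  code <- matchingPursuit(patch, d, k = 10)
  expect_equal(code$coef[12, 1], 1.7, tolerance = 1e-8)
  expect_lt(sqrt(sum(code$residual^2)), 1e-8)
  ## residual norm is non-increasing in the sparsity budget
  set.seed(1)
  y <- matrix(rnorm(256), 256, 1)
  rn <- vapply(1:10, function(k)
    sqrt(sum(matchingPursuit(y, d, k)$residual^2)), numeric(1))
  expect_true(all(diff(rn) <= 1e-12))
  ## zero patch: empty code
  z <- matchingPursuit(matrix(0, 256, 1), d, 10)
  expect_equal(sum(z$coef != 0), 0)
})

test_that("matching pursuit equals projection on an orthonormal dictionary", {
  d <- orthonormalDictionary(40)
  set.seed(31)
  Y <- matrix(rnorm(256 * 5), 256, 5)
  code <- matchingPursuit(Y, d, k = 10)
  proj <- crossprod(atoms(d), Y)   # brute-force projection oracle
  for (j in 1:5) {
    top <- order(abs(proj[, j]), decreasing = TRUE)[1:10]
    got <- which(code$coef[, j] != 0)
    expect_setequal(got, top)
    expect_equal(code$coef[top, j], proj[top, j], tolerance = 1e-10)
  }
})

test_that("reconstruction error matches its definition", {
  d <- initDictionary(50, "coarse", seed = 25)
  ps <- testPatchSet()$coarse
  code <- matchingPursuit(ps, d, 10)
  ## term-by-term brute-force recomputation
  phat <- atoms(d) %*% code$coef
  byHand <- sum(vapply(seq_len(ncol(ps)), function(j) {
    n2 <- sum(ps[, j]^2)
    if (n2 == 0) 0 else sum((ps[, j] - phat[, j])^2) / n2
  }, numeric(1)))
  expect_equal(reconstructionError(ps, code), byHand, tolerance = 1e-10)
  ## perfect reconstruction and empty code limits
  perfect <- list(coef = code$coef, residual = ps * 0)
  expect_equal(reconstructionError(ps, perfect), 0)
  empty <- list(coef = code$coef * 0, residual = ps)
  expect_equal(reconstructionError(ps, empty),
    sum(colSums(ps^2) > 0))
})

test_that("dictionary updates reduce the reconstruction error", {
  ps <- testPatchSet()$coarse
  d <- initDictionary(60, "coarse", seed = 26)
  code <- matchingPursuit(ps, d, 10)
  ## zero residuals leave the dictionary unchanged
  d0 <- updateDictionary(d, ps, list(coef = code$coef, residual = ps * 0))
  expect_equal(atoms(d0), atoms(d), tolerance = 1e-12)
  ## repeated updates on a fixed batch: clear downward trend
  E <- numeric(100)
  for (i in 1:100) {
    code <- matchingPursuit(ps, d, 10)
    E[i] <- reconstructionError(ps, code)
    d <- updateDictionary(d, ps, code)
  }
  expect_lt(E[100], 0.5 * E[1])
  expect_true(all(diff(E) < 0.05 * E[1]))   # monotone within tolerance
  expect_equal(colSums(atoms(d)^2), rep(1, 60), tolerance = 1e-9)
})

test_that("the state vector pools squared coefficients per atom", {
  K <- 30
  coefC <- matrix(0, K, 49)
  coefC[3, 1] <- 2
  codeC <- list(coef = coefC)
  coefF <- matrix(0, K, 225)
  codeF <- list(coef = coefF)
  s <- stateVector(codeC, codeF)
  expect_length(s, 2 * K)
  expect_equal(s[3], 4 / 49)
  expect_true(all(s >= 0))
  expect_equal(sum(s != 0), 1)
  ## invariant to patch ordering
  perm <- sample(49)
  s2 <- stateVector(list(coef = coefC[, perm]), codeF)
  expect_equal(s2, s)
  ## all-zero codes give the zero vector; NFS drops the fine block
  expect_equal(stateVector(list(coef = coefC * 0), NULL), rep(0, K))
})
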