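## Shared fixtures, built once per test session.
.fixtures <- new.env(parent = emptyenv())

testTexture <- function(kind = "blocks", seed = 7L) {
  key <- paste(kind, seed, sep = "_")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- makeTexture(seed, kind, side = 256)
  .fixtures[[key]]
}

testWorld <- function(depth = 1.5, velocity = c(0, 0, 0)) {
  worldState(testTexture("blocks"), testTexture("pink_noise", 8L),
    depth = depth, velocity = velocity)
}

fixatingEyes <- function(depth = 1.5) {
  eyePose(vergence = vergenceTarget(depth))
}

## Dictionary whose atoms are orthonormal (first K columns of a random
## orthogonal basis): matching pursuit must then equal straight projection.
orthonormalDictionary <- function(K = 40L, seed = 3L) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(256 * K), 256, K)))
  d <- initDictionary(K, "coarse", seed = 1L, mode = "white_noise")
  d@atoms <- Q
  d
}

## A standard binocular patch set from a rendered fixating view.
testPatchSet <- function() {
  if (is.null(.fixtures$patchset)) {
    pr <- renderBinocular(testWorld(), fixatingEyes())
    .fixtures$patchset <- preprocessPair(pr, pr)
  }
  .fixtures$patchset
}

randomGaborParams <- function() {
  lambda <- runif(1, 8 / 3, 16)
  c(lambda = lambda, theta = runif(1, 0, 180), psi = runif(1, 0, 360),
    sigma = 2.5, beta = lambda / (0.8 * 8), xc = runif(1, 8 / 3, 8),
    yc = runif(1, 8 / 3, 8))
}
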