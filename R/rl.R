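#' Default action sets
#'
#' Pan and tilt actions are angular accelerations (deg/s^2), vergence actions
#' are vergence angle changes (deg). The standard set is
#' `{-16, -8, -4, -2, -1, -0.5, 0, 0.5, 1, 2, 4, 8, 16}`; the coarse variant
#' (`"CAS"`) removes the +-0.5 actions.
#'
#' @param variant `"STD"` or `"CAS"`.
#' @return sorted numeric vector, symmetric about 0.
#' @export
defaultActions <- function(variant = c("STD", "CAS")) {
  variant <- match.arg(variant)
  a <- c(-16, -8, -4, -2, -1, -0.5, 0, 0.5, 1, 2, 4, 8, 16)
  if (variant == "CAS") a <- setdiff(a, c(-0.5, 0.5))
  a
}

#' Create a reinforcement-learning agent
#'
#' One linear critic and three softmax actors (pan, tilt, vergence) over a
#' shared state vector. All weights start at zero, giving a uniform initial
#' policy and a zero initial value estimate.
#'
#' @param stateDim length of the sensory state vector (`2 K`, or `K` without
#'   the fine scale).
#' @param actions action set shared by the three actors.
#' @param gamma discount factor (0.3).
#' @param alpha critic learning rate (0.4).
#' @param xi average-reward smoothing factor (0.01).
#' @param beta natural-gradient learning rate (0.16).
#' @param eta actor learning rate (0.4).
#' @param temperature softmax temperature (1).
#' @return an [AecAgent-class].
#' @export
newAgent <- function(stateDim, actions = defaultActions(), gamma = 0.3,
                     alpha = 0.4, xi = 0.01, beta = 0.16, eta = 0.4,
                     temperature = 1) {
  nA <- length(actions)
  mk <- function() list(thetaA = matrix(0, nA, stateDim),
    w = matrix(0, nA, stateDim))
  new("AecAgent", actions = as.numeric(actions),
    thetaV = numeric(stateDim), Jhat = 0,
    actors = list(pan = mk(), tilt = mk(), vergence = mk()),
    hyper = list(gamma = gamma, alpha = alpha, xi = xi, beta = beta,
      eta = eta, temperature = temperature),
    stateDim = as.integer(stateDim))
}

#' Critic value estimate
#'
#' Linear value function `V(s) = <thetaV, s>`.
#'
#' @param agent an [AecAgent-class].
#' @param s state vector.
#' @return scalar value estimate.
#' @export
criticValue <- function(agent, s) {
  if (length(s) != agent@stateDim) stop("state dimension mismatch")
  sum(agent@thetaV * s)
}

#' Temporal-difference error with average-reward baseline
#'
#' `delta_t = r_t - Jhat_t + gamma V(s_t) - V(s_{t-2})`: the value of the
#' current state is compared, two steps back, against the state in which the
#' credited action was taken (actions need two iterations to reach their
#' full sensory effect).
#'
#' @param r reward at time t.
#' @param Jhat current average-reward estimate.
#' @param vNow critic value of `s_t`.
#' @param vPrev2 critic value of `s_{t-2}`.
#' @param gamma discount factor.
#' @return scalar TD error.
#' @export
tdError <- function(r, Jhat, vNow, vPrev2, gamma = 0.3) {
  r - Jhat + gamma * vNow - vPrev2
}

#' Low-pass update of the average-reward estimate
#'
#' `Jhat' = (1 - xi) Jhat + xi r`.
#'
#' @param Jhat current estimate.
#' @param r reward.
#' @param xi smoothing factor.
#' @return updated estimate.
#' @export
updateAvgReward <- function(Jhat, r, xi = 0.01) {
  (1 - xi) * Jhat + xi * r
}

#' Critic weight update
#'
#' `thetaV' = thetaV + alpha delta s_{t-2}`.
#'
#' @param agent an [AecAgent-class].
#' @param delta TD error.
#' @param sPrev2 state vector `s_{t-2}`.
#' @return the updated agent.
#' @export
updateCritic <- function(agent, delta, sPrev2) {
  agent@thetaV <- agent@thetaV + agent@hyper$alpha * delta * sPrev2
  agent
}

softmaxProbs <- function(z, temperature) {
  z <- z / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Softmax policy of one actor
#'
#' `pi_a  propto  exp(<theta_a, s> / T)`, numerically stabilized by
#' subtracting the maximum activation.
#'
#' @param agent an [AecAgent-class].
#' @param s state vector.
#' @param joint `"pan"`, `"tilt"` or `"vergence"`.
#' @param temperature softmax temperature (defaults to the agent's).
#' @return probability vector over the action set (sums to 1).
#' @export
policyProbs <- function(agent, s, joint = c("pan", "tilt", "vergence"),
                        temperature = NULL) {
  joint <- match.arg(joint)
  if (is.null(temperature)) temperature <- agent@hyper$temperature
  if (temperature <= 0) stop("temperature must be > 0")
  z <- as.vector(agent@actors[[joint]]$thetaA %*% s)
  softmaxProbs(z, temperature)
}

#' Natural-gradient actor update with advantage parameters
#'
#' For the softmax-linear policy the score is
#' `zeta_{a,i} = (1[a = a_{t-2}] - pi_a(s_{t-2})) s_i`. The advantage
#' parameters follow `w' = w + beta (delta zeta - zeta <zeta, w>)` and the
#' actor weights take a natural-gradient step `theta' = theta + eta w'`.
#'
#' @param agent an [AecAgent-class].
#' @param joint which actor to update.
#' @param delta shared TD error from the critic.
#' @param sPrev2 state `s_{t-2}`.
#' @param aIndex index (into the action set) of the action taken at t-2.
#' @return the updated agent.
#' @export
nacUpdate <- function(agent, joint = c("pan", "tilt", "vergence"), delta,
                      sPrev2, aIndex) {
  joint <- match.arg(joint)
  ac <- agent@actors[[joint]]
  pi0 <- softmaxProbs(as.vector(ac$thetaA %*% sPrev2),
    agent@hyper$temperature)
  ind <- numeric(length(agent@actions))
  ind[aIndex] <- 1
  zeta <- tcrossprod(ind - pi0, sPrev2)          # |A| x |s| score matrix
  zw <- sum(zeta * ac$w)
  ac$w <- ac$w + agent@hyper$beta * (delta * zeta - zeta * zw)
  ac$thetaA <- ac$thetaA + agent@hyper$eta * ac$w
  agent@actors[[joint]] <- ac
  agent
}

#' Choose the three joint actions
#'
#' `"sample"` draws each joint's action from its softmax policy (the
#' training behaviour), `"greedy"` takes the action with maximal activation
#' breaking exact ties towards the lowest-magnitude action (the testing
#' behaviour), `"random"` samples uniformly from the action set (the RNDCTL
#' control). Uses the current R RNG.
#'
#' @param agent an [AecAgent-class].
#' @param s state vector (ignored for `"random"`).
#' @param mode `"sample"`, `"greedy"` or `"random"`.
#' @return list with `actions` (named numeric: pan, tilt, vergence) and
#'   `index` (named integer positions in the action set).
#' @export
chooseActions <- function(agent, s, mode = c("sample", "greedy", "random")) {
  mode <- match.arg(mode)
  A <- agent@actions
  idx <- vapply(c("pan", "tilt", "vergence"), function(joint) {
    if (mode == "random") return(sample.int(length(A), 1))
    z <- as.vector(agent@actors[[joint]]$thetaA %*% s)
    if (mode == "sample") {
      sample.int(length(A), 1, prob = softmaxProbs(z, agent@hyper$temperature))
    } else {
      cand <- which(z == max(z))
      cand[order(abs(A[cand]), A[cand])][1]
    }
  }, integer(1))
  list(actions = stats::setNames(A[idx], names(idx)), index = idx)
}

#' Two-step transition buffer
#'
#' Holds the `(state, action, value)` tuples of the last two iterations so
#' that updates at time t consume exactly `(s_{t-2}, a_{t-2})` together with
#' the current reward. `pushTransition()` appends a tuple, `bufferReady()`
#' says whether a t-2 entry exists (the first two iterations after an
#' episode reset perform no updates).
#'
#' @return `newTransitionBuffer()` returns an empty buffer.
#' @export
newTransitionBuffer <- function() list()

#' @rdname newTransitionBuffer
#' @param buffer the buffer.
#' @param s state vector.
#' @param aIndex named action indices as returned by [chooseActions()].
#' @param tag optional identifier (e.g. the iteration), kept for diagnostics.
#' @export
pushTransition <- function(buffer, s, aIndex, tag = NA) {
  entry <- list(s = s, aIndex = aIndex, tag = tag)
  buffer <- c(buffer, list(entry))
  if (length(buffer) > 2) buffer <- buffer[-1]
  buffer
}

#' @rdname newTransitionBuffer
#' @export
bufferReady <- function(buffer) length(buffer) == 2

#' One full learning update from the buffer
#'
#' Applies, in order: the average-reward update, the TD error with respect
#' to `(s_t, s_{t-2})`, the critic update and one natural-gradient update per
#' actor, all sharing the single TD error. Does nothing unless the buffer
#' holds two past transitions.
#'
#' @param agent an [AecAgent-class].
#' @param buffer a two-entry buffer; entry 1 is the t-2 transition.
#' @param sNow current state `s_t`.
#' @param r current reward `r_t`.
#' @return list with the updated `agent`, the TD error `delta` (NA when no
#'   update was performed), and `usedTag`, the tag of the consumed t-2 entry.
#' @export
agentUpdate <- function(agent, buffer, sNow, r) {
  if (!bufferReady(buffer))
    return(list(agent = agent, delta = NA_real_, usedTag = NA))
  prev2 <- buffer[[1]]
  agent@Jhat <- updateAvgReward(agent@Jhat, r, agent@hyper$xi)
  delta <- tdError(r, agent@Jhat, criticValue(agent, sNow),
    criticValue(agent, prev2$s), agent@hyper$gamma)
  agent <- updateCritic(agent, delta, prev2$s)
  for (joint in c("pan", "tilt", "vergence"))
    agent <- nacUpdate(agent, joint, delta, prev2$s, prev2$aIndex[[joint]])
  list(agent = agent, delta = delta, usedTag = prev2$tag)
}

#' Contextual-bandit sanity check for the actor-critic
#'
#' A desk-scale analogue of the tracking problem: states are one-hot
#' indicators of a true error value taken from the action set, the reward is
#' `-|error + action|`, so the optimal action exactly cancels the error.
#' One actor and the critic are trained on uniformly drawn states; the
#' return value reports how often the greedy policy picks the cancelling
#' action. The default learning rates are scaled to this task (one-hot
#' states of magnitude 1, rewards down to -32, no sensory noise): a small
#' actor step keeps the sampling policy near-uniform so every action is
#' explored in every state, while the accumulated natural gradient ranks
#' the actions; the full-model rates drive the softmax into premature
#' saturation here because the state vector is two orders of magnitude
#' larger than the sparse-coding state.
#'
#' @param nUpdates number of training updates.
#' @param actions action set (also the error values).
#' @param seed RNG seed.
#' @param alpha,beta,eta task-scaled learning rates of critic, advantage
#'   parameters and actor.
#' @return list with `accuracy` (fraction of states whose greedy action is
#'   the error-cancelling one) and the trained `agent`.
#' @export
nacBandit <- function(nUpdates = 20000L, actions = defaultActions(),
                      seed = 1L, alpha = 0.1, beta = 0.01, eta = 0.001) {
  nS <- length(actions)
  withSeed(seed, {
    agent <- newAgent(nS, actions, alpha = alpha, beta = beta, eta = eta)
    for (t in seq_len(nUpdates)) {
      i <- sample.int(nS, 1)
      s <- numeric(nS); s[i] <- 1
      ch <- chooseActions(agent, s, "sample")
      r <- -abs(actions[i] + ch$actions[["pan"]])
      agent@Jhat <- updateAvgReward(agent@Jhat, r, agent@hyper$xi)
      delta <- tdError(r, agent@Jhat, 0, criticValue(agent, s),
        gamma = agent@hyper$gamma)
      agent <- updateCritic(agent, delta, s)
      agent <- nacUpdate(agent, "pan", delta, s, ch$index[["pan"]])
    }
    greedy <- vapply(seq_len(nS), function(i) {
      s <- numeric(nS); s[i] <- 1
      chooseActions(agent, s, "greedy")$actions[["pan"]]
    }, numeric(1))
    list(accuracy = mean(greedy == -actions), agent = agent)
  })
}
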