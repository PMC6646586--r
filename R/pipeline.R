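#' Training configuration
#'
#' All defaults equal the model's values: 5e5 iterations of 100 ms in
#' 40-iteration intervals, 600-atom dictionaries per scale, the standard
#' 13-action sets, stimulus depth in \[1, 2.5\] m with angular speeds up to
#' 7.5 deg/s and depth speeds up to 0.375 m/s, initial fixation distances in
#' \[0.3, 3\] m, joint limits +-15 deg (pan/tilt) and \[0.2, 16.3\] deg
#' (vergence). `deskProfile()` scales the experiment to a workstation
#' (5e4 iterations, 200 atoms, 5 test stimuli).
#'
#' @param totalIterations number of training iterations.
#' @param episodeLength iterations per training interval (40).
#' @param dt iteration duration in seconds (0.1).
#' @param nAtoms dictionary size per scale.
#' @param actionVariant `"STD"` or `"CAS"` (coarse action set, no +-0.5).
#' @param scales `"both"` or `"NFS"` (no fine scale).
#' @param policy `"learned"` or `"RNDCTL"` (uniform random actions).
#' @param nStimuli number of training textures.
#' @param stimulusKinds texture generator kinds cycled over the stimuli.
#' @param stimulusSide texture resolution in pixels.
#' @param depthRange,velMax,fixationRange,panTiltLimit,vergenceRange world
#'   and joint parameter ranges (see [placeStimulus()], [resetGaze()],
#'   [checkLimits()]).
#' @param stimulusSize stimulus plane side, metres.
#' @param backgroundDistance background plane distance, metres.
#' @param mpIterations matching-pursuit non-zero budget (10).
#' @param etaDict dictionary learning rate (0.5).
#' @param dictLearning,rlLearning switches for the two learning systems.
#' @param nTestStimuli test-set size used by [makeTestGrid()].
#' @param checkpoints number of evenly spaced checkpoints.
#' @return a named list of class `aecTrainConfig`.
#' @export
trainConfig <- function(totalIterations = 5e5, episodeLength = 40L, dt = 0.1,
                        nAtoms = 600L, actionVariant = "STD",
                        scales = c("both", "NFS"),
                        policy = c("learned", "RNDCTL"), nStimuli = 100L,
                        stimulusKinds = c("pink_noise", "edges", "blocks"),
                        stimulusSide = 600L, depthRange = c(1, 2.5),
                        velMax = c(7.5, 7.5, 0.375), fixationRange = c(0.3, 3),
                        panTiltLimit = 15, vergenceRange = c(0.2, 16.3),
                        stimulusSize = 1.5, backgroundDistance = 6,
                        mpIterations = 10L, etaDict = 0.5,
                        dictLearning = TRUE, rlLearning = TRUE,
                        nTestStimuli = 50L, checkpoints = 10L) {
  cfg <- list(totalIterations = as.integer(totalIterations),
    episodeLength = as.integer(episodeLength), dt = dt,
    nAtoms = as.integer(nAtoms), actionVariant = actionVariant,
    scales = match.arg(scales), policy = match.arg(policy),
    nStimuli = as.integer(nStimuli), stimulusKinds = stimulusKinds,
    stimulusSide = as.integer(stimulusSide), depthRange = depthRange,
    velMax = velMax, fixationRange = fixationRange,
    panTiltLimit = panTiltLimit, vergenceRange = vergenceRange,
    stimulusSize = stimulusSize, backgroundDistance = backgroundDistance,
    mpIterations = as.integer(mpIterations), etaDict = etaDict,
    dictLearning = dictLearning, rlLearning = rlLearning,
    nTestStimuli = as.integer(nTestStimuli),
    checkpoints = as.integer(checkpoints))
  class(cfg) <- "aecTrainConfig"
  cfg
}

#' @rdname trainConfig
#' @param ... overrides passed on to [trainConfig()].
#' @export
deskProfile <- function(...) {
  args <- list(totalIterations = 5e4, nAtoms = 200L, nStimuli = 10L,
    stimulusSide = 512L, nTestStimuli = 5L)
  override <- list(...)
  args[names(override)] <- override
  do.call(trainConfig, args)
}

#' @rdname trainConfig
#' @export
paperProfile <- function(...) trainConfig(...)

#' Read / write a training configuration as JSON
#'
#' Flat keys mirroring [trainConfig()] arguments; missing keys fall back to
#' the defaults.
#'
#' @param path file path.
#' @param config an `aecTrainConfig` list.
#' @return `readConfig()` returns an `aecTrainConfig`.
#' @export
readConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(trainConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(trainConfig, vals)
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

## Build the cycled training texture set.
makeStimulusSet <- function(cfg, seed) {
  kinds <- rep_len(cfg$stimulusKinds, cfg$nStimuli)
  lapply(seq_len(cfg$nStimuli), function(i)
    makeTexture((seed * 131L + i) %% .Machine$integer.max, kinds[i],
      side = cfg$stimulusSide))
}

## One encode pass over both scales; fine may be disabled (NFS).
encodeFrame <- function(ps, dictC, dictF, k) {
  codeC <- matchingPursuit(ps$coarse, dictC, k)
  Ec <- reconstructionError(ps$coarse, codeC)
  if (is.null(dictF))
    return(list(codeC = codeC, codeF = NULL, Ec = Ec, Ef = 0))
  codeF <- matchingPursuit(ps$fine, dictF, k)
  list(codeC = codeC, codeF = codeF, Ec = Ec,
    Ef = reconstructionError(ps$fine, codeF))
}

#' Train the active efficient coding agent
#'
#' Runs the perception-action loop: render a binocular frame, whiten and cut
#' spatio-temporal patches at both scales, encode them by matching pursuit,
#' use the negative total reconstruction error as reward, update critic and
#' actors with two-step delayed credit, update the dictionaries, choose and
#' apply the next eye commands and advance the world. Every
#' `episodeLength` iterations a new stimulus is placed and the gaze is reset;
#' joint-limit violations zero the eye velocities and reset the gaze; a
#' stimulus closer than 5 cm aborts the interval.
#'
#' @param config an `aecTrainConfig`, see [trainConfig()].
#' @param seed integer master seed; the run is fully reproducible.
#' @param checkpointDir optional directory for RDS checkpoints at
#'   `config$checkpoints` evenly spaced iterations (final one included).
#' @param keepCheckpoints keep in-memory copies of the checkpoints?
#' @param verbose print progress every 1000 iterations?
#' @return list of class `aecRun`: `dictC`, `dictF` (NULL under NFS),
#'   `agent`, `log` (per-iteration data.frame), `config`, `seed`,
#'   `checkpoints` (list, possibly empty).
#' @export
trainAgent <- function(config = deskProfile(), seed = 1L,
                       checkpointDir = NULL, keepCheckpoints = FALSE,
                       verbose = FALSE) {
  cfg <- config
  total <- cfg$totalIterations
  withSeed(seed, {
    stimuli <- makeStimulusSet(cfg, seed)
    background <- makeTexture((seed * 131L + 9999L) %% .Machine$integer.max,
      "pink_noise", side = 512L)
    dictC <- initDictionary(cfg$nAtoms, "coarse", seed = seed %% 1e6 + 1L)
    dictF <- if (cfg$scales == "both")
      initDictionary(cfg$nAtoms, "fine", seed = seed %% 1e6 + 2L) else NULL
    stateDim <- cfg$nAtoms * (if (cfg$scales == "both") 2L else 1L)
    agent <- newAgent(stateDim, defaultActions(cfg$actionVariant))

    world <- worldState(stimuli[[1]], background, depth = 1.5,
      size = cfg$stimulusSize, backgroundDistance = cfg$backgroundDistance)
    eyes <- eyePose(baseline = 0.068)
    buffer <- newTransitionBuffer()
    log <- data.frame(iteration = seq_len(total), episode = NA_integer_,
      Ec = NA_real_, Ef = NA_real_, reward = NA_real_, aPan = NA_real_,
      aTilt = NA_real_, aVerg = NA_real_, pan = NA_real_, tilt = NA_real_,
      vergence = NA_real_, limit = FALSE)
    ckIters <- unique(round(seq(total / cfg$checkpoints, total,
      length.out = cfg$checkpoints)))
    checkpoints <- list()

    episode <- 0L
    newEpisode <- TRUE
    prev <- NULL
    for (t in seq_len(total)) {
      if (newEpisode || (t - 1L) %% cfg$episodeLength == 0L) {
        episode <- episode + 1L
        world <- placeStimulus(world, cfg$depthRange, cfg$velMax,
          stimulus = stimuli[[sample.int(length(stimuli), 1)]])
        eyes <- resetGaze(eyes, cfg$fixationRange, cfg$vergenceRange)
        buffer <- newTransitionBuffer()
        prevP <- framePatches(renderBinocular(world, eyes, t - 1L))
        newEpisode <- FALSE
      }
      curP <- framePatches(renderBinocular(world, eyes, t))
      ps <- patchSetsFromScales(prevP, curP)
      enc <- encodeFrame(ps, dictC, dictF, cfg$mpIterations)
      reward <- -(enc$Ec + enc$Ef)
      if (!is.finite(reward))
        stop("non-finite reward at iteration ", t)
      s <- stateVector(enc$codeC, enc$codeF)

      if (cfg$rlLearning && cfg$policy == "learned") {
        upd <- agentUpdate(agent, buffer, s, reward)
        agent <- upd$agent
      }
      if (cfg$dictLearning) {
        dictC <- updateDictionary(dictC, ps$coarse, enc$codeC, cfg$etaDict)
        if (!is.null(dictF))
          dictF <- updateDictionary(dictF, ps$fine, enc$codeF, cfg$etaDict)
      }

      mode <- if (cfg$policy == "RNDCTL") "random" else "sample"
      ch <- chooseActions(agent, s, mode)
      buffer <- pushTransition(buffer, s, ch$index, tag = t)
      eyes <- applyEyeCommand(eyes, ch$actions[["pan"]], ch$actions[["tilt"]],
        ch$actions[["vergence"]], cfg$dt)

      limit <- checkLimits(eyes, cfg$panTiltLimit, cfg$vergenceRange)
      log[t, c("episode", "Ec", "Ef", "reward", "aPan", "aTilt", "aVerg",
        "pan", "tilt", "vergence", "limit")] <-
        list(episode, enc$Ec, enc$Ef, reward, ch$actions[["pan"]],
          ch$actions[["tilt"]], ch$actions[["vergence"]], eyes@pan,
          eyes@tilt, eyes@vergence, limit)
      if (limit) {
        eyes@panVel <- 0; eyes@tiltVel <- 0
        eyes <- resetGaze(eyes, cfg$fixationRange, cfg$vergenceRange)
        buffer <- newTransitionBuffer()
        prevP <- framePatches(renderBinocular(world, eyes, t))
      } else {
        prevP <- curP
      }
      world <- tryCatch(stepWorld(world, cfg$dt),
        episodeAbort = function(e) NULL)
      if (is.null(world)) {
        world <- worldState(stimuli[[1]], background, depth = 1.5,
          size = cfg$stimulusSize,
          backgroundDistance = cfg$backgroundDistance)
        newEpisode <- TRUE
      }
      if (t %in% ckIters) {
        ck <- list(dictC = dictC, dictF = dictF, agent = agent,
          iteration = t, config = cfg, seed = seed)
        if (!is.null(checkpointDir)) {
          dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
          saveCheckpoint(ck, file.path(checkpointDir,
            sprintf("checkpoint_%07d.rds", t)))
        }
        if (keepCheckpoints) checkpoints[[as.character(t)]] <- ck
      }
      if (verbose && t %% 1000L == 0L)
        message(sprintf("iteration %d / %d, E = %.2f", t, total, -reward))
    }
    structure(list(dictC = dictC, dictF = dictF, agent = agent, log = log,
      config = cfg, seed = seed, checkpoints = checkpoints),
      class = "aecRun")
  })
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a plain list with elements `dictC`, `dictF`, `agent`,
#' `iteration`, `config`, `seed`, stored as an RDS file.
#'
#' @param checkpoint the checkpoint list (an `aecRun` works too).
#' @param path file path.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  keep <- intersect(names(checkpoint),
    c("dictC", "dictF", "agent", "iteration", "config", "seed"))
  saveRDS(checkpoint[keep], path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Build the testing grid
#'
#' The full factorial of test stimuli and the six velocity multipliers
#' `{+-0.1, +-0.5, +-1}` applied per axis to the maximum velocities: for 50
#' stimuli, `50 * 6^3 = 10800` trials.
#'
#' @param nStimuli number of test stimuli.
#' @param multipliers velocity multipliers per axis.
#' @param trialLength iterations per trial (10).
#' @param velMax maximum velocities (deg/s, deg/s, m/s).
#' @return data.frame with one row per trial (`stimulus`, `vH`, `vV`, `vZ`);
#'   `attr(, "trialLength")` carries the trial length.
#' @export
makeTestGrid <- function(nStimuli = 50L,
                         multipliers = c(-1, -0.5, -0.1, 0.1, 0.5, 1),
                         trialLength = 10L, velMax = c(7.5, 7.5, 0.375)) {
  g <- expand.grid(stimulus = seq_len(nStimuli), mH = multipliers,
    mV = multipliers, mZ = multipliers, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(trial = seq_len(nrow(g)), stimulus = g$stimulus,
    vH = g$mH * velMax[1], vV = g$mV * velMax[2], vZ = g$mZ * velMax[3])
  attr(out, "trialLength") <- as.integer(trialLength)
  out
}

#' Hand-coded perfect-tracking policy
#'
#' An oracle that reads the true world and eye state and picks, per joint,
#' the admissible action closest to the error-cancelling command:
#' accelerations `(v_stimulus - v_eye) / dt` for pan and tilt, and the
#' vergence change towards [vergenceTarget()] of the current depth. Used to
#' validate the environment and the testing protocol.
#'
#' @param dt iteration duration, seconds.
#' @return a function `(world, eyes, actions) -> named numeric` suitable for
#'   [testPolicy()]'s `policy` argument.
#' @export
oraclePolicy <- function(dt = 0.1) {
  nearest <- function(x, actions) actions[which.min(abs(actions - x))]
  function(world, eyes, actions) {
    c(pan = nearest((world@velocity[1] - eyes@panVel) / dt, actions),
      tilt = nearest((world@velocity[2] - eyes@tiltVel) / dt, actions),
      vergence = nearest(vergenceTarget(world@depth, eyes@baseline) -
        eyes@vergence, actions))
  }
}

#' Test a policy on the trial grid
#'
#' For every trial the stimulus is placed as during training (fresh texture,
#' centred, depth drawn from the training distribution with a per-trial seed
#' derived from the trial index), the velocities are set from the grid, the
#' gaze is reset, and the policy runs for `trialLength` iterations with all
#' learning switched off. The trial records, at the last iteration, the
#' pursuit errors `dvPan`, `dvTilt` (deg/iteration, stimulus minus eye
#' speed) and the vergence error `dXi` (deg, actual minus desired vergence).
#'
#' @param model an `aecRun` or checkpoint list (`dictC`, `dictF`, `agent`,
#'   `config`); may be `NULL` when a kinematic `policy` is supplied.
#' @param grid a [makeTestGrid()] data.frame.
#' @param seed base seed for the per-trial placements.
#' @param policy optional kinematic policy function
#'   `(world, eyes, actions) -> named numeric` (e.g. [oraclePolicy()]);
#'   when given, rendering and encoding are skipped.
#' @param stimuli optional list of [Texture-class] test stimuli (generated
#'   from the grid's stimulus ids otherwise; kinematic runs need none).
#' @param config a `aecTrainConfig` to take ranges from (defaults to the
#'   model's, or [trainConfig()]).
#' @return data.frame of trial results: `trial`, `stimulus`, `vH`, `vV`,
#'   `vZ`, `dvPan`, `dvTilt`, `dXi`, `aborted`.
#' @export
testPolicy <- function(model = NULL, grid = makeTestGrid(), seed = 1L,
                       policy = NULL, stimuli = NULL, config = NULL) {
  cfg <- config %||% model$config %||% trainConfig()
  trialLength <- attr(grid, "trialLength") %||% 10L
  kinematic <- !is.null(policy)
  actions <- if (kinematic) defaultActions(cfg$actionVariant)
    else actionSet(model$agent)
  if (!kinematic && is.null(stimuli)) {
    ids <- sort(unique(grid$stimulus))
    kinds <- rep_len(cfg$stimulusKinds, length(ids))
    stimuli <- lapply(seq_along(ids), function(i)
      makeTexture((seed * 977L + 5000L + i) %% .Machine$integer.max,
        kinds[i], side = cfg$stimulusSide))
    names(stimuli) <- ids
  }
  background <- makeTexture((seed * 977L + 4999L) %% .Machine$integer.max,
    "pink_noise", side = 512L)

  res <- grid
  res$dvPan <- NA_real_; res$dvTilt <- NA_real_; res$dXi <- NA_real_
  res$aborted <- FALSE
  for (i in seq_len(nrow(grid))) {
    tr <- grid[i, ]
    out <- withSeed((seed * 7919L + tr$trial) %% .Machine$integer.max, {
      tex <- if (kinematic) NULL else stimuli[[as.character(tr$stimulus)]]
      world <- worldState(tex %||% background, background, depth = 1.5,
        size = cfg$stimulusSize,
        backgroundDistance = cfg$backgroundDistance)
      world <- placeStimulus(world, cfg$depthRange, cfg$velMax)
      world@velocity <- c(tr$vH, tr$vV, tr$vZ)
      eyes <- resetGaze(eyePose(baseline = 0.068), cfg$fixationRange,
        cfg$vergenceRange)
      prevP <- if (kinematic) NULL else
        framePatches(renderBinocular(world, eyes, 0L))
      aborted <- FALSE
      for (it in seq_len(trialLength)) {
        a <- if (kinematic) {
          policy(world, eyes, actions)
        } else {
          curP <- framePatches(renderBinocular(world, eyes, it))
          ps <- patchSetsFromScales(prevP, curP)
          enc <- encodeFrame(ps, model$dictC, model$dictF, cfg$mpIterations)
          s <- stateVector(enc$codeC, enc$codeF)
          prevP <- curP
          chooseActions(model$agent, s, "greedy")$actions
        }
        eyes <- applyEyeCommand(eyes, a[["pan"]], a[["tilt"]],
          a[["vergence"]], cfg$dt)
        if (checkLimits(eyes, cfg$panTiltLimit, cfg$vergenceRange)) {
          eyes@panVel <- 0; eyes@tiltVel <- 0
          eyes <- resetGaze(eyes, cfg$fixationRange, cfg$vergenceRange)
          if (!kinematic) prevP <- framePatches(renderBinocular(world, eyes, it))
        }
        world <- tryCatch(stepWorld(world, cfg$dt),
          episodeAbort = function(e) NULL)
        if (is.null(world)) { aborted <- TRUE; break }
      }
      if (aborted) list(NA_real_, NA_real_, NA_real_, TRUE)
      else list((world@velocity[1] - eyes@panVel) * cfg$dt,
        (world@velocity[2] - eyes@tiltVel) * cfg$dt,
        eyes@vergence - vergenceTarget(world@depth, eyes@baseline), FALSE)
    })
    res[i, c("dvPan", "dvTilt", "dXi", "aborted")] <- out
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric samples.
#' @return `(mean(x) - mean(y)) / sd_pooled`.
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 == 0) return(0)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Compare two sets of test results
#'
#' Welch t-tests on the absolute last-iteration errors of each joint, with
#' Cohen's d (pooled SD) as effect size.
#'
#' @param a,b [testPolicy()] result data.frames.
#' @return data.frame with one row per joint: `joint`, `p`, `d`, and the two
#'   median absolute errors.
#' @export
compareRuns <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty result set")
  cols <- c(pan = "dvPan", tilt = "dvTilt", vergence = "dXi")
  do.call(rbind, lapply(names(cols), function(j) {
    x <- abs(a[[cols[j]]]); x <- x[is.finite(x)]
    y <- abs(b[[cols[j]]]); y <- y[is.finite(y)]
    p <- if (sd(x) == 0 && sd(y) == 0) 1 else
      stats::t.test(x, y)$p.value
    data.frame(joint = j, p = p, d = cohensD(x, y),
      medianA = median(x), medianB = median(y))
  }))
}
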