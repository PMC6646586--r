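#' Construct an eye pose
#'
#' @param pan,tilt version angles in degrees.
#' @param panVel,tiltVel version angular velocities in deg/s.
#' @param vergence total vergence angle in degrees.
#' @param baseline interocular distance in metres.
#' @return an [EyePose-class].
#' @export
eyePose <- function(pan = 0, tilt = 0, panVel = 0, tiltVel = 0,
                    vergence = 2, baseline = 0.068) {
  new("EyePose", pan = pan, tilt = tilt, panVel = panVel, tiltVel = tiltVel,
    vergence = vergence, baseline = baseline)
}

#' Construct a world state
#'
#' @param stimulus,background [Texture-class] objects.
#' @param azimuth,elevation angular position of the stimulus centre, degrees.
#' @param depth stimulus distance, metres.
#' @param velocity numeric(3): (deg/s horizontal, deg/s vertical, m/s depth).
#' @param size stimulus plane side, metres.
#' @param backgroundDistance background plane distance, metres.
#' @return a [WorldState-class].
#' @export
worldState <- function(stimulus, background, azimuth = 0, elevation = 0,
                       depth = 1.5, velocity = c(0, 0, 0), size = 1.5,
                       backgroundDistance = 6) {
  new("WorldState", stimulus = stimulus, azimuth = azimuth,
    elevation = elevation, depth = depth, velocity = velocity, size = size,
    background = background, backgroundDistance = backgroundDistance)
}

#' Desired vergence angle for an object distance
#'
#' The vergence angle that makes both optical axes intersect at a point
#' directly ahead at distance `dO`: `2 * atan(dE / (2 dO))`.
#'
#' @param dO object distance, metres (> 0).
#' @param dE interocular baseline, metres.
#' @return desired vergence angle in degrees; decreasing in `dO`.
#' @examples
#' vergenceTarget(1)    # ~3.896 deg
#' vergenceTarget(1e6)  # ~0 deg
#' @export
vergenceTarget <- function(dO, dE = 0.068) {
  if (any(dO <= 0)) stop("object distance must be > 0")
  2 * atan(dE / (2 * dO)) * 180 / pi
}

#' Place a stimulus at the start of a training interval
#'
#' Centres the stimulus on the cyclopean gaze direction (azimuth = elevation
#' = 0), draws its depth uniformly from `depthRange` and its episode-constant
#' velocities uniformly from `velMax` ranges. Uses the current R RNG; seed
#' with `set.seed()` for reproducibility.
#'
#' @param world a [WorldState-class].
#' @param depthRange metres, default \[1, 2.5\].
#' @param velMax maximum magnitudes of (deg/s, deg/s, m/s) velocities,
#'   default (7.5, 7.5, 0.375).
#' @param stimulus optional replacement [Texture-class] (a newly drawn
#'   stimulus).
#' @return the updated [WorldState-class].
#' @export
placeStimulus <- function(world, depthRange = c(1, 2.5),
                          velMax = c(7.5, 7.5, 0.375), stimulus = NULL) {
  if (!is.null(stimulus)) world@stimulus <- stimulus
  world@azimuth <- 0
  world@elevation <- 0
  world@depth <- runif(1, depthRange[1], depthRange[2])
  world@velocity <- c(runif(1, -velMax[1], velMax[1]),
    runif(1, -velMax[2], velMax[2]),
    runif(1, -velMax[3], velMax[3]))
  validObject(world)
  world
}

episodeAbort <- function(msg = "stimulus too close, episode aborted") {
  structure(class = c("episodeAbort", "error", "condition"),
    list(message = msg, call = NULL))
}

#' Advance the world by one iteration
#'
#' Angular position accumulates exactly (`azimuth += vH * dt`), so a constant
#' angular velocity of 7.5 deg/s over ten 0.1 s steps moves the stimulus by
#' exactly 7.5 degrees; depth advances by `vZ * dt`. The plane remains
#' fronto-parallel. If the new depth would be <= 0.05 m an `episodeAbort`
#' condition is signalled.
#'
#' @param world a [WorldState-class].
#' @param dt time step in seconds (one iteration = 0.1 s).
#' @return the advanced [WorldState-class].
#' @export
stepWorld <- function(world, dt = 0.1) {
  nd <- world@depth + world@velocity[3] * dt
  if (nd <= 0.05) stop(episodeAbort())
  world@azimuth <- world@azimuth + world@velocity[1] * dt
  world@elevation <- world@elevation + world@velocity[2] * dt
  world@depth <- nd
  world
}

#' Apply one motor command to the eyes
#'
#' Pan and tilt commands are angular accelerations (deg/s^2), integrated
#' semi-implicitly (velocity first, then position) over `dt`; the vergence
#' command is a direct change of the vergence angle (deg). Joint limits are
#' not enforced here; see [checkLimits()].
#'
#' @param eyes an [EyePose-class].
#' @param aPan,aTilt angular accelerations, deg/s^2.
#' @param aVerg vergence angle change, deg.
#' @param dt time step, seconds.
#' @return the updated [EyePose-class].
#' @export
applyEyeCommand <- function(eyes, aPan = 0, aTilt = 0, aVerg = 0, dt = 0.1) {
  eyes@panVel <- eyes@panVel + aPan * dt
  eyes@tiltVel <- eyes@tiltVel + aTilt * dt
  eyes@pan <- eyes@pan + eyes@panVel * dt
  eyes@tilt <- eyes@tilt + eyes@tiltVel * dt
  eyes@vergence <- eyes@vergence + aVerg
  eyes
}

#' Check joint limits
#'
#' Limits are inclusive: `TRUE` is returned only when a joint lies strictly
#' outside its range (pan/tilt beyond +-15 deg, vergence outside
#' \[0.2, 16.3\] deg). On violation the caller zeroes the joint velocities
#' and resets the gaze ([resetGaze()]).
#'
#' @param eyes an [EyePose-class].
#' @param panTiltLimit half-range for pan and tilt, degrees.
#' @param vergenceRange allowed vergence interval, degrees.
#' @return logical flag, `TRUE` on violation.
#' @export
checkLimits <- function(eyes, panTiltLimit = 15, vergenceRange = c(0.2, 16.3)) {
  abs(eyes@pan) > panTiltLimit || abs(eyes@tilt) > panTiltLimit ||
    eyes@vergence < vergenceRange[1] || eyes@vergence > vergenceRange[2]
}

#' Reset the gaze to a random fixation straight ahead
#'
#' Pan, tilt and all velocities are zeroed; the vergence angle is set to
#' fixate a point directly ahead at a distance drawn uniformly from
#' `fixationRange`, clipped into the vergence joint range. Uses the current
#' R RNG.
#'
#' @param eyes an [EyePose-class].
#' @param fixationRange metres, default \[0.3, 3\].
#' @param vergenceRange clipping interval for the vergence angle, degrees.
#' @return the reset [EyePose-class].
#' @export
resetGaze <- function(eyes, fixationRange = c(0.3, 3),
                      vergenceRange = c(0.2, 16.3)) {
  d <- runif(1, fixationRange[1], fixationRange[2])
  eyes@pan <- 0; eyes@tilt <- 0
  eyes@panVel <- 0; eyes@tiltVel <- 0
  eyes@vergence <- min(max(vergenceTarget(d, eyes@baseline),
    vergenceRange[1]), vergenceRange[2])
  eyes
}
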