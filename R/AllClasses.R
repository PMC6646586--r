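#' @import methods
NULL

#' Texture: a square grayscale image used as a stimulus or background
#'
#' Gray values live in \[0, 1\]. Textures are produced by [makeTexture()] and
#' mapped onto the stimulus and background planes by the renderer.
#'
#' @slot pixels numeric matrix of gray values in \[0, 1\], square, side >= 256.
#' @slot kind character, generator kind (`"pink_noise"`, `"edges"`, `"blocks"`,
#'   `"file"`).
#' @slot seed integer seed the texture was generated with (NA for files).
#' @exportClass Texture
setClass("Texture",
  representation(pixels = "matrix", kind = "character", seed = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) != ncol(p)) return("texture must be square")
    if (nrow(p) < 256) return("texture side must be >= 256")
    if (any(!is.finite(p))) return("texture contains non-finite values")
    if (min(p) < 0 || max(p) > 1) return("gray values must lie in [0, 1]")
    TRUE
  })

#' WorldState: pose, motion and texture of the stimulus plane
#'
#' The stimulus is a fronto-parallel textured plane of side `size` metres in a
#' cyclopean coordinate frame (+x right, +y up, +z depth ahead, origin midway
#' between the cameras). Its direction is tracked as azimuth/elevation angles
#' so that constant angular velocities accumulate exactly; the Cartesian
#' centre is derived as `(d tan(az), d tan(el), d)`. A second textured plane
#' at `backgroundDistance` fills the rest of the visual field.
#'
#' @slot stimulus a [Texture-class].
#' @slot azimuth,elevation angular offset of the plane centre, degrees.
#' @slot depth distance of the plane, metres (> 0).
#' @slot velocity numeric(3): horizontal and vertical angular velocity
#'   (deg/s) and depth velocity (m/s), constant within an episode.
#' @slot size side length of the stimulus plane, metres (default 1.5).
#' @slot background a [Texture-class] for the background plane.
#' @slot backgroundDistance distance of the background plane, metres.
#' @exportClass WorldState
setClass("WorldState",
  representation(stimulus = "Texture", azimuth = "numeric",
    elevation = "numeric", depth = "numeric", velocity = "numeric",
    size = "numeric", background = "Texture",
    backgroundDistance = "numeric"),
  validity = function(object) {
    if (object@depth <= 0) return("stimulus depth must be > 0")
    if (length(object@velocity) != 3) return("velocity must be length 3")
    if (abs(object@azimuth) > 90 || abs(object@elevation) > 90)
      return("angular offsets must be within +/-90 deg")
    if (object@backgroundDistance <= object@depth)
      return("background must be behind the stimulus")
    TRUE
  })

#' EyePose: joint state of the binocular camera rig
#'
#' Pan and tilt are version angles applied to both cameras; vergence is the
#' total angle between the optical axes, split symmetrically (each camera
#' toed in by vergence/2). Units are degrees and deg/s.
#'
#' @slot pan,tilt version angles, degrees.
#' @slot panVel,tiltVel version angular velocities, deg/s.
#' @slot vergence total vergence angle, degrees.
#' @slot baseline interocular distance, metres (default 0.068).
#' @exportClass EyePose
setClass("EyePose",
  representation(pan = "numeric", tilt = "numeric", panVel = "numeric",
    tiltVel = "numeric", vergence = "numeric", baseline = "numeric"),
  validity = function(object) {
    v <- c(object@pan, object@tilt, object@panVel, object@tiltVel,
      object@vergence, object@baseline)
    if (any(!is.finite(v))) return("non-finite pose component")
    if (object@baseline <= 0) return("baseline must be > 0")
    TRUE
  })

#' ImagePair: one binocular frame
#'
#' @slot left,right grayscale matrices, 240 rows x 320 columns.
#' @slot timestamp iteration index the frame was rendered at.
#' @exportClass ImagePair
setClass("ImagePair",
  representation(left = "matrix", right = "matrix", timestamp = "integer"),
  validity = function(object) {
    for (im in list(object@left, object@right)) {
      if (!all(dim(im) == c(240L, 320L)))
        return("images must be 240 x 320")
      if (any(!is.finite(im))) return("non-finite pixel values")
    }
    TRUE
  })

#' ScaleConfig: geometry of one processing scale
#'
#' The coarse scale covers a 36 degree, 128 px sub-window down-sampled by 4
#' (near-peripheral vision); the fine scale an 18 degree, 64 px sub-window at
#' full resolution (macular vision). See [scaleConfig()].
#'
#' @slot name `"coarse"` or `"fine"`.
#' @slot windowPx side of the central sub-window cropped from the camera
#'   image, pixels.
#' @slot windowFovDeg field of view covered by the sub-window, degrees.
#' @slot downsampleFactor Gaussian-pyramid reduction factor (4 or 1).
#' @slot outputPx side of the scale's output image, pixels.
#' @slot patchPx patch side (8).
#' @slot stridePx patch stride (4).
#' @exportClass ScaleConfig
setClass("ScaleConfig",
  representation(name = "character", windowPx = "integer",
    windowFovDeg = "numeric", downsampleFactor = "integer",
    outputPx = "integer", patchPx = "integer", stridePx = "integer"),
  validity = function(object) {
    if (!object@name %in% c("coarse", "fine")) return("name must be coarse/fine")
    if (object@outputPx * object@downsampleFactor != object@windowPx)
      return("outputPx must equal windowPx / downsampleFactor")
    if ((object@outputPx - object@patchPx) %% object@stridePx != 0)
      return("patch grid does not tile the output image")
    TRUE
  })

#' Dictionary: sparse-coding basis functions for one scale
#'
#' Atoms are unit-energy 16 x 16 spatio-temporal binocular basis functions
#' stored as columns of a 256 x K matrix (column-major vectorisation of the
#' 16 x 16 array). Each atom holds four 8 x 8 subfields: rows 1-8 left eye,
#' rows 9-16 right eye; columns 1-8 time t-1, columns 9-16 time t (see
#' [atomSubfield()]).
#'
#' @slot scale `"coarse"` or `"fine"`.
#' @slot atoms numeric matrix, 256 x K, columns with unit Frobenius energy.
#' @slot mode initialization mode, `"gabor"` or `"white_noise"`.
#' @slot seed integer seed used at initialization.
#' @slot iteration number of training updates applied so far.
#' @slot initParams list of per-atom initialization parameters (Gabor mode
#'   only; used by tests and analyses), or empty list.
#' @exportClass Dictionary
setClass("Dictionary",
  representation(scale = "character", atoms = "matrix", mode = "character",
    seed = "integer", iteration = "integer", initParams = "list"),
  validity = function(object) {
    if (nrow(object@atoms) != 256) return("atoms must be 256 x K")
    if (any(!is.finite(object@atoms))) return("non-finite atom weights")
    en <- sqrt(colSums(object@atoms^2))
    if (any(abs(en - 1) > 1e-6)) return("atoms must have unit energy")
    TRUE
  })

#' AecAgent: critic and actor parameters of the reinforcement learner
#'
#' One linear critic and three independent softmax actors (pan, tilt,
#' vergence) sharing the sensory state vector. Each actor keeps its weight
#' matrix `thetaA` (|A| x |s|) and advantage-parameter matrix `w` of the same
#' shape. Hyper-parameters follow the model defaults: gamma = 0.3,
#' alpha = 0.4, xi = 0.01, beta = 0.16, eta = 0.4, temperature = 1.
#'
#' @slot actions numeric action set, symmetric about 0 and sorted.
#' @slot thetaV critic weight vector, length |s|.
#' @slot Jhat running average-reward estimate.
#' @slot actors named list (pan, tilt, vergence) of lists with elements
#'   `thetaA` and `w`.
#' @slot hyper named list of learning hyper-parameters.
#' @slot stateDim length of the state vector.
#' @exportClass AecAgent
setClass("AecAgent",
  representation(actions = "numeric", thetaV = "numeric", Jhat = "numeric",
    actors = "list", hyper = "list", stateDim = "integer"),
  validity = function(object) {
    a <- object@actions
    if (is.unsorted(a)) return("actions must be sorted")
    if (!0 %in% a) return("action set must contain 0")
    if (any(abs(sort(a) + rev(sort(a))) > 1e-12))
      return("action set must be symmetric about 0")
    if (length(object@thetaV) != object@stateDim)
      return("critic dimension mismatch")
    if (!all(c("pan", "tilt", "vergence") %in% names(object@actors)))
      return("actors must be named pan, tilt, vergence")
    for (ac in object@actors) {
      if (!all(dim(ac$thetaA) == c(length(a), object@stateDim)))
        return("actor dimension mismatch")
      if (!all(dim(ac$w) == dim(ac$thetaA)))
        return("advantage-parameter dimension mismatch")
    }
    TRUE
  })

setMethod("show", "Texture", function(object) {
  cat(sprintf("Texture (%s, seed %s): %d x %d, range [%.3f, %.3f]\n",
    object@kind, object@seed, nrow(object@pixels), ncol(object@pixels),
    min(object@pixels), max(object@pixels)))
})

setMethod("show", "WorldState", function(object) {
  cat(sprintf(
    "WorldState: az %.2f deg, el %.2f deg, depth %.3f m\n  velocity (%.2f deg/s, %.2f deg/s, %.3f m/s), plane %.2f m\n",
    object@azimuth, object@elevation, object@depth, object@velocity[1],
    object@velocity[2], object@velocity[3], object@size))
})

setMethod("show", "EyePose", function(object) {
  cat(sprintf(
    "EyePose: pan %.2f deg (%.2f deg/s), tilt %.2f deg (%.2f deg/s), vergence %.3f deg\n",
    object@pan, object@panVel, object@tilt, object@tiltVel, object@vergence))
})

setMethod("show", "Dictionary", function(object) {
  cat(sprintf("Dictionary (%s scale): %d atoms, %s-initialized, %d updates\n",
    object@scale, ncol(object@atoms), object@mode, object@iteration))
})

setMethod("show", "AecAgent", function(object) {
  cat(sprintf(
    "AecAgent: |s| = %d, |A| = %d, Jhat = %.4f (gamma %.2f, T %.2f)\n",
    object@stateDim, length(object@actions), object@Jhat,
    object@hyper$gamma, object@hyper$temperature))
})
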