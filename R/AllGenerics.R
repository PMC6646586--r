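#' Accessors for the core classes
#'
#' Small accessor layer so user code never reaches into slots: `pixels()`
#' returns a texture's gray values, `atoms()` a dictionary's basis matrix,
#' `nAtoms()` its size, `actionSet()` an agent's action values, `degPerPx()`
#' a scale's angular resolution and `nPatches()` its patch count per image.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Texture", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "Dictionary", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Dictionary", function(x) ncol(x@atoms))

#' @rdname accessors
#' @export
setGeneric("actionSet", function(x) standardGeneric("actionSet"))
#' @rdname accessors
#' @export
setMethod("actionSet", "AecAgent", function(x) x@actions)

#' @rdname accessors
#' @export
setGeneric("degPerPx", function(x) standardGeneric("degPerPx"))
#' @rdname accessors
#' @export
setMethod("degPerPx", "ScaleConfig", function(x) x@windowFovDeg / x@outputPx)

#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))
#' @rdname accessors
#' @export
setMethod("nPatches", "ScaleConfig", function(x)
  as.integer(((x@outputPx - x@patchPx) / x@stridePx + 1)^2))

#' Extract one 8 x 8 subfield of a spatio-temporal basis function or patch
#'
#' A 16 x 16 spatio-temporal binocular array holds four 8 x 8 subfields:
#' rows are eyes (left on top, right below), columns are time (t-1 left,
#' t right).
#'
#' @param x a 16 x 16 matrix or a length-256 vector (column-major).
#' @param eye `"left"` or `"right"`.
#' @param time `"t"` or `"t-1"`.
#' @return an 8 x 8 matrix.
#' @export
atomSubfield <- function(x, eye = c("left", "right"), time = c("t", "t-1")) {
  eye <- match.arg(eye)
  time <- match.arg(time)
  if (is.null(dim(x))) x <- matrix(x, 16, 16)
  stopifnot(all(dim(x) == c(16, 16)))
  rows <- if (eye == "left") 1:8 else 9:16
  cols <- if (time == "t-1") 1:8 else 9:16
  x[rows, cols]
}
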