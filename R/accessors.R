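#' Accessors for pasam objects
#'
#' Generic accessors replacing direct slot access: pixel scale, stub
#' identifier, tile list, simulation truth table, and configuration
#' fingerprint.
#'
#' @param x A pasam S4 object.
#' @return `pixelSide()` the pixel side in micrometres; `stubId()` the stub
#'   identifier; `tiles()` the list of [SemTile-class] tiles; `truthTable()`
#'   the generator's truth `data.frame`; `configId()` the configuration
#'   fingerprint string.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSide", function(x) standardGeneric("pixelSide"))
#' @rdname accessors
#' @export
setMethod("pixelSide", "SemTile", function(x) x@pixelSide)
#' @rdname accessors
#' @export
setMethod("pixelSide", "StubImageSet", function(x) x@pixelSide)
#' @rdname accessors
#' @export
setMethod("pixelSide", "SamplerConfig", function(x) x@pixelSide)

#' @rdname accessors
#' @export
setGeneric("stubId", function(x) standardGeneric("stubId"))
#' @rdname accessors
#' @export
setMethod("stubId", "SemTile", function(x) x@stubId)
#' @rdname accessors
#' @export
setMethod("stubId", "StubImageSet", function(x) x@stubId)

#' @rdname accessors
#' @export
setGeneric("tiles", function(x) standardGeneric("tiles"))
#' @rdname accessors
#' @export
setMethod("tiles", "StubImageSet", function(x) x@tiles)

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setMethod("truthTable", "StubImageSet", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("configId", function(x) standardGeneric("configId"))
#' @rdname accessors
#' @export
setMethod("configId", "SamplerConfig", function(x) x@configId)
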