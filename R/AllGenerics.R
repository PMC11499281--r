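#' @include AllClasses.R
NULL

#' Accessors for lineattractor classes
#'
#' Small generics exposing the slots of the package's S4 containers:
#' `activityMatrix` (neurons x frames matrix), `frameRate`, `baselineWindow`,
#' `modelParams`, `diagnostics`, `latentFactors` (D x T matrix),
#' `discreteStates` (length-T integer vector), `groundTruth`, `boutTable`,
#' `cellPositions`, `synapticWeights` and `spectralRadius`.
#'
#' @param object an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("activityMatrix", function(object) standardGeneric("activityMatrix"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("baselineWindow", function(object) standardGeneric("baselineWindow"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))
#' @rdname accessors
#' @export
setGeneric("latentFactors", function(object) standardGeneric("latentFactors"))
#' @rdname accessors
#' @export
setGeneric("discreteStates", function(object) standardGeneric("discreteStates"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("boutTable", function(object) standardGeneric("boutTable"))
#' @rdname accessors
#' @export
setGeneric("cellPositions", function(object) standardGeneric("cellPositions"))
#' @rdname accessors
#' @export
setGeneric("synapticWeights", function(object) standardGeneric("synapticWeights"))
#' @rdname accessors
#' @export
setGeneric("spectralRadius", function(object) standardGeneric("spectralRadius"))

#' @rdname accessors
#' @export
setMethod("activityMatrix", "CalciumActivity",
          function(object) assay(object, "activity"))
#' @rdname accessors
#' @export
setMethod("activityMatrix", "SyntheticSession",
          function(object) assay(object@activity, "activity"))
#' @rdname accessors
#' @export
setMethod("frameRate", "CalciumActivity", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "SyntheticSession",
          function(object) object@activity@frameRate)
#' @rdname accessors
#' @export
setMethod("baselineWindow", "CalciumActivity",
          function(object) object@baselineWindow)
#' @rdname accessors
#' @export
setMethod("modelParams", "RSLDSFit", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("diagnostics", "RSLDSFit", function(object) object@diagnostics)
#' @rdname accessors
#' @export
setMethod("latentFactors", "LatentTrajectory", function(object) object@x)
#' @rdname accessors
#' @export
setMethod("latentFactors", "RSLDSFit", function(object) object@latents@x)
#' @rdname accessors
#' @export
setMethod("latentFactors", "SyntheticSession", function(object) object@latents@x)
#' @rdname accessors
#' @export
setMethod("discreteStates", "LatentTrajectory", function(object) object@z)
#' @rdname accessors
#' @export
setMethod("discreteStates", "RSLDSFit", function(object) object@latents@z)
#' @rdname accessors
#' @export
setMethod("discreteStates", "SyntheticSession", function(object) object@latents@z)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticSession", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("boutTable", "SyntheticSession", function(object) object@bouts)
#' @rdname accessors
#' @export
setMethod("cellPositions", "SyntheticSession", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("synapticWeights", "WeightMatrix", function(object) object@W)
#' @rdname accessors
#' @export
setMethod("spectralRadius", "WeightMatrix", function(object) object@lambdaMax)

#' Number of neurons / frames in an activity container
#'
#' @param object a [CalciumActivity-class] or [SyntheticSession-class].
#' @return An integer count.
#' @export
nNeurons <- function(object) {
    if (is(object, "SyntheticSession")) object <- object@activity
    nrow(object)
}

#' @rdname nNeurons
#' @export
nFrames <- function(object) {
    if (is(object, "SyntheticSession")) object <- object@activity
    ncol(object)
}
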