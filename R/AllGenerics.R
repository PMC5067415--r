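#' @include AllClasses.R
NULL

#' Predict the next symbol from a context
#'
#' @param object a trained model.
#' @param context character vector of preceding symbols (most recent last);
#'   may be empty, in which case the unigram distribution is returned.
#' @param ... further arguments passed to methods.
#' @return a named numeric probability vector over the model alphabet.
#' @export
setGeneric("predictNext", function(object, context = character(0), ...)
  standardGeneric("predictNext"))

#' Alphabet of a model
#' @param object a model object.
#' @return character vector of symbols.
#' @export
setGeneric("alphabet", function(object) standardGeneric("alphabet"))

#' Number of hierarchy levels in a memory
#' @param object a [HierarchicalMemory-class].
#' @return integer count of levels (including the surface).
#' @export
setGeneric("nLevels", function(object) standardGeneric("nLevels"))

#' Extract the streams stored at one hierarchy level
#' @param object a [HierarchicalMemory-class].
#' @param level level index, 0 = surface.
#' @return list of stream data.frames (`symbol`, `onset_ms`).
#' @export
setGeneric("levelStreams", function(object, level = 0L) standardGeneric("levelStreams"))

#' Rebuild the surface streams from a higher level of a memory
#'
#' Recursively expands the chunk labels at `level` through the registries
#' until the surface symbol streams are recovered. By construction this
#' reproduces the level-0 input exactly; the method errors if a label is
#' missing from a registry.
#'
#' @param object a [HierarchicalMemory-class].
#' @param level level to expand from (defaults to the top level).
#' @return list of character vectors, one surface stream per input stream.
#' @export
setGeneric("reconstruct", function(object, level = nLevels(object) - 1L)
  standardGeneric("reconstruct"))

#' Combined expectation strengths of a profile
#' @param object an [ExpectationProfile-class].
#' @return numeric vector of per-bin combined strengths.
#' @export
setGeneric("combinedStrength", function(object) standardGeneric("combinedStrength"))

#' Coordinates of a meter point
#' @param object a [MeterPoint-class].
#' @return named numeric vector.
#' @export
setGeneric("coordinates", function(object) standardGeneric("coordinates"))

#' Drop the tempo dimension of a meter point
#'
#' Projects a meter point onto its tempo-free subspace, abstracting the
#' metrical structure away from the speed at which it was realized.
#'
#' @param object a [MeterPoint-class].
#' @return a [MeterPoint-class] without the `tempo` dimension.
#' @export
setGeneric("abstractTempo", function(object) standardGeneric("abstractTempo"))

#' Phase errors of a tap record
#' @param object a [TapRecord-class].
#' @return numeric vector of signed errors in milliseconds.
#' @export
setGeneric("phaseErrors", function(object) standardGeneric("phaseErrors"))

#' Tap times of a tap record
#' @param object a [TapRecord-class].
#' @return numeric vector of tap times in milliseconds.
#' @export
setGeneric("tapTimes", function(object) standardGeneric("tapTimes"))
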