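#' Accessors for vegbiophys classes
#'
#' Small accessor generics so that slot layout stays private to the package.
#'
#' @param object a vegbiophys S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("schemeName", function(object) standardGeneric("schemeName"))

#' @rdname accessors
#' @export
setGeneric("classCodes", function(object) standardGeneric("classCodes"))

#' @rdname accessors
#' @export
setGeneric("vegetatedClasses",
  function(object) standardGeneric("vegetatedClasses"))

#' @rdname accessors
#' @export
setGeneric("coverFractions", function(object) standardGeneric("coverFractions"))

#' @rdname accessors
#' @export
setGeneric("sceneVariable",
  function(object, name) standardGeneric("sceneVariable"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object, name) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("purePredictionValues",
  function(object) standardGeneric("purePredictionValues"))

#' @rdname accessors
#' @export
setGeneric("predictionCovariance",
  function(object) standardGeneric("predictionCovariance"))

#' @rdname accessors
#' @export
setGeneric("deltaLayer", function(object) standardGeneric("deltaLayer"))

#' @rdname accessors
#' @export
setGeneric("uncertaintyLayer",
  function(object) standardGeneric("uncertaintyLayer"))

#' @rdname accessors
#' @export
setGeneric("sampleCount", function(object) standardGeneric("sampleCount"))

#' @rdname accessors
#' @export
setGeneric("transitionCodes",
  function(object) standardGeneric("transitionCodes"))

#' @rdname accessors
#' @export
setGeneric("monthsOf", function(object) standardGeneric("monthsOf"))
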