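## Generics and accessors. Slots are never reached into directly by user code.

#' @name accessors
#' @title Accessor functions
#' @description Accessors for the core S4 classes: well-array readings,
#'   columns, fraction series, measurements and comparison results.
#' @param object An object of the documented class.
#' @return The value of the corresponding slot (or derived quantity).
NULL

#' @rdname accessors
#' @export
setGeneric("aeb", function(object) standardGeneric("aeb"))

#' @rdname accessors
#' @export
setMethod("aeb", "WellArrayReading", function(object) object@aeb)

#' @rdname accessors
#' @export
setGeneric("fractionOn", function(object) standardGeneric("fractionOn"))

#' @rdname accessors
#' @export
setMethod("fractionOn", "WellArrayReading", function(object) object@fractionOn)

#' @rdname accessors
#' @export
setGeneric("isSaturated", function(object) standardGeneric("isSaturated"))

#' @rdname accessors
#' @export
setMethod("isSaturated", "WellArrayReading", function(object) object@saturated)

#' @rdname accessors
#' @export
setGeneric("concentration", function(object) standardGeneric("concentration"))

#' @rdname accessors
#' @export
setMethod("concentration", "ConcentrationEstimate",
          function(object) object@valuePM)

#' @rdname accessors
#' @export
setGeneric("estimateFlags", function(object) standardGeneric("estimateFlags"))

#' @rdname accessors
#' @export
setMethod("estimateFlags", "ConcentrationEstimate",
          function(object) object@flags)

#' @rdname accessors
#' @export
setGeneric("voidVolume", function(object) standardGeneric("voidVolume"))

#' @rdname accessors
#' @export
setMethod("voidVolume", "SECColumn",
          function(object) object@voidFraction * object@bedVolumeMl)

#' @rdname accessors
#' @export
setGeneric("internalVolume", function(object) standardGeneric("internalVolume"))

#' @rdname accessors
#' @export
setMethod("internalVolume", "SECColumn",
          function(object) object@resin@porosity * object@bedVolumeMl)

#' @rdname accessors
#' @export
setGeneric("profileMass", function(object) standardGeneric("profileMass"))

#' @rdname accessors
#' @export
setMethod("profileMass", "ElutionProfile",
          function(object) sum(object@density) * object@step)

#' @rdname accessors
#' @export
setGeneric("fractionIds", function(object) standardGeneric("fractionIds"))

#' @rdname accessors
#' @export
setMethod("fractionIds", "FractionSeries", function(object) object@fractionIds)

#' @rdname accessors
#' @export
setGeneric("amounts", function(object) standardGeneric("amounts"))

#' @rdname accessors
#' @export
setMethod("amounts", "FractionSeries", function(object) {
  stats::setNames(object@amountsFmol, object@fractionIds)
})

#' @rdname accessors
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setMethod("concentrations", "FractionSeries", function(object) {
  stats::setNames(object@amountsFmol / object@fractionVolumeMl,
                  object@fractionIds)
})

#' @rdname accessors
#' @export
setGeneric("markerValues", function(object) standardGeneric("markerValues"))

#' @rdname accessors
#' @export
setMethod("markerValues", "MethodMeasurement",
          function(object) object@markerValuesPM)

#' @rdname accessors
#' @export
setGeneric("methodName", function(object) standardGeneric("methodName"))

#' @rdname accessors
#' @export
setMethod("methodName", "MethodMeasurement", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("methodName", "RecoveryResult", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("methodName", "PurityResult", function(object) object@method)

#' @rdname accessors
#' @export
setGeneric("combinedRecovery", function(object) standardGeneric("combinedRecovery"))

#' @rdname accessors
#' @export
setMethod("combinedRecovery", "RecoveryResult",
          function(object) object@combinedRecovery)

#' @rdname accessors
#' @export
setGeneric("perMarkerRatio", function(object) standardGeneric("perMarkerRatio"))

#' @rdname accessors
#' @export
setMethod("perMarkerRatio", "RecoveryResult",
          function(object) object@perMarkerRatio)

#' @rdname accessors
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))

#' @rdname accessors
#' @export
setMethod("purity", "PurityResult", function(object) object@purity)

#' @rdname accessors
#' @export
setGeneric("albuminLevel", function(object) standardGeneric("albuminLevel"))

#' @rdname accessors
#' @export
setMethod("albuminLevel", "PurityResult", function(object) object@albuminPM)

#' @rdname accessors
#' @export
setMethod("albuminLevel", "MethodMeasurement",
          function(object) unname(object@markerValuesPM["ALB"]))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticDataset", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setGeneric("measurementTable", function(object) standardGeneric("measurementTable"))

#' @rdname accessors
#' @export
setMethod("measurementTable", "SyntheticDataset",
          function(object) object@measurements)
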