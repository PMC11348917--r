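# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for geniculate containers
#' @description Small accessor family: \code{nCells} (cells in a cluster or
#'   null draw size), \code{typeCounts} (per-type tabulation),
#'   \code{observedTypes}, \code{expectedTypes}, \code{sdTypes},
#'   \code{zScore}, \code{strataFractions}, \code{category}.
#' @param object a geniculate S4 object.
#' @return The corresponding slot value (see individual descriptions).
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setMethod("nCells", "PresynapticCluster", function(object) nrow(object@cells))
#' @rdname accessors
#' @export
setMethod("nCells", "OccupancyNull", function(object) object@nCells)

#' @rdname accessors
#' @export
setGeneric("typeCounts", function(object) standardGeneric("typeCounts"))
#' @rdname accessors
#' @export
setMethod("typeCounts", "PresynapticCluster", function(object) {
  table(factor(object@cells$type_label, levels = object@typeLevels))
})

#' @rdname accessors
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setMethod("cellTable", "PresynapticCluster", function(object) object@cells)

#' @rdname accessors
#' @export
setGeneric("observedTypes", function(object) standardGeneric("observedTypes"))
#' @rdname accessors
#' @export
setMethod("observedTypes", "PresynapticCluster", function(object) {
  length(unique(object@cells$type_label))
})
#' @rdname accessors
#' @export
setMethod("observedTypes", "SpecializationResult",
          function(object) object@observedTypes)

#' @rdname accessors
#' @export
setGeneric("expectedTypes", function(object) standardGeneric("expectedTypes"))
#' @rdname accessors
#' @export
setMethod("expectedTypes", "OccupancyNull", function(object) object@expectedTypes)
#' @rdname accessors
#' @export
setMethod("expectedTypes", "SpecializationResult",
          function(object) object@null@expectedTypes)

#' @rdname accessors
#' @export
setGeneric("sdTypes", function(object) standardGeneric("sdTypes"))
#' @rdname accessors
#' @export
setMethod("sdTypes", "OccupancyNull", function(object) object@sdTypes)
#' @rdname accessors
#' @export
setMethod("sdTypes", "SpecializationResult", function(object) object@null@sdTypes)

#' @rdname accessors
#' @export
setGeneric("zScore", function(object) standardGeneric("zScore"))
#' @rdname accessors
#' @export
setMethod("zScore", "SpecializationResult", function(object) object@zScore)

#' @rdname accessors
#' @export
setGeneric("strataFractions", function(object) standardGeneric("strataFractions"))
#' @rdname accessors
#' @export
setMethod("strataFractions", "StratificationProfile",
          function(object) object@fractions)

#' @rdname accessors
#' @export
setGeneric("category", function(object) standardGeneric("category"))
#' @rdname accessors
#' @export
setMethod("category", "TuningResult", function(object) object@category)

#' @rdname accessors
#' @export
setGeneric("selectivity", function(object) standardGeneric("selectivity"))
#' @rdname accessors
#' @export
setMethod("selectivity", "TuningResult", function(object) {
  c(DSI = object@dsi, OSI = object@osi,
    DSI_neg = object@dsiNeg, OSI_neg = object@osiNeg)
})

setMethod("show", "PresynapticCluster", function(object) {
  cat("PresynapticCluster '", object@postsynapticId, "': ",
      nrow(object@cells), " cells, ",
      length(unique(object@cells$type_label)), " distinct types, ",
      sum(object@cells$eye == "contra"), " contra / ",
      sum(object@cells$eye == "ipsi"), " ipsi\n", sep = "")
})

setMethod("show", "OccupancyNull", function(object) {
  cat(sprintf(
    "OccupancyNull: n = %d cells, E[types] = %.3f, SD = %.3f (%d reps)\n",
    object@nCells, object@expectedTypes, object@sdTypes, object@nReps))
})

setMethod("show", "SpecializationResult", function(object) {
  cat(sprintf(
    "SpecializationResult: observed %d types, expected %.2f (SD %.2f), Z = %.2f%s\n",
    object@observedTypes, object@null@expectedTypes, object@null@sdTypes,
    object@zScore, if (object@zScore < -2) "  [specialized]" else ""))
})

setMethod("show", "ChatBandSurfaces", function(object) {
  cat(sprintf(
    "ChatBandSurfaces over %d x %d columns; mean separation %.2f planes\n",
    nrow(object@offZ), ncol(object@offZ), mean(abs(object@onZ - object@offZ))))
})

setMethod("show", "FlattenedStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "FlattenedStack %d x %d xy, %d depth samples in [%.3f, %.3f] (step 0.025)\n",
    d[1], d[2], d[3], min(object@depths), max(object@depths)))
})

setMethod("show", "StratificationProfile", function(object) {
  cat("StratificationProfile (strata 1..10):\n ",
      paste(sprintf("%.2f", object@fractions), collapse = " "), "\n",
      sprintf(" cofasciculation: OFF=%s ON=%s, asymmetry index %.2f\n",
              object@cofasciculation3, object@cofasciculation7,
              object@asymmetryIndex))
})

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf(
    "ResponseMatrix: 8 directions x %d speeds, %d trials; SNR %.2f (pos %.2f, neg %.2f)\n",
    ncol(object@P), dim(object@trialP)[3], object@snr, object@snrPos,
    object@snrNeg))
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf(
    "TuningResult: %s | DSI %.2f (p %.3f), OSI %.2f (p %.3f), pref dir %.0f deg\n",
    object@category, object@dsi, object@pDS, object@osi, object@pOS,
    object@preferredDirection))
})

setMethod("show", "RFMapPair", function(object) {
  cat(sprintf("RFMapPair %d x %d grid (%.0f deg squares); p_on %s, p_off %s\n",
              nrow(object@onMap), ncol(object@onMap), object@degPerPixel,
              format(object@pOn, digits = 3), format(object@pOff, digits = 3)))
})

setMethod("show", "ReceptiveField", function(object) {
  if (!object@significant) {
    cat("ReceptiveField: not significant\n")
  } else {
    cat(sprintf(
      "ReceptiveField: %s, area %.0f deg^2, center (%.1f, %.1f) deg\n",
      object@polarity, object@areaDeg2, object@center[1], object@center[2]))
  }
})
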