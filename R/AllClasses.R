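# Central S4 containers. Accessors are defined in AllGenerics.R; user code
# should never reach into slots directly.

#' PresynapticCluster: traced RGCs presynaptic to one postsynaptic cell
#'
#' One row per rabies-traced retinal ganglion cell (RGC): its morphological
#' type label, the eye of origin (\code{"contra"} or \code{"ipsi"}), and an
#' optional retinal eccentricity in degrees (0 at the optic nerve, 115 at the
#' peripheral border).
#'
#' @slot postsynapticId label of the postsynaptic (traced-from) cell.
#' @slot cells data.frame with columns \code{type_label}, \code{eye} and
#'   optionally \code{eccentricity_deg}.
#' @slot typeLevels declared label set the types are drawn from.
#' @exportClass PresynapticCluster
setClass("PresynapticCluster",
  representation(postsynapticId = "character",
                 cells = "data.frame",
                 typeLevels = "character"),
  validity = function(object) {
    msg <- character()
    cells <- object@cells
    if (!all(c("type_label", "eye") %in% names(cells)))
      msg <- c(msg, "cells must have columns type_label and eye")
    else {
      if (!all(cells$eye %in% c("contra", "ipsi")))
        msg <- c(msg, "eye must be 'contra' or 'ipsi'")
      if (length(object@typeLevels) &&
          !all(cells$type_label %in% object@typeLevels))
        msg <- c(msg, "type_label outside the declared label set")
      if ("eccentricity_deg" %in% names(cells)) {
        ecc <- cells$eccentricity_deg
        if (any(!is.na(ecc) & (ecc < 0 | ecc > 115)))
          msg <- c(msg, "eccentricity_deg must lie in [0, 115]")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a PresynapticCluster
#'
#' @param typeLabel character vector of per-cell type labels.
#' @param eye character vector, \code{"contra"} or \code{"ipsi"}.
#' @param postsynapticId label of the postsynaptic cell.
#' @param eccentricityDeg optional per-cell retinal eccentricity (degrees).
#' @param typeLevels declared type label set (defaults to labels observed).
#' @return A \linkS4class{PresynapticCluster}.
#' @examples
#' cl <- PresynapticCluster(c("37", "37", "89"), c("contra", "contra", "ipsi"))
#' nCells(cl)
#' @export
PresynapticCluster <- function(typeLabel, eye, postsynapticId = "cell1",
                               eccentricityDeg = NULL, typeLevels = NULL) {
  cells <- data.frame(type_label = as.character(typeLabel),
                      eye = as.character(eye),
                      stringsAsFactors = FALSE)
  if (!is.null(eccentricityDeg)) cells$eccentricity_deg <- eccentricityDeg
  new("PresynapticCluster", postsynapticId = postsynapticId, cells = cells,
      typeLevels = as.character(typeLevels %||% unique(cells$type_label)))
}

#' OccupancyNull: Monte-Carlo null of distinct-type counts
#'
#' Summarizes random draws of \code{nCells} cells from a reference type
#' distribution: the expected number of distinct types present and its
#' simulated standard deviation.
#'
#' @slot nCells draw size.
#' @slot expectedTypes Monte-Carlo mean distinct-type count.
#' @slot sdTypes Monte-Carlo SD of the distinct-type count.
#' @slot nReps number of Monte-Carlo replicates.
#' @slot samples optional raw distinct-type counts (empty unless kept).
#' @slot seed seed used for the simulation.
#' @exportClass OccupancyNull
setClass("OccupancyNull",
  representation(nCells = "integer", expectedTypes = "numeric",
                 sdTypes = "numeric", nReps = "integer",
                 samples = "integer", seed = "integer"),
  validity = function(object) {
    if (object@sdTypes < 0) return("sdTypes must be >= 0")
    if (object@expectedTypes < 0 || object@expectedTypes > object@nCells)
      return("expectedTypes must lie in [0, nCells]")
    TRUE
  })

#' SpecializationResult: observed distinct types against an occupancy null
#'
#' @slot observedTypes observed number of distinct type labels.
#' @slot zScore (observed - expected) / simulated SD.
#' @slot null the \linkS4class{OccupancyNull} the score is referred to.
#' @exportClass SpecializationResult
setClass("SpecializationResult",
  representation(observedTypes = "integer", zScore = "numeric",
                 null = "OccupancyNull"))

#' ChatBandSurfaces: per-column z-coordinates of the two ChAT bands
#'
#' Single-valued surfaces over the xy grid: \code{offZ} for the OFF band
#' (stratum 3) and \code{onZ} for the ON band (stratum 7), with \code{offZ}
#' strictly on one side of \code{onZ} everywhere.
#'
#' @slot offZ matrix (y by x) of z-coordinates of the OFF band.
#' @slot onZ matrix (y by x) of z-coordinates of the ON band.
#' @exportClass ChatBandSurfaces
setClass("ChatBandSurfaces",
  representation(offZ = "matrix", onZ = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@offZ), dim(object@onZ)))
      return("offZ and onZ must share dimensions")
    d <- object@onZ - object@offZ
    if (!(all(d > 0) || all(d < 0)))
      return("band surfaces must not touch or cross")
    TRUE
  })

#' FlattenedStack: stack resampled into ChAT-band-relative depth
#'
#' Intensities over (y, x, relative depth), with the OFF band at depth 0 and
#' the ON band at depth 1, sampled at increments of 0.025. Ten strata of
#' width 0.25 tile the depth range; stratum k is centered at 0.25 (k - 3),
#' so strata 3 and 7 sit on the bands.
#'
#' @slot data numeric array (y, x, depth).
#' @slot depths relative-depth sample points (step exactly 0.025).
#' @exportClass FlattenedStack
setClass("FlattenedStack",
  representation(data = "array", depths = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (dim(object@data)[3L] != length(object@depths))
      return("third dimension must match depths")
    if (length(object@depths) > 1L &&
        max(abs(diff(object@depths) - 0.025)) > 1e-9)
      return("depth sampling step must be exactly 0.025")
    TRUE
  })

#' StratificationProfile: where one cell's dendritic signal lives in depth
#'
#' @slot fractions per-stratum fraction of the cell's dendritic signal
#'   (length 10, sums to 1).
#' @slot cofasciculation3,cofasciculation7 does the cell co-fasciculate with
#'   the OFF / ON ChAT band (quantitative rule, see
#'   \code{\link{stratificationProfile}}).
#' @slot asymmetryIndex |soma - dendritic center of mass| / arbor radius
#'   (NA when no soma position was supplied).
#' @exportClass StratificationProfile
setClass("StratificationProfile",
  representation(fractions = "numeric", cofasciculation3 = "logical",
                 cofasciculation7 = "logical", asymmetryIndex = "numeric"),
  validity = function(object) {
    if (length(object@fractions) != 10L) return("fractions must have length 10")
    if (abs(sum(object@fractions) - 1) > 1e-6)
      return("fractions must sum to 1")
    TRUE
  })

#' ResponseMatrix: baselined responses of one ROI to the 24 grating stimuli
#'
#' Positive (P) and negative (N) response amplitudes, stimulus-period means
#' and baselines for 8 directions x 3 speeds, together with per-trial
#' amplitudes (needed for permutation tests), F0 and SNR measures.
#'
#' @slot P,N 8 x 3 matrices of positive (maximum) and negative (-minimum)
#'   amplitudes of the filtered trial-median response; clipped at 0.
#' @slot meanResp 8 x 3 stimulus-period averages (signed).
#' @slot baselines 8 x 3 per-stimulus baselines (median across trials).
#' @slot trialP,trialN arrays (8, 3, trial) of per-trial amplitudes.
#' @slot F0 smallest baseline of the 24 average responses.
#' @slot snr,snrPos,snrNeg max |amplitude| (respectively max P, max N)
#'   divided by the baseline SD.
#' @slot directions stimulus directions in degrees.
#' @slot speeds stimulus speeds in micrometer/s on the retina.
#' @exportClass ResponseMatrix
setClass("ResponseMatrix",
  representation(P = "matrix", N = "matrix", meanResp = "matrix",
                 baselines = "matrix", trialP = "array", trialN = "array",
                 F0 = "numeric", snr = "numeric", snrPos = "numeric",
                 snrNeg = "numeric", directions = "numeric",
                 speeds = "numeric"),
  validity = function(object) {
    if (any(object@P < 0) || any(object@N < 0))
      return("P and N must be nonnegative")
    if (!is.finite(object@F0)) return("F0 must be finite")
    TRUE
  })

#' TuningResult: selectivity indices, significance and category of one ROI
#'
#' @slot dsi,osi,dsiNeg,osiNeg circular-variance selectivity indices in [0,1].
#' @slot pDS,pOS,pDSNeg,pOSNeg permutation p-values in (0, 1].
#' @slot preferredDirection,preferredOrientation degrees, eye-axis corrected.
#' @slot sbc suppressed-by-contrast flag.
#' @slot pctSuppressed fraction of the 24 average responses below baseline.
#' @slot category one of DS, OS, DS_neg, OS_neg, SbC, broad, none.
#' @slot bestSpeedPos,bestSpeedNeg index of the speed used for the positive /
#'   negative indices.
#' @exportClass TuningResult
setClass("TuningResult",
  representation(dsi = "numeric", osi = "numeric", dsiNeg = "numeric",
                 osiNeg = "numeric", pDS = "numeric", pOS = "numeric",
                 pDSNeg = "numeric", pOSNeg = "numeric",
                 preferredDirection = "numeric",
                 preferredOrientation = "numeric",
                 sbc = "logical", pctSuppressed = "numeric",
                 category = "character",
                 bestSpeedPos = "integer", bestSpeedNeg = "integer"),
  validity = function(object) {
    idx <- c(object@dsi, object@osi, object@dsiNeg, object@osiNeg)
    if (any(idx < -1e-9 | idx > 1 + 1e-9))
      return("selectivity indices must lie in [0, 1]")
    TRUE
  })

#' RFMapPair: ON and OFF sparse-noise response maps for one cell
#'
#' @slot onMap,offMap matrices (rows = elevation, cols = azimuth) of response
#'   amplitudes from the trial-averaged traces.
#' @slot trialOn,trialOff arrays (row, col, trial) of single-trial amplitudes.
#' @slot pOn,pOff shuffle p-values (NA until \code{shuffleSignificance}).
#' @slot degPerPixel stimulus square width in degrees.
#' @slot azimuthDeg,elevationDeg grid coordinates of columns / rows (degrees).
#' @exportClass RFMapPair
setClass("RFMapPair",
  representation(onMap = "matrix", offMap = "matrix",
                 trialOn = "array", trialOff = "array",
                 pOn = "numeric", pOff = "numeric",
                 degPerPixel = "numeric",
                 azimuthDeg = "numeric", elevationDeg = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@onMap), dim(object@offMap)))
      return("onMap and offMap must share the grid")
    TRUE
  })

#' ReceptiveField: half-max region, area and center of a significant map
#'
#' @slot significant was any map significant.
#' @slot polarity \code{"ON"}, \code{"OFF"} or \code{"ON-OFF"} (or \code{"none"}).
#' @slot region logical matrix marking the connected above-half-max region.
#' @slot areaDeg2 region area in degrees squared.
#' @slot center c(azimuth, elevation) in degrees, intensity-weighted.
#' @exportClass ReceptiveField
setClass("ReceptiveField",
  representation(significant = "logical", polarity = "character",
                 region = "matrix", areaDeg2 = "numeric", center = "numeric"))
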