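# Monte-Carlo specialization statistics for presynaptic RGC clusters.
#
# The null hypothesis is that the RGCs presynaptic to a postsynaptic cell are
# drawn at random from a reference distribution of cell types. The number of
# distinct types among n draws (the occupancy count) is simulated; a cluster
# whose observed distinct-type count falls far below the simulated mean is
# specialized. Z = (observed - expected) / simulated SD, with Z < -2 flagging
# specialization.

#' Weighted reference distribution of presynaptic RGC types
#'
#' Combines the empirical type distributions found presynaptic to
#' thalamocortical neurons (TCNs) and to dLGN interneurons into one reference
#' mixture, weighting each population by its prevalence and its mean number
#' of presynaptic RGCs per cell: the mixture is proportional to
#' \code{pTcn * wTcn * nTcn + pIn * wIn * nIn}, then normalized.
#'
#' @param pTcn named probability vector: type distribution presynaptic to TCNs.
#' @param pIn named probability vector over the same labels, for interneurons.
#' @param wTcn,wIn population weights (defaults 0.8 and 0.2, reflecting the
#'   higher prevalence of TCNs).
#' @param nTcn,nIn mean presynaptic RGCs per TCN (20) and per interneuron (96).
#' @return Named probability vector (sums to 1).
#' @examples
#' p <- referenceDistribution(c(a = .5, b = .5), c(a = 1, b = 0))
#' @export
referenceDistribution <- function(pTcn, pIn, wTcn = 0.8, wIn = 0.2,
                                  nTcn = 20, nIn = 96) {
  stopifnot(wTcn >= 0, wIn >= 0, nTcn > 0, nIn > 0)
  if (is.null(names(pTcn)) || is.null(names(pIn)) ||
      !setequal(names(pTcn), names(pIn)))
    stop("pTcn and pIn must be named over the same label set")
  pIn <- pIn[names(pTcn)]
  assertProbs(pTcn, "pTcn"); assertProbs(pIn, "pIn")
  w <- pTcn * wTcn * nTcn + pIn * wIn * nIn
  w / sum(w)
}

#' Monte-Carlo null of the distinct-type count
#'
#' Simulates \code{nReps} random draws of \code{nCells} cells i.i.d. from a
#' type distribution and records the number of distinct types present in each
#' draw, returning its Monte-Carlo mean and SD.
#'
#' @param probs type distribution (numeric, nonnegative, sums to 1) or a
#'   number of equally frequent types.
#' @param nCells draw size (>= 0).
#' @param nReps Monte-Carlo replicates (default 1e5).
#' @param seed integer seed (mandatory for reproducibility).
#' @param keepSamples keep the raw per-replicate counts.
#' @return An \linkS4class{OccupancyNull}.
#' @examples
#' occupancyNull(40, nCells = 50, nReps = 1e4, seed = 1)
#' @export
occupancyNull <- function(probs, nCells, nReps = 1e5, seed,
                          keepSamples = FALSE) {
  if (length(probs) == 1L && probs >= 1 && probs == round(probs))
    probs <- rep(1 / probs, probs)
  assertProbs(probs)
  if (nCells < 0) stop("nCells must be >= 0")
  if (nReps < 1) stop("nReps must be >= 1")
  nCells <- as.integer(nCells); nReps <- as.integer(nReps)
  if (nCells == 0L) {
    counts <- integer(nReps)
  } else {
    counts <- withSeed(seed, {
      draws <- stats::rmultinom(nReps, size = nCells, prob = probs)
      as.integer(colSums(draws > 0L))
    })
  }
  new("OccupancyNull", nCells = nCells,
      expectedTypes = mean(counts),
      sdTypes = if (nReps > 1L) stats::sd(counts) else 0,
      nReps = nReps,
      samples = if (keepSamples) counts else integer(0),
      seed = as.integer(seed))
}

#' Specialization Z score of a cluster against an occupancy null
#'
#' Z = (observed distinct-type count - simulated expectation) / simulated SD.
#' The null must have been built for the cluster's classified-cell count.
#' Z < -2 is the conventional specialization flag.
#'
#' @param cluster a \linkS4class{PresynapticCluster}, or directly an observed
#'   distinct-type count.
#' @param null an \linkS4class{OccupancyNull}.
#' @return A \linkS4class{SpecializationResult}.
#' @export
specializationZ <- function(cluster, null) {
  obs <- if (is(cluster, "PresynapticCluster")) {
    if (nCells(cluster) != null@nCells)
      stop("null was built for n = ", null@nCells,
           " cells but the cluster has ", nCells(cluster))
    observedTypes(cluster)
  } else {
    as.integer(cluster)
  }
  if (null@sdTypes == 0)
    stop("degenerate null: simulated SD of the distinct-type count is 0")
  new("SpecializationResult", observedTypes = as.integer(obs),
      zScore = (obs - null@expectedTypes) / null@sdTypes, null = null)
}

#' Smallest distinct-type count not flagged as specialized
#'
#' Under the convention that Z < \code{zThreshold} indicates specialization,
#' returns the smallest integer type count k with
#' (k - expected) / SD >= \code{zThreshold}: counts below it would be called
#' specialized, counts from it upward are expected by chance.
#'
#' @param null an \linkS4class{OccupancyNull}.
#' @param zThreshold specialization threshold (default -2).
#' @return Integer type count.
#' @export
chanceTypeBoundary <- function(null, zThreshold = -2) {
  as.integer(ceiling(null@expectedTypes + zThreshold * null@sdTypes))
}

#' Specialization of a type subset under label pooling
#'
#' Simulation experiment for how the granularity of a type classification
#' influences specialization Z scores. A cluster specialized toward
#' \code{observedSubset} of a uniform label set is scored against the
#' occupancy null over the (optionally pooled) labels. Following the
#' convention used for the worked examples, the observed count is the number
#' of distinct pooled labels covering the full subset
#' (\code{observed = "subset"}); alternatively the distinct pooled types in a
#' single simulated draw from the subset can be used
#' (\code{observed = "draw"}).
#'
#' @param nTypes number of equally frequent original type labels.
#' @param nCells draw size for the null.
#' @param observedSubset integer vector of original labels (in
#'   \code{1:nTypes}) the cluster is specialized toward.
#' @param poolingMap integer vector of length \code{nTypes} mapping each
#'   original label to a pooled label, or NULL for identity (no pooling).
#' @param nReps Monte-Carlo replicates for the null.
#' @param seed integer seed.
#' @param observed convention for the observed count (see above).
#' @return A \linkS4class{SpecializationResult}.
#' @examples
#' # 20 of 40 uniform types, no pooling, 50 draws: strongly specialized
#' poolingExperiment(40, 50, 1:20, nReps = 1e4, seed = 1)
#' @export
poolingExperiment <- function(nTypes, nCells, observedSubset,
                              poolingMap = NULL, nReps = 1e5, seed,
                              observed = c("subset", "draw")) {
  observed <- match.arg(observed)
  if (!all(observedSubset %in% seq_len(nTypes)))
    stop("observedSubset must be contained in 1:nTypes")
  if (length(observedSubset) == 0L) stop("observedSubset must be non-empty")
  poolingMap <- poolingMap %||% seq_len(nTypes)
  if (length(poolingMap) != nTypes)
    stop("poolingMap must map every original label")
  pooled <- sort(unique(poolingMap))
  null <- occupancyNull(length(pooled), nCells, nReps = nReps,
                        seed = childSeed(seed, "null"))
  obs <- if (observed == "subset") {
    length(unique(poolingMap[observedSubset]))
  } else {
    withSeed(childSeed(seed, "draw"), {
      draw <- sample(observedSubset, nCells, replace = TRUE)
      length(unique(poolingMap[draw]))
    })
  }
  specializationZ(obs, null)
}

#' Dominance: relative abundance of the most prevalent type
#'
#' @param cluster a \linkS4class{PresynapticCluster}.
#' @param byEye compute separately for contra- and ipsilateral sub-clusters.
#' @return Fraction in (0, 1], or a named vector when \code{byEye}.
#' @examples
#' dominance(PresynapticCluster(rep(letters[1:5], 10), rep("contra", 50)))
#' @export
dominance <- function(cluster, byEye = FALSE) {
  stopifnot(is(cluster, "PresynapticCluster"))
  one <- function(labels) {
    if (length(labels) == 0L) stop("empty cluster: dominance undefined")
    max(table(labels)) / length(labels)
  }
  if (!byEye) return(one(cluster@cells$type_label))
  vapply(split(cluster@cells$type_label, cluster@cells$eye), one, numeric(1))
}

#' Canonical functional tags of the morphological RGC types
#'
#' Kinetics follow stratification depth (innermost strata 3-7 are transient,
#' outermost 1-2 and 8-10 sustained); polarity follows the ON (strata 6-10)
#' versus OFF (1-4) sides; DS types are those co-fasciculating with the ChAT
#' bands; JAM-B is the asymmetric strata-1/2 type.
#'
#' @return data.frame with columns \code{type_label}, \code{kinetics},
#'   \code{polarity}, \code{is_DS}, \code{is_JAMB}.
#' @export
rgcTagTable <- function() {
  data.frame(
    type_label = c("12", "12_asym", "37", "7", "4", "89", "189"),
    kinetics = c("sustained", "sustained", "transient", "transient",
                 "transient", "sustained", "sustained"),
    polarity = c("OFF", "OFF", "ON-OFF", "ON", "OFF", "ON", "ON-OFF"),
    is_DS = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    is_JAMB = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Preference indices of a presynaptic cluster
#'
#' Sustained/transient index (# sustained - # transient) / (# sustained +
#' # transient), in [-1, 1] with +1 exclusively sustained; ON/OFF index
#' (# ON * 1 + # OFF * 0 + # ON-OFF * 0.5) / total, in [0, 1]; and the DS
#' ratio, the fraction of classified presynaptic RGCs that are
#' direction-selective, reported both including and excluding JAM-B cells.
#'
#' @param cluster a \linkS4class{PresynapticCluster}.
#' @param tagMap data.frame as from \code{\link{rgcTagTable}} covering every
#'   type label present.
#' @return Named list: \code{st_index}, \code{onoff_index},
#'   \code{ds_ratio}, \code{ds_ratio_with_jamb}, \code{dominance}.
#' @export
preferenceIndices <- function(cluster, tagMap = rgcTagTable()) {
  stopifnot(is(cluster, "PresynapticCluster"))
  labels <- cluster@cells$type_label
  if (length(labels) == 0L) stop("empty cluster")
  unknown <- setdiff(unique(labels), tagMap$type_label)
  if (length(unknown))
    stop("unknown type labels: ", paste(unknown, collapse = ", "))
  tags <- tagMap[match(labels, tagMap$type_label), ]
  nSus <- sum(tags$kinetics == "sustained")
  nTrans <- sum(tags$kinetics == "transient")
  nOn <- sum(tags$polarity == "ON")
  nOff <- sum(tags$polarity == "OFF")
  nOnOff <- sum(tags$polarity == "ON-OFF")
  list(
    st_index = if (nSus + nTrans > 0) (nSus - nTrans) / (nSus + nTrans) else NA_real_,
    onoff_index = if (nOn + nOff + nOnOff > 0)
      (nOn + 0.5 * nOnOff) / (nOn + nOff + nOnOff) else NA_real_,
    ds_ratio = sum(tags$is_DS) / length(labels),
    ds_ratio_with_jamb = sum(tags$is_DS | tags$is_JAMB) / length(labels),
    dominance = dominance(cluster))
}

#' Monte-Carlo test of binocular input randomness
#'
#' Tests whether the split of presynaptic cells across the two eyes deviates
#' from a binomial draw with contralateral probability \code{pContra}. The
#' test statistic is the absolute difference between contra- and ipsilateral
#' cell counts, summed across postsynaptic cells; its null distribution is
#' simulated at matched per-cell totals and the p-value is the Monte-Carlo
#' tail probability of the observed statistic (the absolute difference is
#' already two-sided), with the add-one convention so p is never 0.
#'
#' @param nContra,nIpsi integer vectors (one entry per postsynaptic cell) of
#'   contra- and ipsilateral presynaptic counts.
#' @param pContra contralateral probability under the null (default 0.87, the
#'   average contralateral fraction).
#' @param nReps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return List with \code{p_value}, \code{statistic} and the simulated
#'   \code{null_statistics}.
#' @export
binocularRandomnessTest <- function(nContra, nIpsi, pContra = 0.87,
                                    nReps = 1e4, seed) {
  if (length(nContra) == 0L) stop("empty input")
  if (length(nContra) != length(nIpsi))
    stop("nContra and nIpsi must have one entry per postsynaptic cell")
  if (pContra <= 0 || pContra >= 1) {
    # degenerate null: all cells deterministically on one eye
    tot <- nContra + nIpsi
    statNull <- sum(tot)
    statObs <- sum(abs(nContra - nIpsi))
    return(list(p_value = as.numeric(statNull >= statObs),
                statistic = statObs, null_statistics = statNull))
  }
  tot <- as.integer(nContra + nIpsi)
  statObs <- sum(abs(nContra - nIpsi))
  stats <- withSeed(seed, {
    sim <- vapply(seq_len(nReps), function(i) {
      c <- stats::rbinom(length(tot), tot, pContra)
      sum(abs(2L * c - tot))
    }, numeric(1))
    sim
  })
  list(p_value = (1 + sum(stats >= statObs)) / (1 + nReps),
       statistic = statObs, null_statistics = stats)
}
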