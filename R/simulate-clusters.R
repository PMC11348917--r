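# Synthetic presynaptic-cluster generator with known ground truth.

#' Configuration for a synthetic presynaptic cluster
#'
#' @param nTypes number of RGC type labels in the reference set.
#' @param typeProbs per-type probabilities (default uniform); must be
#'   nonnegative and sum to 1 within 1e-9.
#' @param subset optional character/integer vector of allowed types, to
#'   emulate a specialized cluster (probabilities renormalized over it).
#' @param nCells number of cells to draw (>= 0).
#' @param pContra probability a cell originates from the contralateral eye
#'   (default 0.87, the average contralateral fraction).
#' @param seed integer seed.
#' @return A validated config (list) for \code{\link{simulateClusters}}.
#' @export
clusterSimConfig <- function(nTypes, typeProbs = NULL, subset = NULL,
                             nCells, pContra = 0.87, seed = 1L) {
  labels <- if (!is.null(names(typeProbs))) names(typeProbs)
            else sprintf("type%02d", seq_len(nTypes))
  typeProbs <- typeProbs %||% rep(1 / nTypes, nTypes)
  if (length(typeProbs) != nTypes) stop("typeProbs must have length nTypes")
  assertProbs(typeProbs)
  names(typeProbs) <- labels
  if (!is.null(subset)) {
    if (is.numeric(subset)) subset <- labels[subset]
    if (length(subset) == 0L) stop("subset must be non-empty")
    if (!all(subset %in% labels)) stop("subset outside the type label set")
  }
  if (nCells < 0) stop("nCells must be >= 0")
  if (pContra < 0 || pContra > 1) stop("pContra must lie in [0, 1]")
  structure(list(nTypes = nTypes, typeProbs = typeProbs, subset = subset,
                 nCells = as.integer(nCells), pContra = pContra,
                 seed = as.integer(seed)),
            class = "ClusterSimConfig")
}

#' Draw a synthetic presynaptic cluster
#'
#' Cell types are drawn i.i.d. from the configured distribution (restricted
#' and renormalized to \code{subset} if given); the eye of origin is
#' Bernoulli(\code{pContra}). Bit-identical under identical config and seed.
#'
#' @param cfg a \code{\link{clusterSimConfig}}.
#' @param postsynapticId label for the simulated postsynaptic cell.
#' @return A \linkS4class{PresynapticCluster} whose \code{typeLevels} carry
#'   the full label set.
#' @examples
#' cl <- simulateClusters(clusterSimConfig(40, nCells = 50, seed = 7))
#' observedTypes(cl)
#' @export
simulateClusters <- function(cfg, postsynapticId = "sim1") {
  stopifnot(inherits(cfg, "ClusterSimConfig"))
  probs <- cfg$typeProbs
  if (!is.null(cfg$subset)) {
    probs[!(names(probs) %in% cfg$subset)] <- 0
    if (sum(probs) == 0) stop("subset has zero total probability")
    probs <- probs / sum(probs)
  }
  withSeed(cfg$seed, {
    types <- if (cfg$nCells > 0L)
      sample(names(probs), cfg$nCells, replace = TRUE, prob = probs)
    else character(0)
    eye <- ifelse(stats::runif(cfg$nCells) < cfg$pContra, "contra", "ipsi")
    PresynapticCluster(types, eye, postsynapticId = postsynapticId,
                       typeLevels = names(probs))
  })
}
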