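# ChAT-band detection, band-relative flattening and stratification-based RGC
# typing of flat-mount stacks.
#
# The two ChAT bands (starburst amacrine plexi) are depth landmarks of the
# inner plexiform layer: the OFF band is mapped to relative depth 0, the ON
# band to 1, every column of the stack is resampled on that axis at 0.025
# increments, and ten strata of width 0.25 tile the depth range with strata 3
# and 7 centered on the bands.

#' Relative-depth centers of the ten IPL strata
#' @return Numeric vector of length 10 (stratum 3 at 0, stratum 7 at 1).
#' @export
strataCenters <- function() 0.25 * (1:10 - 3)

#' Stratum index of a relative depth
#' @param depth relative depth (0 = OFF band, 1 = ON band).
#' @return Integer stratum in 1..10 (clipped at the margins).
#' @export
stratumOfDepth <- function(depth) {
  pmin(10L, pmax(1L, as.integer(round(depth / 0.25) + 3L)))
}

#' Band-membership probability stack from a ChAT channel
#'
#' Default classical detector: per-column matched filtering along z with a
#' Gaussian kernel of the expected band width, rectified and normalized to
#' [0, 1]. Any other detector (e.g. a trained network) can be substituted
#' behind the same contract: it must map a 3D single-channel stack to a
#' same-shaped probability stack.
#'
#' @param stack numeric array (y, x, z), single channel.
#' @param bandSigma expected band half-width in planes (kernel SD).
#' @param detector optional function \code{stack -> probability stack}
#'   replacing the classical matched filter.
#' @return Array of the same shape with values in [0, 1].
#' @export
detectBandProbability <- function(stack, bandSigma = 1, detector = NULL) {
  if (length(dim(stack)) != 3L) stop("stack must be a 3D array")
  if (!is.null(detector)) {
    p <- detector(stack)
    if (!identical(dim(p), dim(stack)))
      stop("detector must preserve the stack shape")
    return(array(pmin(1, pmax(0, p)), dim = dim(stack)))
  }
  d <- dim(stack)
  nz <- d[3L]
  half <- max(1L, ceiling(3 * bandSigma))
  kz <- seq(-half, half)
  kernel <- exp(-kz^2 / (2 * bandSigma^2))
  kernel <- kernel / sum(kernel)
  # columns as rows of an (npix x nz) matrix; matched filter as matrix product
  m <- matrix(stack, nrow = d[1L] * d[2L], ncol = nz)
  K <- matrix(0, nz, nz)
  for (i in seq_len(nz)) {
    idx <- i + kz
    ok <- idx >= 1L & idx <= nz
    K[idx[ok], i] <- kernel[ok] / sum(kernel[ok])
  }
  resp <- m %*% K
  resp <- resp - min(resp)
  if (max(resp) > 0) resp <- resp / max(resp)
  array(resp, dim = d)
}

#' Extract the two ChAT-band surfaces from a probability stack
#'
#' Per column, local maxima of the probability profile are located and the
#' two strongest peaks separated by at least \code{minSep} planes taken as
#' band candidates; the surfaces are then smoothed by a running median across
#' xy. Columns where two ridges cannot be found are an error (listed), unless
#' manual curation supplies their coordinates. Ordering is enforced: if the
#' smoothed surfaces touch or cross anywhere, an error is raised rather than
#' silently swapping bands.
#'
#' @param prob probability stack from \code{\link{detectBandProbability}}.
#' @param minSep minimum peak separation in planes.
#' @param peakFloor peaks below \code{peakFloor * max(prob)} are ignored.
#' @param runmedK running-median window (odd) for surface smoothing.
#' @param invert set TRUE for stacks acquired ganglion-cell-side last, which
#'   flips which band is called OFF.
#' @param manual optional curation hook: data.frame with columns \code{y},
#'   \code{x}, \code{off_z}, \code{on_z} overriding those columns.
#' @return A \linkS4class{ChatBandSurfaces}.
#' @export
extractBandSurfaces <- function(prob, minSep = 3, peakFloor = 0.25,
                                runmedK = 5, invert = FALSE, manual = NULL) {
  d <- dim(prob)
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  z1 <- matrix(NA_real_, ny, nx); z2 <- matrix(NA_real_, ny, nx)
  floorVal <- peakFloor * max(prob)
  if (max(prob) <= 0) stop("probability stack is empty; no ridges detectable")
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      p <- prob[y, x, ]
      left <- c(-Inf, p[-nz]); right <- c(p[-1L], -Inf)
      peaks <- which(p >= left & p > right & p > floorVal)
      if (length(peaks) < 2L) next
      ord <- peaks[order(p[peaks], decreasing = TRUE)]
      a <- ord[1L]
      b <- ord[which(abs(ord - a) >= minSep)[1L]]
      if (is.na(b)) next
      z1[y, x] <- min(a, b); z2[y, x] <- max(a, b)
    }
  }
  bad <- which(is.na(z1), arr.ind = TRUE)
  if (nrow(bad) > 0L && !is.null(manual)) {
    idx <- cbind(manual$y, manual$x)
    z1[idx] <- pmin(manual$off_z, manual$on_z)
    z2[idx] <- pmax(manual$off_z, manual$on_z)
    bad <- which(is.na(z1), arr.ind = TRUE)
  }
  if (nrow(bad) > 0L)
    stop("fewer than two ridges detectable in ", nrow(bad),
         " columns (first at y=", bad[1L, 1L], ", x=", bad[1L, 2L], ")")
  smooth2d <- function(m) {
    if (runmedK > 1L) {
      m <- apply(m, 2L, stats::runmed, k = runmedK)
      m <- t(apply(m, 1L, stats::runmed, k = runmedK))
    }
    m
  }
  z1 <- smooth2d(z1); z2 <- smooth2d(z2)
  if (any(z2 - z1 < max(1, minSep / 2)))
    stop("candidate ridges touch or cross; refusing to assign bands")
  if (invert) new("ChatBandSurfaces", offZ = z2, onZ = z1)
  else new("ChatBandSurfaces", offZ = z1, onZ = z2)
}

#' Flatten a stack into ChAT-band-relative depth
#'
#' Per column, the linear map sending the OFF band to relative depth 0 and
#' the ON band to 1 (linear extrapolation beyond the bands) is applied and
#' the intensities are resampled at 0.025 steps over \code{depthRange},
#' which by default exactly tiles strata 1-10.
#'
#' @param stack numeric array (y, x, z), one channel.
#' @param surfaces a \linkS4class{ChatBandSurfaces} over the stack's xy grid.
#' @param depthRange relative-depth range to sample (default
#'   \code{c(-0.625, 1.875)}).
#' @return A \linkS4class{FlattenedStack}.
#' @export
flattenStack <- function(stack, surfaces, depthRange = c(-0.625, 1.875)) {
  d <- dim(stack)
  if (!identical(dim(surfaces@offZ), d[1:2]))
    stop("surfaces must be defined over the stack's xy grid")
  sep <- surfaces@onZ - surfaces@offZ
  if (any(sep == 0)) stop("offZ equals onZ in some columns; cannot flatten")
  depths <- seq(depthRange[1L], depthRange[2L], by = 0.025)
  nz <- d[3L]
  out <- array(0, dim = c(d[1L], d[2L], length(depths)))
  zIdx <- seq_len(nz)
  for (x in seq_len(d[2L])) {
    for (y in seq_len(d[1L])) {
      zq <- surfaces@offZ[y, x] + depths * sep[y, x]
      out[y, x, ] <- stats::approx(zIdx, stack[y, x, ], xout = zq,
                                   yleft = 0, yright = 0)$y
    }
  }
  new("FlattenedStack", data = out, depths = depths)
}

#' Stratum-pseudo-colored maximum projection
#'
#' Per xy position, the stratum in which the brightest pixel along relative
#' depth is located; background positions (maximum intensity below
#' \code{threshold}) are labeled 0.
#'
#' @param flattened a \linkS4class{FlattenedStack}.
#' @param threshold intensity threshold separating background (default 20\%
#'   of the stack maximum).
#' @return List with \code{labels} (matrix of 0..10) and \code{maxIntensity}.
#' @export
stratumColoredProjection <- function(flattened, threshold = NULL) {
  a <- flattened@data
  d <- dim(a)
  m <- matrix(a, nrow = d[1L] * d[2L])
  arg <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), arg)]
  threshold <- threshold %||% (0.2 * max(mx))
  labels <- stratumOfDepth(flattened@depths[arg])
  labels[mx < threshold] <- 0L
  list(labels = matrix(labels, d[1L], d[2L]),
       maxIntensity = matrix(mx, d[1L], d[2L]))
}

#' Stratification profile of one cell's dendritic signal
#'
#' Per-stratum fractions of the masked signal, quantitative co-fasciculation
#' flags for the two ChAT bands, and an arbor asymmetry index. A cell
#' co-fasciculates with band k when at least \code{cofascFrac} of its signal
#' lies within +/-0.125 of that band's depth AND at least
#' \code{chatOverlapFrac} of that in-window signal sits on xy positions with
#' above-threshold ChAT signal in the same window.
#'
#' @param flattened flattened RGC channel (\linkS4class{FlattenedStack}).
#' @param cellMask logical xy matrix marking the cell's dendrites.
#' @param chatFlattened optional flattened ChAT channel for the overlap test
#'   (skipped when NULL).
#' @param somaXy optional soma position c(x, y) in pixels; without it the
#'   asymmetry index is NA.
#' @param cofascFrac fraction of signal required inside a band window.
#' @param chatOverlapFrac required ChAT-overlap fraction of in-window signal.
#' @param chatThreshold ChAT intensity threshold (default 20\% of max).
#' @return A \linkS4class{StratificationProfile}.
#' @export
stratificationProfile <- function(flattened, cellMask, chatFlattened = NULL,
                                  somaXy = NULL, cofascFrac = 0.25,
                                  chatOverlapFrac = 0.5,
                                  chatThreshold = NULL) {
  a <- flattened@data
  d <- dim(a)
  if (!any(cellMask)) stop("empty cell mask")
  depths <- flattened@depths
  strat <- stratumOfDepth(depths)
  maskIdx <- which(cellMask)
  m <- matrix(a, nrow = d[1L] * d[2L])[maskIdx, , drop = FALSE]
  m[m < 0] <- 0
  total <- sum(m)
  if (total <= 0) stop("no signal inside the cell mask")
  fractions <- vapply(1:10, function(k) sum(m[, strat == k]) / total,
                      numeric(1))
  cofasc <- function(bandDepth) {
    win <- abs(depths - bandDepth) <= 0.125
    cellWin <- rowSums(m[, win, drop = FALSE])
    frac <- sum(cellWin) / total
    if (frac < cofascFrac) return(FALSE)
    if (is.null(chatFlattened)) return(TRUE)
    cm <- matrix(chatFlattened@data,
                 nrow = d[1L] * d[2L])[maskIdx, win, drop = FALSE]
    chatE <- rowSums(cm)
    thr <- chatThreshold %||% (0.2 * max(matrix(chatFlattened@data,
                                                nrow = d[1L] * d[2L])))
    onChat <- chatE > thr
    sum(cellWin[onChat]) / max(sum(cellWin), .Machine$double.eps) >=
      chatOverlapFrac
  }
  asym <- NA_real_
  if (!is.null(somaXy)) {
    w <- rowSums(m)
    rc <- arrayInd(maskIdx, d[1:2])
    comX <- sum(rc[, 2L] * w) / sum(w)
    comY <- sum(rc[, 1L] * w) / sum(w)
    radius <- max(sqrt((rc[, 2L] - somaXy[1L])^2 + (rc[, 1L] - somaXy[2L])^2))
    if (radius > 0)
      asym <- sqrt((comX - somaXy[1L])^2 + (comY - somaXy[2L])^2) / radius
  }
  new("StratificationProfile", fractions = fractions / sum(fractions),
      cofasciculation3 = cofasc(0), cofasciculation7 = cofasc(1),
      asymmetryIndex = asym)
}

#' Call an RGC type and functional tags from a stratification profile
#'
#' Deterministic, total rule cascade on the profile: type 37 co-fasciculates
#' with both ChAT bands; type 7 with the ON band only (minor stratum-3
#' signal allowed); types 12 / 12_asym stratify in strata 1-2 (asymmetric
#' arbors are JAM-B-like); 189 spans strata 1-2 and 8-10; 89 sits in 8-10;
#' 4 in stratum 4; everything else is \code{"other"}. Tags follow the
#' stratum rules: innermost strata 3-7 are transient, outermost sustained;
#' strata 6-10 carry ON responses, 1-4 OFF, both sides ON-OFF; types 37 and
#' 7 are direction-selective; 12_asym is JAM-B.
#'
#' @param profile a \linkS4class{StratificationProfile}.
#' @param dominantFrac a stratum counts as occupied at >= this signal
#'   fraction (default 0.10).
#' @param minorFrac type 7 tolerates stratum-3 signal below this (default 0.15).
#' @param asymThreshold JAM-B asymmetry threshold (default 0.3).
#' @return Named list: \code{type_label}, \code{kinetics}, \code{polarity},
#'   \code{is_DS}, \code{is_JAMB}.
#' @export
classifyRgc <- function(profile, dominantFrac = 0.10, minorFrac = 0.15,
                        asymThreshold = 0.3) {
  f <- profile@fractions
  dom <- which(f >= dominantFrac)
  asym <- !is.na(profile@asymmetryIndex) &&
    profile@asymmetryIndex > asymThreshold
  type <- if (profile@cofasciculation3 && profile@cofasciculation7) "37"
  else if (profile@cofasciculation7 && f[3L] < minorFrac) "7"
  else if (length(dom) == 0L) "other"
  else if (all(dom %in% 1:2) && asym) "12_asym"
  else if (all(dom %in% 1:2)) "12"
  else if (all(dom %in% c(1, 2, 8, 9, 10)) && any(dom %in% 1:2) &&
           any(dom %in% 8:10)) "189"
  else if (all(dom %in% 8:10)) "89"
  # stratum 4 holds the majority; adjacent-window spillover is tolerated
  else if (which.max(f) == 4L && f[4L] >= 0.5) "4"
  else "other"
  kinetics <- if (length(dom) && all(dom %in% 3:7)) "transient"
  else if (length(dom) && all(dom %in% c(1, 2, 8, 9, 10))) "sustained"
  else if (sum(f[3:7]) > sum(f[c(1, 2, 8, 9, 10)])) "transient"
  else "sustained"
  hasOff <- any(dom %in% 1:4); hasOn <- any(dom %in% 6:10)
  polarity <- if (hasOff && hasOn) "ON-OFF"
  else if (hasOff) "OFF"
  else if (hasOn) "ON"
  else "ON-OFF"
  list(type_label = type, kinetics = kinetics, polarity = polarity,
       is_DS = type %in% c("37", "7"), is_JAMB = type == "12_asym")
}
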