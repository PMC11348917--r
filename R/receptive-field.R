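# Sparse-noise receptive-field mapping: event-aligned ON/OFF response maps,
# shuffle-based significance via the one-pixel-shift local correlation,
# half-max region extraction and Gaussian-weighted retinotopic interpolation.

#' Event-aligned ON and OFF response maps
#'
#' Per stimulus position, trials are aligned at flash onset, interpolated to
#' \code{interpHz}, averaged and smoothed with a \code{filterS} running
#' average. The ON amplitude is the signed extremum (maximum or minimum,
#' whichever is larger in magnitude) during the flash after subtracting the
#' ON baseline (200-75 ms before onset); the OFF amplitude is taken between
#' flashes against the 200-75 ms pre-offset baseline. Windows exclude
#' +/-75 ms around flash on- and offset to avoid filtering artifacts.
#' Per-trial amplitudes are extracted the same way for the shuffling control.
#'
#' @param trace one cell's trace.
#' @param schedule data.frame with trial, row, col, onset, offset.
#' @param frameRate trace sampling rate (Hz).
#' @param gridRows,gridCols stimulus grid size.
#' @param squareDeg square width in degrees.
#' @param gapS inter-flash gap (s); inferred from the schedule when NULL.
#' @param interpHz interpolation rate (default 33).
#' @param filterS running-average length (default 0.150).
#' @return A \linkS4class{RFMapPair} (p-values NA until
#'   \code{\link{shuffleSignificance}}).
#' @export
eventAlignedMaps <- function(trace, schedule, frameRate, gridRows, gridCols,
                             squareDeg = 8, gapS = NULL, interpHz = 33,
                             filterS = 0.150) {
  tGrid <- (seq_along(trace) - 1) / frameRate
  flashS <- stats::median(schedule$offset - schedule$onset)
  if (is.null(gapS)) {
    byT <- schedule[order(schedule$onset), ]
    gapS <- stats::median(diff(byT$onset)) - flashS
  }
  dt <- 1 / interpHz
  relT <- seq(-0.25, flashS + gapS, by = dt)
  kFilt <- max(1L, round(filterS * interpHz))
  onWin <- relT > 0.075 & relT < flashS - 0.075
  offWin <- relT > flashS + 0.075 & relT < flashS + gapS - 0.075
  onBase <- relT >= -0.200 & relT <= -0.075
  offBase <- relT >= flashS - 0.200 & relT <= flashS - 0.075
  extremum <- function(x) x[which.max(abs(x))]
  nTr <- max(schedule$trial)
  onMap <- matrix(0, gridRows, gridCols)
  offMap <- matrix(0, gridRows, gridCols)
  trialOn <- array(NA_real_, dim = c(gridRows, gridCols, nTr))
  trialOff <- array(NA_real_, dim = c(gridRows, gridCols, nTr))
  for (r in seq_len(gridRows)) for (cc in seq_len(gridCols)) {
    rows <- schedule[schedule$row == r & schedule$col == cc, ]
    if (nrow(rows) == 0L)
      stop("no trials for grid position (", r, ", ", cc, ")")
    segs <- matrix(NA_real_, length(relT), nrow(rows))
    for (i in seq_len(nrow(rows))) {
      segs[, i] <- stats::approx(tGrid - rows$onset[i], trace, xout = relT,
                                 rule = 2)$y
      segF <- runningMean(segs[, i], kFilt)
      trialOn[r, cc, rows$trial[i]] <-
        extremum(segF[onWin] - mean(segF[onBase]))
      trialOff[r, cc, rows$trial[i]] <-
        extremum(segF[offWin] - mean(segF[offBase]))
    }
    avg <- runningMean(rowMeans(segs), kFilt)
    onMap[r, cc] <- extremum(avg[onWin] - mean(avg[onBase]))
    offMap[r, cc] <- extremum(avg[offWin] - mean(avg[offBase]))
  }
  grid <- sparseNoiseGrid(gridRows, gridCols, squareDeg)
  new("RFMapPair", onMap = onMap, offMap = offMap, trialOn = trialOn,
      trialOff = trialOff, pOn = NA_real_, pOff = NA_real_,
      degPerPixel = squareDeg, azimuthDeg = grid$azimuth,
      elevationDeg = grid$elevation)
}

# max Pearson correlation of a map with itself shifted by one pixel in the
# 8 directions, on the overlapping sub-grid; 0 for constant maps
localShiftCorrelation <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  best <- -Inf
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ya <- max(1L, 1L + dy):min(nr, nr + dy)
    xa <- max(1L, 1L + dx):min(nc, nc + dx)
    a <- as.numeric(m[ya, xa]); b <- as.numeric(m[ya - dy, xa - dx])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    best <- max(best, stats::cor(a, b))
  }
  if (is.finite(best)) best else 0
}

#' Shuffle significance of ON and OFF response maps
#'
#' The single-trial amplitudes are randomly permuted across positions (ON and
#' OFF amplitudes of a trial travel together) \code{nShuffles} times; the map
#' statistic is the maximum correlation of the trial-mean map with itself
#' shifted by one pixel (horizontal, vertical or oblique). A map is
#' significant when its statistic exceeds 95\% of the shuffled controls;
#' p = (1 + #\{shuffled >= observed\}) / (1 + nShuffles).
#'
#' @param pair a \linkS4class{RFMapPair}.
#' @param nShuffles number of permutations (default 1e4).
#' @param seed integer seed.
#' @return The pair with \code{pOn} and \code{pOff} filled in.
#' @export
shuffleSignificance <- function(pair, nShuffles = 1e4, seed) {
  d <- dim(pair@trialOn)
  nPos <- d[1L] * d[2L]
  if (d[3L] < 2L) stop("need at least 2 trials")
  An <- matrix(pair@trialOn, nPos, d[3L])
  Af <- matrix(pair@trialOff, nPos, d[3L])
  obsOn <- localShiftCorrelation(matrix(rowMeans(An), d[1L], d[2L]))
  obsOff <- localShiftCorrelation(matrix(rowMeans(Af), d[1L], d[2L]))
  counts <- withSeed(seed, {
    cOn <- 0L; cOff <- 0L
    for (b in seq_len(nShuffles)) {
      perm <- sample.int(length(An))
      sOn <- localShiftCorrelation(matrix(rowMeans(
        matrix(An[perm], nPos, d[3L])), d[1L], d[2L]))
      sOff <- localShiftCorrelation(matrix(rowMeans(
        matrix(Af[perm], nPos, d[3L])), d[1L], d[2L]))
      if (sOn >= obsOn) cOn <- cOn + 1L
      if (sOff >= obsOff) cOff <- cOff + 1L
    }
    c(cOn, cOff)
  })
  pair@pOn <- (1 + counts[1L]) / (1 + nShuffles)
  pair@pOff <- (1 + counts[2L]) / (1 + nShuffles)
  pair
}

#' Receptive field from significant response maps
#'
#' Significant maps are smoothed by a 3x3 running average (shrinking at the
#' borders); the receptive field is the 8-connected region of pixels above
#' half the filtered maximum containing the maximum pixel. Area is the region
#' size times the square area; position is the intensity-weighted center of
#' mass of the filtered map within the region. Cells significant in both
#' polarities (ON-OFF) are measured on the sum of both filtered maps.
#'
#' @param pair a \linkS4class{RFMapPair} with p-values filled in.
#' @param alpha significance level (default 0.05).
#' @return A \linkS4class{ReceptiveField}.
#' @export
rfFromMap <- function(pair, alpha = 0.05) {
  sigOn <- !is.na(pair@pOn) && pair@pOn < alpha
  sigOff <- !is.na(pair@pOff) && pair@pOff < alpha
  if (!sigOn && !sigOff)
    return(new("ReceptiveField", significant = FALSE, polarity = "none",
               region = matrix(FALSE, nrow(pair@onMap), ncol(pair@onMap)),
               areaDeg2 = NA_real_, center = c(NA_real_, NA_real_)))
  polarity <- if (sigOn && sigOff) "ON-OFF" else if (sigOn) "ON" else "OFF"
  mf <- switch(polarity,
               "ON" = meanFilter3(pair@onMap),
               "OFF" = meanFilter3(pair@offMap),
               "ON-OFF" = meanFilter3(pair@onMap) + meanFilter3(pair@offMap))
  peak <- which(mf == max(mf), arr.ind = TRUE)[1L, ]
  region <- connectedRegion(mf > max(mf) / 2, c(peak[1L], peak[2L]))
  w <- mf * region
  az <- sum(t(w) * pair@azimuthDeg) / sum(w)
  el <- sum(w * pair@elevationDeg) / sum(w)
  new("ReceptiveField", significant = TRUE, polarity = polarity,
      region = region, areaDeg2 = sum(region) * pair@degPerPixel^2,
      center = c(azimuth = az, elevation = el))
}

#' Gaussian-weighted retinotopic interpolation
#'
#' At each map coordinate, the Gaussian-weighted (sigma 75 micrometer,
#' support 300 x 300 micrometer) average of the per-cell values (azimuth or
#' elevation of significant receptive fields) is computed; coordinates with
#' zero total weight are NA.
#'
#' @param positionsUm n x 2 matrix of cell positions (micrometer).
#' @param values per-cell values (degrees of azimuth or elevation).
#' @param gridStepUm output grid step (micrometer).
#' @param sigmaUm Gaussian SD (default 75).
#' @param maskUm mask side length (default 300).
#' @return List: \code{x}, \code{y} grid coordinates and \code{map} matrix.
#' @export
retinotopicMap <- function(positionsUm, values, gridStepUm = 10,
                           sigmaUm = 75, maskUm = 300) {
  positionsUm <- as.matrix(positionsUm)
  if (nrow(positionsUm) == 0L)
    stop("no cells with significant receptive fields")
  half <- maskUm / 2
  xs <- seq(min(positionsUm[, 1L]) - half, max(positionsUm[, 1L]) + half,
            by = gridStepUm)
  ys <- seq(min(positionsUm[, 2L]) - half, max(positionsUm[, 2L]) + half,
            by = gridStepUm)
  map <- matrix(NA_real_, length(ys), length(xs))
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    dx <- positionsUm[, 1L] - xs[ix]
    dy <- positionsUm[, 2L] - ys[iy]
    inMask <- abs(dx) <= half & abs(dy) <= half
    if (!any(inMask)) next
    w <- exp(-(dx[inMask]^2 + dy[inMask]^2) / (2 * sigmaUm^2))
    map[iy, ix] <- sum(w * values[inMask]) / sum(w)
  }
  list(x = xs, y = ys, map = map)
}
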