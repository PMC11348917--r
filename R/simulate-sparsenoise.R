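# Synthetic sparse-noise sessions: Gaussian ON/OFF receptive fields probed by
# flashed squares on a grid, with a pseudo-random flash schedule per trial.

#' Configuration for a synthetic sparse-noise session
#'
#' Defaults follow the standard mapping geometry: a screen of 116 x 86
#' degrees divided into squares of about 8 degrees (14 x 11 grid), white
#' squares flashed for 0.6 s with 0.6 s between flashes, 4-7 trials.
#'
#' @param gridRows,gridCols stimulus grid size (rows = elevation).
#' @param squareDeg square width in degrees.
#' @param flashS,gapS flash duration and inter-flash gap (s).
#' @param rfTruth list per cell: \code{centerDeg} c(azimuth, elevation),
#'   \code{sdDeg}, \code{polarity} in ON / OFF / ON-OFF, \code{amplitude}.
#' @param nTrials number of trials (4-7 typical; default 6).
#' @param noiseSd trace noise SD.
#' @param responseTauS time constant of the flash-evoked transient (s); the
#'   default 0.05 lets an ON response decay back to baseline well before flash
#'   offset, as for a transiently responding cell.
#' @param frameRate trace sampling rate (Hz).
#' @param seed integer seed.
#' @return Validated config for \code{\link{simulateSparseNoiseSession}}.
#' @export
sparseNoiseSimConfig <- function(gridRows = 11, gridCols = 14, squareDeg = 8,
                                 flashS = 0.6, gapS = 0.6, rfTruth = list(),
                                 nTrials = 6, noiseSd = 0.05,
                                 responseTauS = 0.05, frameRate = 30,
                                 seed = 1L) {
  azHalf <- gridCols * squareDeg / 2
  elHalf <- gridRows * squareDeg / 2
  for (rf in rfTruth) {
    if (abs(rf$centerDeg[1]) > azHalf || abs(rf$centerDeg[2]) > elHalf)
      stop("rf center outside the screen extent")
    if (!(rf$polarity %in% c("ON", "OFF", "ON-OFF")))
      stop("polarity must be ON, OFF or ON-OFF")
  }
  if (gapS < 0.3) stop("gapS too short for the OFF baseline window")
  structure(list(gridRows = as.integer(gridRows),
                 gridCols = as.integer(gridCols), squareDeg = squareDeg,
                 flashS = flashS, gapS = gapS, rfTruth = rfTruth,
                 nTrials = as.integer(nTrials), noiseSd = noiseSd,
                 responseTauS = responseTauS,
                 frameRate = frameRate, seed = as.integer(seed)),
            class = "SparseNoiseSimConfig")
}

#' Grid coordinates (degrees) of a sparse-noise stimulus grid
#' @param gridRows,gridCols grid size.
#' @param squareDeg square width in degrees.
#' @return List: \code{azimuth} (per column), \code{elevation} (per row).
#' @export
sparseNoiseGrid <- function(gridRows, gridCols, squareDeg = 8) {
  list(azimuth = (seq_len(gridCols) - (gridCols + 1) / 2) * squareDeg,
       elevation = (seq_len(gridRows) - (gridRows + 1) / 2) * squareDeg)
}

#' Simulate a sparse-noise session with known ground truth
#'
#' Each flash at a position inside a cell's true Gaussian receptive field
#' evokes a transient ON response (during the flash) and/or OFF response
#' (after flash offset), with amplitude following the Gaussian profile. The
#' flash schedule is an independent pseudo-random permutation of positions
#' per trial.
#'
#' @param cfg a \code{\link{sparseNoiseSimConfig}}.
#' @return List: \code{traces} (cells x time matrix), \code{schedule}
#'   (data.frame trial, row, col, onset, offset), \code{grid}, \code{rfTruth},
#'   \code{frameRate}, \code{flashS}, \code{gapS}.
#' @export
simulateSparseNoiseSession <- function(cfg) {
  stopifnot(inherits(cfg, "SparseNoiseSimConfig"))
  nPos <- cfg$gridRows * cfg$gridCols
  grid <- sparseNoiseGrid(cfg$gridRows, cfg$gridCols, cfg$squareDeg)
  period <- cfg$flashS + cfg$gapS
  withSeed(cfg$seed, {
    sched <- list()
    for (tr in seq_len(cfg$nTrials)) {
      ord <- sample.int(nPos)
      k <- (tr - 1L) * nPos + seq_len(nPos)
      onset <- cfg$gapS + (k - 1L) * period
      sched[[tr]] <- data.frame(
        trial = tr,
        row = (ord - 1L) %% cfg$gridRows + 1L,
        col = (ord - 1L) %/% cfg$gridRows + 1L,
        onset = onset, offset = onset + cfg$flashS)
    }
    schedule <- do.call(rbind, sched)
    total <- max(schedule$offset) + cfg$gapS
    nT <- ceiling(total * cfg$frameRate)
    tGrid <- (seq_len(nT) - 1) / cfg$frameRate
    tau <- cfg$responseTauS %||% 0.05
    kernel <- function(t0) {
      dt <- tGrid - t0
      k <- (dt / tau) * exp(1 - dt / tau)
      k[dt < 0] <- 0
      k
    }
    traces <- matrix(0, max(1L, length(cfg$rfTruth)), nT)
    for (ci in seq_along(cfg$rfTruth)) {
      rf <- cfg$rfTruth[[ci]]
      tr <- numeric(nT)
      for (ri in seq_len(nrow(schedule))) {
        az <- grid$azimuth[schedule$col[ri]]
        el <- grid$elevation[schedule$row[ri]]
        d2 <- (az - rf$centerDeg[1])^2 + (el - rf$centerDeg[2])^2
        w <- rf$amplitude * exp(-d2 / (2 * rf$sdDeg^2))
        if (w < 1e-4 * abs(rf$amplitude)) next
        if (rf$polarity %in% c("ON", "ON-OFF"))
          tr <- tr + w * kernel(schedule$onset[ri])
        if (rf$polarity %in% c("OFF", "ON-OFF"))
          tr <- tr + w * kernel(schedule$offset[ri])
      }
      traces[ci, ] <- tr
    }
    if (cfg$noiseSd > 0)
      traces <- traces + matrix(stats::rnorm(length(traces), 0, cfg$noiseSd),
                                nrow(traces), ncol(traces))
    list(traces = traces, schedule = schedule, grid = grid,
         rfTruth = cfg$rfTruth, frameRate = cfg$frameRate,
         flashS = cfg$flashS, gapS = cfg$gapS, squareDeg = cfg$squareDeg,
         gridRows = cfg$gridRows, gridCols = cfg$gridCols)
  })
}
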