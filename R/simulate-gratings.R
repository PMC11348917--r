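# Synthetic two-photon grating sessions: von-Mises-tuned cells with
# exponential-indicator dynamics, dendritic compartments sharing the soma's
# tuning scaled by attenuation, rendered into a noisy movie.

#' Drifting-grating stimulus protocol
#'
#' Standard protocol: gratings of 40 degrees per cycle (spatial period 1200
#' micrometer on the retina at 30 micrometer/degree) moving in 8 directions at
#' 45-degree spacing and 3 speeds (400/1200/2400 micrometer/s), each shown for
#' 4 cycles (12/4/2 s, i.e. temporal frequencies 1/3, 1 and 2 Hz), separated
#' by gray interstimulus intervals. Stimulus angles on the screen are offset
#' from the eye's main axis by 20 degrees, which downstream analyses correct.
#'
#' @param directions stimulus directions in degrees.
#' @param speeds speeds in micrometer/s on the retina.
#' @param spatialPeriodUm grating period (micrometer).
#' @param umPerDeg retinal magnification (micrometer per degree).
#' @param nCycles cycles shown per stimulus.
#' @param interstimS gray interval before each stimulus (s); must exceed the
#'   1.75 s pre-onset baseline window.
#' @param nTrials repetitions of the full 24-stimulus set.
#' @param eyeAxisOffsetDeg angle between eye main axis and screen horizontal.
#' @param seed optional seed for per-trial pseudo-random stimulus order
#'   (sequential order when NULL).
#' @return A \code{StimulusProtocol} (list) with the trial \code{schedule}.
#' @examples
#' p <- stimulusProtocol()
#' p$durations   # 12 4 2 seconds
#' @export
stimulusProtocol <- function(directions = seq(0, 315, by = 45),
                             speeds = c(400, 1200, 2400),
                             spatialPeriodUm = 1200, umPerDeg = 30,
                             nCycles = 4, interstimS = 3, nTrials = 4,
                             eyeAxisOffsetDeg = 20, seed = NULL) {
  if (interstimS < 1.75)
    stop("interstimS must cover the 1.75 s pre-onset baseline window")
  durations <- nCycles * spatialPeriodUm / speeds
  temporalFreqs <- speeds / spatialPeriodUm
  stopifnot(max(abs(durations * temporalFreqs - nCycles)) < 1e-9)
  nd <- length(directions); ns <- length(speeds)
  combos <- expand.grid(dirIdx = seq_len(nd), speedIdx = seq_len(ns))
  sched <- list()
  t0 <- 0
  orderOf <- function(trial) {
    if (is.null(seed)) seq_len(nrow(combos))
    else withSeed(childSeed(seed, paste0("order", trial)),
                  sample.int(nrow(combos)))
  }
  for (trial in seq_len(nTrials)) {
    for (i in orderOf(trial)) {
      dur <- durations[combos$speedIdx[i]]
      t0 <- t0 + interstimS
      sched[[length(sched) + 1L]] <-
        data.frame(trial = trial, dirIdx = combos$dirIdx[i],
                   speedIdx = combos$speedIdx[i], onset = t0, duration = dur)
      t0 <- t0 + dur
    }
  }
  schedule <- do.call(rbind, sched)
  structure(list(directions = directions, speeds = speeds,
                 spatialPeriodUm = spatialPeriodUm, umPerDeg = umPerDeg,
                 nCycles = nCycles, durations = durations,
                 temporalFreqs = temporalFreqs, interstimS = interstimS,
                 nTrials = nTrials, eyeAxisOffsetDeg = eyeAxisOffsetDeg,
                 schedule = schedule, totalDuration = t0 + interstimS),
            class = "StimulusProtocol")
}

#' Configuration for a synthetic grating session
#'
#' @param tuningSpecs list with one entry per cell:
#'   \code{kind} in DS, OS, DS_neg, OS_neg, SbC, broad; \code{prefDeg}
#'   preferred direction; \code{kappa} von Mises concentration (default 4);
#'   \code{amplitude} response amplitude (default 1); \code{sbcFraction}
#'   fraction of the 24 stimuli suppressed for SbC cells (default 0.8);
#'   \code{baseline} resting signal (default 0.2; SbC cells 1).
#' @param dendritesPerCell compartments per cell (thin segments radiating
#'   from the soma; response scaled by per-compartment attenuation).
#' @param attenuation function of compartment index j giving attenuation in
#'   (0, 1] (default \code{0.8^j}).
#' @param protocol a \code{\link{stimulusProtocol}}.
#' @param frameRate movie frame rate (Hz).
#' @param noiseSd per-pixel Gaussian noise SD.
#' @param indicatorDecayS calcium-indicator exponential decay constant (s).
#' @param imgSize movie side length in pixels.
#' @param umPerPx pixel size in micrometer.
#' @param seed integer seed.
#' @return Validated config for \code{\link{simulateGratingSession}}.
#' @export
gratingSimConfig <- function(tuningSpecs, dendritesPerCell = 0,
                             attenuation = function(j) 0.8^j,
                             protocol = stimulusProtocol(),
                             frameRate = 10, noiseSd = 0.05,
                             indicatorDecayS = 1.5, imgSize = 32,
                             umPerPx = 2, seed = 1L) {
  if (frameRate <= 0) stop("frameRate must be > 0")
  kinds <- c("DS", "OS", "DS_neg", "OS_neg", "SbC", "broad")
  for (ts in tuningSpecs) {
    if (!ts$kind %in% kinds)
      stop("unknown tuning kind: ", ts$kind)
    pref <- ts$prefDeg %||% 0
    if (pref < 0 || pref >= 360) stop("prefDeg must lie in [0, 360)")
  }
  av <- vapply(seq_len(max(1, dendritesPerCell)), attenuation, numeric(1))
  if (dendritesPerCell > 0 && any(av <= 0 | av > 1))
    stop("attenuation must lie in (0, 1]")
  structure(list(tuningSpecs = tuningSpecs,
                 dendritesPerCell = as.integer(dendritesPerCell),
                 attenuation = attenuation, protocol = protocol,
                 frameRate = frameRate, noiseSd = noiseSd,
                 indicatorDecayS = indicatorDecayS,
                 imgSize = as.integer(imgSize), umPerPx = umPerPx,
                 seed = as.integer(seed)),
            class = "GratingSimConfig")
}

# ground-truth response of a cell to one stimulus, before indicator dynamics
tunedResponse <- function(spec, dirDeg, stimIdx, suppressed) {
  amp <- spec$amplitude %||% 1
  kappa <- spec$kappa %||% 4
  pref <- spec$prefDeg %||% 0
  vm <- exp(kappa * (cos((dirDeg - pref) * pi / 180) - 1))
  vm2 <- exp(kappa * (cos(2 * (dirDeg - pref) * pi / 180) - 1))
  switch(spec$kind,
         DS = amp * vm,
         OS = amp * vm2,
         DS_neg = -amp * vm,
         OS_neg = -amp * vm2,
         SbC = if (suppressed[stimIdx]) -amp else 0.1 * amp,
         broad = amp)
}

#' Simulate a grating session with known ground truth
#'
#' Every frame is the sum of cell and compartment footprints times their
#' tuned, indicator-filtered response trace, plus i.i.d. Gaussian noise.
#' Dendritic compartments share the soma's tuning scaled multiplicatively by
#' their attenuation (noise and baseline are not attenuated).
#'
#' @param cfg a \code{\link{gratingSimConfig}}.
#' @return List: \code{movie} (array y, x, t), \code{rois} (ground-truth
#'   footprints: pixels, kind, cell, compartment, attenuation), \code{tuning}
#'   (ground-truth table), \code{traces} (clean per-ROI traces),
#'   \code{protocol}, \code{frameRate}.
#' @export
simulateGratingSession <- function(cfg) {
  stopifnot(inherits(cfg, "GratingSimConfig"))
  p <- cfg$protocol
  nT <- ceiling(p$totalDuration * cfg$frameRate)
  tGrid <- (seq_len(nT) - 1) / cfg$frameRate
  n <- cfg$imgSize
  nCells <- length(cfg$tuningSpecs)
  withSeed(cfg$seed, {
    # soma centers on a coarse grid with jitter, dendrites radiating outward
    perRow <- ceiling(sqrt(nCells))
    pitch <- n / (perRow + 1)
    rois <- list(); traces <- list(); tuningTab <- list()
    alpha <- exp(-1 / (cfg$frameRate * cfg$indicatorDecayS))
    nStim <- length(p$directions) * length(p$speeds)
    for (ci in seq_len(nCells)) {
      spec <- cfg$tuningSpecs[[ci]]
      baseline <- spec$baseline %||% (if (spec$kind == "SbC") 1 else 0.2)
      nSupp <- ceiling((spec$sbcFraction %||% 0.8) * nStim)
      suppressed <- seq_len(nStim) <= nSupp
      drive <- numeric(nT)
      for (ri in seq_len(nrow(p$schedule))) {
        row <- p$schedule[ri, ]
        stimIdx <- (row$speedIdx - 1L) * length(p$directions) + row$dirIdx
        r <- tunedResponse(spec, p$directions[row$dirIdx], stimIdx, suppressed)
        sel <- tGrid >= row$onset & tGrid < row$onset + row$duration
        drive[sel] <- drive[sel] + r
      }
      resp <- as.numeric(stats::filter(drive * (1 - alpha), alpha,
                                       method = "recursive"))
      cx <- round(pitch * (1 + (ci - 1) %% perRow) + stats::runif(1, -1, 1))
      cy <- round(pitch * (1 + (ci - 1) %/% perRow) + stats::runif(1, -1, 1))
      soma <- which(outer(seq_len(n), seq_len(n),
                          function(y, x) (x - cx)^2 + (y - cy)^2 <= 4))
      rois[[length(rois) + 1L]] <-
        list(pixels = soma, kind = "soma", cell = ci, compartment = 0L,
             attenuation = 1, centerPx = c(cx, cy))
      # fluorescence cannot go below zero: suppression saturates at F = 0
      traces[[length(traces) + 1L]] <- pmax(baseline + resp, 0)
      ang <- stats::runif(1, 0, 2 * pi)
      for (j in seq_len(cfg$dendritesPerCell)) {
        att <- cfg$attenuation(j)
        dist0 <- 3 + 2.5 * j
        px <- integer(0)
        for (r in seq(dist0, dist0 + 2, by = 0.5)) {
          x <- round(cx + r * cos(ang)); y <- round(cy + r * sin(ang))
          if (x >= 1 && x <= n && y >= 1 && y <= n)
            px <- union(px, (x - 1L) * n + y)
        }
        px <- setdiff(px, soma)
        if (!length(px)) next
        rois[[length(rois) + 1L]] <-
          list(pixels = px, kind = "dendrite", cell = ci, compartment = j,
               attenuation = att,
               centerPx = c(round(cx + (dist0 + 1) * cos(ang)),
                            round(cy + (dist0 + 1) * sin(ang))))
        traces[[length(traces) + 1L]] <- pmax(baseline + att * resp, 0)
      }
      tuningTab[[ci]] <- data.frame(cell = ci, kind = spec$kind,
                                    prefDeg = spec$prefDeg %||% 0,
                                    kappa = spec$kappa %||% 4,
                                    amplitude = spec$amplitude %||% 1,
                                    baseline = baseline)
    }
    mat <- matrix(0, n * n, nT)
    for (i in seq_along(rois)) {
      mat[rois[[i]]$pixels, ] <-
        mat[rois[[i]]$pixels, , drop = FALSE] +
        matrix(traces[[i]], nrow = length(rois[[i]]$pixels),
               ncol = nT, byrow = TRUE)
    }
    if (cfg$noiseSd > 0)
      mat <- mat + matrix(stats::rnorm(length(mat), 0, cfg$noiseSd),
                          nrow(mat), ncol(mat))
    list(movie = array(mat, dim = c(n, n, nT)), rois = rois,
         tuning = do.call(rbind, tuningTab),
         traces = traces, protocol = p, frameRate = cfg$frameRate,
         umPerPx = cfg$umPerPx, seed = cfg$seed)
  })
}
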