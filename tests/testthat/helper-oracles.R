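# Independent oracles and small fixture builders used across tests.
# These deliberately do not reuse package internals.

# Closed-form moments of the occupancy count (number of distinct categories
# among n i.i.d. draws from probabilities p):
#   E[D]   = sum_t 1 - (1 - p_t)^n
#   Var(D) = sum_t q_t (1 - q_t) + sum_{t != u} [(1 - p_t - p_u)^n - q_t q_u]
# with q_t = (1 - p_t)^n.
occupancyMoments <- function(p, n) {
  q <- (1 - p)^n
  ev <- sum(1 - q)
  v <- sum(q * (1 - q))
  for (t in seq_along(p)) for (u in seq_along(p)) {
    if (t != u) v <- v + (1 - p[t] - p[u])^n - q[t] * q[u]
  }
  list(mean = ev, sd = sqrt(v))
}

# Brute-force distinct-type simulation independent of the package's
# rmultinom-based path.
occupancyBrute <- function(p, n, reps) {
  counts <- vapply(seq_len(reps), function(i) {
    length(unique(sample.int(length(p), n, replace = TRUE, prob = p)))
  }, numeric(1))
  c(mean = mean(counts), sd = sd(counts))
}

# ResponseMatrix with a prescribed positive 8-vector at speed 1 (zeros at the
# other speeds), for exercising the index formulas in isolation.
makeResp <- function(P8, N8 = rep(0, 8), snrPos = 10, snrNeg = 10,
                     directions = seq(0, 315, by = 45)) {
  P <- cbind(P8, 0, 0); N <- cbind(N8, 0, 0)
  new("ResponseMatrix", P = P, N = N, meanResp = P - N,
      baselines = matrix(0, 8, 3),
      trialP = array(rep(P, 2), dim = c(8, 3, 2)),
      trialN = array(rep(N, 2), dim = c(8, 3, 2)),
      F0 = 0, snr = max(snrPos, snrNeg), snrPos = snrPos, snrNeg = snrNeg,
      directions = directions, speeds = c(400, 1200, 2400))
}

# FlattenedStack with single bright voxels at given (y, x, depth) positions.
makeFlattened <- function(ny = 6, nx = 6, spots = list()) {
  depths <- seq(-0.625, 1.875, by = 0.025)
  a <- array(0, dim = c(ny, nx, length(depths)))
  for (s in spots) {
    k <- which.min(abs(depths - s$depth))
    a[s$y, s$x, k] <- s$value %||% 1
  }
  new("FlattenedStack", data = a, depths = depths)
}

# StratificationProfile built directly from per-stratum fractions.
makeProfile <- function(fractions, cof3 = FALSE, cof7 = FALSE,
                        asym = NA_real_) {
  new("StratificationProfile", fractions = fractions / sum(fractions),
      cofasciculation3 = cof3, cofasciculation7 = cof7,
      asymmetryIndex = asym)
}

# RFMapPair filled with given per-trial amplitude arrays (rows x cols x trials).
makePair <- function(trialOn, trialOff = trialOn, squareDeg = 8) {
  grid <- sparseNoiseGrid(dim(trialOn)[1], dim(trialOn)[2], squareDeg)
  new("RFMapPair",
      onMap = apply(trialOn, c(1, 2), mean),
      offMap = apply(trialOff, c(1, 2), mean),
      trialOn = trialOn, trialOff = trialOff,
      pOn = NA_real_, pOff = NA_real_, degPerPixel = squareDeg,
      azimuthDeg = grid$azimuth, elevationDeg = grid$elevation)
}
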