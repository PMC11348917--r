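# Calcium-imaging tuning analysis: movie preprocessing, local-correlation ROI
# detection, baselined response extraction, circular-variance selectivity
# indices with permutation significance, SbC classification and the category
# hierarchy.

#' Preprocess a calcium movie
#'
#' Corrects bidirectional-scanning line phase (a single integer x-offset of
#' even lines, estimated from the time-average), applies rigid
#' motion-correction (per-frame integer shift against a reference by
#' correlation peak), and filters every pixel with a centered moving average
#' of \code{filterS} seconds.
#'
#' @param movie numeric array (y, x, t).
#' @param frameRate frames per second (> 0).
#' @param filterS moving-average length in seconds (default 0.5).
#' @param maxShift registration search radius in pixels.
#' @param correctBidi,register,filter stage switches.
#' @return List: \code{movie} (filtered array), \code{shifts} (t x 2 matrix
#'   of applied dy, dx), \code{bidiOffset}.
#' @export
preprocessMovie <- function(movie, frameRate, filterS = 0.5, maxShift = 3,
                            correctBidi = TRUE, register = TRUE,
                            filter = TRUE) {
  if (frameRate <= 0) stop("frameRate must be > 0")
  d <- dim(movie)
  ny <- d[1L]; nx <- d[2L]; nT <- d[3L]
  bidiOffset <- 0L
  if (correctBidi && ny >= 4L) {
    avg <- rowMeans(matrix(movie, ny * nx, nT))
    avg <- matrix(avg, ny, nx)
    odd <- avg[seq(1L, ny, by = 2L), , drop = FALSE]
    even <- avg[seq(2L, ny, by = 2L), , drop = FALSE]
    nr <- min(nrow(odd), nrow(even))
    score <- vapply(-2:2, function(o) {
      ia <- max(1L, 1L + o):min(nx, nx + o)
      ib <- ia - o
      -sum((odd[seq_len(nr), ia] - even[seq_len(nr), ib])^2) / length(ia)
    }, numeric(1))
    bidiOffset <- (-2:2)[which.max(score)]
    if (bidiOffset != 0L) {
      rows <- seq(2L, ny, by = 2L)
      src <- pmin(pmax(seq_len(nx) - bidiOffset, 1L), nx)
      movie[rows, , ] <- movie[rows, src, ]
    }
  }
  shifts <- matrix(0L, nT, 2L)
  if (register && maxShift > 0L) {
    ref <- apply(movie[, , seq_len(min(nT, 100L)), drop = FALSE], c(1, 2), mean)
    inner <- (maxShift + 1L):(ny - maxShift)
    innerX <- (maxShift + 1L):(nx - maxShift)
    refSub <- as.numeric(ref[inner, innerX])
    refSub <- refSub - mean(refSub)
    offs <- expand.grid(dy = -maxShift:maxShift, dx = -maxShift:maxShift)
    m <- matrix(movie, ny * nx, nT)
    best <- rep(-Inf, nT); bestIdx <- rep(1L, nT)
    for (k in seq_len(nrow(offs))) {
      ys <- inner + offs$dy[k]; xs <- innerX + offs$dx[k]
      pix <- as.integer(outer(ys, (xs - 1L) * ny, "+"))
      sub <- m[pix, , drop = FALSE]
      sub <- sweep(sub, 2L, colMeans(sub))
      num <- as.numeric(crossprod(refSub, sub))
      den <- sqrt(colSums(sub^2))
      sc <- num / pmax(den, .Machine$double.eps)
      upd <- sc > best
      best[upd] <- sc[upd]; bestIdx[upd] <- k
    }
    for (f in seq_len(nT)) {
      dy <- offs$dy[bestIdx[f]]; dx <- offs$dx[bestIdx[f]]
      shifts[f, ] <- c(dy, dx)  # equals the injected motion of the frame

      if (dy != 0L || dx != 0L) {
        fr <- movie[, , f]
        out <- matrix(stats::median(fr), ny, nx)
        ys <- seq_len(ny); xs <- seq_len(nx)
        oky <- ys + dy >= 1L & ys + dy <= ny
        okx <- xs + dx >= 1L & xs + dx <= nx
        out[ys[oky], xs[okx]] <- fr[ys[oky] + dy, xs[okx] + dx]
        movie[, , f] <- out
      }
    }
  }
  if (filter) {
    k <- max(1L, round(filterS * frameRate))
    m <- t(matrix(movie, ny * nx, nT))
    m <- runningMeanMat(m, k)
    movie <- array(t(m), dim = d)
  }
  list(movie = movie, shifts = shifts, bidiOffset = bidiOffset)
}

#' Local-correlation image of a movie
#'
#' Per pixel, the mean Pearson correlation of its time series with its 8
#' neighbors. Constant pixels contribute correlation 0.
#'
#' @param movie numeric array (y, x, t) with at least 2 frames.
#' @return Matrix (y, x).
#' @export
localCorrelationImage <- function(movie) {
  d <- dim(movie)
  if (d[3L] < 2L) stop("local correlation undefined for a single frame")
  ny <- d[1L]; nx <- d[2L]; nT <- d[3L]
  m <- matrix(movie, ny * nx, nT)
  mu <- rowMeans(m)
  m <- m - mu
  sdv <- sqrt(rowSums(m^2) / (nT - 1))
  zero <- sdv <= .Machine$double.eps
  m[!zero, ] <- m[!zero, , drop = FALSE] / sdv[!zero]
  m[zero, ] <- 0
  Z <- array(m, dim = d)
  acc <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ya <- max(1L, 1L + dy):min(ny, ny + dy)
    xa <- max(1L, 1L + dx):min(nx, nx + dx)
    yb <- ya - dy; xb <- xa - dx
    prod <- rowSums(matrix(Z[ya, xa, , drop = FALSE] *
                           Z[yb, xb, , drop = FALSE],
                           length(ya) * length(xa), nT)) / (nT - 1)
    acc[ya, xa] <- acc[ya, xa] + matrix(prod, length(ya), length(xa))
    cnt[ya, xa] <- cnt[ya, xa] + 1
  }
  acc / cnt
}

#' Segment ROIs from a local-correlation image
#'
#' ROIs are seeded at local maxima of the correlation image above a floor and
#' grown to 8-connected neighbors while the pixel correlation exceeds a
#' threshold depending on both the seed's correlation and the local
#' background correlation. The local background of an ROI is the set of the
#' 5 darkest pixels (by mean intensity) within \code{bgRadiusUm} of it; its
#' trace is subtracted from the ROI trace by \code{\link{roiTrace}}.
#'
#' @param movie filtered movie (y, x, t).
#' @param corrImage from \code{\link{localCorrelationImage}} of that movie.
#' @param umPerPx pixel size in micrometer.
#' @param seedFloor minimum seed correlation (default 0.3).
#' @param fSeed growth threshold as a fraction of the seed value (0.5).
#' @param bgMargin growth threshold margin over background correlation (0.1).
#' @param bgRadiusUm background search radius (15 micrometer).
#' @param minPx,maxPx accepted ROI size range in pixels.
#' @return List of ROIs: \code{pixels} (linear indices), \code{centroidPx}
#'   (x, y), \code{centroidUm}, \code{kind}, \code{background} (pixel
#'   indices), \code{seedValue}.
#' @export
segmentRois <- function(movie, corrImage, umPerPx = 1, seedFloor = 0.3,
                        fSeed = 0.5, bgMargin = 0.1, bgRadiusUm = 15,
                        minPx = 3L, maxPx = 400L) {
  ny <- nrow(corrImage); nx <- ncol(corrImage)
  meanImg <- matrix(rowMeans(matrix(movie, ny * nx, dim(movie)[3L])), ny, nx)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- corrImage
  isMax <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    isMax <- isMax & corrImage >= pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
  }
  seeds <- which(isMax & corrImage > seedFloor)
  seeds <- seeds[order(corrImage[seeds], decreasing = TRUE)]
  claimed <- matrix(FALSE, ny, nx)
  radiusPx <- bgRadiusUm / umPerPx
  darkestNear <- function(cx, cy, exclude) {
    xs <- pmax(1L, round(cx - radiusPx)):pmin(nx, round(cx + radiusPx))
    ys <- pmax(1L, round(cy - radiusPx)):pmin(ny, round(cy + radiusPx))
    cand <- as.integer(outer(ys, (xs - 1L) * ny, "+"))
    rc <- arrayInd(cand, c(ny, nx))
    keep <- (rc[, 2L] - cx)^2 + (rc[, 1L] - cy)^2 <= radiusPx^2
    cand <- setdiff(cand[keep], exclude)
    cand[order(meanImg[cand])][seq_len(min(5L, length(cand)))]
  }
  rois <- list()
  for (s in seeds) {
    rc <- arrayInd(s, c(ny, nx))
    if (claimed[s]) next
    bg <- darkestNear(rc[2L], rc[1L], s)
    bgLevel <- if (length(bg)) mean(corrImage[bg]) else 0
    thr <- max(fSeed * corrImage[s], bgLevel + bgMargin)
    grow <- connectedRegion(corrImage > thr & !claimed, c(rc[1L], rc[2L]))
    px <- which(grow)
    if (length(px) < minPx || length(px) > maxPx) next
    claimed[px] <- TRUE
    prc <- arrayInd(px, c(ny, nx))
    cx <- mean(prc[, 2L]); cy <- mean(prc[, 1L])
    rois[[length(rois) + 1L]] <-
      list(pixels = px, centroidPx = c(cx, cy),
           centroidUm = c(cx, cy) * umPerPx, kind = "unassigned",
           background = darkestNear(cx, cy, px), seedValue = corrImage[s])
  }
  rois
}

#' Background-subtracted trace of one ROI
#' @param movie movie array (y, x, t).
#' @param roi an ROI from \code{\link{segmentRois}} (or any list with
#'   \code{pixels} and optionally \code{background}).
#' @return Numeric trace of length t.
#' @export
roiTrace <- function(movie, roi) {
  d <- dim(movie)
  m <- matrix(movie, d[1L] * d[2L], d[3L])
  tr <- colMeans(m[roi$pixels, , drop = FALSE])
  if (length(roi$background))
    tr <- tr - colMeans(m[roi$background, , drop = FALSE])
  tr
}

#' Extract a ResponseMatrix from a trace and protocol
#'
#' Per stimulus: the baseline is the median signal 1.75-0.25 s before onset;
#' the trial responses are baseline-subtracted, their pointwise median across
#' trials is filtered with the same moving average used in preprocessing, and
#' P (maximum), N (-minimum) and the stimulus-period average are extracted.
#' SNR is the maximum absolute amplitude over the baseline SD; F0 is the
#' smallest baseline of the 24 average responses.
#'
#' @param trace ROI trace (already preprocessed/filtered).
#' @param protocol a \code{\link{stimulusProtocol}}.
#' @param frameRate trace sampling rate (Hz).
#' @param filterS moving-average length for the median response (s).
#' @return A \linkS4class{ResponseMatrix}.
#' @export
extractResponses <- function(trace, protocol, frameRate, filterS = 0.5) {
  p <- protocol
  nd <- length(p$directions); ns <- length(p$speeds)
  tGrid <- (seq_along(trace) - 1) / frameRate
  k <- max(1L, round(filterS * frameRate))
  nTr <- max(p$schedule$trial)
  P <- matrix(0, nd, ns); N <- matrix(0, nd, ns)
  meanResp <- matrix(0, nd, ns); baselines <- matrix(NA_real_, nd, ns)
  trialP <- array(0, dim = c(nd, ns, nTr))
  trialN <- array(0, dim = c(nd, ns, nTr))
  baseResid <- numeric(0)
  missing <- character(0)
  for (s in seq_len(ns)) for (i in seq_len(nd)) {
    rows <- p$schedule[p$schedule$dirIdx == i & p$schedule$speedIdx == s, ]
    if (nrow(rows) == 0L) {
      missing <- c(missing, sprintf("dir %g speed %g", p$directions[i],
                                    p$speeds[s]))
      next
    }
    segs <- list(); bases <- numeric(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      on <- rows$onset[r]; dur <- rows$duration[r]
      bwin <- tGrid >= on - 1.75 & tGrid <= on - 0.25
      swin <- tGrid >= on & tGrid <= on + dur
      if (!any(bwin) || !any(swin))
        stop("trace does not cover all trials")
      bases[r] <- stats::median(trace[bwin])
      baseResid <- c(baseResid, trace[bwin] - bases[r])
      segs[[r]] <- trace[swin] - bases[r]
      segF <- runningMean(segs[[r]], k)
      trialP[i, s, rows$trial[r]] <- max(0, max(segF))
      trialN[i, s, rows$trial[r]] <- max(0, -min(segF))
    }
    L <- min(lengths(segs))
    med <- apply(do.call(cbind, lapply(segs, `[`, seq_len(L))), 1L,
                 stats::median)
    medF <- runningMean(med, k)
    P[i, s] <- max(0, max(medF))
    N[i, s] <- max(0, -min(medF))
    meanResp[i, s] <- mean(medF)
    baselines[i, s] <- stats::median(bases)
  }
  if (length(missing))
    stop("stimuli missing from the schedule: ",
         paste(missing, collapse = "; "))
  sdBase <- stats::sd(baseResid)
  if (!is.finite(sdBase) || sdBase == 0) sdBase <- .Machine$double.eps
  new("ResponseMatrix", P = P, N = N, meanResp = meanResp,
      baselines = baselines, trialP = trialP, trialN = trialN,
      F0 = min(baselines),
      snr = max(abs(c(P, -N))) / sdBase,
      snrPos = max(P) / sdBase, snrNeg = max(N) / sdBase,
      directions = p$directions, speeds = p$speeds)
}

# circular-variance population-vector index on nonnegative amplitudes
vectorIndex <- function(amps, dirsDeg, double = FALSE) {
  amps <- pmax(amps, 0)
  th <- dirsDeg * pi / 180 * (if (double) 2 else 1)
  tot <- sum(amps)
  if (tot == 0) return(list(index = 0, angleDeg = NA_real_))
  re <- sum(amps * cos(th)); im <- sum(amps * sin(th))
  ang <- atan2(im, re) * 180 / pi
  if (double) ang <- ang / 2
  list(index = sqrt(re^2 + im^2) / tot,
       angleDeg = ang %% (if (double) 180 else 360))
}

#' Direction- and orientation-selectivity indices of a ResponseMatrix
#'
#' Circular-variance indices on the 8-direction amplitude vectors (negative
#' values set to zero first): DSI is the resultant length of the population
#' vector, OSI of the doubled-angle vector; the same on negative amplitudes
#' gives DSI_neg / OSI_neg. Preferred direction (orientation) is the (half)
#' complex phase of the population vector, corrected for the eye-axis angle.
#' If no speed is given, the speed evoking the maximum response is selected
#' separately for the positive and negative indices (ties toward the slowest
#' speed). DSI is set to 0 when the positive-response SNR is <= 2.5, and
#' DSI_neg when the negative-response SNR is <= 2.5.
#'
#' @param resp a \linkS4class{ResponseMatrix}.
#' @param speedIdx optional fixed speed index (1..3).
#' @param eyeAxisOffsetDeg screen-to-eye angle subtracted from preferred
#'   angles (default 20; sign configurable via its sign).
#' @param snrGate SNR gate (default 2.5).
#' @return List: dsi, osi, dsiNeg, osiNeg, preferredDirection,
#'   preferredOrientation, bestSpeedPos, bestSpeedNeg, undefinedPos.
#' @examples
#' # single-direction responder: DSI = OSI = 1
#' @export
selectivityIndices <- function(resp, speedIdx = NULL, eyeAxisOffsetDeg = 20,
                               snrGate = 2.5) {
  sPos <- speedIdx %||% which.max(apply(resp@P, 2L, max))
  sNeg <- speedIdx %||% which.max(apply(resp@N, 2L, max))
  dirs <- resp@directions
  dsV <- vectorIndex(resp@P[, sPos], dirs)
  osV <- vectorIndex(resp@P[, sPos], dirs, double = TRUE)
  dsNV <- vectorIndex(resp@N[, sNeg], dirs)
  osNV <- vectorIndex(resp@N[, sNeg], dirs, double = TRUE)
  dsi <- if (resp@snrPos <= snrGate) 0 else dsV$index
  dsiNeg <- if (resp@snrNeg <= snrGate) 0 else dsNV$index
  pd <- if (is.na(dsV$angleDeg)) NA_real_
        else (dsV$angleDeg - eyeAxisOffsetDeg) %% 360
  po <- if (is.na(osV$angleDeg)) NA_real_
        else (osV$angleDeg - eyeAxisOffsetDeg) %% 180
  list(dsi = dsi, osi = osV$index, dsiNeg = dsiNeg, osiNeg = osNV$index,
       preferredDirection = pd, preferredOrientation = po,
       bestSpeedPos = as.integer(sPos), bestSpeedNeg = as.integer(sNeg),
       undefinedPos = is.na(dsV$angleDeg))
}

#' Permutation significance of a selectivity index
#'
#' Whole trials are randomly reassigned across direction labels (within a
#' speed) and the index recomputed; the p-value is the fraction of permuted
#' indices at least as large as the observed one, with the add-one
#' convention: p = (1 + #\{permuted >= observed\}) / (1 + nPerm).
#'
#' @param trialAmps matrix (directions x trials) of per-trial amplitudes.
#' @param dirsDeg direction angles (degrees).
#' @param double FALSE for DSI, TRUE for OSI.
#' @param nPerm permutations (default 1000; a warning is logged below 100).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
permutationSignificance <- function(trialAmps, dirsDeg, double = FALSE,
                                    nPerm = 1000, seed) {
  if (ncol(trialAmps) < 2L) stop("need at least 2 trials per stimulus")
  if (nPerm < 100) warning("nPerm < 100: p-value resolution is poor")
  agg <- apply(trialAmps, 1L, stats::median)
  obs <- vectorIndex(agg, dirsDeg, double)$index
  count <- withSeed(seed, {
    cnt <- 0L
    nd <- nrow(trialAmps)
    for (b in seq_len(nPerm)) {
      perm <- apply(trialAmps, 2L, function(col) col[sample.int(nd)])
      idx <- vectorIndex(apply(perm, 1L, stats::median), dirsDeg,
                         double)$index
      if (idx >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  (1 + count) / (1 + nPerm)
}

#' Suppressed-by-contrast classification
#'
#' A response counts as suppressed when its stimulus-period average is below
#' baseline; the cell is SbC when strictly more than half of the 24 average
#' responses are negative.
#'
#' @param resp a \linkS4class{ResponseMatrix}.
#' @return List: \code{sbc} (logical), \code{pctSuppressed} (fraction).
#' @export
classifySbc <- function(resp) {
  pct <- mean(resp@meanResp < 0)
  list(sbc = pct > 0.5, pctSuppressed = pct)
}

#' Assign the unique response category
#'
#' Hierarchy from high to low: DS, OS, DS_neg, OS_neg, SbC, broad. A cell is
#' DS when DSI > 0.3 and pDS < 0.05 (even if it also shows significant OS or
#' negative selectivity), and so on down the hierarchy; SbC when the
#' suppressed-by-contrast rule fires; broad when DSI < 0.15 and OSI < 0.15
#' and nothing above applied; otherwise none.
#'
#' @param dsi,osi,dsiNeg,osiNeg selectivity indices.
#' @param pDS,pOS,pDSNeg,pOSNeg permutation p-values.
#' @param sbc suppressed-by-contrast flag.
#' @param indexThreshold,broadThreshold,alpha rule constants (0.3, 0.15, 0.05).
#' @return Category string.
#' @export
categorize <- function(dsi, osi, dsiNeg, osiNeg, pDS, pOS, pDSNeg, pOSNeg,
                       sbc, indexThreshold = 0.3, broadThreshold = 0.15,
                       alpha = 0.05) {
  if (dsi > indexThreshold && pDS < alpha) return("DS")
  if (osi > indexThreshold && pOS < alpha) return("OS")
  if (dsiNeg > indexThreshold && pDSNeg < alpha) return("DS_neg")
  if (osiNeg > indexThreshold && pOSNeg < alpha) return("OS_neg")
  if (sbc) return("SbC")
  if (dsi < broadThreshold && osi < broadThreshold) return("broad")
  "none"
}

#' Full tuning analysis of one ROI
#'
#' Runs \code{\link{selectivityIndices}} with the speed-selection rules,
#' permutation significance for all four indices at the selected speeds, SbC
#' classification and the category hierarchy.
#'
#' @param resp a \linkS4class{ResponseMatrix}.
#' @param nPerm permutations per index.
#' @param seed integer seed.
#' @param eyeAxisOffsetDeg eye-axis correction (degrees).
#' @return A \linkS4class{TuningResult}.
#' @export
tuningAnalysis <- function(resp, nPerm = 1000, seed,
                           eyeAxisOffsetDeg = 20) {
  si <- selectivityIndices(resp, eyeAxisOffsetDeg = eyeAxisOffsetDeg)
  dirs <- resp@directions
  ampP <- resp@trialP[, si$bestSpeedPos, , drop = TRUE]
  ampN <- resp@trialN[, si$bestSpeedNeg, , drop = TRUE]
  pDS <- permutationSignificance(ampP, dirs, FALSE, nPerm,
                                 childSeed(seed, "pDS"))
  pOS <- permutationSignificance(ampP, dirs, TRUE, nPerm,
                                 childSeed(seed, "pOS"))
  pDSn <- permutationSignificance(ampN, dirs, FALSE, nPerm,
                                  childSeed(seed, "pDSn"))
  pOSn <- permutationSignificance(ampN, dirs, TRUE, nPerm,
                                  childSeed(seed, "pOSn"))
  sb <- classifySbc(resp)
  cat <- categorize(si$dsi, si$osi, si$dsiNeg, si$osiNeg,
                    pDS, pOS, pDSn, pOSn, sb$sbc)
  new("TuningResult", dsi = si$dsi, osi = si$osi, dsiNeg = si$dsiNeg,
      osiNeg = si$osiNeg, pDS = pDS, pOS = pOS, pDSNeg = pDSn,
      pOSNeg = pOSn,
      preferredDirection = si$preferredDirection %||% NA_real_,
      preferredOrientation = si$preferredOrientation %||% NA_real_,
      sbc = sb$sbc, pctSuppressed = sb$pctSuppressed, category = cat,
      bestSpeedPos = si$bestSpeedPos, bestSpeedNeg = si$bestSpeedNeg)
}

#' Match ROIs across sessions of the same imaging region
#'
#' Rigidly aligns session B to session A by the correlation peak of their
#' mean images, then matches ROIs by centroid distance. Per matched group
#' either the highest-SNR session is retained (default) or responses can be
#' concatenated by the caller.
#'
#' @param roisA,roisB ROI lists from \code{\link{segmentRois}}.
#' @param meanImgA,meanImgB mean images of the two sessions.
#' @param snrA,snrB optional per-ROI SNR vectors used for selection.
#' @param maxShift alignment search radius (pixels).
#' @param maxDistPx maximum centroid distance counted as a match.
#' @param minAlignCor minimum image correlation; below it the fields are
#'   considered non-overlapping and an error is raised.
#' @return data.frame: \code{idxA}, \code{idxB}, \code{distPx},
#'   \code{keep} ("A" or "B" by higher SNR).
#' @export
matchRois <- function(roisA, roisB, meanImgA, meanImgB, snrA = NULL,
                      snrB = NULL, maxShift = 10L, maxDistPx = 3,
                      minAlignCor = 0.2) {
  ny <- nrow(meanImgA); nx <- ncol(meanImgA)
  best <- c(0L, 0L); bestCor <- -Inf
  for (dy in -maxShift:maxShift) for (dx in -maxShift:maxShift) {
    ya <- max(1L, 1L + dy):min(ny, ny + dy)
    xa <- max(1L, 1L + dx):min(nx, nx + dx)
    a <- meanImgA[ya, xa]; b <- meanImgB[ya - dy, xa - dx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cc <- stats::cor(as.numeric(a), as.numeric(b))
    if (cc > bestCor) { bestCor <- cc; best <- c(dy, dx) }
  }
  if (bestCor < minAlignCor)
    stop("imaging fields do not overlap (best image correlation ",
         format(bestCor, digits = 2), ")")
  out <- list()
  usedB <- logical(length(roisB))
  for (i in seq_along(roisA)) {
    ca <- roisA[[i]]$centroidPx
    dists <- vapply(roisB, function(r) {
      cb <- r$centroidPx + c(best[2L], best[1L])  # map B into A's frame
      sqrt(sum((ca - cb)^2))
    }, numeric(1))
    j <- which.min(dists)
    if (length(j) && !usedB[j] && dists[j] <= maxDistPx) {
      usedB[j] <- TRUE
      keep <- if (!is.null(snrA) && !is.null(snrB) && snrB[j] > snrA[i])
        "B" else "A"
      out[[length(out) + 1L]] <-
        data.frame(idxA = i, idxB = j, distPx = dists[j], keep = keep)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(idxA = integer(0), idxB = integer(0),
                  distPx = numeric(0), keep = character(0))
}
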