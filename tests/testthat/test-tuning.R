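# Calcium-tuning analysis: preprocessing, ROI detection, response
# extraction, the circular-variance indices and their permutation tests.

test_that("protocol arithmetic is internally consistent", {
  p <- stimulusProtocol()
  expect_equal(p$durations, c(12, 4, 2))
  expect_equal(p$temporalFreqs, c(1 / 3, 1, 2))
  expect_equal(p$durations * p$temporalFreqs, rep(4, 3))
  expect_equal(nrow(p$schedule), 24 * p$nTrials)
  expect_error(stimulusProtocol(interstimS = 1), "baseline")
})

test_that("preprocessing recovers injected motion and leaves statics alone", {
  withr::with_seed(1, {
    ny <- 20; nx <- 20; nT <- 80
    scene <- matrix(0, ny, nx)
    scene[6:9, 6:9] <- 1; scene[13:16, 12:15] <- 0.6
    shifts <- cbind(sample(-2:2, nT, TRUE), sample(-2:2, nT, TRUE))
    shifts[1:5, ] <- 0L
    mov <- array(0, c(ny, nx, nT))
    for (f in 1:nT) {
      fr <- matrix(0, ny, nx)
      ys <- 1:ny; xs <- 1:nx
      oky <- ys - shifts[f, 1] >= 1 & ys - shifts[f, 1] <= ny
      okx <- xs - shifts[f, 2] >= 1 & xs - shifts[f, 2] <= nx
      fr[ys[oky], xs[okx]] <- scene[ys[oky] - shifts[f, 1],
                                    xs[okx] - shifts[f, 2]]
      mov[, , f] <- fr + rnorm(ny * nx, 0, 0.02)
    }
    pp <- preprocessMovie(mov, frameRate = 10, filter = FALSE)
    expect_gte(mean(rowSums(pp$shifts == shifts) == 2), 0.95)
  })
  # zero-motion movie: all shifts zero; constant movie unchanged by filtering
  blob <- outer(dnorm(1:10, 5, 1.5), dnorm(1:10, 6, 1.5))
  still <- array(rep(blob, 30), dim = c(10, 10, 30))
  pps <- preprocessMovie(still, frameRate = 10, maxShift = 2)
  expect_true(all(pps$shifts == 0))
  expect_equal(pps$bidiOffset, 0L)
  expect_equal(pps$movie, still)
  expect_error(preprocessMovie(still, frameRate = 0), "frameRate")
})

test_that("local correlation separates shared signal from noise", {
  withr::with_seed(3, {
    noise <- array(rnorm(12 * 12 * 200), dim = c(12, 12, 200))
    ci <- localCorrelationImage(noise)
    expect_lt(abs(mean(ci)), 0.05)
    sig <- noise * 0.2
    common <- sin(seq_len(200) / 5)
    for (y in 4:8) for (x in 4:8) sig[y, x, ] <- sig[y, x, ] + common
    ci2 <- localCorrelationImage(sig)
    expect_gt(min(ci2[5:7, 5:7]), 0.8)
  })
  expect_error(localCorrelationImage(array(0, c(4, 4, 1))), "single frame")
})

test_that("ROI segmentation finds phantom somata and ignores pure noise", {
  proto <- stimulusProtocol(nTrials = 1, interstimS = 2)
  ses <- simulateGratingSession(gratingSimConfig(
    list(list(kind = "broad", amplitude = 2),
         list(kind = "broad", amplitude = 2)),
    protocol = proto, frameRate = 4, noiseSd = 0.05, imgSize = 20,
    seed = 9))
  pp <- preprocessMovie(ses$movie, 4, register = FALSE)
  rois <- segmentRois(pp$movie, localCorrelationImage(pp$movie), umPerPx = 2)
  expect_equal(length(rois), 2L)
  expect_length(intersect(rois[[1]]$pixels, rois[[2]]$pixels), 0)
  jac <- vapply(ses$rois, function(g) {
    max(vapply(rois, function(r)
      length(intersect(g$pixels, r$pixels)) /
        length(union(g$pixels, r$pixels)), numeric(1)))
  }, numeric(1))
  expect_true(all(jac >= 0.6))
  # background pixels never overlap the ROI
  for (r in rois) expect_length(intersect(r$pixels, r$background), 0)
  withr::with_seed(10, {
    for (i in 1:3) {
      noise <- array(rnorm(16 * 16 * 300, 0, 1), dim = c(16, 16, 300))
      expect_length(segmentRois(noise, localCorrelationImage(noise),
                                umPerPx = 2), 0)
    }
  })
})

test_that("response extraction recovers amplitudes and flags gaps", {
  proto <- stimulusProtocol(nTrials = 2, interstimS = 2)
  fr <- 4
  nT <- ceiling(proto$totalDuration * fr)
  tGrid <- (seq_len(nT) - 1) / fr
  # flat trace
  resp0 <- extractResponses(rep(1, nT), proto, fr)
  expect_true(all(resp0@P == 0) && all(resp0@N == 0))
  expect_true(all(abs(resp0@meanResp) < 1e-12))
  expect_equal(resp0@F0, 1)
  # boxcar during one stimulus only (both trials)
  rows <- proto$schedule[proto$schedule$dirIdx == 3 &
                           proto$schedule$speedIdx == 2, ]
  tr <- rep(0, nT)
  for (i in seq_len(nrow(rows)))
    tr[tGrid >= rows$onset[i] & tGrid < rows$onset[i] + rows$duration[i]] <- 1
  resp1 <- extractResponses(tr, proto, fr)
  expect_equal(resp1@P[3, 2], 1)
  expect_equal(resp1@N[3, 2], 0)
  expect_gt(resp1@meanResp[3, 2], 0)
  expect_equal(sum(resp1@P > 0.5), 1)
  # truncated trace errors
  expect_error(extractResponses(tr[1:100], proto, fr), "cover")
  # amplitude recovery on a clean tuned cell (fast indicator so responses
  # decay fully within the interstimulus gray)
  ses <- simulateGratingSession(gratingSimConfig(
    list(list(kind = "broad", amplitude = 1.5)), protocol = proto,
    frameRate = fr, noiseSd = 0, imgSize = 10, indicatorDecayS = 0.3,
    seed = 2))
  resp2 <- extractResponses(ses$traces[[1]], proto, fr)
  expect_lt(abs(max(resp2@P) - 1.5), 0.15)
})

test_that("selectivity indices satisfy the circular-variance identities", {
  dirs <- seq(0, 315, by = 45)
  # single-direction responder
  single <- selectivityIndices(makeResp(c(1, rep(0, 7))),
                               eyeAxisOffsetDeg = 0)
  expect_equal(single$dsi, 1)
  expect_equal(single$osi, 1)
  expect_equal(single$preferredDirection, 0)
  # symmetric responder: DSI exactly 0, OSI 1
  symm <- selectivityIndices(makeResp(c(1, 0, 0, 0, 1, 0, 0, 0)),
                             eyeAxisOffsetDeg = 0)
  expect_equal(symm$dsi, 0)
  expect_equal(symm$osi, 1)
  # printed-formula example: P = (2, 1, ..., 1) -> DSI = 1/9
  hand <- selectivityIndices(makeResp(c(2, rep(1, 7))), eyeAxisOffsetDeg = 0)
  expect_equal(hand$dsi, 1 / 9)
  expect_equal(hand$preferredDirection, 0)
  # scale invariance and rotation covariance
  base <- c(2, 1.2, 0.3, 0.1, 0, 0, 0.1, 0.9)
  a <- selectivityIndices(makeResp(base), eyeAxisOffsetDeg = 0)
  b <- selectivityIndices(makeResp(3.7 * base), eyeAxisOffsetDeg = 0)
  expect_equal(a$dsi, b$dsi)
  expect_equal(a$osi, b$osi)
  rot <- selectivityIndices(makeResp(base[c(8, 1:7)]), eyeAxisOffsetDeg = 0)
  expect_equal(rot$preferredDirection,
               (a$preferredDirection + 45) %% 360, tolerance = 1e-6)
  expect_equal(rot$dsi, a$dsi)
  # eye-axis correction rotates reported angles
  corr <- selectivityIndices(makeResp(c(1, rep(0, 7))))
  expect_equal(corr$preferredDirection, 340)
  # direction-symmetric responses have DSI = 0 for any profile
  withr::with_seed(4, {
    for (i in 1:20) {
      half <- runif(4)
      si <- selectivityIndices(makeResp(rep(half, 2)), eyeAxisOffsetDeg = 0)
      expect_lt(si$dsi, 1e-12)
    }
  })
  # zero response vector: DSI 0 and flagged
  z <- selectivityIndices(makeResp(rep(0, 8)))
  expect_equal(z$dsi, 0)
  expect_true(z$undefinedPos)
})

test_that("the SNR gate forces DSI to zero", {
  gated <- selectivityIndices(makeResp(c(5, rep(0, 7)), snrPos = 2.0))
  expect_equal(gated$dsi, 0)
  gatedN <- selectivityIndices(makeResp(rep(0, 8), N8 = c(5, rep(0, 7)),
                                        snrNeg = 2.0))
  expect_equal(gatedN$dsiNeg, 0)
})

test_that("permutation significance separates tuned from untuned", {
  dirs <- seq(0, 315, by = 45)
  flat <- matrix(1, 8, 4)
  expect_gt(permutationSignificance(flat, dirs, nPerm = 200, seed = 1), 0.9)
  tuned <- matrix(0.05, 8, 4) + cbind(c(2, rep(0, 7)), c(2.1, rep(0, 7)),
                                      c(1.9, rep(0, 7)), c(2, rep(0, 7)))
  expect_lt(permutationSignificance(tuned, dirs, nPerm = 200, seed = 1),
            0.05)
  expect_error(permutationSignificance(matrix(1, 8, 1), dirs, seed = 1),
               "2 trials")
  expect_warning(permutationSignificance(flat, dirs, nPerm = 50, seed = 1),
                 "nPerm")
})

test_that("SbC follows the strict majority-of-24 rule", {
  mk <- function(nNeg) {
    m <- matrix(1, 8, 3); m[seq_len(nNeg)] <- -1
    new("ResponseMatrix", P = matrix(0, 8, 3), N = matrix(0, 8, 3),
        meanResp = m, baselines = matrix(0, 8, 3),
        trialP = array(0, c(8, 3, 2)), trialN = array(0, c(8, 3, 2)),
        F0 = 0, snr = 1, snrPos = 1, snrNeg = 1,
        directions = seq(0, 315, 45), speeds = c(400, 1200, 2400))
  }
  expect_true(classifySbc(mk(13))$sbc)
  expect_false(classifySbc(mk(12))$sbc)
  r0 <- classifySbc(mk(0))
  expect_false(r0$sbc)
  expect_equal(r0$pctSuppressed, 0)
})

test_that("the category hierarchy resolves overlapping features", {
  expect_equal(categorize(0.5, 0.9, 0, 0, 0.01, 0.01, 1, 1, sbc = TRUE),
               "DS")
  expect_equal(categorize(0.1, 0.6, 0, 0, 0.5, 0.01, 1, 1, sbc = FALSE),
               "OS")
  expect_equal(categorize(0.1, 0.1, 0.5, 0, 1, 1, 0.01, 1, sbc = FALSE),
               "DS_neg")
  expect_equal(categorize(0.1, 0.1, 0.1, 0.1, 1, 1, 1, 1, sbc = TRUE),
               "SbC")
  expect_equal(categorize(0.1, 0.1, 0.1, 0.1, 1, 1, 1, 1, sbc = FALSE),
               "broad")
  expect_equal(categorize(0.2, 0.2, 0.1, 0.1, 1, 1, 1, 1, sbc = FALSE),
               "none")
})

test_that("ROI matching aligns duplicated and shifted sessions", {
  proto <- stimulusProtocol(nTrials = 1, interstimS = 2)
  ses <- simulateGratingSession(gratingSimConfig(
    list(list(kind = "broad", amplitude = 2),
         list(kind = "broad", amplitude = 2)),
    protocol = proto, frameRate = 4, noiseSd = 0.05, imgSize = 20,
    seed = 9))
  pp <- preprocessMovie(ses$movie, 4, register = FALSE)
  meanImg <- apply(pp$movie, c(1, 2), mean)
  rois <- segmentRois(pp$movie, localCorrelationImage(pp$movie), umPerPx = 2)
  m <- matchRois(rois, rois, meanImg, meanImg)
  expect_equal(nrow(m), length(rois))
  expect_true(all(m$idxA == m$idxB))
  # shifted duplicate: matches recovered through the alignment
  shift <- 3L
  imgB <- meanImg * 0
  imgB[1:(20 - shift), ] <- meanImg[(1 + shift):20, ]
  roisB <- lapply(rois, function(r) {
    r$centroidPx <- r$centroidPx + c(0, -shift)  # (x, y): y moves up
    r
  })
  m2 <- matchRois(rois, roisB, meanImg, imgB)
  expect_equal(nrow(m2), length(rois))
  # disjoint ROI sets in the same field: zero matches
  far <- lapply(rois, function(r) {
    r$centroidPx <- r$centroidPx + c(9, 9); r
  })
  m3 <- matchRois(rois, far, meanImg, meanImg, maxDistPx = 2)
  expect_equal(nrow(m3), 0L)
})
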