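# ChAT-band detection, flattening and stratification-based typing, scored
# against the phantom generator's ground truth.

planarStack <- function(ny = 10, nx = 10, nz = 24, z1 = 8, z2 = 15) {
  a <- array(0, dim = c(ny, nx, nz))
  a[, , z1] <- 1; a[, , z2] <- 1
  a
}

test_that("band probability peaks on noiseless planes", {
  stack <- planarStack()
  prob <- detectBandProbability(stack)
  arg <- apply(prob, c(1, 2), which.max)
  expect_true(all(arg %in% c(8, 15)))
  expect_error(detectBandProbability(matrix(0, 4, 4)), "3D")
  # pluggable detector contract
  passthrough <- detectBandProbability(stack, detector = function(s) s)
  expect_equal(dim(passthrough), dim(stack))
})

test_that("surface extraction recovers planar and curved phantoms", {
  surf <- extractBandSurfaces(detectBandProbability(planarStack()))
  expect_lt(max(abs(surf@offZ - 8)), 0.6)
  expect_lt(max(abs(surf@onZ - 15)), 0.6)
  # curved phantom, high SNR: per-column error within 1 plane
  ph <- simulateRetinaStack(retinaPhantomConfig(xySize = 32, zSize = 36,
                                                bandSep = 8,
                                                curvatureAmp = 3,
                                                noiseSd = 0.02, seed = 6))
  surf2 <- extractBandSurfaces(detectBandProbability(ph$chat))
  offErr <- abs(surf2@offZ - ph$surfaces@offZ)
  onErr <- abs(surf2@onZ - ph$surfaces@onZ)
  expect_gte(mean(offErr <= 1 & onErr <= 1), 0.99)
  expect_lte(mean(offErr), 1)
  expect_lte(mean(onErr), 1)
  # degenerate inputs error instead of guessing
  expect_error(extractBandSurfaces(array(0, dim = c(4, 4, 10))), "ridges")
  touching <- detectBandProbability(planarStack(z1 = 11, z2 = 13))
  expect_error(extractBandSurfaces(touching), "ridges|cross")
})

test_that("manual curation fills columns the detector cannot resolve", {
  stack <- planarStack(ny = 6, nx = 6)
  stack[3, 3, ] <- 0  # one dead column
  prob <- detectBandProbability(stack)
  expect_error(extractBandSurfaces(prob), "y=3, x=3")
  fixed <- extractBandSurfaces(prob, manual = data.frame(
    y = 3, x = 3, off_z = 8, on_z = 15))
  expect_equal(dim(fixed@offZ), c(6L, 6L))
})

test_that("flattening maps bands to 0 and 1 and preserves strata", {
  surf <- new("ChatBandSurfaces", offZ = matrix(8, 6, 6),
              onZ = matrix(16, 6, 6))
  stack <- array(0, dim = c(6, 6, 24))
  stack[2, 2, 8] <- 1    # exactly on the OFF band
  stack[4, 4, 12] <- 1   # midway between bands
  fl <- flattenStack(stack, surf)
  expect_equal(fl@depths[which.max(fl@data[2, 2, ])], 0)
  expect_equal(fl@depths[which.max(fl@data[4, 4, ])], 0.5)
  bad <- new("ChatBandSurfaces", offZ = matrix(8, 6, 6),
             onZ = matrix(c(16, rep(16, 34), 16), 6, 6))
  bad@onZ[1, 1] <- 8.0001
  expect_error(flattenStack(stack, new("ChatBandSurfaces",
                                       offZ = matrix(1:36, 6, 6),
                                       onZ = matrix(1:36, 6, 6))))
  expect_error(flattenStack(array(0, dim = c(3, 3, 5)), surf), "xy grid")
})

test_that("a voxel's stratum is invariant to band curvature", {
  for (amp in c(0, 1.5, 3)) {
    ph <- simulateRetinaStack(retinaPhantomConfig(
      xySize = 28, zSize = 36, bandSep = 8, curvatureAmp = amp,
      cells = list(list(soma = c(14, 14), strata = 5, arborRadius = 8)),
      noiseSd = 0, seed = 7))
    fl <- flattenStack(ph$rgc, ph$surfaces)
    m <- ph$cells[[1]]$mask
    prof <- stratificationProfile(fl, m)
    expect_gt(strataFractions(prof)[5], 0.85)
    # dendrite placed at the stratum-5 center peaks at depth 0.50
    idx <- which(m & matrix(TRUE, 28, 28))
    peak <- fl@depths[which.max(apply(fl@data, 3, function(sl) sum(sl[m])))]
    # when the true depth falls exactly between two z-planes, the rendered
    # tent profile plateaus and the argmax can land one depth sample off
    expect_lte(abs(peak - 0.5), 0.05 + 1e-9)
  }
})

test_that("stratum-colored projection labels by argmax depth", {
  fl <- makeFlattened(spots = list(list(y = 2, x = 2, depth = 1.0),
                                   list(y = 4, x = 5, depth = -0.5)))
  proj <- stratumColoredProjection(fl, threshold = 0.5)
  expect_equal(proj$labels[2, 2], 7L)
  expect_equal(proj$labels[4, 5], 1L)
  expect_equal(proj$labels[1, 1], 0L)  # background
})

test_that("stratification profile quantifies cofasciculation and asymmetry", {
  # all signal in the stratum-7 window, overlapping ChAT
  fl <- makeFlattened(spots = list(list(y = 3, x = 3, depth = 1.0)))
  chat <- makeFlattened(spots = list(list(y = 3, x = 3, depth = 1.0),
                                     list(y = 3, x = 3, depth = 0)))
  mask <- matrix(FALSE, 6, 6); mask[3, 3] <- TRUE
  pr <- stratificationProfile(fl, mask, chat)
  expect_equal(strataFractions(pr)[7], 1)
  expect_true(pr@cofasciculation7)
  expect_false(pr@cofasciculation3)
  expect_error(stratificationProfile(fl, matrix(FALSE, 6, 6)), "empty")
  # radially symmetric arbor: asymmetry near 0; one-sided arbor: large
  sym <- simulateRetinaStack(retinaPhantomConfig(
    xySize = 28, zSize = 30, curvatureAmp = 0,
    cells = list(list(soma = c(14, 14), strata = 1, arborRadius = 8)),
    noiseSd = 0, seed = 3))
  flSym <- flattenStack(sym$rgc, sym$surfaces)
  prSym <- stratificationProfile(flSym, sym$cells[[1]]$mask,
                                 somaXy = c(14, 14))
  expect_lt(prSym@asymmetryIndex, 0.15)
  oneSided <- simulateRetinaStack(retinaPhantomConfig(
    xySize = 28, zSize = 30, curvatureAmp = 0,
    cells = list(list(soma = c(10, 14), strata = 1, asymmetry = TRUE,
                      arborRadius = 9)),
    noiseSd = 0, seed = 3))
  flA <- flattenStack(oneSided$rgc, oneSided$surfaces)
  prA <- stratificationProfile(flA, oneSided$cells[[1]]$mask,
                               somaXy = c(10, 14))
  expect_gt(prA@asymmetryIndex, 0.3)
})

test_that("type calls follow the rule cascade", {
  f37 <- makeProfile(c(0, 0, .5, 0, 0, 0, .5, 0, 0, 0), cof3 = TRUE,
                     cof7 = TRUE)
  c37 <- classifyRgc(f37)
  expect_equal(c37$type_label, "37")
  expect_equal(c37$kinetics, "transient")
  expect_equal(c37$polarity, "ON-OFF")
  expect_true(c37$is_DS)
  f7 <- makeProfile(c(0, 0, .05, 0, 0, 0, .95, 0, 0, 0), cof7 = TRUE)
  expect_equal(classifyRgc(f7)$type_label, "7")
  f12 <- makeProfile(c(.6, .4, rep(0, 8)))
  expect_equal(classifyRgc(f12)$type_label, "12")
  expect_equal(classifyRgc(f12)$polarity, "OFF")
  f12a <- makeProfile(c(.6, .4, rep(0, 8)), asym = 0.5)
  ca <- classifyRgc(f12a)
  expect_equal(ca$type_label, "12_asym")
  expect_true(ca$is_JAMB)
  f189 <- makeProfile(c(.3, .2, 0, 0, 0, 0, 0, .3, .2, 0))
  expect_equal(classifyRgc(f189)$type_label, "189")
  f89 <- makeProfile(c(rep(0, 7), .5, .5, 0))
  c89 <- classifyRgc(f89)
  expect_equal(c89$type_label, "89")
  expect_equal(c89$kinetics, "sustained")
  expect_equal(c89$polarity, "ON")
  f4 <- makeProfile(c(0, 0, 0, 1, rep(0, 6)))
  expect_equal(classifyRgc(f4)$type_label, "4")
  fO <- makeProfile(rep(0.1, 10))
  expect_equal(classifyRgc(fO)$type_label, "other")
  # permuting the strata axis breaks the call (sanity negative)
  fPerm <- makeProfile(rev(strataFractions(f89)))
  expect_false(identical(classifyRgc(fPerm)$type_label, "89"))
})
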