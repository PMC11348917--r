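# Monte-Carlo specialization statistics against closed-form occupancy
# oracles and hand-computed examples.

test_that("reference distribution is the stated weighted mixture", {
  d <- c(a = 0.3, b = 0.7)
  expect_equal(referenceDistribution(d, d), d)
  expect_equal(referenceDistribution(d, c(a = 1, b = 0), wIn = 0), d)
  # uniform-2 TCN component vs (1, 0) interneuron component at the defaults:
  # weights 0.8*20 = 16 and 0.2*96 = 19.2; type-1 mass (16*0.5 + 19.2)/35.2
  mix <- referenceDistribution(c(a = 0.5, b = 0.5), c(a = 1, b = 0))
  expect_equal(unname(mix["a"]), (16 * 0.5 + 19.2) / 35.2, tolerance = 1e-12)
  expect_error(referenceDistribution(c(a = 1), c(b = 1)), "label set")
})

test_that("occupancy null matches closed-form moments", {
  # uniform and a skewed distribution, several draw sizes
  cases <- list(list(p = rep(1 / 40, 40), n = 50),
                list(p = rep(1 / 8, 8), n = 12),
                list(p = (1:10) / sum(1:10), n = 25))
  for (cs in cases) {
    null <- occupancyNull(cs$p, cs$n, nReps = 2e4, seed = 42)
    oracle <- occupancyMoments(cs$p, cs$n)
    seMean <- oracle$sd / sqrt(2e4)
    expect_lt(abs(expectedTypes(null) - oracle$mean), 3 * seMean)
    # SE of the SD estimate, normal approximation
    expect_lt(abs(sdTypes(null) - oracle$sd),
              3 * oracle$sd / sqrt(2 * (2e4 - 1)))
  }
})

test_that("occupancy null handles degenerate draws", {
  expect_equal(expectedTypes(occupancyNull(5, 0, nReps = 100, seed = 1)), 0)
  one <- occupancyNull(c(1), 10, nReps = 100, seed = 1)
  expect_equal(expectedTypes(one), 1)
  expect_equal(sdTypes(one), 0)
  expect_error(specializationZ(1, one), "degenerate")
  expect_error(occupancyNull(c(0.5, 0.6), 5, seed = 1), "sum to 1")
  expect_error(occupancyNull(rep(0.25, 4), -1, seed = 1), ">= 0")
})

test_that("z score matches exhaustive enumeration for tiny draws", {
  # uniform over 3 types, n = 2: all 9 draws equally likely, distinct count
  # is 1 (3 draws) or 2 (6 draws) -> mean 5/3, var 2/9
  draws <- expand.grid(a = 1:3, b = 1:3)
  distinct <- apply(draws, 1, function(r) length(unique(r)))
  expect_equal(mean(distinct), 5 / 3)
  null <- occupancyNull(3, 2, nReps = 1e5, seed = 9)
  z <- zScore(specializationZ(1, null))
  expect_equal(z, (1 - 5 / 3) / sqrt(2 / 9), tolerance = 0.02)
})

test_that("z score is monotone in the observed deficit and 0 at the mean", {
  null <- occupancyNull(40, 50, nReps = 1e4, seed = 3)
  zs <- vapply(15:30, function(k) zScore(specializationZ(k, null)),
               numeric(1))
  expect_true(all(diff(zs) > 0))
  # z is exactly (observed - expected) / sd
  k <- round(expectedTypes(null))
  expect_equal(zScore(specializationZ(k, null)),
               (k - expectedTypes(null)) / sdTypes(null))
})

test_that("z scores of clusters drawn from the null itself are standardized", {
  p <- rep(1 / 8, 8)
  null <- occupancyNull(p, 20, nReps = 2e4, seed = 11)
  counts <- withr::with_seed(12, {
    colSums(rmultinom(500, 20, p) > 0)
  })
  zs <- (counts - expectedTypes(null)) / sdTypes(null)
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("pooling experiment reproduces the four worked specialization cases", {
  # these are the printed simulation examples; asserted at the published
  # tolerance in test-acceptance.R -- here only conventions and errors
  res <- poolingExperiment(40, 50, 1:20, nReps = 5e3, seed = 2)
  expect_equal(observedTypes(res), 20L)
  pool2 <- rep(1:20, each = 2)
  res2 <- poolingExperiment(40, 50, 1:26, poolingMap = pool2,
                            nReps = 5e3, seed = 2)
  expect_equal(observedTypes(res2), 13L)
  crossPool <- rep(1:20, 2)
  res3 <- poolingExperiment(40, 50, 1:20, poolingMap = crossPool,
                            nReps = 5e3, seed = 2)
  expect_equal(observedTypes(res3), 20L)
  expect_gt(zScore(res3), 0)
  expect_error(poolingExperiment(40, 50, c(1, 99), seed = 1), "1:nTypes")
  expect_error(poolingExperiment(40, 50, integer(0), seed = 1), "non-empty")
  # alternative convention: observed from a simulated draw of the subset
  resD <- poolingExperiment(40, 50, 1:20, nReps = 5e3, seed = 2,
                            observed = "draw")
  expect_lte(observedTypes(resD), 20L)
})

test_that("dominance is the modal-type fraction and relabeling-invariant", {
  expect_equal(dominance(PresynapticCluster(rep("x", 7), rep("contra", 7))), 1)
  five <- PresynapticCluster(rep(letters[1:5], each = 10), rep("ipsi", 50))
  expect_equal(dominance(five), 0.2)
  ab <- PresynapticCluster(c("A", "A", "A", "B"), rep("contra", 4))
  expect_equal(dominance(ab), 0.75)
  relab <- PresynapticCluster(c("q", "q", "q", "z"), rep("contra", 4))
  expect_equal(dominance(relab), dominance(ab))
  byEye <- dominance(PresynapticCluster(c("a", "a", "b"),
                                        c("contra", "contra", "ipsi")),
                     byEye = TRUE)
  expect_equal(unname(byEye["contra"]), 1)
  expect_error(dominance(PresynapticCluster(character(0), character(0))),
               "empty")
})

test_that("preference indices hit their endpoints and midpoints", {
  sus <- PresynapticCluster(rep("12", 5), rep("contra", 5))
  expect_equal(preferenceIndices(sus)$st_index, 1)
  mixed <- PresynapticCluster(c("12", "89", "37", "7"), rep("contra", 4))
  expect_equal(preferenceIndices(mixed)$st_index, 0)
  oo <- PresynapticCluster(c("89", "12", "37", "189"), rep("contra", 4))
  expect_equal(preferenceIndices(oo)$onoff_index, (1 + 0 + 0.5 + 0.5) / 4)
  # swapping sustained and transient tags negates the ST index
  tags <- rgcTagTable()
  tagsSwap <- tags
  tagsSwap$kinetics <- ifelse(tags$kinetics == "sustained",
                              "transient", "sustained")
  cl <- PresynapticCluster(c("12", "12", "37"), rep("contra", 3))
  expect_equal(preferenceIndices(cl, tagsSwap)$st_index,
               -preferenceIndices(cl, tags)$st_index)
  # DS ratio with and without JAM-B
  ds <- PresynapticCluster(c("37", "7", "12_asym", "4"), rep("contra", 4))
  pi <- preferenceIndices(ds)
  expect_equal(pi$ds_ratio, 0.5)
  expect_equal(pi$ds_ratio_with_jamb, 0.75)
  expect_error(preferenceIndices(
    PresynapticCluster("unknown_type", "contra")), "unknown")
})

test_that("binocular randomness test is calibrated and handles edge cases", {
  # degenerate null: deterministic eye assignment
  expect_equal(binocularRandomnessTest(c(10, 5), c(0, 0), pContra = 1,
                                       seed = 1)$p_value, 1)
  # exhaustive case: one cell, 2 cells both contra under p = 0.5:
  # null statistic 2 w.p. 1/2, 0 w.p. 1/2 -> p = 0.5
  r <- binocularRandomnessTest(2, 0, pContra = 0.5, nReps = 4000, seed = 7)
  expect_equal(r$statistic, 2)
  expect_equal(r$p_value, 0.5, tolerance = 0.03)
  # type-I error at alpha = 0.05 under the binomial null itself
  tot <- c(80, 120, 60, 100, 90)
  contra <- withr::with_seed(21, {
    matrix(rbinom(500 * length(tot), tot, 0.87), nrow = length(tot))
  })
  rejections <- mean(vapply(seq_len(500), function(i) {
    binocularRandomnessTest(contra[, i], tot - contra[, i], pContra = 0.87,
                            nReps = 399, seed = 1000 + i)$p_value < 0.05
  }, logical(1)))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
  expect_error(binocularRandomnessTest(integer(0), integer(0), seed = 1),
               "empty")
})

test_that("chance boundary follows the z < -2 convention", {
  null <- occupancyNull(40, 50, nReps = 1e4, seed = 5)
  k <- chanceTypeBoundary(null)
  expect_gte((k - expectedTypes(null)) / sdTypes(null), -2)
  expect_lt((k - 1 - expectedTypes(null)) / sdTypes(null), -2)
})
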