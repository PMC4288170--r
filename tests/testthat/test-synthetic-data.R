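test_that("generation is deterministic per seed and exact in the no-noise limit", {
  g1 <- generateExperiment(refSpec, referenceRates(), seed = 7)
  g2 <- generateExperiment(refSpec, referenceRates(), seed = 7)
  expect_identical(g1$datasets[["induction-pre"]]@observations,
                   g2$datasets[["induction-pre"]]@observations)
  g3 <- generateExperiment(refSpec, referenceRates(), seed = 8)
  expect_false(identical(g1$datasets[["induction-pre"]]@observations,
                         g3$datasets[["induction-pre"]]@observations))

  ## cv -> 0, no outliers: replicate means equal the noiseless simulation
  g0 <- generateExperiment(refSpec, referenceRates(),
                           noise = noiseModel(cv = 0, replicates = 3,
                                              outlierRate = 0),
                           seed = 7)
  tt <- seq(0, 225, 15)
  ob <- observables(simulate(refSpec, g0$rates, protocol(tEnd = 225), tt))
  m <- replicateSummary(g0$datasets[["induction-mature"]])$mean
  expect_equal(m, ob$mature, tolerance = 1e-12)
})

test_that("calibration hits the measured baselines and induction fold", {
  g <- generateExperiment(refSpec, referenceRates(),
                          noise = noiseModel(cv = 0, replicates = 2,
                                             outlierRate = 0),
                          seed = 1)
  sPre <- replicateSummary(g$datasets[["induction-pre"]])
  sMat <- replicateSummary(g$datasets[["induction-mature"]])
  expect_equal(sPre$mean[1], 1.1, tolerance = 1e-9)
  expect_equal(sMat$mean[1], 18, tolerance = 1e-9)
  ## baseline ratio ~ 16 (18 / 1.1), the measured mature/pre abundance gap
  expect_equal(sMat$mean[1] / sPre$mean[1], 16.4, tolerance = 0.01)
  ## pre-mRNA reaches a 2-3 fold induction within 225 min
  foldPre <- max(sPre$mean) / sPre$mean[1]
  expect_gt(foldPre, 2)
  expect_lt(foldPre, 3)
  ## mature mRNA rises substantially but lags
  foldMat <- sMat$mean[length(sMat$mean)] / sMat$mean[1]
  expect_gt(foldMat, 1.5)
  expect_lt(foldMat, foldPre + 0.5)
})

test_that("the MAD filter removes gross outliers and is idempotent", {
  expect_equal(madOutlierFilter(c(10, 11, 9, 50)), c(10, 11, 9))
  expect_warning(out <- madOutlierFilter(c(5, 5, 5, 5)), "MAD is zero")
  expect_equal(out, c(5, 5, 5, 5))
  x <- c(10, 11, 9, 50, 10.5, 9.5, 2)
  once <- madOutlierFilter(x)
  expect_equal(madOutlierFilter(once), once)
  expect_error(madOutlierFilter(c(1, 2)))
})

test_that("fold induction follows the 2^-ddCt rule", {
  expect_equal(foldFromCt(20, 15, 20, 15), 1)
  expect_equal(foldFromCt(19, 15, 20, 15), 2)     # one cycle earlier
  expect_equal(foldFromCt(20 - 1.585, 15, 20, 15), 3, tolerance = 1e-3)
})

test_that("standard-curve conversion inverts the forward Ct model", {
  expect_equal(copiesFromStandardCurve(37, -3.32, 37, efficiency = 0.5), 2)
  ## one Ct increase with slope -3.32 halves the copy number
  c0 <- copiesFromStandardCurve(30, -3.32, 37)
  c1 <- copiesFromStandardCurve(31, -3.32, 37)
  expect_equal(c1 / c0, 0.5, tolerance = 0.001)
  ## round trip through the forward model
  for (copies in c(0.3, 1.1, 18, 1e4)) {
    ct <- ctFromCopies(copies, -3.4, 36, efficiency = 0.8)
    expect_equal(copiesFromStandardCurve(ct, -3.4, 36, efficiency = 0.8),
                 copies, tolerance = 1e-9)
  }
  expect_error(copiesFromStandardCurve(30, 3.32, 37))
  expect_error(copiesFromStandardCurve(30, -3.32, 37, efficiency = 0))
})

test_that("the empirical replicate CV converges to the configured one", {
  g <- generateExperiment(refSpec, referenceRates(),
                          noise = noiseModel(cv = 0.2, replicates = 250,
                                             outlierRate = 0),
                          seed = 9)
  obs <- g$datasets[["induction-mature"]]@observations
  cvs <- tapply(obs$value, obs$time_min, function(v) sd(v) / mean(v))
  expect_lt(abs(mean(cvs) - 0.2) / 0.2, 0.1)
})

test_that("outlier injection is caught by the replicate summary's MAD step", {
  g <- generateExperiment(refSpec, referenceRates(),
                          noise = noiseModel(cv = 0.05, replicates = 6,
                                             outlierRate = 0.2),
                          seed = 10)
  s <- replicateSummary(g$datasets[["induction-mature"]])
  raw <- tapply(g$datasets[["induction-mature"]]@observations$value,
                g$datasets[["induction-mature"]]@observations$time_min, mean)
  ## filtered means are systematically below the outlier-inflated raw means
  expect_lt(median(s$mean / as.vector(raw)), 1)
})
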