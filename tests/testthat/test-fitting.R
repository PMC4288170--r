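test_that("the weighted SSR is zero through the data and linear in weights", {
  nl <- makeNoiselessData()
  prob <- fitProblem(refSpec, refCalibrated, nl, free = character())
  expect_lt(weightedSSR(refTruth, prob), 1e-14)

  ## perturbing one rate away from truth raises the objective
  off <- refTruth
  off["k_spl"] <- off["k_spl"] * 1.1
  expect_gt(weightedSSR(off, prob), weightedSSR(refTruth, prob))

  ## explicit weights: doubling them doubles the objective
  ds <- makeStudyData(seed = 11, decay = FALSE)
  d1 <- ds[["induction-pre"]]
  tu <- unique(d1@observations$time_min)
  w <- rep(2, length(tu))
  mk <- function(w) timeCourseDataset("w", "pre", d1@observations,
                                      d1@protocol, weights = w)
  p1 <- fitProblem(refSpec, refCalibrated, list(mk(w)), free = character())
  p2 <- fitProblem(refSpec, refCalibrated, list(mk(2 * w)), free = character())
  expect_equal(weightedSSR(refTruth, p2), 2 * weightedSSR(refTruth, p1),
               tolerance = 1e-12)
})

test_that("the objective is invariant under dataset permutation", {
  ds <- makeStudyData(seed = 12)
  p1 <- fitProblem(refSpec, refCalibrated, ds, free = character())
  p2 <- fitProblem(refSpec, refCalibrated, rev(ds), free = character())
  expect_equal(weightedSSR(refTruth, p1), weightedSSR(refTruth, p2))
})

test_that("CRS solves a standard benchmark and keeps a monotone trace", {
  sphere <- function(x) sum(x^2)
  res <- crsMinimize(sphere, rep(-5, 8), rep(5, 8), maxEvals = 20000,
                     seed = 1)
  expect_lte(res$value, 1e-6)
  expect_false(is.unsorted(rev(res$trace$best)))
  ## deterministic under a fixed seed
  res2 <- crsMinimize(sphere, rep(-5, 8), rep(5, 8), maxEvals = 20000,
                      seed = 1)
  expect_identical(res$par, res2$par)
  ## a different seed explores differently
  res3 <- crsMinimize(sphere, rep(-5, 8), rep(5, 8), maxEvals = 1000,
                      seed = 2)
  expect_false(identical(res3$par, crsMinimize(sphere, rep(-5, 8), rep(5, 8),
                                               maxEvals = 1000, seed = 1)$par))
})

test_that("CRS handles a constant objective and rejects bad input", {
  res <- crsMinimize(function(x) 42, c(-1, -1), c(1, 1),
                     maxEvals = 200, seed = 1)
  expect_equal(res$value, 42)
  expect_error(crsMinimize(function(x) 0, c(1, 1), c(0, 0), maxEvals = 100))
  expect_error(crsMinimize(function(x) 0, -1, 1, maxEvals = 2,
                           populationSize = 30))
})

test_that("a fully frozen fit returns the frozen point and its objective", {
  ds <- makeStudyData(seed = 13, decay = FALSE)
  prob <- fitProblem(refSpec, refCalibrated, ds, free = character())
  fit <- fitModel(prob)
  expect_equal(fittedParameters(fit), refTruth)
  expect_equal(objectiveValue(fit), weightedSSR(refTruth, prob),
               tolerance = 1e-12)
  ## FitResult invariant: objective equals the recomputed weighted SSR
  expect_equal(objectiveValue(fit),
               sum(unlist(fit@residuals)^2), tolerance = 1e-10)
})

test_that("a single-parameter fit matches an independent grid search", {
  nl <- makeNoiselessData()
  prob <- fitProblem(refSpec, refCalibrated, nl, free = "k_spl")
  ref <- refTruth
  ref["k_spl"] <- ref["k_spl"] * 3     # start away from truth
  r <- refitSingle(prob, ref, "k_spl", nGrid = 41)
  ## independent oracle: dense grid on the same box
  grid <- 10^seq(log10(1e-4), log10(1e2), length.out = 3000)
  gv <- vapply(grid, function(v)
    weightedSSR(replace(ref, "k_spl", v), prob), 0)
  expect_equal(r$value, grid[which.min(gv)], tolerance = 0.01)
  expect_equal(r$value, unname(refTruth["k_spl"]), tolerance = 0.01)
})

test_that("chain rates are recovered from noiseless data within 5%", {
  ds <- makeStudyData(seed = 17, cv = 1e-9, replicates = 2,
                      outlierRate = 0)
  cn <- c("k_elo", "k_spl", "k_mat", "k_deg")
  prob <- fitProblem(refSpec, refCalibrated, ds, free = cn)
  fit <- fitModel(prob, crsSettings(maxEvals = 1500, seed = 4, polish = TRUE))
  relErr <- abs(fittedParameters(fit)[cn] / refTruth[cn] - 1)
  expect_lt(max(relErr), 0.05)
  expect_false(is.unsorted(rev(optimizerTrace(fit)$best)))
})

test_that("held-out mature-decay data are predicted from an induction+decay-pre fit", {
  ds <- makeStudyData(seed = 19)
  fitSet <- ds[c("induction-pre", "induction-mature", "decay-pre")]
  valSet <- ds["decay-mature"]
  prob <- fitProblem(refSpec, refCalibrated, fitSet,
                     free = c("k_elo", "k_spl", "k_mat", "k_deg", "f_basal"),
                     validation = valSet)
  fit <- fitModel(prob, crsSettings(maxEvals = 1500, seed = 5, polish = TRUE))
  vres <- unlist(fit@validationResiduals)
  expect_gt(length(vres), 0)
  ## the held-out decay prediction tracks the measurements within the
  ## replicate-scatter scale (CV 0.2 data)
  d <- ds[["decay-mature"]]
  sm <- replicateSummary(d)
  pred <- observables(simulate(refSpec, updateRates(refCalibrated, fit@par),
                               d@protocol, sm$time_min))$mature
  expect_lt(median(abs(pred - sm$mean) / sm$mean), 0.3)
  ## and reproduces the delayed, slow terminal decline
  expect_gt(pred[1] / pred[length(pred)], 1.5)
})
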