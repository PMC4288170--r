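test_that("sensitivities vanish for parameters without influence and scale with weights", {
  ## degradation is strictly downstream of the splicing pool, so a pre-mRNA
  ## series carries no information on k_deg
  ds <- makeStudyData(seed = 31, decay = FALSE)
  probPre <- fitProblem(refSpec, refCalibrated, ds["induction-pre"],
                        free = c("k_spl", "k_deg"))
  S <- sensitivities(refTruth, probPre)
  expect_lt(max(abs(S[, "k_deg"])), 1e-8)
  expect_gt(max(abs(S[, "k_spl"])), 1)

  ## doubling explicit weights scales columns by sqrt(2)
  d1 <- ds[["induction-pre"]]
  tu <- unique(d1@observations$time_min)
  mk <- function(w) timeCourseDataset("w", "pre", d1@observations,
                                      d1@protocol, weights = w)
  pA <- fitProblem(refSpec, refCalibrated, list(mk(rep(1, length(tu)))),
                   free = "k_spl")
  pB <- fitProblem(refSpec, refCalibrated, list(mk(rep(2, length(tu)))),
                   free = "k_spl")
  expect_equal(sensitivities(refTruth, pB),
               sqrt(2) * sensitivities(refTruth, pA), tolerance = 1e-9)
})

test_that("steady-state mature mRNA has log-log sensitivity -1 to k_deg", {
  h <- 1e-5
  m <- function(kdeg) {
    r <- updateRates(refCalibrated, c(k_deg = kdeg))
    observablesFromState(steadyState(refSpec, r, "induced"), refSpec)[["mature"]]
  }
  k0 <- rates(refCalibrated)[["k_deg"]]
  dlogm <- (log(m(k0 * exp(h))) - log(m(k0 * exp(-h)))) / (2 * h)
  expect_equal(dlogm, -1, tolerance = 1e-6)
})

test_that("confidence intervals follow the Fisher-information closed forms", {
  ## diagonal FIM: no correlation, dependent == independent
  fim <- diag(c(4, 9))
  colnames(fim) <- rownames(fim) <- c("a", "b")
  ci <- confidenceIntervals(fim, ssr = 10, nPoints = 20)
  expect_equal(ci$dependent, ci$independent, tolerance = 1e-12)

  ## 2x2 with correlation 0.99: ratio = 1/sqrt(1 - rho^2)
  rho <- 0.99
  fim2 <- matrix(c(1, rho, rho, 1), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  ci2 <- confidenceIntervals(fim2, ssr = 10, nPoints = 20)
  expect_equal(ci2$ratio, rep(1 / sqrt(1 - rho^2), 2), tolerance = 1e-9)
  expect_equal(ci2$ratio[1], 7.09, tolerance = 0.01)

  ## singular FIM: independent interval unbounded
  fim3 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ci3 <- confidenceIntervals(fim3, ssr = 10, nPoints = 20)
  expect_true(all(!is.finite(ci3$independent) | ci3$independent > 1e6))
})

test_that("the synthetic fit reproduces the co-dependence structure", {
  ds <- makeStudyData(seed = 33)
  prob <- fitProblem(refSpec, refCalibrated, ds)
  rep <- identifiabilityReport(refTruth, prob)
  expect_true(isSymmetric(rep$fim, tol = 1e-8))
  expect_gt(min(eigen(rep$fim, only.values = TRUE)$values), -1e-6)
  ci <- rep$intervals
  expect_true(all(ci$independent >= ci$dependent - 1e-9))
  ratios <- setNames(ci$ratio, ci$parameter)
  ## chain rates well constrained, promoter/initiation rates co-dependent
  expect_lt(max(ratios[c("k_elo", "k_spl", "k_mat", "k_deg")]), 5)
  expect_gt(min(ratios[c("k_rev", "k_dea", "k_ini")]), 10)
  ## correlation matrix is a valid correlation matrix
  expect_equal(diag(rep$correlation), rep(1, ncol(rep$fim)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lte(max(abs(rep$correlation)), 1 + 1e-9)
})

test_that("objective profiles are minimal at the optimum and expose co-dependence", {
  nl <- makeNoiselessData()
  prob <- fitProblem(refSpec, refCalibrated, nl)
  prof <- sensitivityProfile(refTruth, prob, grid = c(0.5, 1, 2),
                             parameters = c("k_ini", "k_deg"),
                             pairs = list(c("k_ini", "k_dea")))
  for (p in c("k_ini", "k_deg")) {
    sub <- prof[prof$parameter == p, ]
    expect_equal(sub$objective[sub$factor == 1], 0, tolerance = 1e-12)
    expect_true(all(sub$objective[sub$factor != 1] > 0))
  }
  ## joint (k_ini, k_dea) scaling preserves the production flux far better
  ini2 <- prof$objective[prof$parameter == "k_ini" & prof$factor == 2]
  pair2 <- prof$objective[prof$parameter == "k_ini:k_dea" & prof$factor == 2]
  expect_lt(pair2, ini2 / 10)

  ## on noisy data the k_deg profile rises by more than 5% at a 2-fold change
  dsn <- makeStudyData(seed = 35, decay = FALSE)
  probn <- fitProblem(refSpec, refCalibrated, dsn)
  profn <- sensitivityProfile(refTruth, probn, grid = c(0.5, 1, 2),
                              parameters = "k_deg")
  o1 <- profn$objective[profn$factor == 1]
  expect_gt(profn$objective[profn$factor == 2], 1.05 * o1)
  expect_gt(profn$objective[profn$factor == 0.5], 1.05 * o1)
})
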