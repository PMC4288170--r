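test_that("the vector field matches the hand-written equations", {
  ## n = 1, all rates 1: d(elo1)/dt at the all-ones state is sum(dea) - elo1 = 0
  spec1 <- modelSpec("n1")
  r1 <- rateConstants(1, 1, 1, 1, 1, 1, 1, 1, f_basal = 1)
  rhs <- rateMatrix(spec1, r1, "induced")
  x <- setNames(rep(1, nStates(spec1)), stateNames(spec1))
  dx <- as.vector(rhs$A %*% x + rhs$b)
  names(dx) <- stateNames(spec1)
  expect_equal(unname(dx["elo1"]), 0)

  ## the field is linear in the rates: scaling all rates scales the field
  r2 <- rateConstants(2, 2, 2, 2, 2, 2, 2, 2, f_basal = 1)
  rhs2 <- rateMatrix(spec1, r2, "induced")
  expect_equal(rhs2$A, 2 * rhs$A)
  ## zero state gives a zero field (null dynamics limit)
  expect_equal(as.vector(rhs$A %*% numeric(7)), numeric(7))

  ## regimes: basal damps the first two activation transitions, blocked
  ## zeroes initiation and nothing else
  spec <- modelSpec("n5")
  rr <- referenceRates(f_basal = 0.3)
  Ab <- rateMatrix(spec, rr, "basal")$A
  Ai <- rateMatrix(spec, rr, "induced")$A
  expect_equal(Ab["act1", "act1"], -0.3 * 0.106)
  expect_equal(Ab["act3", "act3"], Ai["act3", "act3"])
  Ablk <- rateMatrix(spec, rr, "blocked")$A
  expect_equal(Ablk["elo1", "dea1"], 0)
  expect_equal(Ablk["mat1", "pro5"], Ai["mat1", "pro5"])
  expect_error(rateMatrix(spec, rr, "bogus"))
})

test_that("promoter mass is conserved by construction and along trajectories", {
  spec <- modelSpec("n5")
  r <- referenceRates(f_basal = 0.2)
  for (regime in c("basal", "induced", "blocked")) {
    A <- rateMatrix(spec, r, regime)$A
    expect_lt(max(abs(colSums(A[1:15, 1:15]))), 1e-12)
  }
  tr <- simulate(spec, r, protocol(tLigand = 30, tBlock = 180, tEnd = 400),
                 seq(0, 400, by = 10))
  promoterMass <- rowSums(states(tr)[, 1:15])
  expect_lt(max(abs(promoterMass - 1)), 1e-9)
})

test_that("observables are the splicing- and degradation-chain totals", {
  spec <- modelSpec("n5")
  x <- setNames(numeric(nStates(spec)), stateNames(spec))
  expect_equal(observablesFromState(x, spec), c(pre = 0, mature = 0))
  x[paste0("spl", 1:5)] <- c(1, 0, 0, 0, 0)
  x[paste0("mat", 1:5)] <- 3
  expect_equal(observablesFromState(x, spec), c(pre = 1, mature = 15))
})

test_that("steady state satisfies the flux identities", {
  spec <- modelSpec("n5")
  r <- referenceRates(f_basal = 0.2)
  x <- steadyState(spec, r, "induced")
  k <- rates(r)
  J <- k[["k_ini"]] * sum(x[paste0("dea", 1:5)])
  for (pool in list(c("elo", "k_elo"), c("spl", "k_spl"),
                    c("pro", "k_mat"), c("mat", "k_deg"))) {
    expect_equal(sum(x[paste0(pool[1], 1:5)]), J * 5 / k[[pool[2]]],
                 tolerance = 1e-12)
  }
  ## mature/pre ratio at steady state is k_spl/k_deg
  ob <- observablesFromState(x, spec)
  expect_equal(unname(ob["mature"] / ob["pre"]), k[["k_spl"]] / k[["k_deg"]],
               tolerance = 1e-12)
  ## symmetric promoter rates split occupancy equally across phases
  rs <- rateConstants(0.5, 0.5, 0.5, 1, 1, 1, 1, 1, f_basal = 1)
  xs <- steadyState(spec, rs, "induced")
  expect_equal(unname(sum(xs[paste0("act", 1:5)])), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(sum(xs[paste0("rev", 1:5)])), 1 / 3, tolerance = 1e-12)
})

test_that("steady state agrees with long-time integration", {
  spec <- modelSpec("n5")
  r <- referenceRates(f_basal = 0.2)
  x <- steadyState(spec, r, "induced")
  tChar <- max(5 / rates(r))          # longest characteristic time
  tEnd <- 10 * tChar
  ## start far from the fixed point but with the conserved gene dosage of 1
  init <- setNames(numeric(length(x)), names(x))
  init["act1"] <- 1
  tr <- simulate(spec, r, protocol(tLigand = 0, tEnd = tEnd), tEnd,
                 init = init)
  expect_lt(max(abs(states(tr)[1, ] - x) / (abs(x) + 1e-12)), 1e-6)
})

test_that("a system started at its own fixed point stays there", {
  spec <- modelSpec("n5")
  r <- referenceRates(f_basal = 1)    # basal == induced
  x <- steadyState(spec, r, "basal")
  tr <- simulate(spec, r, protocol(tLigand = 0, tEnd = 300), seq(0, 300, 25))
  expect_lt(max(abs(sweep(states(tr), 2, x)) / (abs(max(x)))), 1e-10)
})

test_that("matrix-exponential and adaptive-ODE routes agree", {
  for (v in c("n1", "n5")) {
    spec <- modelSpec(v)
    r <- referenceRates(f_basal = 0.2)
    prot <- protocol(tLigand = 0, tBlock = 180, tEnd = 300)
    tt <- seq(0, 300, by = 15)
    sExp <- states(simulate(spec, r, prot, tt, method = "expm"))
    sOde <- states(simulate(spec, r, prot, tt, method = "lsoda",
                            rtol = 1e-10, atol = 1e-14))
    ## relative agreement, with a floor far below one molecule per cell so
    ## that states beneath the integrator's absolute tolerance do not
    ## dominate the comparison
    expect_lt(max(abs(sExp - sOde) / (abs(sExp) + 1e-4)), 1e-6)
  }
})

test_that("RNA observables are linear in the initiation rate", {
  spec <- modelSpec("n5")
  r <- referenceRates(f_basal = 0.2)
  r2 <- updateRates(r, c(k_ini = 3 * rates(r)[["k_ini"]]))
  tt <- seq(0, 225, 15)
  tr1 <- simulate(spec, r, protocol(tEnd = 225), tt)
  tr2 <- simulate(spec, r2, protocol(tEnd = 225), tt)
  expect_equal(observables(tr2)$pre, 3 * observables(tr1)$pre,
               tolerance = 1e-10)
  expect_equal(observables(tr2)$mature, 3 * observables(tr1)$mature,
               tolerance = 1e-10)
  ## promoter occupancies are untouched
  expect_equal(states(tr1)[, 1:15], states(tr2)[, 1:15], tolerance = 1e-10)
})

test_that("mature mRNA responds with a delayed rise relative to pre-mRNA", {
  spec <- modelSpec("n5")
  r <- refCalibrated
  tt <- seq(0, 600, by = 1)
  ob <- observables(simulate(spec, r, protocol(tEnd = 600), tt))
  rise10 <- function(y) tt[min(which(y >= y[1] + 0.1 * (max(y) - y[1])))]
  gap <- rise10(ob$mature) - rise10(ob$pre)
  k <- rates(r)
  expect_gte(gap, 5 / k[["k_elo"]] + 5 / k[["k_spl"]])
  expect_gt(gap, 30)   # tens of minutes, as observed
})

test_that("transcription block collapses pre-mRNA on a ~10-min scale", {
  spec <- modelSpec("n5")
  r <- refCalibrated
  prot <- protocol(tLigand = 0, tBlock = 180, tEnd = 300)
  tt <- seq(180, 300, by = 1)
  ob <- observables(simulate(spec, r, prot, tt))
  tHalfPre <- tt[min(which(ob$pre <= ob$pre[1] / 2))] - 180
  expect_gt(tHalfPre, 2)    # short delay from polymerases already elongating
  expect_lt(tHalfPre, 20)   # decay on the 10-min scale
  ## mature decay is far slower and delayed
  expect_gt(ob$mature[31] / ob$mature[1], 0.8)
})

test_that("characteristic times reproduce the fitted-model table", {
  expect_equal(characteristicTime(0.106, 5), 47.1, tolerance = 0.1 / 47.1)
  expect_equal(characteristicTime(2.272, 5), 2.2, tolerance = 0.1 / 2.2)
  expect_equal(characteristicTime(0.512, 5), 9.8, tolerance = 0.1 / 9.8)
  expect_equal(characteristicTime(0.161, 5), 31.1, tolerance = 0.1 / 31.1)
  expect_equal(characteristicTime(1, 1), 1)
  expect_error(characteristicTime(0, 5))
  expect_error(characteristicTime(1, 0))
})

test_that("degradation-chain median lifetime behaves like a gamma median", {
  spec <- modelSpec("n5")
  r <- referenceRates()
  tHalf <- halvingTimeOfDegradation(r, spec)
  expect_equal(tHalf / 60, 3, tolerance = 0.12)          # approximately 3 h
  ## single stage: exponential median ln2 / k
  r1 <- updateRates(r, c(k_deg = 0.01))
  expect_equal(halvingTimeOfDegradation(r1, modelSpec("n0")),
               log(2) / 0.01, tolerance = 1e-10)
  ## median < mean for every chain length
  for (v in c("n1", "n3", "n5", "n10", "n20")) {
    sp <- modelSpec(v)
    expect_lt(halvingTimeOfDegradation(r, sp), nSub(sp) / rates(r)[["k_deg"]])
  }
})

test_that("the closed-form chain response matches the ODE impulse response", {
  spec <- modelSpec("n5")
  r <- referenceRates()
  cr <- chainResponse(r, spec, tMax = 300, dt = 0.05)
  k <- rates(r)
  expect_equal(cr$mean, 5 / k[["k_elo"]] + 5 / k[["k_spl"]] + 5 / k[["k_mat"]])
  expect_equal(cr$mean, 43.0, tolerance = 0.005)
  expect_equal(sum(cr$density) * 0.05, 1, tolerance = 1e-3)
  ## empirical mean of the density agrees with the closed form
  expect_equal(sum(cr$time * cr$density) * 0.05, cr$mean, tolerance = 1e-3)

  ## single stages with unit rates give an Erlang(3, 1) density
  r1 <- rateConstants(1, 1, 1, 1, 1, 1, 1, 1)
  cr1 <- chainResponse(r1, modelSpec("n1"), tMax = 30, dt = 0.002)
  expect_equal(cr1$mean, 3)
  expect_lt(max(abs(cr1$density - dgamma(cr1$time, shape = 3, rate = 1))),
            5e-3)

  ## ODE route: unit mass in elo1, arrival flux k_mat * pro_n
  A <- rateMatrix(spec, r, "induced")$A
  x0 <- setNames(numeric(35), stateNames(spec))
  x0["elo1"] <- 1
  sol <- deSolve::lsoda(x0, cr$time,
                        function(t, y, p) list(as.vector(A %*% y)),
                        rtol = 1e-10, atol = 1e-14)
  densOde <- k[["k_mat"]] * sol[, "pro5"]
  expect_lt(sum(abs(densOde - cr$density)) * 0.05, 1e-4)
})

test_that("reduced variants have the stated state counts and respond to ligand", {
  expect_equal(nStates(modelSpec("n0")), 2L)
  expect_equal(nStates(modelSpec("n2")), 5L)
  expect_equal(nStates(modelSpec("n5")), 35L)
  expect_equal(nStates(modelSpec("n20")), 140L)
  for (v in c("n0", "n2")) {
    spec <- modelSpec(v)
    r <- referenceRates(f_basal = 0.4)
    tt <- seq(0, 400, 10)
    ob <- observables(simulate(spec, r, protocol(tEnd = 400), tt))
    expect_true(all(is.finite(ob$pre)) && all(ob$pre >= 0))
    ## induction approaches the 1/f_basal steady-state fold
    expect_equal(ob$pre[length(tt)] / ob$pre[1], 1 / 0.4, tolerance = 0.05)
    ## n2 responds with a promoter-activation delay, n0 immediately
    if (v == "n2") {
      expect_lt(ob$pre[2] / ob$pre[1],
                observables(simulate(modelSpec("n0"), r,
                                     protocol(tEnd = 400), tt))$pre[2] /
                  ob$pre[1] + 1e-9)
    }
  }
})

test_that("simulate validates its inputs", {
  spec <- modelSpec("n5")
  r <- referenceRates()
  expect_error(simulate(spec, r, protocol(tEnd = 100), c(10, 5)),
               "ordered")
  expect_error(simulate(spec, r, protocol(tEnd = 100), c(0, 150)),
               "within")
  expect_error(protocol(tLigand = 200, tEnd = 100))
  expect_error(protocol(tLigand = 0, tBlock = 500, tEnd = 100))
})
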