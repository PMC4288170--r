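#' State names of a model variant
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @return character vector in the canonical state order.
#' @export
stateNames <- function(spec) {
  switch(spec@variant,
    n0 = c("pre", "mat"),
    n2 = c("g1", "g2", "g3", "pre", "mat"),
    {
      n <- spec@nSub
      as.vector(vapply(c("act", "dea", "rev", "elo", "spl", "pro", "mat"),
                       function(p) paste0(p, seq_len(n)), character(n)))
    })
}

.checkRegime <- function(regime) {
  match.arg(regime, c("basal", "induced", "blocked"))
}

#' Linear vector field of a model variant under one regime
#'
#' Builds the mass-action right-hand side \code{dx/dt = A x + b} of the
#' variant: the three-phase promoter cycle (activation chain closed by the
#' reversion inflow), the initiation flux \code{k_ini * sum(x_dea)} into the
#' first elongation state, the sequential first-order
#' elongation/splicing/processing/degradation chains, and terminal loss from
#' the last degradation state.  Regimes: \code{"basal"} scales the
#' ligand-sensitive activation transitions by \code{f_basal};
#' \code{"induced"} runs all transitions at full rate; \code{"blocked"}
#' sets the initiation rate to zero (transcription block), all else
#' unchanged.
#'
#' For the reduced variants the ligand-sensitive quantity is the initiation
#' flux itself: \code{"n0"} produces pre-mRNA at \code{f_basal * k_ini}
#' basally and \code{k_ini} when induced; \code{"n2"} keeps its two
#' activation steps frozen basally (promoter inactive) while transcribing at
#' \code{f_basal * k_ini}, and on induction walks the promoter to the active
#' state through two \code{k_act} steps.
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param rates a \code{\link{RateConstants}}.
#' @param regime \code{"basal"}, \code{"induced"} or \code{"blocked"}.
#' @return list with \code{A} (state matrix), \code{b} (constant inflow,
#'   non-zero only for \code{"n0"}) and \code{stateNames}.
#' @export
rateMatrix <- function(spec, rates, regime = "induced") {
  regime <- .checkRegime(regime)
  k <- rates@rates
  f <- rates@fBasal
  sn <- stateNames(spec)
  m <- length(sn)
  A <- matrix(0, m, m, dimnames = list(sn, sn))
  b <- setNames(numeric(m), sn)
  kini <- if (regime == "blocked") 0 else k[["k_ini"]]

  if (spec@variant == "n0") {
    src <- if (regime == "basal") f * kini else kini
    b["pre"] <- src
    A["pre", "pre"] <- -k[["k_spl"]]
    A["mat", "pre"] <- k[["k_spl"]]
    A["mat", "mat"] <- -k[["k_deg"]]
    return(list(A = A, b = b, stateNames = sn))
  }

  if (spec@variant == "n2") {
    kact <- if (regime == "basal") 0 else k[["k_act"]]
    A["g1", "g1"] <- -kact
    A["g2", "g1"] <- kact
    A["g2", "g2"] <- -kact
    A["g3", "g2"] <- kact
    ## active state transcribes at k_ini; inactive states at f_basal*k_ini
    A["pre", "g3"] <- kini
    A["pre", "g1"] <- f * kini
    A["pre", "g2"] <- f * kini
    A["pre", "pre"] <- -k[["k_spl"]]
    A["mat", "pre"] <- k[["k_spl"]]
    A["mat", "mat"] <- -k[["k_deg"]]
    return(list(A = A, b = b, stateNames = sn))
  }

  n <- spec@nSub
  idx <- function(p, i) paste0(p, i)
  ## per-transition activation rates; first `ligandSensitiveSteps` damped basally
  ract <- rep(k[["k_act"]], n)
  if (regime == "basal") {
    nls <- min(spec@ligandSensitiveSteps, n)
    if (nls > 0) ract[seq_len(nls)] <- f * k[["k_act"]]
  }
  chain <- function(prefix, rate_in, from, rate) {
    ## inflow rate_in * from feeds <prefix>1; identical rate down the chain
    A[idx(prefix, 1), from] <<- A[idx(prefix, 1), from] + rate_in
    for (i in seq_len(n)) {
      A[idx(prefix, i), idx(prefix, i)] <<-
        A[idx(prefix, i), idx(prefix, i)] - rate[min(i, length(rate))]
      if (i < n)
        A[idx(prefix, i + 1), idx(prefix, i)] <<- rate[min(i, length(rate))]
    }
  }
  ## promoter cycle: rev_n -> act_1 -> ... -> act_n -> dea_1 -> ... -> rev_1 ...
  A[idx("act", 1), idx("rev", n)] <- k[["k_rev"]]
  for (i in seq_len(n)) {
    A[idx("act", i), idx("act", i)] <- A[idx("act", i), idx("act", i)] - ract[i]
    if (i < n) A[idx("act", i + 1), idx("act", i)] <- ract[i]
  }
  chain("dea", ract[n], idx("act", n), rep(k[["k_dea"]], n))
  chain("rev", k[["k_dea"]], idx("dea", n), rep(k[["k_rev"]], n))
  ## initiation: flux k_ini * sum(dea) into elo_1
  for (i in seq_len(n)) A[idx("elo", 1), idx("dea", i)] <- kini
  for (i in seq_len(n)) {
    A[idx("elo", i), idx("elo", i)] <- A[idx("elo", i), idx("elo", i)] - k[["k_elo"]]
    if (i < n) A[idx("elo", i + 1), idx("elo", i)] <- k[["k_elo"]]
  }
  chain("spl", k[["k_elo"]], idx("elo", n), rep(k[["k_spl"]], n))
  chain("pro", k[["k_spl"]], idx("spl", n), rep(k[["k_mat"]], n))
  chain("mat", k[["k_mat"]], idx("pro", n), rep(k[["k_deg"]], n))
  list(A = A, b = b, stateNames = sn)
}

#' Observables of a state vector
#'
#' Pre-mRNA (intron-1-containing, observable once the polymerase has passed
#' the exon-boundary amplicon) is the total occupancy of the splicing chain;
#' mature polyadenylated mRNA is the total occupancy of the degradation
#' chain.  The elongation chain represents polymerases that escaped the TSS
#' but have not yet reached the amplicon; the processing chain is unobserved
#' downstream elongation/3' processing.
#'
#' @param state named state vector (or matrix with named columns).
#' @param spec a \code{\link{ModelSpec}}.
#' @return named numeric \code{c(pre, mature)} in copies/cell, or a two-column
#'   matrix for matrix input.
#' @export
observablesFromState <- function(state, spec) {
  sn <- stateNames(spec)
  pre_ix <- if (spec@variant %in% c("n0", "n2")) "pre" else grep("^spl", sn, value = TRUE)
  mat_ix <- if (spec@variant %in% c("n0", "n2")) "mat" else grep("^mat", sn, value = TRUE)
  if (is.matrix(state)) {
    cbind(pre = rowSums(state[, pre_ix, drop = FALSE]),
          mature = rowSums(state[, mat_ix, drop = FALSE]))
  } else {
    c(pre = sum(state[pre_ix]), mature = sum(state[mat_ix]))
  }
}

#' Steady state of a variant under one regime
#'
#' For the full variants the promoter is a unidirectional cycle, so each
#' stage's occupancy is proportional to its dwell time (1/outflow rate),
#' normalized to total gene dosage 1; the RNA chains then carry the
#' initiation flux \code{J = k_ini * sum(x_dea)}, every chain state holding
#' \code{J / k_process} (hence every pool equals \code{J * nSub / k}).
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param rates a \code{\link{RateConstants}}.
#' @param regime \code{"basal"}, \code{"induced"} or \code{"blocked"}.
#' @return named state vector at the fixed point.
#' @export
steadyState <- function(spec, rates, regime = "induced") {
  regime <- .checkRegime(regime)
  k <- rates@rates
  f <- rates@fBasal
  sn <- stateNames(spec)
  x <- setNames(numeric(length(sn)), sn)
  kini <- if (regime == "blocked") 0 else k[["k_ini"]]

  if (spec@variant == "n0") {
    src <- if (regime == "basal") f * kini else kini
    x["pre"] <- src / k[["k_spl"]]
    x["mat"] <- src / k[["k_deg"]]
    return(x)
  }
  if (spec@variant == "n2") {
    if (regime == "basal") {
      x["g1"] <- 1
      src <- f * kini
    } else {
      x["g3"] <- 1   # two-step activation is absorbing
      src <- kini
    }
    x["pre"] <- src / k[["k_spl"]]
    x["mat"] <- src / k[["k_deg"]]
    return(x)
  }

  n <- spec@nSub
  ract <- rep(k[["k_act"]], n)
  if (regime == "basal") {
    nls <- min(spec@ligandSensitiveSteps, n)
    if (nls > 0) ract[seq_len(nls)] <- f * k[["k_act"]]
  }
  if (any(ract == 0) || any(k <= 0))
    stop("steady state undefined: a promoter rate is zero")
  dwell <- c(1 / ract, rep(1 / k[["k_dea"]], n), rep(1 / k[["k_rev"]], n))
  occ <- dwell / sum(dwell)
  x[seq_len(3 * n)] <- occ
  J <- kini * sum(x[paste0("dea", seq_len(n))])
  x[paste0("elo", seq_len(n))] <- J / k[["k_elo"]]
  x[paste0("spl", seq_len(n))] <- J / k[["k_spl"]]
  x[paste0("pro", seq_len(n))] <- J / k[["k_mat"]]
  x[paste0("mat", seq_len(n))] <- J / k[["k_deg"]]
  x
}

#' Initiation flux at steady state
#'
#' @param spec,rates,regime as in \code{\link{steadyState}}.
#' @return \code{J = k_ini * sum(x_dea)} (copies/cell/min) at the fixed
#'   point of the given regime.
#' @export
initiationFlux <- function(spec, rates, regime = "induced") {
  x <- steadyState(spec, rates, regime)
  k <- rates@rates
  kini <- if (regime == "blocked") 0 else k[["k_ini"]]
  if (spec@variant == "n0")
    return(if (regime == "basal") rates@fBasal * kini else kini)
  if (spec@variant == "n2")
    return(if (regime == "basal") rates@fBasal * kini else kini)
  kini * sum(x[grep("^dea", names(x))])
}

## exact propagation of dx/dt = A x + b over a step dt: augment the constant
## inflow as an extra state, exponentiate once per unique dt
.propagator <- function(A, b, dt) {
  if (any(b != 0)) {
    m <- nrow(A)
    Aug <- rbind(cbind(A, b), 0)
    as.matrix(Matrix::expm(Aug * dt))
  } else {
    as.matrix(Matrix::expm(A * dt))
  }
}

.stepExact <- function(P, x, affine) {
  if (affine) {
    y <- P %*% c(x, 1)
    y[-length(y)]
  } else {
    as.vector(P %*% x)
  }
}

#' Simulate a model trajectory under a protocol
#'
#' Integrates the piecewise-linear system across the regime switches at
#' \code{tLigand} and \code{tBlock} with state continuity, starting from the
#' basal-regime steady state.  The default method propagates each segment
#' exactly with matrix exponentials (the system is linear with
#' piecewise-constant coefficients); \code{method = "lsoda"} uses adaptive
#' stiff-capable ODE integration (deSolve) and exists as an independent
#' numerical route.
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param rates a \code{\link{RateConstants}}.
#' @param protocol a \code{\link{Protocol}}.
#' @param outputTimes ordered times (min) within \code{[0, tEnd]}.
#' @param method \code{"expm"} (exact, default) or \code{"lsoda"}.
#' @param rtol,atol tolerances for \code{method = "lsoda"}.
#' @param init optional initial state (default: basal steady state).
#' @return a \code{\link{Trajectory}}.
#' @examples
#' tr <- simulate(modelSpec("n5"), referenceRates(), protocol(tEnd = 225),
#'                seq(0, 225, by = 15))
#' head(observables(tr))
#' @export
simulate <- function(spec, rates, protocol, outputTimes,
                     method = c("expm", "lsoda"),
                     rtol = 1e-8, atol = 1e-12, init = NULL) {
  method <- match.arg(method)
  if (is.unsorted(outputTimes, strictly = FALSE))
    stop("outputTimes must be ordered")
  if (min(outputTimes) < 0 || max(outputTimes) > protocol@tEnd)
    stop("outputTimes must lie within [0, tEnd]")
  if (is.null(init)) init <- steadyState(spec, rates, "basal")

  breaks <- c(0, protocol@tLigand,
              if (!is.na(protocol@tBlock)) protocol@tBlock, protocol@tEnd)
  breaks <- sort(unique(breaks))
  regimes <- character(length(breaks) - 1)
  for (s in seq_along(regimes)) {
    t0 <- breaks[s]
    regimes[s] <- if (t0 < protocol@tLigand) "basal"
      else if (!is.na(protocol@tBlock) && t0 >= protocol@tBlock) "blocked"
      else "induced"
  }

  sn <- stateNames(spec)
  out <- matrix(NA_real_, length(outputTimes), length(sn),
                dimnames = list(NULL, sn))
  x <- init
  for (s in seq_along(regimes)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    sel <- which(outputTimes >= t0 & (outputTimes < t1 | (s == length(regimes) & outputTimes <= t1)))
    rhs <- rateMatrix(spec, rates, regimes[s])
    affine <- any(rhs$b != 0)
    tpts <- c(t0, outputTimes[sel], t1)
    if (method == "expm") {
      cache <- new.env(parent = emptyenv())
      for (j in seq_along(tpts)[-1]) {
        dt <- tpts[j] - tpts[j - 1]
        if (dt > 0) {
          key <- sprintf("%.12g", dt)
          P <- cache[[key]]
          if (is.null(P)) {
            P <- .propagator(rhs$A, rhs$b, dt)
            cache[[key]] <- P
          }
          x <- .stepExact(P, x, affine)
        }
        if (j > 1 && j <= length(sel) + 1) out[sel[j - 1], ] <- x
      }
    } else {
      dfun <- function(t, y, p) list(as.vector(rhs$A %*% y + rhs$b))
      sol <- deSolve::lsoda(y = x, times = unique(tpts), func = dfun,
                            rtol = rtol, atol = atol)
      soltimes <- sol[, 1]
      for (j in seq_along(sel)) {
        ix <- which.min(abs(soltimes - outputTimes[sel[j]]))
        out[sel[j], ] <- sol[ix, -1]
      }
      x <- sol[nrow(sol), -1]
    }
    if (any(!is.finite(x)))
      stop("non-finite state encountered; rate constants invalid?")
  }
  obs <- observablesFromState(out, spec)
  new("Trajectory", times = as.numeric(outputTimes), states = out,
      observables = data.frame(time_min = as.numeric(outputTimes),
                               pre = obs[, "pre"], mature = obs[, "mature"]),
      spec = spec)
}

#' Mean transit time of an n-step chain
#'
#' The characteristic time of a process modelled as \code{nSteps} identical
#' first-order sub-steps with rate \code{k} is \code{nSteps / k} minutes.
#'
#' @param k rate constant (min^-1), positive.
#' @param nSteps number of elementary steps, >= 1.
#' @return minutes.
#' @examples
#' characteristicTime(0.106, 5)  # promoter activation, ~47 min
#' @export
characteristicTime <- function(k, nSteps) {
  if (any(k <= 0) || any(nSteps < 1)) stop("need k > 0 and nSteps >= 1")
  nSteps / k
}

#' Closed-form post-initiation impulse response
#'
#' For a unit impulse of initiation flux, the arrival time at the mature
#' pool is the sum of three independent Erlang(n, k) stage times
#' (elongation, splicing, 3' processing), i.e. the convolution
#' Erlang(n, k_elo) * Erlang(n, k_spl) * Erlang(n, k_mat) with mean
#' \code{n (1/k_elo + 1/k_spl + 1/k_mat)}.  Computed by numerical
#' convolution on a regular grid.
#'
#' @param rates a \code{\link{RateConstants}}.
#' @param spec a full-variant \code{\link{ModelSpec}}.
#' @param tMax grid end (min); default 6 times the mean delay.
#' @param dt grid spacing (min).
#' @return list with \code{time}, \code{density} (min^-1) and \code{mean}
#'   (min).
#' @export
chainResponse <- function(rates, spec, tMax = NULL, dt = 0.05) {
  if (spec@variant %in% c("n0", "n2"))
    stop("chain response is defined for the full variants")
  k <- rates@rates
  n <- spec@nSub
  mu <- n * (1 / k[["k_elo"]] + 1 / k[["k_spl"]] + 1 / k[["k_mat"]])
  if (is.null(tMax)) tMax <- 6 * mu
  tt <- seq(0, tMax, by = dt)
  d1 <- stats::dgamma(tt, shape = n, rate = k[["k_elo"]])
  d2 <- stats::dgamma(tt, shape = n, rate = k[["k_spl"]])
  d3 <- stats::dgamma(tt, shape = n, rate = k[["k_mat"]])
  cv <- function(a, b) {
    z <- stats::convolve(a, rev(b), type = "open")[seq_along(tt)] * dt
    pmax(z, 0)
  }
  dens <- cv(cv(d1, d2), d3)
  list(time = tt, density = dens, mean = mu)
}

#' Median lifetime of a mature-mRNA cohort
#'
#' The time at which half of a cohort entering the \code{nSub}-stage
#' first-order degradation chain has been lost: the median of the
#' Erlang(\code{nSub}, \code{k_deg}) lifetime, obtained by inverting the
#' regularized incomplete gamma function.
#'
#' @param rates a \code{\link{RateConstants}}.
#' @param spec a \code{\link{ModelSpec}} (reduced variants have a one-stage
#'   chain).
#' @return minutes.
#' @examples
#' halvingTimeOfDegradation(referenceRates(), modelSpec("n5")) / 60  # ~3 h
#' @export
halvingTimeOfDegradation <- function(rates, spec) {
  k <- rates@rates[["k_deg"]]
  if (k <= 0) stop("k_deg must be positive")
  n <- if (spec@variant %in% c("n0", "n2")) 1L else spec@nSub
  stats::qgamma(0.5, shape = n, rate = k)
}

#' Solve the basal activity for a target induction fold
#'
#' Finds \code{f_basal} such that the induced-to-basal steady-state
#' initiation-flux ratio equals \code{fold} (all RNA pools scale by the same
#' factor at steady state).
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param rates a \code{\link{RateConstants}} (its \code{fBasal} is ignored).
#' @param fold target steady-state induction fold (> 1).
#' @return the \code{f_basal} value in (0, 1].
#' @export
solveBasalActivity <- function(spec, rates, fold = 2.5) {
  if (fold < 1) stop("fold must be >= 1")
  if (spec@variant %in% c("n0", "n2")) return(1 / fold)
  Jind <- initiationFlux(spec, rates, "induced")
  g <- function(f) {
    r <- rateConstants2(rates, f_basal = f)
    Jind / initiationFlux(spec, r, "basal") - fold
  }
  if (fold == 1) return(1)
  stats::uniroot(g, c(1e-8, 1), tol = 1e-12)$root
}

## internal: copy a RateConstants with some entries replaced
rateConstants2 <- function(rates, ..., f_basal = NULL) {
  upd <- c(...)
  r <- rates@rates
  if (length(upd)) r[names(upd)] <- upd
  new("RateConstants", rates = r,
      fBasal = if (is.null(f_basal)) rates@fBasal else f_basal)
}

#' Update parameters of a RateConstants object
#'
#' @param rates a \code{\link{RateConstants}}.
#' @param par named numeric; entries named after rate constants replace
#'   those rates, an entry named \code{f_basal} replaces the basal factor.
#' @return the updated \code{\link{RateConstants}}.
#' @export
updateRates <- function(rates, par) {
  r <- rates@rates
  f <- rates@fBasal
  for (nm in names(par)) {
    if (nm == "f_basal") f <- par[[nm]]
    else if (nm %in% names(r)) r[[nm]] <- par[[nm]]
    else stop("unknown parameter: ", nm)
  }
  new("RateConstants", rates = r, fBasal = f)
}

#' Full named parameter vector of a RateConstants object
#'
#' @param rates a \code{\link{RateConstants}}.
#' @return named numeric of the eight rates plus \code{f_basal}.
#' @export
parameterVector <- function(rates) {
  c(rates@rates, f_basal = rates@fBasal)
}
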