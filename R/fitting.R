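#' Per-time-point replicate summary
#'
#' Collapses replicates to per-time-point means after MAD outlier removal
#' and derives fitting weights
#' \code{w_t = 1 / max(SEM_t, 0.05 mean_t, minSem)^2}: the 5\%-of-mean
#' floor on the effective SEM avoids infinite weight at zero-variance
#' points, and the absolute floor \code{minSem} (copies/cell) encodes the
#' qPCR quantification limit so that deeply decayed points cannot dominate
#' the objective.  Explicit dataset weights, when present, override the
#' derived ones.
#'
#' @param dataset a \code{\link{TimeCourseDataset}}.
#' @param madThreshold threshold for \code{\link{madOutlierFilter}}.
#' @param minSem absolute effective-SEM floor in copies/cell (default
#'   0.01).
#' @return data.frame with columns \code{time_min}, \code{mean}, \code{sem},
#'   \code{n}, \code{weight}.
#' @export
replicateSummary <- function(dataset, madThreshold = 3, minSem = 0.01) {
  obs <- dataset@observations
  tu <- unique(obs$time_min)
  out <- data.frame(time_min = tu, mean = NA_real_, sem = NA_real_,
                    n = NA_integer_, weight = NA_real_)
  for (i in seq_along(tu)) {
    v <- obs$value[obs$time_min == tu[i]]
    if (length(v) >= 3) v <- madOutlierFilter(v, madThreshold, quiet = TRUE)
    out$mean[i] <- mean(v)
    out$n[i] <- length(v)
    out$sem[i] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }
  if (length(dataset@weights)) {
    out$weight <- dataset@weights
  } else {
    semEff <- pmax(out$sem, 0.05 * abs(out$mean), minSem)
    out$weight <- 1 / semEff^2
  }
  out
}

## simulate every dataset's observable under the candidate parameters,
## sharing one simulation per distinct protocol
.simulatedSeries <- function(spec, rates, datasets, summaries) {
  keys <- vapply(datasets, function(d)
    paste(d@protocol@tLigand, d@protocol@tBlock, d@protocol@tEnd), "")
  sims <- vector("list", length(datasets))
  for (key in unique(keys)) {
    ix <- which(keys == key)
    tt <- sort(unique(unlist(lapply(summaries[ix], `[[`, "time_min"))))
    tr <- simulate(spec, rates, datasets[[ix[1]]]@protocol, tt)
    ob <- observables(tr)
    for (i in ix) {
      m <- match(summaries[[i]]$time_min, ob$time_min)
      sims[[i]] <- ob[[datasets[[i]]@species]][m]
    }
  }
  sims
}

.ssrCore <- function(spec, rates, datasets, summaries, scales = NULL,
                     fitScales = c("none", "shared", "per-series")) {
  if (is.logical(fitScales))
    fitScales <- if (fitScales) "per-series" else "none"
  fitScales <- match.arg(fitScales)
  sims <- tryCatch(.simulatedSeries(spec, rates, datasets, summaries),
                   error = function(e) {
                     warning("simulation failed: ", conditionMessage(e))
                     NULL
                   })
  if (is.null(sims))
    return(list(objective = Inf, residuals = NULL, scales = NULL))
  resid <- vector("list", length(datasets))
  usedScales <- numeric(length(datasets))
  sharedScale <- 1
  if (fitScales == "shared") {
    num <- den <- 0
    for (i in seq_along(datasets)) {
      num <- num + sum(summaries[[i]]$weight * summaries[[i]]$mean * sims[[i]])
      den <- den + sum(summaries[[i]]$weight * sims[[i]]^2)
    }
    if (den > 0) sharedScale <- num / den
  }
  for (i in seq_along(datasets)) {
    s <- summaries[[i]]
    sim <- sims[[i]]
    sc <- switch(fitScales,
      "per-series" = {
        den <- sum(s$weight * sim^2)
        if (den > 0) sum(s$weight * s$mean * sim) / den else 1
      },
      "shared" = sharedScale,
      if (!is.null(scales)) scales[i] else 1)
    usedScales[i] <- sc
    resid[[i]] <- sqrt(s$weight) * (s$mean - sc * sim)
  }
  names(resid) <- vapply(datasets, function(d) d@label, "")
  list(objective = sum(unlist(resid)^2), residuals = resid,
       scales = usedScales)
}

#' Weighted sum of squared residuals
#'
#' The fitting objective: over all datasets and time points,
#' \code{sum w_t (mean_replicates(observed) - simulated)^2}, with the model
#' simulated under each dataset's own protocol.
#'
#' @param par named numeric of parameter values (free subset or full
#'   vector); entries update the problem's reference parameters.
#' @param problem a \code{\link{FitProblem}}.
#' @param madThreshold outlier threshold used when collapsing replicates.
#' @return non-negative scalar (\code{Inf} on simulation failure, with a
#'   warning).
#' @export
weightedSSR <- function(par, problem, madThreshold = 3) {
  rates <- updateRates(problem@reference, par)
  summ <- lapply(problem@datasets, replicateSummary, madThreshold = madThreshold)
  .ssrCore(problem@spec, rates, problem@datasets, summ)$objective
}

#' Optimizer settings
#'
#' @param populationSize CRS population size (default \code{10 (d + 1)},
#'   never below \code{2 d + 1}).
#' @param maxEvals total objective-evaluation budget.
#' @param seed integer seed; the optimizer is deterministic given it.
#' @param pReflect probability of a simplex-reflection trial (the
#'   complement is a coordinate-wise mutation around the current best).
#' @param polish run a deterministic Nelder-Mead polish from the CRS
#'   optimum (off by default).
#' @return a settings list for \code{\link{fitModel}}.
#' @export
crsSettings <- function(populationSize = NULL, maxEvals = 3000, seed = 1L,
                        pReflect = 0.7, polish = FALSE) {
  list(populationSize = populationSize, maxEvals = maxEvals,
       seed = as.integer(seed), pReflect = pReflect, polish = polish)
}

#' Controlled Random Search (CRS2 with local mutation) minimizer
#'
#' Population-based derivative-free global minimizer.  A population of
#' points is maintained inside the box; each iteration forms a trial either
#' by reflecting a random population member through the centroid of a
#' random simplex (probability \code{pReflect}) or by coordinate-wise
#' mutation around the current best point scaled by the population spread;
#' the trial replaces the worst member whenever it improves on it.  When
#' the population has collapsed (relative spread below \code{restartTol})
#' with budget remaining, all but the best tenth of the members are
#' resampled uniformly — a diversity restart that lets the search escape
#' premature convergence into a local basin.  The best-so-far value is
#' non-increasing and never worse than the best initial member.
#'
#' @param objective function of a numeric vector, returning a scalar.
#' @param lower,upper finite bounds defining the search box.
#' @param populationSize population size (default \code{10 (d + 1)}).
#' @param maxEvals evaluation budget (>= populationSize).
#' @param seed integer seed (deterministic search).
#' @param pReflect probability of the reflection move.
#' @param restartTol population spread (relative to the box width) below
#'   which a diversity restart is triggered.
#' @return list with \code{par}, \code{value}, \code{trace} (data.frame
#'   \code{eval}, \code{best}), \code{population}, \code{seed}.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- crsMinimize(sphere, rep(-5, 4), rep(5, 4), maxEvals = 4000, seed = 1)
#' res$value
#' @export
crsMinimize <- function(objective, lower, upper, populationSize = NULL,
                        maxEvals = 3000, seed = 1L, pReflect = 0.7,
                        restartTol = 1e-3) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(c(lower, upper))) ||
      any(lower >= upper))
    stop("invalid bounds")
  if (is.null(populationSize)) populationSize <- 10L * (d + 1L)
  populationSize <- max(populationSize, 2L * d + 1L)
  if (maxEvals < populationSize)
    stop("maxEvals must be at least the population size")

  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)

  P <- matrix(stats::runif(populationSize * d, rep(lower, each = populationSize),
                           rep(upper, each = populationSize)),
              populationSize, d)
  fv <- apply(P, 1, objective)
  nev <- populationSize
  trace <- data.frame(eval = seq_len(maxEvals), best = NA_real_)
  trace$best[seq_len(nev)] <- cummin(fv)

  bestPar <- P[which.min(fv), ]
  bestVal <- min(fv)
  width <- upper - lower
  while (nev < maxEvals) {
    ibest <- which.min(fv)
    spread <- apply(P, 2, function(z) diff(range(z)))
    if (max(spread / width) < restartTol &&
        maxEvals - nev > populationSize) {
      ## diversity restart: keep the best tenth, resample the rest
      keep <- order(fv)[seq_len(max(1L, populationSize %/% 10L))]
      drop <- setdiff(seq_len(populationSize), keep)
      P[drop, ] <- matrix(stats::runif(length(drop) * d,
                                       rep(lower, each = length(drop)),
                                       rep(upper, each = length(drop))),
                          length(drop), d)
      fv[drop] <- apply(P[drop, , drop = FALSE], 1, objective)
      trace$best[nev + seq_along(drop)] <-
        pmin(trace$best[nev], cummin(fv[drop]))
      nev <- nev + length(drop)
      if (min(fv) < bestVal) {
        bestVal <- min(fv)
        bestPar <- P[which.min(fv), ]
      }
      next
    }
    if (stats::runif(1) < pReflect) {
      ix <- sample(populationSize, d + 1L)
      centroid <- colMeans(P[ix[seq_len(d)], , drop = FALSE])
      trial <- 2 * centroid - P[ix[d + 1L], ]
    } else {
      popSd <- apply(P, 2, stats::sd)
      trial <- P[ibest, ] + (stats::runif(d) - 0.5) * popSd
      ## occasionally redraw one coordinate across its full range, so a
      ## single badly-placed coordinate cannot trap the whole population
      if (stats::runif(1) < 0.25) {
        j <- sample.int(d, 1L)
        trial[j] <- stats::runif(1, lower[j], upper[j])
      }
    }
    trial <- pmin(pmax(trial, lower), upper)
    fnew <- objective(trial)
    nev <- nev + 1L
    iworst <- which.max(fv)
    if (is.finite(fnew) && fnew < fv[iworst]) {
      P[iworst, ] <- trial
      fv[iworst] <- fnew
      if (fnew < bestVal) {
        bestVal <- fnew
        bestPar <- trial
      }
    }
    trace$best[nev] <- min(trace$best[nev - 1L], fnew)
  }
  list(par = bestPar, value = bestVal, trace = trace,
       population = P, seed = as.integer(seed))
}

## objective over the free parameters in log10 space, with cached summaries
.makeLogObjective <- function(problem, madThreshold = 3, fitScales = FALSE) {
  summ <- lapply(problem@datasets, replicateSummary, madThreshold = madThreshold)
  free <- problem@free
  force(fitScales)
  function(logPar) {
    par <- setNames(10^logPar, free)
    rates <- updateRates(problem@reference, par)
    .ssrCore(problem@spec, rates, problem@datasets, summ,
             fitScales = fitScales)$objective
  }
}

#' Fit a model to time-course data
#'
#' Minimizes the weighted least-squares objective over the problem's free
#' parameters with the CRS global optimizer, working in log10 parameter
#' space inside the problem's bounds.  Validation datasets are simulated at
#' the optimum and their residuals recorded without ever entering the
#' objective.
#'
#' @param problem a \code{\link{FitProblem}}.
#' @param settings from \code{\link{crsSettings}}.
#' @param madThreshold replicate-outlier threshold.
#' @return a \code{\link{FitResult}}.
#' @export
fitModel <- function(problem, settings = crsSettings(), madThreshold = 3) {
  free <- problem@free
  summ <- lapply(problem@datasets, replicateSummary, madThreshold = madThreshold)
  obj <- .makeLogObjective(problem, madThreshold)
  lo <- log10(problem@bounds[1, ])
  hi <- log10(problem@bounds[2, ])

  if (length(free) == 0) {
    res <- .ssrCore(problem@spec, problem@reference, problem@datasets, summ)
    trace <- data.frame(eval = 1L, best = res$objective)
    best <- parameterVector(problem@reference)
    valres <- .validationResiduals(problem, problem@reference, madThreshold)
    return(new("FitResult", par = best, objective = res$objective,
               residuals = res$residuals, validationResiduals = valres,
               trace = trace, seed = settings$seed, free = character()))
  }

  cr <- crsMinimize(obj, lo, hi,
                    populationSize = settings$populationSize,
                    maxEvals = settings$maxEvals, seed = settings$seed,
                    pReflect = settings$pReflect)
  logBest <- cr$par
  if (isTRUE(settings$polish)) {
    pol <- stats::optim(logBest, function(p) obj(pmin(pmax(p, lo), hi)),
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (pol$value < cr$value) {
      logBest <- pmin(pmax(pol$par, lo), hi)
      cr$value <- pol$value
    }
  }
  par <- setNames(10^logBest, free)
  rates <- updateRates(problem@reference, par)
  res <- .ssrCore(problem@spec, rates, problem@datasets, summ)
  valres <- .validationResiduals(problem, rates, madThreshold)
  new("FitResult", par = parameterVector(rates), objective = res$objective,
      residuals = res$residuals, validationResiduals = valres,
      trace = cr$trace, seed = cr$seed, free = free)
}

.validationResiduals <- function(problem, rates, madThreshold = 3) {
  if (!length(problem@validation)) return(list())
  summ <- lapply(problem@validation, replicateSummary, madThreshold = madThreshold)
  .ssrCore(problem@spec, rates, problem@validation, summ)$residuals
}

#' Refit a single parameter, all others pinned
#'
#' One-dimensional global-plus-local minimization of the weighted SSR over
#' the target parameter's bounds (log10 grid scan followed by golden-section
#' refinement of the best bracket); every other parameter stays at its
#' reference value.
#'
#' @param problem a \code{\link{FitProblem}} (its \code{free} slot is
#'   ignored; the target defines the single free direction).
#' @param referencePar named full parameter vector to pin to.
#' @param target name of the parameter to refit.
#' @param nGrid number of log-spaced grid points for the global stage.
#' @param fitScales fit a free multiplicative scale per dataset series
#'   alongside (apparent fold-induction adjustment).
#' @param madThreshold replicate-outlier threshold.
#' @return list with \code{value} (refit parameter), \code{objective},
#'   \code{residuals}, \code{scales} and the per-series objective split.
#' @export
refitSingle <- function(problem, referencePar, target, nGrid = 25,
                        fitScales = FALSE, madThreshold = 3) {
  stopifnot(target %in% .ALL_PARAMS)
  refRates <- updateRates(problem@reference, referencePar)
  summ <- lapply(problem@datasets, replicateSummary, madThreshold = madThreshold)
  bounds <- if (target %in% colnames(problem@bounds))
    problem@bounds[, target] else c(1e-4, if (target == "f_basal") 1 else 1e2)
  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  f1 <- function(lp) {
    rates <- updateRates(refRates, setNames(10^lp, target))
    .ssrCore(problem@spec, rates, problem@datasets, summ,
             fitScales = fitScales)$objective
  }
  grid <- seq(lo, hi, length.out = nGrid)
  gv <- vapply(grid, f1, 0)
  i0 <- which.min(gv)
  bracket <- c(grid[max(1, i0 - 1)], grid[min(nGrid, i0 + 1)])
  opt <- stats::optimize(f1, bracket, tol = 1e-7)
  lpBest <- if (opt$objective < gv[i0]) opt$minimum else grid[i0]
  value <- 10^lpBest
  rates <- updateRates(refRates, setNames(value, target))
  res <- .ssrCore(problem@spec, rates, problem@datasets, summ,
                  fitScales = fitScales)
  bySpecies <- vapply(c("pre", "mature"), function(sp) {
    ix <- which(vapply(problem@datasets, function(d) d@species, "") == sp)
    if (!length(ix)) return(NA_real_)
    sum(unlist(res$residuals[ix])^2)
  }, 0)
  list(parameter = target, value = unname(value),
       objective = res$objective, residuals = res$residuals,
       scales = res$scales,
       objective_pre = bySpecies[["pre"]],
       objective_mature = bySpecies[["mature"]])
}
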