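## stacked weighted residual vector at a parameter point
.weightedResiduals <- function(par, problem, madThreshold = 3) {
  rates <- updateRates(problem@reference, par)
  summ <- lapply(problem@datasets, replicateSummary, madThreshold = madThreshold)
  res <- .ssrCore(problem@spec, rates, problem@datasets, summ)
  if (is.null(res$residuals)) stop("simulation failed at the given parameters")
  unlist(res$residuals, use.names = FALSE)
}

#' Residual sensitivities in log-parameter space
#'
#' Central finite differences of the weighted residual vector with respect
#' to log10 of each free parameter, evaluated at (or near) a fit optimum.
#' Rows follow the stacked dataset/time-point order, columns the problem's
#' canonical free-parameter order; residuals are already scaled by the
#' square-root weights, so the cross-product of this matrix is the Fisher
#' information of the weighted least-squares problem.
#'
#' @param par named full parameter vector at the optimum.
#' @param problem a \code{\link{FitProblem}}.
#' @param relStep central-difference step in log10 units (default 1e-4,
#'   chosen by step-halving stability).
#' @return matrix (residuals x parameters).
#' @export
sensitivities <- function(par, problem, relStep = 1e-4) {
  if (relStep <= 1e-12) stop("relStep underflow")
  free <- problem@free
  full <- parameterVector(updateRates(problem@reference, par))
  cols <- vector("list", length(free))
  for (j in seq_along(free)) {
    up <- full; dn <- full
    up[free[j]] <- 10^(log10(full[free[j]]) + relStep)
    dn[free[j]] <- 10^(log10(full[free[j]]) - relStep)
    rUp <- .weightedResiduals(up, problem)
    rDn <- .weightedResiduals(dn, problem)
    cols[[j]] <- (rUp - rDn) / (2 * relStep)
  }
  S <- do.call(cbind, cols)
  colnames(S) <- free
  S
}

#' Fisher information matrix of a fit
#'
#' @param par,problem,relStep as in \code{\link{sensitivities}}.
#' @return symmetric positive semidefinite matrix (parameters x
#'   parameters) in log10-parameter coordinates.
#' @export
fisherInformation <- function(par, problem, relStep = 1e-4) {
  S <- sensitivities(par, problem, relStep)
  crossprod(S)
}

#' Dependent and independent confidence intervals
#'
#' Conditional ("dependent": all other parameters held fixed) and marginal
#' ("independent": all other parameters free to compensate) half-widths per
#' parameter, from the Fisher information of the weighted least-squares
#' problem: \code{dependent_i = t(level, dof) s sqrt(1/FIM_ii)} and
#' \code{independent_i = t(level, dof) s sqrt((FIM^-1)_ii)} with
#' \code{s^2 = SSR/dof}.  By Cauchy-Schwarz the independent half-width is
#' never smaller than the dependent one; a large ratio flags strong
#' parameter co-dependence.  Note the naming follows the empirical usage of
#' the source analysis (independent = marginal, dependent = conditional);
#' parts of the literature use the opposite convention.
#'
#' @param fim Fisher information matrix (log10 coordinates).
#' @param ssr minimized weighted SSR.
#' @param nPoints number of fitted data points.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns \code{parameter}, \code{dependent},
#'   \code{independent}, \code{ratio} (half-widths in log10 units;
#'   \code{independent} is \code{Inf} where the FIM is singular).
#' @export
confidenceIntervals <- function(fim, ssr, nPoints, level = 0.95) {
  K <- ncol(fim)
  dof <- nPoints - K
  if (dof <= 0) stop("need nPoints > number of parameters")
  s <- sqrt(ssr / dof)
  tq <- stats::qt(1 - (1 - level) / 2, dof)
  dep <- tq * s * sqrt(1 / diag(fim))
  inv <- tryCatch(solve(fim), error = function(e) NULL)
  indep <- if (is.null(inv)) rep(Inf, K) else tq * s * sqrt(pmax(diag(inv), 0))
  data.frame(parameter = colnames(fim), dependent = dep, independent = indep,
             ratio = indep / dep, row.names = NULL)
}

#' Parameter correlation matrix from the Fisher information
#'
#' @param fim Fisher information matrix.
#' @return correlation matrix of the parameter estimates
#'   (\code{cov2cor(FIM^-1)}).
#' @export
parameterCorrelation <- function(fim) {
  stats::cov2cor(solve(fim))
}

#' A posteriori identifiability report
#'
#' Convenience wrapper computing the sensitivity matrix, Fisher
#' information, dependent/independent confidence half-widths and the
#' parameter correlation matrix at a fitted optimum.
#'
#' @param fit a \code{\link{FitResult}} (or a named full parameter vector).
#' @param problem the \code{\link{FitProblem}} the fit came from.
#' @param level confidence level.
#' @param relStep finite-difference step (log10 units).
#' @return list with \code{sensitivities}, \code{fim}, \code{intervals},
#'   \code{correlation}, \code{ssr}, \code{nPoints}.
#' @export
identifiabilityReport <- function(fit, problem, level = 0.95,
                                  relStep = 1e-4) {
  par <- if (is(fit, "FitResult")) fit@par else fit
  S <- sensitivities(par, problem, relStep)
  fim <- crossprod(S)
  ssr <- sum(.weightedResiduals(par, problem)^2)
  nPoints <- nrow(S)
  corr <- tryCatch(parameterCorrelation(fim), error = function(e) NULL)
  list(sensitivities = S, fim = fim,
       intervals = confidenceIntervals(fim, ssr, nPoints, level),
       correlation = corr, ssr = ssr, nPoints = nPoints)
}

#' Objective profiles under single- and co-dependent perturbation
#'
#' Recomputes the weighted SSR while multiplying one parameter at a time by
#' each factor of the grid, all others fixed; optionally also perturbs
#' compensating parameter pairs jointly (both scaled by the same factor,
#' e.g. \code{k_ini} with \code{k_dea}, which approximately preserves the
#' mRNA production flux and so probes the promoter-parameter degeneracy).
#'
#' @param par named full parameter vector (typically a fit optimum).
#' @param problem a \code{\link{FitProblem}}.
#' @param grid multiplicative perturbation factors (default
#'   \code{c(0.25, 0.5, 1, 2, 4)}).
#' @param parameters which single parameters to profile (default: the
#'   problem's free set).
#' @param pairs optional list of length-2 character vectors perturbed
#'   jointly.
#' @return data.frame with columns \code{parameter}, \code{factor},
#'   \code{objective}.
#' @export
sensitivityProfile <- function(par, problem,
                               grid = c(0.25, 0.5, 1, 2, 4),
                               parameters = problem@free, pairs = NULL) {
  full <- parameterVector(updateRates(problem@reference, par))
  summ <- lapply(problem@datasets, replicateSummary)
  evalAt <- function(p) {
    rates <- updateRates(problem@reference, p)
    .ssrCore(problem@spec, rates, problem@datasets, summ)$objective
  }
  rows <- list()
  for (nm in parameters) {
    for (g in grid) {
      p <- full
      p[nm] <- full[nm] * g
      if (nm == "f_basal") p[nm] <- min(p[nm], 1)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = nm, factor = g, objective = evalAt(p))
    }
  }
  for (pr in pairs) {
    stopifnot(length(pr) == 2)
    for (g in grid) {
      p <- full
      p[pr] <- full[pr] * g
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = paste(pr, collapse = ":"), factor = g,
                   objective = evalAt(p))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
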