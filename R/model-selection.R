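#' Least-squares Akaike Information Criterion
#'
#' \code{AIC = N log(SSR/N) + 2K} with, by default, the small-sample
#' correction \code{2K(K+1)/(N-K-1)}, which is the appropriate form when
#' the data-point count is not large against the parameter count.
#'
#' @param ssr minimized weighted sum of squared residuals (> 0).
#' @param nPoints number of fitted data points N (> K + 2 for the
#'   corrected form).
#' @param kParams number of estimated parameters K.
#' @param corrected apply the small-sample correction (default TRUE).
#' @return the criterion value (lower is better).
#' @examples
#' aicc(ssr = 60, nPoints = 60, kParams = 8)
#' @export
aicc <- function(ssr, nPoints, kParams, corrected = TRUE) {
  if (ssr <= 0) stop("ssr must be positive")
  if (corrected && nPoints <= kParams + 2)
    stop("need nPoints > kParams + 2 for the corrected AIC")
  out <- nPoints * log(ssr / nPoints) + 2 * kParams
  if (corrected)
    out <- out + 2 * kParams * (kParams + 1) / (nPoints - kParams - 1)
  out
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Counts runs of equal sign in the residual sequence (zeros dropped) and
#' compares the count with its normal approximation under randomness
#' (mean \code{1 + 2ab/(a+b)}); too few runs indicate systematic misfit.
#' When all residuals share one sign the exact probability of observing a
#' single run is reported instead of the normal approximation.
#'
#' @param residuals numeric residual sequence in time order.
#' @return list with \code{nRuns}, \code{z} and two-sided \code{p}.
#' @examples
#' runsTest(c(1, -1, 1, -1, 1, -1))$nRuns  # 6: perfectly alternating
#' @export
runsTest <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  if (length(s) < 5) stop("need at least 5 nonzero residuals")
  a <- sum(s > 0)
  b <- sum(s < 0)
  nRuns <- 1L + sum(s[-1] != s[-length(s)])
  if (a == 0 || b == 0) {
    ## all one sign: P(single run) over the two monochrome orderings
    return(list(nRuns = nRuns, z = NA_real_, p = 1))
  }
  mu <- 1 + 2 * a * b / (a + b)
  v <- 2 * a * b * (2 * a * b - a - b) / ((a + b)^2 * (a + b - 1))
  z <- (nRuns - mu) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  list(nRuns = nRuns, z = z, p = min(p, 1))
}

#' Flag spurious oscillations in a noiseless mature-mRNA trajectory
#'
#' Detects any adjacent local maximum/minimum pair in the simulated
#' noiseless mature-mRNA induction curve whose relative amplitude
#' \code{(max - min)/max} exceeds the threshold.  This operationalizes the
#' visual screening that disqualified the deep-chain variants (n = 10, 20),
#' whose fits rang with pronounced damped oscillations.
#'
#' @param spec,rates model to simulate.
#' @param tEnd,dt simulation window and step (min).
#' @param threshold relative amplitude above which the flag is raised
#'   (default 0.05).
#' @return logical.
#' @export
oscillationFlag <- function(spec, rates, tEnd = 450, dt = 1,
                            threshold = 0.05) {
  tt <- seq(0, tEnd, by = dt)
  tr <- simulate(spec, rates, protocol(tLigand = 0, tEnd = tEnd), tt)
  y <- observables(tr)$mature
  dy <- diff(y)
  turns <- which(dy[-1] * dy[-length(dy)] < 0) + 1L
  if (length(turns) < 2) return(FALSE)
  ext <- y[turns]
  for (i in seq_len(length(ext) - 1)) {
    hi <- max(ext[i], ext[i + 1]); lo <- min(ext[i], ext[i + 1])
    if (hi > 0 && (hi - lo) / hi > threshold) return(TRUE)
  }
  FALSE
}

#' Fit and rank the model variants
#'
#' Fits each variant independently to the same datasets (identical data and
#' weights, one optimizer budget for all; each variant gets its own seed
#' derived from the shared seed) and tabulates the minimized weighted SSR,
#' the corrected AIC, the runs test per observable series and the
#' oscillation flag of the fitted noiseless mature curve.
#'
#' @param datasets list of \code{\link{TimeCourseDataset}}.
#' @param variants character vector of variant names (default all seven).
#' @param settings \code{\link{crsSettings}} applied to every variant.
#' @param reference a \code{\link{RateConstants}} used as the pinned values
#'   for rates a reduced variant does not use.
#' @param seed root seed; variant i is fitted with \code{seed + i - 1}.
#' @param corrected use the small-sample AIC correction.
#' @return list with \code{table} (one row per variant: K, N, SSR, AIC,
#'   worst runs-test p across series, oscillation flag) and \code{fits}
#'   (named list of \code{\link{FitResult}}; failed fits carry the error
#'   message instead).
#' @export
compareVariants <- function(datasets,
                            variants = c("n0", "n2", "n1", "n3", "n5", "n10", "n20"),
                            settings = crsSettings(),
                            reference = referenceRates(),
                            seed = settings$seed, corrected = TRUE) {
  stopifnot(length(variants) >= 1)
  nPoints <- sum(vapply(datasets, function(d)
    length(unique(d@observations$time_min)), 0L))
  fits <- list()
  rows <- list()
  for (i in seq_along(variants)) {
    v <- variants[i]
    spec <- modelSpec(v)
    free <- c(variantParameters(spec), "f_basal")
    prob <- fitProblem(spec, reference, datasets, free = free)
    st <- settings
    st$seed <- as.integer(seed + i - 1L)
    fit <- tryCatch(fitModel(prob, st), error = function(e) e)
    fits[[v]] <- fit
    if (inherits(fit, "error")) {
      rows[[v]] <- data.frame(variant = v, K = length(free), N = nPoints,
                              ssr = NA_real_, aic = NA_real_,
                              runs_p = NA_real_, oscillation = NA)
      next
    }
    runsP <- vapply(fit@residuals, function(r) runsTest(r)$p, 0)
    ratesFit <- updateRates(reference, fit@par)
    rows[[v]] <- data.frame(
      variant = v, K = length(free), N = nPoints,
      ssr = fit@objective,
      aic = aicc(fit@objective, nPoints, length(free), corrected = corrected),
      runs_p = min(runsP),
      oscillation = oscillationFlag(spec, ratesFit))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits, seed = as.integer(seed))
}
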