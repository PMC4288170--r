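#' Create a model-variant specification
#'
#' @param variant one of \code{"n0"}, \code{"n2"}, \code{"n1"}, \code{"n3"},
#'   \code{"n5"}, \code{"n10"}, \code{"n20"}.  \code{"n5"} is the variant
#'   retained by the model-selection analysis.
#' @param ligandSensitiveSteps how many leading promoter-activation
#'   transitions the ligand accelerates (default 2; full variants only).
#' @return a \code{\link{ModelSpec}}.
#' @examples
#' modelSpec("n5")
#' @export
modelSpec <- function(variant = "n5", ligandSensitiveSteps = 2L) {
  variant <- match.arg(variant, .VARIANTS)
  nSub <- as.integer(sub("^n", "", variant))
  ligandSensitiveSteps <- min(as.integer(ligandSensitiveSteps), nSub)
  new("ModelSpec", variant = variant, nSub = nSub,
      ligandSensitiveSteps = as.integer(ligandSensitiveSteps),
      nInitSteps = 1L)
}

#' Create a rate-constant set
#'
#' @param k_act,k_dea,k_rev,k_ini,k_elo,k_spl,k_mat,k_deg first-order rate
#'   constants, \code{min^-1}.
#' @param f_basal basal-activity factor in \code{[0, 1]} applied to the
#'   ligand-sensitive transitions before ligand addition.
#' @return a \code{\link{RateConstants}}.
#' @export
rateConstants <- function(k_act, k_dea, k_rev, k_ini,
                          k_elo, k_spl, k_mat, k_deg, f_basal = 0.2) {
  r <- c(k_act = k_act, k_dea = k_dea, k_rev = k_rev, k_ini = k_ini,
         k_elo = k_elo, k_spl = k_spl, k_mat = k_mat, k_deg = k_deg)
  new("RateConstants", rates = r, fBasal = f_basal)
}

#' Reference rate constants for the ADRP transcription unit
#'
#' The fitted rate constants of the five-sub-state model for ligand-induced
#' ADRP transcription in HepG2 cells (activation 0.106, deactivation 1.3,
#' reversion 1.145, initiation 3.436, elongation 2.272, splicing 0.512,
#' maturation 0.161, degradation 0.025 min^-1).  \code{f_basal} defaults to
#' 0.2; use \code{\link{solveBasalActivity}} to set it from a target
#' induction fold.
#'
#' @param f_basal basal-activity factor.
#' @return a \code{\link{RateConstants}}.
#' @examples
#' referenceRates()
#' @export
referenceRates <- function(f_basal = 0.2) {
  rateConstants(k_act = 0.106, k_dea = 1.3, k_rev = 1.145, k_ini = 3.436,
                k_elo = 2.272, k_spl = 0.512, k_mat = 0.161, k_deg = 0.025,
                f_basal = f_basal)
}

#' Create an experiment protocol
#'
#' @param tLigand time of ligand addition (min).
#' @param tBlock optional time of transcription block (min), \code{NA} for
#'   none.
#' @param tEnd final simulated time (min).
#' @return a \code{\link{Protocol}}.
#' @examples
#' protocol(tLigand = 0, tEnd = 225)              # induction series
#' protocol(tLigand = 0, tBlock = 180, tEnd = 480) # DRB decay series
#' @export
protocol <- function(tLigand = 0, tBlock = NA_real_, tEnd = 225) {
  new("Protocol", tLigand = as.numeric(tLigand),
      tBlock = as.numeric(tBlock), tEnd = as.numeric(tEnd))
}

#' Create a replicate time-course dataset
#'
#' @param label dataset label.
#' @param species \code{"pre"} or \code{"mature"}.
#' @param observations long data.frame with columns \code{time_min},
#'   \code{replicate}, \code{value}; or a matrix (rows = time points,
#'   columns = replicates) together with \code{times}.
#' @param protocol the \code{\link{Protocol}} under which the series was
#'   recorded.
#' @param weights optional per-time-point weights; derived from replicate
#'   scatter when omitted.
#' @param scaleCorrection multiplicative factor applied to the values on
#'   construction (default 1).
#' @param times time grid (min) when \code{observations} is a matrix.
#' @return a \code{\link{TimeCourseDataset}}.
#' @export
timeCourseDataset <- function(label, species, observations, protocol,
                              weights = numeric(), scaleCorrection = 1,
                              times = NULL) {
  if (is.matrix(observations)) {
    stopifnot(!is.null(times), length(times) == nrow(observations))
    observations <- data.frame(
      time_min = rep(times, ncol(observations)),
      replicate = rep(seq_len(ncol(observations)), each = nrow(observations)),
      value = as.vector(observations))
  }
  observations <- observations[order(observations$time_min,
                                     observations$replicate), , drop = FALSE]
  rownames(observations) <- NULL
  observations$value <- observations$value * scaleCorrection
  new("TimeCourseDataset", label = label, species = species,
      observations = observations, weights = as.numeric(weights),
      protocol = protocol, scaleCorrection = as.numeric(scaleCorrection))
}

#' Assemble a fitting problem
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param reference full \code{\link{RateConstants}} providing values for
#'   pinned parameters and the optimizer's reference point.
#' @param datasets list of \code{\link{TimeCourseDataset}} entering the
#'   objective.
#' @param free names of free parameters; defaults to all parameters the
#'   variant uses plus \code{f_basal}.
#' @param bounds 2-row matrix of linear-scale boxes, or \code{NULL} for the
#'   default box \code{[1e-4, 1e2] min^-1} per rate (and \code{[1e-4, 1]}
#'   for \code{f_basal}).
#' @param validation held-out datasets; residuals tracked, objective
#'   untouched.
#' @return a \code{\link{FitProblem}}.
#' @export
fitProblem <- function(spec, reference, datasets,
                       free = NULL, bounds = NULL, validation = list()) {
  if (is.null(free)) free <- c(variantParameters(spec), "f_basal")
  if (is.null(bounds)) {
    bounds <- matrix(rep(c(1e-4, 1e2), length(free)), nrow = 2,
                     dimnames = list(c("lower", "upper"), free))
    if ("f_basal" %in% free) bounds["upper", "f_basal"] <- 1
  }
  if (is.null(colnames(bounds))) colnames(bounds) <- free
  new("FitProblem", spec = spec, reference = reference, free = free,
      bounds = bounds, datasets = datasets, validation = validation)
}

## ---- accessors ----

#' @rdname accessors
#' @param object a txcycle S4 object.
#' @export
setGeneric("variantName", function(object) standardGeneric("variantName"))
#' Accessors for txcycle objects
#' @name accessors
#' @rdname accessors
#' @aliases variantName,ModelSpec-method
#' @export
setMethod("variantName", "ModelSpec", function(object) object@variant)

#' @rdname accessors
#' @export
setGeneric("nSub", function(object) standardGeneric("nSub"))
#' @rdname accessors
#' @export
setMethod("nSub", "ModelSpec", function(object) object@nSub)

#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @rdname accessors
#' @export
setMethod("rates", "RateConstants", function(object) object@rates)

#' @rdname accessors
#' @export
setGeneric("basalActivity", function(object) standardGeneric("basalActivity"))
#' @rdname accessors
#' @export
setMethod("basalActivity", "RateConstants", function(object) object@fBasal)

#' @rdname accessors
#' @export
setGeneric("observables", function(object) standardGeneric("observables"))
#' @rdname accessors
#' @export
setMethod("observables", "Trajectory", function(object) object@observables)

#' @rdname accessors
#' @export
setGeneric("states", function(object) standardGeneric("states"))
#' @rdname accessors
#' @export
setMethod("states", "Trajectory", function(object) object@states)

#' @rdname accessors
#' @export
setGeneric("fittedParameters", function(object) standardGeneric("fittedParameters"))
#' @rdname accessors
#' @export
setMethod("fittedParameters", "FitResult", function(object) object@par)

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setMethod("objectiveValue", "FitResult", function(object) object@objective)

#' @rdname accessors
#' @export
setGeneric("optimizerTrace", function(object) standardGeneric("optimizerTrace"))
#' @rdname accessors
#' @export
setMethod("optimizerTrace", "FitResult", function(object) object@trace)

#' @rdname accessors
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))
#' @rdname accessors
#' @export
setMethod("scanTable", "ScanResult", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("bestParameter", function(object) standardGeneric("bestParameter"))
#' @rdname accessors
#' @export
setMethod("bestParameter", "ScanResult", function(object) object@best)

#' @rdname accessors
#' @export
setGeneric("percentInhibition", function(object) standardGeneric("percentInhibition"))
#' @rdname accessors
#' @export
setMethod("percentInhibition", "ScanResult", function(object) object@percentInhibition)

#' Parameters used by a model variant
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @return character vector of rate-constant names active in the variant
#'   (excluding \code{f_basal}, which every variant uses).
#' @export
variantParameters <- function(spec) {
  switch(spec@variant,
         n0 = c("k_ini", "k_spl", "k_deg"),
         n2 = c("k_act", "k_ini", "k_spl", "k_deg"),
         .RATE_NAMES)
}

#' Number of dynamic states of a variant
#'
#' Full variants have \code{3 nSub} promoter states and \code{4 nSub} RNA
#' states; \code{"n0"} has 2 states and \code{"n2"} has 5.
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @return integer state count.
#' @export
nStates <- function(spec) {
  switch(spec@variant, n0 = 2L, n2 = 5L, 7L * spec@nSub)
}

## ---- show methods ----

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec variant '%s': %d states", object@variant,
              nStates(object)))
  if (!(object@variant %in% c("n0", "n2")))
    cat(sprintf(" (%d sub-states/process, %d ligand-sensitive activation steps)",
                object@nSub, object@ligandSensitiveSteps))
  cat("\n")
})

setMethod("show", "RateConstants", function(object) {
  cat("RateConstants (min^-1):\n")
  print(signif(object@rates, 4))
  cat(sprintf("f_basal: %.4g\n", object@fBasal))
})

setMethod("show", "Protocol", function(object) {
  cat(sprintf("Protocol: ligand at %g min%s, end %g min\n", object@tLigand,
              if (is.na(object@tBlock)) ""
              else sprintf(", transcription block at %g min", object@tBlock),
              object@tEnd))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g] min, %d states (variant %s)\n",
              length(object@times), min(object@times), max(object@times),
              ncol(object@states), object@spec@variant))
})

setMethod("show", "TimeCourseDataset", function(object) {
  tu <- unique(object@observations$time_min)
  cat(sprintf("TimeCourseDataset '%s' (%s): %d time points, %d observations\n",
              object@label, object@species, length(tu),
              nrow(object@observations)))
})

setMethod("show", "FitProblem", function(object) {
  cat(sprintf("FitProblem: variant %s, %d free parameters (%s), %d dataset(s), %d validation\n",
              object@spec@variant, length(object@free),
              paste(object@free, collapse = ", "),
              length(object@datasets), length(object@validation)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: objective %.6g after %d evaluations (seed %d)\n",
              object@objective, nrow(object@trace), object@seed))
  cat("free:", paste(object@free, collapse = ", "), "\n")
  print(signif(object@par, 4))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: best single-parameter refit = %s (%.1f%% inhibition)\n",
              object@best, object@percentInhibition))
  print(object@table, digits = 4)
  if (nrow(object@pairwise)) {
    cat("pairwise refinement:\n")
    print(object@pairwise, digits = 4)
  }
})
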