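#' @import methods
NULL

## canonical parameter order used everywhere (matrices, scans, reports)
.RATE_NAMES <- c("k_act", "k_dea", "k_rev", "k_ini",
                 "k_elo", "k_spl", "k_mat", "k_deg")
.ALL_PARAMS <- c(.RATE_NAMES, "f_basal")
.VARIANTS   <- c("n0", "n2", "n1", "n3", "n5", "n10", "n20")

#' Structural description of one model variant
#'
#' A \code{ModelSpec} fixes the architecture of a transcription-dynamics
#' model: the number of identical first-order sub-states per process in the
#' promoter cycle and in each RNA-processing chain, and how many of the
#' promoter-activation transitions respond to ligand.  Full variants
#' (\code{"n1"}, \code{"n3"}, \code{"n5"}, \code{"n10"}, \code{"n20"}) have a
#' three-phase promoter cycle (induction, active, inactive; \code{nSub}
#' states each) and four RNA chains (elongation, splicing, 3' processing,
#' degradation; \code{nSub} states each).  The reduced variants are
#' \code{"n0"} (a constitutively transcribing source feeding a pre-mRNA pool
#' and a mature pool; two states) and \code{"n2"} (a two-step promoter
#' activation in front of the same two pools; five states).
#'
#' @slot variant character, one of \code{"n0","n2","n1","n3","n5","n10","n20"}.
#' @slot nSub integer, sub-states per process (0 and 2 label the reduced
#'   variants).
#' @slot ligandSensitiveSteps integer, number of leading activation
#'   transitions scaled by the basal-activity factor before ligand addition.
#' @slot nInitSteps integer, sub-states of the initiation step (always 1).
#' @export
setClass("ModelSpec",
  representation(variant = "character", nSub = "integer",
                 ligandSensitiveSteps = "integer", nInitSteps = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@variant %in% .VARIANTS))
      msg <- c(msg, sprintf("variant must be one of %s",
                            paste(.VARIANTS, collapse = ", ")))
    if (object@nInitSteps != 1L)
      msg <- c(msg, "nInitSteps is fixed at 1")
    if (object@variant %in% c("n1", "n3", "n5", "n10", "n20") &&
        object@ligandSensitiveSteps > object@nSub)
      msg <- c(msg, "ligandSensitiveSteps must not exceed nSub")
    if (length(msg)) msg else TRUE
  })

#' First-order rate constants and basal promoter activity
#'
#' The eight first-order rate constants of the model (all \code{min^-1}) and
#' the dimensionless basal-activity factor \code{fBasal} in \code{[0, 1]}
#' applied to the ligand-sensitive transitions before ligand addition.
#'
#' @slot rates named numeric of length 8 in the canonical order
#'   \code{k_act, k_dea, k_rev, k_ini, k_elo, k_spl, k_mat, k_deg}; all
#'   strictly positive.
#' @slot fBasal numeric scalar in \code{[0, 1]}.
#' @export
setClass("RateConstants",
  representation(rates = "numeric", fBasal = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rates) != 8L ||
        !identical(names(object@rates), .RATE_NAMES))
      msg <- c(msg, "rates must be named k_act, k_dea, k_rev, k_ini, k_elo, k_spl, k_mat, k_deg")
    if (any(!is.finite(object@rates)) || any(object@rates <= 0))
      msg <- c(msg, "all rate constants must be finite and strictly positive")
    if (length(object@fBasal) != 1L || !is.finite(object@fBasal) ||
        object@fBasal < 0 || object@fBasal > 1)
      msg <- c(msg, "fBasal must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Timed experiment protocol
#'
#' Piecewise-constant parameter regimes: basal before \code{tLigand},
#' ligand-induced from \code{tLigand}, and transcription-blocked (initiation
#' shut off, emulating DRB) from \code{tBlock} if given.  All times in
#' minutes.
#'
#' @slot tLigand numeric, time of ligand addition (min).
#' @slot tBlock numeric, time of transcription block (min); \code{NA_real_}
#'   if no block is applied.
#' @slot tEnd numeric, final simulated time (min).
#' @export
setClass("Protocol",
  representation(tLigand = "numeric", tBlock = "numeric", tEnd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@tLigand < 0 || object@tLigand >= object@tEnd)
      msg <- c(msg, "need 0 <= tLigand < tEnd")
    if (!is.na(object@tBlock) &&
        (object@tBlock < object@tLigand || object@tBlock >= object@tEnd))
      msg <- c(msg, "need tLigand <= tBlock < tEnd")
    if (length(msg)) msg else TRUE
  })

#' Simulated model trajectory
#'
#' @slot times numeric, ordered output grid (min).
#' @slot states matrix, one row per time, named state columns.
#' @slot observables data.frame with columns \code{time_min}, \code{pre},
#'   \code{mature} (copies/cell).
#' @slot spec the \code{ModelSpec} that generated the trajectory.
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix",
                 observables = "data.frame", spec = "ModelSpec"))

#' Replicate RNA time-course observations
#'
#' One measured series (one species, one protocol) with biological
#' replicates, in long form.  Weights are per time point; when empty they
#' are derived from the replicate SEM with a 5\%-of-mean floor (see
#' \code{\link{replicateSummary}}).
#'
#' @slot label character, e.g. \code{"induction-pre"}.
#' @slot species \code{"pre"} or \code{"mature"}.
#' @slot observations data.frame with columns \code{time_min},
#'   \code{replicate}, \code{value} (copies/cell).
#' @slot weights numeric, one positive weight per unique time point (may be
#'   empty, meaning "derive from replicate scatter").
#' @slot protocol a \code{Protocol}.
#' @slot scaleCorrection numeric, multiplicative factor applied on load
#'   (e.g. the 0.4 correction reconciling decay- and induction-series
#'   copy-number calibrations).
#' @export
setClass("TimeCourseDataset",
  representation(label = "character", species = "character",
                 observations = "data.frame", weights = "numeric",
                 protocol = "Protocol", scaleCorrection = "numeric"),
  validity = function(object) {
    msg <- character()
    obs <- object@observations
    if (!all(c("time_min", "replicate", "value") %in% names(obs)))
      msg <- c(msg, "observations needs columns time_min, replicate, value")
    if (!(object@species %in% c("pre", "mature")))
      msg <- c(msg, "species must be 'pre' or 'mature'")
    if (nrow(obs) && any(obs$time_min < 0))
      msg <- c(msg, "times must be non-negative")
    tu <- unique(obs$time_min)
    if (is.unsorted(tu))
      msg <- c(msg, "time points must be sorted")
    if (length(object@weights) &&
        (length(object@weights) != length(tu) || any(object@weights <= 0)))
      msg <- c(msg, "weights must be positive, one per unique time point")
    if (object@scaleCorrection <= 0)
      msg <- c(msg, "scaleCorrection must be positive")
    if (length(msg)) msg else TRUE
  })

#' A weighted least-squares fitting problem
#'
#' @slot spec the \code{ModelSpec} being fitted.
#' @slot reference a full \code{RateConstants}; parameters not in
#'   \code{free} stay pinned at these values.
#' @slot free character, names of the free parameters (subset of the eight
#'   rate constants plus \code{"f_basal"}).
#' @slot bounds 2-row matrix (\code{lower}, \code{upper}) of finite positive
#'   linear-scale bounds, one column per free parameter; optimization runs
#'   in log10 space inside these boxes.
#' @slot datasets list of \code{TimeCourseDataset} used by the objective.
#' @slot validation list of \code{TimeCourseDataset} whose residuals are
#'   tracked but never enter the objective.
#' @export
setClass("FitProblem",
  representation(spec = "ModelSpec", reference = "RateConstants",
                 free = "character", bounds = "matrix",
                 datasets = "list", validation = "list"),
  validity = function(object) {
    msg <- character()
    if (!all(object@free %in% .ALL_PARAMS))
      msg <- c(msg, "free parameters must be rate constants or f_basal")
    b <- object@bounds
    if (!is.numeric(b) || nrow(b) != 2L || ncol(b) != length(object@free) ||
        any(!is.finite(b)) || any(b[1, ] >= b[2, ]) || any(b[1, ] <= 0))
      msg <- c(msg, "bounds must be finite, positive, lower < upper, one column per free parameter")
    if (!length(object@datasets))
      msg <- c(msg, "at least one fitting dataset is required")
    if (length(msg)) msg else TRUE
  })

#' Result of a (re)fit
#'
#' @slot par named numeric, the full parameter vector (eight rates plus
#'   \code{f_basal}) at the optimum.
#' @slot objective numeric, minimized weighted sum of squared residuals.
#' @slot residuals list of per-dataset weighted residual vectors.
#' @slot validationResiduals list, same for held-out datasets.
#' @slot trace data.frame with columns \code{eval}, \code{best} (best-so-far
#'   objective; non-increasing).
#' @slot seed integer seed that drove the optimizer.
#' @slot free character, which parameters were free.
#' @export
setClass("FitResult",
  representation(par = "numeric", objective = "numeric",
                 residuals = "list", validationResiduals = "list",
                 trace = "data.frame", seed = "integer", free = "character"))

#' Result of a single-parameter perturbation scan
#'
#' @slot table data.frame, one row per scanned parameter: refit value,
#'   reference value, fold change, overall objective and the pre/mature
#'   split.
#' @slot best character, name of the parameter whose single refit minimizes
#'   the overall objective.
#' @slot percentInhibition numeric, \code{100 * (1 - refit/reference)} for
#'   the best parameter (negative when the refit increased it).
#' @slot pairwise data.frame, pairwise-refinement table (empty until
#'   \code{\link{refinePairwise}} is run).
#' @slot reference named numeric, the unperturbed parameter vector.
#' @slot scales list of fitted per-series scale factors (apparent
#'   fold-induction adjustment), one per dataset.
#' @slot nullObjective numeric, objective at the unscanned reference
#'   (scales fitted, parameters untouched).
#' @export
setClass("ScanResult",
  representation(table = "data.frame", best = "character",
                 percentInhibition = "numeric", pairwise = "data.frame",
                 reference = "numeric", scales = "list",
                 nullObjective = "numeric"))
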