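#' Write datasets as tidy delimited text with a YAML manifest
#'
#' Each dataset becomes \code{<label>.tsv} with columns \code{time_min},
#' \code{species}, \code{replicate}, \code{copies_per_cell}; the manifest
#' records file, species, protocol and scale correction per dataset.
#'
#' @param datasets named list of \code{\link{TimeCourseDataset}}.
#' @param dir output directory (created if missing).
#' @param manifest manifest file name.
#' @return the manifest path, invisibly.
#' @export
writeDatasets <- function(datasets, dir, manifest = "manifest.yaml") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (d in datasets) {
    fn <- paste0(d@label, ".tsv")
    obs <- d@observations
    utils::write.table(
      data.frame(time_min = obs$time_min, species = d@species,
                 replicate = obs$replicate, copies_per_cell = obs$value),
      file.path(dir, fn), sep = "\t", row.names = FALSE, quote = FALSE)
    entries[[d@label]] <- list(
      file = fn, species = d@species,
      protocol = list(t_ligand = d@protocol@tLigand,
                      t_block = if (is.na(d@protocol@tBlock)) NULL
                                else d@protocol@tBlock,
                      t_end = d@protocol@tEnd),
      scale_correction = d@scaleCorrection)
  }
  path <- file.path(dir, manifest)
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Read datasets from a YAML manifest
#'
#' Inverse of \code{\link{writeDatasets}}.  The manifest's
#' \code{scale_correction} is NOT re-applied to the stored values (they
#' were written post-correction); it is carried as metadata.
#'
#' @param manifestPath path to the manifest.
#' @return named list of \code{\link{TimeCourseDataset}}.
#' @export
readDatasets <- function(manifestPath) {
  entries <- yaml::read_yaml(manifestPath)
  dir <- dirname(manifestPath)
  out <- list()
  for (label in names(entries)) {
    e <- entries[[label]]
    tab <- utils::read.table(file.path(dir, e$file), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    prot <- protocol(tLigand = e$protocol$t_ligand,
                     tBlock = if (is.null(e$protocol$t_block)) NA_real_
                              else e$protocol$t_block,
                     tEnd = e$protocol$t_end)
    ds <- timeCourseDataset(label, e$species,
                            data.frame(time_min = tab$time_min,
                                       replicate = tab$replicate,
                                       value = tab$copies_per_cell),
                            prot)
    ds@scaleCorrection <- as.numeric(e$scale_correction)
    out[[label]] <- ds
  }
  out
}

#' Write a trajectory as tidy delimited text
#'
#' Columns \code{time_min}, \code{species}, \code{value} (UTF-8, "."
#' decimal).
#'
#' @param trajectory a \code{\link{Trajectory}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  ob <- observables(trajectory)
  tidy <- rbind(
    data.frame(time_min = ob$time_min, species = "pre", value = ob$pre),
    data.frame(time_min = ob$time_min, species = "mature", value = ob$mature))
  utils::write.table(tidy, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.CONFIG_KEYS <- c("variant", "rates", "f_basal", "protocol", "optimizer",
                  "noise", "calibration", "fold_target", "perturbation",
                  "stages")

#' Read a run configuration
#'
#' YAML configuration for \code{\link{runPipeline}} with keys
#' \code{variant}, \code{rates}, \code{f_basal}, \code{protocol}
#' (\code{t_ligand}, \code{t_block}, \code{t_end}), \code{optimizer}
#' (\code{population}, \code{max_evals}, \code{seed}), \code{noise}
#' (\code{cv}, \code{replicates}, \code{outlier_rate}), \code{calibration},
#' \code{fold_target}, \code{perturbation} (\code{parameter},
#' \code{factor}) and \code{stages}.  Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Write a run configuration
#'
#' @param config configuration list (validated against the known keys).
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

.cfgRates <- function(config) {
  r <- referenceRates()
  if (!is.null(config$rates)) r <- updateRates(r, unlist(config$rates))
  if (!is.null(config$f_basal)) r <- rateConstants2(r, f_basal = config$f_basal)
  r
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in order: \code{generate} (induction + decay series
#' from the configured model), \code{fit} (induction pre/mature and decay
#' pre, with decay mature held out for validation), \code{compare} (variant
#' discrimination table), \code{identify} (identifiability report at the
#' fit optimum) and \code{scan} (perturbation localization on a synthetic
#' series generated under the configured perturbation).  Artifacts are
#' written under \code{outDir}: \code{fit.json}, \code{comparison.csv},
#' \code{report.json}, \code{scan.json}, plus the generated data as tidy
#' TSV with a manifest.  Every artifact records the root seed.  A stage
#' subset can be requested via \code{config$stages}; stages depending on a
#' missing artifact fail with a dependency error.
#'
#' @param config configuration list (see \code{\link{readRunConfig}}).
#' @param outDir output directory.
#' @return named list of artifact paths, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  if (is.null(stages))
    stages <- c("generate", "fit", "compare", "identify", "scan")
  spec <- modelSpec(if (is.null(config$variant)) "n5" else config$variant)
  ratesCfg <- .cfgRates(config)
  opt <- config$optimizer
  seed <- as.integer(if (is.null(opt$seed)) 1L else opt$seed)
  settings <- crsSettings(
    populationSize = opt$population,
    maxEvals = if (is.null(opt$max_evals)) 3000 else opt$max_evals,
    seed = seed)
  nm <- if (is.null(config$noise)) noiseModel() else
    noiseModel(cv = config$noise$cv %||% 0.2,
               replicates = config$noise$replicates %||% 6L,
               outlierRate = config$noise$outlier_rate %||% 0.02)
  foldTarget <- config$fold_target %||% 2.5
  artifacts <- list()
  manifestPath <- file.path(outDir, "data", "manifest.yaml")

  if ("generate" %in% stages) {
    gen <- generateExperiment(spec, ratesCfg, decayTimes = seq(0, 300, 15),
                              noise = nm, foldTarget = foldTarget,
                              seed = seed)
    writeDatasets(gen$datasets, file.path(outDir, "data"))
    jsonlite::write_json(
      list(seed = seed, rates = as.list(parameterVector(gen$rates)),
           species_factors = as.list(gen$speciesFactors)),
      file.path(outDir, "data", "generator.json"), auto_unbox = TRUE,
      digits = NA)
    artifacts$data <- manifestPath
  }
  needData <- function() {
    if (!file.exists(manifestPath))
      stop("stage dependency error: generated data not found; run the 'generate' stage first")
    readDatasets(manifestPath)
  }
  fitPath <- file.path(outDir, "fit.json")
  if ("fit" %in% stages) {
    ds <- needData()
    fitSet <- ds[c("induction-pre", "induction-mature", "decay-pre")]
    valSet <- ds["decay-mature"]
    prob <- fitProblem(spec, ratesCfg, fitSet, validation = valSet)
    fit <- fitModel(prob, settings)
    jsonlite::write_json(
      list(seed = seed, variant = spec@variant,
           par = as.list(fit@par), objective = fit@objective,
           validation_ssr = sum(unlist(fit@validationResiduals)^2)),
      fitPath, auto_unbox = TRUE, digits = NA)
    artifacts$fit <- fitPath
  }
  readFit <- function() {
    if (!file.exists(fitPath))
      stop("stage dependency error: fit.json not found; run the 'fit' stage first")
    f <- jsonlite::read_json(fitPath)
    unlist(f$par)
  }
  if ("compare" %in% stages) {
    ds <- needData()
    cmp <- compareVariants(ds[c("induction-pre", "induction-mature", "decay-pre",
                                "decay-mature")],
                           variants = c("n0", "n2", "n5"),
                           settings = settings, reference = ratesCfg,
                           seed = seed)
    utils::write.csv(cmp$table, file.path(outDir, "comparison.csv"),
                     row.names = FALSE)
    artifacts$comparison <- file.path(outDir, "comparison.csv")
  }
  if ("identify" %in% stages) {
    ds <- needData()
    par <- readFit()
    prob <- fitProblem(spec, ratesCfg,
                       ds[c("induction-pre", "induction-mature", "decay-pre")])
    rep <- identifiabilityReport(par, prob)
    jsonlite::write_json(
      list(seed = seed, intervals = rep$intervals,
           correlation = rep$correlation, ssr = rep$ssr,
           n_points = rep$nPoints),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
    artifacts$report <- file.path(outDir, "report.json")
  }
  if ("scan" %in% stages) {
    par <- readFit()
    pert <- config$perturbation
    pname <- pert$parameter %||% "k_spl"
    pfactor <- pert$factor %||% 0.25
    genRates <- updateRates(.cfgRates(config), par)
    pertRates <- updateRates(genRates,
                             setNames(parameterVector(genRates)[pname] * pfactor,
                                      pname))
    genP <- generateExperiment(spec, pertRates, calibration = NULL,
                               noise = nm, seed = seed + 1L)
    scan <- scanPerturbation(par, spec, genP$datasets)
    scan <- refinePairwise(scan, spec, genP$datasets)
    jsonlite::write_json(
      list(seed = seed, best = scan@best,
           percent_inhibition = scan@percentInhibition,
           table = scan@table, pairwise = scan@pairwise),
      file.path(outDir, "scan.json"), auto_unbox = TRUE, digits = NA)
    artifacts$scan <- file.path(outDir, "scan.json")
  }
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
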