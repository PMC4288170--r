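## shared fixtures: the n = 5 reference model calibrated to the measured
## baselines (18 mature / 1.1 pre copies per cell, 2.5-fold induction)

refSpec <- modelSpec("n5")

## calibrated generator rates (k_ini and f_basal adjusted once, reused)
refCalibrated <- generateExperiment(refSpec, referenceRates(), seed = 1)$rates
refTruth <- parameterVector(refCalibrated)

## induction + decay replicate datasets sampled from the calibrated model
## without per-species calibration distortion (clean recovery studies)
makeStudyData <- function(seed, cv = 0.2, replicates = 6L,
                          decay = TRUE, outlierRate = 0.02) {
  generateExperiment(refSpec, refCalibrated,
                     decayTimes = if (decay) seq(0, 300, by = 15) else NULL,
                     calibration = NULL,
                     noise = noiseModel(cv = cv, replicates = replicates,
                                        outlierRate = outlierRate),
                     seed = seed)$datasets
}

## splicing-inhibition style perturbed induction data (CV 0.3, 4 replicates)
makePerturbedData <- function(seed, parameter = "k_spl", factor = 0.25,
                              cv = 0.3, replicates = 4L) {
  pert <- updateRates(refCalibrated,
                      setNames(refTruth[parameter] * factor, parameter))
  generateExperiment(refSpec, pert, calibration = NULL,
                     noise = noiseModel(cv = cv, replicates = replicates),
                     seed = seed)$datasets
}

## exact (noiseless) dataset pair built directly from the model observables
makeNoiselessData <- function(rates = refCalibrated, times = seq(0, 225, 15),
                              spec = refSpec) {
  prot <- protocol(tLigand = 0, tEnd = max(times))
  ob <- observables(simulate(spec, rates, prot, times))
  list(
    pre = timeCourseDataset("noiseless-pre", "pre",
                            matrix(ob$pre, ncol = 1), prot, times = times),
    mature = timeCourseDataset("noiseless-mature", "mature",
                               matrix(ob$mature, ncol = 1), prot,
                               times = times))
}
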