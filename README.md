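# txcycle

Kinetic modelling of mRNA transcription dynamics for noisy qPCR time-course
data, and inference of *which* molecular process a perturbation hits.

Changes in mRNA levels after a stimulus can originate at many points:
transcription-factor binding, promoter/chromatin cycling, initiation,
elongation, splicing, 3' processing or degradation. Given replicate
time courses of just two observables — intron-containing pre-mRNA and mature
polyadenylated mRNA, in copies per cell — `txcycle` fits a mechanistic
ODE model of the whole production line and then localizes a perturbation by
asking which single rate constant must change to explain the perturbed data.
The package is aimed at systems-biology analysts working with
ligand-induction and transcription-inhibition time courses of a single gene
(the motivating system is a nuclear-receptor target gene in hepatoma cells),
and at methodologists who want a fully synthetic, seedable benchmark of the
whole pipeline.

## The model

The gene's regulatory region moves irreversibly through a promoter cycle of
three phases — induction, active, inactive — each resolved into *n*
identical first-order sub-states (the retained variant has *n* = 5, i.e. 15
promoter states):

```
rev_n -> act_1 -> ... -> act_n -> dea_1 -> ... -> dea_n -> rev_1 -> ... -> rev_n
 (k_rev)      (k_act)                  (k_dea)                 (k_rev)
```

Every "active-phase" state transcribes: initiation injects polymerases at
rate `k_ini * sum(dea_i)` into sequential first-order chains for elongation
(`k_elo`), splicing (`k_spl`), 3' processing (`k_mat`) and degradation
(`k_deg`), *n* sub-states each. An *n*-step chain with per-step rate *k* has
Erlang(*n*, *k*) transit times with mean *n*/*k* (the "characteristic
time"), which is what produces the observed delays — mature mRNA responds
about an hour after pre-mRNA. Observables: pre-mRNA = total occupancy of
the splicing chain, mature mRNA = total occupancy of the degradation chain.
Ligand acts on the first two activation transitions (scaled by `f_basal`
before ligand addition); a transcription block (DRB) sets the initiation
rate to zero.

On top of the model sit:

* **weighted least-squares fitting** with a Controlled Random Search (CRS)
  global optimizer in log10 parameter space (`fitModel`, `crsMinimize`);
* **model discrimination** across seven variants (*n* = 0, 2, 1, 3, 5, 10,
  20) by SSR, corrected AIC, runs tests and an oscillation flag
  (`compareVariants`, `aicc`, `runsTest`);
* **identifiability analysis**: residual sensitivities, Fisher information,
  dependent (conditional) vs independent (marginal) confidence intervals,
  parameter correlations (`identifiabilityReport`);
* **perturbation localization**: single-parameter refit scan with an
  apparent-fold-induction adjustment, pairwise refinement with nested
  F-tests, robustness checks (`scanPerturbation`, `refinePairwise`,
  `robustnessCheck`);
* a **synthetic qPCR experiment generator** with multiplicative log-normal
  replicate noise, outlier injection, MAD outlier filtering and
  Ct/copy-number conversions (`generateExperiment`, `madOutlierFilter`,
  `foldFromCt`, `copiesFromStandardCurve`).

## Worked example

Simulate the fitted five-sub-state model under ligand induction, then
recover a synthetic splicing inhibition:

```r
library(txcycle)
spec  <- modelSpec("n5")
rates <- referenceRates()          # fitted rate constants, min^-1

tr <- simulate(spec, rates, protocol(tLigand = 0, tEnd = 225), seq(0, 225, 45))
observables(tr)
#>   time_min       pre   mature
#> 1        0 0.9862597 20.19860
#> 2       45 2.5639438 20.35043
#> 3       90 2.3144606 24.85928
#> 4      135 2.3285751 30.93045
#> 5      180 2.3304558 36.37893
#> 6      225 2.3302740 40.66989

characteristicTime(rates(rates)[["k_spl"]], 5)   # mean splicing time, min
#> [1] 9.765625
halvingTimeOfDegradation(rates, spec) / 60       # mature half-life, h
#> [1] 3.113939
```

Pre-mRNA (~1 copy/cell basally) responds within tens of minutes and
saturates ~2.4-fold; mature mRNA (~20 copies/cell) follows with a delay of
about an hour. The splicing chain turns over in ~10 min and a mature-mRNA
cohort decays with a ~3 h half-life.

```r
# reference experiment -> truth; perturbed experiment with k_spl / 4
exper     <- generateExperiment(spec, rates, seed = 1,
                                noise = noiseModel(cv = 0.3, replicates = 4))
truth     <- parameterVector(exper$rates)
perturbed <- updateRates(exper$rates, c(k_spl = truth[["k_spl"]] / 4))
ds   <- generateExperiment(spec, perturbed, calibration = NULL,
                           noise = noiseModel(cv = 0.3, replicates = 4),
                           seed = 2)$datasets
scan <- scanPerturbation(truth, spec, ds)
scan
#> ScanResult: best single-parameter refit = k_spl (71.2% inhibition)
#>   parameter reference     refit fold_change objective ...
#> 1     k_spl     0.512   0.14752      0.2881     230.8
#> 2     k_deg     0.025   0.12217      4.8867     355.7
#> 3     k_mat     0.161   0.03417      0.2123    1312.1
#> ...
```

The scan refits one rate constant at a time against the perturbed data:
only the splicing rate restores the fit (objective 231 vs >= 356 for every
other parameter), correctly naming splicing as the perturbed process and
estimating ~71% inhibition for this draw (truth: 75%).

## Further reading

The methods vignette (`vignettes/txcycle-methods.Rmd`) documents the model
assumptions, the regime conventions for the reduced variants, the weighting
scheme, the CRS variant implemented here, the identifiability conventions
and the known limitations of the synthetic benchmark.
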