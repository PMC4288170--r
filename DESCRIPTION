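Package: txcycle
Title: Multi-State Promoter-Cycle Kinetics of mRNA Transcription Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Kinetic modelling of mRNA transcription dynamics with a
    multi-state promoter cycle feeding Erlang-type elongation, splicing,
    maturation and degradation chains. Provides exact piecewise-linear ODE
    simulation under ligand-induction and transcription-block protocols, a
    Controlled Random Search global optimizer for weighted least-squares
    parameter estimation, corrected-AIC and runs-test model discrimination
    across model variants, Fisher-information identifiability analysis with
    dependent and independent confidence intervals, a single-parameter refit
    scan that localizes the molecular site of a perturbation from time-course
    data, and a seedable generator of qPCR-like replicate time courses with
    copy-number calibration and MAD outlier filtering.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, deSolve, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SystemsBiology, TimeCourse, GeneExpression, Transcription
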