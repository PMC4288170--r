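---
title: "txcycle: model, estimation and perturbation-localization methods"
author: "txcycle maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txcycle: model, estimation and perturbation-localization methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcycle)
```

# The model family

`txcycle` describes the mRNA life cycle of a single ligand-inducible gene
with mass-action ODEs. The full variants (`n1`, `n3`, `n5`, `n10`, `n20`)
share one architecture, differing only in the number of sub-states $n$ per
process:

* a **promoter cycle** of three phases — induction ($x^{act}_{1..n}$,
  per-step rate $k_{act}$), active ($x^{dea}_{1..n}$, rate $k_{dea}$) and
  inactive ($x^{rev}_{1..n}$, rate $k_{rev}$) — traversed irreversibly and
  closed by the inflow $k_{rev}\,x^{rev}_n \to x^{act}_1$. Total promoter
  occupancy is conserved (gene dosage, normalized to 1; dosage is absorbed
  into $k_{ini}$ so RNA pools carry copies/cell units).
* **initiation**: every active-phase state transcribes equally, injecting
  flux $k_{ini}\sum_i x^{dea}_i$ into the first elongation state.
* four sequential **RNA chains** — elongation ($k_{elo}$), splicing
  ($k_{spl}$), 3' processing ($k_{mat}$), degradation ($k_{deg}$) — of $n$
  identical first-order steps each, with terminal loss
  $k_{deg}\,x^{mat}_n$.

A chain of $n$ identical first-order steps gives an Erlang$(n, k)$ transit
time with mean $n/k$ — the *characteristic time* reported by
`characteristicTime()`. These distributed delays are the point of the
architecture: a single-step model responds instantaneously, while the
measured mature mRNA lags the pre-mRNA by about an hour.

**Observables.** The measured pre-mRNA is the intron-1-containing species,
detectable from the moment the polymerase passes the intron-spanning
amplicon until the first intron is excised: it is mapped to the total
occupancy of the splicing chain, $\sum_i x^{spl}_i$. The elongation chain
represents polymerases that escaped the TSS but have not yet reached the
amplicon, and the processing chain represents downstream elongation and 3'
processing, both invisible to the two qPCR assays. Mature polyadenylated
mRNA is the degradation-chain total $\sum_i x^{mat}_i$. Whether part of the
elongation chain should contribute to the pre-mRNA signal is not decidable
from the data; the mapping above is one defensible choice and is kept
fixed.

**Regimes and protocols.** A `protocol()` divides time into at most three
piecewise-constant regimes: *basal* (before ligand), *induced*, and
*blocked* (after a transcription-block such as DRB). Ligand acts on the
first `ligandSensitiveSteps` (default 2) activation transitions, which run
at $f_{basal} k_{act}$ basally and $k_{act}$ after induction. DRB is
modelled purely as $k_{ini} \to 0$: elongation, splicing, processing and
degradation continue, which is what produces the observed few-minute delay
then ~10-min collapse of pre-mRNA and the ~1 h delay before mature decay.
The initial state is always the basal steady state.

$f_{basal}$ replaces unavailable fitted initial conditions: it is a single
dimensionless knob in $[0,1]$ setting the basal/induced flux ratio.
`solveBasalActivity()` inverts it from a target steady-state induction fold
(default 2.5, the centre of the measured 2–3-fold induction).

**Reduced variants.** `n0` (two states) is a constitutively transcribing
source feeding a pre pool ($k_{spl}$) and a mature pool ($k_{deg}$); `n2`
(five states) adds a two-step promoter activation ($k_{act}$) in front of
the same pools. Since `n0`/`n2` lack the damped activation transitions of
the full design, the ligand-sensitive quantity is taken to be the
initiation flux itself: production runs at $f_{basal} k_{ini}$ basally and
$k_{ini}$ when fully induced, and `n2` additionally holds its activation
steps frozen until ligand addition (promoter initially inactive). This
keeps a well-defined, non-degenerate basal steady state in every variant
with the quoted state counts.

# Numerics

The system is linear with piecewise-constant coefficients, so each regime
segment is propagated **exactly** by matrix exponentials (`Matrix::expm`),
one exponential per distinct step size, with event times as segment
boundaries (state-continuous switching). Eigendecomposition is not an
option — the chain blocks have repeated eigenvalues and are defective. An
independent adaptive route (`simulate(..., method = "lsoda")`, stiff-capable,
default `rtol = 1e-8`, `atol = 1e-12`) exists purely as a cross-check; the
test suite requires the two routes to agree to a relative $10^{-6}$ (with a
floor of $10^{-4}$ copies/cell, far below one molecule, so states beneath
the integrator's absolute tolerance cannot dominate the comparison).
Steady states are computed in closed form: a unidirectional cycle puts
occupancy $\propto 1/\text{rate}$ on each promoter stage, and every RNA
chain state holds $J/k$ where $J$ is the steady initiation flux — giving
the pool identity $\text{pool} = J\,n/k$ used as an oracle throughout.

# Fitting

**Data and weights.** Replicates are collapsed per time point to
MAD-filtered means (values beyond $3 \times 1.4826 \times \text{MAD}$ of
the median are dropped, mirroring the outlier correction applied to the
real qPCR data). Weights are $w_t = 1/\max(\text{SEM}_t,\;0.05\,
\bar{y}_t,\;0.01)^2$: the 5%-of-mean floor prevents infinite weight at
zero-variance points, and the absolute floor of 0.01 copies/cell encodes
the qPCR quantification limit so that deeply decayed points (formally
$10^{-12}$ copies/cell in a noiseless model) cannot dominate the
objective. The objective is the weighted sum of squared differences
between replicate means and the simulated observable under each dataset's
own protocol; datasets sharing a protocol share one simulation per
evaluation. A `scaleCorrection` attribute per dataset reproduces
calibration reconciliations such as the 0.4 factor applied to the
pre-mRNA decay series of the original data.

**Optimizer.** Rates span four orders of magnitude, so optimization runs in
log10 space inside a default box of $[10^{-4}, 10^2]\ \text{min}^{-1}$
($[10^{-4}, 1]$ for $f_{basal}$). The global stage is a Controlled Random
Search in the CRS2 family: a population (default $10(d+1)$) of points;
each iteration proposes either a reflection of a random member through the
centroid of a random simplex (probability 0.7) or a coordinate-wise
mutation around the current best scaled by the population spread
(probability 0.3); an improving trial replaces the worst member. Two
further moves address failure modes we observed on this model class:
inside the mutation move, one coordinate is redrawn uniformly over its
bounds with probability 0.25 (a single rate pinned at a bound — e.g.
$k_{mat}$ collapsed to $10^{-4}$, silencing the mature observable — can
otherwise trap the entire population on a "dead output" plateau), and when
the population spread falls below $10^{-3}$ of the box with budget
remaining, all but the best tenth of the members are resampled (diversity
restart). The search is deterministic given its seed, the best-so-far
trace is non-increasing, and an optional deterministic Nelder–Mead polish
(off by default) refines the CRS optimum. The published analysis this
package re-implements also used a performance-modified CRS; its
modification is not documented, so the variant above is this package's
own and is fixed here.

**Refits.** `refitSingle()` is the 1-D building block of the perturbation
scan: a log-spaced grid (default 25 points) over the parameter's box
followed by golden-section refinement of the best bracket — global,
deterministic and cheap.

# Model discrimination

`compareVariants()` fits each variant to identical data and weights with
one optimizer budget (per-variant seeds derived from a shared root seed)
and reports: the minimized weighted SSR; the corrected AIC
$N\ln(\text{SSR}/N) + 2K + 2K(K+1)/(N-K-1)$ (the small-sample term
matters at $N \approx 70$, $K \le 9$; plain AIC is a switch); a
Wald–Wolfowitz runs test on each residual series (too few sign runs flag
systematic misfit; the all-one-sign case has exactly one run with
probability 1, which is reported as the exact p); and an oscillation flag.
Parameter counts are $K = 4$ (`n0`), 5 (`n2`) and 9 (full variants),
counting $f_{basal}$. The oscillation flag operationalizes the visual
screening that disqualifies deep-chain variants: any adjacent local
extremum pair of the fitted noiseless mature curve with relative amplitude
above 5% raises it.

# Identifiability

At a fit optimum, `sensitivities()` takes central finite differences of
the $\sqrt{w}$-scaled residual vector with respect to log10 parameters
(step $10^{-4}$, chosen by step-halving stability), so the Fisher
information is simply $S^\top S$. With $s^2 = \text{SSR}/(N-K)$ and the
appropriate $t$ quantile, the **dependent** (conditional; all other
parameters fixed) half-width of parameter $i$ is
$t\,s\sqrt{1/F_{ii}}$ and the **independent** (marginal; others free to
compensate) half-width is $t\,s\sqrt{(F^{-1})_{ii}}$. Cauchy–Schwarz
guarantees independent $\ge$ dependent; a large ratio flags
co-dependence. Note the naming follows the empirical usage of the source
analysis — parts of the literature attach these words the other way
around. The confidence level (default 95%) is a knob; the scientifically
stable claim is the *ordering*: chain rates ($k_{elo}, k_{spl}, k_{mat},
k_{deg}$) have ratios near 1 while $k_{rev}, k_{dea}, k_{ini}$ (and, less
strongly, $k_{act}$) have ratios of tens to hundreds — on synthetic data
the package reproduces exactly this split. `sensitivityProfile()`
complements the local picture with objective-vs-perturbation curves,
including joint scaling of compensating pairs such as
$(k_{ini}, k_{dea})$, which approximately preserves the production flux
and exposes the promoter-parameter degeneracy.

# Perturbation localization

`scanPerturbation()` is the headline method. Given reference parameters
fitted to unperturbed data and a perturbed time course, it refits **one
parameter at a time** (others pinned) and ranks refits by overall weighted
SSR; the winner names the perturbed process and
$100(1-\text{refit}/\text{reference})$ quantifies the inhibition. The
pre/mature objective split is reported for diagnostics only.

**Fold-induction adjustment.** Inhibitor treatments depress overall
induction non-specifically, so a free multiplicative scale is fitted
alongside each refit (closed form at every evaluation). We deliberately
use **one scale shared across the pre and mature series** rather than one
per series: the strongest signature of a splicing block is the *relative*
elevation of pre-mRNA over mature mRNA, and per-series scales absorb
exactly that signal (in trial runs they made the scan prefer an elongation
slowdown over the true splicing inhibition). Per-series scaling remains
available (`fitScales = "per-series"`), as does none.

`refinePairwise()` then frees each remaining parameter together with the
winner (grid-seeded Nelder–Mead in log10 space) and applies a nested
F-test on the weighted SSR with $(1, N-2)$ degrees of freedom at
$\alpha = 0.05$, uncorrected for the multiplicity across candidate second
parameters — the refinement is exploratory, and with seven candidate
second parameters occasional nominal positives are expected and are so
documented in the report. `robustnessCheck()` re-runs the scan after
perturbing each reference parameter (and, optionally, co-dependent pairs
scaled jointly); instability under flux-preserving promoter perturbations
is flagged rather than failed, since promoter-level sites (e.g.
initiation vs deactivation) are not mutually distinguishable from these
data.

# The synthetic-data generator

`generateExperiment()` emulates the real experimental designs: a
ligand-induction series (0–225 min, 15-min sampling) and a
transcription-block decay series (block after 180 min of induction;
default grid 0–300 min post-block). Defaults encode the measured study
conditions: multiplicative log-normal replicate noise (qPCR errors are
fold-errors) with CV 0.2 and 6 replicates for induction experiments, CV
0.3 and 4 replicates for the inhibitor experiment; spurious $\times[2,5]$
outlier replicates at rate 0.02 to exercise the MAD filter; baselines of
1.1 pre-mRNA and 18 mature-mRNA copies/cell; 2.5-fold steady-state
induction.

**Calibration.** The basal mature/pre ratio of the model is pinned by the
kinetics at $k_{spl}/k_{deg} \approx 20.5$, whereas the measured baselines
give $18/1.1 \approx 16.4$ — the two baselines are not jointly reachable
by any choice of $k_{ini}$ and $f_{basal}$ (both scale all RNA pools
equally). The generator therefore matches the mature baseline exactly
through $k_{ini}$, sets $f_{basal}$ from the induction-fold target, and
matches the pre-mRNA baseline with a recorded per-species calibration
factor — mirroring the fact that the two real amplicons were converted to
copies/cell by independent standard curves with acknowledged conversion
error. `calibration = NULL` disables all rescaling for clean
parameter-recovery studies.

**What it does not emulate.** Replicates are independent across time
points; the real data hint at replicate-level timing irreproducibility
(dynamics shifted between biological replicates), for which an optional
per-replicate time jitter exists but defaults to off because its magnitude
is unknown. No PCR chemistry (primer efficiencies, melt behaviour), no
single-cell stochasticity (the model is a population-average ODE; burst
sizes are out of scope), no detection censoring — the quantification limit
enters only through the weight floor. Consequently, passing recovery tests
demonstrates the *inference machinery* under the stated noise structure,
not robustness to every pathology of real qPCR data.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything on synthetic data
at the study conditions: induction 0–225 min at 15-min sampling (16
points/series), decay 0–300 min post-block (21 points/series),
perturbation scans over 8 rate constants with 20 seeded inhibitor
experiments, model discrimination over 10 seeded datasets with a 5000-
evaluation CRS budget per variant, and chain-rate recovery over 10 seeded
fits with 2000 evaluations plus polish. All randomness flows from
explicit integer seeds; the generator, optimizer and pipeline are
bit-reproducible given them.

# Known limitations

* The promoter-side rates ($k_{act}, k_{dea}, k_{rev}, k_{ini}$) are
  structurally co-dependent; only their combinations are well determined,
  and perturbations at the promoter level cannot be localized to a single
  constant.
* $f_{basal}$ is a phenomenological stand-in for unknown basal initial
  conditions; it trades off against $k_{ini}$ and the promoter constants.
* The degradation chain imposes an Erlang lifetime on mature mRNA; the
  implied half-life (~3 h at the reference rates, `halvingTimeOfDegradation()`)
  is shorter than a naive single-exponential fit to delayed decay data
  would suggest, which is precisely why delay-aware fitting matters.
* AIC comparisons assume identical data and weights across variants; the
  comparison table records one fixed weighting for all.
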