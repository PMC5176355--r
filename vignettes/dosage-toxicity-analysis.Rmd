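---
title: "Quantifying gene-dosage toxicity through mass-action sequestration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-dosage toxicity through mass-action sequestration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosetox)
```

## The problem

Overexpressing an enzyme far above its physiological copy number can be
toxic even when the extra catalytic activity itself is harmless. One
mechanism is *sequestration*: a hub enzyme engages functionally related
partners through weak, transient protein-protein interactions (dissociation
constants in the low micromolar range). At physiological abundances (tens
to hundreds of copies per cell, i.e. nanomolar concentrations) only a few
percent of either species is complexed at any instant. Raise the hub a
thousand-fold and simple mass action drives its partners almost entirely
into complexes, depleting their free, catalytically active pools and
unbalancing the downstream metabolic pathways they serve.

`dosetox` packages the quantitative stages of such an analysis: the
equilibrium model itself, the *in vitro* curve fits that supply its
parameters (SPR binding, enzyme kinetics), the *in vivo* readouts
(growth-curve fitness, co-IP interactomes, metabolite pools), and seeded
generators that produce synthetic versions of every input with recorded
ground truth.

## The sequestration model

For a hub at total concentration $D$ and a single partner at total $P$
binding 1:1 with dissociation constant $K$, mass action plus conservation
give the complex concentration as the smaller root of

$$c^2 - (D + P + K)\,c + DP = 0 ,$$

the only root in $[0, \min(D, P)]$. `solve_pairwise()` evaluates it as
$c = 2DP / \big(b + \sqrt{b^2 - 4DP}\big)$ with $b = D+P+K$, which is
algebraically identical but avoids the catastrophic cancellation of the
textbook form when $4DP \ll b^2$ — exactly the physiological regime, where
totals are nanomolar and $K$ micromolar.

With several partners competing for one hub (`solve_competitive()`), the
free hub concentration $h$ solves

$$h + \sum_i \frac{h\,P_{i,T}}{K_i + h} = H_T .$$

The left side is strictly increasing in $h$, so the root is bracketed in
$[0, H_T]$ and found by bisection to a relative tolerance of $10^{-12}$;
free partner pools follow in closed form. Partners are assumed independent:
1:1 sites, no partner-partner binding, no cooperative or higher-order
stoichiometry, no crowding or activity-coefficient corrections. These
assumptions are stated here because the model is routinely applied with
parameters measured in dilute solution.

`copies_to_molar()` converts copy numbers with a default cell volume of
$1.66\times10^{-15}$ L, the value under which 50 copies/cell is exactly
$5\times10^{-8}$ M; it is an explicit argument everywhere.

### Sensitivity to an approximately known KD

Reported percentages are integers (half-up rounding via
`round_half_up()`; unrounded values are always available). When a
dissociation constant is known only as "about 3 µM",
`kd_sensitivity_scan()` tabulates the integer percentages across a
candidate range. The scan matters: between 2 and 4 µM the basal hub-bound
percentage moves from 9% to 5% and the 1000-fold partner-bound percentage
from 96% to 93%, so integer-level agreement with a published figure can
be obtained at slightly different points of the stated range. The package
always computes at the user's stated KD and leaves the scan as an
explicit, documented sidebar.

## Curve-fitting stages

All saturation hyperbolas — the SPR equilibrium isotherm
$RU = R_{max} c/(c + K_D)$, ligand saturation $A = A_{max}L/(K_D+L)$,
Michaelis–Menten $v = V_{max}S/(K_M+S)$, and the depletion branch of the
abundance–fitness curve $f = F_{max}a/(a+K_f)$ — share one
Levenberg–Marquardt backend; the two sigmoids (IC50 inhibition, the
overexpression fitness branch) share a four-parameter logistic backend
with a free Hill slope bounded in $(0, 10]$. Choices that matter:

* **Positivity by log-parameterization.** Amplitudes and midpoints are
  optimized on the log scale so the optimizer cannot wander into negative
  dissociation constants; standard errors are mapped back by the delta
  method.
* **Analytic gradients.** Every model supplies a symbolic Jacobian. A
  finite-difference Jacobian uses steps proportional to the parameter
  value, which underflows when a log-scale parameter converges near zero
  (e.g. an amplitude of exactly 1); the analytic gradient removes that
  failure mode. The 4PL gradient is written by hand because the naive
  derivative evaluates $0\cdot\log 0$ at a zero dose.
* **Starting values.** Hyperbolas start at amplitude = max response and
  midpoint = concentration nearest half-max; sigmoids at the observed
  extremes with Hill slope 1; the Gompertz fit seeds the growth rate from
  the steepest finite-difference slope.
* **Unweighted objective by default**, with a `weights` argument exposed.
* **Equilibrium readout.** SPR isotherms are assembled from the response
  at the time point nearest 100 s after injection (configurable); the
  procedure takes the late-injection response as the equilibrium value
  without kinetic correction, so a slowly equilibrating surface will bias
  $K_D$ upward — a limitation of the readout convention itself.
* **Dissociation tails** are fit globally as
  $R(t) = R_0 e^{-k_d t}$ with one shared $k_d$ across analyte
  concentrations. Because the amplitudes enter linearly, they are profiled
  out exactly and $k_d$ is found by 1-D minimization, which also makes the
  flat-tail boundary ($k_d = 0$) exact rather than a convergence accident.

The growth model is the modified Gompertz on the log-relative scale,
$y(t) = A\exp\!\big(-\exp(\mu e/A\,(\lambda - t) + 1)\big)$ with
$\mu$ in h$^{-1}$, lag $\lambda$ in h and amplitude $A$ in log-OD units,
chosen as the conventional default among the usual bacterial growth-model
candidates (Gompertz/logistic/Richards). The fit runs on $\log(\mathrm{OD})$
with a free baseline term because the Gompertz expression is not exactly
zero at $t = 0$; anchoring to the first reading would bias $\mu$ by a few
parts in $10^{3}$. The first time point serves as blank unless a blank
value is supplied. Flat curves (total rise below 0.05 log units) return
$\mu = 0$ with a warning instead of a spurious fit.

## Statistical conventions

* **t-tests.** Metabolite significance uses Welch's unpaired t-test by
  default (n = 3 vs 3 replicates; a pooled-variance option exists).
  Stars follow the exact boundaries: `*` for $p < 0.05$, `**` for
  $p < 0.001$, no multiple-testing correction by default (an adjustment
  argument is exposed).
* **Spearman correlation** (`rank_correlation()`) uses the exact
  permutation distribution for $n \le 8$ and a t-approximation above,
  with sidedness as an explicit flag. For tie-free monotone data the
  exact rational form of $\rho$ is used so perfectly monotone series
  return hard $\pm 1$. A useful anchor: a strictly decreasing five-point
  series has two-sided exact $p = 2/5! = 0.0167$; a six-point series has
  $2/720 \approx 0.0028$. A published $p$ of 0.0167 alongside
  $\rho = -1$ therefore identifies a five-point series under the
  two-sided exact convention.
* **Ortholog fitness comparison.** The expected growth at an ortholog's
  abundance is read off the fitted overexpression sigmoid and assigned a
  3% standard deviation — the replicate-level scatter plate-reader growth
  rates typically show. The comparison is an unpaired two-sample t-test
  against the observed replicates. The reference side can be supplied as
  draws from the expected distribution (`expected_reps`); the default is
  a deterministic symmetric triple with exactly the assigned mean and SD.
  Treating the curve prediction as a *fixed* summary makes the test
  conservative (the reference then contributes variance it does not
  actually have), so calibration studies should draw both sides from the
  expected distribution; the package treats the 3% SD as genuine
  reference-level uncertainty, under which the two-sample test is exactly
  calibrated.
* **Co-IP hit calling** follows the background-subtraction rule: a
  protein is a hit when its mean peptide count over sample runs strictly
  exceeds its mean over the pooled control runs, with absence counted as
  zero peptides and means taken over all runs. No multiple-testing
  correction is applied by the caller itself. The dataset-level
  enrichment check is a paired t-test across proteins of (mean sample,
  mean control); zero-variance differences are reported as an explicit
  degenerate case ($p = 1$ for all-zero differences, $p = 0$ for a
  constant nonzero shift) rather than NaN.
* **Metabolite normalization** is log2 of the ratio of arithmetic mean
  replicate areas against an explicit control strain (geometric-mean
  option available); zero areas are floored at half the metabolite's
  minimum positive area. Fold change against a designated control — not a
  per-metabolite z-score — is the default heat-map scale.

## The synthetic-data generators

Each `gen_*()` function takes an explicit seed, restores the caller's RNG
state, and attaches a `ground_truth` record. Noise models: multiplicative
Gaussian for continuous signals (SPR responses at 2% CV, initial rates at
3%, OD at 2%, relative growth at 3% SD), Poisson for spectral counts, and
log-normal for metabolite areas (20% CV, three biological replicates).
Concentration grids mirror the assay designs: SPR series of 1.5–48 µM
(six points) and 1–64 µM (eight points), substrate series of 0.1–16 µM
and 20 µM–1 mM, OD sampled every 15 min over 12 h.

The peptide-count generator draws protein-level background rates from a
log-normal (mean 3 peptides/run, sdlog 1) shared between sample and
control, with an enriched subset whose sample-run rate is multiplied by
the enrichment factor (default 8). The shared rates make replicate sample
runs positively correlated, as real pull-down repeats are. Two
consequences worth knowing: with a long-tailed background, a small
fraction of enriched proteins can sit at rates low enough to escape the
mean-comparison rule in an unlucky draw, and the paired t-statistic
varies noticeably between tables — full recall and $p < 0.001$ hold at
the default table but are not guaranteed for every seed.

What the generators deliberately do not emulate: instrument drift and
retention-time artefacts in LC-MS, mass-transport limitation in SPR,
saturation-OD effects in rich media, correlated (batch) noise across
replicates, and peptide-to-protein inference ambiguity. Passing the
recovery suites therefore demonstrates correctness of the estimators
under the stated noise models, not robustness to every artefact of real
data.

## Problem sizes in the test suite

The packaged checks use desk-scale simulation sizes chosen to estimate
medians and type-I rates with comfortable Monte-Carlo margins: 100 seeded
replicates for isotherm, growth-rate and IC50 recovery, 200 for
Michaelis–Menten bias, 1000 random systems for solver/oracle agreement,
and 2000 trials per calibration null. The equilibrium solvers themselves
run in microseconds, so these sizes complete in seconds.

## Known limitations

* The equilibrium module is strictly thermodynamic: no association or
  dissociation kinetics in the cell, and no prediction of *which*
  partners matter — that ordering comes from the co-IP and kinetics
  stages.
* The kinetics module quantifies modulation of $k_{cat}$, $K_M$ and
  $k_{cat}/K_M$ by an added protein but does not infer an inhibition
  mechanism (competitive vs uncompetitive), and crowding-driven
  $k_{cat}$ increases are reported, not modelled.
* Published per-strain source tables (abundance–fitness series,
  metabolite–growth tables) are inputs, not package data; the functions
  that re-analyze them (`read_fitness_table()`, `rank_correlation()`,
  `correlate_with_fitness()`) run on any table with the documented
  columns.

## A worked example

```{r}
# basal abundances: 50 copies of the hub, 200 of the partner, KD = 3 uM
basal <- solve_pairwise(copies_to_molar(50), copies_to_molar(200), 3e-6,
                        hub = "DHFR", partner = "PurH")
round_half_up(100 * basal$fraction_bound, 1)

# a 1000-fold overexpression titration
sys <- equilibrium_system("DHFR", copies_to_molar(50), "PurH",
                          copies_to_molar(200), kds = 3e-6)
titration_scan(sys, c(1, 10, 100, 1000))
```
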