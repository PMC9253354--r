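---
title: "Multi-stage birth-death models with generation tracking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage birth-death models with generation tracking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistage)
```

## The model

A cell's time to division is modelled as an Erlang random variable: the
cell traverses $N$ abstract exponential stages, each at rate $\lambda$
(inverse hours), and divides on leaving stage $N$; at every stage it may
instead die at rate $\mu$.  The stages keep the process Markovian while
giving a humped division-time density with mean $N/\lambda$ — in contrast
to the exponential model, whose density is maximal at zero.  Writing
$M_j(t)$ for the expected number of cells in stage $j$, the means satisfy
a linear ODE system whose only unusual feature is the factor 2 feeding
stage 1 from divisions.

With generations attached (both daughters of a generation-$g$ cell enter
stage 1 of generation $g+1$), the state is a vector over (generation,
stage) compartments and the mean field is
$\dot{\mathbf M} = \mathbf A \mathbf M$ with a block lower-bidiagonal
$\mathbf A$: diagonal entries $-(\lambda_g + \mu_g)$, within-generation
subdiagonal $\lambda_g$, and a single coupling $2\lambda_{g-1}$ from the
last stage of generation $g-1$ into the first stage of generation $g$.
Generations are what CFSE dye dilution measures, so the per-generation
totals $M^g(t) = \sum_j M^g_j(t)$ are the observable.

Three special cases admit closed forms, implemented in `analytic`-layer
functions and used throughout the tests as oracles:

* equal rates, no generations: the root-of-unity sum for $M_j(t)$ and
  $M(t)$ (`ms_mean_stages()`, `ms_mean_total()`);
* identical $(N, \lambda, \mu)$ across generations:
  $M^g_j(t) = 2^g C_0 (\lambda t)^{Ng+j-1} e^{-(\lambda+\mu)t}/(Ng+j-1)!$
  (`msg_uniform_mean()`);
* one stage per generation with generation-dependent rates: the
  partial-fraction form (`msg_exponential_mean()`).

Key consequences of the Erlang construction: the late-time growth
exponent is $(2^{1/N}-1)\lambda - \mu$, *not* $\lambda/N - \mu$; the
stage occupancies converge to the geometric profile
$P^*_j = 2^{(N-j)/N}(2^{1/N}-1)$ independent of both rates and of the
initial distribution; and extinction is certain iff
$\mu \ge (2^{1/N}-1)\lambda$, with supercritical extinction probability
$p_1 = (1-r)^{-N} - 1$, $r = \mu/(\mu+\lambda)$, obtained from the
first-step recursion.

## Relation to the cyton model

The cyton framework describes each cell by independent competing division
and death clocks, reset at division, with a per-generation progressor
fraction $\gamma_g$.  With $\gamma_g \equiv 1$, exponential death clocks
and Erlang (or exponential) division clocks, the cyton flux equations
reproduce the stage model's generation means exactly.  The package
implements the cyton fluxes by trapezoidal convolution on a uniform grid
(`cyton_fluxes()`, `cyton_mean()`) purely as an *independent numerical
route* to the same quantities: the integrator shares no code with the
matrix-exponential solver, so agreement between the two is a meaningful
cross-check, asserted in the test suite at $10^{-4}$ relative error.
Only exponential and Erlang clock families are shipped; the density
interface accepts other families but warns, because no closed-form
target exists here to validate them against.  The mapping is only
claimed for $\gamma_g = 1$; progressor fractions below 1 have no
stage-model counterpart and are not asserted.

## Numerical choices

**Mean-field solver.**  `solve_mean()` evaluates the action
$e^{\mathbf A t}\mathbf n_0$ by uniformization: with
$\theta \ge \max_g(\lambda_g+\mu_g)$, the matrix
$\mathbf P = \mathbf I + \mathbf A/\theta$ is componentwise nonnegative,
so the Poisson-weighted series has no cancellation.  The Poisson
coefficient is carried in log space and the iterate renormalised by
powers of two, so one series pass handles arbitrarily large
$\theta t$.  The kernel is cross-checked in the tests against dense
`Matrix::expm` at $10^{-8}$ relative error (observed agreement is at the
$10^{-14}$ level).  Non-finite results (populations beyond double range)
raise a typed error rather than propagating silently.

**Generation truncation.**  The process has no generation ceiling; only
the dye saturates.  Solves truncate at a ceiling chosen from a Poisson
tail bound on $2^{1/N}\lambda t$ (the series terms are Poisson weights in
the total stage index), then verified: the terminal generation must hold
less than $10^{-6}$ of the population at the last requested time, else
the ceiling is expanded.  The same bound truncates the closed-form
generation series at an omitted mass below $10^{-9}$.  During inference
the solve dimension is additionally capped (about 2500 compartments);
the cap can only bind for prior corners whose predicted populations
exceed any dataset by orders of magnitude, which every tolerance
schedule rejects regardless.  Parameter draws whose optimistic growth
bound $\log C_0 + (2^{1/N}-1)\lambda t$ exceeds double range are
assigned infinite distance without solving.

**Closed-form conditioning.**  The root-of-unity sum is evaluated in
complex arithmetic with an asserted imaginary residue below
$10^{-9} C_0$; factorials go through `lgamma`.  The partial-fraction
form for single-stage generations degenerates when two rate sums
$\lambda_i+\mu_i$ coincide (a typed error directs callers to the
solver), and is ill-conditioned once many near-coincident terms enter —
beyond roughly a dozen generations under the linear death law the
matrix-exponential route is the reliable one, which is why the tests
compare low generations against the closed form and the merged tail by
conservation.

**Simulator.**  The Gillespie engine aggregates hazards per compartment;
cells within a compartment are exchangeable, so the sampled law equals
per-cell simulation at a fraction of the cost.  Both division and death
pick a uniformly random cell of the selected generation (per-cell rates
are stage-independent within a generation).  Generations extend
dynamically with the schedule's generating rule.  Runs exceeding a
configurable cell cap abort with a typed error.  Replicate $r$ of a run
with seed $s$ uses a deterministically derived substream seed, making
datasets byte-identical across reruns and independent of batching.
Extinction estimation declares survival once a population reaches an
escape threshold (default $10^3$ cells): the residual extinction
probability from that size is at most $p_1^{1000}$, far below
Monte-Carlo resolution at the replicate counts used.

**Cyton integrator.**  Uniform grid, trapezoidal (second-order)
convolution via FFT; the default step is $0.02/\max(\text{rate})$, and
halving the step reduces the deviation from the closed forms about
fourfold.  A half-resolution self-consistency check rejects grids too
coarse for their rates.

## The synthetic data generator

No public dataset accompanies the calibration design, so the package
generates its own: each "mouse" is one independent exact realisation of
the model from the same $C_0$ founder cells, observed once at its harvest
time, with generations $\ge 5$ merged into a `"5+"` class.  The default
design uses harvest days 3, 4, 5, 6, 7, 10, 12, 18 with 5, 5, 5, 5, 5,
4, 4, 3 mice — between 3 and 7 animals per time point, fewer at late
harvests, as in adoptive-transfer practice.  The default truth
(`default_truth()`) is a fast-clonotype-like parameterisation:
$C_0 = 4.5\times 10^4$, $N_0 = 3$, $\lambda_0 = 0.05$/h (mean 60 h to
first division), $N = 5$, $\lambda = 0.12$/h, $\alpha = 2\times10^{-4}$/h.

The only noise is demographic stochasticity.  Real CFSE data additionally
carry measurement error (gating, spectral overlap, incomplete recovery of
organs), engraftment variability in $C_0$, and possible between-mouse
rate heterogeneity; none of these are modelled, because the calibration
machinery consumes only means and empirical standard deviations and
specifies no observation model.  Passing tests therefore demonstrate
self-consistency of the pipeline — generator, solver and inference agree
about the same process — not robustness to observation noise.  With few
replicates the sample standard deviation is itself noisy; it is floored
at 1 cell because it enters the calibration distance as a denominator,
which also covers single-replicate time points.

## Calibration

ABC-SMC with the weighted chi-type distance over the six generation
classes and the design's time grid.  Priors: $C_0 = 10^x$,
$x \sim U(4,6)$; $N_0, N$ discrete uniform on $1..50$;
$\lambda_0 = 10^y, \lambda = 10^z$, $y,z \sim U(-3,1)$ per hour;
$\alpha = 10^w$, $w \sim U(-5,-1)$ — parameters spanning orders of
magnitude are sampled on the exponent.  The first tolerance is the
median of prior-predictive distances ($10^4$ draws by default); each
later tolerance is the median of the previous population's accepted
distances, so the schedule decreases strictly.  Perturbation uses a
uniform kernel: continuous parameters on their exponent with half-width
half the weighted standard deviation of the previous population,
stage counts by $\{-1, 0, +1\}$; out-of-support proposals are
re-perturbed, and importance weights use the standard kernel-mixture
correction (the prior is flat on the sampling scale).  Default schedule
length is 16 iterations for the multi-stage model and 7 for the
single-stage reduction; 1000 particles.  An iteration that cannot fill
its population within a configurable proposal budget stops the run
early, returning the last completed population flagged.

Model comparison uses AICc with the squared distance treated as a
weighted residual sum of squares under a Gaussian working likelihood:
$n\ln(d^2_{\min}/n) + 2k + 2k(k+1)/(n-k-1)$, with $n$ the number of
(class, time) cells and $k$ the free-parameter count (6 vs 4).  This is
one defensible convention, not the only one; it is isolated in `aicc()`
so it can be swapped, and comparisons are only meaningful between models
scored on the same cells.

## Scale of the shipped experiments

The recovery experiment in the test suite runs at a reduced scale chosen
as the package's own desk-scale design: 200 particles, 8 iterations
(7 for the single-stage variant), first tolerance from 1000
prior-predictive draws, 10 dataset seeds, and a slow-kinetics truth
($C_0 = 5\times10^4$, $N_0 = 8$, $\lambda_0 = 0.04$, $N = 5$,
$\lambda = 0.04$, $\alpha = 5\times10^{-4}$; all inside the prior
support).  Slow kinetics keep the exact per-mouse simulations light
while the truth remains clearly multi-stage, so the model-comparison
direction is a meaningful check.  At this schedule the tolerances are
still far from zero, so posteriors are deliberately wide; the
experiment checks that 95% credible intervals cover the exponent-scale
truth (pooled over parameters and seeds) and that AICc prefers the
multi-stage variant on multi-stage data, not that point estimates are
sharp.  One consequence of stopping at a loose tolerance deserves
naming: the data constrain mean division *times* ($N_0/\lambda_0$,
$N/\lambda$) much more tightly than stage counts and rates separately,
so the posterior occupies a ridge.  Along that ridge the discrete
uniform prior on the stage count places most mass at large $N_0$, and
the marginal of $\lambda_0$ inherits an upward shift; a truth lying at
the small-$N_0$ end of its ridge can fall into the lower tail of the
$\lambda_0$ marginal more often than the nominal 5%.  Deeper schedules
(the full $T = 16$) shrink the ridge; at desk scale the pooled coverage
check absorbs it.

## Known limitations

* Means only: no variances or higher moments of the counting process
  (the simulator provides ensembles where dispersion matters).
* Serial chains only: general phase-type division-time laws (arbitrary
  initial-distribution/generator pairs) are out of scope.
* No density dependence: birth rates do not respond to population size,
  so fast-growing populations near a carrying capacity are outside the
  model's validity window.
* No lineage correlations: sibling and mother-daughter correlations
  reported in imaging studies are absent by construction.
* Cells start in stage 1: transferred cells mid-cycle at $t = 0$ would
  need an explicit initial vector through `solve_mean()`; the closed
  forms assume stage-1 starts (general starts would require solving a
  Vandermonde system for the series constants, which is not provided).
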