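---
title: "Age-structured matrix population models from minimal life-history data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-structured matrix population models from minimal life-history data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishmpm)
```

## The problem

Matrix population models underpin much of applied conservation and
fisheries demography, but parameterizing one normally requires survival and
reproduction estimates spanning a species' whole life — data that exist for
only a handful of charismatic or commercially important fishes. fishmpm
implements a construction that needs only a minimal, widely available
life-history parameter set per species:

* von Bertalanffy growth parameters `Loo` (asymptotic total length, cm) and
  `K` (per year);
* age at maturity `tm` (yr) and total length at maturity `Lm` (cm);
* maximum age `tmax` (yr);
* a length–mass allometry `W = a L^b` (grams; on a stated length basis,
  with linear length–length conversions when that basis is not total
  length);
* `ln_MASPS`, the log of the maximum annual spawner biomass produced per
  spawner biomass in excess of replacement — a stock–recruitment
  productivity parameter available from predictive life-history databases.

Everything else — age-specific survival, fertility, density dependence —
is derived. Natural mortality in particular comes from the Lorenzen
mass-dependent model rather than from direct estimates, which also means
the models describe expectations *in the absence of fishing mortality*.

## The construction

**Ages.** The matrix has one age class per year, ages `1..tmax`, with
`tmax` the maximum age rounded up; `tmat` is the age at maturity rounded
up, floored at 1 because the first class is age 1. Species whose rounded
maximum age is 1 would give an unstructured annual model and are rejected.
The ceiling is applied after rounding the input to 9 decimals: sampled
parameters that pass through a log transform come back with relative noise
of order 1e-16 (`exp(log(10))` is 10 + 2e-15), and a raw ceiling would
spuriously add a year.

**Growth and mass.** Length at age follows
`L(t) = Loo (1 - exp(-K (t - t0)))`. `t0` is obtained by inverting the
growth curve at the maturity point (`L(tm) = Lm`) and capping the result
from above at -0.1 yr, the convention of the predictive database the
parameters come from. Mass is `W = a L^b` in grams, converting total length
to fork/standard length first when the allometry demands it (single-step
conversions only; the construction never chains them).

**Survival.** The instantaneous mortality rate is `m = -mu W^upsilon` per
year with defaults `mu = 3.00`, `upsilon = -0.288` (the published general
estimates for marine and freshwater fishes). The finite survival rate over
one year of age is `s_t = exp(int_t^{t+1} m(tau) dtau)` with mass evaluated
*continuously* in age inside the integral — the integral form, not a
midpoint approximation. The integral uses adaptive quadrature at absolute
tolerance 1e-12; the test-suite pins it against a fixed-grid Simpson oracle
with a 1e-4 yr step. Because `upsilon < 0` and mass grows with age,
survival rises with age and survivorship `l_t` (from age 1, `l_1 = 1`)
falls.

**Fertility and calibration.** Fertility is proportional to mass for
mature ages, `F_t = c W_t`, and zero before maturity. The constant `c` is
found numerically so the dominant eigenvalue of the Leslie matrix is
exactly 1 — the model is anchored at replacement rather than estimating a
growth rate, since no abundance data enter the construction. The solver is
a bracketing root-find on `log(c)` (the spectral radius is strictly
increasing in `c`) followed by a Newton polish to a residual below 1e-12.
At `lambda = 1` the answer has the Euler–Lotka closed form
`c = 1 / sum(l_t W_t)` over mature ages; the package deliberately keeps the
eigen-based search as the implementation and uses the closed form only as
an independent test oracle, so each route checks the other.

**Density dependence.** The density-dependent variant places compensatory
(Beverton–Holt type) density dependence on the single pathway between
reproduction and age 1: `F_t(B) = D_a W_t / (1 + D_b B)` with `B` the
mature biomass. Its parameters derive from `gamma = exp(ln_MASPS)`:

* `S_bar`, the mean survival after maturation, taken as the arithmetic mean
  of `s_t` over `t = tmat..tmax-1`. The terminal age has no forward
  transition and is excluded; when maturation happens in the terminal class
  the mean is undefined and the density-dependent build fails cleanly. A
  geometric mean would be a defensible alternative reading of "mean
  survival"; the arithmetic mean is the simplest and is what the package
  documents and tests.
* `p = 1 + gamma / (1 - S_bar)`, the maximum lifetime spawner biomass per
  spawner biomass; `p > 1` is required for a positive equilibrium.
* `D_a = p / (M_spawner l_mat)`, where `M_spawner` is the spawner biomass
  per recruit and `l_mat` the survivorship from age 1 to maturation. The
  `l_mat` factor appears because the productivity parameter is defined with
  density dependence acting up to recruitment at maturity, while this model
  applies it before age 1 and tracks survival to maturity explicitly.
* `D_b` is solved numerically so that the equilibrium holds `N_eq` mature
  fish (default 10,000 per unit habitat area — an arbitrary anchor, since
  true habitat areas are rarely known; it is a configurable argument).

The solve is nested: for a candidate `D_b`, the equilibrium biomass is the
root of `lambda_1(A(B)) = 1` (spectral radius strictly decreasing in `B`),
the equilibrium age vector is the corresponding stable age distribution
scaled to that biomass, and an outer quasi-Newton iteration on `log(D_b)`
drives the mature abundance to the target. The outer step exploits the
exact inverse scaling of equilibrium abundance with the density coefficient
in this model class, so it converges in a couple of iterations; the
analytic chain `D_b = (p - 1)/B*`, `n*_t = n*_1 l_t` serves as the
independent oracle in the tests, never as the implementation. Two derived
identities are asserted across the whole fixture sweep: `D_a = p c` and
`1 + D_b B* = p` (equivalently, at equilibrium the compensatory factor
exactly restores the replacement fertilities).

## The seven metrics

From the density-independent matrix: the dominant eigenvalue `lambda_1`
(1 by construction), the stable age distribution `w` (right eigenvector,
normalized to sum to 1), the reproductive value `v` (left eigenvector,
scaled so age 1 has value 1), the damping ratio `rho = lambda_1/|lambda_2|`,
the sensitivity matrix `S = v w^T / (v . w)` (reported masked to the
structural nonzeros of the matrix, with the full rank-1 matrix also
available), the elasticity matrix `e_ij = a_ij s_ij / lambda_1` (sums to
1), and the generation time `G = lambda_1 (v . w) / (v^T F w)` with `F` the
fertility row — the mean age of the parents of a newborn cohort.

From the density-dependent model: the resilience `R = -log(|lambda_J|)`,
where `J` is the Jacobian of the one-step projection map at equilibrium.
Only the fertility row of `J` differs from the equilibrium matrix:

```
J[1, j] = F*_j - 1(j mature) W_j D_b / (1 + D_b B*) sum(F*_t n*_t)
```

Positive `R` means local stability, with perturbations shrinking by
`exp(-R)` per year asymptotically.

Numerical conventions worth knowing:

* Eigen-decompositions are dense (`tmax <= ~40`, so cost is negligible).
  Among eigenvalues tied in modulus the Perron root is identified as the
  one with largest real part — imprimitive Leslie matrices (a single
  fertile age class) put several eigenvalues on the spectral circle and
  LAPACK orders them arbitrarily, so picking "the first largest-modulus
  eigenvalue" can silently select a rotated root.
* `rho = 1` exactly for single-fertile-age models, whose cohort cycles
  never damp; a zero second eigenvalue yields `rho = Inf` with a warning.
* `lambda_2` with a complex pair uses the modulus, which is unaffected by
  which member of the pair is taken.

## Uncertainty propagation

Parameter uncertainty is propagated by sampling the six life-history
coordinates (`Loo, K, tm, Lm, tmax, ln_MASPS`) from a multivariate normal
and rebuilding both models per draw (the reference workflow is 1,000 draws
per species). Predictive databases do not always state the scale their
covariances live on; the package makes this explicit with per-coordinate
log-scale flags, defaulting to log scale for the five strictly positive
parameters and natural scale for `ln_MASPS` (already a log). The flags are
configuration, and the choice is documented as an interpretation.

Draws violating the input invariants (e.g. `Lm >= Loo`, rounded maximum
age of 1) are rejected, not clipped — clipping would distort the sampled
distribution — and `sample_life_histories()` resamples up to a cap of 100
times the requested count. `run_ensemble()` instead accounts for every raw
draw exactly once: `ok`, `rejected` (invalid parameters) or `failed`
(model construction error, e.g. maturation in the terminal age class),
with the error message kept as a reason code, so ensembles never silently
drop replicates. Box-plot summaries use type-7 quantiles (linear
interpolation between order statistics, R's default), whiskers at the
furthest points within 1.5 IQR beyond the quartiles, and outliers beyond.

## The synthetic fixture generator

`generate_fixture_species()` stands in for database queries so the package
is fully buildable and testable offline. It emulates the *marginal* ranges
of teleost life histories (`Loo` 10–200 cm, `tmax` 3–40 yr, `K` 0.1–1.0
per yr, `ln_MASPS` in `[log 0.5, log 20]`, allometric exponent 2.8–3.2)
together with the cross-parameter couplings real fishes show, which matter
more than the margins: fast growers are short-lived (`K` is drawn within
`[1.5, 8]/tmax`), long-lived species are not tiny (`Loo >= tmax` cm),
maturity falls at 12–35% of the lifespan, and the maturity length is
placed on the growth curve at the maturity age. Without these couplings
one draws "species" that mature at age 22 with survivorship 1e-14 to
maturity and compensating fecundities of 1e14 — parameter combinations no
fish exhibits and whose matrices are numerically pathological. The first
three rows are deterministic edge cases: maturity in the first age class,
maturity in the terminal age class, and a long-lived species.

What the generator does *not* emulate: fishing mortality (none of the
models include it), real covariance structure between parameters (draws
are independent uniforms, not a taxonomic predictive posterior),
measurement error in the allometries, and non-teleost life histories
(elasmobranch-style low fecundity is out of range). Passing the test-suite
therefore demonstrates correctness of the construction on realistic
parameter sets, not validity of any particular database's predictions.

## Problem sizes and tolerances used in the tests

The suite builds both model variants for 100 generated species (plus
smaller sweeps per module), checks calibration to 1e-10, equilibrium
abundance to 1e-6 relative, the Euler–Lotka and cohort-generation-time
oracles to 1e-8, elasticity sums to 1e-10, sensitivities against
Richardson-extrapolated finite differences of the dominant eigenvalue to
1e-5, the analytic Jacobian against a finite-difference Jacobian of the
projection map to 1e-6 relative, and empirical decay rates of perturbed
equilibria against `exp(-R)` to 5% on fixtures whose Jacobian spectral gap
makes the asymptotic rate identifiable before the floating-point noise
floor. A 1,000-draw ensemble runs as part of the suite. The whole suite
completes in about a minute on one CPU.

## Limitations

* Age is the only structuring variable; size- or stage-structured dynamics
  are out of scope.
* Density dependence acts only on the reproduction-to-age-1 pathway and
  only compensatorily; no depensation, no density-dependent survival, no
  environmental stochasticity.
* The models exclude fishing mortality by construction.
* `S_bar` and the sampling scales involve the documented interpretive
  choices above.
* Transient indices beyond the damping ratio (reactivity, inertia) are not
  computed.

## A minimal session

```{r example, eval = FALSE}
sp <- species_input("example", Loo = 100, K = 0.5, tm = 2, Lm = 60,
                    tmax = 10, ln_MASPS = log(4),
                    lw = length_weight(0.01, 3))
rep <- compute_metrics(sp)
rep
dist <- distribution_from_species(sp, sd = 0.1)
ens <- run_ensemble(dist, sp, n = 1000, seed = 1)
summarize_ensemble(ens)
```
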