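# fishmpm

Age-structured (Leslie) matrix population models for fishes, built from a
minimal life-history parameter set.

Demographic metrics — damping ratio, generation time, resilience, stable
age distribution, reproductive value, sensitivity and elasticity — are
standard tools in conservation and fisheries science, but parameterizing
the underlying matrix model normally requires survival and reproduction
estimates across a species' whole life. For most fishes those data do not
exist. fishmpm constructs the full model from parameters that *are* widely
available (directly or from predictive life-history databases): von
Bertalanffy growth (L∞, K), age and length at maturity (t_m, L_m), maximum
age (t_max), a length–mass allometry (W = a L^b), and the log of the
maximum annual spawner biomass per spawner biomass in excess of
replacement (ln_MASPS).

The construction, per species:

1. Matrix size = t_max rounded up; age classes 1..t_max (one-year steps).
2. Length at age from L(t) = L∞(1 − e^(−K(t − t₀))), with t₀ solved from
   the maturity point and capped at −0.1 yr.
3. Mass at age from W = a L^b (grams), converting the length basis first
   when the allometry is on fork/standard length.
4. Instantaneous natural mortality from the Lorenzen mass-dependent model
   m = −μ W^υ (defaults μ = 3.00, υ = −0.288), so no direct mortality
   estimates are needed (and the models exclude fishing mortality).
5. Finite survival s_t = exp(∫ₜ^{t+1} m(τ) dτ) on the subdiagonal.
6. Fertility F_t = c·W_t for mature ages in the first row, with c
   calibrated numerically so the dominant eigenvalue λ₁ = 1.
7. A density-dependent variant with compensatory recruitment
   F_t(B) = D_a W_t / (1 + D_b B), where B is mature biomass; D_a derives
   from MASPS and D_b is solved so the equilibrium holds 10,000 mature
   fish (configurable).

From the two variants the package computes λ₁, the damping ratio
ρ = λ₁/|λ₂|, generation time G = λ₁(v·w)/(vᵀFw), stable age distribution
w, reproductive value v, sensitivity S = vwᵀ/(v·w), elasticity
E = (a_ij s_ij)/λ₁, and the resilience R = −ln|λ_J| of the
density-dependent equilibrium (λ_J from the linearized projection map).
Parameter uncertainty is propagated by multivariate-normal Monte-Carlo
simulation with box-plot summaries. A fixture generator produces synthetic
species tables so everything runs offline.

## Worked example

```r
library(fishmpm)

sp <- species_input("red_snapper_like",
                    Loo = 100, K = 0.5, tm = 2, Lm = 60, tmax = 10,
                    ln_MASPS = log(4), lw = length_weight(0.01, 3))
build_age_schedule(sp)
#> <age_schedule> red_snapper_like: ages 1..10, maturity at 2, t0 = -0.1000 yr
#>  age length_cm  mass_g       m      s      l
#>    1     42.31  757.14 -0.4445 0.6970 1.0000
#>    2     65.01 2747.04 -0.3067 0.7558 0.6970
#>    3     78.78 4888.42 -0.2598 0.7806 0.5268
#>  ...
#>   10     99.36 9808.95 -0.2126     NA 0.1103

rep <- compute_metrics(sp)
rep
#> <metrics_report> red_snapper_like
#>   lambda1 = 1.0000000000
#>   damping ratio   rho = 1.3157
#>   generation time G   = 5.4450 yr
#>   resilience      R   = 0.4505 /yr
```

The schedule shows the derived life history: survival rises with age
(mortality falls as fish grow), survivorship `l` declines to 11% by age
10. The metrics say transient fluctuations shrink by a factor 1.32 per
year toward the stable age distribution (ρ), the mean age of parents is
5.4 years (G), and perturbations of the density-dependent equilibrium
decay at e^(−0.45) ≈ 0.64 per year (R). The equilibrium itself holds
10,000 mature fish:

```r
dd <- rep$dd_model
sum(dd$n_star[dd$schedule$ages >= dd$schedule$tmat])
#> [1] 10000
c(p = dd$p, D_a = dd$D_a, D_b = dd$D_b)
#>            p          D_a          D_b
#> 2.044895e+01 1.139347e-03 3.085566e-07
```

Uncertainty propagation (here 200 draws at 10% spread on the log scale):

```r
dist <- distribution_from_species(sp, sd = 0.1)
ens <- run_ensemble(dist, sp, n = 200, seed = 42)
summarize_ensemble(ens)
#>    metric median     q1     q3 whisker_low whisker_high n_outliers   n
#> 1 lambda1 1.0000 1.0000 1.0000      1.0000       1.0000          1 200
#> 2     rho 1.3146 1.3018 1.3276      1.2720       1.3581          5 200
#> 3       G 5.7318 5.4351 5.9670      4.7426       6.6486          0 200
#> 4       R 0.4344 0.4122 0.4528      0.3646       0.5104          3 200
```

A thin command-line interface wraps the same functions:

```sh
Rscript exec/fishmpm fixtures --n 10 --seed 1 --out species.csv
Rscript exec/fishmpm metrics  --table species.csv --outdir results/
Rscript exec/fishmpm ensemble --table species.csv --outdir results/ --n 1000 --seed 1
```

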