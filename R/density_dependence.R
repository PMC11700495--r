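#' Mean survival after maturation
#'
#' Arithmetic mean of the finite survival rates over the mature ages that
#' still have a forward transition, `t = tmat .. tmax - 1`. Undefined when
#' maturation happens in the terminal age class.
#'
#' @param schedule An [build_age_schedule()] result.
#' @return Mean adult survival in (0, 1).
#' @export
mean_adult_survival <- function(schedule) {
  if (schedule$tmat > schedule$tmax - 1L)
    stop("undefined mean adult survival (no post-maturation transitions)")
  mean(schedule$s[seq.int(schedule$tmat, schedule$tmax - 1L)])
}

#' Maximum lifetime spawner biomass per spawner biomass
#'
#' `p = 1 + gamma / (1 - S_bar)`, where `gamma` is the MASPS (the maximum
#' annual spawner biomass produced per spawner biomass in excess of
#' replacement) and `S_bar` the mean survival after maturation. `p > 1` is
#' required for a positive density-dependent equilibrium.
#'
#' @param gamma MASPS, dimensionless, nonnegative (natural scale, i.e.
#'   `exp(ln_MASPS)`).
#' @param S_bar Mean adult survival, in `[0, 1)`.
#' @return `p`, dimensionless, at least 1.
#' @export
#' @examples
#' lifetime_spawner_ratio(1, 0.5)   # 3
lifetime_spawner_ratio <- function(gamma, S_bar) {
  if (gamma < 0) stop("'gamma' must be nonnegative")
  if (S_bar < 0 || S_bar >= 1) stop("'S_bar' must lie in [0, 1)")
  1 + gamma / (1 - S_bar)
}

# Survivorship from age 1 to maturation, l_mat = prod(s_1 .. s_{tmat-1});
# equals 1 when tmat = 1.
survivorship_to_maturity <- function(schedule) {
  prod(schedule$s[seq_len(schedule$tmat - 1L)])
}

#' Spawner biomass per recruit
#'
#' Expected cumulative mature biomass produced per individual surviving to
#' maturity: `M_spawner = sum over mature ages of (l_t / l_mat) * W_t`,
#' where `l_mat` is the survivorship from age 1 to maturation.
#'
#' @param schedule An [build_age_schedule()] result.
#' @return `M_spawner` in grams.
#' @export
spawner_biomass_per_recruit <- function(schedule) {
  l_mat <- survivorship_to_maturity(schedule)
  mature <- schedule$ages >= schedule$tmat
  sum(schedule$l[mature] / l_mat * schedule$mass_g[mature])
}

#' Density-dependent fertility scale
#'
#' `D_a = p / (M_spawner * l_mat)`. The survivorship to maturity appears in
#' the denominator because the stock-recruitment parameterization assumes
#' density dependence acts between reproduction and recruitment at maturity,
#' whereas this model applies it between reproduction and age 1 and tracks
#' survival from age 1 to maturity explicitly.
#'
#' @param p Maximum lifetime spawner biomass per spawner biomass.
#' @param M_spawner Spawner biomass per recruit, grams.
#' @param l_mat Survivorship from age 1 to maturation.
#' @return `D_a`, per gram per year.
#' @export
compute_Da <- function(p, M_spawner, l_mat) {
  if (M_spawner <= 0 || l_mat <= 0) stop("zero denominator in D_a")
  p / (M_spawner * l_mat)
}

#' Solve the density coefficient against the equilibrium target
#'
#' The density-dependent fertility is `F_t(B) = D_a * W_t / (1 + D_b * B)`
#' for mature `t`, with `B` the mature biomass. `D_b` is determined
#' numerically so that the equilibrium age vector sums to `N_eq` mature
#' individuals. For a given `D_b` the equilibrium biomass is found as the
#' root of `lambda_1(A(B)) = 1` (the spectral radius is strictly decreasing
#' in `B`), the equilibrium age vector is the corresponding stable age
#' distribution scaled to that biomass, and an outer quasi-Newton iteration
#' on `log(D_b)` drives the mature abundance to the target (equilibrium
#' abundance scales inversely with the density coefficient in this
#' compensatory model, so the iteration converges in a few steps).
#'
#' @param schedule An [build_age_schedule()] result.
#' @param D_a Density-dependent fertility scale (per gram per year).
#' @param p Maximum lifetime spawner biomass per spawner biomass; must
#'   exceed 1.
#' @param N_eq Target equilibrium abundance of mature fish (default 10,000
#'   individuals per unit area, an arbitrary anchor since true habitat areas
#'   are rarely known).
#' @return List with `D_b` (per gram), `n_star` (equilibrium age vector,
#'   individuals) and `B_star` (equilibrium mature biomass, grams).
#' @export
solve_Db <- function(schedule, D_a, p, N_eq = 10000) {
  if (p <= 1)
    stop("no positive equilibrium (MASPS implies at-or-below replacement)")
  s <- schedule$s
  W <- schedule$mass_g
  mature <- schedule$ages >= schedule$tmat

  lam <- function(B, Db)
    spectral_radius(assemble_leslie(s, D_a * W * mature / (1 + Db * B)))

  uB_hint <- 0
  eq_state <- function(Db) {
    resid <- function(u) 1 - lam(exp(u), Db)     # increasing in u
    u <- log_bracket_root(resid, u0 = uB_hint, tol = 1e-13)
    u <- polish_root(resid, u, target = 1e-14)
    uB_hint <<- u
    Bstar <- exp(u)
    Astar <- assemble_leslie(s, D_a * W * mature / (1 + Db * Bstar))
    e <- eigen(Astar)
    w <- Re(e$vectors[, perron_index(e$values)])
    w <- w / sum(w)
    n <- w * (Bstar / sum(w[mature] * W[mature]))
    list(B = Bstar, n = n, N = sum(n[mature]))
  }

  uD <- log(1e-6)
  st <- eq_state(exp(uD))
  for (k in seq_len(60L)) {
    err <- log(st$N / N_eq)
    if (abs(err) < 1e-12) break
    uD <- uD + err
    st <- eq_state(exp(uD))
  }
  if (abs(st$N / N_eq - 1) > 1e-8)
    stop("equilibrium solve did not converge")
  list(D_b = exp(uD), n_star = st$n, B_star = st$B)
}

#' Build the density-dependent model
#'
#' Extends a calibrated density-independent model with compensatory
#' (Beverton-Holt type) density dependence acting on the fertility pathway
#' between reproduction and age 1. The productivity parameter is
#' `gamma = exp(ln_MASPS)`; the derived quantities are the mean adult
#' survival, the lifetime spawner ratio `p`, the spawner biomass per recruit,
#' the fertility scale `D_a`, and the density coefficient `D_b` solved so
#' that `N_eq` mature fish persist at equilibrium.
#'
#' @param x A [species_input()] or an already-built `leslie_model`.
#' @param coeffs [lorenzen_coefficients()] (used only when `x` is a
#'   species input).
#' @param N_eq Equilibrium abundance of mature fish (default 10,000).
#' @return An object of class `dd_model`.
#' @export
#' @examples
#' sp <- species_input("example", 100, 0.5, 2, 60, 10, log(4))
#' dd <- build_density_dependent(sp)
#' sum(dd$n_star[dd$schedule$ages >= dd$schedule$tmat])   # 10,000
build_density_dependent <- function(x, coeffs = lorenzen_coefficients(),
                                    N_eq = 10000) {
  base <- if (inherits(x, "leslie_model")) x
          else build_density_independent(x, coeffs)
  sched <- base$schedule
  sp <- sched$species
  if (is.null(sp)) stop("schedule does not carry its species input")
  gamma <- exp(sp$ln_MASPS)
  S_bar <- mean_adult_survival(sched)
  p <- lifetime_spawner_ratio(gamma, S_bar)
  l_mat <- survivorship_to_maturity(sched)
  M_spawner <- spawner_biomass_per_recruit(sched)
  D_a <- compute_Da(p, M_spawner, l_mat)
  sol <- solve_Db(sched, D_a, p, N_eq)
  mature <- sched$ages >= sched$tmat
  F_star <- D_a * sched$mass_g * mature / (1 + sol$D_b * sol$B_star)
  A_star <- assemble_leslie(sched$s, F_star)
  structure(list(base = base, schedule = sched, gamma = gamma, p = p,
                 S_bar = S_bar, M_spawner = M_spawner, l_mat = l_mat,
                 D_a = D_a, D_b = sol$D_b, N_eq = N_eq,
                 n_star = sol$n_star, B_star = sol$B_star,
                 F_star = F_star, A_star = A_star),
            class = "dd_model")
}

#' @export
print.dd_model <- function(x, ...) {
  cat(sprintf("<dd_model> %s: p = %.4g, D_a = %.4g, D_b = %.4g\n",
              x$base$species_id, x$p, x$D_a, x$D_b))
  cat(sprintf("  equilibrium: %.1f mature fish, %.4g g mature biomass\n",
              sum(x$n_star[x$schedule$ages >= x$schedule$tmat]), x$B_star))
  invisible(x)
}

#' Project the density-dependent dynamics
#'
#' Iterates `n(x+1) = A(B_x) n(x)`, where only the fertility row responds to
#' the current mature biomass `B_x`; survival is density-independent.
#'
#' @param dd A [build_density_dependent()] model.
#' @param n0 Nonnegative starting age vector, length `tmax`.
#' @param steps Number of yearly time steps.
#' @return An object of class `projection_trajectory` with `times`
#'   (0..steps), `states` (matrix, ages x times) and `biomass` (mature
#'   biomass `B_x` per step).
#' @export
project <- function(dd, n0, steps) {
  stopifnot(inherits(dd, "dd_model"))
  tmax <- dd$schedule$tmax
  if (length(n0) != tmax) stop("'n0' must have one entry per age class")
  if (any(n0 < 0)) stop("negative n0")
  W <- dd$schedule$mass_g
  s <- dd$schedule$s
  mature <- dd$schedule$ages >= dd$schedule$tmat
  states <- matrix(0, tmax, steps + 1L)
  states[, 1L] <- n0
  biomass <- numeric(steps + 1L)
  for (x in seq_len(steps)) {
    n <- states[, x]
    B <- sum(n[mature] * W[mature])
    biomass[x] <- B
    fert <- dd$D_a * W * mature / (1 + dd$D_b * B)
    states[1L, x + 1L] <- sum(fert * n)
    states[2L:tmax, x + 1L] <- s * n[seq_len(tmax - 1L)]
  }
  biomass[steps + 1L] <- sum(states[mature, steps + 1L] * W[mature])
  structure(list(times = 0:steps, states = states, biomass = biomass),
            class = "projection_trajectory")
}
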