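# Shared fixtures and independent oracles for the test suite.

# Minimal hand-made age schedule for operations that only need the
# survival/mass/maturity pieces (bypasses the growth chain).
toy_schedule <- function(s, W, tmat) {
  k <- length(W)
  stopifnot(length(s) == k - 1L)
  structure(list(species_id = "toy", tmat = as.integer(tmat),
                 tmax = as.integer(k), ages = seq_len(k), mass_g = W,
                 s = s, l = c(1, cumprod(s))),
            class = "age_schedule")
}

# Reference species used across tests (also the acceptance fixture).
reference_species <- function(ln_MASPS = log(4)) {
  species_input("reference", Loo = 100, K = 0.5, tm = 2.0, Lm = 60,
                tmax = 10.0, ln_MASPS = ln_MASPS,
                lw = length_weight(0.01, 3.0, "TL"))
}

fixture_species <- function(n, seed) {
  suppressWarnings(species_list_from_table(generate_fixture_species(n, seed)))
}

# Composite-Simpson quadrature on a fixed fine grid: the brute-force oracle
# for the survival integral.
simpson_integral <- function(f, a, b, h = 1e-4) {
  n <- ceiling((b - a) / h)
  if (n %% 2 == 1) n <- n + 1
  x <- seq(a, b, length.out = n + 1)
  y <- f(x)
  wts <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(wts * y) * (b - a) / (3 * n)
}

dominant_mod <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# The Perron branch followed smoothly through perturbations: for the
# nonnegative matrices here it equals the spectral radius, but unlike the
# max-modulus it stays differentiable when a perturbation splits the
# eigenvalue ring of an imprimitive matrix.
perron_root <- function(A) max(Re(eigen(A, only.values = TRUE)$values))

# Finite-difference gradient of the dominant eigenvalue with respect to
# matrix entries (all entries by default). Fixture matrices mix fertilities
# of ~1e7 with survivals of ~0.5, so the step must sit above the
# eigen-solver noise floor (which scales with the matrix norm) while a
# Richardson extrapolation removes the curvature error the larger step
# would otherwise introduce.
fd_lambda_grad <- function(A, h = NULL, entries = seq_along(A)) {
  if (is.null(h)) h <- max(1e-4, 1e-9 * max(abs(A)))
  central <- function(ij, step) {
    Ap <- A; Am <- A
    Ap[ij] <- A[ij] + step
    Am[ij] <- A[ij] - step
    (perron_root(Ap) - perron_root(Am)) / (2 * step)
  }
  G <- matrix(NA_real_, nrow(A), ncol(A))
  for (ij in entries) {
    G[ij] <- (4 * central(ij, h / 2) - central(ij, h)) / 3
  }
  G
}

# One step of the density-dependent map, written independently of project().
dd_one_step <- function(dd, n) {
  W <- dd$schedule$mass_g
  mature <- dd$schedule$ages >= dd$schedule$tmat
  B <- sum(n[mature] * W[mature])
  fert <- dd$D_a * W * mature / (1 + dd$D_b * B)
  c(sum(fert * n), dd$schedule$s * n[-length(n)])
}

# Central finite-difference Jacobian of the one-step map at equilibrium.
# Equilibrium densities span many orders of magnitude, so the step is
# scaled per age class with a floor (to keep the probed change above the
# cancellation noise of the newborn sum, which is dominated by the huge
# first age class) and a cap (to keep the probed biomass change well inside
# the curvature scale of the compensatory factor).
numeric_jacobian <- function(dd, h_rel = 1e-4) {
  n0 <- dd$n_star
  W <- dd$schedule$mass_g
  k <- length(n0)
  central <- function(j, h) {
    e <- numeric(k); e[j] <- h
    (dd_one_step(dd, n0 + e) - dd_one_step(dd, n0 - e)) / (2 * h)
  }
  J <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- h_rel * max(n0[j], 1e-4 * n0[1])
    h <- min(h, 1e-3 * (1 + dd$D_b * dd$B_star) / (dd$D_b * W[j]))
    J[, j] <- (4 * central(j, h / 2) - central(j, h)) / 3
  }
  J
}

# Empirical asymptotic decay rate toward equilibrium: two-point geometric
# rate over the late part of the projection, after the slower transient
# modes have died out and before the distance reaches the floating-point
# noise floor. A long span averages out the rotational modulation a complex
# dominant Jacobian pair imposes on the distance.
empirical_decay_rate <- function(dd, perturb = 1.05) {
  rate_guess <- exp(-resilience(linearized_jacobian(dd)))
  steps <- min(5000L, max(120L, ceiling(22 / -log(rate_guess))))
  tr <- project(dd, perturb * dd$n_star, steps)
  d <- sqrt(colSums((tr$states - dd$n_star)^2))
  usable <- which(d > 1e-8 * sqrt(sum(dd$n_star^2)))
  x1 <- usable[ceiling(0.4 * length(usable))]
  x2 <- usable[length(usable)]
  (d[x2] / d[x1])^(1 / (x2 - x1))
}

# Ratio of subdominant to dominant Jacobian eigenvalue moduli. The
# empirical decay-rate check is only meaningful when this gap is clear:
# otherwise the asymptotic regime is not reached before the projection
# distance hits the floating-point noise floor.
jacobian_gap <- function(dd) {
  ev <- sort(Mod(eigen(linearized_jacobian(dd), only.values = TRUE)$values),
             decreasing = TRUE)
  ev[2] / ev[1]
}

euler_lotka_c <- function(schedule) {
  mature <- schedule$ages >= schedule$tmat
  1 / sum(schedule$l[mature] * schedule$mass_g[mature])
}

cohort_generation_time <- function(schedule, fert) {
  sum(schedule$ages * schedule$l * fert) / sum(schedule$l * fert)
}
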