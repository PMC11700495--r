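# Internal numerical helpers shared by the builder modules.

# Modulus of the dominant eigenvalue (spectral radius).
spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# Index of the Perron root among computed eigenvalues: the eigenvalue of
# largest real part among those tied (to rounding) for the largest modulus.
# Imprimitive Leslie matrices carry several eigenvalues on the spectral
# circle and LAPACK orders them arbitrarily.
perron_index <- function(values) {
  mods <- Mod(values)
  cand <- which(mods >= max(mods) * (1 - 1e-9))
  cand[which.max(Re(values[cand]))]
}

# Find the root of an increasing scalar function f(u) by geometric bracket
# expansion from u0 followed by uniroot. Used on log-transformed unknowns
# (fertility constant, equilibrium biomass, density coefficient), where the
# objectives are smooth and monotone.
log_bracket_root <- function(f, u0 = 0, step = log(10), max_expand = 700L,
                             tol = 1e-13) {
  f0 <- f(u0)
  if (!is.finite(f0)) stop("root search failed: non-finite objective")
  if (f0 == 0) return(u0)
  lo <- u0
  hi <- u0
  if (f0 < 0) {
    for (i in seq_len(max_expand)) {
      hi <- hi + step
      if (f(hi) >= 0) break
      if (i == max_expand) stop("root search failed: no sign change found")
    }
    lo <- hi - step
  } else {
    for (i in seq_len(max_expand)) {
      lo <- lo - step
      if (f(lo) <= 0) break
      if (i == max_expand) stop("root search failed: no sign change found")
    }
    hi <- lo + step
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

# A few damped-Newton polish steps with a finite-difference slope, to push a
# scalar residual below `target` after a bracketing solve.
polish_root <- function(f, u, target = 1e-13, h = 1e-7, max_iter = 10L) {
  for (k in seq_len(max_iter)) {
    r <- f(u)
    if (!is.finite(r) || abs(r) <= target) break
    slope <- (f(u + h) - r) / h
    if (!is.finite(slope) || slope == 0) break
    u <- u - r / slope
  }
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a
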