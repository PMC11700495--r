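#' Lorenzen mass-dependent mortality coefficients
#'
#' The instantaneous natural mortality rate is modelled as a power function
#' of body mass, `m = -mu * W^upsilon` (per year, negative by convention),
#' so that mortality declines as fish grow when `upsilon < 0`. The defaults
#' are the published general estimates for marine and freshwater fishes
#' (`mu = 3.00` at a body mass of 1 g, `upsilon = -0.288`).
#'
#' @param mu Mortality scale at unit mass (1 g), per year, positive.
#' @param upsilon Mass exponent, dimensionless (negative for declining
#'   mortality with size).
#' @return An object of class `mortality_coefficients`.
#' @export
#' @examples
#' lorenzen_coefficients()        # the built-in defaults
#' lorenzen_coefficients(2.5, -0.3)
lorenzen_coefficients <- function(mu = 3.00, upsilon = -0.288) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a positive number")
  if (!is.numeric(upsilon) || length(upsilon) != 1L || !is.finite(upsilon))
    stop("'upsilon' must be a finite number")
  structure(list(mu = mu, upsilon = upsilon), class = "mortality_coefficients")
}

#' Resolve real-valued ages into integer age classes
#'
#' The matrix size is the maximum age rounded up to the nearest integer, and
#' the first reproducing age class is the age at maturity rounded up, with a
#' floor of 1 because the first age class of the model is age 1. Species
#' whose rounded maximum age is 1 would yield an unstructured (annual)
#' model and are rejected.
#'
#' @param tmax_raw Maximum age, years (real, positive).
#' @param tm Age at maturity, years (real, nonnegative).
#' @return A list with integer components `tmax` and `tmat`.
#' @export
#' @examples
#' resolve_integer_ages(7.2, 1.6)   # tmax = 8, tmat = 2
resolve_integer_ages <- function(tmax_raw, tm) {
  if (!is.numeric(tmax_raw) || length(tmax_raw) != 1L || tmax_raw <= 0)
    stop("'tmax_raw' must be a positive number")
  if (!is.numeric(tm) || length(tm) != 1L || tm < 0)
    stop("'tm' must be a nonnegative number")
  # ceiling with a guard against floating-point noise: ages recovered from a
  # log-scale round trip (exp(log(10)) = 10 + 2e-15) must not gain a year
  tol_ceiling <- function(x) as.integer(ceiling(round(x, 9)))
  tmax <- tol_ceiling(tmax_raw)
  tmat <- max(1L, tol_ceiling(tm))
  if (tmax <= 1L) stop("annual population unsupported (maximum age must be > 1)")
  if (tmat > tmax) stop("maturity after maximum age")
  list(tmax = tmax, tmat = tmat)
}

#' Solve for the theoretical age at length zero
#'
#' Inverts the von Bertalanffy growth curve at the maturity point
#' (`L(tm) = Lm`), giving `t0 = tm + log(1 - Lm/Loo) / K`. Values above
#' -0.1 are capped at -0.1 years.
#'
#' @param Loo Asymptotic total length, cm.
#' @param K Growth coefficient, per year.
#' @param tm Age at maturity, years.
#' @param Lm Total length at maturity, cm; must satisfy `0 < Lm < Loo`.
#' @return `t0` in years, never exceeding -0.1.
#' @export
#' @examples
#' solve_t0(100, 0.5, 2, 90)        # -2.60517
#' solve_t0(100, 0.5, 2, 63.2121)   # algebraic solution ~0 -> capped at -0.1
solve_t0 <- function(Loo, K, tm, Lm) {
  if (Lm >= Loo) stop("maturity length at/above asymptote (Lm >= Loo)")
  if (Lm <= 0) stop("'Lm' must be positive")
  t0 <- tm + log(1 - Lm / Loo) / K
  min(t0, -0.1)
}

#' von Bertalanffy length at age
#'
#' `L(t) = Loo * (1 - exp(-K * (t - t0)))`, total length in cm.
#'
#' @param t Age, years (vectorized).
#' @param Loo Asymptotic total length, cm.
#' @param K Growth coefficient, per year.
#' @param t0 Theoretical age at length zero, years.
#' @return Total length at age `t`, cm.
#' @export
length_at_age <- function(t, Loo, K, t0) {
  Loo * (1 - exp(-K * (t - t0)))
}

#' Convert total length to another basis
#'
#' Applies the linear length-length relationship `alpha + beta * L_TL`.
#'
#' @param L_TL Total length, cm (vectorized).
#' @param conv A [length_length_conversion()] with `from == "TL"`.
#' @return Length in the conversion's target basis, cm.
#' @export
convert_total_length <- function(L_TL, conv) {
  if (!inherits(conv, "length_length_conversion"))
    stop("'conv' must be a length_length_conversion object")
  if (conv$from != "TL")
    stop("conversion must start from total length (from = 'TL')")
  conv$alpha + conv$beta * L_TL
}

# Look up the single-step TL -> to_basis conversion; no chaining.
find_conversion <- function(conversions, to_basis) {
  for (conv in conversions) {
    if (conv$from == "TL" && conv$to == to_basis) return(conv)
  }
  stop("missing length-length conversion (TL -> ", to_basis, ")")
}

#' Body mass at age
#'
#' Computes total length from the growth curve, converts to the basis of the
#' length-mass allometry if needed, and applies `W = a * L^b` (grams).
#'
#' @param t Age, years (vectorized; may be fractional).
#' @param growth List with components `Loo`, `K`, `t0`.
#' @param lw A [length_weight()] allometry.
#' @param conversions List of [length_length_conversion()] objects; consulted
#'   only when `lw$basis != "TL"`.
#' @return Mass at age `t`, grams.
#' @export
mass_at_age <- function(t, growth, lw, conversions = list()) {
  L <- length_at_age(t, growth$Loo, growth$K, growth$t0)
  if (lw$basis != "TL") {
    conv <- find_conversion(conversions, lw$basis)
    L <- convert_total_length(L, conv)
  }
  lw$a * L^lw$b
}

#' Instantaneous mortality at mass
#'
#' Lorenzen mass-dependent mortality, `m = -mu * W^upsilon` per year. The
#' returned rate is negative; its magnitude declines with mass when
#' `upsilon < 0`.
#'
#' @param W Body mass, grams, positive (vectorized).
#' @param coeffs [lorenzen_coefficients()].
#' @return Instantaneous mortality rate, per year (negative).
#' @export
#' @examples
#' mortality_at_mass(1)      # -3.00 with the default coefficients
#' mortality_at_mass(1000)   # -0.41035
mortality_at_mass <- function(W, coeffs = lorenzen_coefficients()) {
  if (any(!is.finite(W)) || any(W <= 0)) stop("nonpositive mass")
  -coeffs$mu * W^coeffs$upsilon
}

#' Finite survival rate over one year of age
#'
#' The proportion surviving from age `t` to `t + 1`,
#' `s_t = exp(integral of m(tau) over [t, t+1])`, where the mortality rate
#' `m(tau)` follows the Lorenzen model evaluated at the continuously growing
#' body mass `W(tau)`. The integral is computed by adaptive quadrature
#' (absolute tolerance 1e-12); `m` is smooth and monotone over the interval.
#'
#' @param t Integer age, `1 <= t <= tmax - 1`.
#' @param growth List with components `Loo`, `K`, `t0`.
#' @param lw A [length_weight()] allometry.
#' @param coeffs [lorenzen_coefficients()].
#' @param conversions Length-length conversions, as in [mass_at_age()].
#' @return Survival probability in (0, 1).
#' @export
finite_survival <- function(t, growth, lw, coeffs = lorenzen_coefficients(),
                            conversions = list()) {
  if (t < 1) stop("'t' out of range: ages start at 1")
  integrand <- function(tau) {
    W <- mass_at_age(tau, growth, lw, conversions)
    if (any(W <= 0)) stop("nonpositive mass inside survival integral")
    coeffs$mu * W^coeffs$upsilon
  }
  I <- integrate(integrand, t, t + 1, rel.tol = 1e-12, abs.tol = 1e-12,
                 subdivisions = 200L)$value
  exp(-I)
}

#' Build the per-age life-history schedule
#'
#' Runs the construction chain for one species: integer ages, `t0`, length
#' at age, mass at age, instantaneous mortality, finite survival between
#' consecutive ages, and survivorship from age 1 (`l_1 = 1`,
#' `l_t = prod(s_1 .. s_{t-1})`).
#'
#' @param sp A [species_input()].
#' @param coeffs [lorenzen_coefficients()].
#' @return An object of class `age_schedule` with components `tmat`, `tmax`,
#'   `t0`, `ages` (1..tmax), `length_cm`, `mass_g`, `m` (per year, negative),
#'   `s` (length `tmax - 1`), `l` (length `tmax`), plus the growth/allometry
#'   pieces needed downstream.
#' @export
#' @examples
#' sp <- species_input("example", 100, 0.5, 2, 60, 10, log(4))
#' sched <- build_age_schedule(sp)
#' sched$s   # survival rates increase with age: mortality declines with mass
build_age_schedule <- function(sp, coeffs = lorenzen_coefficients()) {
  stopifnot(inherits(sp, "species_input"))
  idx <- resolve_integer_ages(sp$tmax, sp$tm)
  t0 <- solve_t0(sp$Loo, sp$K, sp$tm, sp$Lm)
  growth <- list(Loo = sp$Loo, K = sp$K, t0 = t0)
  ages <- seq_len(idx$tmax)
  length_cm <- length_at_age(ages, sp$Loo, sp$K, t0)
  mass_g <- mass_at_age(ages, growth, sp$lw, sp$conversions)
  if (any(mass_g <= 0))
    stop("nonpositive mass on the age schedule; check length-length conversion")
  m <- mortality_at_mass(mass_g, coeffs)
  s <- vapply(seq_len(idx$tmax - 1L), finite_survival, numeric(1),
              growth = growth, lw = sp$lw, coeffs = coeffs,
              conversions = sp$conversions)
  if (any(s <= 0 | s >= 1)) stop("finite survival outside (0, 1)")
  l <- c(1, cumprod(s))
  structure(list(species = sp, species_id = sp$species_id,
                 tmat = idx$tmat, tmax = idx$tmax, t0 = t0, ages = ages,
                 length_cm = length_cm, mass_g = mass_g, m = m, s = s, l = l,
                 growth = growth, lw = sp$lw, conversions = sp$conversions,
                 coeffs = coeffs),
            class = "age_schedule")
}

#' @export
print.age_schedule <- function(x, ...) {
  cat(sprintf("<age_schedule> %s: ages 1..%d, maturity at %d, t0 = %.4f yr\n",
              x$species_id %||% "?", x$tmax, x$tmat, x$t0))
  df <- data.frame(age = x$ages, length_cm = round(x$length_cm, 2),
                   mass_g = round(x$mass_g, 2), m = round(x$m, 4),
                   s = c(round(x$s, 4), NA), l = round(x$l, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
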