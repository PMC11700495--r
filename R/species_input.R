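#' Length-mass allometry
#'
#' Describes the allometric relationship `W = a * L^b` converting length (cm)
#' to mass (grams). The length entering the relationship may be measured as
#' total (`TL`), fork (`FL`) or standard (`SL`) length; when the basis is not
#' total length, a matching length-length conversion must be supplied with
#' the species (see [length_length_conversion()]).
#'
#' @param a Allometric coefficient (grams per cm^`b`), positive.
#' @param b Allometric exponent, positive (typically close to 3).
#' @param basis Length basis the relationship was fitted on: `"TL"`, `"FL"`
#'   or `"SL"` (case-insensitive).
#' @return An object of class `length_weight`.
#' @export
#' @examples
#' length_weight(0.01, 3.0, "TL")
length_weight <- function(a, b, basis = "TL") {
  basis <- normalize_basis(basis)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("allometric coefficient 'a' must be a positive number")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("allometric exponent 'b' must be a positive number")
  structure(list(a = a, b = b, basis = basis), class = "length_weight")
}

#' Length-length conversion
#'
#' Linear conversion between length bases, `L_to = alpha + beta * L_from`.
#' The model works internally in total length; conversions are used
#' single-step, from total length to the basis of the length-mass allometry.
#'
#' @param alpha Intercept, cm.
#' @param beta Slope, dimensionless, positive.
#' @param from,to Length-basis tokens (`"TL"`, `"FL"`, `"SL"`); must differ.
#' @return An object of class `length_length_conversion`.
#' @export
length_length_conversion <- function(alpha, beta, from = "TL", to) {
  from <- normalize_basis(from)
  to <- normalize_basis(to)
  if (from == to) stop("length-length conversion requires two different bases")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("conversion intercept 'alpha' must be a finite number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("conversion slope 'beta' must be a positive number")
  structure(list(alpha = alpha, beta = beta, from = from, to = to),
            class = "length_length_conversion")
}

normalize_basis <- function(basis) {
  basis <- toupper(trimws(as.character(basis)))
  if (length(basis) != 1L || !basis %in% c("TL", "FL", "SL"))
    stop("length basis must be one of 'TL', 'FL', 'SL'")
  basis
}

#' Species life-history input
#'
#' Bundles and validates the life-history parameters needed to build an
#' age-structured matrix population model for one species. All lengths are
#' in cm (total length unless noted), masses in grams, ages in years.
#'
#' @param species_id Character label for the species.
#' @param Loo Asymptotic total length of the von Bertalanffy growth curve, cm.
#' @param K von Bertalanffy growth coefficient, per year.
#' @param tm Age at maturity, years (real; rounded up to an integer age class
#'   during model construction).
#' @param Lm Total length at maturity, cm; must be below `Loo`.
#' @param tmax Maximum age, years (real; rounded up to set the matrix size).
#'   Only species with a rounded maximum age greater than 1 are supported.
#' @param ln_MASPS Natural log of the maximum annual spawner biomass per
#'   spawner biomass in excess of replacement (MASPS), the stock-recruitment
#'   productivity parameter used by the density-dependent model.
#' @param lw A [length_weight()] allometry.
#' @param conversions List of [length_length_conversion()] objects. Required
#'   to contain a conversion from `"TL"` to `lw$basis` when the allometry is
#'   not on total length.
#' @return A validated object of class `species_input`.
#' @export
#' @examples
#' species_input("example", Loo = 100, K = 0.5, tm = 2, Lm = 60,
#'               tmax = 10, ln_MASPS = log(4), lw = length_weight(0.01, 3))
species_input <- function(species_id, Loo, K, tm, Lm, tmax, ln_MASPS,
                          lw = length_weight(0.01, 3.0),
                          conversions = list()) {
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", name, "' must be a finite number")
    as.numeric(x)
  }
  Loo <- num1(Loo, "Loo"); K <- num1(K, "K"); tm <- num1(tm, "tm")
  Lm <- num1(Lm, "Lm"); tmax <- num1(tmax, "tmax")
  ln_MASPS <- num1(ln_MASPS, "ln_MASPS")
  if (Loo <= 0) stop("'Loo' must be positive")
  if (K <= 0) stop("'K' must be positive")
  if (tm < 0) stop("'tm' must be nonnegative")
  if (Lm <= 0) stop("'Lm' must be positive")
  if (Lm >= Loo) stop("maturity length at/above asymptote (Lm >= Loo)")
  if (!inherits(lw, "length_weight")) stop("'lw' must be a length_weight object")
  if (!all(vapply(conversions, inherits, logical(1), "length_length_conversion")))
    stop("'conversions' must be a list of length_length_conversion objects")
  # fails early for unsupported annual species or maturation after death
  ages <- resolve_integer_ages(tmax, tm)
  if (lw$basis != "TL") find_conversion(conversions, lw$basis)
  structure(list(species_id = as.character(species_id), Loo = Loo, K = K,
                 tm = tm, Lm = Lm, tmax = tmax, ln_MASPS = ln_MASPS,
                 lw = lw, conversions = conversions),
            class = "species_input")
}

#' @export
print.species_input <- function(x, ...) {
  cat(sprintf("<species_input> %s\n", x$species_id))
  cat(sprintf("  growth:   Loo = %g cm, K = %g /yr\n", x$Loo, x$K))
  cat(sprintf("  maturity: tm = %g yr, Lm = %g cm; tmax = %g yr\n",
              x$tm, x$Lm, x$tmax))
  cat(sprintf("  ln_MASPS = %g; mass = %g * L^%g (%s basis)\n",
              x$ln_MASPS, x$lw$a, x$lw$b, x$lw$basis))
  invisible(x)
}
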