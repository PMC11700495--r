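test_that("ages round up to integer classes with a floor at age 1", {
  expect_equal(resolve_integer_ages(7.2, 1.6), list(tmax = 8L, tmat = 2L))
  expect_equal(resolve_integer_ages(10.0, 3.0), list(tmax = 10L, tmat = 3L))
  expect_equal(resolve_integer_ages(5.0, 0)$tmat, 1L)      # floor at 1
  expect_equal(resolve_integer_ages(5.0, 0.2)$tmat, 1L)
  expect_error(resolve_integer_ages(0.8, 0.5), "annual population unsupported")
  expect_error(resolve_integer_ages(1.0, 0.5), "annual population unsupported")
  expect_error(resolve_integer_ages(4.2, 5.1), "maturity after maximum age")
})

test_that("t0 inverts the growth curve at maturity and is capped at -0.1", {
  # algebraic solution ~0 (Lm/Loo = 1 - exp(-1)) -> cap applies
  expect_identical(solve_t0(100, 0.5, 2, 63.2121), -0.1)
  expect_equal(solve_t0(100, 0.5, 2, 90), 2 + log(0.1) / 0.5,
               tolerance = 1e-12)
  expect_equal(solve_t0(100, 0.5, 2, 90), -2.60517, tolerance = 1e-5)
  expect_error(solve_t0(100, 0.5, 2, 100), "at/above asymptote")
  expect_error(solve_t0(100, 0.5, 2, 150), "at/above asymptote")
  # never exceeds the cap, wherever the algebraic root lands
  for (Lm in c(10, 40, 63.2121, 90, 99)) {
    expect_lte(solve_t0(100, 0.5, 2, Lm), -0.1)
  }
})

test_that("von Bertalanffy length at age behaves across its range", {
  expect_equal(length_at_age(1, 100, 0.5, -0.1), 100 * (1 - exp(-0.55)),
               tolerance = 1e-12)
  expect_equal(length_at_age(1, 100, 0.5, -0.1), 42.305, tolerance = 1e-4)
  expect_equal(length_at_age(1e6, 100, 0.5, -0.1), 100)     # asymptote
  expect_equal(length_at_age(-0.1, 100, 0.5, -0.1), 0)      # zero-length age
})

test_that("length-length conversion is linear and validated", {
  expect_equal(convert_total_length(50, length_length_conversion(0, 1, "TL", "SL")), 50)
  expect_equal(convert_total_length(50, length_length_conversion(1, 0.8, "TL", "SL")), 41)
  expect_error(length_length_conversion(0, 1, "TL", "TL"), "different bases")
  expect_error(length_length_conversion(0, -1, "TL", "SL"), "positive")
  # requesting a basis with no conversion on record fails at input validation
  expect_error(
    species_input("x", 100, 0.5, 2, 60, 10, log(4),
                  lw = length_weight(0.01, 3, "SL")),
    "missing length-length conversion")
})

test_that("mass at age applies the allometry on the right length basis", {
  growth <- list(Loo = 100, K = 0.5, t0 = -0.1)
  lw <- length_weight(0.01, 3, "TL")
  L1 <- length_at_age(1, 100, 0.5, -0.1)
  expect_equal(mass_at_age(1, growth, lw), 0.01 * L1^3, tolerance = 1e-12)
  # exponent->0 limit: mass approaches the coefficient for all lengths
  expect_equal(mass_at_age(c(1, 5, 20), growth, length_weight(5, 1e-12)),
               rep(5, 3), tolerance = 1e-9)
  # identity TL->SL conversion reproduces the TL result
  lw_sl <- length_weight(0.01, 3, "SL")
  conv <- list(length_length_conversion(0, 1, "TL", "SL"))
  expect_equal(mass_at_age(1:5, growth, lw_sl, conv),
               mass_at_age(1:5, growth, lw, list()), tolerance = 1e-14)
})

test_that("Lorenzen mortality matches its anchors and scaling", {
  expect_identical(mortality_at_mass(1), -3.00)
  expect_equal(mortality_at_mass(1000), -3 * 1000^(-0.288), tolerance = 1e-14)
  expect_equal(mortality_at_mass(1000), -0.410318, tolerance = 1e-5)
  # mass-independence limit
  expect_equal(mortality_at_mass(c(1, 10, 1e4), lorenzen_coefficients(2.5, 0)),
               rep(-2.5, 3))
  # magnitude strictly decreasing in mass for upsilon < 0
  W <- c(1, 5, 50, 500, 5000)
  expect_true(all(diff(abs(mortality_at_mass(W))) < 0))
  expect_error(mortality_at_mass(0), "nonpositive mass")
  expect_error(mortality_at_mass(-1), "nonpositive mass")
})

test_that("finite survival integrates mortality over continuous growth", {
  growth <- list(Loo = 100, K = 0.5, t0 = -0.1)
  lw <- length_weight(0.01, 3, "TL")
  # constant-mortality closed form
  const <- lorenzen_coefficients(3, 0)
  for (t in c(1, 3, 7)) {
    expect_equal(finite_survival(t, growth, lw, const), exp(-3),
                 tolerance = 1e-12)
  }
  # fine-grid Simpson oracle (step 1e-4 yr)
  coeffs <- lorenzen_coefficients()
  integrand <- function(tau) {
    coeffs$mu * mass_at_age(tau, growth, lw)^coeffs$upsilon
  }
  s1_oracle <- exp(-simpson_integral(integrand, 1, 2, h = 1e-4))
  expect_equal(finite_survival(1, growth, lw, coeffs), s1_oracle,
               tolerance = 1e-8)
})

test_that("ratio-of-cumulative-exponentials equals the single-interval form", {
  growth <- list(Loo = 80, K = 0.3, t0 = -0.4)
  lw <- length_weight(0.02, 2.9, "TL")
  coeffs <- lorenzen_coefficients()
  m <- function(tau) -coeffs$mu * mass_at_age(tau, growth, lw)^coeffs$upsilon
  cum <- function(upper) integrate(m, 1, upper, rel.tol = 1e-13)$value
  for (t in c(1, 2, 5)) {
    ratio_form <- exp(cum(t + 1)) / exp(cum(t))
    expect_equal(finite_survival(t, growth, lw, coeffs), ratio_form,
                 tolerance = 1e-12)
  }
})

test_that("the age schedule satisfies its structural identities", {
  sched <- build_age_schedule(reference_species())
  expect_equal(sched$tmax, 10L)
  expect_equal(sched$tmat, 2L)
  expect_equal(length(sched$s), 9L)
  expect_equal(sched$l[1], 1)
  expect_equal(sched$l[3], sched$s[1] * sched$s[2], tolerance = 1e-14)
  expect_equal(sched$l[10], prod(sched$s), tolerance = 1e-14)
  expect_equal(sched$m, -3 * sched$mass_g^(-0.288), tolerance = 1e-12)
})

test_that("schedule invariants hold across a fixture sweep", {
  species <- fixture_species(40, seed = 101)
  expect_length(species, 40L)
  for (sp in species) {
    sched <- build_age_schedule(sp)
    expect_true(all(diff(sched$length_cm) > 0))
    expect_true(all(diff(sched$mass_g) > 0))
    expect_true(all(sched$s > 0 & sched$s < 1))
    # upsilon < 0 and growing mass: survival nondecreasing with age
    expect_true(all(diff(sched$s) >= -1e-12))
    expect_true(all(diff(sched$l) <= 0))
    expect_lte(sched$t0, -0.1)
  }
})
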