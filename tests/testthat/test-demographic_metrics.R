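test_that("eigen-analysis recovers the hand 2x2 solution", {
  A <- assemble_leslie(0.5, c(0, 2))
  eig <- eigen_analysis(A)
  expect_equal(eig$lambda1, 1, tolerance = 1e-12)
  expect_equal(eig$w, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(eig$v, c(1, 2), tolerance = 1e-12)
  expect_error(eigen_analysis(matrix(1, 2, 3)), "non-square")
})

test_that("eigenvector normalizations and stationary structure hold", {
  for (sp in fixture_species(20, seed = 41)) {
    mod <- build_density_independent(sp)
    eig <- eigen_analysis(mod$A)
    expect_equal(sum(eig$w), 1, tolerance = 1e-12)
    expect_equal(eig$v[1], 1)
    expect_true(all(eig$w >= 0) && all(eig$v >= 0))
    # classical oracle: at lambda = 1 the stable structure is survivorship
    expect_equal(eig$w, mod$schedule$l / sum(mod$schedule$l),
                 tolerance = 1e-8)
  }
})

test_that("damping ratio follows the eigenvalue moduli", {
  # quadratic characteristic polynomial: lambda^2 - lambda - 0.5 = 0
  eig <- eigen_analysis(assemble_leslie(0.5, c(1, 1)))
  expect_equal(damping_ratio(eig), 2 + sqrt(3), tolerance = 1e-10)
  # imprimitive 2-cycle: eigenvalues +-1, oscillation never damps
  eig2 <- eigen_analysis(assemble_leslie(0.5, c(0, 2)))
  expect_equal(damping_ratio(eig2), 1, tolerance = 1e-12)
  for (sp in fixture_species(10, seed = 43)) {
    eig <- eigen_analysis(build_density_independent(sp)$A)
    expect_gte(damping_ratio(eig), 1 - 1e-12)
  }
})

test_that("sensitivity is the scaled outer product and matches finite differences", {
  A <- assemble_leslie(0.5, c(0, 2))
  eig <- eigen_analysis(A)
  sens <- sensitivity_matrix(eig, A)
  expect_equal(sens$S, matrix(c(0.5, 1, 0.25, 0.5), 2, 2), tolerance = 1e-12)
  expect_equal(sens$S_masked, matrix(c(0, 1, 0.25, 0), 2, 2),
               tolerance = 1e-12)
  expect_equal(qr(sens$S)$rank, 1L)
  # invariance to eigenvector scaling
  eig2 <- eig; eig2$w <- 7 * eig$w; eig2$v <- 0.3 * eig$v
  expect_equal(sensitivity_matrix(eig2)$S, sens$S, tolerance = 1e-12)

  for (sp in fixture_species(4, seed = 47)) {
    mod <- build_density_independent(sp)
    eig <- eigen_analysis(mod$A)
    S <- sensitivity_matrix(eig)$S
    fd <- fd_lambda_grad(mod$A)
    expect_lt(max(abs(S - fd)), 1e-5)
  }
})

test_that("elasticities are nonnegative, structurally zero, and sum to one", {
  A <- assemble_leslie(0.5, c(0, 2))
  eig <- eigen_analysis(A)
  E <- elasticity_matrix(A, sensitivity_matrix(eig)$S, eig$lambda1)
  expect_equal(E, matrix(c(0, 0.5, 0.5, 0), 2, 2), tolerance = 1e-12)
  for (sp in fixture_species(12, seed = 53)) {
    mod <- build_density_independent(sp)
    eig <- eigen_analysis(mod$A)
    E <- elasticity_matrix(mod$A, sensitivity_matrix(eig)$S, eig$lambda1)
    expect_equal(sum(E), 1, tolerance = 1e-10)
    expect_true(all(E >= -1e-14))
    expect_true(all(E[mod$A == 0] == 0))
  }
})

test_that("generation time equals the cohort mean parental age at lambda = 1", {
  # semelparous hand case
  A <- assemble_leslie(0.5, c(0, 2))
  expect_equal(generation_time(A, eigen_analysis(A)), 2, tolerance = 1e-12)
  # all parents age 1
  A1 <- assemble_leslie(0.5, c(1, 0))
  expect_equal(generation_time(A1, eigen_analysis(A1)), 1, tolerance = 1e-12)
  for (sp in fixture_species(12, seed = 59)) {
    mod <- build_density_independent(sp)
    eig <- eigen_analysis(mod$A)
    G <- generation_time(mod$A, eig)
    expect_equal(G, cohort_generation_time(mod$schedule, mod$fert),
                 tolerance = 1e-8)
    expect_gte(G, mod$schedule$tmat - 1e-9)
    expect_lte(G, mod$schedule$tmax + 1e-9)
  }
})

test_that("the analytic Jacobian matches the numerical one at equilibrium", {
  # hand case: J = [[0, 2/3], [0.5, 0]], lambda_J = sqrt(1/3)
  semel <- toy_schedule(s = 0.5, W = c(1, 4), tmat = 2)
  sol <- solve_Db(semel, D_a = 1.5, p = 3, N_eq = 10000)
  dd_toy <- structure(list(schedule = semel, D_a = 1.5, D_b = sol$D_b,
                           B_star = sol$B_star, n_star = sol$n_star,
                           F_star = 1.5 * c(0, 4) / (1 + sol$D_b * sol$B_star),
                           A_star = assemble_leslie(0.5, 1.5 * c(0, 4) /
                                                      (1 + sol$D_b * sol$B_star))),
                      class = "dd_model")
  J <- linearized_jacobian(dd_toy)
  expect_equal(J, matrix(c(0, 0.5, 2 / 3, 0), 2, 2), tolerance = 1e-8)
  expect_equal(resilience(J), log(3) / 2, tolerance = 1e-8)

  for (sp in fixture_species(10, seed = 61)) {
    dd <- tryCatch(build_density_dependent(sp), error = function(e) NULL)
    if (is.null(dd)) next
    J <- linearized_jacobian(dd)
    # survival rows carry no density feedback
    expect_equal(J[-1, ], dd$A_star[-1, ])
    Jn <- numeric_jacobian(dd)
    expect_lt(max(abs(J - Jn)), 1e-6 * max(1, max(abs(J))))
  }
})

test_that("a vanished density feedback returns the density-independent limit", {
  dd <- build_density_dependent(reference_species())
  dd0 <- dd
  dd0$D_b <- 0
  expect_equal(linearized_jacobian(dd0), dd$A_star)
})

test_that("resilience maps the Jacobian spectrum to a return rate", {
  expect_equal(resilience(matrix(1, 1, 1)), 0)            # neutral
  expect_equal(resilience(matrix(exp(-1), 1, 1)), 1)      # unit rate
  # perturbations decay asymptotically at exp(-R); the empirical rate is
  # only identifiable when the Jacobian has a clear spectral gap
  checked <- 0L
  for (sp in fixture_species(8, seed = 67)) {
    dd <- tryCatch(build_density_dependent(sp), error = function(e) NULL)
    if (is.null(dd)) next
    R <- resilience(linearized_jacobian(dd))
    expect_gt(R, 0)   # compensatory equilibria here are locally stable
    if (jacobian_gap(dd) < 0.9) {
      checked <- checked + 1L
      expect_equal(empirical_decay_rate(dd), exp(-R), tolerance = 0.05)
    }
  }
  expect_gte(checked, 2L)
})

test_that("the combined metrics report is coherent", {
  rep <- compute_metrics(reference_species())
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$lambda1, 1, tolerance = 1e-10)
  expect_gte(rep$rho, 1)
  expect_gte(rep$G, rep$model$schedule$tmat)
  expect_gt(rep$R, 0)
  expect_equal(sum(rep$E), 1, tolerance = 1e-10)
  expect_equal(dim(rep$S), c(10L, 10L))
  expect_true(all(rep$S_masked[rep$model$A == 0] == 0))
})
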