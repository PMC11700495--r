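#' Eigen-analysis of a projection matrix
#'
#' Dense eigen-decomposition with eigenvalues ordered by modulus. For the
#' nonnegative Leslie matrices built here the dominant pair is real and
#' positive (Perron-Frobenius). The stable age distribution `w` is the right
#' eigenvector normalized to sum to 1; the reproductive value `v` is the
#' left eigenvector scaled so the first age class has value 1.
#'
#' @param A Square projection matrix.
#' @return An object of class `eigen_analysis` with `lambda1`,
#'   `lambda2_mod`, `w`, `v` and the full modulus-ordered eigenvalue vector
#'   `values`.
#' @export
#' @examples
#' eigen_analysis(assemble_leslie(0.5, c(0, 2)))
eigen_analysis <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("non-square input")
  e <- eigen(A)
  dom <- perron_index(e$values)
  lambda1 <- Re(e$values[dom])
  w <- Re(e$vectors[, dom])
  w <- w / sum(w)
  el <- eigen(t(A))
  v <- Re(el$vectors[, perron_index(el$values)])
  v <- v / v[1L]
  # clamp eigen-solver noise on the Perron vectors
  w[w < 0 & w > -1e-10] <- 0
  v[v < 0 & v > -1e-10] <- 0
  rest <- Mod(e$values[-dom])
  ord <- order(Mod(e$values), decreasing = TRUE)
  structure(list(lambda1 = lambda1,
                 lambda2_mod = if (length(rest)) max(rest) else NA_real_,
                 w = w, v = v, values = e$values[ord]),
            class = "eigen_analysis")
}

#' Damping ratio
#'
#' `rho = lambda_1 / |lambda_2|`: how quickly transient fluctuations decay
#' toward the stable age distribution. `rho = 1` for imprimitive models
#' (e.g. a single fertile age class) whose oscillations never damp.
#'
#' @param eig An [eigen_analysis()] result.
#' @return `rho >= 1`; `Inf` with a warning if the second eigenvalue is 0.
#' @export
damping_ratio <- function(eig) {
  if (!is.finite(eig$lambda2_mod) || eig$lambda2_mod <= 0) {
    warning("second eigenvalue is zero; damping ratio is infinite")
    return(Inf)
  }
  eig$lambda1 / eig$lambda2_mod
}

#' Sensitivity matrix
#'
#' `S = v w^T / (v . w)`: the derivative of the dominant eigenvalue with
#' respect to each matrix entry, a rank-1 outer product invariant to the
#' scalings of `v` and `w`. The masked variant zeroes entries where the
#' projection matrix itself is structurally zero, which is how the matrix is
#' usually displayed.
#'
#' @param eig An [eigen_analysis()] result.
#' @param A Optional projection matrix used to mask structural zeros.
#' @return List with `S` (full rank-1 matrix) and `S_masked` (or `NULL`
#'   when `A` is not supplied).
#' @export
sensitivity_matrix <- function(eig, A = NULL) {
  S <- outer(eig$v, eig$w) / sum(eig$v * eig$w)
  S_masked <- if (!is.null(A)) S * (A != 0) else NULL
  list(S = S, S_masked = S_masked)
}

#' Elasticity matrix
#'
#' `e_ij = a_ij * s_ij / lambda_1`: proportional sensitivities, which are
#' nonnegative, zero on structural zeros, and sum to 1 over the matrix.
#'
#' @param A Projection matrix.
#' @param S Sensitivity matrix (full, unmasked).
#' @param lambda1 Dominant eigenvalue.
#' @return Elasticity matrix of the same dimension as `A`.
#' @export
elasticity_matrix <- function(A, S, lambda1) {
  if (lambda1 <= 0) stop("'lambda1' must be positive")
  A * S / lambda1
}

#' Generation time
#'
#' Mean age of the parents of a newborn cohort,
#' `G = lambda_1 (v . w) / (v^T F w)`, where `F` keeps only the fertility
#' row of the projection matrix. Lies between the age at maturity and the
#' maximum age.
#'
#' @param A Projection matrix (fertilities in row 1).
#' @param eig An [eigen_analysis()] result for `A`.
#' @return Generation time in years.
#' @export
generation_time <- function(A, eig) {
  fert <- A[1L, ]
  den <- eig$v[1L] * sum(fert * eig$w)   # v^T F w with F = fertility row only
  if (den == 0) stop("no reproduction: zero denominator in generation time")
  eig$lambda1 * sum(eig$v * eig$w) / den
}

#' Linearized Jacobian of the density-dependent dynamics
#'
#' Jacobian of the one-step projection map evaluated at the equilibrium
#' `n*`. Survival rows are density-independent and equal the rows of the
#' equilibrium matrix; only the fertility row picks up the density
#' feedback:
#' `J[1, j] = F*_j - 1(j mature) * W_j * D_b / (1 + D_b B*) * sum(F* n*)`.
#'
#' @param dd A [build_density_dependent()] model.
#' @return The Jacobian matrix `J`.
#' @export
linearized_jacobian <- function(dd) {
  stopifnot(inherits(dd, "dd_model"))
  mature <- dd$schedule$ages >= dd$schedule$tmat
  W <- dd$schedule$mass_g
  J <- dd$A_star
  shrink <- dd$D_b / (1 + dd$D_b * dd$B_star) * sum(dd$F_star * dd$n_star)
  J[1L, mature] <- J[1L, mature] - W[mature] * shrink
  J
}

#' Resilience of the density-dependent equilibrium
#'
#' `R = -log(|lambda_J|)`, with `lambda_J` the dominant eigenvalue of the
#' linearized dynamics at equilibrium. Positive `R` means the equilibrium is
#' locally stable, with perturbations shrinking asymptotically by a factor
#' `exp(-R)` per year.
#'
#' @param J Jacobian from [linearized_jacobian()].
#' @return Resilience, per year.
#' @export
resilience <- function(J) {
  -log(spectral_radius(J))
}

#' Compute the full metric set for one species
#'
#' Builds the density-independent and density-dependent models and computes
#' the seven metrics: dominant eigenvalue (1 by construction), damping
#' ratio, generation time, resilience, stable age distribution,
#' reproductive value, and sensitivity and elasticity matrices.
#'
#' @param sp A [species_input()].
#' @param coeffs [lorenzen_coefficients()].
#' @param N_eq Equilibrium abundance of mature fish for the
#'   density-dependent variant.
#' @return An object of class `metrics_report` with scalar metrics
#'   (`lambda1`, `rho`, `G`, `R`), vectors (`w`, `v`), matrices (`S`,
#'   `S_masked`, `E`) and the two fitted models (`model`, `dd_model`).
#' @export
#' @examples
#' sp <- species_input("example", 100, 0.5, 2, 60, 10, log(4))
#' rep <- compute_metrics(sp)
#' c(rep$rho, rep$G, rep$R)
compute_metrics <- function(sp, coeffs = lorenzen_coefficients(),
                            N_eq = 10000) {
  di <- build_density_independent(sp, coeffs)
  dd <- build_density_dependent(di, N_eq = N_eq)
  eig <- eigen_analysis(di$A)
  sens <- sensitivity_matrix(eig, di$A)
  E <- elasticity_matrix(di$A, sens$S, eig$lambda1)
  structure(list(species_id = sp$species_id,
                 lambda1 = eig$lambda1,
                 rho = damping_ratio(eig),
                 G = generation_time(di$A, eig),
                 R = resilience(linearized_jacobian(dd)),
                 w = eig$w, v = eig$v,
                 S = sens$S, S_masked = sens$S_masked, E = E,
                 model = di, dd_model = dd),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s\n", x$species_id))
  cat(sprintf("  lambda1 = %.10f\n", x$lambda1))
  cat(sprintf("  damping ratio   rho = %.4f\n", x$rho))
  cat(sprintf("  generation time G   = %.4f yr\n", x$G))
  cat(sprintf("  resilience      R   = %.4f /yr\n", x$R))
  invisible(x)
}
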