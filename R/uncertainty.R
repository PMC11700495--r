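# Order of the sampled life-history coordinates throughout this module.
lh_parameters <- c("Loo", "K", "tm", "Lm", "tmax", "ln_MASPS")

#' Life-history parameter distribution
#'
#' Multivariate-normal distribution over the six sampled life-history
#' coordinates (`Loo`, `K`, `tm`, `Lm`, `tmax`, `ln_MASPS`). Predictive
#' means and covariances for such parameters are conventionally reported on
#' the log scale for the strictly positive quantities, so by default every
#' coordinate except `ln_MASPS` (already a log) is sampled on the log scale
#' and exponentiated after drawing; the flags are configurable because the
#' scale of an external covariance matrix is an interpretation the user must
#' make explicit.
#'
#' @param mean Numeric vector of length 6 (ordered or named as
#'   `Loo, K, tm, Lm, tmax, ln_MASPS`) on the *sampling* scale, i.e. log
#'   values for log-flagged coordinates.
#' @param cov 6 x 6 symmetric positive-semidefinite covariance matrix on the
#'   same scale.
#' @param log_scale Logical vector of length 6: which coordinates are
#'   sampled on the log scale.
#' @return An object of class `parameter_distribution`.
#' @export
parameter_distribution <- function(mean, cov,
                                   log_scale = c(Loo = TRUE, K = TRUE,
                                                 tm = TRUE, Lm = TRUE,
                                                 tmax = TRUE,
                                                 ln_MASPS = FALSE)) {
  k <- length(lh_parameters)
  if (length(mean) != k) stop("'mean' must have ", k, " entries")
  if (!is.null(names(mean))) mean <- mean[lh_parameters]
  if (any(is.na(mean))) stop("'mean' has missing or misnamed entries")
  cov <- as.matrix(cov)
  if (!all(dim(cov) == k)) stop("'cov' must be ", k, " x ", k)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("'cov' must be symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("'cov' must be positive semi-definite")
  if (length(log_scale) != k) stop("'log_scale' must have ", k, " entries")
  structure(list(mean = setNames(as.numeric(mean), lh_parameters),
                 cov = cov, log_scale = setNames(as.logical(log_scale),
                                                 lh_parameters)),
            class = "parameter_distribution")
}

#' Distribution centred on a species input
#'
#' Convenience constructor: centres a [parameter_distribution()] on the
#' natural-scale parameters of `sp` (taking logs of the log-flagged
#' coordinates) with independent coordinate standard deviations `sd` on the
#' sampling scale. With `sd = 0` the distribution is degenerate at `sp`.
#'
#' @param sp A [species_input()].
#' @param sd Scalar or length-6 vector of sampling-scale standard
#'   deviations (a log-scale sd is approximately a coefficient of
#'   variation).
#' @return A `parameter_distribution`.
#' @export
distribution_from_species <- function(sp, sd = 0.1) {
  natural <- c(Loo = sp$Loo, K = sp$K, tm = sp$tm, Lm = sp$Lm,
               tmax = sp$tmax, ln_MASPS = sp$ln_MASPS)
  log_scale <- c(Loo = TRUE, K = TRUE, tm = TRUE, Lm = TRUE, tmax = TRUE,
                 ln_MASPS = FALSE)
  if (any(log_scale & natural <= 0))
    stop("log-scale coordinates need positive values in 'sp'")
  mu <- natural
  mu[log_scale] <- log(natural[log_scale])
  sd <- rep_len(sd, length(lh_parameters))
  parameter_distribution(mu, diag(sd^2, length(lh_parameters)), log_scale)
}

# Raw draws on the natural scale: n x 6 matrix, invalid rows included.
draw_parameter_matrix <- function(dist, n) {
  Z <- MASS::mvrnorm(n, mu = dist$mean, Sigma = dist$cov)
  if (n == 1L) Z <- matrix(Z, nrow = 1L)
  colnames(Z) <- lh_parameters
  Z[, dist$log_scale] <- exp(Z[, dist$log_scale, drop = FALSE])
  Z
}

# Build a species_input from one natural-scale parameter row, reusing the
# allometry/conversions of a template species. Errors signal invalid draws.
species_from_draw <- function(par, template, label = template$species_id) {
  species_input(label, Loo = par[["Loo"]], K = par[["K"]], tm = par[["tm"]],
                Lm = par[["Lm"]], tmax = par[["tmax"]],
                ln_MASPS = par[["ln_MASPS"]], lw = template$lw,
                conversions = template$conversions)
}

#' Sample valid life histories from a parameter distribution
#'
#' Draws from the multivariate normal (exponentiating log-scale
#' coordinates), rejects draws that violate the species-input invariants
#' (`Loo > 0`, `K > 0`, `0 < Lm < Loo`, rounded `tmax > 1`, maturity not
#' after maximum age), and resamples until `n` valid draws are collected or
#' a cap of `100 * n` attempts is hit. Rejection (rather than clipping)
#' keeps the sampled distribution undistorted.
#'
#' @param dist A [parameter_distribution()].
#' @param n Number of valid draws required.
#' @param template A [species_input()] providing the non-sampled pieces
#'   (label, length-mass allometry, length-length conversions).
#' @param seed Optional integer seed for reproducibility.
#' @return List of `n` validated `species_input` objects, with the number of
#'   rejected draws in `attr(, "n_rejected")`.
#' @export
sample_life_histories <- function(dist, n, template, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  got <- 0L
  attempts <- 0L
  cap <- 100L * n
  while (got < n) {
    batch <- min(n - got, cap - attempts)
    if (batch <= 0L)
      stop("distribution mostly invalid: rejection cap exceeded")
    P <- draw_parameter_matrix(dist, batch)
    attempts <- attempts + batch
    for (i in seq_len(batch)) {
      sp <- tryCatch(species_from_draw(P[i, ], template),
                     error = function(e) NULL)
      if (!is.null(sp)) {
        got <- got + 1L
        out[[got]] <- sp
        if (got == n) break
      }
    }
  }
  attr(out, "n_rejected") <- attempts - n
  out
}

#' Run a Monte-Carlo ensemble of model builds
#'
#' Draws `n` parameter sets, builds both model variants for each draw and
#' computes the scalar metrics. Every draw is accounted for exactly once:
#' draws violating the input invariants are recorded as `"rejected"`, draws
#' where model construction fails (e.g. maturation in the terminal age
#' class) as `"failed"` with the error message as reason code, and
#' successful draws as `"ok"`.
#'
#' @param dist A [parameter_distribution()].
#' @param template A [species_input()] providing label, allometry and
#'   conversions.
#' @param n Number of draws (the reference analysis uses 1,000 per species).
#' @param seed Optional integer seed; fixing it makes the ensemble
#'   bit-reproducible.
#' @param coeffs [lorenzen_coefficients()].
#' @param N_eq Equilibrium mature abundance for the density-dependent model.
#' @return Data frame with one row per draw: draw index, the six sampled
#'   parameters (natural scale), `lambda1`, `rho`, `G`, `R`, `status` and
#'   `reason`. Counts are attached as `attr(, "counts")`
#'   (`n_valid`, `n_failed`, `n_rejected`).
#' @export
run_ensemble <- function(dist, template, n = 1000, seed = NULL,
                         coeffs = lorenzen_coefficients(), N_eq = 10000) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  P <- draw_parameter_matrix(dist, n)
  res <- data.frame(draw = seq_len(n), P,
                    lambda1 = NA_real_, rho = NA_real_, G = NA_real_,
                    R = NA_real_, status = NA_character_,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- tryCatch(species_from_draw(P[i, ], template), error = function(e) e)
    if (inherits(sp, "error")) {
      res$status[i] <- "rejected"
      res$reason[i] <- conditionMessage(sp)
      next
    }
    rep <- tryCatch(compute_metrics(sp, coeffs, N_eq), error = function(e) e)
    if (inherits(rep, "error")) {
      res$status[i] <- "failed"
      res$reason[i] <- conditionMessage(rep)
    } else {
      res$status[i] <- "ok"
      res$lambda1[i] <- rep$lambda1
      res$rho[i] <- rep$rho
      res$G[i] <- rep$G
      res$R[i] <- rep$R
    }
  }
  attr(res, "counts") <- c(n_valid = sum(res$status == "ok"),
                           n_failed = sum(res$status == "failed"),
                           n_rejected = sum(res$status == "rejected"))
  res
}

#' Box-plot summary of an ensemble metric
#'
#' Median, quartiles (linear interpolation between order statistics,
#' `quantile` type 7), whiskers at the furthest data points within 1.5 x IQR
#' beyond the quartiles, and outliers beyond the whiskers.
#'
#' @param values Numeric vector; non-finite entries are dropped.
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers` (sorted) and `n`.
#' @export
#' @examples
#' summarize_boxplot(1:9)
summarize_boxplot <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]), n = length(values))
}

#' Box-plot summaries for all metrics of an ensemble
#'
#' @param ens A [run_ensemble()] result.
#' @return Data frame with one row per scalar metric (`lambda1`, `rho`,
#'   `G`, `R`) computed over the successful draws.
#' @export
summarize_ensemble <- function(ens) {
  ok <- ens[ens$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) stop("no successful draws to summarize")
  rows <- lapply(c("lambda1", "rho", "G", "R"), function(metric) {
    b <- summarize_boxplot(ok[[metric]])
    data.frame(metric = metric, median = b$median, q1 = b$q1, q3 = b$q3,
               whisker_low = b$whisker_low, whisker_high = b$whisker_high,
               n_outliers = length(b$outliers), n = b$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
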