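# Table I/O and synthetic fixture generation. The species-table schema uses
# the conventional database symbols as column names so exports can be pasted
# in directly: species, Loo, K, tm, Lm, tmax, ln_MASPS, lw_a, lw_b,
# lw_basis, plus optional repeatable length-length groups
# ll_alpha[suffix], ll_beta[suffix], ll_from[suffix], ll_to[suffix].

required_columns <- c("species", "Loo", "K", "tm", "Lm", "tmax", "ln_MASPS",
                      "lw_a", "lw_b", "lw_basis")

# Build one species_input from a single data-frame row; errors are row-level
# validation failures.
species_from_row <- function(row) {
  num <- function(col) {
    x <- suppressWarnings(as.numeric(row[[col]]))
    if (length(x) != 1L || is.na(x))
      stop("unparseable numeric in column '", col, "'")
    x
  }
  suffixes <- sub("^ll_alpha", "", grep("^ll_alpha", names(row), value = TRUE))
  conversions <- list()
  for (sfx in suffixes) {
    alpha <- suppressWarnings(as.numeric(row[[paste0("ll_alpha", sfx)]]))
    if (length(alpha) == 0L || is.na(alpha)) next   # unused optional group
    conversions[[length(conversions) + 1L]] <- length_length_conversion(
      alpha = alpha,
      beta = num(paste0("ll_beta", sfx)),
      from = row[[paste0("ll_from", sfx)]],
      to = row[[paste0("ll_to", sfx)]])
  }
  species_input(species_id = as.character(row[["species"]]),
                Loo = num("Loo"), K = num("K"), tm = num("tm"),
                Lm = num("Lm"), tmax = num("tmax"),
                ln_MASPS = num("ln_MASPS"),
                lw = length_weight(num("lw_a"), num("lw_b"),
                                   row[["lw_basis"]]),
                conversions = conversions)
}

#' Convert a species table to a list of validated species inputs
#'
#' @param df Data frame in the species-table schema.
#' @return List of [species_input()] objects; row-level validation errors
#'   are collected in `attr(, "row_errors")` and raised as a warning (or an
#'   error if no row is valid).
#' @export
species_list_from_table <- function(df) {
  miss <- setdiff(required_columns, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  out <- list()
  errors <- character()
  for (i in seq_len(nrow(df))) {
    sp <- tryCatch(species_from_row(df[i, , drop = FALSE]),
                   error = function(e) conditionMessage(e))
    if (is.character(sp)) {
      errors <- c(errors, sprintf("row %d: %s", i, sp))
    } else {
      out[[length(out) + 1L]] <- sp
    }
  }
  if (length(errors)) {
    if (length(out) == 0L)
      stop("no valid rows:\n", paste(errors, collapse = "\n"))
    warning("skipped invalid row(s):\n", paste(errors, collapse = "\n"))
  }
  attr(out, "row_errors") <- errors
  out
}

#' Read a species parameter table
#'
#' Reads a delimited text file (comma- or tab-separated, sniffed from the
#' header line) in the species-table schema and validates each row.
#'
#' @param path Path to the table.
#' @return As [species_list_from_table()].
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  species_list_from_table(df)
}

#' Write a species table
#'
#' @param df Data frame in the species-table schema (e.g. from
#'   [generate_fixture_species()]).
#' @param path Output path; written as comma-separated text with a header.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic fixture species
#'
#' Produces a reproducible table of synthetic species with parameters drawn
#' from plausible teleost ranges, with the cross-parameter couplings real
#' fishes show (so that, e.g., survivorship to maturity never implies
#' absurd compensating fecundities): `tmax` uniform in 3-40 yr; `Loo`
#' log-uniform between `max(10, tmax)` and 200 cm (long-lived species are
#' not tiny); `K` uniform within `[max(0.1, 1.5/tmax), min(1.0, 8/tmax)]`
#' (fast growers are short-lived); `tm` at 12-35% of `tmax`; `Lm` placed on
#' the growth curve at `tm` (maturity length consistent with growth, using
#' a provisional age-at-length-zero in `[-1, -0.1]`); `ln_MASPS` uniform in
#' `[log 0.5, log 20]`; allometry `a` in 0.005-0.05 and `b` in 2.8-3.2,
#' mostly on the TL basis with occasional FL/SL rows carrying their own
#' conversion. The first three rows are deterministic edge cases: maturity
#' in the first age class, maturity in the terminal age class, and a
#' long-lived species (`tmax >= 30`).
#'
#' @param n Number of species, at least 1.
#' @param seed Optional integer seed.
#' @return Data frame in the species-table schema.
#' @export
#' @examples
#' tab <- generate_fixture_species(5, seed = 1)
#' species <- species_list_from_table(tab)
generate_fixture_species <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tmax <- stats::runif(n, 3, 40)
  Loo <- exp(stats::runif(n, log(pmax(10, tmax)), log(200)))
  K <- numeric(n)
  for (i in seq_len(n)) {
    klo <- max(0.1, 1.5 / tmax[i])
    khi <- min(1.0, 8 / tmax[i])
    K[i] <- stats::runif(1, klo, khi)
  }
  tm <- stats::runif(n, pmax(0.4, 0.12 * tmax), pmin(0.35 * tmax, tmax - 0.5))
  t00 <- stats::runif(n, -1.0, -0.1)
  ln_MASPS <- stats::runif(n, log(0.5), log(20))
  lw_a <- stats::runif(n, 0.005, 0.05)
  lw_b <- stats::runif(n, 2.8, 3.2)
  lw_basis <- sample(c("TL", "FL", "SL"), n, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))
  ll_alpha <- ifelse(lw_basis == "TL", NA_real_, stats::runif(n, -0.5, 0.5))
  ll_beta <- ifelse(lw_basis == "TL", NA_real_, stats::runif(n, 0.8, 1.1))
  ll_from <- ifelse(lw_basis == "TL", NA_character_, "TL")
  ll_to <- ifelse(lw_basis == "TL", NA_character_, lw_basis)

  # deterministic edge cases up front
  if (n >= 1L) {                      # maturity in the first age class
    tmax[1] <- 6.3; K[1] <- 0.6; tm[1] <- 0.4
  }
  if (n >= 2L) {                      # maturity in the terminal age class
    tmax[2] <- 4.0; K[2] <- 0.8; tm[2] <- 3.2
  }
  if (n >= 3L) {                      # long-lived species
    tmax[3] <- stats::runif(1, 30, 40); K[3] <- stats::runif(1, 0.1, 0.2)
    tm[3] <- stats::runif(1, 4, 8)
  }
  # maturity length sits on the growth curve at the maturity age
  Lm <- Loo * (1 - exp(-K * (tm - t00)))

  data.frame(species = sprintf("fixture_%03d", seq_len(n)),
             Loo = Loo, K = K, tm = tm, Lm = Lm, tmax = tmax,
             ln_MASPS = ln_MASPS, lw_a = lw_a, lw_b = lw_b,
             lw_basis = lw_basis, ll_alpha = ll_alpha, ll_beta = ll_beta,
             ll_from = ll_from, ll_to = ll_to, stringsAsFactors = FALSE)
}

#' Write model and metric outputs
#'
#' Writes, per species: the projection matrix (`<id>_matrix.csv`, row-major,
#' header-free), the stable age distribution and reproductive value
#' (`<id>_w.csv`, `<id>_v.csv`), the masked sensitivity and the elasticity
#' matrices (`<id>_S.csv`, `<id>_E.csv`, header-free), and, when the
#' density-dependent model is present, the equilibrium age vector
#' (`<id>_equilibrium.csv`). A combined `metrics.csv` holds one row per
#' species (`species_id`, `lambda1`, `rho`, `G`, `R`) and `manifest.json`
#' records the seed, configuration and package version of the run.
#'
#' @param reports A `metrics_report` or list of them.
#' @param outdir Output directory, created if needed.
#' @param seed Seed to record in the manifest (optional).
#' @param config Extra configuration to record in the manifest (optional
#'   list; the mortality coefficients and `N_eq` actually used are taken
#'   from the reports).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(reports, outdir, seed = NULL, config = list()) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(x, name, header = FALSE, col_names = NULL) {
    path <- file.path(outdir, name)
    if (is.matrix(x)) {
      write.table(x, path, sep = ",", row.names = FALSE, col.names = FALSE)
    } else {
      write.csv(x, path, row.names = FALSE, quote = FALSE)
    }
    files <<- c(files, path)
    path
  }
  metrics <- do.call(rbind, lapply(reports, function(r)
    data.frame(species_id = r$species_id, lambda1 = r$lambda1, rho = r$rho,
               G = r$G, R = r$R, stringsAsFactors = FALSE)))
  put(metrics, "metrics.csv")
  for (r in reports) {
    id <- r$species_id
    ages <- seq_along(r$w)
    put(r$model$A, paste0(id, "_matrix.csv"))
    put(data.frame(age = ages, w = r$w), paste0(id, "_w.csv"))
    put(data.frame(age = ages, v = r$v), paste0(id, "_v.csv"))
    put(r$S_masked, paste0(id, "_S.csv"))
    put(r$E, paste0(id, "_E.csv"))
    if (!is.null(r$dd_model))
      put(data.frame(age = ages, n_star = r$dd_model$n_star),
          paste0(id, "_equilibrium.csv"))
  }
  first <- reports[[1L]]
  manifest <- list(seed = seed,
                   package = "fishmpm",
                   version = as.character(packageVersion("fishmpm")),
                   mortality = first$model$schedule$coeffs[c("mu", "upsilon")],
                   N_eq = if (!is.null(first$dd_model)) first$dd_model$N_eq,
                   species = vapply(reports, `[[`, character(1), "species_id"),
                   config = config)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, mpath))
}
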