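# Seeded RNG without touching global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate responses from a known quadratic surface
#'
#' Generates a response column for every run of a CCD by evaluating a known
#' second-order polynomial at the coded design points and adding i.i.d.
#' Gaussian noise. Used to test parameter recovery of the fitting stage:
#' with `sigma = 0` the fit must recover `beta` exactly.
#'
#' @param design A [ccd_design()].
#' @param beta Numeric coefficient vector in canonical term order (intercept,
#'   linear, two-way interactions, quadratics), length `1 + 2k + k(k-1)/2`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed (explicit, never global state).
#' @param response Name of the generated response column.
#' @return The design's runs with the simulated response appended.
#' @examples
#' des <- ajwa_design()
#' truth <- c(23.10, 0.9656, -0.5854, 1.71, -1.22, -1.22, 1.57, -3.78, -4.29, -2.81)
#' simulate_ccd_responses(des, truth, sigma = 0)$y[17] # centre response = 23.10
#' @export
simulate_ccd_responses <- function(design, beta, sigma = 0, seed = NULL,
                                   response = "y") {
  if (sigma < 0) stop("`sigma` must be >= 0.", call. = FALSE)
  fnames <- design$factors$name
  terms <- quadratic_terms(fnames)
  if (length(beta) != nrow(terms)) {
    stop("`beta` must have ", nrow(terms), " entries (canonical term order).",
         call. = FALSE)
  }
  cm <- as.matrix(code_points(design, design$runs[fnames])[fnames])
  mu <- drop(quadratic_model_matrix(cm, terms) %*% beta)
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sigma))
  out <- design$runs
  out[[response]] <- y
  out
}

#' Simulate a four-parameter-logistic dose-response series
#'
#' Mean curve `bottom + (top - bottom) / (1 + (ic50/dose)^hill)` plus
#' Gaussian noise. At `dose = ic50` the noise-free response is the midpoint
#' `(bottom + top) / 2`.
#'
#' @param doses Positive dose vector.
#' @param ic50 Inflection dose (> 0).
#' @param hill Hill slope.
#' @param bottom,top Asymptotes (percent inhibition).
#' @param sigma Noise SD (absolute, percent-inhibition units).
#' @param seed Integer seed.
#' @return A tibble with `dose` and `inhibition` columns.
#' @export
simulate_dose_response <- function(doses, ic50, hill = 1, bottom = 0, top = 100,
                                   sigma = 0, seed = NULL) {
  if (ic50 <= 0) stop("`ic50` must be positive.", call. = FALSE)
  if (any(doses <= 0)) stop("Doses must be positive.", call. = FALSE)
  mu <- four_pl_curve(doses, ic50, hill, bottom, top)
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sigma))
  tibble::tibble(dose = doses, inhibition = y)
}

#' Simulate a sample-by-variable activity matrix with controlled correlation
#'
#' One standard-normal latent factor with loading `sqrt(latent_corr)` on
#' every variable plus idiosyncratic noise with variance `1 - latent_corr`,
#' so every pair of variables has population correlation `latent_corr`
#' (an equicorrelation structure whose leading correlation-matrix eigenvalue
#' is `1 + (n_vars - 1) * latent_corr`).
#'
#' @param n_samples,n_vars Matrix dimensions.
#' @param latent_corr Common pairwise correlation, in \[0, 1).
#' @param seed Integer seed.
#' @return A tibble with a `sample` column and `n_vars` numeric variables.
#' @export
simulate_activity_matrix <- function(n_samples, n_vars, latent_corr, seed = NULL) {
  if (latent_corr < 0 || latent_corr >= 1) {
    stop("`latent_corr` must be in [0, 1).", call. = FALSE)
  }
  X <- with_seed(seed, {
    f <- stats::rnorm(n_samples)
    sqrt(latent_corr) * matrix(f, n_samples, n_vars) +
      sqrt(1 - latent_corr) * matrix(stats::rnorm(n_samples * n_vars),
                                     n_samples, n_vars)
  })
  colnames(X) <- paste0("V", seq_len(n_vars))
  dplyr::bind_cols(tibble::tibble(sample = paste0("S", seq_len(n_samples))),
                   tibble::as_tibble(X))
}
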