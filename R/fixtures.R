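#' Packaged extraction-optimization dataset (unripe Ajwa date pulp)
#'
#' A published 3-factor, 5-level central composite design (20 runs) for heat
#' extraction of polyphenols from unripe Ajwa date pulp: ethanol concentration
#' (%), extraction time (min) and temperature (deg C), with total phenolic
#' content (TPC, mg gallic-acid equivalents/g) and total flavonoid content
#' (TFC, mg catechin equivalents/g) as responses.
#'
#' `ajwa_design()` returns the design (centres 50 / 82.5 / 60, steps
#' 25 / 37.5 / 10, axial levels 0-100 / 15-150 / 40-80, six centre
#' replicates); note the time axial levels code to +/-1.8, not +/-2.
#' `ajwa_runs()` returns the 20 experimental runs in the randomized order
#' they were reported.
#'
#' @return `ajwa_design()`: a [ccd_design()]. `ajwa_runs()`: a tibble with
#'   columns `ethanol`, `time`, `temperature`, `TPC`, `TFC`.
#' @examples
#' rt <- match_runs(ajwa_design(), ajwa_runs(), c("TPC", "TFC"))
#' @export
ajwa_design <- function() {
  ccd_design(
    list(
      ccd_factor("ethanol", 50, 25, 0, 100, units = "%"),
      ccd_factor("time", 82.5, 37.5, 15, 150, units = "min"),
      ccd_factor("temperature", 60, 10, 40, 80, units = "deg C")
    ),
    n_center = 6
  )
}

#' @rdname ajwa_design
#' @export
ajwa_runs <- function() {
  tibble::tribble(
    ~ethanol, ~time, ~temperature, ~TPC, ~TFC,
    100, 82.5, 60, 5.41, 11.02,
    50, 82.5, 60, 23.69, 21.05,
    75, 120, 70, 13.75, 12.90,
    50, 15, 60, 10.24, 11.52,
    75, 120, 50, 10.21, 7.83,
    50, 82.5, 60, 23.12, 24.20,
    0, 82.5, 60, 6.53, 6.85,
    25, 45, 70, 17.50, 11.52,
    25, 120, 50, 8.88, 6.81,
    50, 82.5, 80, 23.00, 16.05,
    50, 82.5, 60, 23.10, 23.59,
    50, 82.5, 60, 23.51, 24.01,
    50, 82.5, 60, 23.92, 24.01,
    25, 45, 50, 7.85, 7.85,
    50, 150, 60, 10.11, 9.25,
    75, 45, 50, 11.01, 15.25,
    25, 120, 70, 19.22, 15.25,
    50, 82.5, 40, 10.05, 9.59,
    50, 82.5, 60, 23.10, 23.25,
    75, 45, 70, 14.58, 12.56
  )
}

#' Published validation pairs at the desirability optimum
#'
#' Experimental (triplicate mean) and model-predicted TPC/TFC at the
#' optimized extraction condition (51.97% ethanol, 81.38 min, 62.76 deg C),
#' as reported.
#'
#' @return A tibble with columns `response`, `experimental`, `predicted`.
#' @export
ajwa_validation <- function() {
  tibble::tribble(
    ~response, ~experimental, ~predicted,
    "TPC", 24.25, 23.97,
    "TFC", 23.98, 23.39
  )
}

#' Packaged ESI-MS(-) peak table
#'
#' The 67 printed rows of the published negative-mode peak table for the
#' optimized extract: compound name (fixture metadata, never asserted by the
#' package), elemental formula, observed and calculated deprotonated m/z, and
#' MS/MS fragment m/z lists. Eight rows whose printed calculated mass or
#' formula was arithmetically inconsistent were curated (the as-printed value
#' is kept in `cm_printed`); see the package vignette.
#'
#' @return A tibble with columns `group`, `no`, `name`, `formula`,
#'   `observed_mz`, `calculated_mz`, `cm_printed`, `fragments` (semicolon
#'   separated), `confidence`.
#' @export
ajwa_peaks <- function() {
  path <- system.file("extdata", "ajwa_peaks.csv", package = "desirsm")
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Synthetic sample-by-assay activity matrix
#'
#' A 7 sample x 7 variable matrix (TPC, TFC and five IC50s) mimicking the
#' published comparison of extraction methods (OP, HM, HE, HW, MM, ME, MW).
#' The paper prints only a handful of its cells, so this fixture is a
#' SYNTHETIC reconstruction: every printed value and every printed ordering
#' is honoured, unprinted cells are plausible interpolations. It supports the
#' chemometrics examples and soft checks only; no quantitative claim about
#' the published matrix should be based on it.
#'
#' @return A tibble with a `sample` column and seven numeric variables.
#' @export
ajwa_activity <- function() {
  path <- system.file("extdata", "activity_matrix_synthetic.csv", package = "desirsm")
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
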