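# Printed second-order model coefficients, canonical term order:
# intercept, linear (ethanol, time, temperature), interactions (1:2, 1:3, 2:3),
# quadratics.
eq_tpc <- c(23.39, -0.3838, 0.0612, 3.06, -0.5475, -1.61, 0.0825,
            -4.37, -4.10, -1.98)
eq_tfc <- c(23.10, 0.9656, -0.5854, 1.71, -1.22, -1.22, 1.57,
            -3.78, -4.29, -2.81)

ajwa_fit <- function(response) {
  fit_quadratic(match_runs(ajwa_design(), ajwa_runs(), c("TPC", "TFC")),
                response, ajwa_design())
}

# independent OLS oracle: explicit normal equations
normal_equations_fit <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

small_design <- function(k = 2, n_center = 2) {
  ccd_design(purrr::map(seq_len(k), function(i) {
    ccd_factor(paste0("f", i), center = 10 * i, step = 2,
               axial_low = 10 * i - 4, axial_high = 10 * i + 4)
  }), n_center = n_center)
}
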