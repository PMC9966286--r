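test_that("coded-unit OLS reproduces the published model coefficients", {
  tpc <- ajwa_fit("TPC")
  tfc <- ajwa_fit("TFC")
  # independently verified against the printed ANOVA table
  expect_equal(unname(coef(tpc)["ethanol"]), -0.3838, tolerance = 2e-4)
  expect_equal(unname(coef(tfc)["ethanol"]), 0.9656, tolerance = 1e-4)
  expect_equal(unname(coef(tfc)["time"]), -0.5854, tolerance = 1e-4)
  expect_equal(unname(coef(tfc)["temperature"]), 1.71, tolerance = 2e-3)
  expect_equal(unname(coef(tfc)["(Intercept)"]), 23.10, tolerance = 5e-3)
})

test_that("OLS solution equals the normal-equations oracle", {
  des <- ajwa_design()
  rt <- match_runs(des, ajwa_runs(), c("TPC", "TFC"))
  cm <- as.matrix(code_points(des, rt)[des$factors$name])
  X <- desirsm:::quadratic_model_matrix(cm, desirsm:::quadratic_terms(des$factors$name))
  for (resp in c("TPC", "TFC")) {
    fit <- fit_quadratic(rt, resp, des)
    oracle <- normal_equations_fit(X, rt[[resp]])
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8)
  }
})

test_that("prediction at the coded origin equals the intercept and residuals are orthogonal to the model", {
  fit <- ajwa_fit("TPC")
  origin <- tibble::tibble(ethanol = 0, time = 0, temperature = 0)
  expect_equal(as.numeric(predict(fit, origin, coded = TRUE)),
               unname(coef(fit)["(Intercept)"]))
  X <- desirsm:::quadratic_model_matrix(fit$coded, fit$terms)
  ip <- drop(crossprod(X, fit$residuals))
  expect_lt(max(abs(ip) / sqrt(colSums(X^2))), 1e-8)
})

test_that("the printed polynomial evaluates as published at the optimum", {
  # instantiate the printed coefficients as a noise-free surface and refit
  des <- ajwa_design()
  sim <- simulate_ccd_responses(des, eq_tpc, sigma = 0)
  fit <- fit_quadratic(sim, "y", des)
  expect_equal(unname(coef(fit)), eq_tpc, tolerance = 1e-9, ignore_attr = TRUE)
  at_origin <- predict(fit, tibble::tibble(ethanol = 0, time = 0, temperature = 0),
                       coded = TRUE)
  expect_equal(as.numeric(at_origin), 23.39)
  at_opt <- predict(fit, tibble::tibble(ethanol = 0.0788, time = -0.0299,
                                        temperature = 0.276), coded = TRUE)
  expect_equal(as.numeric(at_opt), 23.99, tolerance = 2e-3)
})

test_that("ANOVA reproduces pure error, partial SS and the published fit statistics", {
  a_tpc <- rsm_anova(ajwa_fit("TPC"))
  a_tfc <- rsm_anova(ajwa_fit("TFC"))
  row <- function(a, src) dplyr::filter(tidy(a), source == src)
  expect_equal(row(a_tpc, "Pure error")$SS, 0.6247, tolerance = 1e-4)
  expect_equal(row(a_tpc, "Pure error")$df, 5)
  expect_equal(row(a_tfc, "Pure error")$SS, 6.95, tolerance = 1e-3)
  expect_equal(row(a_tfc, "ethanol")$SS, 14.92, tolerance = 1e-4)
  expect_equal(row(a_tfc, "Model")$SS, 751.10, tolerance = 1e-4)
  g <- glance(a_tfc)
  expect_equal(g$r2, 0.9706, tolerance = 1e-4)
  expect_equal(g$adj_r2, 0.9441, tolerance = 1e-4)
  expect_equal(g$cv_percent, 10.25, tolerance = 1e-3)
  expect_equal(g$adeq_precision, 15.9930, tolerance = 1e-4)
  # significance labels mirror the published table
  expect_equal(row(a_tfc, "time")$significance, "Nonsignificant")
  expect_equal(row(a_tfc, "ethanol")$significance, "Significant")
})

test_that("ANOVA additivity identities hold on arbitrary fits", {
  des <- small_design(3, n_center = 4)
  for (seed in 1:5) {
    sim <- simulate_ccd_responses(des, beta = seq(-1, 1, length.out = 10),
                                  sigma = 1, seed = seed)
    fit <- fit_quadratic(sim, "y", des)
    tab <- tidy(rsm_anova(fit))
    g <- function(src) dplyr::filter(tab, source == src)
    expect_equal(g("Model")$SS + g("Residual")$SS, g("Total")$SS,
                 tolerance = 1e-6)
    expect_equal(g("Lack of fit")$SS + g("Pure error")$SS, g("Residual")$SS,
                 tolerance = 1e-6)
    gl <- glance(rsm_anova(fit))
    expect_lte(gl$adj_r2, gl$r2)
  }
})

test_that("ANOVA without replicates drops pure error with a warning", {
  des <- small_design(2, n_center = 1)
  sim <- simulate_ccd_responses(des, beta = c(1, 0.5, -0.5, 0.2, 0.3, -0.1),
                                sigma = 0.3, seed = 1)
  fit <- fit_quadratic(sim, "y", des)
  expect_warning(a <- rsm_anova(fit), "No replicated runs")
  expect_false(any(tidy(a)$source %in% c("Pure error", "Lack of fit")))
})

test_that("linear-coefficient recovery is unbiased under noise on the packaged design", {
  des <- ajwa_design()
  truth <- eq_tfc
  ests <- vapply(1:200, function(s) {
    sim <- simulate_ccd_responses(des, truth, sigma = 0.5, seed = 9000 + s)
    unname(coef(fit_quadratic(sim, "y", des))[2:4])
  }, numeric(3))
  bias <- rowMeans(ests) - truth[2:4]
  expect_lt(mean(abs(bias)), 0.05)
})

test_that("a saturated fit interpolates with R^2 = 1 and rank deficiency is named", {
  des <- small_design(2, n_center = 1) # 9 runs, 6 terms
  sim <- simulate_ccd_responses(des, beta = c(2, 1, -1, 0.5, 0.25, -0.25),
                                sigma = 0.4, seed = 3)
  # collapse to 6 distinct points -> saturated
  six <- sim[c(1:4, 5, 7), ]
  fit <- fit_quadratic(six, "y", des)
  expect_equal(fit$fitted_values, six$y, tolerance = 1e-8, ignore_attr = TRUE)
  dup <- sim
  dup$f2 <- dup$f1 # aliased factor
  expect_error(fit_quadratic(dup, "y", des), "aliased")
})

test_that("backward elimination preserves hierarchy and drops known-null terms", {
  fit <- ajwa_fit("TPC")
  # alpha = 1 never removes anything (every p <= 1)
  expect_equal(reduce_model(fit, alpha = 0.999999)$terms$term, fit$terms$term)
  red <- reduce_model(fit, alpha = 0.05)
  # time is retained by hierarchy (p = 0.66) because time^2 stays
  expect_true("time" %in% red$terms$term)
  expect_true("time^2" %in% red$terms$term)
  expect_false("time:temperature" %in% red$terms$term)
  # a truly null interaction is eliminated on low-noise synthetic data
  des <- ajwa_design()
  truth <- eq_tfc
  truth[5] <- 0 # ethanol:time
  sim <- simulate_ccd_responses(des, truth, sigma = 0.05, seed = 42)
  red2 <- reduce_model(fit_quadratic(sim, "y", des), alpha = 0.05)
  expect_false("ethanol:time" %in% red2$terms$term)
})

test_that("surface grids have the right shape and curvature", {
  fit <- ajwa_fit("TPC")
  g <- surface_grid(fit, fixed = c(time = 82.5), resolution = 3)
  expect_equal(nrow(g), 9)
  expect_named(g, c("ethanol", "temperature", ".pred"))
  expect_error(surface_grid(fit, fixed = c(time = 82.5, ethanol = 50)),
               "Exactly 2")
  # interior maximum along temperature at centre ethanol/time
  gt <- surface_grid(fit, fixed = c(ethanol = 50), resolution = 41)
  centre_slice <- gt$.pred[abs(gt$time - 82.5) == min(abs(gt$time - 82.5))]
  imax <- which.max(centre_slice)
  expect_gt(imax, 1)
  expect_lt(imax, length(centre_slice))
  # a pure-linear surface grids to a plane (zero second differences)
  des <- small_design(2, n_center = 2)
  lin <- simulate_ccd_responses(des, beta = c(1, 2, -3, 0, 0, 0), sigma = 0)
  lfit <- fit_quadratic(lin, "y", des)
  lg <- surface_grid(lfit, fixed = setNames(numeric(0), character(0)),
                     resolution = 5)
  m <- matrix(lg$.pred, 5, 5, byrow = TRUE)
  expect_equal(max(abs(diff(diff(m)))), 0, tolerance = 1e-9)
  expect_equal(max(abs(t(diff(diff(t(m)))))), 0, tolerance = 1e-9)
})
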