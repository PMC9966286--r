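test_that("individual desirability follows the Derringer ramp", {
  g <- desirability_goal("y", "maximize", lower = 10, upper = 20)
  expect_equal(d_individual(g, 10), 0)
  expect_equal(d_individual(g, 20), 1)
  expect_equal(d_individual(g, 5), 0)
  expect_equal(d_individual(g, 25), 1)
  expect_equal(d_individual(g, 15), 0.5)
  g2 <- desirability_goal("y", "maximize", lower = 10, upper = 20, exponent = 2)
  expect_equal(d_individual(g2, 15), 0.25)
  gm <- desirability_goal("y", "minimize", lower = 10, upper = 20)
  expect_equal(d_individual(gm, 10), 1)
  expect_equal(d_individual(gm, 20), 0)
  gt <- desirability_goal("y", "target", lower = 10, upper = 20)
  expect_equal(d_individual(gt, 20), 1)
  expect_equal(d_individual(gt, c(10, 30)), c(0, 0))
  # published worked value: TFC bounds 6.81/24.20, prediction 23.39
  gp <- desirability_goal("TFC", "maximize", lower = 6.81, upper = 24.20)
  expect_equal(d_individual(gp, 23.39), 0.9534, tolerance = 1e-4)
  expect_error(desirability_goal("y", "maximize", 5, 5), "lower")
})

test_that("composite D is a weighted geometric mean with the right edge cases", {
  expect_equal(d_composite(c(1, 0.9534)), 0.9764, tolerance = 1e-4)
  expect_equal(d_composite(c(1, 1, 1)), 1)
  expect_equal(d_composite(c(0.5, 0)), 0)
  expect_equal(d_composite(c(0.25, 0.5), w = c(2, 1)),
               (0.25^2 * 0.5)^(1 / 3))
  expect_error(d_composite(c(0.5), w = c(1, 1)), "lengths")
  expect_error(d_composite(c(1.5, 0.5)), "\\[0, 1\\]")
})

test_that("d and D stay in [0,1] and D is monotone in each d", {
  set.seed(7)
  g <- desirability_goal("y", "maximize", lower = -1, upper = 1, exponent = 0.5)
  y <- runif(100, -3, 3)
  d <- d_individual(g, y)
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:50) {
    d <- runif(3)
    w <- runif(3, 0.5, 2)
    D <- d_composite(d, w)
    expect_gte(D, min(d) - 1e-12)
    expect_lte(D, max(d) + 1e-12)
    j <- sample(3, 1)
    d2 <- d
    d2[j] <- min(1, d[j] + runif(1, 0, 1 - d[j]))
    expect_gte(d_composite(d2, w), D - 1e-12)
  }
})

test_that("joint optimization of both fitted responses attains the published desirability", {
  des <- ajwa_design()
  rt <- match_runs(des, ajwa_runs(), c("TPC", "TFC"))
  fits <- list(fit_quadratic(rt, "TPC", des), fit_quadratic(rt, "TFC", des))
  goals <- observed_range_goals(rt, c("TPC", "TFC"))
  expect_equal(goals$lower, c(5.41, 6.81))
  expect_equal(goals$upper, c(23.92, 24.20))
  opt <- optimize_desirability(fits, goals)
  expect_equal(opt$D, 0.977, tolerance = 2e-3)
  # optimum sits where the paper found it (52% ethanol, 81 min, 63 C)
  nat <- as.numeric(opt$natural[1, c("ethanol", "time", "temperature")])
  expect_equal(nat, c(52, 81, 63), tolerance = 0.02)
  expect_gte(opt$D, min(opt$d) - 1e-12)
  expect_lte(opt$D, max(opt$d) + 1e-12)
})

test_that("single-response optimization matches the closed-form stationary point", {
  fit <- ajwa_fit("TPC")
  k <- 3
  b <- coef(fit)
  A <- diag(2 * b[8:10])
  A[1, 2] <- A[2, 1] <- b["ethanol:time"]
  A[1, 3] <- A[3, 1] <- b["ethanol:temperature"]
  A[2, 3] <- A[3, 2] <- b["time:temperature"]
  x_star <- solve(A, -b[2:4]) # gradient = 0
  goal <- desirability_goal("TPC", "maximize", lower = 0, upper = 100)
  opt <- optimize_desirability(list(fit), goal, resolution = 21)
  expect_equal(as.numeric(opt$coded[1, ]), unname(x_star), tolerance = 1e-4)
})

test_that("the polished optimum never falls below the best grid value and plateaus clip to d = 1", {
  des <- ajwa_design()
  rt <- match_runs(des, ajwa_runs(), c("TPC", "TFC"))
  fit <- fit_quadratic(rt, "TPC", des)
  goals <- observed_range_goals(rt, "TPC")
  coarse <- optimize_desirability(list(fit), goals, resolution = 5)
  fine <- optimize_desirability(list(fit), goals, resolution = 41)
  expect_gte(fine$D, coarse$D - 1e-9)
  # target far below the whole surface -> desirability saturates at 1
  low <- desirability_goal("TPC", "maximize", lower = -100, upper = -50)
  opt <- optimize_desirability(list(fit), low, resolution = 5)
  expect_equal(opt$D, 1)
})

test_that("validation reproduces the published RSDs and flags pass below 10%", {
  val <- validate_optimum(c(TPC = 23.97, TFC = 23.39),
                          c(TPC = 24.25, TFC = 23.98))
  expect_equal(val$std, c(0.20, 0.42), tolerance = 2e-2)
  expect_equal(val$rsd_percent, c(0.82, 1.76), tolerance = 5e-3)
  expect_true(all(val$pass))
  same <- validate_optimum(c(A = 5), c(A = 5))
  expect_equal(same$std, 0)
  expect_equal(same$rsd_percent, 0)
  expect_error(validate_optimum(c(A = 5), c(B = 5)), "No prediction")
})
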