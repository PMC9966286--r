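#' Define a per-response desirability goal
#'
#' Derringer-style goal for one response: the response value is mapped to a
#' desirability d in \[0, 1\]. For `"maximize"`, d = 0 at or below `lower`,
#' ((y - L)/(T - L))^s between the bounds, and 1 at or above `upper`;
#' `"minimize"` is the mirror image; `"target"` ramps up to 1 at the target
#' (`upper`) and back down to 0 at `2*upper - lower`; `"in_range"` is 1
#' inside \[lower, upper\] and 0 outside.
#'
#' @param response Response name.
#' @param goal One of `"maximize"`, `"minimize"`, `"target"`, `"in_range"`.
#' @param lower,upper The L and T bounds (L < T).
#' @param weight Relative weight w > 0 in the composite geometric mean.
#' @param exponent Shape exponent s > 0 of the ramp.
#' @return A one-row tibble of class `desirability_goal`.
#' @export
desirability_goal <- function(response, goal = c("maximize", "minimize", "target", "in_range"),
                              lower, upper, weight = 1, exponent = 1) {
  goal <- match.arg(goal)
  if (!(lower < upper)) stop("`lower` must be < `upper`.", call. = FALSE)
  if (weight <= 0 || exponent <= 0) {
    stop("`weight` and `exponent` must be positive.", call. = FALSE)
  }
  out <- tibble::tibble(response = response, goal = goal, lower = lower,
                        upper = upper, weight = weight, exponent = exponent)
  class(out) <- c("desirability_goal", class(out))
  out
}

#' Individual desirability of observed/predicted response values
#'
#' @param goal A [desirability_goal()].
#' @param y Numeric vector of response values.
#' @return Desirabilities in \[0, 1\], vectorized over `y`.
#' @examples
#' g <- desirability_goal("TFC", "maximize", lower = 6.81, upper = 24.20)
#' d_individual(g, 23.39) # 0.9534
#' @export
d_individual <- function(goal, y) {
  L <- goal$lower; T_ <- goal$upper; s <- goal$exponent
  ramp_up <- function(y) pmin(pmax((y - L) / (T_ - L), 0), 1)^s
  switch(goal$goal,
    maximize = ramp_up(y),
    minimize = pmin(pmax((T_ - y) / (T_ - L), 0), 1)^s,
    target = {
      up <- pmin(pmax((y - L) / (T_ - L), 0), 1)^s
      down <- pmin(pmax((2 * T_ - L - y) / (T_ - L), 0), 1)^s
      ifelse(y <= T_, up, down)
    },
    in_range = as.numeric(y >= L & y <= T_)
  )
}

#' Composite Derringer desirability
#'
#' Weighted geometric mean D = (prod d_i^w_i)^(1/sum w_i); 0 whenever any
#' individual desirability is 0.
#'
#' @param d Vector of individual desirabilities in \[0, 1\].
#' @param w Positive weights, same length as `d` (default equal).
#' @return D in \[0, 1\].
#' @examples
#' d_composite(c(1, 0.9534)) # 0.9764
#' @export
d_composite <- function(d, w = rep(1, length(d))) {
  if (length(d) != length(w)) stop("`d` and `w` lengths differ.", call. = FALSE)
  if (any(d < -1e-12 | d > 1 + 1e-12)) stop("`d` must lie in [0, 1].", call. = FALSE)
  if (any(w <= 0)) stop("Weights must be positive.", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(w * log(d)) / sum(w))
}

#' Goals that maximize every response over its observed range
#'
#' Convenience constructor matching common practice when no explicit bounds
#' are chosen: each response gets a maximize goal with L and T equal to its
#' observed minimum and maximum in the run table, weight 1, exponent 1.
#'
#' @param data Run table containing the response columns.
#' @param responses Character vector of response names.
#' @return A tibble of stacked [desirability_goal()] rows.
#' @export
observed_range_goals <- function(data, responses) {
  dplyr::bind_rows(purrr::map(responses, function(r) {
    desirability_goal(r, "maximize",
                      lower = min(data[[r]]), upper = max(data[[r]]))
  }))
}

#' Multi-response desirability optimization over the design region
#'
#' Maximizes the composite desirability of several fitted response surfaces
#' over the coded design region (bounded per factor by the axial levels).
#' Deterministic two-stage search: an exhaustive coarse grid
#' (`resolution` points per axis) followed by a Nelder-Mead polish started
#' from the best grid point, with out-of-bounds proposals clamped to the
#' region. The polished optimum can never fall below the best grid value.
#'
#' @param fits List of [fit_quadratic()] objects (one per goal, same design).
#' @param goals A tibble of [desirability_goal()] rows, one per fit, matched
#'   to fits by response name.
#' @param resolution Coarse-grid points per axis.
#' @return An object of class `desirability_optimum`: a list with `coded` and
#'   `natural` coordinate tibbles, `predicted` responses, `d` (individual
#'   desirabilities), and `D`.
#' @examples
#' des <- ajwa_design()
#' fits <- list(fit_quadratic(ajwa_runs(), "TPC", des),
#'              fit_quadratic(ajwa_runs(), "TFC", des))
#' goals <- observed_range_goals(ajwa_runs(), c("TPC", "TFC"))
#' optimize_desirability(fits, goals)$D # 0.977
#' @export
optimize_desirability <- function(fits, goals, resolution = 41) {
  responses <- purrr::map_chr(fits, "response")
  if (!setequal(responses, goals$response) || length(fits) != nrow(goals)) {
    stop("Need exactly one goal per fitted response.", call. = FALSE)
  }
  goals <- goals[match(responses, goals$response), ]
  design <- fits[[1]]$design
  fnames <- design$factors$name
  bounds <- coded_bounds(design)

  pred_all <- function(cm) {
    purrr::map(fits, function(f) {
      X <- quadratic_model_matrix(cm, f$terms)
      drop(X %*% f$coefficients)
    })
  }
  D_of <- function(cm) {
    ys <- pred_all(cm)
    dmat <- purrr::map(seq_along(ys), function(i) d_individual(goals[i, ], ys[[i]]))
    w <- goals$weight
    dm <- do.call(cbind, dmat)
    out <- exp(as.vector(log(pmax(dm, 0)) %*% w) / sum(w))
    out[apply(dm == 0, 1, any)] <- 0
    out
  }

  axes <- purrr::map(seq_len(nrow(bounds)), function(i) {
    seq(bounds$lower[i], bounds$upper[i], length.out = resolution)
  })
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- fnames
  Dv <- D_of(grid)
  best <- which.max(Dv)
  if (Dv[best] == 0) {
    warning("Composite desirability is 0 everywhere on the search grid; ",
            "returning the best-effort grid point.", call. = FALSE)
  }
  clamp <- function(x) pmin(pmax(x, bounds$lower), bounds$upper)
  opt <- stats::optim(
    grid[best, ], function(x) -D_of(matrix(clamp(x), 1, dimnames = list(NULL, fnames))),
    method = "Nelder-Mead",
    control = list(reltol = 1e-10, maxit = 5000)
  )
  x_star <- clamp(opt$par)
  D_star <- D_of(matrix(x_star, 1))
  if (D_star < Dv[best]) { # polish never degrades the grid optimum
    x_star <- grid[best, ]
    D_star <- Dv[best]
  }
  cm <- matrix(x_star, 1, dimnames = list(NULL, fnames))
  ys <- purrr::map_dbl(pred_all(cm), 1)
  names(ys) <- responses
  d <- purrr::map_dbl(seq_along(fits), function(i) d_individual(goals[i, ], ys[i]))
  names(d) <- responses
  coded <- tibble::as_tibble(as.list(stats::setNames(x_star, fnames)))
  structure(
    list(coded = coded,
         natural = decode_points(design, coded),
         predicted = ys, d = d, D = D_star,
         goals = goals, design = design),
    class = "desirability_optimum"
  )
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat("Desirability optimum: D =", format(round(x$D, 4)), "\n")
  nat <- round(as.numeric(x$natural[1, x$design$factors$name]), 2)
  cat("at", paste(x$design$factors$name, "=", nat,
                  x$design$factors$units, collapse = ", "), "\n")
  cat("predicted:", paste(names(x$predicted), "=",
                          round(x$predicted, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Validate predicted optima against confirmation experiments
#'
#' For each response, compares the model prediction at the optimum with the
#' experimentally measured value via the relative standard deviation of the
#' pair: std is the sample standard deviation of (experimental, predicted),
#' i.e. |experimental - predicted| / sqrt(2), and RSD% = 100 std / mean.
#' An RSD below `rsd_limit` (default 10%) counts as a successful validation.
#'
#' @param optimum A [optimize_desirability()] result, or a named numeric
#'   vector of predicted response values.
#' @param experimental Named numeric vector of measured values (names are
#'   response names).
#' @param rsd_limit Pass threshold on RSD%.
#' @return A tibble with columns `response`, `experimental`, `predicted`,
#'   `std`, `rsd_percent`, `pass`.
#' @examples
#' validate_optimum(c(TPC = 23.97, TFC = 23.39), c(TPC = 24.25, TFC = 23.98))
#' @export
validate_optimum <- function(optimum, experimental, rsd_limit = 10) {
  predicted <- if (inherits(optimum, "desirability_optimum")) optimum$predicted else optimum
  resp <- names(experimental)
  if (!all(resp %in% names(predicted))) {
    stop("No prediction for response(s): ",
         paste(setdiff(resp, names(predicted)), collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(resp, function(r) {
    e <- experimental[[r]]; p <- predicted[[r]]
    s <- abs(e - p) / sqrt(2)
    rsd <- 100 * s / mean(c(e, p))
    tibble::tibble(response = r, experimental = e, predicted = p,
                   std = s, rsd_percent = rsd, pass = rsd < rsd_limit)
  })
}

#' Composite-desirability grid over two factors
#'
#' Analogue of [surface_grid()] for the composite desirability D, for
#' visualising the optimization landscape.
#'
#' @inheritParams optimize_desirability
#' @param fixed Named natural-unit values for all but two factors.
#' @param resolution Grid points per free axis.
#' @return A `surface_grid` tibble whose `.pred` column holds D.
#' @export
desirability_grid <- function(fits, goals, fixed, resolution = 41) {
  design <- fits[[1]]$design
  fs <- design$factors
  free <- setdiff(fs$name, names(fixed))
  if (length(free) != 2) stop("Exactly 2 factors must be free.", call. = FALSE)
  responses <- purrr::map_chr(fits, "response")
  goals <- goals[match(responses, goals$response), ]
  axes <- purrr::map(free, function(nm) {
    i <- match(nm, fs$name)
    seq(fs$axial_low[i], fs$axial_high[i], length.out = resolution)
  })
  grid <- tidyr::expand_grid(!!!rlang::set_names(axes, free))
  for (nm in names(fixed)) grid[[nm]] <- fixed[[nm]]
  cm <- as.matrix(code_points(design, grid[fs$name])[fs$name])
  dm <- do.call(cbind, purrr::map(seq_along(fits), function(i) {
    f <- fits[[i]]
    y <- drop(quadratic_model_matrix(cm, f$terms) %*% f$coefficients)
    d_individual(goals[i, ], y)
  }))
  w <- goals$weight
  D <- exp(as.vector(log(pmax(dm, 1e-300)) %*% w) / sum(w))
  D[apply(dm == 0, 1, any)] <- 0
  out <- grid[, free]
  out$.pred <- D
  class(out) <- c("surface_grid", class(out))
  attr(out, "response") <- "D"
  attr(out, "fixed") <- fixed
  out
}
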