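# Canonical second-order model terms for k factors:
# intercept, linear (factor order), two-way interactions (combn order),
# pure quadratics. This ordering is used everywhere: coefficient vectors,
# ANOVA rows, synthetic-surface truth vectors.
quadratic_terms <- function(fnames) {
  k <- length(fnames)
  pairs <- if (k >= 2) utils::combn(k, 2) else matrix(nrow = 2, ncol = 0)
  tibble::tibble(
    term = c(
      "(Intercept)", fnames,
      apply(pairs, 2, function(ij) paste(fnames[ij], collapse = ":")),
      paste0(fnames, "^2")
    ),
    type = rep(c("intercept", "linear", "interaction", "quadratic"),
               c(1, k, ncol(pairs), k)),
    i = c(NA, seq_len(k), pairs[1, ], seq_len(k)),
    j = c(NA, rep(NA, k), pairs[2, ], seq_len(k))
  )
}

quadratic_model_matrix <- function(coded, terms) {
  X <- matrix(1, nrow(coded), nrow(terms))
  for (r in seq_len(nrow(terms))) {
    X[, r] <- switch(terms$type[r],
      intercept = 1,
      linear = coded[, terms$i[r]],
      interaction = coded[, terms$i[r]] * coded[, terms$j[r]],
      quadratic = coded[, terms$i[r]]^2
    )
  }
  colnames(X) <- terms$term
  X
}

#' Fit the full second-order response-surface model
#'
#' Ordinary least squares fit of the complete quadratic polynomial
#' (intercept, linear, two-way interaction and pure quadratic terms) to one
#' response of a designed experiment. Fitting is done in coded units computed
#' from the natural factor levels, which reproduces the coded coefficients
#' conventionally reported for central composite designs; set
#' `coding = "natural"` to fit on raw units instead.
#'
#' @param data Run table: a data frame with the design's factor columns in
#'   natural units plus the response column (e.g. the output of
#'   [match_runs()], but any row order works).
#' @param response Name of the response column.
#' @param design A [ccd_design()] describing the factors.
#' @param coding `"coded"` (default) or `"natural"`.
#' @return An object of class `quadratic_fit`.
#' @examples
#' fit <- fit_quadratic(ajwa_runs(), "TPC", ajwa_design())
#' coef(fit)[["ethanol"]] # -0.38375, prints as -0.3838
#' @export
fit_quadratic <- function(data, response, design, coding = c("coded", "natural")) {
  coding <- match.arg(coding)
  fnames <- design$factors$name
  if (!response %in% names(data)) {
    stop("Response `", response, "` not found in the run table.", call. = FALSE)
  }
  if (anyNA(data[[response]])) stop("Missing responses are not allowed.", call. = FALSE)
  y <- as.numeric(data[[response]])
  coded <- if (coding == "coded") {
    as.matrix(code_points(design, data[fnames])[fnames])
  } else {
    as.matrix(data[fnames])
  }
  terms <- quadratic_terms(fnames)
  X <- quadratic_model_matrix(coded, terms)
  p <- ncol(X)
  if (length(y) < p) {
    stop("Need at least ", p, " runs to fit ", p, " model terms; got ",
         length(y), ".", call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("Design is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df_res <- length(y) - p
  xtx_inv <- chol2inv(qr.R(qrx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(
    list(
      design = design, response = response, coding = coding,
      terms = terms, coefficients = beta,
      fitted_values = fitted, residuals = res,
      df_residual = df_res,
      mse = if (df_res > 0) sum(res^2) / df_res else NA_real_,
      xtx_inv = xtx_inv, data = tibble::as_tibble(data), coded = coded
    ),
    class = "quadratic_fit"
  )
}

#' @export
coef.quadratic_fit <- function(object, ...) object$coefficients

#' @export
print.quadratic_fit <- function(x, ...) {
  cat("Second-order response-surface fit (", x$coding, " units)\n",
      "Response: ", x$response, ", ", length(x$coefficients), " terms, ",
      x$df_residual, " residual df\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a response-surface fit
#'
#' @param object A [fit_quadratic()] result.
#' @param newdata Data frame of factor columns; natural units unless
#'   `coded = TRUE`. Defaults to the fitted runs.
#' @param coded Set `TRUE` if `newdata` is already in coded units.
#' @param ... Unused.
#' @return Numeric vector of predictions. Points outside the axial range are
#'   flagged in an `"extrapolated"` attribute.
#' @export
predict.quadratic_fit <- function(object, newdata = NULL, coded = FALSE, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  fnames <- object$design$factors$name
  newdata <- tibble::as_tibble(newdata)
  if (coded && object$coding == "coded") {
    cm <- as.matrix(newdata[fnames])
    bounds <- coded_bounds(object$design)
    extrap <- apply(sweep(cm, 2, bounds$lower, `<`) | sweep(cm, 2, bounds$upper, `>`), 1, any)
  } else {
    if (coded) newdata[fnames] <- decode_points(object$design, newdata[fnames])[fnames]
    cp <- code_points(object$design, newdata[fnames])
    extrap <- cp$extrapolated
    cm <- if (object$coding == "coded") as.matrix(cp[fnames]) else as.matrix(newdata[fnames])
  }
  X <- quadratic_model_matrix(cm, object$terms)
  out <- drop(X %*% object$coefficients)
  attr(out, "extrapolated") <- extrap
  out
}

replicate_groups <- function(data, fnames) {
  key <- do.call(paste, c(lapply(data[fnames], function(v) sprintf("%.10g", v)), sep = "|"))
  split(seq_along(key), key)
}

#' ANOVA table for a response-surface fit
#'
#' Decomposes the model into per-term partial (extra) sums of squares, the
#' lack-of-fit / pure-error split of the residual, and the usual
#' response-surface fit statistics. Pure error is computed from replicated
#' design points (runs with identical factor settings); the lack-of-fit F
#' statistic is MS_LOF / MS_PE. Fit statistics: R^2 = SS_model / SS_total,
#' adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p), CV% = 100 sqrt(MSE) / mean(y),
#' and adequate precision = (max - min fitted value at the design points) /
#' sqrt(p MSE / n) (a signal-to-noise ratio; > 4 is conventionally adequate).
#'
#' @param fit A [fit_quadratic()] result.
#' @param alpha Significance threshold for the `significance` labels.
#' @return An object of class `rsm_anova` with a `table` tibble (term rows,
#'   model, lack-of-fit, pure-error, total) and a `stats` list.
#' @examples
#' an <- rsm_anova(fit_quadratic(ajwa_runs(), "TPC", ajwa_design()))
#' dplyr::filter(generics::tidy(an), source == "Pure error")$SS # 0.6247
#' @export
rsm_anova <- function(fit, alpha = 0.05) {
  y <- fit$fitted_values + fit$residuals
  n <- length(y)
  p <- length(fit$coefficients)
  ss_total <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  ss_model <- ss_total - ss_res
  df_model <- p - 1
  mse <- fit$mse

  idx <- which(fit$terms$type != "intercept")
  term_ss <- purrr::map_dbl(idx, function(r) {
    fit$coefficients[r]^2 / fit$xtx_inv[r, r]
  })
  term_f <- term_ss / mse
  term_p <- stats::pf(term_f, 1, fit$df_residual, lower.tail = FALSE)

  groups <- replicate_groups(fit$data, fit$design$factors$name)
  reps <- groups[lengths(groups) >= 2]
  has_pe <- length(reps) > 0
  ss_pe <- if (has_pe) sum(purrr::map_dbl(reps, function(ix) sum((y[ix] - mean(y[ix]))^2))) else NA_real_
  df_pe <- if (has_pe) sum(lengths(reps) - 1L) else NA_integer_
  ss_lof <- ss_res - ss_pe
  df_lof <- fit$df_residual - df_pe
  f_lof <- if (has_pe && df_lof > 0 && df_pe > 0) (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_
  p_lof <- if (is.na(f_lof)) NA_real_ else stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)

  f_model <- (ss_model / df_model) / mse
  p_model <- stats::pf(f_model, df_model, fit$df_residual, lower.tail = FALSE)
  r2 <- ss_model / ss_total
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  cv <- 100 * sqrt(mse) / mean(y)
  adeq <- diff(range(fit$fitted_values)) / sqrt(p * mse / n)

  lab <- function(pv) ifelse(is.na(pv), NA_character_,
                             ifelse(pv < alpha, "Significant", "Nonsignificant"))
  table <- dplyr::bind_rows(
    tibble::tibble(source = "Model", coefficient = NA_real_, SS = ss_model,
                   df = df_model, MS = ss_model / df_model, F = f_model,
                   p = p_model, significance = lab(p_model)),
    tibble::tibble(source = "(Intercept)",
                   coefficient = unname(fit$coefficients[1]), SS = NA_real_,
                   df = NA_integer_, MS = NA_real_, F = NA_real_, p = NA_real_,
                   significance = NA_character_),
    tibble::tibble(source = fit$terms$term[idx],
                   coefficient = unname(fit$coefficients[idx]), SS = term_ss,
                   df = 1L, MS = term_ss, F = term_f, p = term_p,
                   significance = lab(term_p)),
    tibble::tibble(source = "Lack of fit", coefficient = NA_real_, SS = ss_lof,
                   df = df_lof, MS = ss_lof / df_lof, F = f_lof, p = p_lof,
                   significance = lab(p_lof)),
    tibble::tibble(source = "Pure error", coefficient = NA_real_, SS = ss_pe,
                   df = df_pe, MS = if (has_pe) ss_pe / df_pe else NA_real_,
                   F = NA_real_, p = NA_real_, significance = NA_character_),
    tibble::tibble(source = "Residual", coefficient = NA_real_, SS = ss_res,
                   df = fit$df_residual, MS = mse, F = NA_real_, p = NA_real_,
                   significance = NA_character_),
    tibble::tibble(source = "Total", coefficient = NA_real_, SS = ss_total,
                   df = n - 1L, MS = NA_real_, F = NA_real_, p = NA_real_,
                   significance = NA_character_)
  )
  if (!has_pe) {
    table <- dplyr::filter(table, !.data$source %in% c("Lack of fit", "Pure error"))
    warning("No replicated runs: pure error and lack of fit are undefined.",
            call. = FALSE)
  }
  structure(
    list(table = table,
         stats = list(r2 = r2, adj_r2 = adj_r2, cv_percent = cv,
                      adeq_precision = adeq, mse = mse, n = n, p = p),
         response = fit$response),
    class = "rsm_anova"
  )
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat("ANOVA for quadratic model, response", x$response, "\n")
  print(as.data.frame(x$table), digits = 4)
  with(x$stats, cat(sprintf(
    "R2 %.4f  adj R2 %.4f  CV%% %.2f  Adeq precision %.4f\n",
    r2, adj_r2, cv_percent, adeq_precision
  )))
  invisible(x)
}

#' Backward elimination of non-significant terms
#'
#' Repeatedly removes the non-significant (partial-F p > `alpha`) model term
#' with the largest p value, refitting after each removal, while preserving
#' model hierarchy: a linear term is never removed while any interaction or
#' quadratic term involving its factor remains. Ties in p are broken by
#' canonical term order. Deterministic.
#'
#' @param fit A [fit_quadratic()] result.
#' @param data The run table the fit was computed from (defaults to the one
#'   stored in the fit).
#' @param alpha Retention threshold.
#' @return A `quadratic_fit` restricted to the retained terms (absent
#'   coefficients are reported as zero in `coef()`).
#' @export
reduce_model <- function(fit, data = fit$data, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1).", call. = FALSE)
  terms <- fit$terms
  keep <- rep(TRUE, nrow(terms))
  y <- as.numeric(data[[fit$response]])
  coded <- fit$coded
  repeat {
    X <- quadratic_model_matrix(coded, terms[keep, ])
    qrx <- qr(X)
    beta <- qr.coef(qrx, y)
    res <- y - drop(X %*% beta)
    df_res <- length(y) - ncol(X)
    if (df_res == 0) break
    mse <- sum(res^2) / df_res
    xtx_inv <- chol2inv(qr.R(qrx))
    cur <- terms[keep, ]
    pvals <- rep(NA_real_, nrow(cur))
    for (r in seq_len(nrow(cur))) {
      if (cur$type[r] == "intercept") next
      fstat <- beta[r]^2 / xtx_inv[r, r] / mse
      pvals[r] <- stats::pf(fstat, 1, df_res, lower.tail = FALSE)
    }
    protected <- purrr::map_lgl(seq_len(nrow(cur)), function(r) {
      if (cur$type[r] != "linear") return(FALSE)
      any(cur$type %in% c("interaction", "quadratic") &
            (cur$i == cur$i[r] | (!is.na(cur$j) & cur$j == cur$i[r])))
    })
    removable <- which(!is.na(pvals) & pvals > alpha & !protected &
                         cur$type != "intercept")
    if (!length(removable)) break
    drop_row <- removable[which.max(pvals[removable])]
    keep[which(keep)[drop_row]] <- FALSE
  }
  out <- fit
  out$terms <- terms[keep, ]
  X <- quadratic_model_matrix(coded, out$terms)
  qrx <- qr(X)
  out$coefficients <- qr.coef(qrx, y)
  out$fitted_values <- drop(X %*% out$coefficients)
  out$residuals <- y - out$fitted_values
  out$df_residual <- length(y) - ncol(X)
  out$mse <- if (out$df_residual > 0) sum(out$residuals^2) / out$df_residual else NA_real_
  out$xtx_inv <- chol2inv(qr.R(qrx))
  dimnames(out$xtx_inv) <- list(colnames(X), colnames(X))
  out
}

#' Evaluate a fitted surface on a 2-factor grid
#'
#' Predicts the response over a `resolution` x `resolution` grid of two free
#' factors (spanning their axial ranges), with all remaining factors held at
#' the values in `fixed`. The numeric grid is suitable for contour/surface
#' plotting with any graphics system; see [autoplot.surface_grid()].
#'
#' @param fit A [fit_quadratic()] result.
#' @param fixed Named numeric vector fixing all but two factors, natural units.
#' @param resolution Grid points per free axis.
#' @return A tibble of class `surface_grid`: the two free factor columns
#'   (natural units) and `.pred`.
#' @export
surface_grid <- function(fit, fixed, resolution = 41) {
  fs <- fit$design$factors
  free <- setdiff(fs$name, names(fixed))
  if (length(free) != 2) {
    stop("Exactly 2 factors must be free; got ", length(free),
         " (fix the others via `fixed`).", call. = FALSE)
  }
  axes <- purrr::map(free, function(nm) {
    i <- match(nm, fs$name)
    seq(fs$axial_low[i], fs$axial_high[i], length.out = resolution)
  })
  grid <- tidyr::expand_grid(!!!rlang::set_names(axes, free))
  for (nm in names(fixed)) grid[[nm]] <- fixed[[nm]]
  grid$.pred <- as.numeric(predict(fit, grid))
  out <- grid[, c(free, ".pred")]
  class(out) <- c("surface_grid", class(out))
  attr(out, "response") <- fit$response
  attr(out, "fixed") <- fixed
  out
}
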