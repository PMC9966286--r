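#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a response-surface fit
#'
#' @param x A [fit_quadratic()] result.
#' @param ... Unused.
#' @return A tibble with `term`, `type`, `estimate`, `std.error`,
#'   `statistic` (t), `p.value`.
#' @export
tidy.quadratic_fit <- function(x, ...) {
  se <- sqrt(x$mse * diag(x$xtx_inv))
  tstat <- x$coefficients / se
  tibble::tibble(
    term = x$terms$term, type = x$terms$type,
    estimate = unname(x$coefficients), std.error = unname(se),
    statistic = unname(tstat),
    p.value = 2 * stats::pt(abs(tstat), x$df_residual, lower.tail = FALSE)
  )
}

#' @rdname tidy.quadratic_fit
#' @export
glance.quadratic_fit <- function(x, ...) {
  glance(rsm_anova(x))
}

#' @rdname tidy.quadratic_fit
#' @param data Optional run table to augment (defaults to the fitted one).
#' @export
augment.quadratic_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    out <- x$data
    out$.fitted <- x$fitted_values
    out$.resid <- x$residuals
  } else {
    out <- tibble::as_tibble(data)
    out$.fitted <- as.numeric(predict(x, data))
  }
  out
}

#' Tidy an ANOVA table
#'
#' @param x An [rsm_anova()] result.
#' @param ... Unused.
#' @return The full decomposition as a tibble (`source`, `coefficient`,
#'   `SS`, `df`, `MS`, `F`, `p`, `significance`).
#' @export
tidy.rsm_anova <- function(x, ...) x$table

#' @rdname tidy.rsm_anova
#' @export
glance.rsm_anova <- function(x, ...) {
  tibble::as_tibble(x$stats[c("r2", "adj_r2", "cv_percent", "adeq_precision",
                              "mse", "n", "p")])
}

#' Tidy a desirability optimum
#'
#' @param x An [optimize_desirability()] result.
#' @param ... Unused.
#' @return One row per response: coordinates are repeated for convenience.
#' @export
tidy.desirability_optimum <- function(x, ...) {
  tibble::tibble(response = names(x$predicted),
                 predicted = unname(x$predicted),
                 desirability = unname(x$d))
}

#' @rdname tidy.desirability_optimum
#' @export
glance.desirability_optimum <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(D = x$D), x$natural)
}

#' Tidy a correlation analysis
#'
#' @param x A [pearson_matrix()] result.
#' @param ... Unused.
#' @return Long tibble of the lower triangle: `var1`, `var2`, `r`, `p`,
#'   `significance` ("p<0.01", "p<0.05" or "ns").
#' @export
tidy.pearson_cor <- function(x, ...) {
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = colnames(x$r)[idx[, 2]],
    var2 = rownames(x$r)[idx[, 1]],
    r = x$r[idx], p = x$p[idx],
    significance = dplyr::case_when(
      is.na(x$p[idx]) ~ NA_character_,
      x$p[idx] < 0.01 ~ "p<0.01",
      x$p[idx] < 0.05 ~ "p<0.05",
      TRUE ~ "ns"
    )
  )
}

#' Tidy a correlation-matrix PCA
#'
#' @param x An [activity_pca()] result.
#' @param matrix One of `"eigenvalues"`, `"scores"`, `"loadings"`.
#' @param ... Unused.
#' @return A tibble of the requested component.
#' @export
tidy.activity_pca <- function(x, matrix = c("eigenvalues", "scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble::tibble(
      component = paste0("PC", seq_along(x$eigenvalues)),
      eigenvalue = x$eigenvalues,
      explained_percent = x$explained_percent,
      cumulative_percent = cumsum(x$explained_percent)
    ),
    scores = dplyr::bind_cols(tibble::tibble(sample = rownames(x$scores)),
                              tibble::as_tibble(x$scores)),
    loadings = dplyr::bind_cols(tibble::tibble(variable = rownames(x$loadings)),
                                tibble::as_tibble(x$loadings))
  )
}

#' Tidy an IC50 fit
#'
#' @param x An [estimate_ic50()] result.
#' @param ... Unused.
#' @export
tidy.ic50_fit <- function(x, ...) {
  if (is.null(x$parameters)) {
    return(tibble::tibble(term = "ic50", estimate = x$ic50))
  }
  tibble::tibble(term = names(x$parameters), estimate = unname(x$parameters))
}

#' @rdname tidy.ic50_fit
#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, method = x$method, converged = x$converged,
                 residual_se = x$residual_se)
}
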