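#' Define a factor of a central composite design
#'
#' A CCD factor is described in natural units by its centre, its step (half the
#' factorial range, i.e. natural units per coded unit) and its two axial
#' ("star") levels. Axial levels are given directly in natural units rather
#' than through a single alpha so that designs whose axial distance differs by
#' factor (e.g. an extraction-time factor coded to +/-1.8 while the others sit
#' at +/-2) are represented exactly as run.
#'
#' @param name Factor name (used as a column name in run tables).
#' @param center Centre level, natural units.
#' @param step Natural units per coded unit; must be > 0.
#' @param axial_low,axial_high Axial levels in natural units; must lie strictly
#'   outside the factorial range `center +/- step`.
#' @param units Free-text unit label.
#' @return A one-row tibble of class `ccd_factor`.
#' @examples
#' ccd_factor("ethanol", center = 50, step = 25, axial_low = 0, axial_high = 100, units = "%")
#' @export
ccd_factor <- function(name, center, step, axial_low, axial_high, units = "") {
  if (!is.numeric(step) || step <= 0) {
    stop("`step` must be a positive number (got ", step, ").", call. = FALSE)
  }
  if (!(axial_low < center - step && center + step < axial_high)) {
    stop(
      "Axial levels of factor `", name, "` must lie outside the factorial ",
      "range [", center - step, ", ", center + step, "].",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    name = as.character(name), center = as.numeric(center),
    step = as.numeric(step), axial_low = as.numeric(axial_low),
    axial_high = as.numeric(axial_high), units = as.character(units)
  )
  class(out) <- c("ccd_factor", class(out))
  out
}

#' Construct a central composite design
#'
#' Builds the full run list of a face-independent CCD: a complete two-level
#' factorial at `center +/- step`, axial points at each factor's
#' `axial_low`/`axial_high` with the remaining factors at centre, and
#' `n_center` replicated centre points. Runs are returned in standard order
#' (factorial, then axial low/high per factor, then centre). Each factor
#' therefore takes exactly five distinct natural levels.
#'
#' @param factors A list of [ccd_factor()] specifications (or a tibble made by
#'   row-binding them), length k >= 2.
#' @param n_center Number of centre replicates (>= 1).
#' @return An object of class `ccd_design`: a list with elements `factors`
#'   (tibble of factor specifications) and `runs` (tibble with `std_order`,
#'   `run_type` and one natural-unit column per factor).
#' @examples
#' des <- ccd_design(list(
#'   ccd_factor("a", 0, 1, -2, 2),
#'   ccd_factor("b", 10, 5, 0, 20)
#' ), n_center = 1)
#' nrow(des$runs) # 2^2 + 2*2 + 1 = 9
#' @export
ccd_design <- function(factors, n_center = 6) {
  if (inherits(factors, "data.frame")) {
    fs <- tibble::as_tibble(factors)
  } else {
    fs <- dplyr::bind_rows(factors)
  }
  class(fs) <- c("tbl_df", "tbl", "data.frame")
  k <- nrow(fs)
  if (k < 2) stop("A CCD needs at least 2 factors.", call. = FALSE)
  if (n_center < 1) stop("`n_center` must be >= 1.", call. = FALSE)
  if (anyDuplicated(fs$name)) stop("Factor names must be unique.", call. = FALSE)
  # re-validate in case a raw tibble was supplied
  purrr::pwalk(fs, function(name, center, step, axial_low, axial_high, units) {
    ccd_factor(name, center, step, axial_low, axial_high, units)
  })

  # factorial block, standard (Yates) order: first factor cycles fastest
  fact_coded <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  fact_nat <- sweep(sweep(fact_coded, 2, fs$step, `*`), 2, fs$center, `+`)

  # axial block: per factor, low then high
  ax_nat <- matrix(rep(fs$center, each = 2 * k), nrow = 2 * k)
  for (i in seq_len(k)) {
    ax_nat[2 * i - 1, i] <- fs$axial_low[i]
    ax_nat[2 * i, i] <- fs$axial_high[i]
  }

  ctr_nat <- matrix(rep(fs$center, each = n_center), nrow = n_center)

  runs <- rbind(fact_nat, ax_nat, ctr_nat)
  colnames(runs) <- fs$name
  runs <- tibble::as_tibble(runs)
  runs <- dplyr::bind_cols(
    tibble::tibble(
      std_order = seq_len(nrow(runs)),
      run_type = rep(c("factorial", "axial", "center"), c(2^k, 2 * k, n_center))
    ),
    runs
  )

  structure(
    list(factors = fs, runs = runs, n_factorial = 2^k, n_axial = 2 * k,
         n_center = as.integer(n_center)),
    class = "ccd_design"
  )
}

#' @export
print.ccd_design <- function(x, ...) {
  k <- nrow(x$factors)
  cat("Central composite design: ", k, " factors, ",
      x$n_factorial, " factorial + ", x$n_axial, " axial + ",
      x$n_center, " centre = ", nrow(x$runs), " runs\n", sep = "")
  print(x$factors)
  invisible(x)
}

#' Code natural factor levels
#'
#' Transforms natural units to coded units, `(natural - center) / step`, one
#' column per design factor. Axial points need not land on +/-2: the coded
#' value is always computed from the natural level, never assumed.
#'
#' @param design A [ccd_design()].
#' @param data A data frame containing the design's factor columns in natural
#'   units (extra columns are carried through unchanged).
#' @return `data` with each factor column replaced by its coded value. An
#'   `extrapolated` logical column flags points outside the axial range.
#' @examples
#' des <- ajwa_design()
#' code_points(des, tibble::tibble(ethanol = 100, time = 150, temperature = 40))
#' @export
code_points <- function(design, data) {
  fs <- design$factors
  missing <- setdiff(fs$name, names(data))
  if (length(missing)) {
    stop("Missing factor column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  extrap <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(fs))) {
    nm <- fs$name[i]
    coded <- (out[[nm]] - fs$center[i]) / fs$step[i]
    lo <- (fs$axial_low[i] - fs$center[i]) / fs$step[i]
    hi <- (fs$axial_high[i] - fs$center[i]) / fs$step[i]
    extrap <- extrap | coded < lo - 1e-12 | coded > hi + 1e-12
    out[[nm]] <- coded
  }
  out$extrapolated <- extrap
  out
}

#' Decode coded factor levels back to natural units
#'
#' Exact inverse of [code_points()]: `natural = center + step * coded`.
#'
#' @inheritParams code_points
#' @param coded A data frame of coded factor columns.
#' @return `coded` with factor columns in natural units.
#' @export
decode_points <- function(design, coded) {
  fs <- design$factors
  missing <- setdiff(fs$name, names(coded))
  if (length(missing)) {
    stop("Missing factor column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(coded)
  for (i in seq_len(nrow(fs))) {
    nm <- fs$name[i]
    out[[nm]] <- fs$center[i] + fs$step[i] * out[[nm]]
  }
  out$extrapolated <- NULL
  out
}

#' Coded bounds of the design region
#'
#' @param design A [ccd_design()].
#' @return A tibble with one row per factor and coded `lower`/`upper` bounds
#'   given by the axial levels.
#' @export
coded_bounds <- function(design) {
  fs <- design$factors
  tibble::tibble(
    name = fs$name,
    lower = (fs$axial_low - fs$center) / fs$step,
    upper = (fs$axial_high - fs$center) / fs$step
  )
}

#' Attach measured responses to a design by matching factor settings
#'
#' Accepts a run table in any row order (e.g. the randomized order an
#' experiment was executed in) and matches rows to design points by their
#' factor settings, never by position.
#'
#' @param design A [ccd_design()].
#' @param data A data frame with the design's factor columns (natural units)
#'   plus one column per response.
#' @param responses Character vector naming the response columns.
#' @param tol Matching tolerance on natural factor levels.
#' @return A tibble in design standard order: `std_order`, `run_type`, factor
#'   columns, response columns.
#' @export
match_runs <- function(design, data, responses, tol = 1e-8) {
  fs <- design$factors$name
  missing <- setdiff(c(fs, responses), names(data))
  if (length(missing)) {
    stop("Run table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[responses])) stop("Run table has missing responses.", call. = FALSE)
  dm <- as.matrix(data[fs])
  used <- rep(FALSE, nrow(dm))
  idx <- purrr::map_int(seq_len(nrow(design$runs)), function(i) {
    target <- as.numeric(design$runs[i, fs])
    hit <- which(!used & apply(abs(sweep(dm, 2, target)), 1, max) <= tol)
    if (!length(hit)) {
      stop("No run in the data matches design point ", i, " (",
           paste(fs, "=", target, collapse = ", "), ").", call. = FALSE)
    }
    used[hit[1]] <<- TRUE
    hit[1]
  })
  dplyr::bind_cols(
    design$runs[, c("std_order", "run_type", fs)],
    tibble::as_tibble(data[idx, responses, drop = FALSE])
  )
}

#' Write / read a design run table as CSV with a JSON factor sidecar
#'
#' The CSV holds the run table (factors in natural units plus any responses);
#' the sidecar `<path>.json` stores the factor specifications so the design
#' can be rebuilt on read.
#'
#' @param design A [ccd_design()].
#' @param data Optional run table to write (defaults to the design's runs).
#' @param path CSV path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a list with `design` and `runs`.
#' @export
write_design <- function(design, path, data = NULL) {
  if (is.null(data)) data <- design$runs
  utils::write.csv(data, path, row.names = FALSE)
  jsonlite::write_json(design$factors, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  fs <- tibble::as_tibble(jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE))
  runs <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  n_center <- sum(purrr::map_lgl(seq_len(nrow(runs)), function(i) {
    all(abs(as.numeric(runs[i, fs$name]) - fs$center) < 1e-9)
  }))
  list(design = ccd_design(fs, n_center = max(n_center, 1L)), runs = runs)
}
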