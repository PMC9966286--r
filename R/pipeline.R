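round_sig <- function(x, digits = 6) {
  if (is.list(x)) return(purrr::map(x, round_sig, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates design construction, quadratic fitting + ANOVA per response,
#' desirability optimization, RSD validation, chemometrics and peak
#' annotation, writing per-stage delimited outputs and a combined JSON report
#' to `out_dir`. Any stage failure halts with an error naming the stage.
#' Reruns with identical config produce byte-identical JSON (numbers are
#' rounded to 6 significant digits in the report; delimited outputs keep full
#' precision).
#'
#' @param config A list, or the path of a YAML file, with elements:
#'   `factors` (list of lists with name/center/step/axial_low/axial_high and
#'   optional units), `n_center`, `runs` (CSV path of the run table; factor
#'   columns in natural units plus responses), `responses` (character),
#'   optional `alpha` (backward-elimination threshold; when present reduced
#'   models are also reported), optional `resolution`, optional
#'   `experimental` (named list of confirmation means for validation),
#'   optional `activity` (CSV path, sample column + variables), optional
#'   `peaks` (CSV path with formula/observed_mz/fragments), optional
#'   `tol_da`, and `out_dir`.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("`out_dir` is required.", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()

  design <- stage_try("design", {
    fs <- purrr::map(config$factors, function(f) {
      ccd_factor(f$name, f$center, f$step, f$axial_low, f$axial_high,
                 units = f$units %||% "")
    })
    ccd_design(fs, n_center = config$n_center %||% 6)
  })
  write_design(design, file.path(out_dir, "design.csv"))
  report$design <- list(
    factors = design$factors$name,
    n_runs = nrow(design$runs),
    n_center = design$n_center
  )

  runs <- stage_try("load_runs", {
    if (is.null(config$runs)) stop("`runs` is required.")
    if (!file.exists(config$runs)) stop("run table not found: ", config$runs)
    data <- tibble::as_tibble(utils::read.csv(config$runs, check.names = FALSE))
    missing <- setdiff(config$responses, names(data))
    if (length(missing)) {
      stop("response(s) not in run table: ", paste(missing, collapse = ", "))
    }
    match_runs(design, data, config$responses)
  })

  fits <- stage_try("fit", {
    purrr::map(config$responses, function(r) fit_quadratic(runs, r, design))
  })
  names(fits) <- config$responses
  report$fit <- purrr::map(fits, function(f) {
    an <- rsm_anova(f)
    utils::write.csv(tidy(an), file.path(out_dir, paste0("anova_", f$response, ".csv")),
                     row.names = FALSE)
    utils::write.csv(tidy(f), file.path(out_dir, paste0("coefficients_", f$response, ".csv")),
                     row.names = FALSE)
    list(coefficients = round_sig(as.list(f$coefficients)),
         stats = round_sig(an$stats))
  })
  if (!is.null(config$alpha)) {
    report$reduced <- purrr::map(fits, function(f) {
      rf <- reduce_model(f, alpha = config$alpha)
      round_sig(as.list(rf$coefficients))
    })
  }

  opt <- stage_try("optimize", {
    goals <- observed_range_goals(runs, config$responses)
    optimize_desirability(fits, goals, resolution = config$resolution %||% 41)
  })
  report$optimum <- list(
    D = round_sig(opt$D),
    natural = round_sig(as.list(opt$natural[1, design$factors$name])),
    coded = round_sig(as.list(opt$coded[1, ])),
    predicted = round_sig(as.list(opt$predicted)),
    d = round_sig(as.list(opt$d))
  )

  if (!is.null(config$experimental)) {
    val <- stage_try("validate", {
      validate_optimum(opt, unlist(config$experimental))
    })
    utils::write.csv(val, file.path(out_dir, "validation.csv"), row.names = FALSE)
    report$validation <- purrr::transpose(round_sig(as.list(val)))
  }

  if (!is.null(config$activity)) {
    report$chemometrics <- stage_try("chemometrics", {
      act <- tibble::as_tibble(utils::read.csv(config$activity, check.names = FALSE))
      pc <- pearson_matrix(act)
      utils::write.csv(tidy(pc), file.path(out_dir, "correlation.csv"),
                       row.names = FALSE)
      pca <- activity_pca(act)
      utils::write.csv(tidy(pca, "scores"), file.path(out_dir, "pca_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(tidy(pca, "loadings"), file.path(out_dir, "pca_loadings.csv"),
                       row.names = FALSE)
      hca <- activity_hca(act)
      hca_newick(hca, file.path(out_dir, "dendrogram.nwk"))
      list(eigenvalues = round_sig(pca$eigenvalues),
           explained_percent = round_sig(pca$explained_percent),
           clusters = as.list(stats::setNames(cut_clusters(hca, 3)$cluster,
                                              cut_clusters(hca, 3)$sample)))
    })
  }

  if (!is.null(config$peaks)) {
    report$annotation <- stage_try("annotate", {
      peaks <- tibble::as_tibble(utils::read.csv(config$peaks, check.names = FALSE))
      ann <- annotate_peaks(peaks, tol_da = config$tol_da %||% 0.05)
      flat <- dplyr::select(ann, -dplyr::any_of("losses"))
      utils::write.csv(flat, file.path(out_dir, "peaks_annotated.csv"),
                       row.names = FALSE)
      list(n_peaks = nrow(ann),
           max_abs_ppm = round_sig(max(abs(ann$ppm))),
           mean_abs_ppm = round_sig(mean(abs(ann$ppm))))
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
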