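# IUPAC monoisotopic atomic masses (u) for the elements handled here.
MONOISOTOPIC_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069
)
HYDROGEN_ATOM <- 1.007825
PROTON <- 1.00727646677

#' Parse an elemental formula
#'
#' Parses text like `"C15H10O6"` into element counts. Supported elements:
#' C, H, N, O, S. `formula_string()` writes counts back in Hill order
#' (C, H, then alphabetical), so `formula_string(parse_formula(x))` is the
#' identity on canonical strings.
#'
#' @param formula Formula text.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C15H10O6")
#' @export
parse_formula <- function(formula) {
  f <- gsub("[[:space:]_]", "", formula)
  tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
  if (!length(tokens) || nchar(f) != sum(nchar(tokens))) {
    stop("Cannot parse formula: ", formula, call. = FALSE)
  }
  els <- gsub("[0-9]", "", tokens)
  ns <- as.integer(ifelse(gsub("[^0-9]", "", tokens) == "", "1",
                          gsub("[^0-9]", "", tokens)))
  unknown <- setdiff(els, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("Unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(ns, els, sum)
  counts <- counts[order(match(names(counts), c("C", "H"), nomatch = 3L),
                         names(counts))]
  stats::setNames(as.integer(counts), names(counts))
}

#' @rdname parse_formula
#' @param counts Named integer vector as returned by `parse_formula()`.
#' @export
formula_string <- function(counts) {
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Monoisotopic mass and deprotonated m/z
#'
#' `monoisotopic_mass()` sums the monoisotopic atomic masses of a neutral
#' formula. `mz_deprotonated()` returns the \[M-H\]- ion m/z; by default the
#' hydrogen ATOM mass (1.007825) is subtracted, the convention used by common
#' deconvolution software for printed "calculated mass" columns. The more
#' physical convention (subtract a proton, i.e. keep the extra electron)
#' differs by the electron mass (~0.00055) and is available via
#' `convention = "proton"`.
#'
#' @param formula Formula text or parsed counts.
#' @param convention `"hydrogen"` (default) or `"proton"`.
#' @return Mass in u (m/z for singly charged ions).
#' @examples
#' mz_deprotonated("C15H10O6") # 285.0399
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(MONOISOTOPIC_MASS[names(formula)] * formula)
}

#' @rdname monoisotopic_mass
#' @export
mz_deprotonated <- function(formula, convention = c("hydrogen", "proton")) {
  convention <- match.arg(convention)
  monoisotopic_mass(formula) -
    if (convention == "hydrogen") HYDROGEN_ATOM else PROTON
}

#' Signed mass error in parts per million
#'
#' `1e6 * (observed - calculated) / calculated`.
#'
#' @param observed,calculated m/z values (`calculated` > 0).
#' @return ppm error, vectorized.
#' @export
ppm_error <- function(observed, calculated) {
  if (any(calculated <= 0)) stop("`calculated` must be positive.", call. = FALSE)
  1e6 * (observed - calculated) / calculated
}

#' Library of diagnostic neutral losses
#'
#' Exact monoisotopic masses of neutral losses commonly diagnostic in
#' negative-mode MS/MS of plant polyphenols: glycoside residues (hexose
#' 162.0528, deoxyhexose 146.0579, pentose 132.0423), galloyl 152.0110,
#' and small molecules (water, CO, ketene, CO2, SO3, methyl, 2CO, C-glycoside
#' cross-ring cleavages 60/90/120).
#'
#' @return A tibble with `loss` and `mass` columns.
#' @export
loss_library <- function() {
  tibble::tribble(
    ~loss, ~mass,
    "hexose residue", 162.0528,
    "deoxyhexose residue", 146.0579,
    "pentose residue", 132.0423,
    "galloyl", 152.0110,
    "water", 18.0106,
    "CO", 27.9949,
    "ketene", 42.0106,
    "CO2", 43.9898,
    "2CO", 55.9898,
    "SO3", 79.9568,
    "methyl radical", 15.0235,
    "cross-ring C2H4O2", 60.0211,
    "cross-ring C3H6O3", 90.0317,
    "cross-ring C4H8O4", 120.0423
  )
}

#' Annotate fragment ions by neutral-loss matching
#'
#' For each fragment m/z, reports every library loss whose mass matches the
#' precursor-to-fragment difference within `tol_da`, plus (optionally) all
#' fragment-to-fragment differences, so sequential losses (e.g. glycoside
#' then water) are annotated. Differences with no library match are still
#' reported numerically.
#'
#' @param precursor_mz Precursor ion m/z.
#' @param fragment_mzs Numeric vector of fragment m/z values.
#' @param library A loss table as from [loss_library()].
#' @param tol_da Matching tolerance in Da (> 0). Default 0.05 Da, suited to
#'   fragment m/z printed to two decimals.
#' @param pairwise Also match fragment-to-fragment differences.
#' @return A tibble with columns `from`, `from_mz`, `to_mz`, `delta`,
#'   `matched_loss` (NA when unmatched), `loss_mass`, `error_da`.
#' @examples
#' annotate_losses(515.1611, c(353.10, 311.05, 297.04))
#' @export
annotate_losses <- function(precursor_mz, fragment_mzs, library = loss_library(),
                            tol_da = 0.05, pairwise = TRUE) {
  if (tol_da <= 0) stop("`tol_da` must be positive.", call. = FALSE)
  edges <- tibble::tibble(from = "precursor", from_mz = precursor_mz,
                          to_mz = fragment_mzs)
  if (pairwise && length(fragment_mzs) >= 2) {
    pairs <- utils::combn(sort(fragment_mzs, decreasing = TRUE), 2)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = "fragment", from_mz = pairs[1, ], to_mz = pairs[2, ]
    ))
  }
  edges$delta <- edges$from_mz - edges$to_mz
  purrr::pmap_dfr(edges, function(from, from_mz, to_mz, delta) {
    hit <- library[abs(library$mass - delta) <= tol_da, ]
    if (nrow(hit) == 0) {
      tibble::tibble(from = from, from_mz = from_mz, to_mz = to_mz,
                     delta = delta, matched_loss = NA_character_,
                     loss_mass = NA_real_, error_da = NA_real_)
    } else {
      tibble::tibble(from = from, from_mz = from_mz, to_mz = to_mz,
                     delta = delta, matched_loss = hit$loss,
                     loss_mass = hit$mass, error_da = delta - hit$mass)
    }
  })
}

#' Annotate a peak table
#'
#' Computes the calculated deprotonated m/z and ppm error for every row of a
#' peak table and annotates its fragment list by neutral-loss matching
#' against the observed precursor m/z.
#'
#' @param peaks A data frame with columns `formula`, `observed_mz` and
#'   optionally `fragments` (semicolon-separated m/z list); e.g.
#'   [ajwa_peaks()].
#' @inheritParams annotate_losses
#' @inheritParams mz_deprotonated
#' @return The input with `calculated_mz` (recomputed), `ppm` columns and a
#'   list-column `losses` of per-row annotation tibbles.
#' @export
annotate_peaks <- function(peaks, library = loss_library(), tol_da = 0.05,
                           convention = c("hydrogen", "proton")) {
  convention <- match.arg(convention)
  out <- tibble::as_tibble(peaks)
  out$calculated_mz <- purrr::map_dbl(out$formula, mz_deprotonated,
                                      convention = convention)
  out$ppm <- ppm_error(out$observed_mz, out$calculated_mz)
  if ("fragments" %in% names(out)) {
    out$losses <- purrr::map2(out$observed_mz, out$fragments, function(mz, fr) {
      fmz <- suppressWarnings(as.numeric(strsplit(as.character(fr), ";")[[1]]))
      fmz <- fmz[!is.na(fmz)]
      if (!length(fmz)) return(tibble::tibble())
      annotate_losses(mz, fmz, library = library, tol_da = tol_da)
    })
  }
  out
}
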