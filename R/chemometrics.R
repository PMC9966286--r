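split_activity <- function(data, sample_col = "sample") {
  data <- tibble::as_tibble(data)
  if (sample_col %in% names(data)) {
    labels <- as.character(data[[sample_col]])
    X <- as.matrix(data[setdiff(names(data), sample_col)])
  } else {
    labels <- rownames(data) %||% paste0("S", seq_len(nrow(data)))
    X <- as.matrix(data)
  }
  if (anyNA(X)) stop("Activity matrix has missing cells.", call. = FALSE)
  rownames(X) <- labels
  X
}

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson correlations between all variables of a sample-by-variable
#' activity matrix, with two-sided p-values from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` on n - 2 degrees of freedom and significance
#' flags at 0.05 / 0.01.
#'
#' @param data Data frame with an optional `sample` label column and numeric
#'   variable columns; at least 3 samples for p-values.
#' @param sample_col Name of the label column, if present.
#' @return An object of class `pearson_cor`: list with matrices `r` and `p`
#'   and the sample size `n`. Zero-variance variables yield `NA` correlations
#'   with a warning.
#' @examples
#' generics::tidy(pearson_matrix(ajwa_activity()))
#' @export
pearson_matrix <- function(data, sample_col = "sample") {
  X <- split_activity(data, sample_col)
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("Zero-variance variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "),
            "; their correlations are undefined (NA).", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(X))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[r^2 >= 1] <- 0
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "pearson_cor")
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat("Pearson correlations over", x$n, "samples\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Principal component analysis of the correlation matrix
#'
#' Eigendecomposition of the sample correlation matrix (appropriate when
#' variables mix units, e.g. mg/g contents and mg/mL IC50s): the eigenvalues
#' sum to the number of variables and `explained_percent` is 100 lambda /
#' sum(lambda). Scores are the standardized data projected on the
#' eigenvectors. Sign convention: within each component the loading with the
#' largest magnitude is made positive, so results are deterministic.
#'
#' @inheritParams pearson_matrix
#' @return An object of class `activity_pca`: list with `eigenvalues`,
#'   `explained_percent`, `loadings` (variables x components) and `scores`
#'   (samples x components).
#' @export
activity_pca <- function(data, sample_col = "sample") {
  X <- split_activity(data, sample_col)
  if (ncol(X) < 2 || nrow(X) < 2) {
    stop("PCA needs at least 2 samples and 2 variables.", call. = FALSE)
  }
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("Constant variable(s) cannot be standardized for correlation PCA.",
         call. = FALSE)
  }
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  scores <- scale(X) %*% V
  structure(
    list(eigenvalues = eig$values,
         explained_percent = 100 * eig$values / sum(eig$values),
         loadings = V, scores = scores),
    class = "activity_pca"
  )
}

#' @export
print.activity_pca <- function(x, ...) {
  cat("Correlation-matrix PCA\n")
  print(tibble::tibble(component = paste0("PC", seq_along(x$eigenvalues)),
                       eigenvalue = round(x$eigenvalues, 3),
                       explained_percent = round(x$explained_percent, 1)))
  invisible(x)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters samples on Euclidean distances between z-scored variables
#' (standardization makes the result invariant to affine rescaling of any
#' raw variable). Linkages: Ward (`"ward"`, implemented as Ward's minimum
#' variance on squared Euclidean distances), `"average"` or `"complete"`.
#' Tie-breaking between equal-height merges follows the input row order.
#'
#' @inheritParams pearson_matrix
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return An object of class `activity_hca` wrapping the `hclust` tree.
#' @examples
#' h <- activity_hca(ajwa_activity())
#' cut_clusters(h, k = 3)
#' @export
activity_hca <- function(data, linkage = c("ward", "average", "complete"),
                         sample_col = "sample") {
  linkage <- match.arg(linkage)
  X <- split_activity(data, sample_col)
  if (nrow(X) < 2) stop("Clustering needs at least 2 samples.", call. = FALSE)
  Z <- scale(X)
  Z[, apply(X, 2, stats::sd) == 0] <- 0
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  tree <- stats::hclust(stats::dist(Z), method = method)
  structure(list(tree = tree, linkage = linkage, labels = rownames(X)),
            class = "activity_hca")
}

#' @export
print.activity_hca <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, " linkage, Euclidean on ",
      "z-scores) of ", length(x$labels), " samples\n", sep = "")
  cat("merge heights:", paste(round(x$tree$height, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Cut a cluster tree into k groups
#'
#' @param hca An [activity_hca()] result.
#' @param k Number of clusters.
#' @return A tibble with `sample` and `cluster` columns.
#' @export
cut_clusters <- function(hca, k) {
  cl <- stats::cutree(hca$tree, k = k)
  tibble::tibble(sample = names(cl), cluster = unname(cl))
}

#' Export a cluster tree as Newick text
#'
#' @param hca An [activity_hca()] result.
#' @param path Optional file path; if omitted the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
hca_newick <- function(hca, path = NULL) {
  phy <- ape::as.phylo(hca$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
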