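test_that("Pearson correlations match hand-computed values", {
  m <- tibble::tibble(sample = c("a", "b", "c"),
                      x = c(1, 2, 3), y = c(1, 2, 4), z = c(6, 4, 2),
                      w = 2 * c(1, 2, 3) + 1)
  pc <- pearson_matrix(m)
  expect_equal(pc$r["x", "y"], 0.9820, tolerance = 1e-4)
  expect_equal(pc$r["x", "z"], -1)
  expect_equal(pc$r["x", "w"], 1)
  expect_equal(pc$p["x", "z"], 0)
  # symmetric, unit diagonal, positive semidefinite
  expect_equal(pc$r, t(pc$r))
  expect_equal(diag(pc$r), rep(1, 4), ignore_attr = TRUE)
  expect_gte(min(eigen(pc$r, symmetric = TRUE)$values), -1e-10)
})

test_that("zero-variance variables are reported as undefined", {
  m <- tibble::tibble(sample = c("a", "b", "c"), x = c(1, 2, 3), k = c(1, 1, 1))
  expect_warning(pc <- pearson_matrix(m), "Zero-variance")
  expect_true(is.na(pc$r["x", "k"]))
})

test_that("correlation PCA has the closed-form equicorrelation spectrum", {
  # 2 variables with correlation r -> eigenvalues 1 + |r|, 1 - |r|
  set.seed(2)
  n <- 200
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  m <- tibble::tibble(sample = as.character(1:n), x = x, y = y)
  r <- cor(x, y)
  p <- activity_pca(m)
  expect_equal(p$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-9)
  # eigenvalue sum equals the variable count; explained sums to 100
  a <- activity_pca(ajwa_activity())
  expect_equal(sum(a$eigenvalues), 7, tolerance = 1e-9)
  expect_equal(sum(a$explained_percent), 100)
  expect_true(all(diff(a$eigenvalues) <= 1e-12))
  # scores are uncorrelated across components
  sc <- a$scores[, a$eigenvalues > 1e-8]
  cv <- crossprod(scale(sc, scale = FALSE)) / (nrow(sc) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # deterministic sign convention: dominant loading positive
  for (j in seq_len(ncol(a$loadings))) {
    expect_gte(a$loadings[which.max(abs(a$loadings[, j])), j], 0)
  }
  expect_error(activity_pca(tibble::tibble(sample = c("a", "b"), x = c(1, 1),
                                           y = c(1, 2))), "Constant")
})

test_that("identity-correlation data gives flat eigenvalues in expectation", {
  m <- simulate_activity_matrix(800, 4, latent_corr = 0, seed = 5)
  p <- activity_pca(m)
  expect_equal(p$eigenvalues, rep(1, 4), tolerance = 0.15)
})

test_that("hierarchical clustering merges by similarity with exact expected order", {
  # identical rows merge first at height 0
  m <- tibble::tibble(sample = c("a", "b", "c"),
                      x = c(1, 1, 5), y = c(2, 2, 9))
  h <- activity_hca(m)
  expect_equal(h$tree$height[1], 0)
  expect_equal(sort(cut_clusters(h, 2)$cluster[1:2]), c(1, 1))
  # 1D points 0, 1, 10: {0,1} merge before 10 joins, any linkage
  m2 <- tibble::tibble(sample = c("p", "q", "r"), x = c(0, 1, 10),
                       y = c(0, 0, 0) + 1e-9 * c(1, 2, 3))
  for (link in c("ward", "average", "complete")) {
    h2 <- activity_hca(m2, linkage = link)
    cl <- cut_clusters(h2, 2)
    expect_equal(cl$cluster[cl$sample %in% c("p", "q")], c(1, 1))
    expect_true(all(diff(h2$tree$height) >= 0))
  }
  # cut at k = n gives singletons
  expect_equal(sort(cut_clusters(h, 3)$cluster), 1:3)
})

test_that("clustering on z-scores is invariant to affine rescaling of variables", {
  m <- ajwa_activity()
  h1 <- activity_hca(m)
  m2 <- dplyr::mutate(m, TPC = 1000 * TPC - 7, DPPH = DPPH / 55 + 2)
  h2 <- activity_hca(m2)
  expect_equal(h1$tree$merge, h2$tree$merge)
  expect_equal(h1$tree$height, h2$tree$height, tolerance = 1e-9)
})

test_that("the packaged activity fixture reproduces the published qualitative pattern", {
  act <- ajwa_activity()
  tab <- tidy(pearson_matrix(act))
  sig <- function(v1, v2) {
    dplyr::filter(tab, (var1 == v1 & var2 == v2) | (var1 == v2 & var2 == v1))
  }
  # radical scavenging and tyrosinase inhibition track polyphenol content
  expect_equal(sig("TFC", "DPPH")$significance, "p<0.01")
  expect_equal(sig("TFC", "TYR")$significance, "p<0.01")
  expect_equal(sig("TPC", "DPPH")$significance, "p<0.05")
  expect_equal(sig("TPC", "TYR")$significance, "p<0.05")
  expect_equal(sig("TPC", "ABTS")$significance, "ns")
  expect_equal(sig("TPC", "ELA")$significance, "ns")
  # three clusters: {OP, HM}, the mid group, {MW}
  cl <- cut_clusters(activity_hca(act), 3)
  memb <- setNames(cl$cluster, cl$sample)
  expect_equal(memb[["OP"]], memb[["HM"]])
  expect_length(unique(memb[c("HE", "HW", "MM", "ME")]), 1)
  expect_false(memb[["MW"]] %in% memb[c("OP", "HE")])
  # first component dominates, in the vicinity of the published share
  p <- activity_pca(act)
  expect_gt(p$explained_percent[1], 50)
  # Newick export round-trips through ape
  nwk <- hca_newick(activity_hca(act))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, act$sample)
})
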