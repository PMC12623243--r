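test_that("preprocess scales cells to a common total and excludes keratins", {
  counts <- rbind(c(10, 0, 10), c(1, 2, 3))
  colnames(counts) <- c("KRT5", "KRT10", "ACTB")
  prep <- preprocess(toy_cells(counts), exclude_pattern = "^KRT", target = 20)
  expect_equal(prep$genes, "ACTB")
  expect_setequal(prep$excluded_genes, c("KRT5", "KRT10"))
  # row sums hit the target exactly before log1p (no exclusions)
  set.seed(1)
  m <- matrix(stats::rpois(200, 3), 10, 20,
              dimnames = list(NULL, paste0("g", 1:20)))
  prep2 <- preprocess(toy_cells(m), exclude_pattern = NULL, target = 1e4)
  expect_equal(unname(rowSums(expm1(prep2$mat))), rep(1e4, 10), tolerance = 1e-9)
  # zero-total cells are dropped with a warning
  m[1, ] <- 0
  expect_warning(prep3 <- preprocess(toy_cells(m), exclude_pattern = NULL),
                 "zero total")
  expect_equal(prep3$kept_cells, 2:10)
})

test_that("PCA of two distinct points loads everything on PC1", {
  mat <- rbind(c(0, 0, 0), c(2, 1, 2))
  colnames(mat) <- paste0("g", 1:3)
  p <- fit_pooled_pca(mat, n_components = 2)
  expect_equal(p$explained_variance_ratio[1], 1)
  expect_equal(p$explained_variance_ratio[2], 0, tolerance = 1e-12)
})

test_that("full-rank PCA reconstructs the centered matrix", {
  set.seed(2)
  mat <- matrix(stats::rnorm(15 * 6), 15, 6,
                dimnames = list(NULL, paste0("g", 1:6)))
  p <- fit_pooled_pca(mat, n_components = 6)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, unname(sweep(mat, 2, colMeans(mat))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # loadings are orthonormal; explained variance ratios are sorted in [0,1]
  expect_equal(crossprod(p$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_true(all(p$explained_variance_ratio >= 0 &
                    p$explained_variance_ratio <= 1))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
})

test_that("explained variances match an independent eigendecomposition", {
  set.seed(3)
  mat <- matrix(stats::rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, paste0("g", 1:20)))
  p <- fit_pooled_pca(mat, n_components = 10)
  ev <- eigen(stats::cov(mat), symmetric = TRUE)$values
  expect_equal(p$explained_variance_ratio[1:10], (ev / sum(ev))[1:10],
               tolerance = 1e-8)
  expect_error(fit_pooled_pca(mat, n_components = 21), "parameter error")
})

test_that("PCA scores are stable under gene permutation", {
  set.seed(4)
  mat <- matrix(stats::rnorm(30 * 12), 30, 12,
                dimnames = list(NULL, paste0("g", 1:12)))
  p1 <- fit_pooled_pca(mat, n_components = 3)
  perm <- sample(12)
  p2 <- fit_pooled_pca(mat[, perm], n_components = 3)
  expect_equal(abs(p2$scores), abs(p1$scores), tolerance = 1e-8)
  expect_equal(abs(p2$loadings), abs(p1$loadings[perm, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("batch correction centers scores per sample", {
  set.seed(5)
  mat <- matrix(stats::rnorm(40 * 8), 40, 8,
                dimnames = list(NULL, paste0("g", 1:8)))
  mat[1:20, ] <- mat[1:20, ] + 3   # sample shift
  sid <- rep(c("s1", "s2"), each = 20)
  p <- fit_pooled_pca(mat, sample_ids = sid, n_components = 3,
                      batch_correct = TRUE)
  for (s in c("s1", "s2"))
    expect_equal(colMeans(p$scores[sid == s, ]), rep(0, 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("t-ellipse fitting is rotation-equivariant", {
  set.seed(6)
  pts <- cbind(stats::rnorm(200, sd = 3), stats::rnorm(200, sd = 1))
  th <- pi / 5
  Rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  f1 <- fit_t_ellipse(pts)
  f2 <- fit_t_ellipse(pts %*% t(Rot))
  expect_equal(f2$center, as.numeric(Rot %*% f1$center), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(f2$scatter, Rot %*% f1$scatter %*% t(Rot), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("t-ellipse scatter of an isotropic cloud is near-isotropic", {
  set.seed(7)
  pts <- matrix(stats::rnorm(10000), ncol = 2)
  f <- fit_t_ellipse(pts)
  ev <- eigen(f$scatter, symmetric = TRUE)$values
  expect_lt(sqrt(ev[1] / ev[2]), 1.05)
})

test_that("the 95% ellipse covers 95% of draws from the fitted model", {
  set.seed(8)
  pts <- cbind(stats::rnorm(400), stats::rnorm(400))
  pts[, 2] <- pts[, 1] * 0.6 + pts[, 2]
  f <- fit_t_ellipse(pts, level = 0.95, df = 4)
  draws <- sample_t_ellipse(f, 10000)
  cov <- mean(ellipse_contains(f, draws))
  expect_gt(cov, 0.94)
  expect_lt(cov, 0.96)
})

test_that("degenerate ellipse inputs raise fit errors", {
  expect_error(fit_t_ellipse(rbind(c(0, 0), c(1, 1))), "fit error")
  col_pts <- cbind(1:10, 2 * (1:10))
  expect_error(fit_t_ellipse(col_pts), "fit error")
})
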