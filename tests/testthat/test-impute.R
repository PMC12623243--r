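test_that("choose_rank finds a constructed spectral gap", {
  # exact rank 3: three large values, then a flat noise floor
  s <- c(100, 50, 25, rep(1, 30))
  expect_equal(choose_rank(s), 3L)
  # all-equal spectrum: no signal, k = 1 with warning
  expect_warning(k <- choose_rank(rep(5, 30)), "no signal")
  expect_equal(k, 1L)
  expect_error(choose_rank(c(3, 2, 1)), "parameter error")
})

test_that("choose_rank recovers a planted rank from a noisy spectrum", {
  expect_equal(choose_rank(svd(planted_rank5_matrix())$d), 5L)
})

test_that("alra preserves zeros, non-negativity, and all-zero genes", {
  set.seed(13)
  w <- matrix(stats::runif(40 * 3), 40, 3)
  h <- matrix(stats::runif(3 * 25), 3, 25)
  x <- w %*% h
  x[, 25] <- 0                       # an all-zero gene
  colnames(x) <- paste0("g", 1:25)
  res <- alra(x, k = 3)
  expect_true(all(res$imputed >= 0))
  expect_equal(unname(res$imputed[, 25]), rep(0, 40))
})

test_that("alra is a near-fixed-point on noiseless low-rank input", {
  set.seed(14)
  w <- matrix(stats::runif(30 * 4, 1, 2), 30, 4)
  h <- matrix(stats::runif(4 * 20, 1, 2), 4, 20)
  x <- w %*% h
  colnames(x) <- paste0("g", 1:20)
  res <- alra(x, k = 4)
  expect_lt(max(abs(res$imputed - x)) / max(x), 1e-6)
})

test_that("alra rescaling matches original non-zero moments per gene", {
  set.seed(15)
  w <- matrix(stats::runif(60 * 4), 60, 4)
  h <- matrix(stats::runif(4 * 30), 4, 30)
  x <- w %*% h
  colnames(x) <- paste0("g", 1:30)
  drop <- matrix(stats::runif(60 * 30) < 0.2, 60, 30)
  xd <- x; xd[drop] <- 0
  res <- alra(xd, k = 4)
  for (g in which(res$rescaled)) {
    imp_nz <- res$imputed[, g][res$imputed[, g] > 0]
    orig_nz <- xd[, g][xd[, g] > 0]
    if (all(imp_nz > 1e-12)) {     # no post-rescale clamping occurred
      expect_equal(mean(imp_nz), mean(orig_nz), tolerance = 1e-6)
      expect_equal(stats::sd(imp_nz), stats::sd(orig_nz), tolerance = 1e-6)
    }
  }
})

test_that("alra restores planted dropouts and improves gene-wise truth correlation", {
  set.seed(16)
  n <- 150; g <- 80; r <- 5
  w <- matrix(stats::runif(n * r, 0.5, 2), n, r)
  h <- matrix(0, r, g)
  for (k in seq_len(r)) h[k, ((k - 1) * (g / r) + 1):(k * (g / r))] <-
    stats::runif(g / r, 1, 3)
  truth <- w %*% h
  colnames(truth) <- paste0("g", 1:g)
  pos <- which(truth > 0)
  drop <- sample(pos, round(0.3 * length(pos)))
  observed <- truth
  observed[drop] <- 0
  res <- alra(observed, k = r)
  # > 80% of dropped entries restored to positive values
  expect_gt(mean(res$imputed[drop] > 0), 0.8)
  # no all-zero gene gains expression
  zero_genes <- which(colSums(observed) == 0)
  if (length(zero_genes))
    expect_true(all(res$imputed[, zero_genes] == 0))
  # gene-wise correlation with truth does not degrade, and improves overall
  cors <- function(m) vapply(seq_len(g), function(j) {
    if (stats::sd(m[, j]) < 1e-12 || stats::sd(truth[, j]) < 1e-12) return(NA_real_)
    stats::cor(m[, j], truth[, j])
  }, numeric(1))
  c_raw <- cors(observed); c_imp <- cors(res$imputed)
  ok <- !is.na(c_raw) & !is.na(c_imp)
  expect_gt(mean(c_imp[ok] - c_raw[ok]), 0)
  expect_gt(mean(c_imp[ok] >= c_raw[ok] - 1e-8), 0.9)
})

test_that("alra rejects invalid ranks and negative input", {
  x <- matrix(stats::runif(20), 4, 5, dimnames = list(NULL, paste0("g", 1:5)))
  expect_error(alra(x, k = 10), "parameter error")
  expect_error(alra(x - 1, k = 2), "non-negative")
})
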