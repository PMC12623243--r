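#' Normalize counts and exclude keratin genes
#'
#' Library-size normalization of raw counts to a common per-cell total
#' (default 10,000) followed by log1p, with genes matching an exclusion
#' pattern removed before dimensionality reduction. Keratin genes (prefix
#' "KRT") are excluded by default so that the strong structural keratin
#' signal does not dominate the principal components of the pooled selected
#' cells. Cells with zero total counts are dropped with a warning.
#'
#' @param cells a [cell_matrix()] or a cell x gene matrix.
#' @param exclude_pattern regular expression of genes to remove before PCA
#'   (default `"^KRT"`); `NULL` keeps all genes.
#' @param target common per-cell total after scaling.
#' @return list with `mat` (dense normalized cell x gene matrix), `genes`,
#'   `excluded_genes`, `kept_cells` (indices into the input), `target`.
#' @export
preprocess <- function(cells, exclude_pattern = "^KRT", target = 1e4) {
  counts <- if (inherits(cells, "cell_matrix")) cells$counts else as_dgc(cells)
  tot <- Matrix::rowSums(counts)
  keep <- tot > 0
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with zero total counts excluded")
    counts <- counts[keep, , drop = FALSE]
    tot <- tot[keep]
  }
  norm <- Matrix::Diagonal(x = target / tot) %*% counts
  dimnames(norm) <- dimnames(counts)
  genes <- colnames(counts)
  excluded <- character(0)
  if (!is.null(exclude_pattern)) {
    excluded <- grep(exclude_pattern, genes, value = TRUE)
    if (length(excluded))
      norm <- norm[, setdiff(genes, excluded), drop = FALSE]
  }
  list(mat = log1p(as.matrix(norm)), genes = colnames(norm),
       excluded_genes = excluded, kept_cells = unname(which(keep)),
       target = target)
}

#' Pooled principal component analysis
#'
#' Gene-centered SVD of the pooled normalized matrix across samples.
#' Loadings have unit-norm columns; explained variance ratios derive from
#' the singular values relative to the total variance. The sign of each
#' component is fixed so that the largest-magnitude loading entry is
#' positive, making loadings comparable across runs. With `batch_correct`,
#' the per-sample mean of every score component is subtracted after
#' projection — a declared per-sample-centering surrogate for mixing
#' samples in the embedding, not an implementation of Harmony.
#'
#' @param mat dense normalized cell x gene matrix (from [preprocess()]).
#' @param sample_ids per-cell sample identifiers (needed when
#'   `batch_correct = TRUE`).
#' @param n_components number of components to retain.
#' @param batch_correct subtract per-sample score means component-wise.
#' @return object of class `pca_result`: `scores`, `loadings`,
#'   `explained_variance_ratio`, `genes`, `center`, `batch_correct`.
#' @export
fit_pooled_pca <- function(mat, sample_ids = NULL, n_components = 10,
                           batch_correct = FALSE) {
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  if (n_components > min(dim(mat)))
    stop("parameter error: n_components exceeds min(cells, genes)")
  center <- colMeans(mat)
  x <- sweep(mat, 2, center)
  sv <- svd(x, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  total_var <- sum(sv$d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(d, n_components)
  # sign convention: largest-magnitude loading entry positive per component
  for (k in seq_len(n_components)) {
    s <- sign(loadings[which.max(abs(loadings[, k])), k])
    if (s < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(loadings) <- colnames(mat)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- rownames(mat)
  if (batch_correct) {
    if (is.null(sample_ids)) stop("sample_ids required for batch correction")
    for (s in unique(sample_ids)) {
      ix <- sample_ids == s
      scores[ix, ] <- sweep(scores[ix, , drop = FALSE], 2,
                            colMeans(scores[ix, , drop = FALSE]))
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = d^2 / total_var,
                 genes = colnames(mat), center = center,
                 batch_correct = batch_correct),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d cells x %d genes, %d components%s\n",
              nrow(x$scores), length(x$genes), ncol(x$scores),
              if (x$batch_correct) " (per-sample centered)" else ""))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio[1:min(3, ncol(x$scores))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Fit a 95% confidence ellipse from a bivariate t-distribution
#'
#' Fits the location and scale of a bivariate t-distribution with fixed
#' degrees of freedom to 2-D embedding scores by EM (iteratively reweighted
#' moments), then defines the confidence ellipse boundary
#' \{x : (x - mu)' Sigma^{-1} (x - mu) = r^2\} at the requested coverage.
#' Because the squared Mahalanobis distance of a bivariate t with `df`
#' degrees of freedom satisfies d/2 ~ F(2, df), the boundary radius is
#' r^2 = 2 F^{-1}(level; 2, df), which calibrates coverage exactly under
#' the fitted model.
#'
#' @param points n x 2 matrix of embedding coordinates (n >= 3,
#'   non-collinear).
#' @param level nominal coverage in (0, 1); default 0.95.
#' @param df t degrees of freedom (default 4; heavier-than-normal tails).
#' @param max_iter,tol EM controls.
#' @return object of class `ellipse_fit`: `center`, `scatter` (2x2 scale
#'   matrix), `df`, `level`, `radius2`.
#' @export
fit_t_ellipse <- function(points, level = 0.95, df = 4,
                          max_iter = 200, tol = 1e-9) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, level > 0, level < 1, df > 0)
  n <- nrow(points)
  if (n < 3) stop("fit error: need at least 3 points")
  mu <- colMeans(points)
  sigma <- stats::cov(points) * (n - 1) / n
  if (abs(det(sigma)) < 1e-12 * max(diag(sigma), 1)^2)
    stop("fit error: points are (near) collinear")
  for (it in seq_len(max_iter)) {
    d <- stats::mahalanobis(points, mu, sigma)
    w <- (df + 2) / (df + d)
    mu_new <- colSums(points * w) / sum(w)
    xc <- sweep(points, 2, mu_new)
    sigma_new <- crossprod(xc * w, xc) / n
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) break
  }
  if (abs(det(sigma)) < 1e-15) stop("fit error: degenerate scatter")
  structure(list(center = mu, scatter = sigma, df = df, level = level,
                 radius2 = 2 * stats::qf(level, 2, df)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> level %.2f, df %g, center (%.3g, %.3g)\n",
              x$level, x$df, x$center[1], x$center[2]))
  invisible(x)
}

#' Test points for ellipse membership
#'
#' @param fit an [fit_t_ellipse()] result.
#' @param points n x 2 matrix.
#' @return logical vector; TRUE when the point lies inside or on the
#'   ellipse boundary.
#' @export
ellipse_contains <- function(fit, points) {
  stopifnot(inherits(fit, "ellipse_fit"))
  points <- as.matrix(points)
  stats::mahalanobis(points, fit$center, fit$scatter) <= fit$radius2
}

#' Boundary polygon of a fitted ellipse
#'
#' @param fit an [fit_t_ellipse()] result.
#' @param n number of boundary vertices.
#' @return n x 2 matrix tracing the ellipse boundary.
#' @export
ellipse_boundary <- function(fit, n = 100) {
  th <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(th), sin(th)) * sqrt(fit$radius2)
  ch <- chol(fit$scatter)
  sweep(circ %*% ch, 2, fit$center, "+")
}

#' Sample from a fitted bivariate t-distribution
#'
#' @param fit an [fit_t_ellipse()] result.
#' @param n number of draws.
#' @return n x 2 matrix of draws from the fitted t.
#' @export
sample_t_ellipse <- function(fit, n) {
  z <- matrix(stats::rnorm(2 * n), ncol = 2) %*% chol(fit$scatter)
  u <- sqrt(fit$df / stats::rchisq(n, fit$df))
  sweep(z * u, 2, fit$center, "+")
}
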