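#' Choose the low-rank dimension from singular-value spacings
#'
#' Selects the approximation rank for zero-preserving imputation from the
#' spacings of the singular-value spectrum: noise-level mean and standard
#' deviation are estimated from the last `n_noise_spacings` spacings, and k
#' is the largest index whose spacing exceeds mean + 6 sd. If no spacing
#' clears the threshold, k = 1 is returned with a warning that no signal
#' was detected.
#'
#' @param singular_values singular values in descending order.
#' @param n_noise_spacings number of trailing spacings treated as noise
#'   (default 20).
#' @return integer rank k.
#' @export
choose_rank <- function(singular_values, n_noise_spacings = 20) {
  s <- as.numeric(singular_values)
  if (length(s) < n_noise_spacings + 2)
    stop("parameter error: need at least n_noise_spacings + 2 singular values")
  d <- s[-length(s)] - s[-1]
  noise <- utils::tail(d, n_noise_spacings)
  thr <- mean(noise) + 6 * stats::sd(noise)
  above <- which(d > thr)
  if (!length(above)) {
    warning("no signal detected in singular-value spacings; using k = 1")
    return(1L)
  }
  as.integer(max(above))
}

#' Zero-preserving low-rank imputation (ALRA)
#'
#' Adaptively-thresholded low-rank approximation of a normalized expression
#' matrix. The matrix is approximated at rank k by truncated SVD; then, per
#' gene, reconstructed entries smaller than the magnitude of that gene's
#' most negative reconstructed value are set to zero (the zero-preservation
#' step, which exploits the symmetry of reconstruction error around zero),
#' and the surviving entries are rescaled per gene to match the mean and
#' standard deviation of the gene's original non-zero values. Genes that
#' were entirely zero stay entirely zero; original zeros whose
#' reconstruction clears the threshold are restored to positive values.
#'
#' @param mat normalized non-negative cell x gene matrix (dense or sparse).
#' @param k approximation rank; if `NULL`, chosen by [choose_rank()] from
#'   the spectrum of `mat`.
#' @param n_noise_spacings passed to [choose_rank()] when `k` is `NULL`.
#' @return object of class `imputation_result`: `imputed` (dense cell x
#'   gene matrix), `k`, `threshold` (per gene), `rescaled` (per-gene flag).
#' @export
alra <- function(mat, k = NULL, n_noise_spacings = 20) {
  x <- as.matrix(mat)
  if (any(x < 0)) stop("input matrix must be non-negative")
  maxk <- min(dim(x))
  sv <- svd(x)
  if (is.null(k)) k <- choose_rank(sv$d, n_noise_spacings)
  if (k < 1 || k > maxk) stop("parameter error: k outside [1, min(dim)]")
  recon <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  dimnames(recon) <- dimnames(x)
  n_genes <- ncol(x)
  threshold <- numeric(n_genes)
  rescaled <- logical(n_genes)
  out <- recon
  for (g in seq_len(n_genes)) {
    orig_nz <- x[, g][x[, g] > 0]
    if (!length(orig_nz)) {        # all-zero gene stays all-zero
      out[, g] <- 0
      next
    }
    thr <- abs(min(recon[, g], 0))
    threshold[g] <- thr
    col <- recon[, g]
    col[col < thr] <- 0
    nz <- col > 0
    if (any(nz)) {
      mu_o <- mean(orig_nz); sd_o <- stats::sd(orig_nz)
      mu_n <- mean(col[nz]); sd_n <- stats::sd(col[nz])
      if (!is.na(sd_o) && !is.na(sd_n) && sd_n > 1e-12 && sd_o > 1e-12) {
        col[nz] <- (col[nz] - mu_n) / sd_n * sd_o + mu_o
        rescaled[g] <- TRUE
      } else {
        col[nz] <- col[nz] - mu_n + mu_o
      }
      col[col < 0] <- 0
    }
    out[, g] <- col
  }
  structure(list(imputed = out, k = as.integer(k),
                 threshold = stats::setNames(threshold, colnames(x)),
                 rescaled = rescaled),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> rank %d; %.1f%% of entries non-zero\n",
              x$k, 100 * mean(x$imputed > 0)))
  invisible(x)
}
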