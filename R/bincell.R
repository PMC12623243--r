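#' Expand nuclear labels to nearby bins
#'
#' Grows nuclear seed labels outward on the bin lattice, assigning every
#' unlabeled bin within Euclidean distance `d_max` of a seed bin the label
#' of its nearest seed bin. This is the label-expansion step of bin-to-cell
#' reconstruction from 2 um binned HD spatial data. Ties in distance are
#' broken toward the smaller label id; bins that already carry a label are
#' never changed. The operation is idempotent for a fixed seed set: re-applying
#' it to its own output with `seed_mask` marking the original nuclei leaves
#' the result unchanged (by default every labeled bin counts as a seed, so
#' repeated application without the mask would keep growing).
#'
#' @param label_image integer matrix; positive labels on nuclear seeds,
#'   0 elsewhere.
#' @param d_max maximum expansion distance in bins (Euclidean, >= 0).
#' @param seed_mask optional logical matrix restricting which labeled bins
#'   act as expansion seeds (default: all labeled bins).
#' @return integer matrix of expanded labels.
#' @export
expand_labels <- function(label_image, d_max, seed_mask = NULL) {
  if (d_max < 0) stop("parameter error: d_max must be >= 0")
  stopifnot(is.matrix(label_image))
  out <- label_image
  if (d_max == 0) return(out)
  seed_img <- label_image
  if (!is.null(seed_mask)) seed_img[!seed_mask] <- 0L
  seeds <- which(seed_img > 0, arr.ind = TRUE)
  if (nrow(seeds) == 0) return(out)
  r <- floor(d_max)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off$d2 <- off$dr^2 + off$dc^2
  off <- off[off$d2 <= d_max^2 & off$d2 > 0, ]
  if (nrow(off) == 0) return(out)
  R <- nrow(out); C <- ncol(out)
  labs <- seed_img[seeds]
  # candidate assignments: every (seed, offset) pair, resolved per target bin
  n_s <- nrow(seeds); n_o <- nrow(off)
  tr <- rep(seeds[, 1], times = n_o) + rep(off$dr, each = n_s)
  tc <- rep(seeds[, 2], times = n_o) + rep(off$dc, each = n_s)
  d2 <- rep(off$d2, each = n_s)
  lab <- rep(labs, times = n_o)
  ok <- tr >= 1 & tr <= R & tc >= 1 & tc <= C
  tr <- tr[ok]; tc <- tc[ok]; d2 <- d2[ok]; lab <- lab[ok]
  tgt <- (tc - 1L) * R + tr
  free <- label_image[tgt] == 0
  tgt <- tgt[free]; d2 <- d2[free]; lab <- lab[free]
  if (!length(tgt)) return(out)
  # keep, per target bin, the nearest seed; ties toward the smaller label
  o <- order(tgt, d2, lab)
  keep <- o[!duplicated(tgt[o])]
  out[tgt[keep]] <- lab[keep]
  out
}

#' Aggregate bin counts into cells
#'
#' Sums the counts of every bin sharing a cell label into one cell profile
#' and records the cell centroid as the unweighted mean of its occupied bin
#' coordinates. Bins with label 0 are discarded, so total UMIs over labeled
#' bins are conserved exactly.
#'
#' @param grid a [bin_grid()].
#' @param labels integer label matrix aligned to the grid's coordinate frame.
#' @param sample_id sample identifier attached to the resulting cells.
#' @return a [cell_matrix()] with one row per distinct positive label
#'   present under occupied bins; rownames are the label ids.
#' @export
aggregate_bins <- function(grid, labels, sample_id = "sample1") {
  stopifnot(inherits(grid, "bin_grid"), is.matrix(labels))
  lab <- labels[grid$coords]
  keep <- lab > 0
  if (!any(keep)) {
    warning("no labeled bins: returning empty cell matrix")
    return(cell_matrix(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0),
                                            dims = c(0, ncol(grid$counts)),
                                            dimnames = list(NULL, grid$gene_ids)),
                       sample_id = character(0)))
  }
  lab <- lab[keep]
  counts <- grid$counts[keep, , drop = FALSE]
  coords <- grid$coords[keep, , drop = FALSE]
  ids <- sort(unique(lab))
  f <- match(lab, ids)
  ind <- Matrix::sparseMatrix(i = f, j = seq_along(f), x = 1,
                              dims = c(length(ids), length(f)))
  agg <- ind %*% counts
  rownames(agg) <- as.character(ids)
  centroids <- cbind(
    row = as.numeric(ind %*% coords[, 1]) / as.numeric(Matrix::rowSums(ind)),
    col = as.numeric(ind %*% coords[, 2]) / as.numeric(Matrix::rowSums(ind)))
  cell_matrix(agg, centroids = centroids, sample_id = sample_id)
}

#' Quality-control filter on reconstructed cells
#'
#' Retains cells by detected-gene and UMI thresholds, preserving order, and
#' reports the per-sample median depth so under-sequenced samples can be
#' recognized and dropped by configuration.
#'
#' @param cells a [cell_matrix()].
#' @param min_genes minimum detected genes per cell.
#' @param min_umis,max_umis inclusive UMI bounds per cell.
#' @param verbose print the filter report.
#' @return the filtered [cell_matrix()]; attribute `qc_report` holds a
#'   data frame of per-sample medians and retention.
#' @export
qc_filter <- function(cells, min_genes = 20, min_umis = 50, max_umis = Inf,
                      verbose = FALSE) {
  stopifnot(min_genes >= 0, min_umis >= 0, max_umis >= 0)
  if (min_umis > max_umis) stop("parameter error: min_umis > max_umis")
  keep <- cells$n_genes >= min_genes & cells$n_umis >= min_umis &
    cells$n_umis <= max_umis
  rep_df <- do.call(rbind, lapply(split(seq_along(keep), cells$sample_id),
    function(ix) data.frame(
      sample_id = cells$sample_id[ix[1]],
      n_cells = length(ix), n_kept = sum(keep[ix]),
      median_genes = stats::median(cells$n_genes[ix]),
      median_umis = stats::median(cells$n_umis[ix]))))
  if (verbose && !is.null(rep_df)) {
    message("qc_filter report:")
    for (i in seq_len(nrow(rep_df)))
      message(sprintf("  %s: kept %d/%d (median %g genes, %g UMIs)",
                      rep_df$sample_id[i], rep_df$n_kept[i], rep_df$n_cells[i],
                      rep_df$median_genes[i], rep_df$median_umis[i]))
  }
  if (!any(keep)) warning("qc_filter removed every cell")
  out <- subset_cells(cells, which(keep))
  attr(out, "qc_report") <- rep_df
  out
}
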