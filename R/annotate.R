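## Region assignment and rank-sum machinery for the histomorphological
## selection emulation: cells are attributed to annotated tissue compartments
## by centroid containment, marker-negative cells are excluded, and per-gene
## comparisons between compartments use the Mann-Whitney/Wilcoxon rank-sum
## test (unadjusted, as for the spot-level tumor-vs-epidermis comparisons).

# even-odd (ray casting) point-in-polygon; boundary points count as inside
point_in_polygon <- function(pr, pc, poly, eps = 1e-9) {
  vr <- poly[, 1]; vc <- poly[, 2]
  n <- nrow(poly)
  jj <- c(n, seq_len(n - 1))
  # boundary check: point on any edge segment
  for (k in seq_len(n)) {
    ar <- vr[jj[k]]; ac <- vc[jj[k]]; br <- vr[k]; bc <- vc[k]
    cross <- (br - ar) * (pc - ac) - (bc - ac) * (pr - ar)
    if (abs(cross) <= eps * (abs(br - ar) + abs(bc - ac) + 1)) {
      dot <- (pr - ar) * (br - ar) + (pc - ac) * (bc - ac)
      len2 <- (br - ar)^2 + (bc - ac)^2
      if (dot >= -eps && dot <= len2 + eps) return(TRUE)
    }
  }
  inside <- FALSE
  for (k in seq_len(n)) {
    ar <- vr[jj[k]]; ac <- vc[jj[k]]; br <- vr[k]; bc <- vc[k]
    if ((ac > pc) != (bc > pc)) {
      xint <- ar + (pc - ac) / (bc - ac) * (br - ar)
      if (pr < xint) inside <- !inside
    }
  }
  inside
}

polygon_area <- function(poly) {
  r <- poly[, 1]; c <- poly[, 2]
  n <- length(r)
  j <- c(n, seq_len(n - 1))
  abs(sum(r[j] * c - r * c[j])) / 2
}

#' Assign cells to annotated regions
#'
#' Gives each cell the class of the annotated polygon containing its
#' centroid. Boundary points count as inside; a centroid falling inside
#' several polygons takes the class of the smallest-area polygon (so nested
#' annotations resolve to the most specific compartment); centroids outside
#' every polygon are left unassigned (`NA`).
#'
#' @param cells a [cell_matrix()] with centroids.
#' @param regions a [region_annotation()].
#' @return character vector of region classes per cell (`NA` = unassigned).
#' @export
assign_regions <- function(cells, regions) {
  stopifnot(inherits(cells, "cell_matrix"), inherits(regions, "region_annotation"))
  if (is.null(cells$centroids)) stop("cells carry no centroids")
  polys <- regions$polygons
  areas <- vapply(polys, function(p) polygon_area(as.matrix(p$coords)), numeric(1))
  n <- nrow(cells$centroids)
  out <- rep(NA_character_, n)
  best_area <- rep(Inf, n)
  for (k in seq_along(polys)) {
    poly <- as.matrix(polys[[k]]$coords)
    for (i in seq_len(n)) {
      if (areas[k] < best_area[i] &&
          point_in_polygon(cells$centroids[i, 1], cells$centroids[i, 2], poly)) {
        out[i] <- polys[[k]]$class
        best_area[i] <- areas[k]
      }
    }
  }
  out
}

#' Keep cells positive for a marker gene
#'
#' Retains cells with a raw count above zero for the given marker; used to
#' exclude non-tumor cells (e.g. keratinocytes) from region-selected sets by
#' requiring the MCC marker CCER2. Zero/non-zero is decided on raw counts,
#' which is invariant to normalization.
#'
#' @param cells a [cell_matrix()].
#' @param marker gene id present in the gene universe.
#' @param verbose print the retained fraction.
#' @return the filtered [cell_matrix()].
#' @export
select_marker_positive <- function(cells, marker, verbose = FALSE) {
  if (!marker %in% colnames(cells$counts))
    stop("gene-not-found error: '", marker, "' absent from gene universe")
  pos <- as.numeric(cells$counts[, marker]) > 0
  if (verbose)
    message(sprintf("select_marker_positive(%s): retained %d/%d (%.1f%%)",
                    marker, sum(pos), length(pos), 100 * mean(pos)))
  if (!any(pos)) warning("no cell is positive for ", marker)
  subset_cells(cells, which(pos))
}

#' Mann-Whitney/Wilcoxon rank-sum comparison
#'
#' Two-sample rank-sum test with tie correction. The exact null distribution
#' is used when the combined sample size is at most 25 and the pooled data
#' carry no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used. P values are unadjusted. If
#' every pooled value is tied the data carry no ordering information and
#' p = 1 is returned.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param alternative "two.sided" (default), "greater" (a tends larger) or
#'   "less".
#' @return list with `statistic` (the Mann-Whitney U of group_a) and
#'   `p.value`.
#' @export
rank_sum_compare <- function(group_a, group_b,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(group_a) || !length(group_b))
    stop("statistical error: both groups must be non-empty")
  m <- length(group_a); n <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (all(pooled == pooled[1])) {
    return(list(statistic = u, p.value = 1))
  }
  if (!has_ties && (m + n) <= 25) {
    p_less <- stats::pwilcox(u, m, n)
    p_greater <- stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_less, p_greater)),
                greater = p_greater,
                less = p_less)
  } else {
    N <- m + n
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    sigma <- sqrt(sigma2)
    z_g <- (u - mu - 0.5) / sigma
    z_l <- (u - mu + 0.5) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two.sided = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                           stats::pnorm(z_l))))
  }
  list(statistic = u, p.value = p)
}

#' Per-gene rank-sum comparison between two region selections
#'
#' Convenience wrapper comparing each listed gene between two groups of
#' cells (e.g. CCER2-positive cells from epidermal versus dermal tumor
#' regions) on normalized expression, with unadjusted p values.
#'
#' @param mat_a,mat_b cell x gene matrices (same gene universe).
#' @param genes genes to test (default: all shared genes).
#' @return data frame with gene, U statistic, p, and group means.
#' @export
region_gene_compare <- function(mat_a, mat_b, genes = NULL) {
  genes <- genes %||% intersect(colnames(mat_a), colnames(mat_b))
  res <- lapply(genes, function(g) {
    ts <- rank_sum_compare(as.numeric(mat_a[, g]), as.numeric(mat_b[, g]))
    data.frame(gene = g, statistic = ts$statistic, p.value = ts$p.value,
               mean_a = mean(mat_a[, g]), mean_b = mean(mat_b[, g]))
  })
  do.call(rbind, res)
}
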