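#' AUCell-style per-cell gene-set activity
#'
#' Scores one gene set per cell as the normalized area under the gene-set
#' recovery curve over the top fraction of that cell's expression-ranked
#' genes. Per cell, genes are ranked by expression in descending order with
#' ties broken by a seeded random shuffle; with T = ceiling(top_fraction x
#' N) and hits(x) the number of set genes at rank <= x, the raw AUC is
#' sum_{x=1..T} hits(x), normalized by its maximum sum_{x=1..T} min(x, |S|)
#' so the score lies in [0, 1]. The score depends only on ranks, so it is
#' invariant to any strictly monotone transform of a cell's expression.
#'
#' @param cells a [cell_matrix()] or cell x gene expression matrix.
#' @param gene_set character vector of gene ids.
#' @param top_fraction fraction of the ranking scanned (default 0.05).
#' @param seed seed for the tie-breaking shuffle.
#' @return numeric vector of per-cell scores in [0, 1].
#' @export
aucell <- function(cells, gene_set, top_fraction = 0.05, seed = 1) {
  mat <- if (inherits(cells, "cell_matrix")) cells$counts else cells
  stopifnot(top_fraction > 0, top_fraction < 1)
  genes <- colnames(mat)
  set_idx <- which(genes %in% unique(gene_set))
  if (!length(set_idx))
    stop("coverage error: gene set does not overlap the expression universe")
  N <- ncol(mat)
  T_top <- ceiling(top_fraction * N)
  S <- length(set_idx)
  max_auc <- sum(pmin(seq_len(T_top), S))
  dense <- as.matrix(mat)
  n <- nrow(dense)
  scores <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      rk <- rank(-dense[i, ], ties.method = "random")
      r_set <- rk[set_idx]
      inside <- r_set[r_set <= T_top]
      scores[i] <- sum(T_top - inside + 1) / max_auc
    }
  })
  names(scores) <- rownames(mat)
  scores
}

#' Activity matrix over a gene-set collection
#'
#' Runs [aucell()] for every set of a collection (metaprograms or regulons).
#' For signed regulons only the positive (activated) targets are scored.
#'
#' @param cells a [cell_matrix()] or cell x gene matrix.
#' @param collection a [gene_set_collection()].
#' @param top_fraction,seed passed to [aucell()].
#' @return cell x set matrix of AUC scores in [0, 1].
#' @export
aucell_collection <- function(cells, collection, top_fraction = 0.05, seed = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  cols <- lapply(names(collection$sets), function(nm) {
    genes <- collection$sets[[nm]]
    if (!is.null(collection$signs))
      genes <- genes[collection$signs[[nm]] > 0]
    aucell(cells, genes, top_fraction = top_fraction, seed = seed)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(collection$sets)
  out
}

# Jensen-Shannon divergence between two probability vectors, base-2 logs
jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity scores
#'
#' For each regulon (activity column) and cell class, the specificity score
#' RSS = 1 - sqrt(JSD(P, Q)), where P is the activity column normalized to
#' sum to one over cells, Q is the class-indicator distribution, and JSD is
#' the Jensen-Shannon divergence in base-2 logs (so JSD and RSS lie in
#' [0, 1]). RSS = 1 when activity is uniform over exactly the class's cells
#' and 0 when activity is supported entirely outside the class.
#'
#' @param activity cell x regulon matrix of non-negative activities.
#' @param labels class label per cell.
#' @return object of class `rss_table`: `rss` (regulon x class matrix;
#'   regulons with all-zero activity are `NA`) and `ranking` (per class,
#'   regulons ordered by decreasing RSS).
#' @export
regulon_specificity <- function(activity, labels) {
  activity <- as.matrix(activity)
  if (any(activity < 0)) stop("activity must be non-negative")
  stopifnot(nrow(activity) == length(labels))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("need at least 2 classes")
  rss <- matrix(NA_real_, nrow = ncol(activity), ncol = length(classes),
                dimnames = list(colnames(activity), classes))
  for (r in seq_len(ncol(activity))) {
    a <- activity[, r]
    tot <- sum(a)
    if (tot == 0) next                      # undefined: reported missing
    p <- a / tot
    for (ci in seq_along(classes)) {
      q <- as.numeric(labels == classes[ci])
      q <- q / sum(q)
      rss[r, ci] <- 1 - sqrt(jsd(p, q))
    }
  }
  ranking <- lapply(stats::setNames(classes, classes), function(cl) {
    v <- rss[, cl]
    names(sort(v[!is.na(v)], decreasing = TRUE))
  })
  structure(list(rss = rss, ranking = ranking), class = "rss_table")
}

#' @export
print.rss_table <- function(x, ...) {
  cat("<rss_table>", nrow(x$rss), "regulons x", ncol(x$rss), "classes\n")
  invisible(x)
}

#' Regulons with enhanced activity in one class
#'
#' Declares a regulon "enhanced" in a target class when (i) its specificity
#' score in that class exceeds its score in every other class and (ii) its
#' mean activity in the class differs from the rest of the cells with a
#' rank-sum p below `alpha`.
#'
#' @param activity cell x regulon activity matrix.
#' @param labels class label per cell.
#' @param target class of interest (e.g. "epiMCC").
#' @param alpha rank-sum significance cutoff (default 0.05).
#' @return character vector of enhanced regulon names.
#' @export
enhanced_regulons <- function(activity, labels, target, alpha = 0.05) {
  rt <- regulon_specificity(activity, labels)
  rss <- rt$rss
  others <- setdiff(colnames(rss), target)
  out <- character(0)
  for (r in rownames(rss)) {
    if (is.na(rss[r, target])) next
    if (all(rss[r, target] > rss[r, others], na.rm = TRUE)) {
      in_cl <- labels == target
      ts <- rank_sum_compare(activity[in_cl, r], activity[!in_cl, r],
                             alternative = "greater")
      if (ts$p.value < alpha) out <- c(out, r)
    }
  }
  out
}
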