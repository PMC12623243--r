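#' Rank-based enrichment of a marker panel among PC loadings
#'
#' Tests whether the members of a marker panel (e.g. cSCC marker genes)
#' concentrate among the top-ranked loadings of one principal component.
#' Genes are ranked by loading value in descending order and the marker
#' loadings are compared against the non-marker loadings with a one-sided
#' Mann-Whitney rank-sum test ("greater": markers load higher). Marker
#' ranks are returned for the ranked-loading display.
#'
#' @param loadings named numeric vector: one PC's loading per gene.
#' @param markers character vector of marker gene ids.
#' @param alternative "greater" (default), "less" or "two.sided".
#' @return list with `statistic` (Mann-Whitney U of the markers), `p.value`,
#'   `marker_ranks` (named, rank 1 = highest loading), `n_markers_used`.
#' @export
loading_rank_test <- function(loadings, markers,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(!is.null(names(loadings)))
  markers <- unique(markers)
  present <- intersect(markers, names(loadings))
  if (!length(present))
    stop("coverage error: no marker overlaps the loading universe")
  if (length(present) == length(loadings))
    stop("degenerate-input error: markers equal the whole universe")
  is_marker <- names(loadings) %in% present
  ts <- rank_sum_compare(loadings[is_marker], loadings[!is_marker],
                         alternative = alternative)
  rk <- rank(-loadings, ties.method = "average")
  list(statistic = ts$statistic, p.value = ts$p.value,
       marker_ranks = stats::setNames(rk[is_marker], names(loadings)[is_marker]),
       n_markers_used = length(present))
}

#' Over-representation (hypergeometric) test
#'
#' Upper-tail hypergeometric probability that a drawn gene list (e.g.
#' upregulated genes) overlaps a gene set at least as much as observed:
#' p = P(X >= overlap) with X ~ Hypergeometric(universe, set, drawn).
#'
#' @param overlap observed overlap between the drawn list and the set.
#' @param universe gene universe size.
#' @param set_size gene-set size.
#' @param n_drawn drawn list size.
#' @return upper-tail p value.
#' @export
ora_test <- function(overlap, universe, set_size, n_drawn) {
  stopifnot(length(overlap) == 1, length(universe) == 1)
  if (set_size > universe || n_drawn > universe)
    stop("parameter error: set or drawn list larger than universe")
  if (overlap > min(set_size, n_drawn))
    stop("parameter error: overlap exceeds min(set size, drawn)")
  if (overlap < max(0, set_size + n_drawn - universe))
    stop("parameter error: overlap below the attainable minimum")
  stats::phyper(overlap - 1, set_size, universe - set_size, n_drawn,
                lower.tail = FALSE)
}

#' Over-representation across a gene-set collection
#'
#' Applies [ora_test()] to each set of a collection against a drawn gene
#' list, with Benjamini-Hochberg adjustment across sets.
#'
#' @param drawn character vector of drawn genes (e.g. significant DGE hits).
#' @param collection a [gene_set_collection()].
#' @param universe character vector: the full gene universe.
#' @return data frame with set, set size, overlap, p, BH-adjusted p and the
#'   overlapping genes (comma-separated), ordered by p.
#' @export
ora_collection <- function(drawn, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  drawn <- intersect(unique(drawn), universe)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    ov <- intersect(set, drawn)
    p <- if (length(set)) ora_test(length(ov), length(universe),
                                   length(set), length(drawn)) else NA_real_
    data.frame(set = nm, set_size = length(set), overlap = length(ov),
               p.value = p, genes = paste(ov, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$p.adj <- stats::p.adjust(out$p.value, method = "BH")
  out[order(out$p.value), c("set", "set_size", "overlap", "p.value", "p.adj", "genes")]
}
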