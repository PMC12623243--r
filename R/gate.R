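#' Default MCC subtype gating rules
#'
#' The boolean marker rules defining the three MCC subpopulations in
#' single-cell data, evaluated on raw counts (non-zero means count > 0):
#' \itemize{
#'   \item epiMCC: non-zero CCER2 and KRT5, plus CALML3 or CALML5;
#'   \item vasMCC: non-zero CCER2 and KRT20, plus COL3A1 or COL1A1;
#'   \item cMCC: co-expression of CCER2 and KRT20 with no detectable
#'     COL3A1, COL1A1 or KRT5.
#' }
#' Rules are tested in the order epiMCC, vasMCC, cMCC; the first match
#' assigns the class. The epiMCC and cMCC rules are disjoint by
#' construction (cMCC requires KRT5 == 0); the precedence resolves the
#' epi/vas overlap in favour of the rarer, more specific epidermal call.
#'
#' @return ordered list of `(class, expr)` rules.
#' @export
default_gating_rules <- function() {
  list(
    list(class = "epiMCC",
         expr = "CCER2 > 0 & KRT5 > 0 & (CALML3 > 0 | CALML5 > 0)"),
    list(class = "vasMCC",
         expr = "CCER2 > 0 & KRT20 > 0 & (COL3A1 > 0 | COL1A1 > 0)"),
    list(class = "cMCC",
         expr = "CCER2 > 0 & KRT20 > 0 & COL3A1 == 0 & COL1A1 == 0 & KRT5 == 0")
  )
}

#' Apply boolean gating rules to cells
#'
#' Evaluates each rule's boolean expression over the raw count columns of
#' the cells (atoms of the form `gene > 0` / `gene == 0`), in precedence
#' order; the first matching rule assigns the class and unmatched cells are
#' left unlabeled (`NA`). Gating is deterministic and invariant to cell
#' order.
#'
#' @param cells a [cell_matrix()] or cell x gene count matrix.
#' @param rules ordered rule list as from [default_gating_rules()].
#' @param verbose print per-class counts.
#' @return character vector of class labels per cell (`NA` = unlabeled).
#' @export
apply_gates <- function(cells, rules = default_gating_rules(), verbose = FALSE) {
  mat <- if (inherits(cells, "cell_matrix")) cells$counts else cells
  genes <- colnames(mat)
  need <- unique(unlist(lapply(rules, function(r) all.vars(str2lang(r$expr)))))
  missing <- setdiff(need, genes)
  if (length(missing))
    stop("config error: rule references missing gene(s): ",
         paste(missing, collapse = ", "))
  env <- new.env(parent = baseenv())
  for (g in need) assign(g, as.numeric(mat[, g]), envir = env)
  out <- rep(NA_character_, nrow(mat))
  for (r in rules) {
    hit <- eval(str2lang(r$expr), envir = env)
    out[is.na(out) & hit] <- r$class
  }
  if (verbose) {
    tab <- table(factor(out, levels = vapply(rules, `[[`, "", "class")),
                 useNA = "ifany")
    message("apply_gates: ", paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  out
}

#' Balanced subsampling across gated classes
#'
#' Downsamples every class without replacement to the size of the smallest
#' class so that no subtype dominates downstream embeddings or tests;
#' unlabeled cells are dropped. Reproducible under a fixed seed.
#'
#' @param labels class label per cell (`NA` = unlabeled).
#' @param seed integer seed.
#' @return sorted integer vector of retained cell indices.
#' @export
balanced_subsample <- function(labels, seed = 1) {
  lab <- as.character(labels)
  keep <- !is.na(lab)
  if (!any(keep)) stop("empty labeling: nothing to subsample")
  sizes <- table(lab[keep])
  n_min <- min(sizes)
  with_seed(seed, {
    idx <- unlist(lapply(names(sizes), function(cl) {
      ix <- which(keep & lab == cl)
      if (length(ix) > n_min) sort(sample(ix, n_min)) else ix
    }))
  })
  sort(idx)
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene rank-sum comparison of normalized expression between two gated
#' groups, with Benjamini-Hochberg adjustment across genes and a log2 fold
#' change of group means stabilized by a small pseudocount. The table can
#' then be filtered by significance and ranked by fold change.
#'
#' @param mat normalized cell x gene matrix.
#' @param labels class label per cell.
#' @param group_a,group_b class names to compare (log2FC > 0 means higher
#'   in `group_a`).
#' @param pseudocount added to both means before the ratio (default 1e-9).
#' @return data frame of class `dge_table`: gene, log2 fold change, U
#'   statistic, p, BH-adjusted p, direction ("up" = higher in group_a).
#' @export
wilcoxon_dge <- function(mat, labels, group_a, group_b, pseudocount = 1e-9) {
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("degenerate groups: need at least 2 cells per group")
  mat <- as.matrix(mat)
  res <- data.frame(gene = colnames(mat),
                    log2fc = NA_real_, statistic = NA_real_,
                    p.value = NA_real_)
  for (g in seq_len(ncol(mat))) {
    a <- mat[ia, g]; b <- mat[ib, g]
    ts <- rank_sum_compare(a, b)
    res$statistic[g] <- ts$statistic
    res$p.value[g] <- ts$p.value
    res$log2fc[g] <- log2((mean(a) + pseudocount) / (mean(b) + pseudocount))
  }
  res$p.adj <- stats::p.adjust(res$p.value, method = "BH")
  res$direction <- ifelse(res$log2fc > 0, "up", ifelse(res$log2fc < 0, "down", "flat"))
  class(res) <- c("dge_table", "data.frame")
  res
}

#' Significant genes of a DGE table, ranked by fold change
#'
#' @param dge a [wilcoxon_dge()] table.
#' @param alpha significance cutoff (default 0.05).
#' @param adjusted filter on BH-adjusted p (default) or raw p.
#' @param direction "up", "down" or "both".
#' @return the filtered table ordered by decreasing |log2FC|.
#' @export
top_dge <- function(dge, alpha = 0.05, adjusted = TRUE, direction = "both") {
  p <- if (adjusted) dge$p.adj else dge$p.value
  keep <- p < alpha
  if (direction != "both") keep <- keep & dge$direction == direction
  out <- dge[keep, , drop = FALSE]
  out[order(-abs(out$log2fc)), , drop = FALSE]
}

#' Intersect upregulated genes with enhanced-regulon targets
#'
#' Returns the genes that are both upregulated (input list) and targets of
#' at least one enhanced transcription-factor regulon, recording which
#' regulon(s) cover each gene.
#'
#' @param upregulated character vector of upregulated gene ids.
#' @param enhanced_regulons a [gene_set_collection()] restricted to the
#'   enhanced regulons.
#' @return character vector of intersected genes; attribute `provenance`
#'   is a named list mapping each gene to its covering regulons.
#' @export
tf_target_intersect <- function(upregulated, enhanced_regulons) {
  if (is.null(enhanced_regulons) || !length(enhanced_regulons$sets)) {
    out <- character(0)
    attr(out, "provenance") <- list()
    return(out)
  }
  stopifnot(inherits(enhanced_regulons, "gene_set_collection"))
  targets <- unique(unlist(enhanced_regulons$sets))
  out <- intersect(unique(upregulated), targets)
  prov <- lapply(stats::setNames(out, out), function(g)
    names(Filter(function(s) g %in% s, enhanced_regulons$sets)))
  attr(out, "provenance") <- prov
  out
}
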