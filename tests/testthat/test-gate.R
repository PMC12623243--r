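gating_toy <- function() {
  genes <- c("CCER2", "KRT5", "KRT20", "CALML3", "CALML5", "COL1A1", "COL3A1")
  counts <- rbind(
    c(2, 1, 0, 1, 0, 0, 0),   # epiMCC
    c(1, 0, 3, 0, 0, 2, 0),   # vasMCC
    c(1, 0, 2, 0, 0, 0, 0),   # cMCC
    c(0, 9, 0, 0, 0, 0, 0),   # CCER2-negative: unlabeled
    c(0, 0, 0, 0, 0, 0, 0)    # all-zero: unlabeled
  )
  colnames(counts) <- genes
  toy_cells(counts)
}

test_that("apply_gates evaluates the subtype rules with precedence", {
  got <- apply_gates(gating_toy())
  expect_equal(got, c("epiMCC", "vasMCC", "cMCC", NA, NA))
  # a cell satisfying both the epi and vas written rules takes epiMCC
  both <- toy_cells(rbind(c(1, 1, 1, 1, 0, 1, 0)),
                    genes = colnames(gating_toy()$counts))
  expect_equal(apply_gates(both), "epiMCC")
  expect_error(apply_gates(gating_toy()$counts[, 1:3]), "config error")
})

test_that("gating is deterministic and order-invariant", {
  cells <- gating_toy()
  perm <- c(3, 5, 1, 4, 2)
  expect_equal(apply_gates(subset_cells(cells, perm)),
               apply_gates(cells)[perm])
})

test_that("gated classes are mutually exclusive by rule construction", {
  # cMCC requires KRT5 == 0, epiMCC requires KRT5 > 0: provably disjoint
  set.seed(19)
  genes <- colnames(gating_toy()$counts)
  counts <- matrix(stats::rpois(500 * 7, 0.7), 500, 7,
                   dimnames = list(NULL, genes))
  lab <- apply_gates(toy_cells(counts))
  epi_rule <- counts[, "CCER2"] > 0 & counts[, "KRT5"] > 0 &
    (counts[, "CALML3"] > 0 | counts[, "CALML5"] > 0)
  c_rule <- counts[, "CCER2"] > 0 & counts[, "KRT20"] > 0 &
    counts[, "COL3A1"] == 0 & counts[, "COL1A1"] == 0 & counts[, "KRT5"] == 0
  expect_false(any(epi_rule & c_rule))
  expect_true(all(lab[epi_rule] == "epiMCC"))
})

test_that("balanced_subsample downsamples every class to the minimum size", {
  labels <- c(rep("a", 10), rep("b", 4), rep("c", 7), NA, NA)
  idx <- balanced_subsample(labels, seed = 3)
  expect_equal(as.integer(table(labels[idx])), rep(4L, 3))
  expect_true(all(!is.na(labels[idx])))
  # equal sizes: identity up to order
  eq <- rep(c("a", "b", "c"), each = 5)
  expect_equal(balanced_subsample(eq, seed = 1), 1:15)
  # determinism under the seed
  expect_identical(balanced_subsample(labels, seed = 9),
                   balanced_subsample(labels, seed = 9))
  expect_error(balanced_subsample(c(NA, NA)), "empty labeling")
})

test_that("wilcoxon_dge flags planted shifts and stays flat on identical groups", {
  set.seed(20)
  mat <- matrix(stats::rnorm(40 * 30), 40, 30,
                dimnames = list(NULL, paste0("g", 1:30)))
  labels <- rep(c("x", "y"), each = 20)
  mat[labels == "x", "g7"] <- mat[labels == "x", "g7"] + 50
  dge <- wilcoxon_dge(exp(mat), labels, "x", "y")
  expect_equal(dge$gene[which.min(dge$p.value)], "g7")
  expect_gt(dge$log2fc[dge$gene == "g7"], 0)
  expect_true(all(dge$p.adj >= dge$p.value - 1e-12))
  # identical groups: p = 1, log2FC = 0 everywhere
  same <- rbind(mat[1:5, ], mat[1:5, ])
  dge2 <- wilcoxon_dge(same, rep(c("x", "y"), each = 5), "x", "y")
  expect_true(all(dge2$p.value == 1))
  expect_true(all(dge2$log2fc == 0))
  expect_error(wilcoxon_dge(mat, labels, "x", "zz"), "degenerate")
})

test_that("wilcoxon_dge p values match exhaustive permutation enumeration", {
  set.seed(22)
  for (rep in 1:5) {
    a <- stats::rlnorm(4); b <- stats::rlnorm(4) * 2
    mat <- matrix(c(a, b), ncol = 1, dimnames = list(NULL, "g"))
    dge <- wilcoxon_dge(mat, rep(c("x", "y"), each = 4), "x", "y")
    expect_equal(dge$p.value, oracle_ranksum_p(a, b))
  }
})

test_that("top_dge filters by significance and ranks by fold change", {
  dge <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(2, -3, 0.5, 1),
                    statistic = 1:4,
                    p.value = c(0.001, 0.002, 0.3, 0.01))
  dge$p.adj <- stats::p.adjust(dge$p.value, "BH")
  dge$direction <- ifelse(dge$log2fc > 0, "up", "down")
  class(dge) <- c("dge_table", "data.frame")
  out <- top_dge(dge, alpha = 0.05)
  expect_equal(out$gene, c("b", "a", "d"))
  expect_equal(top_dge(dge, alpha = 0.05, direction = "up")$gene, c("a", "d"))
})

test_that("tf_target_intersect returns covered genes with provenance", {
  regs <- gene_set_collection(list(TF1 = c("B", "C", "D"), TF2 = c("C", "E")))
  out <- tf_target_intersect(c("A", "B", "C"), regs)
  expect_setequal(out, c("B", "C"))
  prov <- attr(out, "provenance")
  expect_equal(prov$B, "TF1")
  expect_setequal(prov$C, c("TF1", "TF2"))
  empty <- tf_target_intersect(c("A", "B"), gene_set_collection(stats::setNames(list(), character(0))))
  expect_length(empty, 0)
})
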