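square <- function(cls, r0, r1, c0, c1, id = cls) {
  list(class = cls, id = id,
       coords = cbind(row = c(r0, r0, r1, r1), col = c(c0, c1, c1, c0)))
}

test_that("assign_regions: containment, boundary, nesting and unassigned", {
  regions <- region_annotation(list(
    square("tumor_core", 0, 10, 0, 10),
    square("perivascular", 2, 6, 2, 6)   # nested, smaller area wins
  ))
  cells <- toy_cells(matrix(1, 4, 1, dimnames = list(NULL, "g")),
                     centroids = rbind(c(8, 8), c(4, 4), c(20, 20), c(0, 5)))
  got <- assign_regions(cells, regions)
  expect_equal(got, c("tumor_core", "perivascular", NA, "tumor_core"))
  expect_error(region_annotation(list(list(class = "epidermis", id = "x",
                                           coords = rbind(c(0, 0), c(1, 1))))),
               "annotation error")
})

test_that("assign_regions matches the ray-casting oracle on random points", {
  set.seed(3)
  regions <- region_annotation(list(
    square("tumor_core", 1, 9, 1, 9),
    square("epidermis", 3, 7, 3, 7)
  ))
  pts <- cbind(stats::runif(100, 0, 11), stats::runif(100, 0, 11))
  cells <- toy_cells(matrix(1, 100, 1, dimnames = list(NULL, "g")),
                     centroids = pts)
  expect_equal(assign_regions(cells, regions),
               oracle_assign(pts, regions$polygons))
})

test_that("assign_regions is invariant to cell order", {
  set.seed(8)
  regions <- region_annotation(list(
    square("epidermis", 1, 30, 1, 100),
    square("follicle", 20, 60, 40, 70)
  ))
  pts <- cbind(stats::runif(50, 1, 80), stats::runif(50, 1, 100))
  cells <- toy_cells(matrix(1, 50, 1, dimnames = list(NULL, "g")),
                     centroids = pts)
  perm <- sample(50)
  got <- assign_regions(cells, regions)
  got_perm <- assign_regions(subset_cells(cells, perm), regions)
  expect_equal(got_perm, got[perm])
})

test_that("select_marker_positive keeps exactly the raw-count-positive cells", {
  counts <- cbind(CCER2 = c(0, 1, 2, 0), OTHER = c(5, 5, 5, 5))
  cells <- toy_cells(counts)
  kept <- select_marker_positive(cells, "CCER2")
  expect_equal(nrow(kept$counts), 2)
  expect_true(all(kept$counts[, "CCER2"] > 0))
  all_pos <- toy_cells(cbind(CCER2 = c(1, 3), OTHER = c(0, 0)))
  expect_equal(nrow(select_marker_positive(all_pos, "CCER2")$counts), 2)
  none <- toy_cells(cbind(CCER2 = c(0, 0), OTHER = c(1, 1)))
  expect_warning(out <- select_marker_positive(none, "CCER2"), "no cell")
  expect_equal(nrow(out$counts), 0)
  expect_error(select_marker_positive(cells, "NOPE"), "gene-not-found")
})

test_that("rank_sum_compare reproduces exact enumeration probabilities", {
  # all 6 rank assignments of {1,2} vs {3,4}: one-sided 1/6, two-sided 1/3
  expect_equal(rank_sum_compare(c(1, 2), c(3, 4), "less")$p.value, 1 / 6)
  expect_equal(rank_sum_compare(c(1, 2), c(3, 4))$p.value, 1 / 3)
  expect_equal(rank_sum_compare(c(3, 4), c(1, 2), "greater")$p.value, 1 / 6)
  # identical constant groups carry no information
  expect_equal(rank_sum_compare(rep(2, 5), rep(2, 7))$p.value, 1)
  expect_error(rank_sum_compare(numeric(0), 1:3), "statistical error")
})

test_that("rank_sum_compare agrees with wilcox.test in both regimes", {
  set.seed(21)
  for (rep in 1:10) {
    a <- stats::rnorm(sample(3:10, 1))
    b <- stats::rnorm(sample(3:10, 1)) + stats::runif(1, -1, 1)
    ours <- rank_sum_compare(a, b)
    ref <- stats::wilcox.test(a, b, exact = length(a) + length(b) <= 25)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
  # tied data: normal approximation with tie correction
  a <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9, 10, 11, 12, 12)
  b <- c(2, 3, 3, 4, 5, 7, 7, 8, 10, 10, 11, 13, 14, 14)
  ours <- rank_sum_compare(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("rank_sum_compare is invariant to strictly monotone transforms", {
  set.seed(4)
  a <- stats::rexp(12); b <- stats::rexp(15) * 1.5
  p0 <- rank_sum_compare(a, b)$p.value
  for (f in list(log, sqrt, function(x) x^3, function(x) 5 * x - 2)) {
    expect_equal(rank_sum_compare(f(a), f(b))$p.value, p0)
  }
})

test_that("region_gene_compare reports per-gene statistics", {
  a <- cbind(PERP = c(5, 6, 7, 8), CCER2 = c(2, 2, 3, 3))
  b <- cbind(PERP = c(0, 1, 0, 1), CCER2 = c(2, 3, 2, 3))
  out <- region_gene_compare(a, b)
  expect_equal(out$gene, c("PERP", "CCER2"))
  expect_lt(out$p.value[out$gene == "PERP"], 0.05)
  expect_gt(out$p.value[out$gene == "CCER2"], 0.5)
})
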