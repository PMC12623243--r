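test_that("expand_labels geometry: identity at d=0 and axis neighbors at d=1", {
  img <- matrix(0L, 10, 10)
  img[5, 5] <- 3L
  expect_identical(expand_labels(img, 0), img)
  out <- expand_labels(img, 1)
  expect_equal(sum(out > 0), 5)
  expect_equal(out[4, 5], 3L)
  expect_equal(out[6, 5], 3L)
  expect_equal(out[5, 4], 3L)
  expect_equal(out[5, 6], 3L)
  expect_equal(out[6, 6], 0L)  # distance sqrt(2) > 1
  expect_error(expand_labels(img, -1), "parameter error")
})

test_that("expand_labels matches the exhaustive nearest-seed oracle", {
  set.seed(42)
  for (rep in 1:3) {
    img <- matrix(0L, 30, 30)
    seeds <- cbind(sample(30, 2), sample(30, 2))
    img[seeds] <- c(2L, 1L)
    expect_identical(expand_labels(img, 3), oracle_expand(img, 3))
  }
  # dense many-seed case, including equidistant ties
  img <- matrix(0L, 20, 20)
  img[cbind(c(5, 5, 12, 15), c(5, 9, 12, 3))] <- c(4L, 1L, 3L, 2L)
  expect_identical(expand_labels(img, 2.5), oracle_expand(img, 2.5))
})

test_that("expand_labels is idempotent for a fixed seed set", {
  set.seed(7)
  img <- matrix(0L, 25, 25)
  img[cbind(sample(25, 5), sample(25, 5))] <- 1:5
  out <- expand_labels(img, 3)
  # with the original nuclei as the seed set, re-application is a no-op
  expect_identical(expand_labels(out, 3, seed_mask = img > 0), out)
  expect_true(all(out[img > 0] == img[img > 0]))
})

test_that("aggregate_bins sums labeled bins and drops unlabeled counts", {
  labels <- matrix(0L, 4, 4)
  labels[1, 1] <- 1L; labels[1, 2] <- 1L; labels[2, 2] <- 2L
  coords <- rbind(c(1, 1), c(1, 2), c(2, 2), c(3, 3))
  counts <- rbind(c(3, 0), c(4, 1), c(5, 2), c(9, 9))  # last bin unlabeled
  grid <- bin_grid(coords, counts, gene_ids = c("gA", "gB"))
  cells <- aggregate_bins(grid, labels)
  expect_equal(as.numeric(cells$counts["1", ]), c(7, 1))
  expect_equal(as.numeric(cells$counts["2", ]), c(5, 2))
  expect_equal(sum(cells$counts), sum(counts[1:3, ]))
  expect_equal(unname(cells$centroids["1", ]), c(1, 1.5))
  expect_warning(aggregate_bins(grid, matrix(0L, 4, 4)), "no labeled bins")
})

test_that("aggregate_bins equals an independent group-by-sum oracle", {
  set.seed(11)
  R <- 15; C <- 15; G <- 8
  labels <- matrix(sample(0:5, R * C, replace = TRUE), R, C)
  occupied <- which(matrix(stats::runif(R * C) < 0.7, R, C), arr.ind = TRUE)
  counts <- matrix(stats::rpois(nrow(occupied) * G, 2), ncol = G)
  grid <- bin_grid(occupied, counts, gene_ids = paste0("g", 1:G))
  cells <- aggregate_bins(grid, labels)
  lab <- labels[occupied]
  for (id in sort(unique(lab[lab > 0]))) {
    oracle <- colSums(counts[lab == id, , drop = FALSE])
    expect_equal(as.numeric(cells$counts[as.character(id), ]), oracle)
  }
})

test_that("qc_filter applies the depth thresholds and preserves order", {
  counts <- diag(c(10, 60, 200, 700, 5))
  colnames(counts) <- paste0("g", 1:5)
  cells <- toy_cells(counts)
  kept <- qc_filter(cells, min_genes = 0, min_umis = 50, max_umis = 650)
  expect_equal(unname(kept$n_umis), c(60, 200))
  # identity with wide-open thresholds
  all_kept <- qc_filter(cells, min_genes = 0, min_umis = 0, max_umis = Inf)
  expect_equal(unname(all_kept$n_umis), unname(cells$n_umis))
  expect_warning(qc_filter(cells, min_umis = 1e6), "removed every cell")
  expect_error(qc_filter(cells, min_umis = 100, max_umis = 50), "parameter error")
})

test_that("aggregation recovers the generator's cell draws when d_max covers the footprint", {
  cfg <- small_sim_config(seed = 5, ambient = 0)
  sim <- generate_spatial_truth(cfg)
  grid <- generate_bin_counts(sim$label_image, sim$truth, cfg)
  expanded <- expand_labels(sim$label_image, max(cfg$cell_radius))
  cells <- aggregate_bins(grid, expanded)
  draws <- attr(grid, "cell_counts")
  ids <- as.integer(rownames(cells$counts))
  expect_equal(unname(as.matrix(cells$counts)), unname(draws[ids, ]))
})
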