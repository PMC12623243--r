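test_that("empty configurations yield empty fixtures", {
  cfg <- small_sim_config()
  cfg0 <- sim_config(grid_nrow = 40, grid_ncol = 40, n_genes = 120,
                     n_cells = c(epiMCC = 0, cMCC = 0, vasMCC = 0,
                                 bK = 0, sbK = 0, other = 0),
                     sc_n_cells = c(epiMCC = 0, cMCC = 0, vasMCC = 0,
                                    other = 0))
  sim <- generate_spatial_truth(cfg0)
  expect_true(all(sim$label_image == 0))
  expect_equal(nrow(sim$truth$cells), 0)
  sc <- generate_scrnaseq(cfg0)
  expect_equal(nrow(sc$cells$counts), 0)
})

test_that("one distinct label is placed per requested cell", {
  cfg <- small_sim_config(seed = 1)
  sim <- generate_spatial_truth(cfg)
  labs <- sort(unique(sim$label_image[sim$label_image > 0]))
  expect_equal(length(labs), sum(cfg$n_cells))
  expect_equal(labs, sim$truth$cells$cell_id)
  # each cell's type is consistent with its region
  centers <- cell_matrix(Matrix::Matrix(0, nrow(sim$truth$cells), 1, sparse = TRUE),
                         centroids = sim$truth$cells[, c("row", "col")])
  reg <- assign_regions(centers, sim$regions)
  expected <- c(epiMCC = "epidermis", bK = "epidermis", sbK = "epidermis",
                cMCC = "tumor_core", vasMCC = "perivascular",
                other = "follicle")
  expect_equal(reg, unname(expected[sim$truth$cells$type]))
})

test_that("fixtures are bit-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 7)
  s1 <- generate_spatial_truth(cfg)
  s2 <- generate_spatial_truth(cfg)
  expect_identical(s1$label_image, s2$label_image)
  expect_identical(s1$truth$cells, s2$truth$cells)
  g1 <- generate_bin_counts(s1$label_image, s1$truth, cfg)
  g2 <- generate_bin_counts(s2$label_image, s2$truth, cfg)
  expect_identical(as.matrix(g1$counts), as.matrix(g2$counts))
  sc1 <- generate_scrnaseq(cfg)
  sc2 <- generate_scrnaseq(cfg)
  expect_identical(as.matrix(sc1$cells$counts), as.matrix(sc2$cells$counts))
})

test_that("bin splits conserve each cell's drawn counts", {
  cfg <- small_sim_config(seed = 3, ambient = 0)
  sim <- generate_spatial_truth(cfg)
  grid <- generate_bin_counts(sim$label_image, sim$truth, cfg)
  draws <- attr(grid, "cell_counts")
  # sum bins of each cell footprint via full-distance expansion
  exp_img <- expand_labels(sim$label_image, max(cfg$cell_radius))
  cells <- aggregate_bins(grid, exp_img)
  ids <- as.integer(rownames(cells$counts))
  expect_equal(as.matrix(cells$counts),
               matrix(draws[ids, ], nrow = length(ids),
                      dimnames = dimnames(cells$counts)))
  expect_equal(sum(cells$counts), sum(draws))
})

test_that("the infinite-dispersion limit is Poisson (variance equals mean)", {
  cfg <- sim_config(n_genes = 200, dispersion = Inf, zero_effects = TRUE,
                    sc_n_cells = c(epiMCC = 0, cMCC = 1200, vasMCC = 0,
                                   other = 0),
                    sc_mean_umis = 400, seed = 11)
  sc <- generate_scrnaseq(cfg)
  x <- as.matrix(sc$cells$counts)
  mu <- colMeans(x)
  vm <- apply(x, 2, stats::var) / mu
  expect_gt(mean(vm), 0.95)
  expect_lt(mean(vm), 1.05)
})

test_that("empirical depth tracks the configured mean UMIs within 10%", {
  cfg <- sim_config(n_genes = 200,
                    sc_n_cells = c(epiMCC = 0, cMCC = 1000, vasMCC = 0,
                                   other = 0),
                    sc_mean_umis = 200, seed = 5)
  sc <- generate_scrnaseq(cfg)
  m <- mean(Matrix::rowSums(sc$cells$counts))
  expect_gt(m, 180)
  expect_lt(m, 220)
})

test_that("zero marker effects make cell types exchangeable", {
  # under zero effects, a rank-sum comparison of any marker gene between two
  # types should produce uniform p values across replicate simulations
  ps <- vapply(1:60, function(s) {
    cfg <- sim_config(n_genes = 60, zero_effects = TRUE,
                      sc_n_cells = c(epiMCC = 25, cMCC = 25, vasMCC = 0,
                                     other = 0),
                      sc_mean_umis = 100, seed = 1000 + s)
    sc <- generate_scrnaseq(cfg)
    x <- as.numeric(sc$cells$counts[, "CCER2"])
    tp <- sc$truth$cells$type
    rank_sum_compare(x[tp == "epiMCC"], x[tp == "cMCC"])$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted single-cell identities are recoverable by gating", {
  cfg <- small_sim_config(seed = 2)
  sc <- generate_scrnaseq(cfg)
  conf <- gating_confusion(apply_gates(sc$cells), sc$truth$cells$type)
  expect_true(all(conf$precision >= 0.9))
  expect_true(all(conf$recall >= 0.9))
})

test_that("dropout masks only mark formerly positive entries", {
  cfg <- sim_config(n_genes = 100, dropout_rate = 0.2,
                    sc_n_cells = c(epiMCC = 40, cMCC = 40, vasMCC = 0,
                                   other = 0),
                    sc_mean_umis = 300, seed = 9)
  sc <- generate_scrnaseq(cfg)
  mask <- sc$truth$dropout_mask
  expect_true(any(mask))
  expect_true(all(as.matrix(sc$cells$counts)[mask] == 0))
})

test_that("undersized grids raise a sizing error", {
  expect_error(generate_spatial_truth(
    sim_config(grid_nrow = 30, grid_ncol = 30, n_genes = 120)),
    "sizing error")
})
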