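#' Default gene-set fixtures for scoring
#'
#' Metaprogram and regulon sets built over the synthetic gene universe: an
#' EMT-related tumor metaprogram (MP12-like: collagen genes, VIM), an
#' epithelial differentiation metaprogram, and a small regulon collection
#' in which the TP63-like regulon targets the epidermal differentiation
#' program (PERP, SFN, calmodulin-like and S100 genes) and control regulons
#' target background genes. These are fixtures over synthetic data, not a
#' redistribution of any curated resource.
#'
#' @return list with `metaprograms` and `regulons`, both
#'   [gene_set_collection()]s.
#' @export
default_gene_sets <- function() {
  panels <- default_marker_panels()
  list(
    metaprograms = gene_set_collection(list(
      MP12_EMT = panels$emt,
      MP_epithelial = setdiff(panels$epidermal, c("KRT6A", "KRT6B"))
    )),
    regulons = gene_set_collection(list(
      TP63 = c("PERP", "SFN", "CALML3", "CALML5", "S100A2", "SPRR1B"),
      CTRL1 = sprintf("BG%04d", 1:20),
      CTRL2 = sprintf("BG%04d", 21:40)
    ))
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the stages end to end on synthetic data: tissue simulation,
#' bin-to-cell reconstruction (label expansion, aggregation, QC), region
#' assignment with marker-positive selection, pooled keratin-excluded PCA
#' with per-class multivariate-t ellipses, PC1 marker enrichment,
#' zero-preserving imputation, metaprogram/regulon scoring with specificity
#' scores, and the single-cell branch (gating, balanced subsampling,
#' rank-sum differential expression, TF-target intersection). Three spatial
#' samples are simulated from seeds derived from the global seed and pooled,
#' mirroring a multi-sample design. The run is deterministic under a fixed
#' seed.
#'
#' @param config a [sim_config()]; its `seed` is the global seed.
#' @param n_samples number of spatial samples to simulate and pool.
#' @param d_max label expansion distance in bins.
#' @param n_components number of principal components.
#' @param out_dir optional directory; when given, stage outputs are written
#'   (MTX/TSV/GMT/GeoJSON/JSON) under it.
#' @param stages character vector of stages to run, in dependency order;
#'   subsets must be dependency-closed. Default: all.
#' @return a run report (list) with per-stage outputs, counts, statistics
#'   and the seeds used.
#' @export
run_pipeline <- function(config = sim_config(), n_samples = 3, d_max = 2,
                         n_components = 10, out_dir = NULL,
                         stages = c("simulate", "segment", "annotate", "pca",
                                    "enrich", "impute", "score", "gate",
                                    "dge")) {
  stopifnot(inherits(config, "sim_config"))
  report <- list(seed = config$seed, stages = stages,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages)
      stop("dependency error: stage '", stage, "' needs '", dep, "'")
  }
  need("segment", "simulate"); need("annotate", "segment")
  need("pca", "annotate"); need("enrich", "pca"); need("impute", "annotate")
  need("score", "annotate"); need("dge", "gate")
  sets <- default_gene_sets()

  samples <- NULL
  if ("simulate" %in% stages) {
    samples <- lapply(seq_len(n_samples), function(s) {
      cfg_s <- config
      cfg_s$seed <- derive_seed(config$seed, 100 + s)
      sim <- generate_spatial_truth(cfg_s)
      grid <- generate_bin_counts(sim$label_image, sim$truth, cfg_s)
      list(config = cfg_s, sim = sim, grid = grid,
           truth = attr(grid, "truth"))
    })
    report$simulate <- list(
      n_samples = n_samples,
      cells_per_sample = vapply(samples, function(s) nrow(s$truth$cells), 1L),
      seeds = vapply(samples, function(s) s$config$seed, 1L))
    if (!is.null(out_dir)) {
      for (s in seq_along(samples)) {
        d <- file.path(out_dir, sprintf("sample%d", s))
        write_bin_grid(samples[[s]]$grid, file.path(d, "bins"))
        write_label_image(samples[[s]]$sim$label_image,
                          file.path(d, "labels.pgm"))
        write_regions(samples[[s]]$sim$regions, file.path(d, "regions.geojson"))
        utils::write.table(samples[[s]]$truth$cells,
                           file.path(d, "truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
  }

  pooled <- NULL
  if ("segment" %in% stages) {
    seg <- lapply(seq_along(samples), function(s) {
      expanded <- expand_labels(samples[[s]]$sim$label_image, d_max)
      cells <- aggregate_bins(samples[[s]]$grid, expanded,
                              sample_id = sprintf("sample%d", s))
      qc_filter(cells, min_genes = 20, min_umis = 50)
    })
    pooled <- do.call(rbind_cells, seg)
    # truth types follow the label ids kept after QC
    truth_types <- unlist(lapply(seq_along(samples), function(s) {
      ids <- as.integer(rownames(seg[[s]]$counts))
      samples[[s]]$truth$cells$type[match(ids, samples[[s]]$truth$cells$cell_id)]
    }))
    pooled$labels <- truth_types
    report$segment <- list(n_cells = nrow(pooled$counts),
                           median_umis = stats::median(pooled$n_umis),
                           median_genes = stats::median(pooled$n_genes))
  }

  if ("annotate" %in% stages) {
    region_class <- unlist(lapply(seq_along(samples), function(s) {
      cs <- pooled$sample_id == sprintf("sample%d", s)
      assign_regions(subset_cells(pooled, which(cs)), samples[[s]]$sim$regions)
    }))
    report$annotate <- list(region_counts = as.list(table(region_class,
                                                          useNA = "ifany")))
    pooled$region <- region_class
    tumor_cells <- select_marker_positive(pooled, "CCER2")
    report$annotate$ccer2_positive <- nrow(tumor_cells$counts)
  }

  pca <- NULL; prep <- NULL
  if ("pca" %in% stages) {
    prep <- preprocess(pooled, exclude_pattern = "^KRT")
    kept <- prep$kept_cells
    pca <- fit_pooled_pca(prep$mat, sample_ids = pooled$sample_id[kept],
                          n_components = n_components, batch_correct = TRUE)
    types <- pooled$labels[kept]
    cls <- c("epiMCC", "cMCC", "vasMCC", "bK", "sbK")
    ellipses <- lapply(stats::setNames(cls, cls), function(cl) {
      pts <- pca$scores[types == cl, 1:2, drop = FALSE]
      if (nrow(pts) >= 3) fit_t_ellipse(pts) else NULL
    })
    centroids <- vapply(cls, function(cl)
      mean(pca$scores[types == cl, 1]), numeric(1))
    report$pca <- list(
      explained_variance_pct = round(100 * pca$explained_variance_ratio, 3),
      pc1_centroids = as.list(centroids),
      epi_between = unname(
        centroids["epiMCC"] > min(centroids["cMCC"],
                                  mean(centroids[c("bK", "sbK")])) &
        centroids["epiMCC"] < max(centroids["cMCC"],
                                  mean(centroids[c("bK", "sbK")]))))
    report$pca_types <- types
    attr(pca, "ellipses") <- ellipses
  }

  if ("enrich" %in% stages) {
    cscc <- setdiff(default_marker_panels()$epidermal, c("PERP"))
    lr <- loading_rank_test(pca$loadings[, 1], cscc)
    report$enrich <- list(pc1_cscc_p = lr$p.value,
                          median_marker_rank = stats::median(lr$marker_ranks),
                          n_markers = lr$n_markers_used)
  }

  if ("impute" %in% stages) {
    imp <- alra(prep$mat)
    report$impute <- list(k = imp$k,
                          nonzero_before = mean(prep$mat > 0),
                          nonzero_after = mean(imp$imputed > 0))
  }

  if ("score" %in% stages) {
    norm_all <- preprocess(pooled, exclude_pattern = NULL)
    act <- aucell_collection(norm_all$mat, sets$metaprograms, seed = config$seed)
    types <- pooled$labels[norm_all$kept_cells]
    mp12 <- act[, "MP12_EMT"]
    ts <- rank_sum_compare(mp12[types == "vasMCC"], mp12[types == "cMCC"],
                           alternative = "greater")
    ract <- aucell_collection(norm_all$mat, sets$regulons, seed = config$seed)
    rss <- regulon_specificity(ract, types)
    report$score <- list(
      mp12_mean_by_type = as.list(tapply(mp12, types, mean)),
      mp12_vas_vs_core_p = ts$p.value,
      tp63_rss_top_class = colnames(rss$rss)[which.max(rss$rss["TP63", ])])
  }

  gated <- NULL; sc <- NULL
  if ("gate" %in% stages) {
    sc <- generate_scrnaseq(config)
    gated <- apply_gates(sc$cells)
    conf <- gating_confusion(gated, sc$truth$cells$type)
    report$gate <- list(class_counts = as.list(table(gated, useNA = "ifany")),
                        precision = as.list(conf$precision),
                        recall = as.list(conf$recall),
                        subsample_seed = derive_seed(config$seed, 4))
  }

  if ("dge" %in% stages) {
    idx <- balanced_subsample(gated, seed = derive_seed(config$seed, 4))
    sub <- subset_cells(sc$cells, idx)
    sub_norm <- preprocess(sub, exclude_pattern = NULL)
    lab <- gated[idx][sub_norm$kept_cells]
    dge <- wilcoxon_dge(sub_norm$mat, lab, "epiMCC", "cMCC")
    up <- top_dge(dge, direction = "up")$gene
    enh <- enhanced_regulons(
      aucell_collection(sub_norm$mat, sets$regulons, seed = config$seed),
      lab, "epiMCC")
    enh_sets <- gene_set_collection(sets$regulons$sets[enh])
    inter <- tf_target_intersect(up, enh_sets)
    ora <- ora_collection(up, sets$metaprograms, universe = colnames(sub_norm$mat))
    report$dge <- list(n_significant_up = length(up),
                       enhanced_regulons = enh,
                       tf_target_intersection = length(inter),
                       ora_top_set = ora$set[1])
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

# strip non-serializable bulk from the report before writing
report_to_json <- function(report) {
  report$pca_types <- NULL
  report
}

#' Gating confusion summary against planted truth
#'
#' @param predicted gated class per cell (`NA` = unlabeled).
#' @param truth planted type per cell.
#' @param classes classes to evaluate.
#' @return list with per-class `precision` and `recall`.
#' @export
gating_confusion <- function(predicted, truth,
                             classes = c("epiMCC", "cMCC", "vasMCC")) {
  precision <- recall <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp <- sum(predicted == cl & truth == cl, na.rm = TRUE)
    precision[cl] <- tp / max(1, sum(predicted == cl, na.rm = TRUE))
    recall[cl] <- tp / max(1, sum(truth == cl))
  }
  list(precision = precision, recall = recall)
}

#' Concatenate cell matrices over a shared gene universe
#'
#' @param ... `cell_matrix` objects with identical gene order.
#' @return one pooled [cell_matrix()].
#' @export
rbind_cells <- function(...) {
  parts <- list(...)
  g <- colnames(parts[[1]]$counts)
  for (p in parts) stopifnot(identical(colnames(p$counts), g))
  counts <- do.call(rbind, lapply(parts, function(p) p$counts))
  rn <- unlist(lapply(seq_along(parts), function(i)
    paste0("s", i, "_", rownames(parts[[i]]$counts))))
  rownames(counts) <- rn
  cent <- if (all(!vapply(parts, function(p) is.null(p$centroids), TRUE)))
    do.call(rbind, lapply(parts, function(p) p$centroids))
  cell_matrix(counts,
              centroids = cent,
              sample_id = unlist(lapply(parts, function(p) p$sample_id)),
              labels = {
                labs <- lapply(parts, function(p) p$labels)
                if (all(!vapply(labs, is.null, TRUE))) unlist(labs)
              })
}
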