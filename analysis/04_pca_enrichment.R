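#!/usr/bin/env Rscript
# Pooled keratin-excluded PCA of the truth-typed selected cells across the
# three samples, per-sample score centering, 95% multivariate-t ellipses per
# cell type, PC1 centroid ordering, and rank-based enrichment of the
# cSCC-like marker panel among PC1 loadings.

suppressPackageStartupMessages(library(epimcc))

out <- "results/pca"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pooled <- NULL
types <- character(0)
for (s in 1:3) {
  cells <- read_cell_matrix(file.path("results/cells", sprintf("sample%d", s)))
  truth <- read.table(file.path("results/fixtures", sprintf("sample%d", s),
                                "truth.tsv"), header = TRUE, sep = "\t")
  ids <- as.integer(sub("^s\\d+_", "", rownames(cells$counts)))
  types <- c(types, truth$type[match(ids, truth$cell_id)])
  pooled <- if (is.null(pooled)) cells else rbind_cells(pooled, cells)
}

prep <- preprocess(pooled, exclude_pattern = "^KRT")
message("Excluded ", length(prep$excluded_genes),
        " keratin genes from PCA: ",
        paste(head(prep$excluded_genes, 8), collapse = ", "), " ...")
types <- types[prep$kept_cells]

pca <- fit_pooled_pca(prep$mat, sample_ids = pooled$sample_id[prep$kept_cells],
                      n_components = 10, batch_correct = TRUE)
message(sprintf("Explained variance: PC1 %.1f%%, PC2 %.1f%%",
                100 * pca$explained_variance_ratio[1],
                100 * pca$explained_variance_ratio[2]))

write.table(data.frame(cell = rownames(pca$scores), type = types,
                       pca$scores),
            file.path(out, "scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene = rownames(pca$loadings), pca$loadings),
            file.path(out, "loadings.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cls <- c("epiMCC", "cMCC", "vasMCC", "bK", "sbK")
ellipses <- lapply(setNames(cls, cls), function(cl)
  fit_t_ellipse(pca$scores[types == cl, 1:2]))
jsonlite::write_json(
  lapply(ellipses, function(e) list(center = e$center,
                                    scatter = as.vector(e$scatter),
                                    df = e$df, level = e$level,
                                    radius2 = e$radius2)),
  file.path(out, "ellipses.json"), auto_unbox = TRUE, digits = NA)

cen <- vapply(cls, function(cl) mean(pca$scores[types == cl, 1]), numeric(1))
message("PC1 centroids: ", paste(cls, round(cen, 2), sep = "=", collapse = ", "))
kerat <- mean(cen[c("bK", "sbK")])
message("epiMCC centroid between tumor core and keratinocytes on PC1: ",
        cen["epiMCC"] > min(cen["cMCC"], kerat) &
          cen["epiMCC"] < max(cen["cMCC"], kerat))

cscc <- setdiff(default_marker_panels()$epidermal, "PERP")
lr <- loading_rank_test(pca$loadings[, 1], cscc)
message(sprintf("cSCC marker enrichment among PC1 loadings: U = %.0f, one-sided p = %.3g (median marker rank %d of %d genes)",
                lr$statistic, lr$p.value, median(lr$marker_ranks),
                nrow(pca$loadings)))
write.table(data.frame(marker = names(lr$marker_ranks),
                       rank = lr$marker_ranks),
            file.path(out, "pc1_cscc_marker_ranks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
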