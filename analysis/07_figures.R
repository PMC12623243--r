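#!/usr/bin/env Rscript
# Figure outputs mirroring the study's displays: spatial class map, PCA
# embedding with multivariate-t ellipses, ranked PC1 loadings with cSCC
# markers highlighted, CCER2/PERP two-colour co-expression, MP12 violin and
# regulon-specificity heatmap. PNGs under results/figures/.

suppressPackageStartupMessages(library(epimcc))

out <- "results/figures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
save <- function(p, name, w = 6, h = 5)
  ggplot2::ggsave(file.path(out, name), p, width = w, height = h, dpi = 150)

cells1 <- read_cell_matrix("results/cells/sample1")
truth1 <- read.table("results/fixtures/sample1/truth.tsv", header = TRUE,
                     sep = "\t")
types1 <- truth1$type[match(as.integer(rownames(cells1$counts)),
                            truth1$cell_id)]
save(plot_spatial_classes(cells1, types1), "spatial_classes_sample1.png")
save(plot_coexpression(cells1, "CCER2", "PERP"), "ccer2_perp_coexpression.png")

scores <- read.table("results/pca/scores.tsv", header = TRUE, sep = "\t")
cls <- c("epiMCC", "cMCC", "vasMCC", "bK", "sbK")
ell <- lapply(setNames(cls, cls), function(cl)
  fit_t_ellipse(as.matrix(scores[scores$type == cl, c("PC1", "PC2")])))
save(plot_scores_with_ellipses(as.matrix(scores[, c("PC1", "PC2")]),
                               scores$type, ell),
     "pca_ellipses.png")

loadings <- read.table("results/pca/loadings.tsv", header = TRUE, sep = "\t")
pc1 <- setNames(loadings$PC1, loadings$gene)
save(plot_loading_ranks(pc1, setdiff(default_marker_panels()$epidermal, "PERP")),
     "pc1_loadings_cscc.png")

act <- read.table("results/scores/metaprogram_activity.tsv", header = TRUE,
                  sep = "\t")
save(plot_violin_by_class(act$MP12_EMT, act$type, ylab = "MP12 (EMT) activity"),
     "mp12_violin.png")

rss <- read.table("results/scores/regulon_specificity.tsv", header = TRUE,
                  sep = "\t")
m <- as.matrix(rss[, -1]); rownames(m) <- rss$regulon
save(plot_score_heatmap(m, value_name = "RSS"), "regulon_specificity.png")

message("Wrote figures to ", out)
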