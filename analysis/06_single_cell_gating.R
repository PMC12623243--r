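#!/usr/bin/env Rscript
# Single-cell validation branch: rule-based gating of MCC subtypes on raw
# counts, balanced subsampling, Wilcoxon rank-sum differential expression
# ranked by fold change, over-representation of metaprograms among the
# upregulated genes, and the intersection of epiMCC-upregulated genes with
# the targets of enhanced TF regulons.

suppressPackageStartupMessages(library(epimcc))

seed <- 1L
out <- "results/single_cell"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- read_cell_matrix("results/fixtures/scrnaseq")
truth <- read.table("results/fixtures/scrnaseq/truth.tsv", header = TRUE,
                    sep = "\t")

gated <- apply_gates(sc, verbose = TRUE)
conf <- gating_confusion(gated, truth$type)
message("Per-class precision: ",
        paste(names(conf$precision), round(conf$precision, 3),
              sep = "=", collapse = ", "))
message("Per-class recall:    ",
        paste(names(conf$recall), round(conf$recall, 3),
              sep = "=", collapse = ", "))

idx <- balanced_subsample(gated, seed = seed)
message("Balanced subsample: ", length(idx), " cells (",
        paste(names(table(gated[idx])), table(gated[idx]), sep = "=",
              collapse = ", "), ")")

sub <- subset_cells(sc, idx)
norm <- preprocess(sub, exclude_pattern = NULL)
lab <- gated[idx][norm$kept_cells]

dge <- wilcoxon_dge(norm$mat, lab, "epiMCC", "cMCC")
write.table(dge, file.path(out, "dge_epi_vs_core.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
up <- top_dge(dge, direction = "up")
message("Significant epiMCC-upregulated genes (BH p < 0.05), top by fold change:")
print(head(up[, c("gene", "log2fc", "p.adj")], 10), digits = 3)

sets <- list(metaprograms = read_gmt("results/fixtures/metaprograms.gmt"),
             regulons = read_gmt("results/fixtures/regulons.gmt"))
ora <- ora_collection(up$gene, sets$metaprograms,
                      universe = colnames(norm$mat))
write.table(ora, file.path(out, "ora_metaprograms.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Over-representation of metaprograms among upregulated genes:")
print(ora[, 1:5], digits = 3)

ract <- aucell_collection(norm$mat, sets$regulons, seed = seed)
enh <- enhanced_regulons(ract, lab, "epiMCC")
inter <- tf_target_intersect(
  up$gene, gene_set_collection(sets$regulons$sets[enh]))
message("Enhanced regulons in epiMCC: ", paste(enh, collapse = ", "))
message("Genes both upregulated in epiMCC and regulated by them (n = ",
        length(inter), "): ", paste(inter, collapse = ", "))
write.table(data.frame(gene = inter,
                       regulons = vapply(attr(inter, "provenance"),
                                         paste, "", collapse = ",")),
            file.path(out, "tf_target_intersection.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
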