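#!/usr/bin/env Rscript
# Simulate the study's data structure: three HD spatial samples of MCC with
# epidermotropism (2 um bin counts, nuclear label image, region annotation,
# ground truth) and one single-cell RNA-seq validation dataset. All outputs
# are plain text under results/fixtures/.

suppressPackageStartupMessages(library(epimcc))

seed <- 1L
cfg <- sim_config(seed = seed)
out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating ", 3, " spatial samples on a ",
        cfg$grid_nrow, "x", cfg$grid_ncol, " bin lattice (2 um pitch)...")
for (s in 1:3) {
  cfg_s <- cfg
  cfg_s$seed <- epimcc:::derive_seed(seed, 100 + s)
  sim <- generate_spatial_truth(cfg_s)
  grid <- generate_bin_counts(sim$label_image, sim$truth, cfg_s)
  d <- file.path(out, sprintf("sample%d", s))
  write_bin_grid(grid, file.path(d, "bins"))
  write_label_image(sim$label_image, file.path(d, "labels.pgm"))
  write_regions(sim$regions, file.path(d, "regions.geojson"))
  write.table(attr(grid, "truth")$cells, file.path(d, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("  sample%d: %d cells, %d occupied bins, %d total UMIs",
                  s, nrow(sim$truth$cells), nrow(grid$counts),
                  sum(grid$counts)))
}

message("Simulating the single-cell validation dataset...")
sc <- generate_scrnaseq(cfg)
write_cell_matrix(sc$cells, file.path(out, "scrnaseq"))
write.table(sc$truth$cells, file.path(out, "scrnaseq", "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d cells at median %0.f UMIs",
                nrow(sc$cells$counts), median(Matrix::rowSums(sc$cells$counts))))

sets <- default_gene_sets()
write_gmt(sets$metaprograms, file.path(out, "metaprograms.gmt"))
write_gmt(sets$regulons, file.path(out, "regulons.gmt"))
message("Wrote gene-set fixtures; done.")
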