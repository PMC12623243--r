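## Plain-text readers/writers for the formats used across the pipeline:
## Matrix Market counts with features/barcodes TSV, GMT gene sets, ASCII PGM
## label images, GeoJSON region polygons, JSON configs/reports.

#' Write a cell_matrix as MTX + TSV
#'
#' Writes `matrix.mtx` (genes x cells, Matrix Market), `features.tsv`,
#' `barcodes.tsv` and, when centroids are present, `centroids.tsv`
#' (barcode, row, col, sample_id, label).
#'
#' @param cells a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(cells$counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(cells$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(cells$counts), file.path(dir, "barcodes.tsv"))
  meta <- data.frame(barcode = rownames(cells$counts),
                     row = if (is.null(cells$centroids)) NA else cells$centroids[, 1],
                     col = if (is.null(cells$centroids)) NA else cells$centroids[, 2],
                     sample_id = cells$sample_id,
                     label = if (is.null(cells$labels)) NA else cells$labels)
  utils::write.table(meta, file.path(dir, "centroids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell_matrix written by [write_cell_matrix()]
#'
#' @param dir directory holding matrix.mtx, features.tsv, barcodes.tsv and
#'   optionally centroids.tsv.
#' @return a [cell_matrix()].
#' @export
read_cell_matrix <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(cells, genes)
  cent <- NULL; sample_id <- "sample1"; labels <- NULL
  meta_path <- file.path(dir, "centroids.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    if (!all(is.na(meta$row))) cent <- cbind(meta$row, meta$col)
    sample_id <- meta$sample_id
    if (!all(is.na(meta$label))) labels <- meta$label
  }
  cell_matrix(m, centroids = cent, sample_id = sample_id, labels = labels)
}

#' Write a bin_grid as MTX + coordinate TSV
#'
#' @param grid a [bin_grid()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bin_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(grid$counts), file.path(dir, "matrix.mtx"))
  writeLines(grid$gene_ids, file.path(dir, "features.tsv"))
  utils::write.table(as.data.frame(grid$coords), file.path(dir, "bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bin_grid written by [write_bin_grid()]
#'
#' @param dir directory holding matrix.mtx, features.tsv, bins.tsv.
#' @return a [bin_grid()].
#' @export
read_bin_grid <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "features.tsv"))
  coords <- utils::read.table(file.path(dir, "bins.tsv"), sep = "\t",
                              header = TRUE)
  colnames(m) <- genes
  bin_grid(as.matrix(coords), m, gene_ids = genes)
}

#' Write an integer label image as ASCII PGM (P2)
#'
#' @param img integer matrix of labels.
#' @param path output path (.pgm).
#' @return `path`, invisibly.
#' @export
write_label_image <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(max(img, 1))), con)
  utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ASCII PGM (P2) label image
#'
#' @param path path to a P2 PGM file written by [write_label_image()].
#' @return integer matrix of labels.
#' @export
read_label_image <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  stopifnot(lines[1] == "P2")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description, genes.
#' Genes suffixed `+`/`-` are read as signed regulon targets.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); signs <- list(); any_signed <- FALSE
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    genes <- parts[-(1:2)]
    sg <- rep(1, length(genes))
    signed <- grepl("[+-]$", genes)
    if (any(signed)) {
      any_signed <- TRUE
      sg[signed] <- ifelse(substring(genes[signed], nchar(genes[signed])) == "-", -1, 1)
      genes[signed] <- substring(genes[signed], 1, nchar(genes[signed]) - 1)
    }
    sets[[parts[1]]] <- genes
    signs[[parts[1]]] <- sg
  }
  gene_set_collection(sets, signs = if (any_signed) signs else NULL)
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    genes <- collection$sets[[nm]]
    if (!is.null(collection$signs))
      genes <- paste0(genes, ifelse(collection$signs[[nm]] < 0, "-", ""))
    paste(c(nm, nm, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write region annotations as GeoJSON
#'
#' Polygons are emitted in `[col, row]` (x, y) vertex order with the region
#' class and id in `properties`.
#'
#' @param regions a [region_annotation()].
#' @param path output path (.geojson).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  features <- lapply(regions$polygons, function(p) {
    ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(class = p$class, id = p$id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                           c(ring[i, 2], ring[i, 1])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region annotations from GeoJSON
#'
#' @param path GeoJSON path written by [write_regions()] (or compatible:
#'   Polygon features with a `class` property).
#' @return a [region_annotation()].
#' @export
read_regions <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(v)
      c(row = as.numeric(v[[2]]), col = as.numeric(v[[1]]))))
    if (all(coords[1, ] == coords[nrow(coords), ]))
      coords <- coords[-nrow(coords), , drop = FALSE]
    list(class = f$properties$class, id = f$properties$id %||% "region",
         coords = coords)
  })
  region_annotation(polys)
}
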