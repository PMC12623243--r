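#' Cell-by-gene count container
#'
#' Light-weight container for a sparse cell x gene UMI count matrix with
#' per-cell metadata: spatial centroid (bin units, `(row, col)`), sample id,
#' and an optional class label. Per-cell totals (`n_umis`) and detected gene
#' counts (`n_genes`) are derived from the counts and kept in sync.
#'
#' @param counts sparse (or dense) cell x gene matrix of non-negative
#'   integer UMI counts; rownames are cell ids, colnames gene ids.
#' @param centroids optional numeric matrix (n_cells x 2) of `(row, col)`
#'   centroids in bin units.
#' @param sample_id character scalar or per-cell vector of sample ids.
#' @param labels optional per-cell class labels (character or factor).
#' @return An object of class `cell_matrix`: a list with elements `counts`,
#'   `centroids`, `sample_id`, `labels`, `n_umis`, `n_genes`.
#' @export
cell_matrix <- function(counts, centroids = NULL, sample_id = "sample1",
                        labels = NULL) {
  counts <- as_dgc(counts)
  if (any(counts@x < 0)) stop("counts must be non-negative")
  n <- nrow(counts)
  if (n > 0 && is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(n))
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    stopifnot(nrow(centroids) == n, ncol(centroids) == 2)
    colnames(centroids) <- c("row", "col")
    rownames(centroids) <- rownames(counts)
  }
  if (length(sample_id) == 1L) sample_id <- rep(sample_id, n)
  stopifnot(length(sample_id) == n)
  if (!is.null(labels)) stopifnot(length(labels) == n)
  structure(list(
    counts = counts,
    centroids = centroids,
    sample_id = as.character(sample_id),
    labels = labels,
    n_umis = Matrix::rowSums(counts),
    n_genes = Matrix::rowSums(counts > 0)
  ), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes; median UMIs %.0f, median genes %.0f\n",
              nrow(x$counts), ncol(x$counts),
              stats::median(x$n_umis), stats::median(x$n_genes)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "ifany")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by cell index
#'
#' @param cells a `cell_matrix`.
#' @param idx integer or logical index over cells.
#' @return the subset `cell_matrix`, order following `idx`.
#' @export
subset_cells <- function(cells, idx) {
  cell_matrix(cells$counts[idx, , drop = FALSE],
              centroids = if (!is.null(cells$centroids)) cells$centroids[idx, , drop = FALSE],
              sample_id = cells$sample_id[idx],
              labels = if (!is.null(cells$labels)) cells$labels[idx])
}

#' Spatial bin-grid container
#'
#' Sparse gene counts on a 2 micrometre bin lattice. Each occupied bin is one
#' row of `counts`; `coords` gives its `(row, col)` position (1-based bin
#' indices) on the lattice.
#'
#' @param coords integer matrix (n_bins x 2) of unique `(row, col)` bin
#'   coordinates.
#' @param counts sparse bin x gene matrix of non-negative integer counts.
#' @param gene_ids ordered gene identifiers (defaults to `colnames(counts)`).
#' @param bin_pitch_um physical bin pitch in micrometres; fixed at 2 to match
#'   HD spatial sequencing output.
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(coords, counts, gene_ids = colnames(counts),
                     bin_pitch_um = 2) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  colnames(coords) <- c("row", "col")
  counts <- as_dgc(counts)
  stopifnot(nrow(coords) == nrow(counts))
  if (any(counts@x < 0)) stop("counts must be non-negative")
  key <- paste(coords[, 1], coords[, 2])
  if (anyDuplicated(key)) stop("bin coordinates must be unique")
  colnames(counts) <- gene_ids
  structure(list(coords = coords, counts = counts, gene_ids = gene_ids,
                 bin_pitch_um = bin_pitch_um),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d occupied bins x %d genes (%g um pitch), %.0f total UMIs\n",
              nrow(x$counts), ncol(x$counts), x$bin_pitch_um, sum(x$counts)))
  invisible(x)
}

#' Region annotation container
#'
#' Labeled simple polygons in bin coordinates, standing in for the
#' histomorphological annotation of tissue compartments. Class labels come
#' from a fixed vocabulary: epidermis, tumor_core, perivascular, follicle,
#' background.
#'
#' @param polygons list of lists, each with `class` (character), `id`
#'   (character) and `coords` (vertex matrix, columns `(row, col)`, not
#'   closed).
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(polygons) {
  vocab <- c("epidermis", "tumor_core", "perivascular", "follicle", "background")
  for (p in polygons) {
    stopifnot(is.matrix(p$coords) || is.data.frame(p$coords))
    if (nrow(p$coords) < 3) stop("annotation error: polygon with fewer than 3 vertices")
    if (!p$class %in% vocab)
      stop("annotation error: unknown region class '", p$class, "'")
  }
  structure(list(polygons = polygons), class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cls <- vapply(x$polygons, function(p) p$class, character(1))
  cat("<region_annotation>", length(cls), "polygons:",
      paste(cls, collapse = ", "), "\n")
  invisible(x)
}

#' Gene-set collection
#'
#' Named gene sets (marker panels, tumor metaprograms, TF regulons). For
#' regulons, per-gene signs may be carried (`+1` activated target, `-1`
#' repressed); scoring uses positive targets only.
#'
#' @param sets named list of character vectors of gene ids.
#' @param signs optional named list matching `sets`, numeric +/-1 per gene.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, signs = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (anyDuplicated(g)) stop("genes within a set must be unique")
    g
  })
  if (!is.null(signs)) stopifnot(identical(names(signs), names(sets)))
  structure(list(sets = sets, signs = signs), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection>", length(x$sets), "sets; sizes:",
      paste(vapply(x$sets, length, 1L), collapse = ", "), "\n")
  invisible(x)
}
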