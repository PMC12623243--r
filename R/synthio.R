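#' Marker panels used by the synthetic tissue generator
#'
#' The four gene programs planted by the generator: the MCC tumor core panel
#' (neuroendocrine identity: CCER2, SOX2, HES6, ATOH1, CHGA, plus KRT20),
#' the keratinocyte structural panel (KRT5, KRT1, KRT10, CSTA), the
#' epidermal/cSCC-like differentiation panel (SFN, S100 family, CALML3/5,
#' FABP5, SPRR1B, KRT6A/B, PERP) and the EMT panel (COL1A1, COL3A1, VIM).
#'
#' @return named list of character vectors.
#' @export
default_marker_panels <- function() {
  list(
    mcc_core   = c("CCER2", "SOX2", "HES6", "ATOH1", "CHGA", "KRT20"),
    keratin    = c("KRT5", "KRT1", "KRT10", "CSTA"),
    epidermal  = c("SFN", "S100A2", "S100A8", "S100A9", "S100A16",
                   "CALML3", "CALML5", "FABP5", "SPRR1B", "KRT6A", "KRT6B",
                   "PERP"),
    emt        = c("COL1A1", "COL3A1", "VIM")
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic spatial and single-cell generators. Counts
#' follow a negative binomial per gene per cell (mean = library size x
#' type-specific gene proportion, shared dispersion), split multinomially
#' over the cell's bins in the spatial case. Defaults emulate the structure
#' of HD spatial data from MCC with epidermotropism: a 2 um bin lattice, an
#' epidermis band with basal/suprabasal keratinocytes and intraepidermal
#' tumor nests, a dermal tumor nodule, a perivascular ring and a hair
#' follicle. Default per-type depths span roughly 150-650 UMIs per cell,
#' the range of per-sample means typical of segmented HD cells.
#'
#' Marker genes are modeled as program-exclusive: a type expresses a marker
#' only when the gene belongs to that type's program (log-fold effect
#' `-Inf`, i.e. weight zero, outside it). This mirrors the on/off marker
#' biology that zero/non-zero gating relies on. Setting `zero_effects =
#' TRUE` zeroes the whole effects matrix, making all types statistically
#' exchangeable.
#'
#' @param grid_nrow,grid_ncol lattice size in bins.
#' @param bin_pitch_um bin pitch, micrometres; fixed at 2.
#' @param cell_radius integer range (min, max) of cell footprint radii in
#'   bins; nuclear seeds have radius 1.
#' @param n_cells named integer vector of spatial cells per type
#'   (epiMCC, cMCC, vasMCC, bK, sbK, other).
#' @param mean_umis named numeric vector of mean library size per type.
#' @param dispersion shared negative-binomial size parameter (Inf = Poisson).
#' @param core_lfc,program_lfc log2 effects for the tumor-core panel and the
#'   type-specific accessory programs.
#' @param n_genes total gene universe size (markers plus background genes).
#' @param ambient_lambda Poisson rate of ambient background counts per bin
#'   per gene on bins outside any cell footprint; near-zero by default.
#' @param dropout_rate probability that an individual positive count is
#'   technically zeroed (recorded in the ground-truth dropout mask).
#' @param sc_n_cells named integer vector of single-cell counts per type for
#'   [generate_scrnaseq()] (types epiMCC, cMCC, vasMCC, other).
#' @param sc_mean_umis mean library size for single-cell draws.
#' @param zero_effects if TRUE, all program effects are set to zero
#'   (exchangeability control).
#' @param seed integer seed governing every random draw.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_nrow = 160, grid_ncol = 200,
                       bin_pitch_um = 2,
                       cell_radius = c(1, 2),
                       n_cells = c(epiMCC = 60, cMCC = 70, vasMCC = 55,
                                   bK = 40, sbK = 40, other = 30),
                       mean_umis = c(epiMCC = 300, cMCC = 400, vasMCC = 350,
                                     bK = 300, sbK = 250, other = 150),
                       dispersion = 2,
                       core_lfc = 6,
                       program_lfc = 5,
                       n_genes = 1000,
                       ambient_lambda = 1e-5,
                       dropout_rate = 0,
                       sc_n_cells = c(epiMCC = 300, cMCC = 2100,
                                      vasMCC = 300, other = 300),
                       sc_mean_umis = 2000,
                       zero_effects = FALSE,
                       seed = 1) {
  if (bin_pitch_um != 2) stop("bin pitch is fixed at 2 um")
  types <- c("epiMCC", "cMCC", "vasMCC", "bK", "sbK", "other")
  stopifnot(grid_nrow > 0, grid_ncol > 0,
            length(cell_radius) == 2, all(cell_radius >= 1),
            cell_radius[1] <= cell_radius[2],
            all(n_cells >= 0), all(mean_umis > 0), dispersion > 0,
            n_genes > 0, ambient_lambda >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            all(sc_n_cells >= 0), sc_mean_umis > 0)
  n_cells <- n_cells[types[types %in% names(n_cells)]]
  missing_types <- setdiff(types, names(n_cells))
  n_cells[missing_types] <- 0L
  n_cells <- n_cells[types]
  stopifnot(all(types %in% names(mean_umis)))
  panels <- default_marker_panels()
  markers <- unique(unlist(panels))
  if (n_genes < length(markers) + 10)
    stop("config error: n_genes too small for the marker universe")
  genes <- c(markers, sprintf("BG%04d", seq_len(n_genes - length(markers))))
  cfg <- list(grid_nrow = as.integer(grid_nrow), grid_ncol = as.integer(grid_ncol),
              bin_pitch_um = 2, cell_radius = as.integer(cell_radius),
              n_cells = n_cells, mean_umis = mean_umis,
              dispersion = dispersion, core_lfc = core_lfc,
              program_lfc = program_lfc, n_genes = as.integer(n_genes),
              genes = genes, panels = panels,
              ambient_lambda = ambient_lambda, dropout_rate = dropout_rate,
              sc_n_cells = sc_n_cells, sc_mean_umis = sc_mean_umis,
              zero_effects = isTRUE(zero_effects), seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %dx%d bins (2 um), %d genes, seed %d\n",
              x$grid_nrow, x$grid_ncol, x$n_genes, x$seed))
  cat("  spatial cells:", paste(names(x$n_cells), x$n_cells, sep = "=",
                                collapse = ", "), "\n")
  invisible(x)
}

# gene x type matrix of log2 effects; -Inf marks program-exclusive silencing
program_effects_matrix <- function(config) {
  panels <- config$panels
  types <- names(config$n_cells)
  markers <- unique(unlist(panels))
  eff <- matrix(-Inf, nrow = length(markers), ncol = length(types),
                dimnames = list(markers, types))
  add <- function(genes, type, lfc) eff[genes, type] <<- lfc
  add(panels$mcc_core, "cMCC", config$core_lfc)
  add(panels$mcc_core, "epiMCC", config$core_lfc)
  add(panels$mcc_core, "vasMCC", config$core_lfc)
  add(panels$epidermal, "epiMCC", config$program_lfc)
  add(c("KRT5", "KRT6A", "KRT6B"), "epiMCC", config$program_lfc)
  add(panels$emt, "vasMCC", config$program_lfc)
  add(panels$epidermal, "bK", config$program_lfc)
  add(c("KRT5", "CSTA"), "bK", config$program_lfc)
  add(panels$epidermal, "sbK", config$program_lfc)
  add(c("KRT1", "KRT10", "CSTA"), "sbK", config$program_lfc)
  add("KRT5", "sbK", config$program_lfc - 3)
  # 'other' cells (follicular/stromal filler) carry no marker program
  if (config$zero_effects) eff[] <- 0
  eff
}

# gene x type expression weight matrix (proportions after normalization)
type_weights <- function(config) {
  eff <- program_effects_matrix(config)
  types <- colnames(eff)
  w <- matrix(1, nrow = config$n_genes, ncol = length(types),
              dimnames = list(config$genes, types))
  w[rownames(eff), ] <- 2^eff
  sweep(w, 2, colSums(w), "/")
}

## ---- spatial layout ---------------------------------------------------------

circle_polygon <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = center[1] + radius * sin(th), col = center[2] + radius * cos(th))
}

rect_polygon <- function(r0, r1, c0, c1) {
  cbind(row = c(r0, r0, r1, r1), col = c(c0, c1, c1, c0))
}

# hard-coded tissue architecture, scaled to the configured grid
tissue_layout <- function(config) {
  R <- config$grid_nrow; C <- config$grid_ncol
  sr <- R / 160; sc <- C / 200
  epi_rows <- c(1, round(30 * sr))
  basal_top <- round(17 * sr)
  fol <- c(epi_rows[2] + 1, round(90 * sr), round(165 * sc), round(195 * sc))
  tum_c <- c(95 * sr, 60 * sc); tum_r <- 34 * min(sr, sc)
  pv_c <- c(105 * sr, 135 * sc); pv_r <- 28 * min(sr, sc); pv_lumen <- 5 * min(sr, sc)
  list(epi_rows = epi_rows, basal_top = basal_top,
       fol = fol, tum_c = tum_c, tum_r = tum_r,
       pv_c = pv_c, pv_r = pv_r, pv_lumen = pv_lumen)
}

layout_regions <- function(config) {
  lay <- tissue_layout(config)
  C <- config$grid_ncol
  region_annotation(list(
    list(class = "epidermis", id = "epidermis1",
         coords = rect_polygon(lay$epi_rows[1], lay$epi_rows[2], 1, C)),
    list(class = "tumor_core", id = "tumor1",
         coords = circle_polygon(lay$tum_c, lay$tum_r)),
    list(class = "perivascular", id = "perivascular1",
         coords = circle_polygon(lay$pv_c, lay$pv_r)),
    list(class = "follicle", id = "follicle1",
         coords = rect_polygon(lay$fol[1], lay$fol[2], lay$fol[3], lay$fol[4]))
  ))
}

# candidate bin centers for each cell type, as an n x 2 matrix
region_candidates <- function(config, type) {
  lay <- tissue_layout(config)
  R <- config$grid_nrow; C <- config$grid_ncol
  pad <- config$cell_radius[2] + 1
  grid <- expand.grid(row = seq(pad, R - pad), col = seq(pad, C - pad))
  rr <- grid$row; cc <- grid$col
  keep <- switch(type,
    epiMCC = rr >= lay$epi_rows[1] + 2 & rr <= lay$epi_rows[2] - 2,
    sbK    = rr >= lay$epi_rows[1] + 1 & rr < lay$basal_top,
    bK     = rr >= lay$basal_top & rr <= lay$epi_rows[2] - 1,
    cMCC   = (rr - lay$tum_c[1])^2 + (cc - lay$tum_c[2])^2 <= (lay$tum_r - 2)^2,
    vasMCC = {
      d2 <- (rr - lay$pv_c[1])^2 + (cc - lay$pv_c[2])^2
      d2 <= (lay$pv_r - 2)^2 & d2 >= (lay$pv_lumen + 1)^2
    },
    other  = rr >= lay$fol[1] + 1 & rr <= lay$fol[2] - 1 &
             cc >= lay$fol[3] + 1 & cc <= lay$fol[4] - 1,
    stop("unknown type ", type))
  as.matrix(grid[keep, , drop = FALSE])
}

# random sequential placement with a global minimum center separation
place_cells <- function(config) {
  min_sep2 <- (2 * config$cell_radius[2] + 1)^2
  placed <- matrix(numeric(0), ncol = 2)
  out <- list()
  for (type in names(config$n_cells)) {
    n <- config$n_cells[[type]]
    if (n == 0) next
    cand <- region_candidates(config, type)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    got <- 0L; i <- 1L
    centers <- matrix(NA_real_, nrow = n, ncol = 2)
    while (got < n && i <= nrow(cand)) {
      p <- cand[i, ]; i <- i + 1L
      if (nrow(placed) == 0 ||
          min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) >= min_sep2) {
        got <- got + 1L
        centers[got, ] <- p
        placed <- rbind(placed, p)
      }
    }
    if (got < n)
      stop(sprintf("sizing error: grid too small to place %d '%s' cells (placed %d)",
                   n, type, got))
    out[[type]] <- centers
  }
  out
}

#' Generate synthetic tissue geometry and ground truth
#'
#' Lays out a synthetic skin section on the configured bin lattice: an
#' epidermis band holding suprabasal and basal keratinocytes plus
#' intraepidermal tumor nests (epiMCC), a dermal tumor nodule (cMCC), a
#' perivascular ring (vasMCC) and a hair follicle (follicular cells, type
#' `other`). Every cell receives a compact nuclear seed (disk of radius 1
#' bin) in the returned label image; cell footprints (used later to split
#' counts over bins) are disks of the per-cell radius around the same
#' centers.
#'
#' @param config a [sim_config()].
#' @return list with `label_image` (integer matrix, 0 = unlabeled),
#'   `regions` ([region_annotation()]), and `truth` (class `ground_truth`:
#'   per-cell data frame `cells` with id/type/center/radius, the gene x type
#'   `program_effects` matrix, a `dropout_mask` slot filled by the count
#'   generators, and the seed).
#' @export
generate_spatial_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1), {
    img <- matrix(0L, nrow = config$grid_nrow, ncol = config$grid_ncol)
    total <- sum(config$n_cells)
    if (total == 0) {
      truth <- ground_truth(
        cells = data.frame(cell_id = integer(0), type = character(0),
                           row = integer(0), col = integer(0),
                           radius = integer(0)),
        program_effects = program_effects_matrix(config), seed = config$seed)
      return(list(label_image = img, regions = layout_regions(config),
                  truth = truth))
    }
    centers <- place_cells(config)
    cells <- do.call(rbind, lapply(names(centers), function(type) {
      data.frame(type = type, row = centers[[type]][, 1],
                 col = centers[[type]][, 2])
    }))
    cells$cell_id <- seq_len(nrow(cells))
    cells$radius <- sample(seq(config$cell_radius[1], config$cell_radius[2]),
                           nrow(cells), replace = TRUE)
    cells <- cells[, c("cell_id", "type", "row", "col", "radius")]
    # nuclear seeds: disk of radius 1 (plus-shape, 5 bins)
    seed_off <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    for (i in seq_len(nrow(cells))) {
      rr <- cells$row[i] + seed_off[, 1]
      cc <- cells$col[i] + seed_off[, 2]
      ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
      img[cbind(rr[ok], cc[ok])] <- cells$cell_id[i]
    }
    truth <- ground_truth(cells = cells,
                          program_effects = program_effects_matrix(config),
                          seed = config$seed)
    list(label_image = img, regions = layout_regions(config), truth = truth)
  })
}

ground_truth <- function(cells, program_effects, dropout_mask = NULL, seed = NA) {
  structure(list(cells = cells, program_effects = program_effects,
                 dropout_mask = dropout_mask, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$cells), "cells; types:",
      paste(names(table(x$cells$type)), table(x$cells$type), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# disk offsets of integer radius r (Euclidean)
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE])
}

# per-cell negative binomial draws: cells x genes integer matrix
draw_cell_counts <- function(types, mean_umis, config) {
  W <- type_weights(config)
  n <- length(types)
  counts <- matrix(0L, nrow = n, ncol = config$n_genes,
                   dimnames = list(NULL, config$genes))
  for (i in seq_len(n)) {
    mu <- mean_umis[[types[i]]] * W[, types[i]]
    counts[i, ] <- if (is.finite(config$dispersion))
      stats::rnbinom(config$n_genes, mu = mu, size = config$dispersion)
    else stats::rpois(config$n_genes, mu)
  }
  counts
}

# apply technical dropout in place; returns list(counts, mask)
apply_dropout <- function(counts, rate) {
  mask <- matrix(FALSE, nrow = nrow(counts), ncol = ncol(counts),
                 dimnames = dimnames(counts))
  if (rate > 0) {
    pos <- which(counts > 0)
    drop <- pos[stats::runif(length(pos)) < rate]
    mask[drop] <- TRUE
    counts[drop] <- 0L
  }
  list(counts = counts, mask = mask)
}

#' Generate binned spatial counts from tissue ground truth
#'
#' Draws each cell's gene counts from the negative-binomial model (mean =
#' type library size x type gene proportion, shared dispersion), then splits
#' every gene's count multinomially (uniform) over the bins of the cell's
#' footprint, so that summing a cell's bins recovers its pre-split draw
#' exactly. Bins outside any footprint receive ambient Poisson background at
#' `config$ambient_lambda` per gene.
#'
#' @param label_image integer label matrix from [generate_spatial_truth()]
#'   (used for grid geometry; footprints come from `truth`).
#' @param truth `ground_truth` from [generate_spatial_truth()].
#' @param config the same [sim_config()].
#' @return a [bin_grid()]; attribute `cell_counts` holds the pre-split
#'   cell x gene draws (after dropout), and `truth` is returned updated with
#'   the dropout mask via attribute `truth`.
#' @export
generate_bin_counts <- function(label_image, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  cells <- truth$cells
  with_seed(derive_seed(config$seed, 2), {
    cc_draw <- draw_cell_counts(cells$type, config$mean_umis, config)
    dd <- apply_dropout(cc_draw, config$dropout_rate)
    cell_counts <- dd$counts
    R <- nrow(label_image); C <- ncol(label_image)
    occupied <- matrix(FALSE, R, C)
    rows_i <- list(); cols_i <- list(); vals_i <- list(); bins_i <- list()
    bin_coord <- list()
    nbin_total <- 0L
    for (i in seq_len(nrow(cells))) {
      off <- disk_offsets(cells$radius[i])
      rr <- cells$row[i] + off[, 1]; cc2 <- cells$col[i] + off[, 2]
      ok <- rr >= 1 & rr <= R & cc2 >= 1 & cc2 <= C
      rr <- rr[ok]; cc2 <- cc2[ok]
      occupied[cbind(rr, cc2)] <- TRUE
      B <- length(rr)
      bin_ids <- nbin_total + seq_len(B)
      bin_coord[[i]] <- cbind(rr, cc2)
      nbin_total <- nbin_total + B
      x <- cell_counts[i, ]
      nz <- which(x > 0)
      if (length(nz)) {
        split <- vapply(x[nz], function(n)
          stats::rmultinom(1, n, rep(1 / B, B))[, 1], numeric(B))
        if (B == 1) split <- matrix(split, nrow = 1)
        idx <- which(split > 0, arr.ind = TRUE)
        rows_i[[i]] <- bin_ids[idx[, 1]]
        cols_i[[i]] <- nz[idx[, 2]]
        vals_i[[i]] <- split[idx]
      }
    }
    coords <- if (nbin_total) do.call(rbind, bin_coord) else
      matrix(integer(0), ncol = 2)
    # ambient background on unoccupied bins
    amb_rows <- integer(0); amb_cols <- integer(0); amb_vals <- numeric(0)
    if (config$ambient_lambda > 0) {
      free <- which(!occupied, arr.ind = TRUE)
      tot <- stats::rpois(nrow(free), config$ambient_lambda * config$n_genes)
      hot <- which(tot > 0)
      if (length(hot)) {
        coords <- rbind(coords, free[hot, , drop = FALSE])
        for (k in seq_along(hot)) {
          g <- sample.int(config$n_genes, tot[hot[k]], replace = TRUE)
          tb <- table(g)
          amb_rows <- c(amb_rows, rep(nbin_total + k, length(tb)))
          amb_cols <- c(amb_cols, as.integer(names(tb)))
          amb_vals <- c(amb_vals, as.numeric(tb))
        }
      }
    }
    counts <- Matrix::sparseMatrix(
      i = c(unlist(rows_i), amb_rows),
      j = c(unlist(cols_i), amb_cols),
      x = c(unlist(vals_i), amb_vals),
      dims = c(nrow(coords), config$n_genes),
      dimnames = list(NULL, config$genes))
    grid <- bin_grid(coords, counts, gene_ids = config$genes)
    attr(grid, "cell_counts") <- cell_counts
    truth$dropout_mask <- dd$mask
    attr(grid, "truth") <- truth
    grid
  })
}

#' Generate a synthetic single-cell RNA-seq dataset
#'
#' Draws dissociated cells from the same negative-binomial expression model
#' as the spatial generator, at single-cell depth. Planted identities follow
#' the gating marker logic: epiMCC cells express CCER2, KRT5 and
#' CALML3/CALML5; cMCC cells express CCER2 and KRT20 with no KRT5 or
#' collagen genes; vasMCC cells express CCER2, KRT20 and COL1A1/COL3A1;
#' `other` cells carry no tumor identity.
#'
#' @param config a [sim_config()]; fields `sc_n_cells` and `sc_mean_umis`
#'   control size and depth.
#' @return list with `cells` (a [cell_matrix()] of raw counts) and `truth`
#'   (a `ground_truth` with the planted types and dropout mask).
#' @export
generate_scrnaseq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rule_genes <- unique(unlist(lapply(default_gating_rules(), function(r)
    all.vars(str2lang(r$expr)))))
  missing <- setdiff(rule_genes, config$genes)
  if (length(missing))
    stop("config error: gating marker genes missing from gene universe: ",
         paste(missing, collapse = ", "))
  with_seed(derive_seed(config$seed, 3), {
    types <- rep(names(config$sc_n_cells), config$sc_n_cells)
    eff <- program_effects_matrix(config)
    if (length(types) == 0) {
      cells <- cell_matrix(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0),
                                                dims = c(0, config$n_genes),
                                                dimnames = list(NULL, config$genes)),
                           sample_id = character(0))
      return(list(cells = cells,
                  truth = ground_truth(
                    cells = data.frame(cell_id = integer(0), type = character(0)),
                    program_effects = eff, seed = config$seed)))
    }
    types <- sample(types)  # shuffle so order carries no information
    mean_umis <- stats::setNames(rep(config$sc_mean_umis, length(config$n_cells)),
                                 names(config$n_cells))
    counts <- draw_cell_counts(types, mean_umis, config)
    dd <- apply_dropout(counts, config$dropout_rate)
    cm <- cell_matrix(dd$counts, sample_id = "sc1")
    truth <- ground_truth(
      cells = data.frame(cell_id = seq_along(types), type = types),
      program_effects = eff, dropout_mask = dd$mask, seed = config$seed)
    list(cells = cm, truth = truth)
  })
}
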