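# Shared fixtures, built in code at test time.

# small, fast spatial config: fewer cells, smaller grid, no ambient noise
small_sim_config <- function(seed = 1, ambient = 0, ...) {
  sim_config(grid_nrow = 80, grid_ncol = 100,
             n_cells = c(epiMCC = 12, cMCC = 15, vasMCC = 10,
                         bK = 8, sbK = 8, other = 6),
             n_genes = 120, ambient_lambda = ambient, seed = seed, ...)
}

# tiny cell_matrix from a dense count matrix with gene names
toy_cells <- function(counts, genes = colnames(counts), ...) {
  colnames(counts) <- genes
  cell_matrix(counts, ...)
}

# brute-force nearest-seed label expansion (independent oracle)
oracle_expand <- function(img, d_max) {
  out <- img
  seeds <- which(img > 0, arr.ind = TRUE)
  if (nrow(seeds) == 0) return(out)
  labs <- img[seeds]
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (img[r, c] != 0) next
    d2 <- (seeds[, 1] - r)^2 + (seeds[, 2] - c)^2
    ok <- d2 <= d_max^2
    if (any(ok)) {
      dmin <- min(d2[ok])
      cand <- labs[ok & d2 == dmin]
      out[r, c] <- min(cand)
    }
  }
  out
}

# brute-force even-odd point-in-polygon with smallest-area tie-break
oracle_assign <- function(pts, polys) {
  pip <- function(pr, pc, poly) {
    n <- nrow(poly); inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      ar <- poly[j, 1]; ac <- poly[j, 2]; br <- poly[k, 1]; bc <- poly[k, 2]
      # boundary: collinear and within the segment's bounding box
      cr <- (br - ar) * (pc - ac) - (bc - ac) * (pr - ar)
      if (abs(cr) < 1e-9 &&
          pr >= min(ar, br) - 1e-9 && pr <= max(ar, br) + 1e-9 &&
          pc >= min(ac, bc) - 1e-9 && pc <= max(ac, bc) + 1e-9) return(TRUE)
      if ((ac > pc) != (bc > pc) &&
          pr < ar + (pc - ac) / (bc - ac) * (br - ar)) inside <- !inside
      j <- k
    }
    inside
  }
  area <- function(poly) {
    n <- nrow(poly); j <- c(n, seq_len(n - 1))
    abs(sum(poly[j, 1] * poly[, 2] - poly[, 1] * poly[j, 2])) / 2
  }
  out <- rep(NA_character_, nrow(pts))
  best <- rep(Inf, nrow(pts))
  for (p in polys) {
    a <- area(p$coords)
    for (i in seq_len(nrow(pts))) {
      if (a < best[i] && pip(pts[i, 1], pts[i, 2], p$coords)) {
        out[i] <- p$class; best[i] <- a
      }
    }
  }
  out
}

# rank-5 signal plus tiny i.i.d. noise, for spectral rank selection
planted_rank5_matrix <- function(seed = 12) {
  set.seed(seed)
  u <- qr.Q(qr(matrix(stats::rnorm(100 * 5), 100, 5)))
  v <- qr.Q(qr(matrix(stats::rnorm(60 * 5), 60, 5)))
  u %*% diag(c(50, 40, 30, 20, 10)) %*% t(v) +
    matrix(stats::rnorm(100 * 60, sd = 0.01), 100, 60)
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_p <- function(a, b) {
  m <- length(a); N <- m + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * (N - m) / 2
  combos <- utils::combn(N, m)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
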