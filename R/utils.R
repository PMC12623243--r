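## internal helpers shared across modules

# coerce any matrix-like input to dgCMatrix (general, column-sparse, double)
as_dgc <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(x, "generalMatrix")
  x <- methods::as(x, "CsparseMatrix")
  methods::as(x, "dMatrix")
}

# seeded evaluation that restores the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# derive a stream-specific 32-bit seed from a base seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
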