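# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of
# (arguments, seed).
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and an index, staying inside the
# 32-bit integer range R requires for set.seed().
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + index * 1117) %% 2147483647
}

fisher_z <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  atanh(r)
}

fisher_z_inv <- function(z) tanh(z)

is_square_matrix <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is_square_matrix(m)) {
    stop(sprintf("%s must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("%s must be symmetric", name), call. = FALSE)
  }
  invisible(TRUE)
}

upper_tri_index <- function(n) which(upper.tri(matrix(0, n, n)))

default_region_labels <- function(n) sprintf("R%03d", seq_len(n))
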