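# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed` must be a single finite integer-like value.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Canonical ordering of the six unique symmetric-tensor components used
# throughout the package: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
TENSOR_COMPONENTS <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")

# 3x3 symmetric matrix -> length-6 component vector (canonical order).
tensor_to_vec <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# length-6 component vector -> 3x3 symmetric matrix.
vec_to_tensor <- function(v) {
  matrix(c(
    v[1], v[4], v[5],
    v[4], v[2], v[6],
    v[5], v[6], v[3]
  ), nrow = 3, byrow = TRUE)
}
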