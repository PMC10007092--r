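# Small internal numerics shared across modules.

.lrelu <- function(x, alpha) pmax(x, 0) + alpha * pmin(x, 0)

# Subgradient at 0 taken as alpha (deterministic, matches the negative branch).
.lrelu_grad <- function(x, alpha) (x > 0) + alpha * (x <= 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.assert_finite_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

# Kaiming-uniform initialization: U(-sqrt(6/fan_in), sqrt(6/fan_in)).
.kaiming <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

# Broadcast an (r, c, 1, n) array across `L` entries of the third axis.
.bcast3 <- function(m, L) {
  d <- dim(m)
  aperm(array(m, c(d[1], d[2], d[4], L)), c(1L, 2L, 4L, 3L))
}
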