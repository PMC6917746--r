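# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
vec_norm <- function(x) sqrt(sum(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# wrap angles to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

is_orthonormal <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !all(is.finite(R))) {
    return("not a finite 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) return("R'R != I")
  if (abs(det(R) - 1) > sqrt(tol)) return("det(R) != +1")
  TRUE
}

# Evaluate per-cell reproducible RNG substream: runs `expr` under a seed
# derived from (seed, counter) and restores the caller's RNG state, so output
# for cell i is invariant to how many other cells are simulated.
with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  sub <- (as.double(seed) * 1000003 + as.double(counter) * 7919) %% 2147483647
  set.seed(as.integer(sub))
  expr
}

# deterministic moving-average smoother (odd window), edges truncated
moving_average <- function(x, width = 5L) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- width %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(x[j])
  }
  out
}
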