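# Internal helpers shared across modules.

# mg L^-1 -> kg m^-3 (and back); exact conversion, applied only at module
# boundaries. Internally the reaction-diffusion model works in kg m^-3, m, h.
MGL_TO_KGM3 <- 1e-3
UM_TO_M <- 1e-6

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a run-level seed
#' @noRd
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 101L + as.integer(offset)) %% 2147483629L
}

#' Solve a tridiagonal linear system (Thomas algorithm)
#'
#' @param lower subdiagonal (length n-1), `diag` main diagonal (length n),
#'   `upper` superdiagonal (length n-1), `rhs` right-hand side.
#' Works for real and complex inputs.
#' @noRd
solve_tridiag <- function(lower, diagonal, upper, rhs) {
  n <- length(diagonal)
  cp <- vector(mode(diagonal), n)
  dp <- vector(mode(rhs), n)
  cp[1] <- upper[1] / diagonal[1]
  dp[1] <- rhs[1] / diagonal[1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m <- diagonal[i] - lower[i - 1] * cp[i - 1]
      cp[i] <- upper[i] / m
      dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
    }
  }
  m <- diagonal[n] - lower[n - 1] * cp[n - 1]
  dp[n] <- (rhs[n] - lower[n - 1] * dp[n - 1]) / m
  x <- dp
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Complex-step derivative of a scalar-or-vector valued function
#'
#' Computes f'(x) as Im(f(x + i h))/h. For analytic f this is accurate to
#' machine precision because no subtractive cancellation occurs.
#'
#' @param f function of a single numeric argument; must accept complex input.
#' @param x point at which to differentiate.
#' @param h imaginary step size (default 1e-20).
#' @return numeric derivative, same shape as `f(x)`.
#' @export
#' @examples
#' complex_step_derivative(function(x) x^3 + sin(x), 1.2)
complex_step_derivative <- function(f, x, h = 1e-20) {
  Im(f(x + 1i * h)) / h
}

#' Piecewise-linear interpolation with flat extrapolation
#' @noRd
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

stop_pellet <- function(...) stop(sprintf(...), call. = FALSE)
warn_pellet <- function(...) warning(sprintf(...), call. = FALSE)
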