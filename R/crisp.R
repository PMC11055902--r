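#' Crisp population recursion
#'
#' The real-valued counterpart of the fuzzy model (and the recursion each
#' endpoint obeys under Case I):
#' `y[n+1] = p + a*y[n] + y[n]/(y[n-1]*y[n-2])`.
#'
#' @param p Process-error parameter, > 0.
#' @param a Threshold-density parameter, >= 0.
#' @param y_init Three positive initial values `(y[-2], y[-1], y[0])`.
#' @param n_steps Number of steps.
#' @param guard Divergence guard (default 1e12); exceeding it stops the
#'   run and sets the `"diverged"` attribute.
#' @return Numeric vector of iterates named by index `-2, -1, 0, 1, ...`.
#' @examples
#' simulate_crisp(1.75, 0.25, c(1, 1, 1), 2) # ends 3.0, 5.5
#' @export
simulate_crisp <- function(p, a, y_init, n_steps, guard = 1e12) {
  stopifnot(p > 0, a >= 0, length(y_init) == 3L, all(y_init > 0),
            n_steps >= 1)
  y <- c(y_init, numeric(n_steps))
  diverged <- FALSE
  n_done <- n_steps
  for (k in seq_len(n_steps)) {
    i <- k + 2L
    y[i + 1L] <- p + a * y[i] + y[i] / (y[i - 1L] * y[i - 2L])
    if (!is.finite(y[i + 1L]) || y[i + 1L] > guard) {
      diverged <- TRUE; n_done <- k; break
    }
  }
  y <- y[seq_len(n_done + 3L)]
  names(y) <- seq.int(-2L, n_done)
  attr(y, "diverged") <- diverged
  y
}

#' Coupled crisp system of the Case II endpoint recursions
#'
#' `y[n+1] = p + a*y[n] + z[n]/(z[n-1]*z[n-2])`,
#' `z[n+1] = q + b*z[n] + y[n]/(y[n-1]*y[n-2])` — the system the left and
#' right endpoints jointly satisfy at one alpha level under Case II, with
#' `(p, a) = (A_l, B_l)` and `(q, b) = (A_r, B_r)`.
#'
#' @param p,a,q,b Positive parameters (`a`, `b` in \[0, 1) for bounded
#'   dynamics).
#' @param y_init,z_init Three positive initial values each.
#' @inheritParams simulate_crisp
#' @return A two-column matrix `(y, z)` with rows indexed `-2, -1, 0, ...`
#'   and a `"diverged"` attribute.
#' @export
simulate_coupled_case2 <- function(p, a, q, b, y_init, z_init, n_steps,
                                   guard = 1e12) {
  stopifnot(p > 0, q > 0, a >= 0, b >= 0,
            length(y_init) == 3L, length(z_init) == 3L,
            all(y_init > 0), all(z_init > 0), n_steps >= 1)
  y <- c(y_init, numeric(n_steps))
  z <- c(z_init, numeric(n_steps))
  diverged <- FALSE
  n_done <- n_steps
  for (k in seq_len(n_steps)) {
    i <- k + 2L
    y[i + 1L] <- p + a * y[i] + z[i] / (z[i - 1L] * z[i - 2L])
    z[i + 1L] <- q + b * z[i] + y[i] / (y[i - 1L] * y[i - 2L])
    if (max(y[i + 1L], z[i + 1L]) > guard ||
        !all(is.finite(c(y[i + 1L], z[i + 1L])))) {
      diverged <- TRUE; n_done <- k; break
    }
  }
  keep <- seq_len(n_done + 3L)
  out <- cbind(y = y[keep], z = z[keep])
  rownames(out) <- seq.int(-2L, n_done)
  attr(out, "diverged") <- diverged
  out
}

#' Crisp simulation of the generalized population family
#'
#' `x[n+1] = A + B*x[n] + C*x[n]/(D + prod_k x[n-k]^p_k)` for `k = 1..m`.
#' With `C = 1, D = 0, m = 2, p_1 = p_2 = 1` this reduces exactly to
#' [simulate_crisp()]; with `B = 0, D = 1, m = 1, p_1 = d` it is the
#' classical density-dependent map `f(u) = a + c*u/(1 + u^d)`.
#' Only the crisp dynamics of this generalization are supported.
#'
#' @param A,B,D Nonnegative reals; `C` positive.
#' @param C Positive real.
#' @param p_k Positive exponents, length `m` (the delay).
#' @param inits `m + 1` positive initial values `(x[-m], ..., x[0])`.
#' @inheritParams simulate_crisp
#' @return Numeric vector of iterates named by index `-m, ..., 0, 1, ...`
#'   with a `"diverged"` attribute.
#' @export
simulate_gfbqp_crisp <- function(A, B, C, D, p_k, inits, n_steps,
                                 guard = 1e12) {
  m <- length(p_k)
  stopifnot(m >= 1, all(p_k > 0), C > 0, A >= 0, B >= 0, D >= 0,
            length(inits) == m + 1L, all(inits > 0), n_steps >= 1)
  x <- c(inits, numeric(n_steps))
  diverged <- FALSE
  n_done <- n_steps
  for (k in seq_len(n_steps)) {
    i <- k + m # index of x[n] in the storage vector
    den <- D + prod(x[i - seq_len(m)]^p_k)
    x[i + 1L] <- A + B * x[i] + C * x[i] / den
    if (!is.finite(x[i + 1L]) || x[i + 1L] > guard) {
      diverged <- TRUE; n_done <- k; break
    }
  }
  x <- x[seq_len(n_done + m + 1L)]
  names(x) <- seq.int(-m, n_done)
  attr(x, "diverged") <- diverged
  x
}
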