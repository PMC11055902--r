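#' Crisp equilibrium of the population recursion
#'
#' The unique positive fixed point of `y = p + a*y + 1/y`:
#' `ybar = (p + sqrt(p^2 + 4(1-a))) / (2(1-a))`.
#'
#' @param p Process-error parameter, > 0.
#' @param a Threshold-density parameter in \[0, 1).
#' @return The equilibrium value (scalar).
#' @examples
#' crisp_equilibrium_case1(1.75, 0.25) # 2.8081
#' @export
crisp_equilibrium_case1 <- function(p, a) {
  stopifnot(p > 0)
  if (a >= 1) stop("`a` must be < 1 for a positive equilibrium")
  (p + sqrt(p^2 + 4 * (1 - a))) / (2 * (1 - a))
}

#' Fuzzy equilibrium under Case I
#'
#' Under Case I the endpoint recursions decouple, so the equilibrium
#' endpoints at each level are the crisp equilibria of the two decoupled
#' recursions: `x_l = (A_l + sqrt(A_l^2 + 4(1-B_l)))/(2(1-B_l))` and the
#' analogous right form.
#'
#' @param A,B Positive fuzzy parameters on one grid; every endpoint of `B`
#'   must be < 1.
#' @return A list of class `"fbqp_equilibrium"` with `kind = "fuzzy_case1"`
#'   and `value`, a validated `"fuzzy_number"`.
#' @export
fuzzy_equilibrium_case1 <- function(A, B) {
  if (!same_grid(A, B)) stop_grid_mismatch()
  if (any(B$right >= 1)) stop("all endpoints of B must be < 1")
  eq <- fuzzy_number(A$alpha,
                     crisp_equilibrium_case1_vec(A$left, B$left),
                     crisp_equilibrium_case1_vec(A$right, B$right))
  structure(list(kind = "fuzzy_case1", value = eq),
            class = "fbqp_equilibrium")
}

crisp_equilibrium_case1_vec <- function(p, a)
  (p + sqrt(p^2 + 4 * (1 - a))) / (2 * (1 - a))

#' Equilibrium of the coupled Case II system
#'
#' The unique positive solution of `y = p + a*y + 1/z`,
#' `z = q + b*z + 1/y`:
#' `ytil = (pq - (b-a) + sqrt((pq + a - b)^2 + 4pq(1-a))) / (2q(1-a))` and
#' symmetrically for `ztil` with `(p, a)` and `(q, b)` exchanged.
#'
#' @param p,a,q,b Parameters with `p, q > 0` and `a, b` in \[0, 1).
#' @return Named numeric vector `c(y = ytil, z = ztil)`.
#' @examples
#' coupled_equilibrium_case2(1.5, 0.15, 2.0, 0.35) # (2.0728, 3.8192)
#' @export
coupled_equilibrium_case2 <- function(p, a, q, b) {
  stopifnot(p > 0, q > 0)
  if (a >= 1 || b >= 1) stop("`a` and `b` must be < 1")
  y <- (p * q - (b - a) + sqrt((p * q + a - b)^2 + 4 * p * q * (1 - a))) /
    (2 * q * (1 - a))
  z <- (p * q + (b - a) + sqrt((p * q + b - a)^2 + 4 * p * q * (1 - b))) /
    (2 * p * (1 - b))
  c(y = y, z = z)
}

#' Fuzzy equilibrium under Case II
#'
#' Under Case II the endpoints at each level solve the coupled system with
#' `(p, a) = (A_l, B_l)`, `(q, b) = (A_r, B_r)`:
#' `x_l = (B_l - B_r + A_l A_r + sqrt((B_l - B_r + A_l A_r)^2 +
#' 4 A_l A_r (1-B_l))) / (2 A_r (1-B_l))` and the mirrored right form.
#' With crisp `A`, `B` this coincides with [fuzzy_equilibrium_case1()].
#'
#' @inheritParams fuzzy_equilibrium_case1
#' @return A list of class `"fbqp_equilibrium"` with `kind = "fuzzy_case2"`
#'   and `value`, a validated `"fuzzy_number"`.
#' @export
fuzzy_equilibrium_case2 <- function(A, B) {
  if (!same_grid(A, B)) stop_grid_mismatch()
  if (any(B$right >= 1)) stop("all endpoints of B must be < 1")
  s <- A$left * A$right
  dl <- B$left - B$right + s
  dr <- B$right - B$left + s
  xl <- (dl + sqrt(dl^2 + 4 * s * (1 - B$left))) / (2 * A$right * (1 - B$left))
  xr <- (dr + sqrt(dr^2 + 4 * s * (1 - B$right))) / (2 * A$left * (1 - B$right))
  structure(list(kind = "fuzzy_case2",
                 value = fuzzy_number(A$alpha, xl, xr)),
            class = "fbqp_equilibrium")
}

#' @export
print.fbqp_equilibrium <- function(x, ...) {
  cat("<fbqp_equilibrium> kind=", x$kind, "\n", sep = "")
  print(x$value)
  invisible(x)
}

#' Boundedness envelope for the crisp recursion
#'
#' When `0 < a < 1` and `(1-a)p^2 > 1`, all iterates from step 4 onwards
#' satisfy `p < y[n] < p^3/((1-a)p^2 - 1) + y3`, where `y3` is the third
#' iterate (caller-supplied, since tabulated envelopes may substitute an
#' initial value for it).
#'
#' @inheritParams crisp_equilibrium_case1
#' @param y3 The additive constant of the upper bound.
#' @return Named vector `c(lower = p, upper = ...)`.
#' @export
bound_case1 <- function(p, a, y3) {
  stopifnot(p > 0)
  if (a <= 0 || a >= 1) stop("`a` must lie in (0, 1)")
  if ((1 - a) * p^2 <= 1) stop("requires (1 - a) * p^2 > 1")
  c(lower = p, upper = p^3 / ((1 - a) * p^2 - 1) + y3)
}

#' Boundedness envelope for the coupled Case II system
#'
#' For `0 < a, b < 1`, iterates satisfy `p <= y[n] <= c1/(1-a) + y2` and
#' `q <= z[n] <= c2/(1-b) + z2`, with
#' `c1 = p + (1+b)/q + (1+a)/(q^2 p) + 1/(q^3 p^2)` and `c2` the same
#' expression with `(p, a)` and `(q, b)` exchanged.
#'
#' @inheritParams coupled_equilibrium_case2
#' @param y2,z2 Additive constants of the upper bounds (second iterates).
#' @return A list with `c1`, `c2`, `y_bounds` and `z_bounds` (each a
#'   `c(lower, upper)` pair).
#' @export
bounds_case2 <- function(p, a, q, b, y2, z2) {
  stopifnot(p > 0, q > 0)
  if (a <= 0 || a >= 1 || b <= 0 || b >= 1)
    stop("`a` and `b` must lie in (0, 1)")
  c1 <- p + (1 + b) / q + (1 + a) / (q^2 * p) + 1 / (q^3 * p^2)
  c2 <- q + (1 + a) / p + (1 + b) / (p^2 * q) + 1 / (p^3 * q^2)
  list(c1 = c1, c2 = c2,
       y_bounds = c(lower = p, upper = c1 / (1 - a) + y2),
       z_bounds = c(lower = q, upper = c2 / (1 - b) + z2))
}

#' Linearized stability of the crisp equilibrium
#'
#' The linearization of the crisp recursion about its equilibrium is
#' `y[n+1] - (a + G) y[n] + G y[n-1] + G y[n-2] = 0` with
#' `G = 2(1-a)^2 / (p^2 + 2(1-a) + p*sqrt(p^2 + 4(1-a)))` (equivalently
#' `G = 1/ybar^2`). The equilibrium is asymptotically stable when
#' `6(1-a) / (p^2 + 2(1-a) + p*sqrt(p^2 + 4(1-a))) < 1`, i.e.
#' `a + 3G < 1`, which holds in particular whenever `3p^2 > 4(1-a)`.
#'
#' @inheritParams crisp_equilibrium_case1
#' @return A list of class `"fbqp_stability"` with elements `G`,
#'   `criterion` (the value of `6(1-a)/(...)`), `stable`,
#'   `sufficient_3p2` (`3p^2 > 4(1-a)`), and `equilibrium`.
#' @export
linearization_case1 <- function(p, a) {
  stopifnot(p > 0)
  if (a <= 0 || a >= 1) stop("`a` must lie in (0, 1)")
  den <- p^2 + 2 * (1 - a) + p * sqrt(p^2 + 4 * (1 - a))
  G <- 2 * (1 - a)^2 / den
  crit <- 6 * (1 - a) / den
  structure(list(G = G, criterion = crit, stable = crit < 1,
                 sufficient_3p2 = 3 * p^2 > 4 * (1 - a),
                 equilibrium = crisp_equilibrium_case1(p, a)),
            class = "fbqp_stability")
}

#' Weighted-norm stability check of the coupled Case II equilibrium
#'
#' Builds the 6x6 linearization matrix `T` of the coupled system about its
#' equilibrium `(ytil, ztil)` (state `(y[n], y[n-1], y[n-2], z[n], z[n-1],
#' z[n-2])`), picks a weight `eps` in the admissible open interval
#' `( ((1-b)/(1-a) * p^2/q^2)^(1/6), 1 )`, and computes the similarity
#' transform `L = G T G^{-1}` with `G = diag(1, eps, ..., eps^5)` — the
#' weighting under which the off-diagonal quotient entries acquire the
#' factors `1/(eps^3 ztil^2)`, `eps^3/ytil^2`, etc. Stability is
#' certified when the infinity norm of `L` is below 1.
#' Requires `p^2/(1-a) < q^2/(1-b)` (otherwise the interval is empty).
#'
#' @inheritParams coupled_equilibrium_case2
#' @param eps Optional weight in the admissible interval; default is its
#'   midpoint.
#' @return A list of class `"fbqp_stability"` with `T`, `L`, `eps`,
#'   `eps_interval`, `norm` (infinity norm of `L`), `stable`, and
#'   `equilibrium` (the `c(y, z)` pair).
#' @export
jacobian_case2 <- function(p, a, q, b, eps = NULL) {
  stopifnot(p > 0, q > 0)
  if (a <= 0 || a >= 1 || b <= 0 || b >= 1)
    stop("`a` and `b` must lie in (0, 1)")
  lo <- (((1 - b) / (1 - a)) * p^2 / q^2)^(1 / 6)
  if (lo >= 1)
    stop("requires p^2/(1-a) < q^2/(1-b): admissible weight interval is empty")
  if (is.null(eps)) eps <- (lo + 1) / 2
  if (eps <= lo || eps >= 1)
    stop(sprintf("`eps` must lie in (%.6f, 1)", lo))
  yz <- coupled_equilibrium_case2(p, a, q, b)
  y2 <- yz[["y"]]^2; z2 <- yz[["z"]]^2
  T6 <- rbind(
    c(a, 0, 0, 1 / z2, -1 / z2, -1 / z2),
    c(1, 0, 0, 0, 0, 0),
    c(0, 1, 0, 0, 0, 0),
    c(1 / y2, -1 / y2, -1 / y2, b, 0, 0),
    c(0, 0, 0, 1, 0, 0),
    c(0, 0, 0, 0, 1, 0))
  G <- diag(eps^(0:5))
  L <- G %*% T6 %*% solve(G)
  nrm <- max(rowSums(abs(L)))
  structure(list(T = T6, L = L, eps = eps, eps_interval = c(lo, 1),
                 norm = nrm, stable = nrm < 1, equilibrium = yz),
            class = "fbqp_stability")
}

#' @export
print.fbqp_stability <- function(x, ...) {
  if (!is.null(x$G)) {
    cat(sprintf("<fbqp_stability> G = %.5f, criterion = %.5f (%s)\n",
                x$G, x$criterion, if (x$stable) "stable" else "unstable"))
  } else {
    cat(sprintf("<fbqp_stability> eps = %.4f, ||L||_inf = %.5f (%s)\n",
                x$eps, x$norm, if (x$stable) "stable" else "unstable"))
  }
  invisible(x)
}
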