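#' Random scenario inside (or outside) a stability regime
#'
#' Rejection-samples parabolic (center, spread) tuples for `A`, `B` and
#' the three initial values until the named condition set passes
#' ([check_conditions()]), or fails for the `"unstable"` regime.
#' Strict cross-endpoint inequalities are required only at alpha < 1
#' levels, where they are informative (they degenerate to equality at the
#' core; see [check_conditions()]). Deterministic given `seed`.
#'
#' Sampling ranges (centers/spreads, chosen once as representative of each
#' regime): `thm3.3` draws `A` around 0.72–0.92 with small spread and `B`
#' around 0.78–0.95 (the literal regime forces `A < 1`, hence a strong
#' density-dependence `B` to keep the growth conditions alive);
#' `thm3.5` draws `A` in 1.4–2.2 and `B` in 0.10–0.35 with moderate
#' spreads (the worked example's neighbourhood); `"unstable"` draws both
#' parameters small so every growth condition fails.
#'
#' @param regime `"thm3.3"`, `"thm3.5"` or `"unstable"`.
#' @param seed Integer seed.
#' @param grid An [alpha_grid()].
#' @param max_attempts Sampling budget (default 500).
#' @return An [fbqp_scenario()] with an `"attempts"` attribute.
#' @export
random_scenario <- function(regime = c("thm3.3", "thm3.5", "unstable"),
                            seed, grid = alpha_grid(),
                            max_attempts = 500L) {
  regime <- match.arg(regime)
  grid <- as_alpha_grid(grid)
  set.seed(seed)
  draw <- function(c_lo, c_hi, s_lo, s_hi) {
    c(center = stats::runif(1, c_lo, c_hi), spread = stats::runif(1, s_lo, s_hi))
  }
  for (attempt in seq_len(max_attempts)) {
    par <- switch(regime,
      "thm3.3" = list(A = draw(0.72, 0.92, 0.01, 0.05),
                      B = draw(0.78, 0.95, 0.005, 0.03)),
      "thm3.5" = list(A = draw(1.4, 2.2, 0.05, 0.15),
                      B = draw(0.10, 0.35, 0.02, 0.08)),
      "unstable" = list(A = draw(0.10, 0.45, 0.01, 0.05),
                        B = draw(0.05, 0.35, 0.01, 0.05)))
    if (par$A[["center"]] + par$A[["spread"]] >= 0.97 && regime == "thm3.3") next
    if (par$B[["center"]] + par$B[["spread"]] >= 0.99) next
    inits <- replicate(3, draw(0.7, 1.5, 0.05, 0.20), simplify = FALSE)
    sc <- fbqp_scenario(
      A = parabolic_fuzzy_number(par$A[["center"]], par$A[["spread"]], grid),
      B = parabolic_fuzzy_number(par$B[["center"]], par$B[["spread"]], grid),
      x_m2 = parabolic_fuzzy_number(inits[[1]][["center"]], inits[[1]][["spread"]], grid),
      x_m1 = parabolic_fuzzy_number(inits[[2]][["center"]], inits[[2]][["spread"]], grid),
      x_0 = parabolic_fuzzy_number(inits[[3]][["center"]], inits[[3]][["spread"]], grid))
    ok <- switch(regime,
      "thm3.3" = conditions_pass_interior(check_conditions(sc, "thm3.3")),
      "thm3.5" = conditions_pass_interior(check_conditions(sc, "thm3.5")),
      "unstable" = !conditions_pass_interior(check_conditions(sc, "thm3.3")) &&
                   !conditions_pass_interior(check_conditions(sc, "thm3.5")))
    if (ok) {
      attr(sc, "attempts") <- attempt
      attr(sc, "regime") <- regime
      return(sc)
    }
  }
  stop("sampling budget exhausted for regime ", regime)
}

round_half_up <- function(x, digits = 4) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Equilibrium and envelope table for a scenario
#'
#' For each requested alpha level: the exact alpha-cut endpoints of `A`,
#' `B` and the initial values (exact for parabolic/crisp families), the
#' boundedness envelope, and the fuzzy equilibrium endpoints of the
#' requested case. Raw values are returned; the print method displays
#' them rounded half-up to 4 decimals.
#'
#' The envelope columns follow the tabulated convention: under Case I the
#' left envelope is `(A_l, A_l^3/((1-B_l)A_l^2 - 1) + x_{-2,l})` and the
#' right `(A_r, A_r^3/((1-B_r)A_r^2 - 1) + x_{0,r})`; under Case II the
#' additive constants are `x_{0,l}` and `x_{0,r}` with the coupled-system
#' constants `c1`, `c2` of [bounds_case2()].
#'
#' @param scenario An [fbqp_scenario()].
#' @param alphas Levels in \[0, 1\] (default `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param case `"CASE_I"` or `"CASE_II"`.
#' @return A data frame of class `"fbqp_table"`, one row per level, with
#'   columns `alpha`, `A_l`, `A_r`, `B_l`, `B_r`, the six initial
#'   endpoints, `bound_l_lower`, `bound_l_upper`, `bound_r_lower`,
#'   `bound_r_upper`, `eq_l`, `eq_r`, `case`.
#' @export
reproduce_table <- function(scenario, alphas = c(0, 0.25, 0.5, 0.75, 1),
                            case = c("CASE_I", "CASE_II")) {
  case <- match.arg(case)
  stopifnot(inherits(scenario, "fbqp_scenario"),
            all(alphas >= 0 & alphas <= 1))
  cuts <- lapply(scenario, alpha_cut, a = alphas)
  Al <- cuts$A[, "left"]; Ar <- cuts$A[, "right"]
  Bl <- cuts$B[, "left"]; Br <- cuts$B[, "right"]
  if (any(Br >= 1)) stop("equilibrium formulas require B endpoints < 1")
  if (case == "CASE_I") {
    eq_l <- crisp_equilibrium_case1_vec(Al, Bl)
    eq_r <- crisp_equilibrium_case1_vec(Ar, Br)
    bl_up <- Al^3 / ((1 - Bl) * Al^2 - 1) + cuts$x_m2[, "left"]
    br_up <- Ar^3 / ((1 - Br) * Ar^2 - 1) + cuts$x_0[, "right"]
  } else {
    s <- Al * Ar
    dl <- Bl - Br + s
    dr <- Br - Bl + s
    eq_l <- (dl + sqrt(dl^2 + 4 * s * (1 - Bl))) / (2 * Ar * (1 - Bl))
    eq_r <- (dr + sqrt(dr^2 + 4 * s * (1 - Br))) / (2 * Al * (1 - Br))
    c1 <- Al + (1 + Br) / Ar + (1 + Bl) / (Ar^2 * Al) + 1 / (Ar^3 * Al^2)
    c2 <- Ar + (1 + Bl) / Al + (1 + Br) / (Al^2 * Ar) + 1 / (Al^3 * Ar^2)
    bl_up <- c1 / (1 - Bl) + cuts$x_0[, "left"]
    br_up <- c2 / (1 - Br) + cuts$x_0[, "right"]
  }
  out <- data.frame(alpha = alphas,
                    A_l = Al, A_r = Ar, B_l = Bl, B_r = Br,
                    x_m2_l = cuts$x_m2[, "left"], x_m2_r = cuts$x_m2[, "right"],
                    x_m1_l = cuts$x_m1[, "left"], x_m1_r = cuts$x_m1[, "right"],
                    x_0_l = cuts$x_0[, "left"], x_0_r = cuts$x_0[, "right"],
                    bound_l_lower = Al, bound_l_upper = bl_up,
                    bound_r_lower = Ar, bound_r_upper = br_up,
                    eq_l = eq_l, eq_r = eq_r,
                    case = case)
  class(out) <- c("fbqp_table", "data.frame")
  out
}

#' @export
print.fbqp_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Compare g-division and extension-principle evolutions
#'
#' Runs the model under g-division (auto case classification) and under
#' the Zadeh extension-principle quotient from the same scenario, and
#' tabulates per step the support (alpha = 0) widths of both together
#' with the crisp (alpha = 1) trajectory slice. The g-division run can
#' never be wider.
#'
#' @param scenario An [fbqp_scenario()].
#' @param n_steps Number of steps.
#' @return A list with `table` (data frame: `step`, `width_g`,
#'   `width_zadeh`, `crisp`), `terminal_g` and `terminal_zadeh` (fuzzy
#'   numbers), and the two trajectories.
#' @export
compare_division <- function(scenario, n_steps) {
  tg <- fbqp_simulate(scenario, n_steps, mode = "auto")
  tz <- fbqp_simulate(scenario, n_steps, mode = "zadeh")
  m <- length(tg$alpha)
  k <- min(nrow(tg$left), nrow(tz$left))
  tab <- data.frame(step = tg$step[seq_len(k)],
                    width_g = (tg$right[, 1L] - tg$left[, 1L])[seq_len(k)],
                    width_zadeh = (tz$right[, 1L] - tz$left[, 1L])[seq_len(k)],
                    crisp = tg$left[seq_len(k), m])
  list(table = tab,
       terminal_g = trajectory_state(tg, tg$step[length(tg$step)]),
       terminal_zadeh = trajectory_state(tz, tz$step[length(tz$step)]),
       trajectory_g = tg, trajectory_zadeh = tz)
}

#' Eventual stability from multiple starting population levels
#'
#' Simulates the model from several crisp initial population levels
#' (above and below the equilibrium) under the given fuzzy parameters and
#' reports the terminal distance of each run to the case-appropriate
#' fuzzy equilibrium — the "no Allee effect" demonstration: every
#' positive start returns to the same fuzzy equilibrium.
#'
#' @param A,B Positive fuzzy parameters (`B` endpoints < 1).
#' @param init_centers Positive starting levels; each is used for all
#'   three crisp initial values.
#' @param n_steps Steps per run (default 500).
#' @param mode Recursion mode (default `"case1"`).
#' @return A data frame with columns `start`, `terminal_distance`,
#'   `converged` plus an `"equilibrium"` attribute (the reference fuzzy
#'   equilibrium) and a `"trajectories"` attribute (list).
#' @export
multistart_demo <- function(A, B, init_centers, n_steps = 500L,
                            mode = c("case1", "case2", "auto")) {
  mode <- match.arg(mode)
  stopifnot(all(init_centers > 0))
  eq <- if (mode == "case2") fuzzy_equilibrium_case2(A, B)
        else fuzzy_equilibrium_case1(A, B)
  trajs <- lapply(init_centers, function(v) {
    x0 <- crisp_fuzzy_number(v, A$alpha)
    fbqp_simulate(fbqp_scenario(A, B, x0, x0, x0), n_steps, mode = mode)
  })
  d <- vapply(trajs, function(tr)
    unname(utils::tail(trajectory_distance(tr, eq$value), 1L)), numeric(1))
  out <- data.frame(start = init_centers, terminal_distance = d,
                    converged = d < 1e-6)
  attr(out, "equilibrium") <- eq
  attr(out, "trajectories") <- trajs
  out
}
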