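#' Classify the g-division case of a model step
#'
#' The quotient term `x[n] / (x[n-1]*x[n-2])` falls under g-division
#' Case I when `x_{n,l} x_{n-1,r} x_{n-2,r} <= x_{n,r} x_{n-1,l} x_{n-2,l}`
#' at every alpha level, and Case II when the reverse inequality holds at
#' every level. Ties (which always occur at alpha = 1 for single-point
#' cores) are compatible with either case; an all-tie comparison resolves
#' to Case I, and genuinely mixed signs across levels are an error.
#'
#' @param x_n,x_nm1,x_nm2 Positive fuzzy numbers on one grid (current and
#'   two preceding states).
#' @param tol Tie tolerance, default `1e-12` times the product scale.
#' @return `"CASE_I"` or `"CASE_II"`.
#' @export
classify_case <- function(x_n, x_nm1, x_nm2, tol = NULL) {
  if (!same_grid(x_n, x_nm1) || !same_grid(x_n, x_nm2)) stop_grid_mismatch()
  d <- x_n$left * x_nm1$right * x_nm2$right -
       x_n$right * x_nm1$left * x_nm2$left
  if (is.null(tol)) tol <- 1e-12 * max(abs(d), 1)
  # d <= 0 everywhere -> Case I (ties included); d >= 0 with a strict
  # excess somewhere -> Case II; mixed -> error.
  case <- division_case(d, tol)
  if (is.na(case)) {
    stop(sprintf(
      "case classification is not uniform across alpha levels (sign changes at alpha = %s)",
      paste(signif(x_n$alpha[utils::head(which(diff(sign(d)) != 0), 3)], 3),
            collapse = ", ")), call. = FALSE)
  }
  case
}

#' One step of the fuzzy population recursion
#'
#' Advances the per-level endpoint recursions of
#' `x[n+1] = A + B*x[n] + x[n]/(x[n-1]*x[n-2])` under the stated
#' g-division case. Case I decouples the endpoints:
#' `L' = A_l + B_l L + L/(L1 L2)`, `R' = A_r + B_r R + R/(R1 R2)`.
#' Case II cross-assigns the quotient term:
#' `L' = A_l + B_l L + R/(R1 R2)`, `R' = A_r + B_r R + L/(L1 L2)`.
#'
#' @param A,B Fuzzy parameters.
#' @param x_n,x_nm1,x_nm2 Current and two preceding fuzzy states.
#' @param case `"CASE_I"` or `"CASE_II"`.
#' @param check Error on an improper result (default `TRUE`). Forced-case
#'   analyses on data whose actual g-division case differs can transiently
#'   leave the space of proper fuzzy numbers; [fbqp_simulate()] turns this
#'   off in force modes and records per-step validity instead.
#' @return The next fuzzy state (validated when `check = TRUE`).
#' @export
fbqp_step <- function(A, B, x_n, x_nm1, x_nm2, case = c("CASE_I", "CASE_II"),
                      check = TRUE) {
  case <- match.arg(case)
  qL <- x_n$left / (x_nm1$left * x_nm2$left)
  qR <- x_n$right / (x_nm1$right * x_nm2$right)
  if (any(!is.finite(qL)) || any(!is.finite(qR)))
    stop("zero or non-finite denominator in the quotient term")
  if (case == "CASE_I") {
    L <- A$left + B$left * x_n$left + qL
    R <- A$right + B$right * x_n$right + qR
  } else {
    L <- A$left + B$left * x_n$left + qR
    R <- A$right + B$right * x_n$right + qL
  }
  out <- fuzzy_number(x_n$alpha, L, R, check = FALSE)
  if (check) {
    v <- validate_fuzzy_number(out, tol = 1e-10 * max(abs(R), 1))
    if (!v$valid)
      stop("step produced an invalid fuzzy number: ",
           paste(v$messages, collapse = "; "), call. = FALSE)
  }
  out
}

#' Simulate the fuzzy population model
#'
#' Iterates the endpoint recursions for `n_steps` steps. In `"auto"` mode
#' each step is classified by [classify_case()]; `"case1"` and `"case2"`
#' force one recursion throughout (reproducing the two global analyses);
#' `"zadeh"` replaces the g-division quotient with the extension-principle
#' quotient `[L/(R1 R2), R/(L1 L2)]` for comparison. Iterates exceeding
#' `guard` in magnitude stop the run with a divergence flag.
#'
#' Validation: `"auto"` and `"zadeh"` iterates must be proper fuzzy
#' numbers and the run errors otherwise. In the force modes the endpoint
#' systems of the corresponding global analysis are iterated as such;
#' when the data's actual g-division case differs from the forced one the
#' iterates can transiently fail to be proper fuzzy numbers (endpoints
#' cross) before both endpoint sequences settle onto the forced-case
#' equilibrium, so force modes record a per-step `valid` flag instead of
#' erroring.
#'
#' @param scenario An [fbqp_scenario()].
#' @param n_steps Number of steps (>= 1).
#' @param mode One of `"auto"`, `"case1"`, `"case2"`, `"zadeh"`.
#' @param guard Divergence guard on the iterate magnitude (default 1e12).
#' @return An object of class `"fbqp_trajectory"`: list with `alpha`, the
#'   endpoint matrices `left` and `right` (rows indexed n = -2, -1, 0, 1,
#'   ...), `step` (the row indices), `case` (per-step label, `NA` for the
#'   initial rows and for zadeh mode), `valid` (per-row propriety flag),
#'   `mode` and `diverged`.
#' @examples
#' s <- fbqp_example_scenario(alpha_grid(11))
#' tr <- fbqp_simulate(s, 50, mode = "case2")
#' utils::tail(trajectory_distance(tr, fuzzy_equilibrium_case2(s$A, s$B)$value), 1)
#' @export
fbqp_simulate <- function(scenario, n_steps,
                          mode = c("auto", "case1", "case2", "zadeh"),
                          guard = 1e12) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "fbqp_scenario"), n_steps >= 1)
  A <- scenario$A; B <- scenario$B
  alpha <- A$alpha
  m <- length(alpha)
  left <- matrix(NA_real_, nrow = n_steps + 3L, ncol = m)
  right <- matrix(NA_real_, nrow = n_steps + 3L, ncol = m)
  init <- list(scenario$x_m2, scenario$x_m1, scenario$x_0)
  for (j in 1:3) {
    left[j, ] <- init[[j]]$left
    right[j, ] <- init[[j]]$right
  }
  case <- rep(NA_character_, n_steps + 3L)
  valid <- rep(TRUE, n_steps + 3L)
  diverged <- FALSE
  mk <- function(i) fuzzy_number(alpha, left[i, ], right[i, ], check = FALSE)
  n_done <- 0L
  for (k in seq_len(n_steps)) {
    i <- k + 2L # row of x_{n}
    x_n <- mk(i); x_nm1 <- mk(i - 1L); x_nm2 <- mk(i - 2L)
    if (mode == "zadeh") {
      den <- fz_multiply(x_nm1, x_nm2)
      q <- zadeh_divide(x_n, den)
      nxt <- fz_add(fz_add(A, fuzzy_number(alpha, B$left * x_n$left,
                                           B$right * x_n$right,
                                           check = FALSE)), q)
      v <- validate_fuzzy_number(nxt, tol = 1e-10 * max(abs(nxt$right), 1))
      if (!v$valid)
        stop("zadeh-mode step ", k, " produced an invalid fuzzy number",
             call. = FALSE)
      ck <- NA_character_
    } else {
      ck <- switch(mode,
        auto = tryCatch(classify_case(x_n, x_nm1, x_nm2),
                        error = function(e) stop("auto-mode classification failed at step ",
                                                 k, ": ", conditionMessage(e),
                                                 call. = FALSE)),
        case1 = "CASE_I",
        case2 = "CASE_II")
      nxt <- fbqp_step(A, B, x_n, x_nm1, x_nm2, ck, check = (mode == "auto"))
    }
    left[i + 1L, ] <- nxt$left
    right[i + 1L, ] <- nxt$right
    case[i + 1L] <- ck
    valid[i + 1L] <- validate_fuzzy_number(
      nxt, tol = 1e-10 * max(abs(nxt$right), 1))$valid
    n_done <- k
    if (max(abs(nxt$right)) > guard) { diverged <- TRUE; break }
  }
  keep <- seq_len(n_done + 3L)
  structure(list(alpha = as.numeric(alpha),
                 step = seq.int(-2L, n_done),
                 left = left[keep, , drop = FALSE],
                 right = right[keep, , drop = FALSE],
                 case = case[keep],
                 valid = valid[keep],
                 mode = mode,
                 diverged = diverged),
            class = "fbqp_trajectory")
}

#' @export
print.fbqp_trajectory <- function(x, ...) {
  cat("<fbqp_trajectory> mode=", x$mode, ", steps ",
      x$step[1L], "..", x$step[length(x$step)],
      if (x$diverged) " (diverged)" else "", "\n", sep = "")
  invisible(x)
}

#' Fuzzy state of a trajectory at step n
#'
#' @param traj An `"fbqp_trajectory"`.
#' @param n Step index (>= -2).
#' @return A `"fuzzy_number"` (unchecked; consult `traj$valid`).
#' @export
trajectory_state <- function(traj, n) {
  i <- match(n, traj$step)
  if (is.na(i)) stop("step ", n, " not in trajectory")
  fuzzy_number(traj$alpha, traj$left[i, ], traj$right[i, ], check = FALSE)
}

#' Long format of a trajectory
#'
#' One row per (step, alpha level), with columns `step`, `alpha`, `left`,
#' `right`, `case` — the CSV layout used by the writers.
#' @param x An `"fbqp_trajectory"`.
#' @param ... Unused.
#' @export
as.data.frame.fbqp_trajectory <- function(x, ...) {
  m <- length(x$alpha)
  k <- length(x$step)
  data.frame(step = rep(x$step, each = m),
             alpha = rep(x$alpha, times = k),
             left = as.vector(t(x$left)),
             right = as.vector(t(x$right)),
             case = rep(x$case, each = m))
}

#' Distance of each trajectory state to a reference fuzzy number
#'
#' Applies the supremum metric `D` to every stored state.
#'
#' @param traj An `"fbqp_trajectory"`.
#' @param ref A fuzzy number on the same grid.
#' @return Numeric vector of distances, one per stored step (including the
#'   initial states), named by step index.
#' @export
trajectory_distance <- function(traj, ref) {
  if (length(ref$alpha) != length(traj$alpha) ||
      any(ref$alpha != traj$alpha)) stop_grid_mismatch()
  d <- pmax(apply(abs(sweep(traj$left, 2L, ref$left)), 1L, max),
            apply(abs(sweep(traj$right, 2L, ref$right)), 1L, max))
  names(d) <- traj$step
  d
}
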