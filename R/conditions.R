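#' Evaluate the sufficient stability/boundedness condition sets
#'
#' Evaluates, literally as stated, the parameter inequalities of the
#' model's boundedness and convergence results at every alpha level of a
#' scenario. The state-dependent case inequality (which of the two
#' g-division cases the trajectory occupies) is a property of the iterates
#' and is reported per step by [fbqp_simulate()], not here.
#'
#' Condition sets (per level, with `A_l, A_r, B_l, B_r` the alpha-cut
#' endpoints):
#' \describe{
#'   \item{thm3.2 (Case I bounded/persistent)}{`A_r <= A_r0 < 1`;
#'     `(1-B_l) A_l^2 > 1`; `(1-B_r) A_r^2 > 1`.}
#'   \item{thm3.3 (Case I convergence)}{`A_r0 < 1`;
#'     `A_r B_l - A_l B_r < A_r - A_l`; `3 A_l^2 > 4(1-B_l)`;
#'     `3 A_r^2 > 4(1-B_r)`.}
#'   \item{thm3.4 (Case II bounded/persistent)}{`B_r <= B_r0 < 1`.}
#'   \item{thm3.5 (Case II convergence)}{`B_r0 < 1`;
#'     `(1-B_r) A_l^2 < (1-B_l) A_r^2`;
#'     `1 < (1-B_l)(1-B_r) A_l^2 A_r^2`.}
#'   \item{lem3.2}{`0 < B < 1` and `(1-B) A^2 > 1` per endpoint.}
#'   \item{lem3.4}{`0 < B < 1` and `3 A^2 > 4(1-B)` per endpoint.}
#'   \item{lem3.7}{`0 < B < 1`; `(1-B_r) A_l^2 < (1-B_l) A_r^2`;
#'     `1 < (1-B_l)(1-B_r) A_l^2 A_r^2`.}
#' }
#'
#' The first condition of thm3.2/thm3.3 bounds the right endpoint of `A`
#' by 1 even though the remaining conditions push `A` above 1; it is
#' evaluated literally by default. `alternate = TRUE` substitutes the
#' reading that bounds `B` instead (`B_r <= B_r0 < 1`), and the report
#' records which reading was used.
#'
#' Strict cross-endpoint inequalities (thm3.5's second condition and
#' lem3.7's analogue) necessarily degenerate to equality at alpha = 1 when
#' the inputs have single-point cores; the report carries a
#' `degenerate_at_core` marker for those conditions so callers can decide
#' whether the alpha = 1 tie should count against the scenario.
#'
#' @param scenario An [fbqp_scenario()].
#' @param which One of `"thm3.2"`, `"thm3.3"`, `"thm3.4"`, `"thm3.5"`,
#'   `"lem3.2"`, `"lem3.4"`, `"lem3.7"`.
#' @param alternate Use the `B`-bounded reading of the first thm3.2/thm3.3
#'   condition. Default `FALSE` (literal).
#' @return A list of class `"fbqp_conditions"`: `which`, `alternate`,
#'   `alpha`, `conditions` (a named list, each with `description`, `holds`
#'   — a per-level logical vector — and `degenerate_at_core`), and
#'   `overall` (all conditions at all levels).
#' @export
check_conditions <- function(scenario,
                             which = c("thm3.2", "thm3.3", "thm3.4",
                                       "thm3.5", "lem3.2", "lem3.4",
                                       "lem3.7"),
                             alternate = FALSE) {
  which <- match.arg(which)
  stopifnot(inherits(scenario, "fbqp_scenario"))
  Al <- scenario$A$left; Ar <- scenario$A$right
  Bl <- scenario$B$left; Br <- scenario$B$right
  alpha <- scenario$A$alpha
  m <- length(alpha)
  cond <- function(desc, holds, degenerate = FALSE)
    list(description = desc, holds = holds, degenerate_at_core = degenerate)

  a_bound <- if (alternate)
    cond("B_r,alpha <= B_r,0 < 1 (alternate reading)",
         Br <= Br[1L] & Br[1L] < 1)
  else
    cond("A_r,alpha <= A_r,0 < 1 (literal)", Ar <= Ar[1L] & Ar[1L] < 1)

  conditions <- switch(which,
    "thm3.2" = list(
      bound_param = a_bound,
      left_growth = cond("(1-B_l) A_l^2 > 1", (1 - Bl) * Al^2 > 1),
      right_growth = cond("(1-B_r) A_r^2 > 1", (1 - Br) * Ar^2 > 1)),
    "thm3.3" = list(
      bound_param = a_bound,
      mixed = cond("A_r B_l - A_l B_r < A_r - A_l",
                   Ar * Bl - Al * Br < Ar - Al, degenerate = TRUE),
      left_suff = cond("3 A_l^2 > 4(1-B_l)", 3 * Al^2 > 4 * (1 - Bl)),
      right_suff = cond("3 A_r^2 > 4(1-B_r)", 3 * Ar^2 > 4 * (1 - Br))),
    "thm3.4" = list(
      bound_param = cond("B_r,alpha <= B_r,0 < 1",
                         Br <= Br[1L] & Br[1L] < 1)),
    "thm3.5" = list(
      bound_param = cond("B_r,alpha <= B_r,0 < 1",
                         Br <= Br[1L] & Br[1L] < 1),
      ordering = cond("(1-B_r) A_l^2 < (1-B_l) A_r^2",
                      (1 - Br) * Al^2 < (1 - Bl) * Ar^2, degenerate = TRUE),
      product = cond("1 < (1-B_l)(1-B_r) A_l^2 A_r^2",
                     1 < (1 - Bl) * (1 - Br) * Al^2 * Ar^2)),
    "lem3.2" = list(
      b_open = cond("0 < B < 1", Bl > 0 & Br < 1),
      left_growth = cond("(1-B_l) A_l^2 > 1", (1 - Bl) * Al^2 > 1),
      right_growth = cond("(1-B_r) A_r^2 > 1", (1 - Br) * Ar^2 > 1)),
    "lem3.4" = list(
      b_open = cond("0 < B < 1", Bl > 0 & Br < 1),
      left_suff = cond("3 A_l^2 > 4(1-B_l)", 3 * Al^2 > 4 * (1 - Bl)),
      right_suff = cond("3 A_r^2 > 4(1-B_r)", 3 * Ar^2 > 4 * (1 - Br))),
    "lem3.7" = list(
      b_open = cond("0 < B < 1", Bl > 0 & Br < 1),
      ordering = cond("(1-B_r) A_l^2 < (1-B_l) A_r^2",
                      (1 - Br) * Al^2 < (1 - Bl) * Ar^2, degenerate = TRUE),
      product = cond("1 < (1-B_l)(1-B_r) A_l^2 A_r^2",
                     1 < (1 - Bl) * (1 - Br) * Al^2 * Ar^2)))

  structure(list(which = which, alternate = alternate, alpha = alpha,
                 conditions = conditions,
                 overall = all(vapply(conditions,
                                      function(cc) all(cc$holds), logical(1)))),
            class = "fbqp_conditions")
}

#' Overall pass ignoring degenerate core-level ties
#'
#' Like the report's `overall` flag, but strict cross-endpoint conditions
#' (marked `degenerate_at_core`) are evaluated only at alpha < 1 levels:
#' at the core they reduce to `0 < 0` for single-point-core inputs and
#' carry no information.
#'
#' @param report An `"fbqp_conditions"` report.
#' @return Logical.
#' @export
conditions_pass_interior <- function(report) {
  m <- length(report$alpha)
  all(vapply(report$conditions, function(cc) {
    h <- cc$holds
    if (cc$degenerate_at_core && length(h) == m) h <- h[-m]
    all(h)
  }, logical(1)))
}

#' @export
print.fbqp_conditions <- function(x, ...) {
  cat("<fbqp_conditions> ", x$which,
      if (x$alternate) " (alternate reading)", "\n", sep = "")
  for (nm in names(x$conditions)) {
    cc <- x$conditions[[nm]]
    n_fail <- sum(!cc$holds)
    cat(sprintf("  [%s] %-38s %s\n", if (n_fail == 0) "ok" else "FAIL",
                cc$description,
                if (n_fail == 0) "" else sprintf("(%d level(s) fail)", n_fail)))
  }
  cat("  overall:", if (x$overall) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Serialize a condition or stability report to JSON
#'
#' @param x An `"fbqp_conditions"` or `"fbqp_stability"` object.
#' @return A JSON string.
#' @export
report_to_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
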