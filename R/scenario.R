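#' Model scenario: fuzzy parameters and initial population sizes
#'
#' Bundles the five fuzzy inputs of the population recursion
#' `x[n+1] = A + B*x[n] + x[n]/(x[n-1]*x[n-2])`: the process-error
#' parameter `A`, the threshold-density parameter `B`, and the three
#' initial population sizes `x[-2]`, `x[-1]`, `x[0]`. All must be positive
#' fuzzy numbers on one shared alpha grid.
#'
#' @param A,B Positive fuzzy parameters.
#' @param x_m2,x_m1,x_0 Positive fuzzy initial values (indices -2, -1, 0).
#' @return An object of class `"fbqp_scenario"`.
#' @seealso [fbqp_example_scenario()], [random_scenario()], [fbqp_simulate()]
#' @export
fbqp_scenario <- function(A, B, x_m2, x_m1, x_0) {
  members <- list(A = A, B = B, x_m2 = x_m2, x_m1 = x_m1, x_0 = x_0)
  for (nm in names(members)) {
    m <- members[[nm]]
    if (!inherits(m, "fuzzy_number")) stop(nm, " is not a fuzzy_number")
    v <- validate_fuzzy_number(m)
    if (!v$valid) stop(nm, " is invalid: ", paste(v$messages, collapse = "; "))
    if (!v$positive) stop(nm, " must be a positive fuzzy number")
    if (!same_grid(A, m)) stop(nm, " is not on the same alpha grid as A")
  }
  structure(members, class = "fbqp_scenario")
}

#' Reference scenario with parabolic fuzzy inputs
#'
#' The worked demonstration scenario: all five inputs are symmetric
#' parabolic fuzzy numbers, `A = parabolic(1.75, 0.25)` (supp \[1.5, 2\]),
#' `B = parabolic(0.25, 0.1)` (supp \[0.15, 0.35\]), and unit-centered
#' initial sizes with growing ambiguity,
#' `x[-2] = parabolic(1, 0.25)`, `x[-1] = parabolic(1, 0.35)`,
#' `x[0] = parabolic(1, 0.45)`.
#'
#' @param grid An [alpha_grid()].
#' @return An `"fbqp_scenario"`.
#' @export
fbqp_example_scenario <- function(grid = alpha_grid()) {
  grid <- as_alpha_grid(grid)
  fbqp_scenario(
    A = parabolic_fuzzy_number(1.75, 0.25, grid),
    B = parabolic_fuzzy_number(0.25, 0.10, grid),
    x_m2 = parabolic_fuzzy_number(1, 0.25, grid),
    x_m1 = parabolic_fuzzy_number(1, 0.35, grid),
    x_0 = parabolic_fuzzy_number(1, 0.45, grid))
}

#' @export
print.fbqp_scenario <- function(x, ...) {
  cat("<fbqp_scenario> on", length(x$A$alpha), "alpha levels\n")
  for (nm in names(x)) {
    s <- fz_support(x[[nm]])
    cat(sprintf("  %-4s supp [%.4f, %.4f]\n", nm, s[1L], s[2L]))
  }
  invisible(x)
}
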