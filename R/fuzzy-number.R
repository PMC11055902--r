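#' Fuzzy numbers as alpha-cut endpoint families
#'
#' A fuzzy number is stored by the left and right endpoints of its
#' alpha-cuts over a shared [alpha_grid()]: `[L(alpha), R(alpha)]` at every
#' grid level. Left endpoints must be nondecreasing in alpha, right
#' endpoints nonincreasing, with `L(1) <= R(1)`; the alpha = 0 interval is
#' the (closure of the) support. Model inputs must in addition be positive,
#' i.e. `L(0) > 0`.
#'
#' @param alpha An [alpha_grid()] (or numeric vector of levels).
#' @param left,right Numeric vectors of endpoints, one per level.
#' @param family Optional family tag ("alphacut", "parabolic", "crisp");
#'   set by the specialised constructors.
#' @param check If `TRUE` (default), reject invalid endpoint families.
#' @return An object of class `"fuzzy_number"`: a list with elements
#'   `alpha`, `left`, `right` and attributes describing the family.
#' @seealso [parabolic_fuzzy_number()], [crisp_fuzzy_number()],
#'   [validate_fuzzy_number()]
#' @export
fuzzy_number <- function(alpha, left, right, family = "alphacut", check = TRUE) {
  alpha <- as_alpha_grid(alpha)
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(alpha) || length(right) != length(alpha))
    stop("`left` and `right` must have one endpoint per grid level")
  x <- structure(list(alpha = as.numeric(alpha), left = left, right = right),
                 class = "fuzzy_number", family = family)
  if (check) {
    v <- validate_fuzzy_number(x)
    if (!v$valid)
      stop("invalid fuzzy number: ", paste(v$messages, collapse = "; "),
           call. = FALSE)
  }
  x
}

#' Parabolic fuzzy number
#'
#' Quadratic membership `1 - ((x - center)/spread)^2` on
#' `[center - spread, center + spread]`, zero outside; the alpha-cut at
#' level a is `[center - spread*sqrt(1 - a), center + spread*sqrt(1 - a)]`.
#' A symmetric, smooth alternative to the triangular fuzzy number: the
#' support has half-width `spread` and the core is the single point
#' `center`.
#'
#' @param center Membership-1 point.
#' @param spread Half support width, > 0.
#' @param grid An [alpha_grid()].
#' @param positive Require a positive support (`center - spread > 0`),
#'   as all model inputs must be. Default `TRUE`.
#' @return A `"fuzzy_number"` carrying `center` and `spread` attributes so
#'   that exact alpha-cuts off the grid remain available via [alpha_cut()].
#' @examples
#' A <- parabolic_fuzzy_number(1.75, 0.25, alpha_grid(5))
#' alpha_cut(A, 0)     # the support [1.5, 2]
#' alpha_cut(A, 0.25)
#' @export
parabolic_fuzzy_number <- function(center, spread, grid = alpha_grid(),
                                   positive = TRUE) {
  if (!is.finite(center) || !is.finite(spread)) stop("non-finite parameters")
  if (spread <= 0) stop("`spread` must be > 0")
  if (positive && center - spread <= 0)
    stop("positive fuzzy number requires center - spread > 0")
  grid <- as_alpha_grid(grid)
  h <- spread * sqrt(1 - as.numeric(grid))
  x <- fuzzy_number(grid, center - h, center + h, family = "parabolic")
  attr(x, "center") <- center
  attr(x, "spread") <- spread
  x
}

#' Crisp (trivial) fuzzy number
#'
#' A real number embedded as a zero-width fuzzy number:
#' `L(alpha) = R(alpha) = value` at every level.
#'
#' @param value A finite real.
#' @param grid An [alpha_grid()].
#' @return A `"fuzzy_number"` of family `"crisp"`.
#' @export
crisp_fuzzy_number <- function(value, grid = alpha_grid()) {
  if (!is.finite(value)) stop("`value` must be finite")
  grid <- as_alpha_grid(grid)
  x <- fuzzy_number(grid, rep(value, length(grid)), rep(value, length(grid)),
                    family = "crisp")
  attr(x, "center") <- value
  x
}

#' Validate a fuzzy-number endpoint family
#'
#' Checks the defining alpha-cut properties: left endpoints nondecreasing
#' in alpha, right endpoints nonincreasing, nested (`L(a) <= R(a)` at every
#' level, which together with monotonicity gives
#' `L(a1) <= L(a2) <= R(a2) <= R(a1)` for `a1 <= a2`), finiteness, and
#' reports whether the number is positive (`L(0) > 0`).
#'
#' @param x A `"fuzzy_number"` (not checked at construction when built
#'   internally).
#' @param tol Slack for the monotonicity comparisons (absolute), guarding
#'   against harmless floating-point jitter. Default 0.
#' @return A list with elements `valid` (logical), `positive` (logical)
#'   and `messages` (character vector of failures, empty when valid).
#' @export
validate_fuzzy_number <- function(x, tol = 0) {
  msgs <- character()
  if (!is.list(x) || is.null(x$alpha) || is.null(x$left) || is.null(x$right)) {
    return(list(valid = FALSE, positive = FALSE,
                messages = "not a fuzzy_number structure"))
  }
  L <- x$left; R <- x$right
  if (anyNA(L) || anyNA(R) || any(!is.finite(L)) || any(!is.finite(R)))
    msgs <- c(msgs, "non-finite endpoints")
  else {
    if (any(diff(L) < -tol)) msgs <- c(msgs, "left endpoints not nondecreasing in alpha")
    if (any(diff(R) > tol)) msgs <- c(msgs, "right endpoints not nonincreasing in alpha")
    if (any(R - L < -tol)) msgs <- c(msgs, "left endpoint exceeds right endpoint")
  }
  list(valid = length(msgs) == 0L,
       positive = length(msgs) == 0L && L[1L] > 0,
       messages = msgs)
}

is_positive_fuzzy <- function(x) x$left[1L] > 0

#' Alpha-cut of a fuzzy number
#'
#' For parabolic and crisp families the cut is evaluated exactly from the
#' (center, spread) specification at any `a` in \[0, 1\]; for generic
#' alpha-cut families, endpoints are linearly interpolated between grid
#' levels.
#'
#' @param x A `"fuzzy_number"`.
#' @param a Membership level(s) in \[0, 1\].
#' @return A matrix with columns `left` and `right`, one row per level in `a`.
#' @export
alpha_cut <- function(x, a) {
  a <- as.numeric(a)
  if (any(a < 0 | a > 1)) stop("alpha levels must lie in [0, 1]")
  fam <- attr(x, "family")
  if (identical(fam, "parabolic")) {
    h <- attr(x, "spread") * sqrt(1 - a)
    cbind(left = attr(x, "center") - h, right = attr(x, "center") + h)
  } else if (identical(fam, "crisp")) {
    v <- rep(attr(x, "center"), length(a))
    cbind(left = v, right = v)
  } else {
    cbind(left = stats::approx(x$alpha, x$left, xout = a)$y,
          right = stats::approx(x$alpha, x$right, xout = a)$y)
  }
}

# Support (alpha = 0 cut) and core (alpha = 1 cut) accessors.
fz_support <- function(x) c(x$left[1L], x$right[1L])
fz_core <- function(x) c(x$left[length(x$alpha)], x$right[length(x$alpha)])

# Width of each alpha-cut.
fz_width <- function(x) x$right - x$left

#' @export
print.fuzzy_number <- function(x, digits = 4, ...) {
  fam <- attr(x, "family")
  cat("<fuzzy_number:", fam, "> ", length(x$alpha), " levels\n", sep = "")
  cat("  support [", format(x$left[1L], digits = digits), ", ",
      format(x$right[1L], digits = digits), "]  core [",
      format(fz_core(x)[1L], digits = digits), ", ",
      format(fz_core(x)[2L], digits = digits), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fuzzy_number <- function(x, ...) {
  data.frame(alpha = x$alpha, left = x$left, right = x$right)
}

# Membership grade of sample points, from the grid representation:
# mu(v) = max{alpha_i : L(alpha_i) <= v <= R(alpha_i)}, 0 outside support.
fz_membership <- function(x, v) {
  m <- length(x$alpha)
  vapply(v, function(p) {
    ok <- x$left <= p & x$right >= p
    if (any(ok)) x$alpha[max(which(ok))] else 0
  }, numeric(1))
}
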