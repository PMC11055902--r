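#' Membership-level grid for alpha-cut arithmetic
#'
#' An alpha grid is the ordered set of membership levels at which fuzzy
#' numbers are represented by their alpha-cut interval endpoints. The grid
#' must start at 0 (the support), end at 1 (the core) and be strictly
#' increasing.
#'
#' @param n Number of uniformly spaced levels (default 101).
#' @param levels Optional explicit numeric vector of levels; overrides `n`.
#' @return A numeric vector of class `"alpha_grid"`.
#' @examples
#' alpha_grid(5)
#' alpha_grid(levels = c(0, 0.25, 0.5, 0.75, 1))
#' @export
alpha_grid <- function(n = 101L, levels = NULL) {
  if (is.null(levels)) {
    if (!is.numeric(n) || length(n) != 1L || n < 2)
      stop("`n` must be a single integer >= 2")
    levels <- seq(0, 1, length.out = as.integer(n))
  }
  levels <- as.numeric(levels)
  if (length(levels) < 2L) stop("an alpha grid needs at least 2 levels")
  if (levels[1L] != 0) stop("the first level must be 0 (the support level)")
  if (levels[length(levels)] != 1) stop("the last level must be 1 (the core)")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  structure(levels, class = "alpha_grid")
}

#' @export
print.alpha_grid <- function(x, ...) {
  cat("<alpha_grid> ", length(x), " levels in [0, 1]\n", sep = "")
  invisible(x)
}

# Coerce and check; accepts an alpha_grid or a bare numeric vector.
as_alpha_grid <- function(x) {
  if (inherits(x, "alpha_grid")) return(x)
  alpha_grid(levels = x)
}

same_grid <- function(H, P) {
  length(H$alpha) == length(P$alpha) && all(H$alpha == P$alpha)
}

stop_grid_mismatch <- function() {
  stop("operands are defined on different alpha grids", call. = FALSE)
}
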