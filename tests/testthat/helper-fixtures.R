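# Shared fixtures, built in code.

g5 <- alpha_grid(5)
g11 <- alpha_grid(11)

# Fuzzy number with the same interval at every level.
const_fz <- function(lo, hi, grid = g11) {
  fuzzy_number(grid, rep(lo, length(grid)), rep(hi, length(grid)))
}

# Random positive parabolic operand (support bounded away from zero).
rand_parabolic <- function(grid = g11, c_lo = 0.8, c_hi = 4, s_frac = 0.6) {
  center <- runif(1, c_lo, c_hi)
  spread <- runif(1, 0.05, s_frac * center * 0.9)
  parabolic_fuzzy_number(center, spread, grid)
}

expect_valid_fuzzy <- function(x, tol = 0) {
  v <- validate_fuzzy_number(x, tol = tol)
  expect_true(v$valid, info = paste(v$messages, collapse = "; "))
}
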