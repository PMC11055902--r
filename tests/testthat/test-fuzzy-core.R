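# Alpha-cut representation and fuzzy arithmetic.

test_that("alpha grids enforce their invariants", {
  g <- alpha_grid(5)
  expect_equal(as.numeric(g), c(0, 0.25, 0.5, 0.75, 1))
  expect_error(alpha_grid(levels = c(0.1, 0.5, 1)), "first level")
  expect_error(alpha_grid(levels = c(0, 0.5, 0.9)), "last level")
  expect_error(alpha_grid(levels = c(0, 0.5, 0.5, 1)), "strictly increasing")
  expect_error(alpha_grid(1), ">= 2")
})

test_that("parabolic construction matches the alpha-cut formula", {
  A <- parabolic_fuzzy_number(1.75, 0.25, g5)
  expect_equal(unname(alpha_cut(A, 0)), cbind(1.5, 2.0))
  expect_equal(unname(alpha_cut(A, 1)), cbind(1.75, 1.75))
  # right endpoint at alpha = 0.25 tabulated as 1.9665
  expect_equal(unname(alpha_cut(A, 0.25)[, "right"]),
               1.75 + 0.25 * sqrt(0.75))
  expect_equal(round(unname(alpha_cut(A, 0.25)[, "right"]), 4), 1.9665,
               tolerance = 1e-12)
  expect_valid_fuzzy(A)
  expect_error(parabolic_fuzzy_number(1, -0.5, g5), "spread")
  expect_error(parabolic_fuzzy_number(0.2, 0.5, g5), "positive")
})

test_that("crisp numbers are zero-width and equal the zero-spread limit", {
  cz <- crisp_fuzzy_number(1.75, g5)
  expect_equal(cz$left, rep(1.75, 5))
  expect_equal(cz$right, rep(1.75, 5))
  z <- crisp_fuzzy_number(0, g5)
  expect_false(validate_fuzzy_number(z)$positive)
  tiny <- parabolic_fuzzy_number(1.75, 1e-9, g5)
  expect_lt(metric_D(tiny, cz), 1e-8)
})

test_that("validation flags non-nested endpoint families", {
  g <- alpha_grid(levels = c(0, 1))
  bad <- fuzzy_number(g, c(1, 0.9), c(2, 2), check = FALSE)
  v <- validate_fuzzy_number(bad)
  expect_false(v$valid)
  expect_match(v$messages, "nondecreasing", all = FALSE)
  expect_error(fuzzy_number(g, c(1, 0.9), c(2, 2)), "invalid")
})

test_that("addition, scaling and multiplication act endpoint-wise", {
  H <- const_fz(1, 2); P <- const_fz(3, 4)
  S <- fz_add(H, P)
  expect_equal(S$left, rep(4, 11)); expect_equal(S$right, rep(6, 11))
  expect_equal(metric_D(fz_add(H, crisp_fuzzy_number(0, g11)), H), 0)
  A <- parabolic_fuzzy_number(1.75, 0.25, g11)
  B <- parabolic_fuzzy_number(0.25, 0.1, g11, positive = TRUE)
  AB <- fz_add(A, B)
  expect_equal(fz_support(AB), c(1.65, 2.35))
  expect_equal(metric_D(fz_scale(1, H), H), 0)
  expect_equal(fz_support(fz_scale(2, const_fz(1, 3))), c(2, 6))
  expect_equal(fz_support(fz_scale(0.5, parabolic_fuzzy_number(2, 1, g11))),
               c(0.5, 1.5))
  expect_error(fz_scale(-1, H), "positive")
  M <- fz_multiply(H, P)
  expect_equal(fz_support(M), c(3, 8))
  expect_equal(metric_D(fz_multiply(H, crisp_fuzzy_number(1, g11)), H), 0)
  # product of the demo initial-value supports
  xm1 <- parabolic_fuzzy_number(1, 0.35, g11)
  xm2 <- parabolic_fuzzy_number(1, 0.25, g11)
  expect_equal(fz_support(fz_multiply(xm1, xm2)), c(0.65 * 0.75, 1.35 * 1.25))
})

test_that("g-division picks the proper case and satisfies its identities", {
  # Case I: [2,4]/[1,2] -> crisp 2; multiplicative identity [H]=[P][W]
  r1 <- g_divide(const_fz(2, 4), const_fz(1, 2))
  expect_equal(r1$case, "CASE_I")
  expect_equal(fz_support(r1$quotient), c(2, 2))
  expect_lt(metric_D(fz_multiply(const_fz(1, 2), r1$quotient),
                     const_fz(2, 4)), 1e-12)
  # Case II: [2,3]/[1,4] -> [0.75,2]; identity [P]=[H][W]^{-1}
  r2 <- g_divide(const_fz(2, 3), const_fz(1, 4))
  expect_equal(r2$case, "CASE_II")
  expect_equal(fz_support(r2$quotient), c(0.75, 2))
  Winv <- fuzzy_number(g11, 1 / r2$quotient$right, 1 / r2$quotient$left)
  expect_lt(metric_D(fz_multiply(const_fz(2, 3), Winv), const_fz(1, 4)),
            1e-12)
  # crisp / crisp
  r3 <- g_divide(crisp_fuzzy_number(6, g11), crisp_fuzzy_number(2, g11))
  expect_equal(r3$case, "CASE_I")
  expect_equal(fz_support(r3$quotient), c(3, 3))
})

test_that("g-division roundtrip identities hold on random positive pairs", {
  set.seed(42)
  for (i in 1:50) {
    H <- rand_parabolic(); P <- rand_parabolic()
    r <- tryCatch(g_divide(H, P), error = function(e) NULL)
    if (is.null(r)) next # mixed-case pair, rejected by design
    scale <- max(H$right, P$right)
    if (r$case == "CASE_I") {
      expect_lt(metric_D(fz_multiply(P, r$quotient), H), 1e-12 * scale)
    } else {
      Winv <- fuzzy_number(H$alpha, 1 / r$quotient$right, 1 / r$quotient$left)
      expect_lt(metric_D(fz_multiply(H, Winv), P), 1e-12 * scale)
    }
  }
})

test_that("mixed-sign g-division across levels is rejected with a diagnostic", {
  g <- alpha_grid(levels = c(0, 0.5, 1))
  # H_l P_r - H_r P_l changes sign between the support and the core
  H <- fuzzy_number(g, c(1, 1.8, 2), c(3, 2.2, 2))
  P <- fuzzy_number(g, c(0.5, 1.4, 1.5), c(4, 1.7, 1.5))
  d <- H$left * P$right - H$right * P$left
  expect_true(any(d > 0) && any(d < 0)) # fixture sanity
  expect_error(g_divide(H, P), "not uniform")
})

test_that("Zadeh division is the interval quotient and dominates g-division in width", {
  Z <- zadeh_divide(const_fz(2, 3), const_fz(1, 4))
  expect_equal(fz_support(Z), c(0.5, 3))
  zc <- zadeh_divide(crisp_fuzzy_number(6, g11), crisp_fuzzy_number(2, g11))
  expect_equal(fz_support(zc), c(3, 3))
  set.seed(7)
  for (i in 1:25) {
    H <- rand_parabolic(); P <- rand_parabolic()
    r <- tryCatch(g_divide(H, P), error = function(e) NULL)
    if (is.null(r)) next
    wz <- zadeh_divide(H, P)
    expect_true(all((wz$right - wz$left) - (r$quotient$right - r$quotient$left)
                    >= -1e-12))
  }
})

test_that("sup-min sampling oracle agrees with the interval division", {
  o <- extension_divide_oracle(const_fz(2, 3), const_fz(1, 4),
                               n_samples = 2000L)
  expect_equal(fz_support(o), c(0.5, 3), tolerance = 5e-3)
  oc <- extension_divide_oracle(crisp_fuzzy_number(6, g11),
                                crisp_fuzzy_number(2, g11), n_samples = 10L)
  expect_equal(fz_support(oc), c(3, 3))
  set.seed(11)
  for (i in 1:50) {
    H <- rand_parabolic(); P <- rand_parabolic()
    o <- extension_divide_oracle(H, P, n_samples = 400L)
    z <- zadeh_divide(H, P)
    # sampling error O(1/n) scaled by quotient magnitude
    tol <- 0.05 * max(z$right)
    expect_lt(metric_D(o, z), tol)
  }
})

test_that("the supremum metric behaves as a metric on endpoint families", {
  H <- parabolic_fuzzy_number(1.75, 0.25, g11)
  expect_equal(metric_D(H, H), 0)
  expect_equal(metric_D(const_fz(1, 2), const_fz(1.5, 2.5)), 0.5)
  expect_equal(metric_D(H, crisp_fuzzy_number(1.75, g11)), 0.25)
  expect_error(metric_D(H, parabolic_fuzzy_number(1.75, 0.25, g5)),
               "different alpha grids")
})

test_that("crisp operands degenerate to ordinary real arithmetic", {
  a <- crisp_fuzzy_number(2.5, g11); b <- crisp_fuzzy_number(0.8, g11)
  expect_equal(fz_support(fz_add(a, b)), rep(3.3, 2))
  expect_equal(fz_support(fz_multiply(a, b)), rep(2, 2))
  expect_equal(fz_support(g_divide(a, b)$quotient), rep(2.5 / 0.8, 2))
  expect_equal(fz_support(zadeh_divide(a, b)), rep(2.5 / 0.8, 2))
})

test_that("fuzzy numbers roundtrip through JSON in all families", {
  A <- parabolic_fuzzy_number(1.75, 0.25, g11)
  expect_equal(metric_D(fuzzy_from_json(fuzzy_to_json(A), g11), A), 0)
  cz <- crisp_fuzzy_number(3, g11)
  expect_equal(metric_D(fuzzy_from_json(fuzzy_to_json(cz), g11), cz), 0)
  ac <- const_fz(1, 2)
  back <- fuzzy_from_json(fuzzy_to_json(ac))
  expect_equal(back$left, ac$left)
  expect_equal(back$right, ac$right)
})

test_that("nestedness holds for arithmetic outputs across levels", {
  set.seed(3)
  for (i in 1:20) {
    H <- rand_parabolic(); P <- rand_parabolic()
    for (out in list(fz_add(H, P), fz_multiply(H, P), zadeh_divide(H, P))) {
      expect_valid_fuzzy(out, tol = 1e-12 * max(out$right))
    }
  }
})
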