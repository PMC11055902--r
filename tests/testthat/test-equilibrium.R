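# Closed-form equilibria, envelopes, stability reports, condition checkers.

resid_case1 <- function(y, p, a) abs(y - (p + a * y + 1 / y))

test_that("crisp equilibrium solves its fixed-point equation", {
  y <- crisp_equilibrium_case1(1.75, 0.25)
  expect_equal(round(y, 4), 2.8081)
  expect_lt(resid_case1(y, 1.75, 0.25), 1e-12)
  expect_equal(crisp_equilibrium_case1(2, 0), 1 + sqrt(2))
  expect_equal(crisp_equilibrium_case1(1e-12, 0), 1, tolerance = 1e-9)
  expect_error(crisp_equilibrium_case1(1, 1), "< 1")
})

test_that("Case-I fuzzy equilibrium matches the tabulated endpoints", {
  s <- fbqp_example_scenario(g5)
  eq <- fuzzy_equilibrium_case1(s$A, s$B)
  expect_s3_class(eq$value, "fuzzy_number")
  ends <- cbind(eq$value$left, eq$value$right)
  expect_equal(round(ends[1, ], 4), c(2.2806, 3.5147)) # support
  expect_equal(round(ends[3, 2], 4), 3.2846)           # alpha = 0.5 right
  expect_equal(round(ends[5, ], 4), c(2.8081, 2.8081)) # core
  # degenerate inputs reduce to the crisp closed form
  cz <- fuzzy_equilibrium_case1(crisp_fuzzy_number(1.75, g5),
                                crisp_fuzzy_number(0.25, g5))
  expect_equal(fz_support(cz$value), rep(crisp_equilibrium_case1(1.75, 0.25), 2))
  expect_error(fuzzy_equilibrium_case1(s$A, crisp_fuzzy_number(1, g5)), "< 1")
})

test_that("coupled Case-II equilibrium solves the coupled fixed-point system", {
  eq <- coupled_equilibrium_case2(1.5, 0.15, 2.0, 0.35)
  expect_equal(round(unname(eq), 4), c(2.0728, 3.8192))
  expect_lt(abs(eq[["y"]] - (1.5 + 0.15 * eq[["y"]] + 1 / eq[["z"]])), 1e-12)
  expect_lt(abs(eq[["z"]] - (2.0 + 0.35 * eq[["z"]] + 1 / eq[["y"]])), 1e-12)
  sym <- coupled_equilibrium_case2(1.75, 0.25, 1.75, 0.25)
  expect_equal(unname(sym), rep(crisp_equilibrium_case1(1.75, 0.25), 2),
               tolerance = 1e-12)
})

test_that("Case-II fuzzy equilibrium matches the tabulated endpoints", {
  s <- fbqp_example_scenario(g5)
  eq <- fuzzy_equilibrium_case2(s$A, s$B)
  ends <- cbind(eq$value$left, eq$value$right)
  expect_equal(round(ends[1, ], 4), c(2.0728, 3.8192)) # support
  expect_equal(round(ends[3, ], 4), c(2.2664, 3.4860)) # alpha = 0.5
  expect_equal(round(ends[5, 1], 4), 2.8081)           # core
  # equals the coupled closed form applied per level
  for (j in 1:5) {
    cp <- coupled_equilibrium_case2(s$A$left[j], s$B$left[j],
                                    s$A$right[j], s$B$right[j])
    expect_equal(unname(cp), c(ends[j, 1], ends[j, 2]), tolerance = 1e-12)
  }
  # crisp parameters collapse both cases onto one equilibrium
  A <- crisp_fuzzy_number(1.75, g5); B <- crisp_fuzzy_number(0.25, g5)
  expect_equal(metric_D(fuzzy_equilibrium_case2(A, B)$value,
                        fuzzy_equilibrium_case1(A, B)$value), 0)
})

test_that("per-level fixed-point residuals vanish for both fuzzy equilibria", {
  s <- fbqp_example_scenario(g11)
  e1 <- fuzzy_equilibrium_case1(s$A, s$B)$value
  expect_lt(max(resid_case1(e1$left, s$A$left, s$B$left)), 1e-12)
  expect_lt(max(resid_case1(e1$right, s$A$right, s$B$right)), 1e-12)
  e2 <- fuzzy_equilibrium_case2(s$A, s$B)$value
  expect_lt(max(abs(e2$left - (s$A$left + s$B$left * e2$left + 1 / e2$right))),
            1e-12)
  expect_lt(max(abs(e2$right - (s$A$right + s$B$right * e2$right + 1 / e2$left))),
            1e-12)
})

test_that("Case-I envelope matches tabulated bounds and rejects bad parameters", {
  b1 <- bound_case1(1.75, 0.25, y3 = 1)
  expect_equal(round(b1[["upper"]], 4), 5.1325)
  expect_equal(b1[["lower"]], 1.75)
  b0 <- bound_case1(2, 0.35, y3 = 1.45)
  expect_equal(round(b0[["upper"]], 4), 6.4500)
  expect_error(bound_case1(0.5, 0.5, 1), "p\\^2 > 1")
})

test_that("coupled envelope constants and containment", {
  b <- bounds_case2(1, 0.5, 1, 0.5, y2 = 1, z2 = 1)
  expect_equal(b$c1, 5.0)
  expect_equal(b$c1, b$c2)
  s <- simulate_coupled_case2(1, 0.5, 1, 0.5, c(1, 1, 1), c(1, 1, 1), 1000)
  bb <- bounds_case2(1, 0.5, 1, 0.5, y2 = s["2", "y"], z2 = s["2", "z"])
  body <- as.integer(rownames(s)) >= 1
  expect_true(all(s[body, "y"] >= bb$y_bounds[["lower"]]))
  expect_true(all(s[body, "y"] <= bb$y_bounds[["upper"]]))
  expect_true(all(s[body, "z"] <= bb$z_bounds[["upper"]]))
  expect_error(bounds_case2(1, 1.2, 1, 0.5, 1, 1), "\\(0, 1\\)")
})

test_that("crisp linearization coefficient and stability criterion", {
  st <- linearization_case1(1.75, 0.25)
  expect_equal(st$G, 0.12681, tolerance = 1e-4)
  expect_equal(st$criterion, 4.5 / 8.871375, tolerance = 1e-6)
  expect_true(st$stable)
  expect_true(st$sufficient_3p2)
  # G is 1/ybar^2: two routes to the same coefficient
  expect_equal(st$G, 1 / crisp_equilibrium_case1(1.75, 0.25)^2,
               tolerance = 1e-12)
  # the sufficient condition implies the criterion
  set.seed(9)
  for (i in 1:25) {
    p <- runif(1, 0.2, 3); a <- runif(1, 0.05, 0.95)
    st <- linearization_case1(p, a)
    if (st$sufficient_3p2) expect_true(st$stable)
  }
  expect_false(linearization_case1(0.05, 0.05)$stable)
})

test_that("weighted-norm certificate for the coupled equilibrium", {
  st <- jacobian_case2(1.5, 0.15, 2.0, 0.35)
  expect_gt(st$eps, st$eps_interval[1])
  expect_lt(st$eps, 1)
  expect_lt(st$norm, 1)
  expect_true(st$stable)
  expect_equal(unname(st$equilibrium),
               unname(coupled_equilibrium_case2(1.5, 0.15, 2.0, 0.35)))
  # the certificate also holds near the interval's lower end
  lo <- st$eps_interval[1]
  st2 <- jacobian_case2(1.5, 0.15, 2.0, 0.35, eps = lo + 0.01)
  expect_lt(st2$norm, 1)
  # L really is the similarity transform of T
  G <- diag(st$eps^(0:5))
  expect_equal(st$L, G %*% st$T %*% solve(G))
  # symmetric parameters leave no admissible weight
  expect_error(jacobian_case2(1.5, 0.2, 1.5, 0.2), "empty")
  # certified stability is corroborated by simulation
  s <- simulate_coupled_case2(1.5, 0.15, 2.0, 0.35, c(0.8, 1.2, 1),
                              c(1.1, 0.9, 1.3), 5000)
  expect_lt(max(abs(utils::tail(s, 1) - st$equilibrium)), 1e-8)
})

test_that("condition checkers evaluate the printed inequality sets literally", {
  s <- fbqp_example_scenario(g5)
  # Case-II convergence set: product condition holds at the support
  r5 <- check_conditions(s, "thm3.5")
  expect_true(all(r5$conditions$product$holds))
  expect_true(0.85 * 0.65 * 1.5^2 * 2^2 > 1) # the alpha=0 instance
  expect_true(conditions_pass_interior(r5))
  # literal Case-I set fails on this scenario: A_r0 = 2 >= 1
  r2 <- check_conditions(s, "thm3.2")
  expect_false(all(r2$conditions$bound_param$holds))
  expect_false(r2$overall)
  # the alternate reading bounds B instead and passes that clause
  r2b <- check_conditions(s, "thm3.2", alternate = TRUE)
  expect_true(all(r2b$conditions$bound_param$holds))
  # crisp scenario: the 3A^2 > 4(1-B) growth condition holds (9.1875 > 3)
  cz <- fbqp_scenario(crisp_fuzzy_number(1.75, g5), crisp_fuzzy_number(0.25, g5),
                      crisp_fuzzy_number(1, g5), crisp_fuzzy_number(1, g5),
                      crisp_fuzzy_number(1, g5))
  r3 <- check_conditions(cz, "thm3.3")
  expect_true(all(r3$conditions$left_suff$holds))
  expect_true(all(r3$conditions$right_suff$holds))
  # reports serialize to JSON
  expect_match(as.character(report_to_json(r5)), "\"which\":\"thm3.5\"")
})

test_that("random compliant scenarios converge to their case equilibrium", {
  g <- alpha_grid(21)
  for (i in 1:50) {
    sc <- random_scenario("thm3.3", seed = 1000 + i, grid = g)
    tr <- fbqp_simulate(sc, 2000, mode = "case1")
    eq <- fuzzy_equilibrium_case1(sc$A, sc$B)$value
    expect_lt(unname(utils::tail(trajectory_distance(tr, eq), 1)), 1e-6)
  }
  for (i in 1:50) {
    sc <- random_scenario("thm3.5", seed = 2000 + i, grid = g)
    tr <- fbqp_simulate(sc, 2000, mode = "case2")
    eq <- fuzzy_equilibrium_case2(sc$A, sc$B)$value
    expect_lt(unname(utils::tail(trajectory_distance(tr, eq), 1)), 1e-6)
  }
})
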