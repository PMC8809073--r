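test_that("the loop-random walk is optimal on C_3 from every start, both goals", {
  g3 <- g_cycle(3)
  for (s0 in c("(0,0)", "(0,1)")) {
    o <- optimize_laziness(g3, 3, goal_distancing(1), start = s0)
    expect_equal(o$p_bar, 1/3, tolerance = 1e-6)
  }
  for (s0 in c("(0,1)", "(1,1)")) {
    o <- optimize_laziness(g3, 3, goal_gathering(), start = s0)
    expect_equal(o$p_bar, 1/3, tolerance = 1e-6)
  }
  o <- optimize_laziness(g3, 3, goal_gathering(), start = "(0,1)")
  expect_equal(o$t_bar, 3, tolerance = 1e-8)
  o <- optimize_laziness(g3, 3, goal_gathering(), start = "(1,1)")
  expect_equal(o$t_bar, 27/7, tolerance = 1e-8)
})

test_that("the symbolic derivative factors through (p - 1/3) on C_3", {
  r <- absorption_times(build_chain(g_cycle(3), 3, goal_distancing(1),
                                    symbolic_strategy("uniform")))
  d <- rat_deriv(r$t[["(0,0)"]], "p")
  # root at exactly 1/3 ...
  expect_equal(poly_eval(d$num, c(p = 1/3)), 0, tolerance = 1e-12)
  # ... and the quotient matches (p - 1/3) * 36 / ((3p+1)^2 (p-1)^2)
  for (p in c(0.1, 0.5, 0.9))
    expect_equal(rat_eval(d, c(p = p)),
                 (p - 1/3) * 36 / ((3 * p + 1)^2 * (p - 1)^2),
                 tolerance = 1e-10)
})

test_that("common-laziness optimum for two adjacent agents on C_n (n >= 5) is 1/5", {
  o <- optimize_laziness(g_cycle(5), 2, goal_distancing(2), start = "(1)")
  expect_equal(o$p_bar, 1/5, tolerance = 1e-7)
  expect_equal(o$t_bar, 25/8, tolerance = 1e-9)
  o6 <- optimize_laziness(g_cycle(6), 2, goal_distancing(2), start = "(1)")
  expect_equal(o6$p_bar, 1/5, tolerance = 1e-6)
})

test_that("population-dependent optimum on C_n: always move when sharing a node", {
  set.seed(5)
  o <- optimize_laziness(g_cycle(5), 2, goal_distancing(2), start = "(1)",
                         mode = "population")
  expect_equal(o$argmin[2], 0, tolerance = 1e-6)                 # r-bar
  expect_equal(o$argmin[1], (sqrt(33) - 5) / 2, tolerance = 1e-4)
  expect_equal(o$t_bar, (sqrt(33) + 15) / 8, tolerance = 1e-7)
  # the population-dependent optimum can only improve on the common-p one
  expect_lt(o$t_bar, 25/8 + 1e-9)
})

test_that("the C_4 variant: boundary popdep optimum and the interior scalar one", {
  set.seed(6)
  g4 <- g_cycle(4)
  o1 <- optimize_laziness(g4, 2, goal_distancing(2), start = "(0)",
                          mode = "population")
  # any p attains the optimum once r = 0 (the together class exits at rate
  # 1/2 whatever the alone-laziness), so only r and the value are unique
  expect_equal(o1$argmin[2], 0, tolerance = 1e-6)
  expect_equal(o1$t_bar, 2, tolerance = 1e-7)
  o2 <- optimize_laziness(g4, 2, goal_distancing(2), start = "(1)",
                          mode = "population")
  expect_equal(o2$argmin, c(0.5, 0), tolerance = 1e-4)
  expect_equal(o2$t_bar, 3, tolerance = 1e-7)
  # common laziness from the adjacent start: interior optimum near 0.38272
  # (derived independently: the real root of the cubic stationarity condition)
  o3 <- optimize_laziness(g4, 2, goal_distancing(2), start = "(1)")
  p_star <- (-1 + (49 - 20 * sqrt(6))^(1/3) + (49 + 20 * sqrt(6))^(1/3)) / 10
  expect_equal(o3$p_bar, p_star, tolerance = 1e-6)
  expect_equal(o3$t_bar, 4.459665898538, tolerance = 1e-8)
})

test_that("unreachable goals are rejected; t diverges at the right boundary", {
  expect_error(minimize_scalar_laziness(function(p) Inf), "unreachable")
  o <- optimize_laziness(g_cycle(5), 2, goal_distancing(2), start = "(1)")
  expect_lt(o$p_bar, 0.99)
  tail_t <- o$profile$t[which.max(o$profile$p)]
  expect_gt(tail_t, 100)  # frozen agents cannot separate
  # grid-vs-refined agreement
  expect_lte(o$t_bar, min(o$profile$t) + 1e-6)
})

test_that("the scalar minimiser accepts a plain function objective", {
  o <- minimize_scalar_laziness(function(p) (p - 0.4)^2 + 1, grid_step = 0.01)
  expect_equal(o$p_bar, 0.4, tolerance = 1e-6)
  expect_equal(o$t_bar, 1, tolerance = 1e-10)
  # ties break toward the smallest p
  o2 <- minimize_scalar_laziness(function(p) 1, grid_step = 0.1)
  expect_equal(o2$p_bar, 0)
})
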