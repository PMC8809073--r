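# the chain builder against the hand-derived transient blocks, plus its
# structural invariants

sym_B_equal <- function(chain, ref) {
  labs <- rownames(ref)
  for (i in labs) for (j in labs)
    expect_poly_equal(chain$B[[i, j]], ref[[i, j]])
}

test_that("two-agent distancing blocks on C_n and C_4 match the hand derivation", {
  st2 <- symbolic_strategy("population_dependent", m = 2)
  for (n in c(5, 6, 7)) {
    ch <- build_chain(g_cycle(n), 2, goal_distancing(2), st2)
    sym_B_equal(ch, ref_B_two_agents_distancing(pv("p1"), pv("p2"), n = n))
  }
  ch4 <- build_chain(g_cycle(4), 2, goal_distancing(2), st2)
  sym_B_equal(ch4, ref_B_two_agents_distancing(pv("p1"), pv("p2"), n = 4))
  # moving apart on C_4 re-enters the adjacent class: b22 = p^2 + q^2
  expect_poly_equal(ch4$B[["(1)", "(1)"]], pv("p1")^2 + (1 - pv("p1"))^2)
  # adjacent agents on C_5 under pure random walks exit at rate 1/4
  chn <- chain_eval(build_chain(g_cycle(5), 2, goal_distancing(2), st2),
                    c(p1 = 0, p2 = 0))
  expect_equal(chn$R["(1)", "(2)"], 1/4, ignore_attr = TRUE)
})

test_that("the C_3 and C_5 blocks match the hand derivations symbolically", {
  stp <- symbolic_strategy("uniform")
  sym_B_equal(build_chain(g_cycle(3), 3, goal_distancing(1), stp),
              ref_B_c3_distancing(pv("p")))
  sym_B_equal(build_chain(g_cycle(3), 3, goal_gathering(), stp),
              ref_B_c3_gathering(pv("p")))
  sym_B_equal(build_chain(g_cycle(5), 3, goal_gathering(), stp),
              ref_B_c5_gathering(pv("p")))
  sym_B_equal(build_chain(g_cycle(5), 3, goal_distancing(1), stp),
              ref_B_c5_distancing(pv("p")))
})

test_that("the capture block matches the kernel derivation and differs from the benchmark in exactly three coefficients", {
  g3 <- g_cycle(3)
  stc <- list(searcher = laziness_uniform(pv("s")), hider = laziness_uniform(pv("h")))
  ch <- build_chain(g3, NULL, goal_capture(2), stc)
  apart <- vapply(ch$states, function(x) length(unique(x$searchers)) == 2L, logical(1))
  ord <- order(!apart)
  refk <- ref_B_c3_search_kernel(pv("h"), pv("s"))
  refb <- ref_B_c3_search_benchmark(pv("h"), pv("s"))
  for (i in 1:2) for (j in 1:2)
    expect_poly_equal(ch$B[[ord[i], ord[j]]], refk[[i, j]])
  # the documented three-term discrepancy of the benchmark block
  h <- pv("h"); s <- pv("s"); hp <- 1 - h; sp <- 1 - s
  expect_poly_equal(refk[[1, 1]], refb[[1, 1]])                       # b11 agrees
  expect_poly_equal(refk[[1, 2]] - refb[[1, 2]], 0.25 * hp * s * sp)  # b12
  expect_poly_equal(refb[[2, 1]] - refk[[2, 1]], 0.25 * h * sp^2)     # b21
  expect_poly_equal(refb[[2, 2]] - refk[[2, 2]], 0.125 * hp * sp^2)   # b22
})

test_that("all three agents at a C_3 node re-coalesce with the printed leading terms", {
  # distancing state [3,0,0]: successor all-at-one-node has weight p^3 + q^3/4
  g3 <- g_cycle(3)
  ch <- build_chain(g3, 3, goal_distancing(1), symbolic_strategy("uniform"))
  expect_poly_equal(ch$B[["(0,0)", "(0,0)"]],
                    pv("p")^3 + 0.25 * (1 - pv("p"))^3)
})

test_that("joint move expansion is the exact kernel product", {
  g <- g_cycle(3)
  jd <- joint_move_distribution(c(2), g, list(0))
  expect_equal(sort(jd$configs[, 1]), c(1, 3))
  expect_equal(unlist(jd$probs), c(0.5, 0.5), ignore_attr = TRUE)
  jd2 <- joint_move_distribution(c(1, 3), g, list(1, 1))   # frozen agents
  expect_equal(jd2$configs, matrix(c(1, 3), 1), ignore_attr = TRUE)
  expect_equal(jd2$probs[[1]], 1)
  jd3 <- joint_move_distribution(c(1, 2), g, list(0.5, 0.5))
  expect_equal(nrow(jd3$configs), 9)
  expect_equal(sum(unlist(jd3$probs)), 1)
  expect_error(joint_move_distribution(rep(1, 9), g, as.list(rep(0.5, 9))),
               "8 agents")
})

test_that("rows of [B | R] are stochastic for every goal and laziness", {
  goals <- list(goal_distancing(1), goal_gathering())
  for (g in list(g_cycle(5), g_line(5), build_graph("grid", 3))) {
    for (goal in goals) for (p in c(0, 0.3, 0.7, 1)) {
      ch <- build_chain(g, 3, goal, laziness_uniform(p))
      expect_equal(unname(rowSums(ch$B) + rowSums(ch$R)),
                   rep(1, nrow(ch$B)), tolerance = 1e-12)
      expect_true(all(ch$B >= 0) && all(ch$R >= 0))
    }
  }
})

test_that("gathering chains are block-triangular in the occupied-node count", {
  for (n in c(5, 7)) {
    ch <- build_chain(g_cycle(n), 3, goal_gathering(), laziness_uniform(0.4))
    k_of <- vapply(ch$states, function(st) length(st$occupied), integer(1))
    for (i in seq_along(k_of)) for (j in seq_along(k_of))
      if (k_of[j] > k_of[i]) expect_equal(ch$B[i, j], 0, ignore_attr = TRUE)
  }
})

test_that("searcher exchangeability: labelled chain is symmetric under equal lazinesses", {
  g3 <- g_cycle(3)
  st <- list(searcher = laziness_uniform(0.25), hider = laziness_uniform(0.6))
  ch <- build_chain(g3, NULL, goal_capture(2, labelled = TRUE), st)
  A <- absorption_probabilities(ch)
  expect_equal(unname(A[, "wins:1"]), unname(A[, "wins:2"]), tolerance = 1e-12)
})

test_that("gap-state reachability is derived, not hard-coded: (j-2, k-2) is unreachable", {
  # from gap state (2,3) on a long cycle, the two closest agents moving
  # toward each other precludes the second pair also closing by two
  ch <- build_chain(g_cycle(12), 3, goal_gathering(), laziness_uniform(0.4))
  expect_equal(ch$B["(2,3)", "(0,1)"], 0, ignore_attr = TRUE)
  expect_gt(ch$B["(2,3)", "(1,2)"], 0)     # (j-1,k-1) is reachable
})

test_that("numeric chains round-trip through labelled CSV", {
  ch <- build_chain(g_cycle(5), 2, goal_distancing(2), laziness_uniform(0.2))
  path <- tempfile(fileext = ".csv")
  write_chain_csv(ch, path)
  expect_match(readLines(path, n = 1), "^#")
  back <- read_chain_csv(path)
  expect_equal(back$B, ch$B, tolerance = 0)
  expect_equal(back$R, ch$R, tolerance = 0)
})
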