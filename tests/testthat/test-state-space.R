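test_that("minimum pairwise distance follows the distance statistic d", {
  gl <- g_line(6)
  expect_equal(min_pairwise_distance(c(1, 0, 0, 1, 0, 1), gl), 2L)
  expect_equal(min_pairwise_distance(c(0, 2, 0, 1, 0, 0), gl), 0L)
  expect_equal(min_pairwise_distance(c(1, 0, 1, 0, 1), g_cycle(5)), 1L)
  expect_error(min_pairwise_distance(c(1, 0, 0, 0, 0, 0), gl), "two agents")
})

test_that("absorbing states match each goal", {
  gl <- g_line(6)
  s <- c(1, 0, 0, 1, 0, 1)
  expect_true(is_absorbing(s, goal_distancing(1), gl))
  expect_true(is_absorbing(s, goal_distancing(2), gl))
  expect_false(is_absorbing(s, goal_distancing(3), gl))
  expect_true(is_absorbing(4, goal_gathering(), gl))
  expect_false(is_absorbing(c(2, 5), goal_gathering(), gl))
  expect_true(is_absorbing(list(searchers = c(1, 2), hider = 2),
                           goal_capture(2), gl))
  expect_false(is_absorbing(list(searchers = c(1, 2), hider = 4),
                            goal_capture(2), gl))
})

test_that("state counts match the closed forms", {
  g3 <- g_cycle(3)
  ss <- enumerate_states(g3, 3, goal_distancing(1), lump = "none")
  expect_length(ss$states, choose(3 + 3 - 1, 3))    # stars and bars: 10
  sg <- enumerate_states(g3, 3, goal_gathering(), lump = "none")
  expect_length(sg$states, 2^3 - 1)                 # nonempty subsets: 7
  for (n in 4:6) for (m in 2:3) {
    expect_length(enumerate_states(g_cycle(n), m, goal_distancing(1),
                                   lump = "none")$states,
                  choose(n + m - 1, m))
  }
})

test_that("cycle lumping reproduces the hand reductions", {
  # three agents on C_5: gap classes (1,1),(1,2),(0,1),(0,2),(0,0)
  ss <- enumerate_states(g_cycle(5), 3, goal_distancing(1))
  expect_setequal(ss$labels, c("(1,1)", "(1,2)", "(0,1)", "(0,2)", "(0,0)"))
  expect_setequal(ss$labels[ss$absorbing], c("(1,1)", "(1,2)"))
  # class sizes recover the random-start weights (6,6,6,6,1)/25 later
  expect_equal(sum(ss$class_sizes), choose(5 + 3 - 1, 3))

  # two agents on C_n: one class per inter-agent distance
  for (n in 4:7) {
    ss2 <- enumerate_states(g_cycle(n), 2, goal_distancing(2))
    expect_equal(sort(ss2$labels),
                 sort(paste0("(", 0:(n %/% 2), ")")))
  }

  # three agents on C_3: classes = number of distinct occupied nodes
  ss3 <- enumerate_states(g_cycle(3), 3, goal_distancing(1))
  expect_length(ss3$states, 3)

  expect_error(enumerate_states(g_line(4), 2, goal_distancing(1), lump = "cycle"),
               "cycle")
})

test_that("the lumping map sends each raw state to its dihedral class", {
  g <- g_cycle(5)
  tab <- lump_cycle_states(g, list(c(1, 1, 1, 0, 0), c(0, 0, 1, 1, 1),
                                   c(2, 0, 1, 0, 0), c(3, 0, 0, 0, 0)),
                           goal_distancing(1), m = 3)
  expect_equal(tab$class, c("(1,1)", "(1,1)", "(0,2)", "(0,0)"))
  # d is invariant under graph automorphisms
  set.seed(11)
  for (n in 4:7) {
    g <- g_cycle(n)
    perms <- lazywalks:::cycle_automorphisms(n)
    for (rep in 1:5) {
      counts <- tabulate(sample(n, 3, replace = TRUE), nbins = n)
      d0 <- min_pairwise_distance(counts, g)
      for (perm in perms[sample(length(perms), 3)]) {
        img <- integer(n); img[perm] <- counts
        expect_equal(min_pairwise_distance(img, g), d0)
      }
    }
  }
})

test_that("degenerate goals are rejected with the reason", {
  expect_error(enumerate_states(g_cycle(5), 3, goal_distancing(2)),
               "infeasible.*D-independence")
  expect_error(enumerate_states(g_cycle(5), 1, goal_distancing(1)),
               "at least two agents")
})

test_that("the pretty printer uses bracket and gap notation", {
  g <- g_cycle(5)
  expect_equal(format_state(c(1, 0, 0, 1, 0), goal_distancing(1), g),
               "[1,0,0,1,0]")
  expect_equal(format_state(c(1, 1, 1, 0, 0), goal_distancing(1), g,
                            lumped = TRUE, m = 3), "(1,1)")
  expect_equal(format_state(c(2, 4), goal_gathering(), g), "{2,4}")
  expect_equal(format_state(3, goal_gathering(), g, lumped = TRUE, m = 3),
               "(0,0)")
})
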