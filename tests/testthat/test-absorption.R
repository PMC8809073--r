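test_that("structural traps give infinite times; reachable starts solve exactly", {
  # adjacent agents on C_4 under pure random walks never separate
  ch4 <- build_chain(g_cycle(4), 2, goal_distancing(2), laziness_uniform(0))
  r4 <- absorption_times(ch4)
  expect_equal(r4$t[["(1)"]], Inf)
  expect_false(r4$almost_sure[["(1)"]])
  # ... but the together class still absorbs almost surely (b12 = 0 at p = 0)
  expect_equal(r4$t[["(0)"]], 2)
  expect_true(r4$almost_sure[["(0)"]])

  # on C_n, n >= 5, the random walk separates adjacent agents in 4 periods
  for (n in 5:7) {
    ch <- build_chain(g_cycle(n), 2, goal_distancing(2), laziness_uniform(0))
    expect_equal(absorption_times(ch)$t[["(1)"]], 4)
  }

  # gathering on C_3 at the loop-random walk: 3 periods from two occupied
  ch3 <- build_chain(g_cycle(3), 3, goal_gathering(), laziness_uniform(1/3))
  r3 <- absorption_times(ch3)
  expect_equal(r3$t[["(0,1)"]], 3)
  expect_equal(r3$t[["(1,1)"]], 27/7)
})

test_that("t = F 1 and A = F R hold, and F matches the Neumann series", {
  ch <- build_chain(g_cycle(5), 3, goal_distancing(1), laziness_uniform(0.35))
  r <- absorption_times(ch)
  expect_equal(unname(r$t), as.numeric(r$F %*% rep(1, 3)))
  expect_equal(r$A, r$F %*% ch$R, ignore_attr = TRUE)
  expect_equal(unname(rowSums(r$A)), rep(1, 3), tolerance = 1e-10)
  expect_equal(unname(r$t), neumann_times(ch), tolerance = 1e-8)
})

test_that("one-step toy chains absorb with the written probabilities", {
  chain <- structure(list(states = list(NULL), labels = "s1",
                          classes = c("a", "b"),
                          B = matrix(0, 1, 1, dimnames = list("s1", "s1")),
                          R = matrix(c(0.3, 0.7), 1, 2,
                                     dimnames = list("s1", c("a", "b"))),
                          symbolic = FALSE, vars = character(0),
                          lumped = FALSE, g = NULL, m = 1L,
                          goal = goal_gathering(), strategy = NULL),
                     class = "lrw_chain")
  r <- absorption_times(chain)
  expect_equal(unname(r$A[1, ]), c(0.3, 0.7))
  expect_equal(r$t[["s1"]], 1)
})

test_that("symbolic absorption reproduces the closed-form time curves", {
  stp <- symbolic_strategy("uniform")
  grid <- c(0.1, 0.25, 0.5, 0.8)

  r3d <- absorption_times(build_chain(g_cycle(3), 3, goal_distancing(1), stp))
  for (p in grid) {
    expect_equal(rat_eval(r3d$t[["(0,0)"]], c(p = p)),
                 ref_t_c3_distancing(p)[, "(0,0)"], ignore_attr = TRUE)
    expect_equal(rat_eval(r3d$t[["(0,1)"]], c(p = p)),
                 ref_t_c3_distancing(p)[, "(0,1)"], ignore_attr = TRUE)
  }

  r3g <- absorption_times(build_chain(g_cycle(3), 3, goal_gathering(), stp))
  r5g <- absorption_times(build_chain(g_cycle(5), 3, goal_gathering(), stp))
  r5d <- absorption_times(build_chain(g_cycle(5), 3, goal_distancing(1), stp))
  for (p in grid) {
    expect_equal(sapply(colnames(ref_t_c3_gathering(p)),
                        function(l) rat_eval(r3g$t[[l]], c(p = p))),
                 ref_t_c3_gathering(p)[1, ], tolerance = 1e-10)
    expect_equal(sapply(colnames(ref_t_c5_gathering(p)),
                        function(l) rat_eval(r5g$t[[l]], c(p = p))),
                 ref_t_c5_gathering(p)[1, ], tolerance = 1e-10)
    expect_equal(sapply(colnames(ref_t_c5_distancing(p)),
                        function(l) rat_eval(r5d$t[[l]], c(p = p))),
                 ref_t_c5_distancing(p)[1, ], tolerance = 1e-10)
  }

  # common-laziness two-agent curve t2(p,p) on C_5
  r52 <- absorption_times(build_chain(g_cycle(5), 2, goal_distancing(2), stp))
  for (p in grid)
    expect_equal(rat_eval(r52$t[["(1)"]], c(p = p)), ref_t2_two_agents_common(p))
})

test_that("random-start weights are derived by enumeration, not entered", {
  ch <- build_chain(g_cycle(5), 3, goal_gathering(), laziness_uniform(0.3))
  w <- random_start_distribution(ch)
  expect_equal(w[c("(1,1)", "(1,2)", "(0,1)", "(0,2)", "(0,0)")],
               c(6, 6, 6, 6, 1) / 25, ignore_attr = TRUE)

  stc <- list(searcher = laziness_uniform(0.3), hider = laziness_uniform(0.3))
  chc <- build_chain(g_cycle(3), NULL, goal_capture(2), stc)
  wc <- random_start_distribution(chc)
  apart_lab <- chc$labels[vapply(chc$states, function(x)
    length(unique(x$searchers)) == 2L, logical(1))]
  together_lab <- setdiff(chc$labels, apart_lab)
  expect_equal(wc[[apart_lab]], 2/9)
  expect_equal(wc[[together_lab]], 2/9)
  expect_equal(sort(unname(wc[chc$classes])), sort(c(4/9, 1/9)))

  # distancing on C_5: the dispersed share of a random start is 12/25
  chd <- build_chain(g_cycle(5), 3, goal_distancing(1), laziness_uniform(0.3))
  wd <- random_start_distribution(chd)
  expect_equal(sum(wd[chd$classes]), 12/25)
})

test_that("expected time from a start distribution averages and zeroes absorbing starts", {
  ch <- build_chain(g_cycle(5), 3, goal_gathering(), laziness_uniform(0.3))
  r <- absorption_times(ch)
  w <- random_start_distribution(ch)
  expect_equal(expected_time_from(r, w),
               sum(w[ch$labels] * r$t[ch$labels]))
  expect_equal(expected_time_from(r, "(0,0)"), 0)       # absorbing point mass
  expect_equal(expected_time_from(r, "(0,2)"), r$t[["(0,2)"]])
  bad <- w; bad[1] <- bad[1] + 0.1
  expect_error(expected_time_from(r, bad), "sum to")
  expect_error(expected_time_from(r, "(9,9)"), "unknown")
})

test_that("lumped and full chains agree on absorption times (oracle equivalence)", {
  cases <- list(list(n = 5, m = 2, goal = goal_distancing(2)),
                list(n = 6, m = 2, goal = goal_distancing(2)),
                list(n = 5, m = 3, goal = goal_distancing(1)),
                list(n = 7, m = 3, goal = goal_distancing(1)),
                list(n = 6, m = 3, goal = goal_gathering()))
  for (cs in cases) for (p in c(0.25, 0.6)) {
    g <- g_cycle(cs$n)
    full <- absorption_times(build_chain(g, cs$m, cs$goal,
                                         laziness_uniform(p), lump = "none"))
    lump <- absorption_times(build_chain(g, cs$m, cs$goal,
                                         laziness_uniform(p), lump = "cycle"))
    states <- lapply(full$chain$states, function(st)
      if (cs$goal$type == "gathering") st$occupied else st$counts)
    map <- lump_cycle_states(g, states, cs$goal, m = cs$m)
    expect_equal(unname(full$t),
                 unname(lump$t[map$class]), tolerance = 1e-9,
                 label = sprintf("n=%d m=%d %s p=%.2f", cs$n, cs$m,
                                 cs$goal$type, p))
  }
})

test_that("exchangeable-agent lumping agrees with the labelled-agent oracle", {
  for (cs in list(list(g = g_cycle(4), m = 3, goal = goal_distancing(1)),
                  list(g = g_line(4), m = 2, goal = goal_distancing(2)),
                  list(g = g_cycle(4), m = 3, goal = goal_gathering()))) {
    p <- 0.3
    oracle <- labelled_absorption_times(cs$g, cs$m, cs$goal, p)
    res <- absorption_times(build_chain(cs$g, cs$m, cs$goal,
                                        laziness_uniform(p), lump = "none"))
    for (k in names(oracle)) {
      cfg <- as.integer(strsplit(k, ",")[[1]])
      st <- if (cs$goal$type == "gathering") unique(cfg)
            else tabulate(cfg, nbins = cs$g$n)
      lab <- format_state(st, cs$goal, cs$g)
      expect_equal(oracle[[k]], res$t[[lab]], tolerance = 1e-9)
    }
  }
})
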